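# Stage 1: delineate cluster candidates on the brightfield channel, and a
# reference rule-based cluster / non-cluster decision.
#
# The segmenter is a pluggable backend.  The reference backend is a
# classical pipeline (Otsu binarization, morphological open/close, hole
# filling, connected components, area filter); a learned detector can be
# registered under the same contract and everything downstream is
# backend-agnostic.

#' Segmenter configuration
#'
#' @param min_component_area Discard components smaller than this (px,
#'   default 30).
#' @param morph_radius Disk radius for the open-then-close cleanup (default
#'   2; 0 disables morphology).
#' @param invert Cells darker than background (default `TRUE`): foreground
#'   is the sub-threshold side of the Otsu split.
#' @param fill_holes Fill enclosed background holes in each component
#'   (default `TRUE`).
#' @return An object of class `segmenter_config`.
#' @export
segmenter_config <- function(min_component_area = 30L, morph_radius = 2L,
                             invert = TRUE, fill_holes = TRUE) {
  min_component_area <- as.integer(min_component_area)
  if (is.na(min_component_area) || min_component_area < 1L)
    stop("min_component_area must be >= 1", call. = FALSE)
  if (morph_radius < 0L) stop("morph_radius must be >= 0", call. = FALSE)
  structure(list(min_component_area = min_component_area,
                 morph_radius = as.integer(morph_radius),
                 invert = isTRUE(invert), fill_holes = isTRUE(fill_holes)),
            class = "segmenter_config")
}

new_segmentation_result <- function(mask, instances, scores) {
  stopifnot(length(instances) == length(scores))
  structure(list(mask = mask, instances = instances, scores = scores),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: %d instance(s), union area %d px>\n",
              length(x$instances), mask_area(x$mask)))
  invisible(x)
}

#' Segment cluster candidates on a brightfield image
#'
#' Reference classical backend: global Otsu threshold (inverted so dark
#' cells are foreground), one morphological opening then closing, hole
#' filling, 4-connected component labelling, and an area filter.  Instances
#' are sorted by area descending (ties: lower top-left row-major raster
#' index first); reference confidence scores are `area / largest area`.
#' Deterministic; a blank image yields an empty result.
#'
#' @param brightfield A grayscale `channel_image`.
#' @param cfg A [segmenter_config()].
#' @return A `segmentation_result`: `mask` (union of accepted components),
#'   `instances` (list of per-component `binary_mask`s), `scores`.
#' @export
segment_clusters <- function(brightfield, cfg = segmenter_config()) {
  stopifnot(inherits(brightfield, "channel_image"))
  if (im_is_rgb(brightfield))
    stop("segment_clusters expects a grayscale brightfield image",
         call. = FALSE)
  h <- im_height(brightfield); w <- im_width(brightfield)
  empty <- function() new_segmentation_result(
    binary_mask(matrix(FALSE, h, w)), list(), numeric(0))
  thr <- otsu_threshold(brightfield$pixels)
  if (is.na(thr)) return(empty())
  fg <- if (cfg$invert) brightfield$pixels <= thr else brightfield$pixels > thr
  m <- binary_mask(matrix(fg, h, w))
  if (cfg$morph_radius > 0L)
    m <- mask_close(mask_open(m, cfg$morph_radius), cfg$morph_radius)
  if (cfg$fill_holes) m <- mask_fill_holes(m)
  lab <- label_components(m, connectivity = 4L)
  n_comp <- max(lab)
  if (n_comp == 0L) return(empty())
  areas <- tabulate(lab[lab > 0L], nbins = n_comp)
  keep <- which(areas >= cfg$min_component_area)
  if (!length(keep)) return(empty())
  # raster index (0-based, row-major) of each component's first pixel
  first_raster <- vapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    min((idx[, 1] - 1L) * w + (idx[, 2] - 1L))
  }, numeric(1))
  ord <- order(-areas[keep], first_raster)
  keep <- keep[ord]
  instances <- lapply(keep, function(k) binary_mask(lab == k))
  union <- binary_mask(matrix(lab %in% keep & lab > 0L, h, w))
  scores <- areas[keep] / max(areas[keep])
  new_segmentation_result(union, instances, scores)
}

#' Cluster-decision rules
#'
#' A segmented component is called a cluster when its footprint is
#' consistent with at least two touching cells: area at least
#' `min_cluster_area` and either low solidity (a multi-lobed outline) or at
#' least `min_minima` interior intensity minima (one per cell, since cells
#' are darkest at their centres).
#'
#' @param min_cluster_area Minimum component area in px (default 150).
#' @param max_solidity Solidity (area / convex-hull area) at or below which
#'   the component counts as multi-lobed (default 0.92).
#' @param min_minima Minimum count of distinct interior intensity minima
#'   (default 2).
#' @param smooth_radius Mean-filter radius applied before minima detection
#'   (default 1).
#' @param minima_depth Required depth of a minimum below the level at which
#'   its basin merges with another, in intensity units (default 2).
#' @return An object of class `cluster_rules`.
#' @export
cluster_rules <- function(min_cluster_area = 150L, max_solidity = 0.92,
                          min_minima = 2L, smooth_radius = 1L,
                          minima_depth = 2) {
  structure(list(min_cluster_area = as.integer(min_cluster_area),
                 max_solidity = max_solidity,
                 min_minima = as.integer(min_minima),
                 smooth_radius = as.integer(smooth_radius),
                 minima_depth = minima_depth),
            class = "cluster_rules")
}

# Solidity = component area / area of its rasterized convex hull (pixels
# whose centers fall inside the hull of the component's pixel centers).
component_solidity <- function(grid) {
  idx <- which(grid, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(1)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  hull <- grDevices::chull(pts)
  hv <- pts[hull, , drop = FALSE]
  if (nrow(hv) < 3L) return(1)
  h <- nrow(grid); w <- ncol(grid)
  lab <- polygon_label(0L, cbind((hv[, 1] - 0.5) / w, (hv[, 2] - 0.5) / h))
  hull_mask <- polygon_to_mask(lab, h, w)
  hull_area <- max(mask_area(hull_mask), nrow(idx))
  nrow(idx) / hull_area
}

# Count distinct interior intensity minima of the smoothed brightfield
# within a component, by threshold decomposition: for each intensity level
# t, count the connected basins {smoothed <= t} inside the component that
# are at least 9 px and dip at least `minima_depth` below t; report the
# maximum count over levels.  Cells are darkest at their centres, so a
# k-cell cluster attains k basins at a level just under the saddle between
# cells, while a single cell (convex intensity bowl) never exceeds 1.
count_intensity_minima <- function(brightfield_px, grid, rules) {
  sm <- mean_filter(brightfield_px, rules$smooth_radius)
  vals <- sm[grid]
  lo <- min(vals); hi <- max(vals)
  if (hi - lo < rules$minima_depth) return(1L)
  best <- 0L
  for (t in seq(lo + rules$minima_depth, hi, by = 2)) {
    sub <- grid & sm <= t
    if (!any(sub)) next
    lab <- label_components(binary_mask(sub), connectivity = 8L)
    n_comp <- max(lab)
    if (n_comp <= best) next
    n <- 0L
    for (k in seq_len(n_comp)) {
      sel <- lab == k
      if (sum(sel) >= 9L && min(sm[sel]) <= t - rules$minima_depth)
        n <- n + 1L
    }
    best <- max(best, n)
  }
  best
}

# Diamond-metric distance-to-background transform by iterative radius-1
# erosion: dist = erosion round at which a pixel disappears.
distance_transform <- function(grid) {
  dist <- matrix(0L, nrow(grid), ncol(grid))
  cur <- binary_mask(grid)
  k <- 0L
  while (mask_area(cur) > 0L) {
    k <- k + 1L
    dist[cur$grid] <- k
    cur <- mask_erode(cur, 1L)
  }
  dist
}

# Count cell-core basins of the component's distance transform: the maximum
# over levels k of the number of connected {dist >= k} regions that are at
# least 9 px and peak at least 2 above k.  Two touching convex cells yield
# two distance peaks separated by a shallower neck; a single convex cell
# yields one.
count_distance_basins <- function(grid) {
  dist <- distance_transform(grid)
  hi <- max(dist)
  if (hi < 3L) return(1L)
  best <- 1L
  for (k in seq_len(hi - 2L)) {
    sub <- dist >= k
    lab <- label_components(binary_mask(sub), connectivity = 8L)
    n_comp <- max(lab)
    if (n_comp <= best) next
    n <- 0L
    for (j in seq_len(n_comp)) {
      sel <- lab == j
      if (sum(sel) >= 9L && max(dist[sel]) >= k + 2L) n <- n + 1L
    }
    best <- max(best, n)
  }
  best
}

#' Decide cluster vs non-cluster from a segmentation
#'
#' Reference rule-based stand-in for a learned stage-1 classifier: the
#' record is a cluster iff the largest instance satisfies the
#' [cluster_rules()].  An empty segmentation is always `"non_cluster"`.
#'
#' @param seg A `segmentation_result`.
#' @param rules A [cluster_rules()].
#' @param brightfield Optional grayscale `channel_image`; when supplied the
#'   intensity-minima criterion is available, otherwise only solidity is
#'   used.
#' @return `"cluster"` or `"non_cluster"`.
#' @export
classify_cluster <- function(seg, rules = cluster_rules(), brightfield = NULL) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (!length(seg$instances)) return("non_cluster")
  grid <- seg$instances[[1]]$grid
  area <- sum(grid)
  if (area < rules$min_cluster_area) return("non_cluster")
  if (component_solidity(grid) <= rules$max_solidity) return("cluster")
  n_min <- count_distance_basins(grid)
  if (!is.null(brightfield))
    n_min <- max(n_min,
                 count_intensity_minima(brightfield$pixels, grid, rules))
  if (n_min >= rules$min_minima) return("cluster")
  "non_cluster"
}

# --- pluggable backend registry ---------------------------------------------

.backends <- new.env(parent = emptyenv())

#' Segmentation backend registry
#'
#' External detector adapters plug in by name; each backend is a
#' `function(brightfield, cfg)` returning a `segmentation_result` whose
#' union invariant (mask = union of instances) is verified on every call.
#' The classical reference backend is pre-registered as `"reference"`.
#'
#' @param name Backend name.
#' @param fn Backend function.
#' @return `get_backend()` returns the wrapped backend function;
#'   `list_backends()` the registered names.
#' @export
register_backend <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .backends)
  invisible(name)
}

#' @rdname register_backend
#' @export
get_backend <- function(name = "reference") {
  if (!exists(name, envir = .backends))
    stop(sprintf("unknown segmentation backend '%s'", name), call. = FALSE)
  fn <- get(name, envir = .backends)
  function(brightfield, cfg) {
    res <- fn(brightfield, cfg)
    if (!inherits(res, "segmentation_result"))
      stop("backend contract violation: not a segmentation_result",
           call. = FALSE)
    if (length(res$instances)) {
      u <- Reduce(`|`, lapply(res$instances, function(m) m$grid))
      if (!identical(u, res$mask$grid))
        stop("backend contract violation: mask != union of instances",
             call. = FALSE)
    } else if (mask_area(res$mask) != 0L) {
      stop("backend contract violation: non-empty mask with no instances",
           call. = FALSE)
    }
    res
  }
}

#' @rdname register_backend
#' @export
list_backends <- function() ls(.backends)
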