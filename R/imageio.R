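#' @useDynLib cccpheno, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm sd quantile
#' @importFrom utils read.csv write.csv head
NULL

# ---------------------------------------------------------------------------
# Core data model: channel images, binary masks, polygon labels, records.
#
# Coordinate convention (used throughout the package): row-major pixel grid,
# origin at the top-left pixel, 0-based pixel indices.  Normalized polygon
# coordinates are x = column / width, y = row / height, measured on the
# pixel-corner lattice so that the full frame spans exactly [0, 1] x [0, 1].
# ---------------------------------------------------------------------------

#' Construct a channel image
#'
#' A channel image is an 8-bit intensity grid: a `height x width` integer
#' matrix (grayscale) or a `height x width x 3` array (RGB), every value in
#' `[0, 255]`.
#'
#' @param pixels Numeric matrix (grayscale) or 3-plane array (RGB).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels) {
  if (is.matrix(pixels)) {
    dims <- dim(pixels)
  } else if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    dims <- dim(pixels)
  } else {
    stop("pixels must be a matrix or an h x w x 3 array", call. = FALSE)
  }
  if (dims[1] < 1L || dims[2] < 1L)
    stop("image dimensions must be at least 1 x 1", call. = FALSE)
  px <- as.vector(pixels)
  if (anyNA(px) || any(px < 0) || any(px > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels), class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image %d x %d, %s>\n", im_height(x), im_width(x),
              if (im_is_rgb(x)) "RGB" else "grayscale"))
  invisible(x)
}

#' Image dimensions and colour mode
#' @param img A `channel_image`.
#' @return Height/width in pixels, or a logical for [im_is_rgb()].
#' @export
im_height <- function(img) dim(img$pixels)[1]

#' @rdname im_height
#' @export
im_width <- function(img) dim(img$pixels)[2]

#' @rdname im_height
#' @export
im_is_rgb <- function(img) length(dim(img$pixels)) == 3L

#' Promote a grayscale image to RGB by plane replication
#' @param img A `channel_image`.
#' @return An RGB `channel_image` (returned unchanged if already RGB).
#' @export
im_to_rgb <- function(img) {
  if (im_is_rgb(img)) return(img)
  channel_image(array(img$pixels, dim = c(dim(img$pixels), 3L)))
}

#' Construct a binary mask
#'
#' Pixel-aligned boolean region (a cluster contour fill or a stain region).
#'
#' @param grid Logical matrix.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid) {
  if (!is.matrix(grid)) stop("grid must be a matrix", call. = FALSE)
  if (!is.logical(grid)) {
    g <- grid != 0
    dim(g) <- dim(grid)
    grid <- g
  }
  if (anyNA(grid)) stop("mask may not contain NA", call. = FALSE)
  structure(list(grid = grid), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, area %d px>\n",
              nrow(x$grid), ncol(x$grid), mask_area(x)))
  invisible(x)
}

#' Mask area (count of true pixels)
#' @param mask A `binary_mask`.
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) sum(mask$grid)

#' Closed label vocabularies
#'
#' `ccc_classes()` is the stage-1 vocabulary (cluster vs non-cluster);
#' `ccc_phenotypes()` the stage-2 vocabulary (RBC / platelet / WBC /
#' WBC+platelet cluster, or a record excluded because its only stain
#' evidence lies wholly outside the cluster contour).
#' @return Character vector of allowed labels.
#' @export
ccc_classes <- function() c("cluster", "non_cluster")

#' @rdname ccc_classes
#' @export
ccc_phenotypes <- function() {
  c("rbc_cluster", "platelet_cluster", "wbc_cluster",
    "wbc_platelet_cluster", "excluded_artifact")
}

match_enum <- function(value, allowed, what) {
  if (is.null(value)) return(NULL)
  if (!is.character(value) || length(value) != 1L || !value %in% allowed)
    stop(sprintf("%s must be one of: %s", what, paste(allowed, collapse = ", ")),
         call. = FALSE)
  value
}

#' Construct a multi-channel record
#'
#' One co-registered image triplet: a grayscale brightfield channel and two
#' RGB fluorescence channels (CD61, stained regions appear green; CD45,
#' stained regions appear yellow), with optional ground truth.
#'
#' @param record_id Character identifier.
#' @param brightfield Grayscale `channel_image`.
#' @param cd61,cd45 RGB `channel_image`s (grayscale inputs are promoted to
#'   RGB by plane replication).
#' @param truth_mask Optional `binary_mask` of the true cluster footprint.
#' @param truth_class Optional element of [ccc_classes()].
#' @param truth_phenotype Optional element of [ccc_phenotypes()].
#' @return An object of class `ccc_record`.
#' @export
ccc_record <- function(record_id, brightfield, cd61, cd45,
                       truth_mask = NULL, truth_class = NULL,
                       truth_phenotype = NULL) {
  stopifnot(inherits(brightfield, "channel_image"),
            inherits(cd61, "channel_image"),
            inherits(cd45, "channel_image"))
  cd61 <- im_to_rgb(cd61)
  cd45 <- im_to_rgb(cd45)
  h <- im_height(brightfield); w <- im_width(brightfield)
  if (im_height(cd61) != h || im_width(cd61) != w)
    stop(sprintf("registration error: cd61 is %d x %d but brightfield is %d x %d",
                 im_height(cd61), im_width(cd61), h, w), call. = FALSE)
  if (im_height(cd45) != h || im_width(cd45) != w)
    stop(sprintf("registration error: cd45 is %d x %d but brightfield is %d x %d",
                 im_height(cd45), im_width(cd45), h, w), call. = FALSE)
  if (!is.null(truth_mask)) {
    stopifnot(inherits(truth_mask, "binary_mask"))
    if (!all(dim(truth_mask$grid) == c(h, w)))
      stop("registration error: truth_mask shape differs from channels",
           call. = FALSE)
  }
  structure(list(
    record_id = as.character(record_id),
    brightfield = brightfield, cd61 = cd61, cd45 = cd45,
    truth_mask = truth_mask,
    truth_class = match_enum(truth_class, ccc_classes(), "truth_class"),
    truth_phenotype = match_enum(truth_phenotype, ccc_phenotypes(),
                                 "truth_phenotype")
  ), class = "ccc_record")
}

#' @export
print.ccc_record <- function(x, ...) {
  cat(sprintf("<ccc_record '%s' %d x %d%s%s>\n", x$record_id,
              im_height(x$brightfield), im_width(x$brightfield),
              if (!is.null(x$truth_class)) paste0(", class=", x$truth_class) else "",
              if (!is.null(x$truth_phenotype)) paste0(", phenotype=", x$truth_phenotype) else ""))
  invisible(x)
}

#' Construct a polygon label
#'
#' A detection-style instance label: a class id plus an ordered ring of
#' vertices normalized to `[0, 1]` (x = column / width, y = row / height).
#'
#' @param class_id Non-negative integer class id.
#' @param vertices Two-column numeric matrix of (x, y) pairs, at least 3 rows.
#' @return An object of class `polygon_label`.
#' @export
polygon_label <- function(class_id, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("format error: a polygon needs at least 3 (x, y) vertices",
         call. = FALSE)
  if (anyNA(vertices) || any(vertices < 0) || any(vertices > 1))
    stop("vertex coordinates must lie in [0, 1]", call. = FALSE)
  class_id <- as.integer(class_id)
  if (is.na(class_id) || class_id < 0L)
    stop("class_id must be a non-negative integer", call. = FALSE)
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(class_id = class_id, vertices = vertices),
            class = "polygon_label")
}

# ---------------------------------------------------------------------------
# File I/O: 8-bit PNG images, {0,255} mask PNGs, polygon label text files,
# dataset manifests.
# ---------------------------------------------------------------------------

#' Read / write an 8-bit image
#'
#' PNG only: the image source for this pipeline is an imaging flow
#' cytometer export, assumed 8-bit.  Grayscale files load as matrices, RGB
#' (alpha dropped) as 3-plane arrays.
#'
#' @param path File path ending in `.png`.
#' @param img A `channel_image` (for writing).
#' @return `read_image()` returns a `channel_image`; `write_image()` its
#'   path, invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input error: file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    stop("input error: TIFF is not supported in this build; convert to PNG",
         call. = FALSE)
  if (ext != "png")
    stop(sprintf("input error: unsupported image extension '.%s'", ext),
         call. = FALSE)
  arr <- png::readPNG(path)
  px <- round(arr * 255)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE] else px <- px[, , 1L]
    if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1L]
  }
  channel_image(px)
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

#' Read / write a binary mask as a single-plane PNG with values {0, 255}
#'
#' The round trip through disk is bit-exact.
#'
#' @param path File path.
#' @param mask A `binary_mask` (for writing).
#' @return `read_mask()` returns a `binary_mask`.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  px <- img$pixels
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  binary_mask(px >= 128L)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(ifelse(mask$grid, 1, 0), target = path)
  invisible(path)
}

#' Read / write polygon label text files
#'
#' One line per instance: `class_id x1 y1 x2 y2 ...`, space-separated,
#' 6-decimal fixed precision, coordinates normalized to `[0, 1]`.
#'
#' @param labels A `polygon_label` or list of them (for writing).
#' @param path File path.
#' @return `read_polygon_labels()` returns a list of `polygon_label`s.
#' @export
write_polygon_labels <- function(labels, path) {
  if (inherits(labels, "polygon_label")) labels <- list(labels)
  lines <- vapply(labels, function(lab) {
    paste(c(lab$class_id, sprintf("%.6f", t(lab$vertices))), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_polygon_labels
#' @export
read_polygon_labels <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input error: file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line) {
    vals <- as.numeric(strsplit(trimws(line), "\\s+")[[1]])
    if (length(vals) < 7L || length(vals) %% 2L == 0L)
      stop("format error: malformed polygon label line", call. = FALSE)
    polygon_label(vals[1], matrix(vals[-1], ncol = 2, byrow = TRUE))
  })
}

#' Read a multi-channel record from image files
#'
#' @param brightfield_path,cd61_path,cd45_path Paths to co-registered 8-bit
#'   PNG files.  Grayscale fluorescence inputs are promoted to RGB by plane
#'   replication; an RGB brightfield is collapsed to its first plane.
#' @param record_id Identifier; defaults to the brightfield file stem.
#' @return A `ccc_record`.
#' @export
read_record <- function(brightfield_path, cd61_path, cd45_path,
                        record_id = NULL) {
  bf <- read_image(brightfield_path)
  if (im_is_rgb(bf)) bf <- channel_image(bf$pixels[, , 1L])
  cd61 <- read_image(cd61_path)
  cd45 <- read_image(cd45_path)
  if (im_height(cd61) != im_height(bf) || im_width(cd61) != im_width(bf))
    stop(sprintf("registration error: cd61 (%s) is %d x %d but brightfield is %d x %d",
                 basename(cd61_path), im_height(cd61), im_width(cd61),
                 im_height(bf), im_width(bf)), call. = FALSE)
  if (im_height(cd45) != im_height(bf) || im_width(cd45) != im_width(bf))
    stop(sprintf("registration error: cd45 (%s) is %d x %d but brightfield is %d x %d",
                 basename(cd45_path), im_height(cd45), im_width(cd45),
                 im_height(bf), im_width(bf)), call. = FALSE)
  if (is.null(record_id))
    record_id <- tools::file_path_sans_ext(basename(brightfield_path))
  ccc_record(record_id, bf, cd61, cd45)
}

#' Read / write a dataset manifest
#'
#' CSV with columns `record_id, brightfield, cd61, cd45, class, phenotype`
#' (plus `mask` when ground-truth masks are on disk).  Paths are relative to
#' the manifest's directory.
#'
#' @param path Manifest path.
#' @param manifest Data frame (for writing).
#' @return `read_manifest()` returns a data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input error: manifest not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "brightfield", "cd61", "cd45")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("input error: manifest lacks columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Mask <-> polygon conversion
# ---------------------------------------------------------------------------

#' Convert the largest connected region of a mask to a polygon label
#'
#' Traces the outer contour of the largest 4-connected true region (holes
#' filled) on the pixel-corner lattice, so the polygon is the exact outline
#' of the union of pixel squares.  Vertices are normalized by width/height
#' and oriented counter-clockwise (positive shoelace area); collinear
#' intermediate vertices are dropped.
#'
#' @param mask A non-empty `binary_mask`.
#' @param class_id Class id for the label (default 0).
#' @return A `polygon_label`.
#' @export
mask_to_polygon_label <- function(mask, class_id = 0L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask_area(mask) == 0L)
    stop("empty-region error: mask has no true pixels", call. = FALSE)
  g <- mask$grid
  lab <- label_components(binary_mask(g), connectivity = 4L)
  areas <- tabulate(lab[lab > 0L])
  keep <- which.max(areas)
  comp <- binary_mask(lab == keep)
  comp <- mask_fill_holes(comp)
  ring <- trace_outer_contour(comp$grid)
  h <- nrow(g); w <- ncol(g)
  verts <- cbind(x = ring[, "x"] / w, y = ring[, "y"] / h)
  polygon_label(class_id, verts)
}

# Trace the outer boundary of a single hole-free 4-connected component as a
# closed ring of corner-lattice points (x = column, y = row, 0-based).
# Directed boundary edges are emitted per exposed pixel side; at pinch
# corners (two in- and two out-edges) the walk takes the out-edge with the
# largest z-cross against the incoming direction, which keeps the loop on
# the square it arrived on.  Returned open (last vertex != first), CCW by
# shoelace sign, collinear runs merged.
trace_outer_contour <- function(grid) {
  h <- nrow(grid); w <- ncol(grid)
  idx <- which(grid, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  pad <- function(dr, dc) {
    rr <- r + dr; cc <- c + dc
    inb <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    nb <- logical(length(r))
    nb[inb] <- grid[cbind(rr[inb], cc[inb])]
    nb
  }
  up <- !pad(-1, 0); dn <- !pad(1, 0); lf <- !pad(0, -1); rt <- !pad(0, 1)
  # corner coords: pixel (r, c) spans x in [c-1, c], y in [r-1, r]
  e_from <- rbind(
    cbind(c[up] - 1, r[up] - 1),   # top:    (c-1, r-1) -> (c,   r-1)
    cbind(c[rt],     r[rt] - 1),   # right:  (c,   r-1) -> (c,   r)
    cbind(c[dn],     r[dn]),       # bottom: (c,   r)   -> (c-1, r)
    cbind(c[lf] - 1, r[lf]))       # left:   (c-1, r)   -> (c-1, r-1)
  e_to <- rbind(
    cbind(c[up],     r[up] - 1),
    cbind(c[rt],     r[rt]),
    cbind(c[dn] - 1, r[dn]),
    cbind(c[lf] - 1, r[lf] - 1))
  n <- nrow(e_from)
  key <- function(p) p[, 1] * (h + 2L) + p[, 2]
  from_key <- key(e_from)
  order_by_start <- split(seq_len(n), from_key)
  used <- logical(n)
  best <- NULL
  for (start in seq_len(n)) {
    if (used[start]) next
    loop <- integer(0)
    cur <- start
    repeat {
      used[cur] <- TRUE
      loop <- c(loop, cur)
      nxt_cands <- order_by_start[[as.character(key(e_to[cur, , drop = FALSE]))]]
      nxt_cands <- nxt_cands[!used[nxt_cands]]
      if (!length(nxt_cands)) break
      if (length(nxt_cands) > 1L) {
        din <- e_to[cur, ] - e_from[cur, ]
        cross <- vapply(nxt_cands, function(j) {
          dout <- e_to[j, ] - e_from[j, ]
          din[1] * dout[2] - din[2] * dout[1]
        }, numeric(1))
        nxt_cands <- nxt_cands[which.max(cross)]
      }
      cur <- nxt_cands[1]
    }
    pts <- e_from[loop, , drop = FALSE]
    area <- abs(shoelace(pts))
    if (is.null(best) || area > best$area) best <- list(pts = pts, area = area)
  }
  pts <- best$pts
  # drop collinear intermediate vertices
  m <- nrow(pts)
  prev <- pts[c(m, seq_len(m - 1)), , drop = FALSE]
  nxt <- pts[c(seq(2, m), 1), , drop = FALSE]
  d1 <- pts - prev; d2 <- nxt - pts
  keep <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1] != 0
  pts <- pts[keep, , drop = FALSE]
  if (shoelace(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  colnames(pts) <- c("x", "y")
  pts
}

shoelace <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Rasterize a polygon label to a binary mask
#'
#' A pixel is true iff its center lies inside the polygon (even-odd rule) or
#' on its boundary (within 1e-9 of an edge).
#'
#' @param label A `polygon_label`.
#' @param height,width Output dimensions in pixels.
#' @return A `binary_mask`.
#' @export
polygon_to_mask <- function(label, height, width) {
  stopifnot(inherits(label, "polygon_label"))
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 1L || width < 1L)
    stop("parameter error: dimensions must be positive", call. = FALSE)
  v <- label$vertices
  if (abs(shoelace(v)) < 1e-12)  # degenerate (collinear) polygon
    return(binary_mask(matrix(FALSE, height, width)))
  px <- rep((seq_len(width) - 0.5) / width, each = height)
  py <- rep((seq_len(height) - 0.5) / height, times = width)
  inside <- logical(height * width)
  on_edge <- logical(height * width)
  nv <- nrow(v)
  eps <- 1e-9
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    # even-odd crossing test (half-open in y)
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xi <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- px[crosses] < xi
      inside[crosses][hit] <- !inside[crosses][hit]
    }
    # distance from pixel centers to the segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 < eps) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d2 <- (px - x1 - t * dx)^2 + (py - y1 - t * dy)^2
    }
    on_edge <- on_edge | d2 <= eps
  }
  binary_mask(matrix(inside | on_edge, nrow = height, ncol = width))
}
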