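# Synthetic multi-channel records with exact ground truth.
#
# The generator emulates the scene taxonomy of real imaging-flow-cytometry
# events: blank fields, single cells, multiple separated cells, and
# touching/overlapping cell clusters, with fluorescence staining that may
# cover the cluster, partially cover it, or lie entirely outside it
# (a staining artifact from cell debris).  Cells are dark shaded ellipses on
# a bright noisy background (brightfield appearance); fluorescence channels
# are near-black except where stain is painted.

#' Scene specification
#'
#' @param kind One of `"blank"`, `"single_cell"`, `"separated_cells"`,
#'   `"cluster"`.
#' @param n_cells Number of cells (forced to 0 for blank; must be >= 2 for
#'   clusters).  Defaults: 1 for single, 3 otherwise.
#' @param cell_radius Interval of cell radii in pixels (default c(8, 14)).
#' @param overlap_frac For clusters, how far neighbouring cells
#'   interpenetrate: consecutive centres sit at distance
#'   `(1 - overlap_frac) * (r_i + r_j)`, so any value in \[0, 1) gives a
#'   touching/overlapping (connected) cluster.  Default 0.25.
#' @param background_level Mean background intensity (default 200).
#' @param noise_sigma Gaussian background noise sd (default 5; 0 = noise-free).
#' @param image_size Square frame side in pixels (default 96).
#' @param seed Integer seed; the record is deterministic given the spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(kind = c("blank", "single_cell", "separated_cells", "cluster"),
                       n_cells = NULL, cell_radius = c(8, 14),
                       overlap_frac = 0.25, background_level = 200,
                       noise_sigma = 5, image_size = 96L, seed = 0L) {
  kind <- match.arg(kind)
  if (is.null(n_cells))
    n_cells <- switch(kind, blank = 0L, single_cell = 1L,
                      separated_cells = 3L, cluster = 3L)
  n_cells <- as.integer(n_cells)
  if (kind == "blank" && n_cells != 0L)
    stop("blank scenes have n_cells = 0", call. = FALSE)
  if (kind == "single_cell" && n_cells != 1L)
    stop("single_cell scenes have n_cells = 1", call. = FALSE)
  if (kind == "cluster" && n_cells < 2L)
    stop("cluster scenes need n_cells >= 2", call. = FALSE)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)", call. = FALSE)
  structure(list(kind = kind, n_cells = n_cells, cell_radius = cell_radius,
                 overlap_frac = overlap_frac,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Stain specification
#'
#' @param target_phenotype Element of [ccc_phenotypes()]; determines which
#'   channels receive in-cluster stain (platelet -> green/CD61,
#'   wbc -> yellow/CD45, wbc_platelet -> both, rbc and excluded_artifact ->
#'   neither).
#' @param coverage_frac Fraction of the cluster mask painted per implied
#'   channel (default 0.6).
#' @param artifact_area_px Stained pixels placed entirely outside (>= 2 px
#'   from) the cluster mask (default 0); painted on the implied channels,
#'   or on CD61 when no channel is implied.
#' @param intensity HSV value (brightness) of painted stain, 0-255
#'   (default 200).
#' @param saturation HSV saturation of painted stain (default 220).
#' @param seed Integer seed for stain placement.
#' @return An object of class `stain_spec`.
#' @export
stain_spec <- function(target_phenotype, coverage_frac = 0.6,
                       artifact_area_px = 0L, intensity = 200L,
                       saturation = 220L, seed = 0L) {
  target_phenotype <- match_enum(target_phenotype, ccc_phenotypes(),
                                 "target_phenotype")
  if (coverage_frac < 0 || coverage_frac > 1)
    stop("coverage_frac must lie in [0, 1]", call. = FALSE)
  if (artifact_area_px < 0)
    stop("artifact_area_px must be >= 0", call. = FALSE)
  structure(list(target_phenotype = target_phenotype,
                 coverage_frac = coverage_frac,
                 artifact_area_px = as.integer(artifact_area_px),
                 intensity = as.integer(intensity),
                 saturation = as.integer(saturation),
                 seed = as.integer(seed)),
            class = "stain_spec")
}

# Rasterize one shaded elliptical cell.  Returns the footprint (logical) and
# an intensity surface: base intensity at the centre rising by `shade` at
# the rim, which gives every cell an interior intensity minimum.
render_cell <- function(h, w, cy, cx, a, b, theta, base, shade = 30) {
  rr <- rep(seq_len(h), times = w) - cy
  cc <- rep(seq_len(w), each = h) - cx
  u <- (cos(theta) * cc + sin(theta) * rr) / a
  v <- (-sin(theta) * cc + cos(theta) * rr) / b
  rho2 <- u^2 + v^2
  inside <- rho2 <= 1
  val <- matrix(Inf, h, w)
  val[inside] <- base + shade * rho2[inside]
  list(footprint = matrix(inside, h, w), intensity = val)
}

#' Generate a synthetic brightfield scene with ground truth
#'
#' Dark elliptical cells on a bright noisy background.  For clusters, each
#' cell after the first is attached to a previously placed cell at centre
#' distance `(1 - overlap_frac) * (r_i + r_j)`, so the contact graph is
#' connected; for separated scenes all pairwise gaps are >= 3 px.  The
#' fluorescence channels are initialized dark (value < 20).  `truth_mask` is
#' the union of cell footprints; `truth_class` is `"cluster"` iff the kind
#' is cluster.
#'
#' @param spec A [scene_spec()].
#' @return A `ccc_record` with `truth_mask` and `truth_class` set, plus a
#'   `truth_instances` attribute holding per-cell footprints.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  s <- spec$image_size
  with_local_seed(spec$seed, {
    bg <- matrix(spec$background_level, s, s)
    if (spec$noise_sigma > 0)
      bg <- bg + matrix(rnorm(s * s, 0, spec$noise_sigma), s, s)
    cells <- list()
    if (spec$n_cells > 0L) {
      margin <- max(spec$cell_radius) + 2
      place_ok <- function(cy, cx, r) {
        cy - r >= 1 && cy + r <= s && cx - r >= 1 && cx + r <= s
      }
      for (i in seq_len(spec$n_cells)) {
        r <- runif(1, spec$cell_radius[1], spec$cell_radius[2])
        placed <- FALSE
        for (try in 1:200) {
          if (i == 1L || spec$kind != "cluster") {
            cy <- runif(1, margin, s - margin)
            cx <- runif(1, margin, s - margin)
          } else {
            anchor <- cells[[sample.int(length(cells), 1L)]]
            d <- (1 - spec$overlap_frac) * (anchor$r + r)
            ang <- runif(1, 0, 2 * pi)
            cy <- anchor$cy + d * sin(ang)
            cx <- anchor$cx + d * cos(ang)
          }
          if (!place_ok(cy, cx, r)) next
          if (spec$kind == "separated_cells" && length(cells)) {
            # contract is gap >= 3 px; enforce 6 so that rasterization and a
            # radius-2 morphological closing can never bridge neighbours
            gaps <- vapply(cells, function(cl) {
              sqrt((cl$cy - cy)^2 + (cl$cx - cx)^2) - (cl$r + r)
            }, numeric(1))
            if (any(gaps < 6)) next
          }
          placed <- TRUE
          break
        }
        if (!placed)
          stop("generation error: could not place cells within retry budget",
               call. = FALSE)
        ratio <- runif(1, 0.7, 1)
        cells[[i]] <- list(cy = cy, cx = cx, r = r, a = r, b = r * ratio,
                           theta = runif(1, 0, pi),
                           base = runif(1, 40, 120))
      }
    }
    union <- matrix(FALSE, s, s)
    surface <- matrix(Inf, s, s)
    instances <- list()
    for (cl in cells) {
      rc <- render_cell(s, s, cl$cy, cl$cx, cl$a, cl$b, cl$theta, cl$base)
      instances[[length(instances) + 1L]] <- binary_mask(rc$footprint)
      union <- union | rc$footprint
      surface <- pmin(surface, rc$intensity)
    }
    bf <- bg
    bf[union] <- surface[union]
    bf <- pmin(pmax(round(bf), 0), 255)
    dark <- function() {
      m <- matrix(sample.int(11L, s * s, replace = TRUE) - 1L, s, s)
      array(m, c(s, s, 3L))
    }
    rec <- ccc_record(
      record_id = sprintf("synth_%s_%d", spec$kind, spec$seed),
      brightfield = channel_image(bf),
      cd61 = channel_image(dark()),
      cd45 = channel_image(dark()),
      truth_mask = binary_mask(union),
      truth_class = if (spec$kind == "cluster") "cluster" else "non_cluster"
    )
    attr(rec, "truth_instances") <- instances
    attr(rec, "scene_spec") <- spec
    rec
  })
}

# Pick a coherent region of `k` pixels from `allowed`: the k pixels nearest
# (squared Euclidean distance, raster order tie-break) to a seed pixel
# chosen uniformly from `allowed`.
grow_region <- function(allowed, k) {
  idx <- which(allowed, arr.ind = TRUE)
  if (nrow(idx) < k)
    stop("generation error: region smaller than requested area", call. = FALSE)
  seedpix <- idx[sample.int(nrow(idx), 1L), ]
  d2 <- (idx[, 1] - seedpix[1])^2 + (idx[, 2] - seedpix[2])^2
  ord <- order(d2, idx[, 1], idx[, 2])
  sel <- idx[ord[seq_len(k)], , drop = FALSE]
  out <- matrix(FALSE, nrow(allowed), ncol(allowed))
  out[sel] <- TRUE
  out
}

paint_channel <- function(img, region, hue, saturation, intensity) {
  px <- img$pixels
  col <- hsv255_to_rgb(matrix(hue, 1, 1), matrix(saturation, 1, 1),
                       matrix(intensity, 1, 1))
  for (kk in 1:3) {
    plane <- px[, , kk]
    plane[region] <- col[1, 1, kk]
    px[, , kk] <- plane
  }
  channel_image(px)
}

#' Paint fluorescence stain onto a record
#'
#' Paints the requested hue into the CD61 (green, hue 60) and/or CD45
#' (yellow, hue 30) channels: a coherent region covering `coverage_frac` of
#' the truth-mask area per implied channel, plus `artifact_area_px` pixels
#' placed at least 2 px outside the mask.  Painted pixels carry the spec's
#' saturation and value; untouched fluorescence pixels stay dark.
#'
#' @param record A `ccc_record` with a non-empty `truth_mask` (required
#'   whenever in-mask coverage is requested).
#' @param stain A [stain_spec()].
#' @return The record with painted fluorescence channels and
#'   `truth_phenotype` set to the stain target.
#' @export
apply_staining <- function(record, stain) {
  stopifnot(inherits(record, "ccc_record"), inherits(stain, "stain_spec"))
  channels <- switch(stain$target_phenotype,
                     platelet_cluster = "cd61",
                     wbc_cluster = "cd45",
                     wbc_platelet_cluster = c("cd61", "cd45"),
                     rbc_cluster = character(0),
                     excluded_artifact = character(0))
  artifact_channels <- if (length(channels)) channels else "cd61"
  hue_of <- c(cd61 = 60L, cd45 = 30L)
  need_mask <- (length(channels) && stain$coverage_frac > 0) ||
    stain$artifact_area_px > 0L
  if (need_mask && (is.null(record$truth_mask) || mask_area(record$truth_mask) == 0L))
    stop("input error: staining requires a record with a non-empty truth_mask",
         call. = FALSE)
  with_local_seed(stain$seed, {
    if (length(channels) && stain$coverage_frac > 0) {
      area <- mask_area(record$truth_mask)
      k <- round(stain$coverage_frac * area)
      for (ch in channels) {
        if (k > 0L) {
          region <- grow_region(record$truth_mask$grid, k)
          record[[ch]] <- paint_channel(record[[ch]], region, hue_of[[ch]],
                                        stain$saturation, stain$intensity)
        }
      }
    }
    if (stain$artifact_area_px > 0L) {
      outside <- !mask_dilate(record$truth_mask, 2L)$grid
      # keep a 1-px border margin so artifact blobs stay inside the frame
      outside[c(1, nrow(outside)), ] <- FALSE
      outside[, c(1, ncol(outside))] <- FALSE
      for (ch in artifact_channels) {
        region <- grow_region(outside, stain$artifact_area_px)
        record[[ch]] <- paint_channel(record[[ch]], region, hue_of[[ch]],
                                      stain$saturation, stain$intensity)
      }
    }
  })
  record$truth_phenotype <- stain$target_phenotype
  record
}

#' Generate a synthetic dataset on disk
#'
#' Writes per-record PNGs (brightfield, CD61, CD45, truth mask) and a
#' manifest CSV with ground truth.  Cluster records are stained for a
#' phenotype drawn from `phenotype_mix`; with probability `artifact_rate` a
#' cluster record instead receives artifact-only staining (no in-mask
#' coverage) and is labelled `excluded_artifact`.  Deterministic given
#' `seed`: two runs produce byte-identical manifests.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_records Number of records, >= 1.
#' @param class_mix Named probabilities for `cluster` / `non_cluster`
#'   (default 50/50); must sum to 1.
#' @param phenotype_mix Named probabilities over the four biological
#'   phenotypes (default uniform); must sum to 1.
#' @param artifact_rate Probability that a cluster record is an
#'   artifact-only record (default 0).
#' @param coverage_range Coverage fraction interval for true stains
#'   (default c(0.4, 0.9)).
#' @param intensity Stain brightness (default 200).
#' @param noise_sigma,image_size Passed to [scene_spec()].
#' @param seed Integer seed.
#' @return The manifest data frame, invisibly; side effect: files under
#'   `out_dir`.
#' @export
generate_dataset <- function(out_dir, n_records,
                             class_mix = c(cluster = 0.5, non_cluster = 0.5),
                             phenotype_mix = c(rbc_cluster = 0.25,
                                               platelet_cluster = 0.25,
                                               wbc_cluster = 0.25,
                                               wbc_platelet_cluster = 0.25),
                             artifact_rate = 0,
                             coverage_range = c(0.4, 0.9),
                             intensity = 200L,
                             noise_sigma = 5, image_size = 96L, seed = 0L) {
  if (n_records < 1L) stop("n_records must be >= 1", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-8 || abs(sum(phenotype_mix) - 1) > 1e-8)
    stop("class_mix and phenotype_mix must each sum to 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("I/O error: cannot create output directory %s", out_dir),
         call. = FALSE)
  # keep scenes feasible at small frame sizes
  radius <- pmax(4, c(8, 14) * image_size / 96)
  rows <- with_local_seed(seed, {
    lapply(seq_len(n_records), function(i) {
      rec_seed <- sample.int(2^30, 1L)
      cls <- sample(names(class_mix), 1L, prob = class_mix)
      if (cls == "cluster") {
        spec <- scene_spec("cluster", n_cells = sample(2:4, 1L),
                           cell_radius = radius,
                           noise_sigma = noise_sigma,
                           image_size = image_size, seed = rec_seed)
        rec <- generate_scene(spec)
        if (artifact_rate > 0 && runif(1) < artifact_rate) {
          st <- stain_spec("excluded_artifact", coverage_frac = 0,
                           artifact_area_px = sample(30:80, 1L),
                           intensity = intensity, seed = rec_seed + 1L)
        } else {
          ph <- sample(names(phenotype_mix), 1L, prob = phenotype_mix)
          st <- stain_spec(ph,
                           coverage_frac = runif(1, coverage_range[1],
                                                 coverage_range[2]),
                           intensity = intensity, seed = rec_seed + 1L)
        }
        rec <- apply_staining(rec, st)
      } else {
        kind <- sample(c("blank", "single_cell", "separated_cells"), 1L)
        spec <- scene_spec(kind, cell_radius = radius,
                           noise_sigma = noise_sigma,
                           image_size = image_size, seed = rec_seed)
        rec <- generate_scene(spec)
      }
      id <- sprintf("rec_%04d", i)
      rec$record_id <- id
      paths <- c(brightfield = sprintf("%s_bf.png", id),
                 cd61 = sprintf("%s_cd61.png", id),
                 cd45 = sprintf("%s_cd45.png", id),
                 mask = sprintf("%s_mask.png", id))
      write_image(rec$brightfield, file.path(out_dir, paths["brightfield"]))
      write_image(rec$cd61, file.path(out_dir, paths["cd61"]))
      write_image(rec$cd45, file.path(out_dir, paths["cd45"]))
      write_mask(rec$truth_mask, file.path(out_dir, paths["mask"]))
      data.frame(record_id = id,
                 brightfield = unname(paths["brightfield"]),
                 cd61 = unname(paths["cd61"]),
                 cd45 = unname(paths["cd45"]),
                 mask = unname(paths["mask"]),
                 class = rec$truth_class,
                 phenotype = if (is.null(rec$truth_phenotype)) ""
                             else rec$truth_phenotype,
                 stringsAsFactors = FALSE)
    })
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
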