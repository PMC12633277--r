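# End-to-end pipeline driver, the brightness x overlap threshold-sweep
# harness, and configuration plumbing.

#' Sweep grid
#'
#' The brightness lower bound `v_lo` (also called X or V) and overlap
#' threshold grid explored when selecting the operating point: brightness
#' in \{100, 140, 170\} crossed with overlap thresholds
#' \{5, 8, 10, 13, 15, 18, 20, 30\} percent.
#'
#' @param v_values Brightness thresholds, each in `[0, 255]`.
#' @param overlap_values Overlap thresholds in percent, each in (0, 100].
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(v_values = c(100, 140, 170),
                       overlap_values = c(5, 8, 10, 13, 15, 18, 20, 30)) {
  if (!length(v_values) || !length(overlap_values))
    stop("sweep grid must be non-empty", call. = FALSE)
  if (any(v_values < 0 | v_values > 255))
    stop("v_values must lie in [0, 255]", call. = FALSE)
  if (any(overlap_values <= 0 | overlap_values > 100))
    stop("overlap_values must lie in (0, 100]", call. = FALSE)
  structure(list(v_values = v_values, overlap_values = overlap_values),
            class = "sweep_grid")
}

#' Pipeline configuration
#'
#' Composite of all stage configurations with every pipeline constant as a
#' named default: gray padding 173, input side 224, augmentation x5, HSV
#' channel ranges with brightness bound 140, overlap threshold 15%, and the
#' default sweep grid.
#'
#' @param v_lo Brightness lower bound for both stain channels (default 140).
#' @param overlap_threshold_pct Phenotype presence threshold (default 15).
#' @param segmenter A [segmenter_config()].
#' @param rules A [cluster_rules()].
#' @param augmentation An [augmentation_config()].
#' @param phenotype A [phenotype_config()] (built from
#'   `overlap_threshold_pct` when omitted).
#' @param grid A [sweep_grid()].
#' @param backend Segmentation backend name (default `"reference"`).
#' @param pad_fill_rgb Gray padding colour (default `c(173, 173, 173)`).
#' @param input_side Classifier input side (default 224).
#' @param seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(v_lo = 140, overlap_threshold_pct = 15,
                            segmenter = segmenter_config(),
                            rules = cluster_rules(),
                            augmentation = augmentation_config(),
                            phenotype = NULL,
                            grid = sweep_grid(),
                            backend = "reference",
                            pad_fill_rgb = c(173L, 173L, 173L),
                            input_side = 224L,
                            seed = 0L) {
  if (is.null(phenotype)) phenotype <- phenotype_config(overlap_threshold_pct)
  structure(list(
    v_lo = v_lo,
    segmenter = segmenter, rules = rules, augmentation = augmentation,
    phenotype = phenotype, grid = grid, backend = backend,
    channels = list(green = stain_channel("cd61_green", v_lo = v_lo),
                    yellow = stain_channel("cd45_yellow", v_lo = v_lo)),
    pad_fill_rgb = pad_fill_rgb, input_side = as.integer(input_side),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys (all optional): `hsv.v_lo`, `phenotype.overlap_threshold_pct`,
#' `segmenter.*`, `rules.*`, `augmentation.multiplicity`, `sweep.v_values`,
#' `sweep.overlap_values`, `backend`, `seed`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  get_or <- function(x, name, default) {
    if (!is.null(x[[name]])) x[[name]] else default
  }
  seg <- y$segmenter
  rl <- y$rules
  pipeline_config(
    v_lo = get_or(y$hsv, "v_lo", 140),
    overlap_threshold_pct = get_or(y$phenotype, "overlap_threshold_pct", 15),
    segmenter = segmenter_config(
      min_component_area = get_or(seg, "min_component_area", 30L),
      morph_radius = get_or(seg, "morph_radius", 2L),
      invert = get_or(seg, "invert", TRUE),
      fill_holes = get_or(seg, "fill_holes", TRUE)),
    rules = cluster_rules(
      min_cluster_area = get_or(rl, "min_cluster_area", 150L),
      max_solidity = get_or(rl, "max_solidity", 0.92)),
    augmentation = augmentation_config(
      multiplicity = get_or(y$augmentation, "multiplicity", 5L)),
    grid = sweep_grid(
      v_values = get_or(y$sweep, "v_values", c(100, 140, 170)),
      overlap_values = get_or(y$sweep, "overlap_values",
                              c(5, 8, 10, 13, 15, 18, 20, 30))),
    backend = get_or(y, "backend", "reference"),
    seed = get_or(y, "seed", 0L))
}

#' Run the two-stage pipeline on one record
#'
#' Stage 1 segments the brightfield channel and decides cluster vs
#' non-cluster; non-cluster records stop there (the stage acts as a
#' filter).  Stage 2 extracts both stain masks and classifies the phenotype
#' against the largest segmented instance.  A stage disagreement (called
#' cluster but the segmentation is empty) is flagged, not an error.
#'
#' @param record A `ccc_record`.
#' @param cfg A [pipeline_config()].
#' @return List with `class` (`"cluster"` / `"non_cluster"`), `report` (an
#'   `overlap_report`, or `NULL` when stage 1 stops), `seg` (the
#'   `segmentation_result`), and `flag` (`""` or a disagreement note).
#' @export
run_pipeline <- function(record, cfg = pipeline_config()) {
  stopifnot(inherits(record, "ccc_record"))
  backend <- get_backend(cfg$backend)
  seg <- backend(record$brightfield, cfg$segmenter)
  cls <- classify_cluster(seg, cfg$rules, record$brightfield)
  if (cls == "non_cluster")
    return(list(class = "non_cluster", report = NULL, seg = seg, flag = ""))
  if (!length(seg$instances))
    return(list(class = "cluster", report = NULL, seg = seg,
                flag = "stage_disagreement_empty_mask"))
  report <- classify_phenotype(record, seg$instances[[1]],
                               cfg$phenotype, cfg$channels)
  list(class = "cluster", report = report, seg = seg, flag = "")
}

load_record_from_manifest <- function(row, dir) {
  rec <- read_record(file.path(dir, row$brightfield),
                     file.path(dir, row$cd61),
                     file.path(dir, row$cd45),
                     record_id = row$record_id)
  if (!is.null(row$mask) && nzchar(row$mask))
    rec$truth_mask <- read_mask(file.path(dir, row$mask))
  if (!is.null(row$class) && nzchar(row$class)) rec$truth_class <- row$class
  if (!is.null(row$phenotype) && nzchar(row$phenotype))
    rec$truth_phenotype <- row$phenotype
  rec
}

#' Run the brightness-by-overlap threshold sweep
#'
#' For each grid cell (V, thr) the stage-2 phenotyping is re-run with the
#' brightness bound `v_lo = V` and presence threshold `thr`, and phenotype
#' accuracy against ground truth is recorded.  The brightfield segmentation
#' does not depend on V, so it is computed once per record.
#'
#' @param records List of `ccc_record`s carrying `truth_phenotype`, or a
#'   manifest data frame with a `dir` attribute / `manifest_dir` argument.
#' @param grid A [sweep_grid()].
#' @param cfg A [pipeline_config()].
#' @param manifest_dir Directory for manifest-relative paths.
#' @param artifact_mode `"exclude"` (default): records whose ground truth
#'   is `excluded_artifact` are dropped before computing accuracy, matching
#'   the practice of removing artifact images before phenotype scoring;
#'   `"as_class"`: they count as their own class.
#' @return Long-format data frame: `v, overlap_thr, accuracy, n`.
#' @export
run_sweep <- function(records, grid = sweep_grid(), cfg = pipeline_config(),
                      manifest_dir = NULL,
                      artifact_mode = c("exclude", "as_class")) {
  artifact_mode <- match.arg(artifact_mode)
  if (is.data.frame(records)) {
    dir <- if (!is.null(manifest_dir)) manifest_dir else attr(records, "dir")
    if (is.null(dir)) stop("input error: manifest_dir required", call. = FALSE)
    records <- lapply(seq_len(nrow(records)),
                      function(i) load_record_from_manifest(records[i, ], dir))
  }
  truth <- vapply(records, function(r) {
    if (is.null(r$truth_phenotype)) NA_character_ else r$truth_phenotype
  }, character(1))
  if (all(is.na(truth)))
    stop("input error: sweep needs records with ground-truth phenotypes",
         call. = FALSE)
  keep <- !is.na(truth)
  records <- records[keep]; truth <- truth[keep]
  backend <- get_backend(cfg$backend)
  cluster_masks <- lapply(records, function(r) {
    seg <- backend(r$brightfield, cfg$segmenter)
    if (length(seg$instances)) seg$instances[[1]] else NULL
  })
  usable <- !vapply(cluster_masks, is.null, logical(1))
  rows <- list()
  for (v in grid$v_values) {
    channels <- list(green = stain_channel("cd61_green", v_lo = v),
                     yellow = stain_channel("cd45_yellow", v_lo = v))
    stains <- lapply(which(usable), function(i) {
      list(green = extract_stain_mask(records[[i]]$cd61, channels$green),
           yellow = extract_stain_mask(records[[i]]$cd45, channels$yellow))
    })
    for (thr in grid$overlap_values) {
      pcfg <- phenotype_config(overlap_threshold_pct = thr)
      pred <- rep(NA_character_, length(records))
      pred[usable] <- vapply(seq_along(stains), function(k) {
        i <- which(usable)[k]
        classify_phenotype(records[[i]], cluster_masks[[i]], pcfg,
                           stain_masks = stains[[k]])$label
      }, character(1))
      sel <- if (artifact_mode == "exclude") truth != "excluded_artifact"
             else rep(TRUE, length(truth))
      # NA predictions (unusable segmentation) count as wrong
      acc <- mean(!is.na(pred[sel]) & pred[sel] == truth[sel])
      rows[[length(rows) + 1L]] <-
        data.frame(v = v, overlap_thr = thr, accuracy = acc, n = sum(sel))
    }
  }
  do.call(rbind, rows)
}

#' Build an in-memory dataset that separates true from spurious overlap
#'
#' A demonstration dataset for the threshold-selection logic: every
#' cluster's true stain covers at least 30% of the mask while every
#' spurious (off-target) stain overlaps at most 5%, so sweeping the overlap
#' threshold must find its best accuracy strictly between those bounds.
#' Boundary cases are forced on both sides: some spurious stains sit
#' exactly at 5% (breaking threshold 5, which is inclusive) and some true
#' stains fall just short of 30% after rasterization (breaking threshold
#' 30).  Stain brightness is 150, so the brightness sweep value 170 empties
#' every stain mask.
#'
#' @param n Number of records (balanced over the four phenotypes).
#' @param seed Integer seed.
#' @param noise_sigma Background noise (default 0: noise-free).
#' @return List of `ccc_record`s with ground truth.
#' @export
sweep_demo_dataset <- function(n = 40L, seed = 0L, noise_sigma = 0) {
  phenos <- rep(c("rbc_cluster", "platelet_cluster", "wbc_cluster",
                  "wbc_platelet_cluster"), length.out = n)
  with_local_seed(seed, {
    seeds <- sample.int(2^30, n)
    boundary_low <- rep(c(TRUE, FALSE), length.out = n)   # spurious at exactly 5%
    boundary_high <- rep(c(FALSE, TRUE), length.out = n)  # true stain just under 30%
    lapply(seq_len(n), function(i) {
      rec <- generate_scene(scene_spec("cluster", noise_sigma = noise_sigma,
                                       seed = seeds[i]))
      area <- mask_area(rec$truth_mask)
      target <- phenos[i]
      on_channels <- switch(target,
                            platelet_cluster = "cd61",
                            wbc_cluster = "cd45",
                            wbc_platelet_cluster = c("cd61", "cd45"),
                            rbc_cluster = character(0))
      cover <- if (boundary_high[i]) (ceiling(0.30 * area) - 1) / area
               else runif(1, 0.35, 0.6)
      spur <- if (boundary_low[i]) ceiling(0.05 * area) / area
              else runif(1, 0.01, 0.04)
      hue_of <- c(cd61 = 60L, cd45 = 30L)
      with_local_seed(seeds[i] + 1L, {
        for (ch in c("cd61", "cd45")) {
          frac <- if (ch %in% on_channels) cover else spur
          k <- max(1L, round(frac * area))
          region <- grow_region(rec$truth_mask$grid, k)
          rec[[ch]] <- paint_channel(rec[[ch]], region, hue_of[[ch]],
                                     220L, 150L)
        }
      })
      rec$truth_phenotype <- target
      rec
    })
  })
}
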