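# Stage 2: quantify stain/cluster mask overlap and assign the phenotype.
#
# Decision logic: a channel is "present" when its stain overlaps at least
# `overlap_threshold_pct` of the cluster-mask area (the denominator is
# always the brightfield cluster mask, not the union, not the stain area).
# A channel whose stain lies wholly outside the contour is an "artifact";
# a record whose only stain evidence is artifact is excluded from
# phenotyping.  Mixed evidence (some overlap plus stain beyond the contour)
# is not an artifact: classification proceeds on the overlap.

#' Phenotype configuration
#'
#' @param overlap_threshold_pct Presence threshold in percent, in (0, 100];
#'   default 15, the operating point selected by the overlap sweep.
#'   Comparison is inclusive (overlap >= threshold counts as present).
#' @param artifact_requires_zero_overlap Artifact state requires exactly
#'   zero overlapping pixels (default `TRUE`; kept explicit because it is
#'   the boundary between "excluded" and "sub-threshold but valid").
#' @return An object of class `phenotype_config`.
#' @export
phenotype_config <- function(overlap_threshold_pct = 15,
                             artifact_requires_zero_overlap = TRUE) {
  if (is.na(overlap_threshold_pct) || overlap_threshold_pct <= 0 ||
      overlap_threshold_pct > 100)
    stop("overlap_threshold_pct must lie in (0, 100]", call. = FALSE)
  structure(list(overlap_threshold_pct = overlap_threshold_pct,
                 artifact_requires_zero_overlap =
                   isTRUE(artifact_requires_zero_overlap)),
            class = "phenotype_config")
}

check_same_shape <- function(a, b) {
  if (!all(dim(a$grid) == dim(b$grid)))
    stop("registration error: masks have different shapes", call. = FALSE)
}

#' Overlap percentage between a cluster mask and a stain mask
#'
#' `100 * |cluster AND stain| / |cluster|` where `|.|` counts true pixels.
#' The denominator is the brightfield cluster mask area, so a stain that
#' covers the whole cluster scores 100 even if it extends beyond it.
#'
#' @param cluster_mask Non-empty `binary_mask` from brightfield
#'   segmentation.
#' @param stain_mask `binary_mask` of the same shape from HSV extraction.
#' @return Percentage in `[0, 100]`.
#' @export
overlap_percentage <- function(cluster_mask, stain_mask) {
  stopifnot(inherits(cluster_mask, "binary_mask"),
            inherits(stain_mask, "binary_mask"))
  check_same_shape(cluster_mask, stain_mask)
  denom <- mask_area(cluster_mask)
  if (denom == 0L)
    stop("undefined-denominator error: cluster mask is empty", call. = FALSE)
  100 * sum(cluster_mask$grid & stain_mask$grid) / denom
}

#' Per-channel stain state
#'
#' `"no_stain"` if the stain mask is empty; `"artifact"` if stain exists but
#' none of it overlaps the cluster; `"present"` if the overlap percentage
#' reaches the threshold; `"absent"` otherwise (positive but sub-threshold
#' overlap).
#'
#' @inheritParams overlap_percentage
#' @param cfg A [phenotype_config()].
#' @return One of `"present"`, `"absent"`, `"artifact"`, `"no_stain"`.
#' @export
channel_state <- function(cluster_mask, stain_mask, cfg = phenotype_config()) {
  if (mask_area(stain_mask) == 0L) return("no_stain")
  pct <- overlap_percentage(cluster_mask, stain_mask)
  if (pct == 0) return("artifact")
  if (pct >= cfg$overlap_threshold_pct) return("present")
  "absent"
}

phenotype_from_states <- function(green_state, yellow_state) {
  g <- green_state == "present"; y <- yellow_state == "present"
  if (g && y) return("wbc_platelet_cluster")
  if (g) return("platelet_cluster")
  if (y) return("wbc_cluster")
  states <- c(green_state, yellow_state)
  if (any(states == "artifact") && !any(states == "absent"))
    return("excluded_artifact")
  "rbc_cluster"
}

#' Classify the phenotype of a cluster record
#'
#' Extracts both stain masks (unless supplied), computes each channel's
#' overlap with the cluster mask, and applies the decision table:
#' green+yellow present = WBC+platelet cluster; green only = platelet
#' cluster; yellow only = WBC cluster; only-artifact evidence = excluded;
#' otherwise (no stain, or sub-threshold overlap) = RBC cluster, since an
#' unstained cluster is taken to consist of unstained cells.
#'
#' @param record A `ccc_record`.
#' @param cluster_mask Non-empty `binary_mask` of the cluster footprint.
#' @param cfg A [phenotype_config()].
#' @param channels Named list with `green` and `yellow` [stain_channel()]s
#'   (defaults: both at `v_lo = 140`).
#' @param stain_masks Optional named list with pre-extracted `green` and
#'   `yellow` `binary_mask`s (skips HSV extraction).
#' @return An object of class `overlap_report`: `overlap_pct_green`,
#'   `overlap_pct_yellow`, `green_state`, `yellow_state`, `label`.
#' @export
classify_phenotype <- function(record, cluster_mask, cfg = phenotype_config(),
                               channels = list(green = stain_channel("cd61_green"),
                                               yellow = stain_channel("cd45_yellow")),
                               stain_masks = NULL) {
  stopifnot(inherits(record, "ccc_record"))
  if (is.null(stain_masks)) {
    stain_masks <- list(
      green = extract_stain_mask(record$cd61, channels$green),
      yellow = extract_stain_mask(record$cd45, channels$yellow))
  }
  pct <- function(m) if (mask_area(m) == 0L) 0
                     else overlap_percentage(cluster_mask, m)
  pg <- pct(stain_masks$green)
  py <- pct(stain_masks$yellow)
  gs <- channel_state(cluster_mask, stain_masks$green, cfg)
  ys <- channel_state(cluster_mask, stain_masks$yellow, cfg)
  structure(list(overlap_pct_green = pg, overlap_pct_yellow = py,
                 green_state = gs, yellow_state = ys,
                 label = phenotype_from_states(gs, ys)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report: green %.1f%% (%s), yellow %.1f%% (%s) -> %s>\n",
              x$overlap_pct_green, x$green_state,
              x$overlap_pct_yellow, x$yellow_state, x$label))
  invisible(x)
}
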