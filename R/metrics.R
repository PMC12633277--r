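# Evaluation: classification metrics from a confusion table, mask IoU,
# average precision over IoU thresholds, and cross-validation aggregation.

#' Confusion counts
#'
#' Cell clusters are the positive class: `tp` = clusters called clusters,
#' `fp` = non-clusters called clusters, `tn` = non-clusters called
#' non-clusters, `fn` = clusters called non-clusters.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, tn = 0L, fn = 0L) {
  vals <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(vals) || any(vals < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  vals <- unname(as.integer(vals))
  structure(list(tp = vals[1], fp = vals[2], tn = vals[3], fn = vals[4]),
            class = "confusion_counts")
}

#' Classification accuracy
#'
#' `(tp + tn) / (tp + tn + fp + fn)`.
#'
#' @param c A [confusion_counts()].
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0L)
    stop("undefined-metric error: empty confusion table", call. = FALSE)
  (c$tp + c$tn) / total
}

#' Precision, recall and F1
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2PR / (P + R)`.  A zero denominator yields 0 for that metric, with
#' a warning.
#'
#' @param c A [confusion_counts()].
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  p <- safe_div(c$tp, c$tp + c$fp, "precision")
  r <- safe_div(c$tp, c$tp + c$fn, "recall")
  f1 <- safe_div(2 * p * r, p + r, "F1")
  c(precision = p, recall = r, f1 = f1)
}

#' Intersection over union of two masks
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both masks are empty.
#'
#' @param a,b `binary_mask`s of the same shape.
#' @return Fraction in `[0, 1]`.
#' @export
iou <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_shape(a, b)
  un <- sum(a$grid | b$grid)
  if (un == 0L) return(1)
  sum(a$grid & b$grid) / un
}

#' Construct a detection set
#'
#' @param predictions List of predicted `binary_mask`s.
#' @param confidences Numeric vector of confidences in `[0, 1]`, one per
#'   prediction.
#' @param truths List of ground-truth `binary_mask`s.
#' @return An object of class `detection_set`.
#' @export
detection_set <- function(predictions, confidences, truths) {
  stopifnot(length(predictions) == length(confidences))
  if (length(confidences) && (any(confidences < 0) || any(confidences > 1)))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  structure(list(predictions = predictions, confidences = confidences,
                 truths = truths), class = "detection_set")
}

# Greedy matching in descending confidence (ties: input order); each truth
# matched at most once; a match requires IoU >= iou_thr.  Returns the
# TP/FP flag per ranked prediction.
match_detections <- function(d, iou_thr) {
  ord <- order(-d$confidences, seq_along(d$confidences))
  matched <- logical(length(d$truths))
  tp <- logical(length(ord))
  for (i in seq_along(ord)) {
    pred <- d$predictions[[ord[i]]]
    best_iou <- -1; best_j <- 0L
    for (j in seq_along(d$truths)) {
      if (matched[j]) next
      v <- iou(pred, d$truths[[j]])
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0L && best_iou >= iou_thr) {
      matched[best_j] <- TRUE
      tp[i] <- TRUE
    }
  }
  tp
}

#' Average precision at one IoU threshold
#'
#' Predictions are greedily matched to ground truths in descending
#' confidence; AP is the area under the interpolated precision-recall curve
#' using 101-point interpolation at recalls 0, 0.01, ..., 1.00 (the
#' convention behind "mAP@0.5:0.95").
#'
#' @param d A [detection_set()].
#' @param iou_thr IoU threshold in (0, 1].
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(d, iou_thr = 0.5) {
  stopifnot(inherits(d, "detection_set"))
  if (iou_thr <= 0 || iou_thr > 1)
    stop("iou_thr must lie in (0, 1]", call. = FALSE)
  n_truth <- length(d$truths)
  if (n_truth == 0L)
    stop("undefined-metric error: no ground truths", call. = FALSE)
  if (!length(d$predictions)) return(0)
  tp <- match_detections(d, iou_thr)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- cum_tp / n_truth
  recall_grid <- seq(0, 1, by = 0.01)
  p_interp <- vapply(recall_grid, function(r) {
    ok <- recall >= r - 1e-12
    if (!any(ok)) 0 else max(precision[ok])
  }, numeric(1))
  mean(p_interp)
}

#' Mean average precision over a threshold range
#'
#' Mean of [average_precision()] over the thresholds (default 0.50 to 0.95
#' in steps of 0.05, the "mAP@0.5:0.95" range).
#'
#' @param d A [detection_set()].
#' @param thresholds IoU thresholds (default `seq(0.5, 0.95, by = 0.05)`).
#' @return mAP in `[0, 1]`.
#' @export
map_range <- function(d, thresholds = seq(0.5, 0.95, by = 0.05)) {
  mean(vapply(thresholds, function(t) average_precision(d, t), numeric(1)))
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) per
#' metric across cross-validation folds.  With a single fold the sd is
#' reported as 0 and flagged.
#'
#' @param per_fold_metrics Data frame (rows = folds, columns = metrics) or
#'   a named list of numeric vectors.
#' @return Data frame with columns `metric, mean, sd, n_folds, flag`.
#' @export
aggregate_cv <- function(per_fold_metrics) {
  df <- as.data.frame(per_fold_metrics)
  if (nrow(df) < 1L) stop("need at least one fold", call. = FALSE)
  single <- nrow(df) == 1L
  out <- data.frame(
    metric = names(df),
    mean = vapply(df, mean, numeric(1)),
    sd = if (single) 0 else vapply(df, sd, numeric(1)),
    n_folds = nrow(df),
    flag = if (single) "single_fold_sd_undefined" else "",
    stringsAsFactors = FALSE, row.names = NULL)
  out
}
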