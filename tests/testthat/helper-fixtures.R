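# Shared fixtures: small masks, flat colour images, and an independent
# all-point average-precision oracle.

disk_mask <- function(h, w, cy, cx, r) {
  m <- matrix(FALSE, h, w)
  for (row in seq_len(h)) for (col in seq_len(w))
    if ((row - cy)^2 + (col - cx)^2 <= r^2) m[row, col] <- TRUE
  binary_mask(m)
}

rect_mask <- function(h, w, r1, r2, c1, c2) {
  m <- matrix(FALSE, h, w)
  m[r1:r2, c1:c2] <- TRUE
  binary_mask(m)
}

flat_rgb <- function(h, w, rgb) {
  arr <- array(0L, c(h, w, 3L))
  for (k in 1:3) arr[, , k] <- rgb[k]
  channel_image(arr)
}

# Independent AP oracle: greedy confidence-ordered matching (recomputed
# from scratch) followed by all-point interpolated integration of the
# precision-recall curve.
ap_oracle <- function(preds, confs, truths, iou_thr) {
  pairwise_iou <- function(a, b) {
    un <- sum(a$grid | b$grid)
    if (un == 0) 1 else sum(a$grid & b$grid) / un
  }
  ord <- order(-confs, seq_along(confs))
  matched <- logical(length(truths))
  tp <- logical(length(ord))
  for (i in seq_along(ord)) {
    ious <- vapply(seq_along(truths), function(j) {
      if (matched[j]) -1 else pairwise_iou(preds[[ord[i]]], truths[[j]])
    }, numeric(1))
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_thr) {
      matched[j] <- TRUE
      tp[i] <- TRUE
    }
  }
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / length(truths)
  # all-point integration with right-to-left precision envelope
  env <- rev(cummax(rev(prec)))
  r_prev <- 0
  ap <- 0
  for (i in seq_along(rec)) {
    ap <- ap + (rec[i] - r_prev) * env[i]
    r_prev <- rec[i]
  }
  ap
}

random_detection_case <- function(seed) {
  set.seed(seed)
  n_truth <- sample(1:5, 1)
  n_pred <- sample(0:10, 1)
  truths <- lapply(seq_len(n_truth), function(i)
    rect_mask(32, 32, (i - 1) * 6 + 1, (i - 1) * 6 + 5, 3, 12))
  preds <- lapply(seq_len(n_pred), function(i) {
    j <- sample(n_truth, 1)
    jitter <- sample(-3:3, 1)
    r1 <- max(1, (j - 1) * 6 + 1 + jitter)
    rect_mask(32, 32, r1, min(32, r1 + 4), max(1, 3 + jitter), 12)
  })
  confs <- round(runif(n_pred), 3)
  list(preds = preds, confs = confs, truths = truths)
}
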