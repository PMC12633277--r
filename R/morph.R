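# Binary morphology and small spatial filters.  Structuring elements are
# discrete disks: offsets (dr, dc) with dr^2 + dc^2 <= radius^2.  All
# operations treat pixels outside the frame as background.

disk_offsets <- function(radius) {
  radius <- as.integer(radius)
  if (radius <= 0L) return(matrix(0L, nrow = 1, ncol = 2))
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

shift_logical <- function(grid, dr, dc, fill = FALSE) {
  h <- nrow(grid); w <- ncol(grid)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- grid[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Binary morphology on masks
#'
#' Dilation, erosion, opening (erode then dilate), closing (dilate then
#' erode) with a discrete disk structuring element, and hole filling (true
#' regions of the complement not connected to the frame border, using
#' 8-connectivity for the background).
#'
#' @param mask A `binary_mask`.
#' @param radius Disk radius in pixels; `radius = 0` is the identity.
#' @return A `binary_mask`.
#' @export
mask_dilate <- function(mask, radius = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius <= 0L) return(mask)
  off <- disk_offsets(radius)
  acc <- matrix(FALSE, nrow(mask$grid), ncol(mask$grid))
  for (i in seq_len(nrow(off)))
    acc <- acc | shift_logical(mask$grid, off[i, 1], off[i, 2], fill = FALSE)
  binary_mask(acc)
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, radius = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius <= 0L) return(mask)
  off <- disk_offsets(radius)
  acc <- matrix(TRUE, nrow(mask$grid), ncol(mask$grid))
  for (i in seq_len(nrow(off)))
    acc <- acc & shift_logical(mask$grid, off[i, 1], off[i, 2], fill = FALSE)
  binary_mask(acc)
}

#' @rdname mask_dilate
#' @export
mask_open <- function(mask, radius = 1L) mask_dilate(mask_erode(mask, radius), radius)

#' @rdname mask_dilate
#' @export
mask_close <- function(mask, radius = 1L) mask_erode(mask_dilate(mask, radius), radius)

#' @rdname mask_dilate
#' @export
mask_fill_holes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  bg <- label_components(binary_mask(!mask$grid), connectivity = 8L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  holes <- bg > 0L & !(bg %in% border_labels)
  dim(holes) <- dim(bg)
  binary_mask(mask$grid | holes)
}

#' Connected-component labelling
#'
#' @param mask A `binary_mask`.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return Integer matrix: 0 for background, components numbered from 1 in
#'   row-major (top-left first) order of first appearance.
#' @export
label_components <- function(mask, connectivity = 4L) {
  stopifnot(inherits(mask, "binary_mask"))
  .label_components_cpp(mask$grid, as.integer(connectivity))
}

# Mean filter with a (2r+1)^2 box kernel, replicate padding, via summed-area
# table; used to denoise the brightfield before looking for per-cell
# intensity minima.
mean_filter <- function(mat, radius = 2L) {
  if (radius <= 0L) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  padr <- c(rep(1L, radius), 1:h, rep(h, radius))
  padc <- c(rep(1L, radius), 1:w, rep(w, radius))
  p <- mat[padr, padc, drop = FALSE]
  sat <- t(apply(apply(p, 2, cumsum), 1, cumsum))
  sat <- rbind(0, cbind(0, sat))
  k <- 2L * radius + 1L
  r1 <- 1:h; c1 <- 1:w
  s <- sat[r1 + k, c1 + k, drop = FALSE] - sat[r1, c1 + k, drop = FALSE] -
    sat[r1 + k, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
  s / (k * k)
}

# Separable Gaussian blur with replicate padding.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  radius <- max(1L, ceiling(3 * sigma))
  x <- -radius:radius
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(mat); w <- ncol(mat)
  padr <- c(rep(1L, radius), 1:h, rep(h, radius))
  p <- mat[padr, , drop = FALSE]
  v <- matrix(0, h, w)
  for (i in seq_along(k)) v <- v + k[i] * p[(1:h) + i - 1L, , drop = FALSE]
  padc <- c(rep(1L, radius), 1:w, rep(w, radius))
  p <- v[, padc, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * p[, (1:w) + i - 1L, drop = FALSE]
  out
}

#' Otsu's threshold for an 8-bit intensity matrix
#'
#' Maximizes between-class variance over the 256-bin histogram.  Returns the
#' threshold `t` such that the two classes are `{<= t}` and `{> t}`, or `NA`
#' if the image has no separation (fewer than two occupied bins).
#'
#' @param mat Integer matrix of intensities in `[0, 255]`.
#' @return Integer threshold in `[0, 254]`, or `NA_integer_`.
#' @export
otsu_threshold <- function(mat) {
  counts <- as.numeric(tabulate(as.vector(mat) + 1L, nbins = 256L))
  n <- sum(counts)
  if (sum(counts > 0L) < 2L) return(NA_integer_)
  levels <- 0:255
  w0 <- cumsum(counts)
  mu <- cumsum(counts * levels)
  mu_t <- mu[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, 256)
  bc[valid] <- (mu_t * w0[valid] - n * mu[valid])^2 / (w0[valid] * w1[valid])
  as.integer(which.max(bc) - 1L)
}
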