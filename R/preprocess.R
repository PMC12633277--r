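# Standardized preprocessing for classifier input: RGB conversion, square
# gray padding, bilinear resize to 224 x 224, a five-fold multi-augmentation
# scheme, and stratified cross-validation folds.

#' Pad an image to a square with gray borders
#'
#' The shorter side is padded symmetrically with gray pixels
#' (RGB = \[173, 173, 173\]); when the split is odd the extra pixel goes to
#' the right/bottom.  Original pixel values are never altered.
#'
#' @param img A `channel_image`.
#' @param fill_rgb Padding colour, length-3 integer vector (default
#'   `c(173, 173, 173)`); grayscale images use its first element.
#' @return A square `channel_image` of side `max(height, width)`.
#' @export
pad_to_square <- function(img, fill_rgb = c(173L, 173L, 173L)) {
  stopifnot(inherits(img, "channel_image"))
  h <- im_height(img); w <- im_width(img)
  if (h == w) return(img)
  side <- max(h, w)
  top <- (side - h) %/% 2L
  left <- (side - w) %/% 2L
  if (im_is_rgb(img)) {
    out <- array(rep(as.integer(fill_rgb), each = side * side),
                 dim = c(side, side, 3L))
    out[top + seq_len(h), left + seq_len(w), ] <- img$pixels
  } else {
    out <- matrix(as.integer(fill_rgb[1]), side, side)
    out[top + seq_len(h), left + seq_len(w)] <- img$pixels
  }
  channel_image(out)
}

# Bilinear sampling of one plane at fractional (row, col) positions, with
# coordinates clamped to the frame (half-pixel-center convention).
bilinear_plane <- function(mat, rr, cc) {
  h <- nrow(mat); w <- ncol(mat)
  rr <- pmin(pmax(rr, 1), h)
  cc <- pmin(pmax(cc, 1), w)
  r0 <- floor(rr); c0 <- floor(cc)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- rr - r0; fc <- cc - c0
  v00 <- mat[cbind(r0, c0)]; v01 <- mat[cbind(r0, c1)]
  v10 <- mat[cbind(r1, c0)]; v11 <- mat[cbind(r1, c1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

apply_planes <- function(img, f) {
  if (im_is_rgb(img)) {
    planes <- lapply(1:3, function(k) f(img$pixels[, , k]))
    out <- array(0L, c(dim(planes[[1]]), 3L))
    for (k in 1:3) out[, , k] <- planes[[k]]
    channel_image(pmin(pmax(round(out), 0), 255))
  } else {
    channel_image(pmin(pmax(round(f(img$pixels)), 0), 255))
  }
}

#' Resize an image to the standard classifier input size
#'
#' Bilinear interpolation with the half-pixel-center convention; output is
#' `side x side` RGB (grayscale input is promoted by plane replication
#' first, matching the RGB-conversion step of the preprocessing pipeline).
#'
#' @param img A `channel_image`.
#' @param side Output side in pixels (default 224).
#' @return An RGB `channel_image` of dimensions `side x side`.
#' @export
resize_to_standard <- function(img, side = 224L) {
  side <- as.integer(side)
  if (is.na(side) || side < 1L)
    stop("parameter error: side must be a positive integer", call. = FALSE)
  img <- im_to_rgb(img)
  h <- im_height(img); w <- im_width(img)
  rr <- ((seq_len(side) - 0.5) * h / side) + 0.5
  cc <- ((seq_len(side) - 0.5) * w / side) + 0.5
  grid_r <- rep(rr, times = side)
  grid_c <- rep(cc, each = side)
  apply_planes(img, function(p) {
    matrix(bilinear_plane(p, grid_r, grid_c), side, side)
  })
}

#' Augmentation configuration
#'
#' The fixed-rate multi-augmentation scheme: each image yields
#' `multiplicity` independently transformed copies per epoch (default 5,
#' emulating an offline five-fold expansion of the training set).
#' Transform families: random resized crop (area scale 0.8-1.0), full
#' 360-degree rotation, horizontal/vertical flips, colour jitter, Gaussian
#' blur.  Jitter and blur magnitudes are package defaults (brightness /
#' contrast / saturation +-20%, hue +-5% of the full circle, blur sigma
#' U\[0.1, 2\]); the transform families are the stated pipeline, the
#' magnitudes are not externally specified.
#'
#' @param multiplicity Copies per image, >= 1 (default 5).
#' @param crop_scale Area-scale interval within (0, 1] (default c(0.8, 1)).
#' @param rotation_degrees Rotation interval in degrees (default c(0, 360)).
#' @param hflip,vflip Enable random horizontal/vertical flips (default on).
#' @param jitter_strength Named list with `brightness`, `contrast`,
#'   `saturation` (fractions) and `hue` (fraction of the full hue circle).
#' @param blur_sigma Gaussian blur sigma interval (default c(0.1, 2)).
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(multiplicity = 5L,
                                crop_scale = c(0.8, 1.0),
                                rotation_degrees = c(0, 360),
                                hflip = TRUE, vflip = TRUE,
                                jitter_strength = list(brightness = 0.2,
                                                       contrast = 0.2,
                                                       saturation = 0.2,
                                                       hue = 0.05),
                                blur_sigma = c(0.1, 2.0)) {
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1L)
    stop("multiplicity must be >= 1", call. = FALSE)
  if (crop_scale[1] <= 0 || crop_scale[2] > 1 || crop_scale[1] > crop_scale[2])
    stop("crop_scale must lie within (0, 1]", call. = FALSE)
  structure(list(multiplicity = multiplicity, crop_scale = crop_scale,
                 rotation_degrees = rotation_degrees,
                 hflip = isTRUE(hflip), vflip = isTRUE(vflip),
                 jitter_strength = jitter_strength,
                 blur_sigma = blur_sigma),
            class = "augmentation_config")
}

random_resized_crop <- function(img, scale_lo, scale_hi) {
  h <- im_height(img); w <- im_width(img)
  s <- sqrt(runif(1, scale_lo, scale_hi))
  ch <- max(1, round(h * s)); cw <- max(1, round(w * s))
  r0 <- sample.int(h - ch + 1L, 1L) - 1L
  c0 <- sample.int(w - cw + 1L, 1L) - 1L
  rr <- r0 + ((seq_len(h) - 0.5) * ch / h) + 0.5
  cc <- c0 + ((seq_len(w) - 0.5) * cw / w) + 0.5
  grid_r <- rep(rr, times = w)
  grid_c <- rep(cc, each = h)
  apply_planes(img, function(p) matrix(bilinear_plane(p, grid_r, grid_c), h, w))
}

rotate_image <- function(img, degrees, fill = 173L) {
  if (degrees %% 360 == 0) return(img)
  h <- im_height(img); w <- im_width(img)
  th <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- rep(seq_len(h), times = w) - cy
  cc <- rep(seq_len(w), each = h) - cx
  # inverse map: rotate output coords by -theta into the source frame
  src_r <- cos(th) * rr + sin(th) * cc + cy
  src_c <- -sin(th) * rr + cos(th) * cc + cx
  oob <- src_r < 0.5 | src_r > h + 0.5 | src_c < 0.5 | src_c > w + 0.5
  apply_planes(img, function(p) {
    v <- bilinear_plane(p, src_r, src_c)
    v[oob] <- fill
    matrix(v, h, w)
  })
}

color_jitter <- function(img, js) {
  out <- img
  if (!is.null(js$brightness) && js$brightness > 0) {
    f <- runif(1, 1 - js$brightness, 1 + js$brightness)
    out <- apply_planes(out, function(p) p * f)
  }
  if (!is.null(js$contrast) && js$contrast > 0) {
    f <- runif(1, 1 - js$contrast, 1 + js$contrast)
    m <- mean(out$pixels)
    out <- apply_planes(out, function(p) (p - m) * f + m)
  }
  if (im_is_rgb(out) &&
      ((!is.null(js$saturation) && js$saturation > 0) ||
       (!is.null(js$hue) && js$hue > 0))) {
    sf <- if (!is.null(js$saturation) && js$saturation > 0)
      runif(1, 1 - js$saturation, 1 + js$saturation) else 1
    hs <- if (!is.null(js$hue) && js$hue > 0)
      runif(1, -js$hue, js$hue) * 180 else 0
    hsv <- rgb_to_hsv255(out)
    h2 <- (hsv$h + round(hs)) %% 180
    s2 <- pmin(pmax(round(hsv$s * sf), 0), 255)
    out <- channel_image(hsv255_to_rgb(h2, s2, hsv$v))
  }
  out
}

#' Randomly augment an image
#'
#' Produces exactly `cfg$multiplicity` images, each the input's size, each
#' from an independent draw of crop / rotation / flips / colour jitter /
#' blur.  Fully reproducible: the same `rng_seed` yields pixel-identical
#' output lists.
#'
#' @param img A `channel_image`.
#' @param cfg An [augmentation_config()].
#' @param rng_seed Integer seed.
#' @return List of `channel_image`s of length `cfg$multiplicity`.
#' @export
augment <- function(img, cfg, rng_seed = 0L) {
  stopifnot(inherits(img, "channel_image"), inherits(cfg, "augmentation_config"))
  with_local_seed(rng_seed, {
    lapply(seq_len(cfg$multiplicity), function(i) {
      out <- img
      if (cfg$crop_scale[1] < 1 || cfg$crop_scale[2] < 1)
        out <- random_resized_crop(out, cfg$crop_scale[1], cfg$crop_scale[2])
      if (diff(range(cfg$rotation_degrees)) > 0 || any(cfg$rotation_degrees != 0)) {
        deg <- runif(1, cfg$rotation_degrees[1], cfg$rotation_degrees[2])
        out <- rotate_image(out, deg)
      }
      if (cfg$hflip && runif(1) < 0.5)
        out <- apply_planes(out, function(p) p[, rev(seq_len(ncol(p))), drop = FALSE])
      if (cfg$vflip && runif(1) < 0.5)
        out <- apply_planes(out, function(p) p[rev(seq_len(nrow(p))), , drop = FALSE])
      out <- color_jitter(out, cfg$jitter_strength)
      if (!is.null(cfg$blur_sigma) && max(cfg$blur_sigma) > 0) {
        sigma <- runif(1, cfg$blur_sigma[1], cfg$blur_sigma[2])
        out <- apply_planes(out, function(p) gaussian_blur(p, sigma))
      }
      out
    })
  })
}

# Run code under a temporary RNG state so package randomness never disturbs
# the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Build stratified cross-validation folds
#'
#' Records are shuffled within each class (deterministically from `seed`)
#' and dealt to `k` folds so per-class fold sizes differ by at most one;
#' remainder records go to the lowest-index folds.  With 855 + 713 records
#' and k = 5 this yields fold test-set totals 314, 314, 314, 313, 313.
#'
#' @param records Data frame with columns `record_id` and `class`, or a
#'   named character vector of classes.
#' @param k Number of folds, >= 2 (default 5).
#' @param seed Integer seed for the within-class shuffle.
#' @return An object of class `fold_split`: list with `k` and `assignments`
#'   (named integer vector of fold indices in `[0, k)`).
#' @export
make_folds <- function(records, k = 5L, seed = 0L) {
  if (is.data.frame(records)) {
    ids <- as.character(records$record_id)
    classes <- as.character(records$class)
  } else {
    ids <- names(records)
    classes <- as.character(records)
  }
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids))
    stop("split error: records need unique ids", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("split error: k must be >= 2", call. = FALSE)
  tab <- table(classes)
  if (any(tab < k))
    stop(sprintf("split error: class '%s' has fewer than k = %d records",
                 names(tab)[which.min(tab)], k), call. = FALSE)
  assignments <- integer(length(ids))
  names(assignments) <- ids
  with_local_seed(seed, {
    for (cl in names(tab)) {
      members <- ids[classes == cl]
      members <- sample(members)
      n <- length(members)
      sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
      assignments[members] <- rep(0:(k - 1L), times = sizes)
    }
  })
  structure(list(k = k, assignments = assignments), class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split k=%d over %d records>\n", x$k, length(x$assignments)))
  print(table(fold = x$assignments))
  invisible(x)
}

#' Serialize / load a fold split as CSV
#' @param split A `fold_split`.
#' @param path CSV path (columns `record_id, fold`).
#' @return `read_fold_split()` returns a `fold_split`.
#' @export
write_fold_split <- function(split, path) {
  write.csv(data.frame(record_id = names(split$assignments),
                       fold = unname(split$assignments)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fold_split
#' @export
read_fold_split <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  a <- as.integer(df$fold)
  names(a) <- as.character(df$record_id)
  structure(list(k = max(a) + 1L, assignments = a), class = "fold_split")
}

#' Printed per-fold dataset counts
#'
#' The published five-fold split of the 1,568-image cluster / non-cluster
#' dataset: per-fold train and test counts per class.  Augmented train
#' counts are obtained by multiplying the train columns by the augmentation
#' multiplicity (5).
#'
#' @return Data frame with columns `fold, train_cluster, train_non_cluster,
#'   test_cluster, test_non_cluster`.
#' @export
ccc_fold_table <- function() {
  path <- system.file("extdata", "fold_counts.csv", package = "cccpheno")
  read.csv(path, stringsAsFactors = FALSE)
}
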