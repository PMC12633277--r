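# HSV-range stain extraction.
#
# Hue dialect: the half-degree 0-179 scale (H = round(degrees / 2)), under
# which pure green sits at 60 and pure yellow at 30, so the printed channel
# ranges (green 35-85, yellow 20-40) bracket their colours.  Saturation and
# value are scaled to 0-255, with V = max(R, G, B) and S = 0 where V = 0.

#' Construct an HSV range
#'
#' A hue/saturation/value box with inclusive bounds at both ends.  `v_lo` is
#' the tunable fluorescence-brightness lower bound (the sweep parameter
#' usually called X or V): raising it shrinks every extracted stain region.
#'
#' @param h_lo,h_hi Hue bounds on the 0-179 half-degree scale.
#' @param s_lo,s_hi Saturation bounds, 0-255.
#' @param v_lo,v_hi Value (brightness) bounds, 0-255.
#' @return An object of class `hsv_range`.
#' @export
hsv_range <- function(h_lo, h_hi, s_lo, s_hi, v_lo, v_hi) {
  vals <- c(h_lo = h_lo, h_hi = h_hi, s_lo = s_lo, s_hi = s_hi,
            v_lo = v_lo, v_hi = v_hi)
  if (anyNA(vals)) stop("HSV bounds may not be NA", call. = FALSE)
  if (h_lo < 0 || h_hi > 179 || h_lo > h_hi)
    stop("hue bounds must satisfy 0 <= h_lo <= h_hi <= 179", call. = FALSE)
  if (s_lo < 0 || s_hi > 255 || s_lo > s_hi)
    stop("saturation bounds must satisfy 0 <= s_lo <= s_hi <= 255", call. = FALSE)
  if (v_lo < 0 || v_hi > 255 || v_lo > v_hi)
    stop("value bounds must satisfy 0 <= v_lo <= v_hi <= 255", call. = FALSE)
  structure(as.list(vals), class = "hsv_range")
}

#' Stain channel presets
#'
#' Default HSV boxes for the two markers: CD61 (platelets, green hue 35-85)
#' and CD45 (leukocytes, yellow hue 20-40), both with saturation 100-255 and
#' value `v_lo`-255.  The default brightness lower bound is `v_lo = 140`,
#' the operating point selected by the brightness sweep; the ranges overlap
#' in hue 35-40, so a pixel may legitimately belong to both masks.
#'
#' @param name `"cd61_green"` or `"cd45_yellow"`.
#' @param v_lo Brightness lower bound, 0-255 (default 140).
#' @param morph_open Apply one radius-1 morphological opening to remove
#'   speckle after thresholding (default `TRUE`).
#' @return An object of class `stain_channel`.
#' @export
stain_channel <- function(name = c("cd61_green", "cd45_yellow"), v_lo = 140,
                          morph_open = TRUE) {
  name <- match.arg(name)
  range <- if (name == "cd61_green") hsv_range(35, 85, 100, 255, v_lo, 255)
           else hsv_range(20, 40, 100, 255, v_lo, 255)
  structure(list(name = name, range = range, morph_open = isTRUE(morph_open)),
            class = "stain_channel")
}

#' Convert an RGB image to 8-bit HSV planes
#'
#' @param img An RGB `channel_image`.
#' @return A list of three integer matrices `h` (0-179), `s` (0-255),
#'   `v` (0-255).
#' @export
rgb_to_hsv255 <- function(img) {
  stopifnot(inherits(img, "channel_image"))
  if (!im_is_rgb(img))
    stop("channel-count error: rgb_to_hsv255 needs an RGB image", call. = FALSE)
  d <- dim(img$pixels)
  r <- matrix(img$pixels[, , 1], d[1], d[2])
  g <- matrix(img$pixels[, , 2], d[1], d[2])
  b <- matrix(img$pixels[, , 3], d[1], d[2])
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- v - mn
  hdeg <- matrix(0, nrow(r), ncol(r))
  nz <- delta > 0
  i_r <- nz & v == r
  i_g <- nz & v == g & !i_r
  i_b <- nz & v == b & !i_r & !i_g
  hdeg[i_r] <- 60 * (((g[i_r] - b[i_r]) / delta[i_r]) %% 6)
  hdeg[i_g] <- 60 * ((b[i_g] - r[i_g]) / delta[i_g] + 2)
  hdeg[i_b] <- 60 * ((r[i_b] - g[i_b]) / delta[i_b] + 4)
  h <- round(hdeg / 2) %% 180
  s <- matrix(0, nrow(r), ncol(r))
  vpos <- v > 0
  s[vpos] <- round(255 * delta[vpos] / v[vpos])
  storage.mode(h) <- "integer"
  storage.mode(s) <- "integer"
  storage.mode(v) <- "integer"
  list(h = h, s = s, v = v)
}

# Inverse transform (used by the synthetic generator and colour jitter):
# h on 0-179, s and v on 0-255; returns an h x w x 3 integer array.
hsv255_to_rgb <- function(h, s, v) {
  hdeg <- (h %% 180) * 2
  sf <- s / 255; vf <- v / 255
  c_ <- vf * sf
  x <- c_ * (1 - abs((hdeg / 60) %% 2 - 1))
  m <- vf - c_
  r <- g <- b <- matrix(0, nrow(as.matrix(h)), ncol(as.matrix(h)))
  sect <- floor(hdeg / 60) %% 6
  pick <- function(sel, rr, gg, bb) {
    r[sel] <<- rr[sel]; g[sel] <<- gg[sel]; b[sel] <<- bb[sel]
  }
  zero <- matrix(0, nrow(r), ncol(r))
  pick(sect == 0, c_, x, zero)
  pick(sect == 1, x, c_, zero)
  pick(sect == 2, zero, c_, x)
  pick(sect == 3, zero, x, c_)
  pick(sect == 4, x, zero, c_)
  pick(sect == 5, c_, zero, x)
  out <- array(0L, c(nrow(r), ncol(r), 3L))
  out[, , 1] <- as.integer(round(pmin(pmax((r + m) * 255, 0), 255)))
  out[, , 2] <- as.integer(round(pmin(pmax((g + m) * 255, 0), 255)))
  out[, , 3] <- as.integer(round(pmin(pmax((b + m) * 255, 0), 255)))
  out
}

#' Extract a binary stain mask from a fluorescence channel
#'
#' A pixel is selected iff its (H, S, V) triple lies inclusively inside the
#' channel's HSV box; one radius-1 morphological opening then removes
#' isolated speckle (disable via the channel's `morph_open` flag).  The
#' in-range stage is monotone in `v_lo`: raising the brightness bound never
#' adds pixels, so stained area shrinks as the bound rises.
#'
#' @param img An RGB `channel_image`.
#' @param channel A `stain_channel`.
#' @return A `binary_mask`.
#' @export
extract_stain_mask <- function(img, channel) {
  stopifnot(inherits(channel, "stain_channel"))
  hsv <- rgb_to_hsv255(img)
  rg <- channel$range
  sel <- hsv$h >= rg$h_lo & hsv$h <= rg$h_hi &
         hsv$s >= rg$s_lo & hsv$s <= rg$s_hi &
         hsv$v >= rg$v_lo & hsv$v <= rg$v_hi
  m <- binary_mask(sel)
  if (channel$morph_open) m <- mask_open(m, 1L)
  m
}
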