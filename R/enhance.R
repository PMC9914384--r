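#' RGB to HSI colour-space conversion
#'
#' Converts an RGB image (H x W x 3 array, channels in \[0, 1\]) to the
#' hue-saturation-intensity representation using the standard geometric
#' formulas: intensity `I = (R + G + B)/3`, saturation
#' `S = 1 - min(R, G, B)/I` (0 where `I = 0`), and hue from
#' `theta = acos(0.5 * ((R-G) + (R-B)) / sqrt((R-G)^2 + (R-B)(G-B)))`, with
#' `H = theta` when `B <= G` and `H = 360 - theta` otherwise. Gray pixels
#' (zero chroma) get `H = 0` and `S = 0` by convention.
#'
#' @param img Numeric H x W x 3 array with finite values in \[0, 1\].
#' @return List of class `hsi_image` with matrices `h` (degrees in
#'   \[0, 360)), `s` and `i` (both in \[0, 1\]).
#' @export
rgb_to_hsi <- function(img) {
  validate_rgb(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 0), -1), 1)) * 180 / pi
  h <- ifelse(b <= g, theta, 360 - theta)
  gray <- den == 0
  h[gray] <- 0
  s[gray & !(i > 0)] <- 0
  h[h >= 360] <- 0
  structure(list(h = h, s = s, i = i), class = "hsi_image")
}

#' HSI to RGB colour-space conversion
#'
#' Inverse of [rgb_to_hsi()] by the standard 120-degree sector formulas;
#' out-of-gamut values produced by extreme saturation/intensity pairs are
#' clipped to \[0, 1\].
#'
#' @param hsi An `hsi_image` (list with matrices `h`, `s`, `i`).
#' @return Numeric H x W x 3 RGB array in \[0, 1\].
#' @export
hsi_to_rgb <- function(hsi) {
  h <- hsi$h %% 360
  s <- hsi$s
  i <- hsi$i
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  sector <- findInterval(h, c(0, 120, 240), rightmost.closed = FALSE)
  hh <- h - (sector - 1) * 120
  # channel hit by the hue, its successor, and the minimum channel
  c_min <- i * (1 - s)
  denom <- cos((60 - hh) * pi / 180)
  c_hue <- i * (1 + s * cos(hh * pi / 180) / ifelse(denom == 0, 1e-12, denom))
  c_rest <- 3 * i - (c_min + c_hue)
  pick <- function(a, bb, cc) {
    out <- matrix(0, nrow(h), ncol(h))
    out[sector == 1] <- a[sector == 1]
    out[sector == 2] <- bb[sector == 2]
    out[sector == 3] <- cc[sector == 3]
    out
  }
  r <- pick(c_hue, c_min, c_rest)
  g <- pick(c_rest, c_hue, c_min)
  b <- pick(c_min, c_rest, c_hue)
  out <- array(0, c(nrow(h), ncol(h), 3))
  out[, , 1] <- pmin(pmax(r, 0), 1)
  out[, , 2] <- pmin(pmax(g, 0), 1)
  out[, , 3] <- pmin(pmax(b, 0), 1)
  out
}

#' Histogram equalization of an intensity channel
#'
#' Classical CDF-mapping equalization: the channel is quantized into
#' `levels` equal-width bins over \[0, 1\] and each value is mapped to the
#' empirical cumulative distribution at its bin. The mapping is monotone
#' non-decreasing, so pixel rank order is preserved. A constant channel is
#' returned unchanged (degenerate single-bin case).
#'
#' @param channel Numeric matrix with values in \[0, 1\].
#' @param levels Number of quantization levels (>= 2). Default 256.
#' @return Equalized matrix with values in \[0, 1\].
#' @export
equalize_intensity <- function(channel, levels = 256) {
  if (levels < 2) abort("levels must be >= 2", class = "ecmpa_error_config")
  if (any(!is.finite(channel)) || any(channel < 0) || any(channel > 1)) {
    abort("channel values must be finite and in [0, 1]",
          class = "ecmpa_error_invalid_value")
  }
  idx <- pmin(floor(channel * levels), levels - 1L) + 1L
  counts <- tabulate(idx, nbins = levels)
  if (sum(counts > 0) <= 1L) return(channel)
  cdf <- cumsum(counts) / length(channel)
  matrix(cdf[idx], nrow(channel), ncol(channel))
}

#' Colour histogram equalization in HSI space
#'
#' Contrast enhancement that redistributes intensity while keeping colour:
#' (1) convert RGB to HSI, (2) take the intensity matrix, (3) histogram-
#' equalize it, (4) put the equalized intensity back, (5) convert back to
#' RGB. Hue and saturation are untouched in HSI space, so colour shifts can
#' only arise from gamut clipping on the inverse conversion.
#'
#' @param img Numeric H x W x 3 RGB array in \[0, 1\].
#' @param levels Quantization levels of the equalizer.
#' @return Enhanced RGB array of the same shape.
#' @export
enhance_image <- function(img, levels = 256) {
  hsi <- rgb_to_hsi(img)
  hsi$i <- equalize_intensity(hsi$i, levels = levels)
  hsi_to_rgb(hsi)
}

validate_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    abort("expected an H x W x 3 RGB array", class = "ecmpa_error_type")
  }
  if (any(!is.finite(img)) || any(img < 0) || any(img > 1)) {
    abort("RGB values must be finite and in [0, 1]",
          class = "ecmpa_error_invalid_value")
  }
  invisible(img)
}

#' Read or write a PNG image
#'
#' Thin wrappers over the \pkg{png} package returning/accepting the H x W
#' x 3 arrays used by [enhance_image()]. Grayscale or alpha-channel images
#' are expanded/truncated to 3 channels on read.
#'
#' @param path File path.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file not found: ", path),
          class = "ecmpa_error_missing_file")
  }
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) {
    x <- array(rep(x, 3), c(dim(x), 3))
  } else if (dim(x)[3] > 3) {
    x <- x[, , 1:3, drop = FALSE]
  }
  x
}

#' @rdname read_image
#' @param img H x W x 3 array in \[0, 1\].
#' @export
write_image <- function(img, path) {
  validate_rgb(img)
  png::writePNG(img, path)
  invisible(path)
}
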