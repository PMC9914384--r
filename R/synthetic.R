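#' Generate a synthetic fused deep-feature table
#'
#' Emulates the feature tables produced by concatenating global-average-pool
#' activations of two convolutional backbones: all values are non-negative
#' (post-ReLU, half-normal), most columns are uninformative, a `sparsity`
#' fraction of the noise columns is near-zero (mimicking the dead/zero
#' units common in deep feature vectors), and a small planted set of
#' columns carries the class signal. Informative column `j` for a sample of
#' class `c` is `|Normal(mu_c, 1)|` with class means `mu_c = (c - 1) *
#' effect`, so adjacent classes are `effect` noise-SDs apart. Classes are
#' balanced (sizes differ by at most 1 when `n` is not divisible).
#'
#' @param n Number of samples.
#' @param n_features Total feature count D.
#' @param n_informative Number of planted class-informative columns.
#' @param n_classes Number of classes (>= 2). With 5 classes the labels are
#'   the five leukocyte subtypes; otherwise `class1`, `class2`, ...
#' @param effect Class-mean separation in noise-SD units (>= 0).
#' @param sparsity Fraction of noise columns replaced by near-zero
#'   half-normal activations (scale 0.01), in \[0, 1\]. Default 0.5.
#' @param seed Integer RNG seed; the generator is fully deterministic.
#' @return List with `data` (tibble: feature columns `f1..fD` plus
#'   `label`), `planted` (1-based indices of the informative columns,
#'   ascending), and the echoed spec fields.
#' @export
gen_feature_dataset <- function(n, n_features, n_informative, n_classes = 5,
                                effect = 3, sparsity = 0.5, seed = 1) {
  if (n_informative > n_features) {
    abort("n_informative must be <= n_features", class = "ecmpa_error_config")
  }
  if (n_classes < 2) abort("need >= 2 classes", class = "ecmpa_error_config")
  if (effect < 0) abort("effect must be >= 0", class = "ecmpa_error_config")
  if (sparsity < 0 || sparsity > 1) {
    abort("sparsity must be in [0, 1]", class = "ecmpa_error_config")
  }
  withr::with_seed(seed, {
    sizes <- rep(n %/% n_classes, n_classes) +
      c(rep(1, n %% n_classes), rep(0, n_classes - n %% n_classes))
    cls <- rep(seq_len(n_classes), times = sizes)
    planted <- sort(sample.int(n_features, n_informative))
    vals <- matrix(abs(rnorm(n * n_features)), n, n_features)
    noise_cols <- setdiff(seq_len(n_features), planted)
    n_sparse <- round(sparsity * length(noise_cols))
    sparse_cols <- if (n_sparse > 0) sample(noise_cols, n_sparse) else integer(0)
    if (length(sparse_cols) > 0) {
      vals[, sparse_cols] <- abs(matrix(rnorm(n * length(sparse_cols), 0, 0.01),
                                        n, length(sparse_cols)))
    }
    for (j in planted) {
      vals[, j] <- abs(rnorm(n, mean = (cls - 1) * effect, sd = 1))
    }
    colnames(vals) <- paste0("f", seq_len(n_features))
    lab_names <- if (n_classes == 5) {
      c("neutrophil", "eosinophil", "basophil", "lymphocyte", "monocyte")
    } else {
      paste0("class", seq_len(n_classes))
    }
    data <- as_tibble(vals)
    data$label <- factor(lab_names[cls], levels = lab_names)
    list(data = data, planted = planted,
         spec = list(n = n, n_features = n_features,
                     n_informative = n_informative, n_classes = n_classes,
                     effect = effect, sparsity = sparsity, seed = seed))
  })
}

#' Generate synthetic cell-like test images
#'
#' Simple stand-ins for stained leukocyte micrographs: a light, faintly
#' pink background with a darker purple elliptical "nucleus" blob plus
#' Gaussian pixel noise. With `contrast = "low"` the intensity range is
#' compressed into \[0.4, 0.6\], giving the enhancement stage something to
#' stretch.
#'
#' @param count Number of images.
#' @param size Image side length in pixels (>= 32).
#' @param contrast `"normal"` or `"low"`.
#' @param seed Integer RNG seed.
#' @return List of `size x size x 3` RGB arrays in \[0, 1\].
#' @export
gen_cell_images <- function(count = 1, size = 64,
                            contrast = c("normal", "low"), seed = 1) {
  contrast <- match.arg(contrast)
  if (size < 32) abort("size must be >= 32", class = "ecmpa_error_config")
  withr::with_seed(seed, {
    lapply(seq_len(count), function(i) {
      cx <- runif(1, 0.35, 0.65) * size
      cy <- runif(1, 0.35, 0.65) * size
      a <- runif(1, 0.15, 0.25) * size
      b <- runif(1, 0.12, 0.22) * size
      ang <- runif(1, 0, pi)
      xs <- matrix(rep(seq_len(size), each = size), size, size)
      ys <- matrix(rep(seq_len(size), times = size), size, size)
      xr <- (xs - cx) * cos(ang) + (ys - cy) * sin(ang)
      yr <- -(xs - cx) * sin(ang) + (ys - cy) * cos(ang)
      inside <- (xr / a)^2 + (yr / b)^2 <= 1
      # background: light, faintly pink; nucleus: darker purple. Pixel noise
      # is a shared luminance jitter so chromaticity (hue/saturation) stays
      # exactly piecewise-constant, as in a stain-free sensor-noise model.
      img <- array(0, c(size, size, 3))
      bg <- c(0.92, 0.87, 0.89)
      nuc <- c(0.45, 0.28, 0.55)
      for (ch in 1:3) {
        plane <- matrix(bg[ch], size, size)
        plane[inside] <- nuc[ch]
        img[, , ch] <- plane
      }
      lum_noise <- matrix(rnorm(size * size, 0, 0.015), size, size)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 + lum_noise)
      img <- pmin(pmax(img, 0), 1)
      if (contrast == "low") {
        intens <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
        lo <- min(intens); hi <- max(intens)
        target <- 0.4 + (intens - lo) / max(hi - lo, 1e-9) * 0.2
        scale <- target / pmax(intens, 1e-9)
        for (ch in 1:3) img[, , ch] <- img[, , ch] * scale
        img <- pmin(pmax(img, 0), 1)
      }
      img
    })
  })
}
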