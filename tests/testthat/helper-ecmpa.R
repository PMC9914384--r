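# Shared fixture builders; everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny labelled feature table with known values.
toy_table <- function() {
  tibble::tibble(a = c(1, 2, 3), b = c(0.5, 0.25, 0.125),
                 label = c("x", "y", "x"))
}

# Well-separated two-class table: the first `n_informative` columns carry
# the signal, the rest are half-normal noise.
separable_table <- function(n = 60, n_features = 6, n_informative = 2,
                            effect = 6, seed = 42) {
  gen_feature_dataset(n = n, n_features = n_features,
                      n_informative = n_informative, n_classes = 2,
                      effect = effect, sparsity = 0, seed = seed)
}

# All 255 non-empty masks over d bits (columns of a logical matrix).
all_masks <- function(d) {
  stopifnot(d <= 16)
  vapply(seq_len(2^d - 1),
         function(m) as.logical(bitwAnd(m, 2^(seq_len(d) - 1))),
         logical(d))
}

# Exhaustive wrapper-cost minimum over all non-empty subsets.
exhaustive_best_cost <- function(values, labels, partition, k = 5) {
  masks <- all_masks(ncol(values))
  min(apply(masks, 2, cost_function, values = values, labels = labels,
            partition = partition, k = k))
}

# Circular hue difference in degrees.
hue_diff <- function(h1, h0) {
  d <- abs(h1 - h0) %% 360
  pmin(d, 360 - d)
}
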