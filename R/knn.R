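# Exact Euclidean k-nearest-neighbour classifier used as the wrapper
# fitness and as the "knn" evaluation classifier. Implemented in-package so
# the tie rules are deterministic: equal distances are resolved by training
# row order, and tied votes go to the smallest class index (first factor
# level among the tied classes). Majority vote over the k neighbours.
knn_predict <- function(train_x, train_y, test_x, k = 5) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (!is.factor(train_y)) train_y <- factor(train_y)
  n_train <- nrow(train_x)
  if (n_train < k) {
    abort(sprintf("need at least k = %d training rows, have %d", k, n_train),
          class = "ecmpa_error_too_few_rows")
  }
  # squared Euclidean distances via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  cross <- tcrossprod(test_x, train_x)
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") - 2 * cross
  y_int <- as.integer(train_y)
  n_class <- nlevels(train_y)
  pred <- integer(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nb <- y_int[order(d2[i, ])[seq_len(k)]]
    votes <- tabulate(nb, nbins = n_class)
    pred[i] <- which.max(votes)  # which.max takes the smallest tied index
  }
  factor(levels(train_y)[pred], levels = levels(train_y))
}

# Misclassification fraction of knn_predict on a fixed train/test split.
knn_error <- function(train_x, train_y, test_x, test_y, k = 5) {
  pred <- knn_predict(train_x, train_y, test_x, k = k)
  mean(pred != test_y)
}

# Stratified row split: returns list(train =, test =) of row indices.
# Within each class the rows are permuted (seeded by the caller's RNG
# state) and the first round(test_fraction * n_c) go to the test side,
# with at least one row kept on each side when the class has >= 2 rows.
stratified_split <- function(labels, test_fraction) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test fraction must be in (0, 1)", class = "ecmpa_error_config")
  }
  labels <- as.factor(labels)
  test_idx <- integer(0)
  for (cl in levels(labels)) {
    rows <- which(labels == cl)
    n_c <- length(rows)
    if (n_c < 2) {
      abort(sprintf("class '%s' has fewer than 2 samples; cannot split", cl),
            class = "ecmpa_error_too_few_rows")
    }
    n_test <- min(n_c - 1L, max(1L, round(test_fraction * n_c)))
    test_idx <- c(test_idx, sample(rows)[seq_len(n_test)])
  }
  test_idx <- sort(test_idx)
  list(train = setdiff(seq_along(labels), test_idx), test = test_idx)
}
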