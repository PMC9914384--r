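#' Per-column Shannon entropy of a feature table
#'
#' First stage of the ECMPA selector: an unsupervised ranking of feature
#' columns by the Shannon entropy of their empirical distribution. Each
#' column is binned into `bins` equal-width bins spanning that column's own
#' \[min, max\] range, and the entropy is \eqn{-\sum_b p_b \log_2 p_b} over
#' the non-empty bins (so the result is in bits and bounded by
#' \eqn{\log_2(\mathrm{bins})}). A constant column occupies a single bin and
#' has entropy 0.
#'
#' @param data Feature table (tibble with a label column) or numeric matrix.
#' @param bins Number of histogram bins (>= 2). Default 256, the 8-bit
#'   convention.
#' @param label_column Label column name (ignored for matrix input).
#' @return A tibble with columns `index` (original column position),
#'   `feature_id`, and `entropy` (bits); the bin count is kept in the
#'   `bins` attribute.
#' @export
column_entropy <- function(data, bins = 256, label_column = "label") {
  if (!is.numeric(bins) || length(bins) != 1 || bins < 2) {
    abort("bins must be a single integer >= 2", class = "ecmpa_error_config")
  }
  bins <- as.integer(bins)
  vals <- if (is.matrix(data)) {
    data
  } else {
    lab <- if (label_column %in% names(data)) label_column else NULL
    as_feature_matrix(data, lab)$values
  }
  ent <- unname(apply(vals, 2, bin_entropy_bits, bins = bins))
  ids <- colnames(vals) %||% paste0("f", seq_len(ncol(vals)))
  out <- tibble(index = seq_len(ncol(vals)), feature_id = ids, entropy = ent)
  attr(out, "bins") <- bins
  out
}

bin_entropy_bits <- function(x, bins) {
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) return(0)
  # equal-width binning over the column's own range; top edge closed
  idx <- pmin(floor((x - lo) / (hi - lo) * bins), bins - 1L) + 1L
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Retain the top-entropy features
#'
#' Second step of the entropy stage: sort the entropies in descending order
#' and keep the first `ec` percent of columns, with a floor of one column so
#' the candidate set is never empty. Ties are broken in favour of the lower
#' original column index.
#'
#' @param entropy Result of [column_entropy()] (or a numeric entropy vector).
#' @param ec Retention percentage in (0, 100].
#' @return Integer vector of `max(1, ceiling(ec/100 * D))` column indices,
#'   in descending-entropy order.
#' @export
select_top_entropy <- function(entropy, ec) {
  if (!is.numeric(ec) || length(ec) != 1 || ec <= 0 || ec > 100) {
    abort("ec must be a percentage in (0, 100]", class = "ecmpa_error_config")
  }
  e <- if (is.data.frame(entropy)) entropy$entropy else as.numeric(entropy)
  d <- length(e)
  keep <- max(1L, as.integer(ceiling(ec / 100 * d)))
  ord <- order(-e, seq_len(d))
  ord[seq_len(keep)]
}

#' Extract a column subset of a feature table
#'
#' Keeps the feature columns at the given (1-based) indices, in the order
#' given, together with the label column. The original column names are
#' retained so the subset can always be mapped back to positions in the
#' original feature space.
#'
#' @param data Feature table (tibble with a label column).
#' @param idx Non-empty vector of unique, in-range column indices (indices
#'   refer to feature columns only, not the label column).
#' @param label_column Label column name.
#' @return Tibble with `length(idx)` feature columns plus the label column.
#' @export
reduce_matrix <- function(data, idx, label_column = "label") {
  fm <- as_feature_matrix(data, label_column)
  if (length(idx) == 0) {
    abort("idx must be non-empty", class = "ecmpa_error_index")
  }
  idx <- as.integer(idx)
  if (anyNA(idx) || any(idx < 1L) || any(idx > fm$D)) {
    abort(sprintf("index out of range 1..%d", fm$D),
          class = "ecmpa_error_index")
  }
  if (anyDuplicated(idx)) {
    abort("duplicate indices", class = "ecmpa_error_index")
  }
  out <- data[c(fm$feature_ids[idx], label_column)]
  as_tibble(out)
}
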