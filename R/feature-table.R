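#' Read a delimited feature table
#'
#' Reads a CSV file with one row per sample, one numeric column per feature,
#' and one class-label column. This is the on-disk form of a fused
#' deep-feature table: each feature column holds one activation (for example
#' a global-average-pool unit of a convolutional backbone) and the label
#' column holds the sample's class.
#'
#' @param path Path to a CSV file with a header row.
#' @param label_column Name of the class-label column. Default `"label"`.
#' @return A tibble whose feature columns are numeric (in file order) and
#'   whose label column is a factor with levels in order of first appearance.
#' @details Every feature cell must parse to a finite number; `NA`, `NaN`,
#'   `Inf` or non-numeric text raise an error. Row order is preserved.
#' @seealso [write_feature_table()], [fuse_features()]
#' @export
read_feature_table <- function(path, label_column = "label") {
  if (!file.exists(path)) {
    abort(paste0("feature table file not found: ", path),
          class = "ecmpa_error_missing_file")
  }
  tbl <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(tbl)) {
    abort(paste0("label column '", label_column, "' not present in ", path),
          class = "ecmpa_error_missing_label")
  }
  feat <- tbl[setdiff(names(tbl), label_column)]
  if (ncol(feat) < 1L) {
    abort("feature table has no feature columns",
          class = "ecmpa_error_invalid_value")
  }
  bad <- !vapply(feat, function(x) is.numeric(x) && all(is.finite(x)),
                 logical(1))
  if (any(bad)) {
    abort(paste0("non-numeric/invalid value in feature column(s): ",
                 paste(names(feat)[bad], collapse = ", ")),
          class = "ecmpa_error_invalid_value")
  }
  labels <- as.character(tbl[[label_column]])
  out <- as_tibble(feat)
  out[[label_column]] <- factor(labels, levels = unique(labels))
  out
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: a write/read round trip reproduces the
#' feature values exactly and the labels identically.
#'
#' @param data Tibble or data frame with numeric feature columns and one
#'   label column, or a numeric matrix (then `labels` must be supplied).
#' @param path Output file path.
#' @param label_column Name of the label column in `data`.
#' @param labels Optional class-label vector paired with a matrix `data`;
#'   must have one entry per row.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, label_column = "label",
                                labels = NULL) {
  if (is.matrix(data)) {
    if (is.null(labels)) {
      abort("a matrix input needs a paired label vector",
            class = "ecmpa_error_missing_label")
    }
    if (length(labels) != nrow(data)) {
      abort("label vector length does not match sample count",
            class = "ecmpa_error_dim_mismatch")
    }
    if (is.null(colnames(data)) && ncol(data) > 0) {
      colnames(data) <- paste0("f", seq_len(ncol(data)))
    }
    data <- as_tibble(data)
    data[[label_column]] <- as.character(labels)
  }
  as_feature_matrix(data, label_column)  # validate invariants before writing
  # 17 significant digits guarantee an exact double round-trip
  out <- data
  for (nm in setdiff(names(out), label_column)) {
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  readr::write_csv(out, path, progress = FALSE, quote = "needed")
  invisible(path)
}

#' Serially fuse two feature tables
#'
#' Column-wise (serial) concatenation of two per-sample feature tables,
#' `Z = [X Y]`: the fused table keeps X's columns first, then Y's, for the
#' same samples in the same row order. Feature names are prefixed (`"x."`,
#' `"y."` by default) so the provenance of each backbone's features is kept
#' and names stay unique. Fusing a 1024-wide and a 1920-wide table yields
#' 2944 features per sample.
#'
#' @param x,y Feature tables (tibbles with a label column, as returned by
#'   [read_feature_table()] or [gen_feature_dataset()]). `y` may omit the
#'   label column; if present, its labels must equal `x`'s.
#' @param label_column Label column name.
#' @param prefixes Length-2 character vector of feature-name prefixes.
#' @return Fused tibble with `ncol(x) + ncol(y)` feature columns and `x`'s
#'   labels.
#' @export
fuse_features <- function(x, y, label_column = "label",
                          prefixes = c("x.", "y.")) {
  fx <- as_feature_matrix(x, label_column)
  has_label_y <- label_column %in% names(y)
  fy <- as_feature_matrix(y, if (has_label_y) label_column else NULL)
  if (fx$n != fy$n) {
    abort(sprintf("sample counts differ: x has %d rows, y has %d", fx$n, fy$n),
          class = "ecmpa_error_dim_mismatch")
  }
  if (has_label_y && !identical(as.character(fx$labels),
                                as.character(fy$labels))) {
    abort("label columns of x and y disagree",
          class = "ecmpa_error_label_mismatch")
  }
  vals <- cbind(fx$values, fy$values)
  colnames(vals) <- c(paste0(prefixes[1], fx$feature_ids),
                      paste0(prefixes[2], fy$feature_ids))
  out <- as_tibble(vals)
  out[[label_column]] <- fx$labels
  out
}

#' Selection-mask utilities
#'
#' A selection mask is a binary (0/1 or logical) vector with one entry per
#' feature column. `mask_to_indices()` returns the 1-based positions of the
#' selected features in ascending order; `apply_mask()` keeps exactly those
#' columns of a feature table, in their original relative order.
#'
#' @param mask Binary or logical vector, one entry per feature column.
#' @param data Feature table (tibble with a label column).
#' @param label_column Label column name.
#' @return `mask_to_indices()`: an integer vector; `apply_mask()`: a tibble
#'   with the selected feature columns plus the label column.
#' @examples
#' mask_to_indices(c(0, 1, 1, 0))  # 2 3
#' @export
mask_to_indices <- function(mask) {
  bits <- validate_mask(mask)
  which(bits)
}

#' @rdname mask_to_indices
#' @export
apply_mask <- function(data, mask, label_column = "label") {
  fm <- as_feature_matrix(data, label_column)
  bits <- validate_mask(mask)
  if (length(bits) != fm$D) {
    abort(sprintf("mask length %d does not match feature count %d",
                  length(bits), fm$D),
          class = "ecmpa_error_dim_mismatch")
  }
  if (!any(bits)) {
    abort("mask selects no features; an empty feature table is not allowed",
          class = "ecmpa_error_empty_mask")
  }
  keep <- c(fm$feature_ids[bits], label_column)
  data[keep]
}

validate_mask <- function(mask) {
  if (is.logical(mask)) {
    if (anyNA(mask)) abort("mask contains NA", class = "ecmpa_error_mask")
    return(mask)
  }
  if (!is.numeric(mask) || anyNA(mask) || !all(mask %in% c(0, 1))) {
    abort("mask entries must all be 0 or 1", class = "ecmpa_error_mask")
  }
  mask > 0.5
}

# Internal canonical form of a feature table: list(values = n x D numeric
# matrix, feature_ids, labels = factor or NULL, n, D). Validates invariants.
as_feature_matrix <- function(data, label_column = "label") {
  if (!is.data.frame(data)) {
    abort("expected a data frame of features", class = "ecmpa_error_type")
  }
  labels <- NULL
  feat <- data
  if (!is.null(label_column)) {
    if (!label_column %in% names(data)) {
      abort(paste0("label column '", label_column, "' not found"),
            class = "ecmpa_error_missing_label")
    }
    raw <- data[[label_column]]
    labels <- if (is.factor(raw)) raw else factor(as.character(raw),
                                                  levels = unique(as.character(raw)))
    feat <- data[setdiff(names(data), label_column)]
  }
  if (ncol(feat) < 1L) {
    abort("feature table must have at least one feature column (D >= 1)",
          class = "ecmpa_error_invalid_value")
  }
  if (nrow(feat) < 1L) {
    abort("feature table must have at least one row",
          class = "ecmpa_error_invalid_value")
  }
  ok <- vapply(feat, function(x) is.numeric(x) && all(is.finite(x)), logical(1))
  if (!all(ok)) {
    abort(paste0("non-numeric/invalid value in feature column(s): ",
                 paste(names(feat)[!ok], collapse = ", ")),
          class = "ecmpa_error_invalid_value")
  }
  if (anyDuplicated(names(feat))) {
    abort("feature names must be unique", class = "ecmpa_error_invalid_value")
  }
  if (!is.null(labels) && length(labels) != nrow(feat)) {
    abort("label vector length does not match sample count",
          class = "ecmpa_error_dim_mismatch")
  }
  list(values = as.matrix(feat), feature_ids = names(feat), labels = labels,
       n = nrow(feat), D = ncol(feat))
}
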