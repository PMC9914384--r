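#' Stratified train/test split of a feature table
#'
#' Splits rows into disjoint, exhaustive train and test sets, stratified by
#' class, deterministic under `seed`.
#'
#' @param data Feature table (tibble with a label column).
#' @param train_fraction Fraction of each class assigned to the training
#'   side, in (0, 1).
#' @param seed Integer RNG seed.
#' @param label_column Label column name.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1,
                          label_column = "label") {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)", class = "ecmpa_error_config")
  }
  fm <- as_feature_matrix(data, label_column)
  part <- withr::with_seed(seed,
                           stratified_split(fm$labels, 1 - train_fraction))
  list(train = data[part$train, , drop = FALSE],
       test = data[part$test, , drop = FALSE])
}

#' Train and evaluate a classifier on selected features
#'
#' Fits a k-NN or SVM classifier on the training table and evaluates it on
#' the test table, reporting overall accuracy, the confusion matrix (rows =
#' true class), and per-class true-positive and false-negative rates
#' (row-normalized, so `TPR + FNR = 1` per class). SVM kernels mirror the
#' common naming: `linear`, `quadratic` (polynomial degree 2), `cubic`
#' (polynomial degree 3), and `rbf`; multiclass SVM uses one-vs-one voting
#' (via \pkg{e1071}). Polynomial kernels use `coef0 = 1` and regularization
#' constant `cost = 1`.
#'
#' @param train,test Feature tables with the same columns.
#' @param classifier `"knn"` or `"svm"`.
#' @param kernel SVM kernel id (ignored for knn).
#' @param k Neighbour count for knn.
#' @param cost SVM regularization constant.
#' @param label_column Label column name.
#' @return Object of class `eval_report`; see [eval_report()].
#' @export
train_eval_classifier <- function(train, test, classifier = c("knn", "svm"),
                                  kernel = c("linear", "quadratic", "cubic",
                                             "rbf"),
                                  k = 5, cost = 1, label_column = "label") {
  classifier <- match.arg(classifier)
  tr <- as_feature_matrix(train, label_column)
  te <- as_feature_matrix(test, label_column)
  if (!identical(tr$feature_ids, te$feature_ids)) {
    abort("train and test feature columns differ",
          class = "ecmpa_error_dim_mismatch")
  }
  truth <- factor(as.character(te$labels), levels = levels(tr$labels))
  if (classifier == "knn") {
    pred <- knn_predict(tr$values, tr$labels, te$values, k = k)
    spec_id <- paste0("knn(", k, ")")
  } else {
    kernel <- match.arg(kernel)
    svm_args <- switch(kernel,
      linear = list(kernel = "linear"),
      quadratic = list(kernel = "polynomial", degree = 2, coef0 = 1),
      cubic = list(kernel = "polynomial", degree = 3, coef0 = 1),
      rbf = list(kernel = "radial"))
    fit <- do.call(e1071::svm,
                   c(list(x = tr$values, y = tr$labels, cost = cost,
                          scale = FALSE), svm_args))
    pred <- predict(fit, te$values)
    spec_id <- paste0("svm(", kernel, ")")
  }
  eval_report(truth, pred, classifier = spec_id)
}

#' Build an evaluation report from truth and predictions
#'
#' @param truth,predicted Factors (or vectors coercible to factors with the
#'   same level set) of true and predicted class labels.
#' @param classifier Identifier string stored in the report.
#' @return Object of class `eval_report`: list with `accuracy`, `confusion`
#'   (C x C count matrix, rows = true class), `per_class` (tibble with
#'   `class`, `n`, `tpr`, `fnr`), and `classifier`.
#' @export
eval_report <- function(truth, predicted, classifier = "classifier") {
  if (!is.factor(truth)) truth <- factor(truth)
  predicted <- factor(as.character(predicted), levels = levels(truth))
  if (length(truth) != length(predicted)) {
    abort("truth and predicted lengths differ",
          class = "ecmpa_error_dim_mismatch")
  }
  conf <- table(truth = truth, predicted = predicted)
  conf <- unclass(conf)
  n_per <- rowSums(conf)
  tpr <- ifelse(n_per > 0, diag(conf) / n_per, NA_real_)
  structure(list(accuracy = sum(diag(conf)) / sum(conf),
                 confusion = conf,
                 per_class = tibble(class = rownames(conf),
                                    n = as.integer(n_per),
                                    tpr = as.numeric(tpr),
                                    fnr = 1 - as.numeric(tpr)),
                 classifier = classifier),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation of %s: accuracy %.4f on %d test samples\n",
              x$classifier, x$accuracy, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' @describeIn eval_report Per-class TPR/FNR table.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  x$per_class
}

#' @describeIn eval_report One-row accuracy summary.
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble(classifier = x$classifier, accuracy = x$accuracy,
         n_test = sum(x$confusion), n_classes = nrow(x$confusion))
}

#' One-way analysis of variance on grouped accuracy values
#'
#' Standard one-way ANOVA decomposition comparing group means (for example
#' the classification accuracies of several classifiers over repeated
#' runs): `SS_total = SS_between + SS_within`, `F = MS_between/MS_within`,
#' with the p-value from the upper tail of the F distribution at
#' (`df_between`, `df_within`) degrees of freedom. When every value is
#' identical (zero variance everywhere) the F ratio is 0/0; by convention
#' the report is `F = 0`, `p = 1`. The decomposition is obtained with
#' [stats::aov()].
#'
#' @param groups Named (or unnamed) list of numeric vectors, one per group,
#'   each of length >= 2; or a data frame with columns `value` and `group`.
#' @return Object of class `anova_table`: list with `ss_between`,
#'   `ss_within`, `ss_total`, `df_between`, `df_within`, `df_total`,
#'   `ms_between`, `ms_within`, `statistic` (F), and `p_value`.
#' @export
anova_one_way <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    df <- data.frame(value = groups$value, group = factor(groups$group))
  } else {
    if (length(groups) < 2) {
      abort("need at least 2 groups", class = "ecmpa_error_config")
    }
    sizes <- lengths(groups)
    if (any(sizes < 2)) {
      abort("every group needs at least 2 values",
            class = "ecmpa_error_config")
    }
    nm <- names(groups) %||% paste0("g", seq_along(groups))
    if (is.null(names(groups))) names(groups) <- nm
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(names(groups), lengths(groups))))
  }
  if (nlevels(df$group) < 2) {
    abort("need at least 2 groups", class = "ecmpa_error_config")
  }
  # suppress the perfect-fit warning; the 0/0 case is handled by convention
  tab <- suppressWarnings(anova(aov(value ~ group, data = df)))
  ss_b <- tab$`Sum Sq`[1]
  ss_w <- tab$`Sum Sq`[2]
  df_b <- tab$Df[1]
  df_w <- tab$Df[2]
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  if (ss_b <= .Machine$double.eps^0.75 && ss_w <= .Machine$double.eps^0.75) {
    f_stat <- 0
    p <- 1
  } else {
    f_stat <- ms_b / ms_w
    p <- f_pvalue(f_stat, df_b, df_w)
  }
  structure(list(ss_between = ss_b, ss_within = ss_w, ss_total = ss_b + ss_w,
                 df_between = df_b, df_within = df_w, df_total = df_b + df_w,
                 ms_between = ms_b, ms_within = ms_w,
                 statistic = f_stat, p_value = p),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("One-way ANOVA\n")
  cat(sprintf("  between: SS = %.6g, df = %d, MS = %.6g\n",
              x$ss_between, x$df_between, x$ms_between))
  cat(sprintf("  within:  SS = %.6g, df = %d, MS = %.6g\n",
              x$ss_within, x$df_within, x$ms_within))
  cat(sprintf("  F = %.4f, p = %.4f\n", x$statistic, x$p_value))
  invisible(x)
}

#' @describeIn anova_one_way Source-by-source decomposition table.
#' @param x An `anova_table`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.anova_table <- function(x, ...) {
  tibble(source = c("between", "within", "total"),
         ss = c(x$ss_between, x$ss_within, x$ss_total),
         df = c(x$df_between, x$df_within, x$df_total),
         ms = c(x$ms_between, x$ms_within, NA_real_),
         statistic = c(x$statistic, NA_real_, NA_real_),
         p_value = c(x$p_value, NA_real_, NA_real_))
}

#' @describeIn anova_one_way One-row F/p summary.
#' @exportS3Method generics::glance
glance.anova_table <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         df_between = x$df_between, df_within = x$df_within)
}

#' Upper-tail F probability
#'
#' `P(F(d1, d2) > F)`, the p-value of an observed F statistic. For
#' `d1 = 2` this equals the closed form `(1 + F*d1/d2)^(-d2/2)`.
#'
#' @param f Observed F statistic (>= 0).
#' @param d1,d2 Numerator and denominator degrees of freedom.
#' @return Probability in \[0, 1\].
#' @examples
#' f_pvalue(0.37, 2, 6)  # about 0.705
#' @export
f_pvalue <- function(f, d1, d2) {
  if (f < 0 || d1 < 1 || d2 < 1) {
    abort("need f >= 0 and d1, d2 >= 1", class = "ecmpa_error_config")
  }
  pf(f, d1, d2, lower.tail = FALSE)
}

#' ANOVA assumption checks
#'
#' `variance_homogeneity()` runs Bartlett's test of equal group variances
#' (chi-squared upper-tail p-value); `normality()` runs the Shapiro-Wilk
#' test on one sample (higher p = more consistent with normality). Both
#' delegate to the standard \pkg{stats} routines.
#'
#' @param groups As in [anova_one_way()].
#' @return A list with `statistic` and `p_value`.
#' @export
variance_homogeneity <- function(groups) {
  if (is.data.frame(groups)) {
    values <- split(groups$value, groups$group)
  } else {
    values <- groups
  }
  if (any(vapply(values, function(g) var(g) == 0, logical(1)))) {
    abort("Bartlett's test is undefined for a zero-variance group",
          class = "ecmpa_error_config")
  }
  bt <- bartlett.test(values)
  list(statistic = unname(bt$statistic), p_value = bt$p.value)
}

#' @rdname variance_homogeneity
#' @param x Numeric vector (3 to 5000 values).
#' @export
normality <- function(x) {
  sw <- shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}
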