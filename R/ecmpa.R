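#' ECMPA configuration
#'
#' All tunables of the two-stage entropy-controlled marine predators
#' selector. Stage 1 keeps the top `ec` percent of feature columns by
#' Shannon entropy ([column_entropy()], [select_top_entropy()]); stage 2
#' runs the marine predators optimizer over \eqn{[lb, ub]^{d_2}} where an
#' agent position is binarized against the threshold `t` and scored by the
#' holdout misclassification error of a k-nearest-neighbour classifier.
#'
#' @param ec Entropy retention percentage in (0, 100]. Default 5.
#' @param t Binarization threshold; a feature is selected when its agent
#'   coordinate is strictly greater than `t`. Must lie in \[lb, ub\].
#'   Default 0.5, the midpoint of the default unit box, so the expected
#'   initial subset size is half the retained dimensions.
#' @param ho Holdout (test) fraction of the fitness partition, in (0, 1).
#' @param k Neighbour count of the fitness classifier.
#' @param entropy_bins Histogram bins of the entropy estimator.
#' @param N,IMax,P,FADs,beta,lb,ub Marine predators parameters, see
#'   [mpa_params()].
#' @param resample_split If `TRUE`, the fitness partition is redrawn at
#'   every cost evaluation; by default it is drawn once per run (stratified,
#'   seeded) and reused, which keeps costs comparable across iterations.
#' @param seed Integer seed; all randomness of the run flows from it.
#' @return A validated list of class `ecmpa_config`.
#' @export
ecmpa_config <- function(ec = 5, t = 0.5, ho = 0.2, k = 5,
                         entropy_bins = 256, N = 20, IMax = 30, P = 0.5,
                         FADs = 0.2, beta = 1.5, lb = 0, ub = 1,
                         resample_split = FALSE, seed = 1) {
  cfg <- list(ec = ec, t = t, ho = ho, k = as.integer(k),
              entropy_bins = as.integer(entropy_bins), N = as.integer(N),
              IMax = as.integer(IMax), P = P, FADs = FADs, beta = beta,
              lb = lb, ub = ub, resample_split = isTRUE(resample_split),
              seed = as.integer(seed))
  if (cfg$ec <= 0 || cfg$ec > 100) {
    abort("ec must be in (0, 100]", class = "ecmpa_error_config")
  }
  if (cfg$t < cfg$lb || cfg$t > cfg$ub) {
    abort("threshold t must lie in [lb, ub]", class = "ecmpa_error_config")
  }
  if (cfg$ho <= 0 || cfg$ho >= 1) {
    abort("ho must be in (0, 1)", class = "ecmpa_error_config")
  }
  if (cfg$k < 1) abort("k must be >= 1", class = "ecmpa_error_config")
  structure(cfg, class = "ecmpa_config")
}

#' Binarize an agent position into a selection mask
#'
#' Bit `j` is 1 exactly when `agent[j] > t` (strict inequality, so a
#' coordinate equal to the threshold is not selected).
#'
#' @param agent Numeric vector (an optimizer position).
#' @param t Scalar threshold.
#' @return Logical selection mask of the same length.
#' @export
binarize <- function(agent, t) {
  agent > t
}

#' Wrapper fitness: k-NN holdout error of a feature subset
#'
#' The cost of a candidate mask is the misclassification fraction of a
#' k-nearest-neighbour classifier (Euclidean, majority vote, deterministic
#' tie-breaking) trained on the masked training rows and evaluated on the
#' masked test rows of a fixed partition. The empty subset costs 1.0 (the
#' worst possible error) without fitting, which keeps the objective total.
#'
#' @param mask Logical/binary selection mask over the columns of `values`.
#' @param values Numeric matrix of candidate features (rows = samples).
#' @param labels Factor of class labels, one per row.
#' @param partition List with integer `train` and `test` row indices.
#' @param k Neighbour count.
#' @return Cost in \[0, 1\].
#' @export
cost_function <- function(mask, values, labels, partition, k = 5) {
  bits <- validate_mask(mask)
  if (length(bits) != ncol(values)) {
    abort("mask length does not match feature count",
          class = "ecmpa_error_dim_mismatch")
  }
  if (!any(bits)) return(1.0)
  sub <- values[, bits, drop = FALSE]
  knn_error(sub[partition$train, , drop = FALSE], labels[partition$train],
            sub[partition$test, , drop = FALSE], labels[partition$test],
            k = k)
}

#' Entropy-controlled marine predators feature selection
#'
#' Runs the full two-stage ECMPA selector on a feature table. Stage 1 ranks
#' the columns by unsupervised Shannon entropy and keeps the top `ec`
#' percent. Stage 2 searches the continuous box \eqn{[lb, ub]^{d_2}} over
#' the retained columns with the marine predators optimizer; a position is
#' mapped to a feature subset by thresholding at `t`, and its fitness is
#' the k-NN holdout error of that subset. The best agent's subset, mapped
#' back to positions in the original feature space, is the selection.
#'
#' @param data Feature table: tibble with numeric feature columns and a
#'   label column (at least two classes).
#' @param config An [ecmpa_config()] object.
#' @param label_column Label column name.
#' @return Object of class `ecmpa_result`: list with
#'   \describe{
#'     \item{selected_indices}{1-based positions of the selected features in
#'       the original feature space, ascending.}
#'     \item{selected_features}{their column names.}
#'     \item{retained_indices}{entropy-stage survivors (descending-entropy
#'       order), a superset of `selected_indices`.}
#'     \item{mask}{logical mask over the retained set.}
#'     \item{best_cost}{final fitness (k-NN holdout error) of the selection.}
#'     \item{trace}{per-iteration best-cost tibble (non-increasing).}
#'     \item{n_features}{original feature count D.}
#'     \item{config}{the configuration echo.}
#'   }
#'   Deterministic under `config$seed`.
#' @examples
#' sim <- gen_feature_dataset(n = 100, n_features = 40, n_informative = 5,
#'                            n_classes = 2, effect = 3, seed = 1)
#' res <- run_ecmpa(sim$data, ecmpa_config(ec = 50, IMax = 10, N = 10, seed = 1))
#' res$selected_indices
#' @export
run_ecmpa <- function(data, config = ecmpa_config(), label_column = "label") {
  stopifnot(inherits(config, "ecmpa_config"))
  fm <- as_feature_matrix(data, label_column)
  if (is.null(fm$labels) || nlevels(fm$labels) < 2) {
    abort("need at least 2 classes for wrapper selection",
          class = "ecmpa_error_config")
  }
  # stage 1: entropy-controlled reduction (unsupervised)
  ent <- column_entropy(fm$values, bins = config$entropy_bins)
  retained <- select_top_entropy(ent, config$ec)
  d2 <- length(retained)
  F2 <- fm$values[, retained, drop = FALSE]

  # stage 2: marine predators search over the retained dimensions
  labels <- fm$labels
  withr::with_seed(config$seed, {
    partition <- stratified_split(labels, config$ho)
    if (length(partition$train) < config$k) {
      abort("fewer training rows than k neighbours",
            class = "ecmpa_error_too_few_rows")
    }
    cost <- if (config$resample_split) {
      function(x) {
        part <- stratified_split(labels, config$ho)
        cost_function(binarize(x, config$t), F2, labels, part, k = config$k)
      }
    } else {
      function(x) {
        cost_function(binarize(x, config$t), F2, labels, partition,
                      k = config$k)
      }
    }
    params <- mpa_params(d = d2, N = config$N, IMax = config$IMax,
                         P = config$P, FADs = config$FADs, beta = config$beta,
                         lb = config$lb, ub = config$ub,
                         seed = sample.int(.Machine$integer.max, 1))
    opt <- optimize_mpa(cost, params)
  })
  mask <- binarize(opt$best, config$t)
  selected <- sort(retained[mask])
  structure(list(selected_indices = selected,
                 selected_features = fm$feature_ids[selected],
                 retained_indices = retained,
                 retained_features = fm$feature_ids[retained],
                 mask = mask,
                 best_cost = opt$best_cost,
                 trace = opt$trace,
                 evaluations = opt$evaluations,
                 n_features = fm$D,
                 partition = partition,
                 config = config),
            class = "ecmpa_result")
}

#' @export
print.ecmpa_result <- function(x, ...) {
  cat("Entropy-controlled marine predators feature selection\n")
  cat(sprintf("  features: %d -> retained %d (entropy stage) -> selected %d\n",
              x$n_features, length(x$retained_indices),
              length(x$selected_indices)))
  cat(sprintf("  reduction: %.2f%%\n",
              100 * (1 - length(x$selected_indices) / x$n_features)))
  cat(sprintf("  best cost (k-NN holdout error): %.4f over %d evaluations\n",
              x$best_cost, x$evaluations))
  invisible(x)
}

#' @describeIn run_ecmpa Per-feature selection table: one row per original
#'   feature that survived the entropy stage, with its entropy-stage rank
#'   and whether it was finally selected.
#' @param x,object An `ecmpa_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ecmpa_result <- function(x, ...) {
  tibble(index = x$retained_indices,
         feature_id = x$retained_features,
         entropy_rank = seq_along(x$retained_indices),
         selected = x$retained_indices %in% x$selected_indices)
}

#' @describeIn run_ecmpa One-row summary: counts, reduction percentage and
#'   final cost.
#' @exportS3Method generics::glance
glance.ecmpa_result <- function(x, ...) {
  tibble(n_features = x$n_features,
         n_retained = length(x$retained_indices),
         n_selected = length(x$selected_indices),
         reduction_pct = 100 * (1 - length(x$selected_indices) / x$n_features),
         best_cost = x$best_cost,
         evaluations = x$evaluations)
}

#' @describeIn run_ecmpa Convergence plot of the best cost per iteration.
#' @exportS3Method ggplot2::autoplot
autoplot.ecmpa_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_cost)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Best cost (k-NN holdout error)",
                  title = "ECMPA convergence") +
    ggplot2::theme_minimal()
}
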