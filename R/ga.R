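#' Genetic-algorithm baseline configuration
#'
#' Textbook generational GA over binary feature-subset chromosomes, used as
#' the convergence baseline against ECMPA: tournament selection (size 2),
#' uniform crossover, per-bit mutation, and elitism. The fitness is the
#' identical k-NN holdout cost used by ECMPA ([cost_function()]), on the
#' same fixed partition, so costs of identical masks are bit-identical
#' across the two optimizers.
#'
#' @param N Population size.
#' @param IMax Number of generations.
#' @param pc Crossover probability per offspring pair.
#' @param pm Per-bit mutation probability; `NULL` (default) means `1/d2`,
#'   set at run time from the chromosome length.
#' @param elitism Number of best individuals copied unchanged (>= 0, < N).
#' @param seed Integer RNG seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(N = 20, IMax = 30, pc = 0.8, pm = NULL, elitism = 1,
                      seed = 1) {
  cfg <- list(N = as.integer(N), IMax = as.integer(IMax), pc = pc, pm = pm,
              elitism = as.integer(elitism), seed = as.integer(seed))
  if (cfg$pc < 0 || cfg$pc > 1) {
    abort("pc must be in [0, 1]", class = "ecmpa_error_config")
  }
  if (!is.null(pm) && (pm < 0 || pm > 1)) {
    abort("pm must be in [0, 1]", class = "ecmpa_error_config")
  }
  if (cfg$elitism < 0 || cfg$elitism >= cfg$N) {
    abort("need 0 <= elitism < N", class = "ecmpa_error_config")
  }
  structure(cfg, class = "ga_config")
}

#' Run the GA baseline on a (reduced) feature table
#'
#' Searches binary masks over the feature columns of `data` with the same
#' k-NN holdout fitness as ECMPA's stage 2, on a fixed stratified partition
#' drawn once from the seed. Pass the entropy-reduced table to compare
#' against ECMPA's stage 2 on identical footing.
#'
#' @param data Feature table (tibble with a label column).
#' @param config A [ga_config()] object.
#' @param ho Holdout fraction of the fitness partition.
#' @param k Neighbour count of the fitness classifier.
#' @param label_column Label column name.
#' @return Object of class `ga_result`: list with `best_mask` (logical),
#'   `selected_indices`, `best_cost`, `trace` (tibble `iteration`,
#'   `best_cost`, `cum_evals`), `evaluations`, and `config`.
#' @export
run_ga <- function(data, config = ga_config(), ho = 0.2, k = 5,
                   label_column = "label") {
  stopifnot(inherits(config, "ga_config"))
  fm <- as_feature_matrix(data, label_column)
  if (is.null(fm$labels) || nlevels(fm$labels) < 2) {
    abort("need at least 2 classes", class = "ecmpa_error_config")
  }
  d2 <- fm$D
  N <- config$N
  pm <- config$pm %||% (1 / d2)
  withr::with_seed(config$seed, {
    partition <- stratified_split(fm$labels, ho)
    score <- function(bits) {
      cost_function(bits, fm$values, fm$labels, partition, k = k)
    }
    pop <- matrix(runif(N * d2) < 0.5, N, d2)
    fit <- vapply(seq_len(N), function(i) score(pop[i, ]), numeric(1))
    evals <- N
    best_i <- which.min(fit)
    best_mask <- pop[best_i, ]
    best_cost <- fit[best_i]
    trace <- numeric(config$IMax)
    cum <- numeric(config$IMax)
    for (gen in seq_len(config$IMax)) {
      ord <- order(fit)
      new_pop <- matrix(FALSE, N, d2)
      n_elite <- config$elitism
      if (n_elite > 0) new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ]
      i <- n_elite
      while (i < N) {
        p1 <- tournament_pick(fit, 2)
        p2 <- tournament_pick(fit, 2)
        kids <- crossover_uniform(pop[p1, ], pop[p2, ], config$pc)
        for (kid in kids) {
          if (i >= N) break
          i <- i + 1
          flip <- runif(d2) < pm
          new_pop[i, ] <- xor(kid, flip)
        }
      }
      pop <- new_pop
      fit <- vapply(seq_len(N), function(j) score(pop[j, ]), numeric(1))
      evals <- evals + N
      gen_best <- which.min(fit)
      if (fit[gen_best] < best_cost) {
        best_cost <- fit[gen_best]
        best_mask <- pop[gen_best, ]
      }
      trace[gen] <- best_cost
      cum[gen] <- evals
    }
    structure(list(best_mask = best_mask,
                   selected_indices = which(best_mask),
                   best_cost = best_cost,
                   trace = tibble(iteration = seq_len(config$IMax),
                                  best_cost = trace, cum_evals = cum),
                   evaluations = evals,
                   partition = partition,
                   config = config),
              class = "ga_result")
  })
}

tournament_pick <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = TRUE)
  cand[which.min(fit[cand])]
}

crossover_uniform <- function(a, b, pc) {
  if (runif(1) < pc) {
    swap <- runif(length(a)) < 0.5
    child1 <- ifelse(swap, b, a)
    child2 <- ifelse(swap, a, b)
    list(as.logical(child1), as.logical(child2))
  } else {
    list(a, b)
  }
}

#' @export
print.ga_result <- function(x, ...) {
  cat("Genetic-algorithm baseline feature selection\n")
  cat(sprintf("  selected %d features; best cost %.4f over %d evaluations\n",
              length(x$selected_indices), x$best_cost, x$evaluations))
  invisible(x)
}

#' Align two convergence traces at equal evaluation budgets
#'
#' Compares the best-so-far cost trajectories of two optimizers, aligned by
#' cumulative fitness evaluations so the comparison is budget-fair. Both
#' runs must have spent the same total number of evaluations.
#'
#' @param trace_a,trace_b Trace tibbles with columns `iteration`,
#'   `best_cost`, `cum_evals` (as produced by [run_ecmpa()], [run_ga()], or
#'   [optimize_mpa()]), or result objects carrying a `$trace`.
#' @param labels Length-2 character vector naming the two traces.
#' @param threshold Optional cost threshold; the summary reports the first
#'   evaluation count at which each trace reaches it.
#' @return Object of class `convergence_comparison`: list with `aligned`
#'   (long tibble: `algorithm`, `iteration`, `cum_evals`, `best_cost`) and
#'   `summary` (per-algorithm final cost and evaluations-to-threshold).
#' @export
compare_convergence <- function(trace_a, trace_b,
                                labels = c("A", "B"), threshold = NULL) {
  ta <- extract_trace(trace_a)
  tb <- extract_trace(trace_b)
  if (max(ta$cum_evals) != max(tb$cum_evals)) {
    abort(sprintf("evaluation budgets differ: %d vs %d",
                  max(ta$cum_evals), max(tb$cum_evals)),
          class = "ecmpa_error_budget")
  }
  ta$algorithm <- labels[1]
  tb$algorithm <- labels[2]
  aligned <- dplyr::bind_rows(ta, tb)[, c("algorithm", "iteration",
                                          "cum_evals", "best_cost")]
  thr <- threshold %||% NA_real_
  summarise_one <- function(tr, lab) {
    reach <- if (!is.na(thr)) {
      hit <- which(tr$best_cost <= thr)
      if (length(hit)) tr$cum_evals[hit[1]] else NA_real_
    } else NA_real_
    tibble(algorithm = lab, final_cost = tr$best_cost[nrow(tr)],
           evals_to_threshold = reach, total_evals = max(tr$cum_evals))
  }
  summary <- dplyr::bind_rows(summarise_one(ta, labels[1]),
                              summarise_one(tb, labels[2]))
  structure(list(aligned = aligned, summary = summary, threshold = threshold),
            class = "convergence_comparison")
}

extract_trace <- function(x) {
  tr <- if (is.data.frame(x)) x else x$trace
  if (is.null(tr) || !all(c("iteration", "best_cost", "cum_evals") %in%
                          names(tr))) {
    abort("not a convergence trace", class = "ecmpa_error_type")
  }
  as_tibble(tr)
}

#' @export
print.convergence_comparison <- function(x, ...) {
  cat("Convergence comparison (aligned by fitness evaluations)\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn compare_convergence Long aligned trace table.
#' @param x,object A `convergence_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.convergence_comparison <- function(x, ...) {
  x$aligned
}

#' @describeIn compare_convergence Per-algorithm summary table.
#' @exportS3Method generics::glance
glance.convergence_comparison <- function(x, ...) {
  x$summary
}

#' @describeIn compare_convergence Overlaid convergence curves.
#' @exportS3Method ggplot2::autoplot
autoplot.convergence_comparison <- function(object, ...) {
  ggplot2::ggplot(object$aligned,
                  ggplot2::aes(x = .data$cum_evals, y = .data$best_cost,
                               colour = .data$algorithm)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Fitness evaluations", y = "Best cost",
                  colour = NULL, title = "Convergence comparison") +
    ggplot2::theme_minimal()
}
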