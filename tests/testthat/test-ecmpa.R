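test_that("binarize thresholds strictly", {
  expect_equal(binarize(c(0.2, 0.7, 0.5), 0.5), c(FALSE, TRUE, FALSE))
  expect_true(all(!binarize(c(0.1, 0.4), 0.5)))
  expect_true(all(binarize(c(0.1, 0.4), 0)))   # t = lb, all entries above
})

test_that("the wrapper cost is the k-NN holdout error", {
  sep <- separable_table(n = 80, n_features = 6, n_informative = 2)
  fm <- as.matrix(sep$data[1:6])
  lab <- sep$data$label
  part <- withr::with_seed(1, ecmpa:::stratified_split(lab, 0.25))

  # empty subset costs 1 without fitting
  expect_equal(cost_function(rep(FALSE, 6), fm, lab, part), 1.0)
  # planted features separate the classes perfectly
  planted_mask <- seq_len(6) %in% sep$planted
  expect_equal(cost_function(planted_mask, fm, lab, part, k = 5), 0)
  expect_error(cost_function(rep(TRUE, 5), fm, lab, part),
               class = "ecmpa_error_dim_mismatch")
  # too few training rows for k neighbours
  tiny <- list(train = part$train[1:3], test = part$test)
  expect_error(cost_function(planted_mask, fm, lab, tiny, k = 5),
               class = "ecmpa_error_too_few_rows")
})

test_that("cost on permuted labels sits at chance level", {
  sim <- gen_feature_dataset(n = 500, n_features = 30, n_informative = 10,
                             n_classes = 5, effect = 3, seed = 9)
  withr::with_seed(21, {
    lab <- sample(sim$data$label)   # break any feature-label association
    part <- ecmpa:::stratified_split(lab, 0.2)
  })
  fm <- as.matrix(sim$data[1:30])
  cost <- cost_function(rep(TRUE, 30), fm, lab, part, k = 5)
  # 5 balanced classes: expected error 0.8, binomial SE ~ 0.04 on 100 tests
  expect_gt(cost, 0.65)
  expect_lt(cost, 0.95)
})

test_that("run_ecmpa keeps the two-stage containment invariants", {
  sim <- gen_feature_dataset(n = 120, n_features = 50, n_informative = 5,
                             n_classes = 3, effect = 3, seed = 2)
  for (ec in c(10, 37, 100)) {
    res <- run_ecmpa(sim$data, ecmpa_config(ec = ec, IMax = 5, N = 6, seed = 1))
    expect_length(res$retained_indices, max(1, ceiling(ec * 50 / 100)))
    expect_true(all(res$selected_indices %in% res$retained_indices))
    expect_true(all(res$retained_indices %in% 1:50))
    expect_true(all(diff(res$trace$best_cost) <= 0))
    expect_true(res$best_cost >= 0 && res$best_cost <= 1)
  }
})

test_that("reported best cost re-evaluates to itself on the run partition", {
  sim <- gen_feature_dataset(n = 100, n_features = 20, n_informative = 4,
                             n_classes = 2, effect = 2, seed = 6)
  res <- run_ecmpa(sim$data, ecmpa_config(ec = 100, IMax = 8, N = 8, seed = 5))
  fm <- as.matrix(sim$data[1:20])[, res$retained_indices, drop = FALSE]
  re_cost <- cost_function(res$mask, fm, sim$data$label, res$partition, k = 5)
  expect_equal(re_cost, res$best_cost)
})

test_that("identical seeds give identical selection results", {
  sim <- gen_feature_dataset(n = 90, n_features = 30, n_informative = 4,
                             n_classes = 3, effect = 3, seed = 8)
  cfg <- ecmpa_config(ec = 50, IMax = 8, N = 8, seed = 13)
  r1 <- run_ecmpa(sim$data, cfg)
  r2 <- run_ecmpa(sim$data, cfg)
  expect_identical(r1$selected_indices, r2$selected_indices)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_cost, r2$best_cost)
})

test_that("ECMPA matches the exhaustive subset optimum on a small box", {
  hits <- 0
  for (s in 1:3) {
    sim <- gen_feature_dataset(n = 100, n_features = 8, n_informative = 3,
                               n_classes = 2, effect = 3, sparsity = 0.25,
                               seed = s)
    res <- run_ecmpa(sim$data, ecmpa_config(ec = 100, IMax = 30, N = 10,
                                            seed = s))
    fm <- as.matrix(sim$data[1:8])[, res$retained_indices, drop = FALSE]
    best <- exhaustive_best_cost(fm, sim$data$label, res$partition, k = 5)
    hits <- hits + (abs(res$best_cost - best) < 1e-12)
  }
  expect_gte(hits, 2)
})

test_that("per-evaluation resampling mode runs and stays in contract", {
  sim <- gen_feature_dataset(n = 80, n_features = 12, n_informative = 3,
                             n_classes = 2, effect = 3, seed = 3)
  res <- run_ecmpa(sim$data, ecmpa_config(ec = 100, IMax = 5, N = 6,
                                          resample_split = TRUE, seed = 2))
  expect_true(res$best_cost >= 0 && res$best_cost <= 1)
  expect_true(all(res$selected_indices %in% 1:12))
})

test_that("selection result methods expose tidy summaries", {
  sim <- gen_feature_dataset(n = 80, n_features = 20, n_informative = 3,
                             n_classes = 2, effect = 3, seed = 4)
  res <- run_ecmpa(sim$data, ecmpa_config(ec = 50, IMax = 5, N = 6, seed = 1))
  td <- tidy(res)
  expect_equal(nrow(td), length(res$retained_indices))
  expect_equal(sum(td$selected), length(res$selected_indices))
  gl <- glance(res)
  expect_equal(gl$n_selected, length(res$selected_indices))
  expect_equal(gl$reduction_pct, 100 * (1 - gl$n_selected / 20))
  expect_s3_class(autoplot(res), "ggplot")
  expect_output(print(res), "reduction")
})

test_that("run_ecmpa validates inputs", {
  one_class <- tibble::tibble(a = c(1, 2), b = c(3, 4), label = c("x", "x"))
  expect_error(run_ecmpa(one_class, ecmpa_config()),
               class = "ecmpa_error_config")
  expect_error(ecmpa_config(ec = 0), class = "ecmpa_error_config")
  expect_error(ecmpa_config(t = 2), class = "ecmpa_error_config")
  expect_error(ecmpa_config(ho = 1), class = "ecmpa_error_config")
})
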