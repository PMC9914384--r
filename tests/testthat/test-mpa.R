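test_that("step-control factor CF has the right endpoints and decay", {
  expect_equal(compute_cf(0, 50), 1)
  expect_equal(compute_cf(50, 50), 0)
  expect_equal(compute_cf(25, 50), 0.5)    # (1/2)^1
  grid <- sapply(1:49, compute_cf, IMax = 50)
  expect_true(all(diff(grid) < 0))         # strictly decreasing inside (0, IMax)
  expect_error(compute_cf(-1, 50), class = "ecmpa_error_config")
})

test_that("initialization is the affine map of uniforms onto [lb, ub]", {
  p <- mpa_params(d = 3, N = 5, lb = -2, ub = 3, seed = 1)
  testthat::local_mocked_bindings(
    runif = function(n, ...) rep(0, n), .package = "ecmpa")
  expect_true(all(init_population(p) == -2))
  testthat::local_mocked_bindings(
    runif = function(n, ...) rep(1, n), .package = "ecmpa")
  expect_true(all(init_population(p) == 3))
  testthat::local_mocked_bindings(
    runif = function(n, ...) rep(0.3, n), .package = "ecmpa")
  expect_equal(unique(as.vector(init_population(p))), -2 + 0.3 * 5)
})

test_that("population initialization stays in bounds and is seed-stable", {
  p <- mpa_params(d = 10, N = 20, lb = -1, ub = 2, seed = 9)
  a <- withr::with_seed(9, init_population(p))
  b <- withr::with_seed(9, init_population(p))
  expect_identical(a, b)
  expect_true(all(a >= -1 & a <= 2))
  expect_error(mpa_params(d = 2, lb = 1, ub = 1), class = "ecmpa_error_config")
})

test_that("Levy sampler is seeded and heavy-tailed", {
  a <- withr::with_seed(4, sample_levy(1.5, 100))
  b <- withr::with_seed(4, sample_levy(1.5, 100))
  expect_identical(a, b)

  withr::with_seed(1, {
    levy <- sample_levy(1.5, 1e5)
    norm <- rnorm(1e5)
  })
  expect_gt(mean(abs(levy) > 10), mean(abs(norm) > 10))
  expect_gt(mean(abs(levy) > 10), 0)

  # at beta = 2 Mantegna's sigma_u collapses to ~0: draws are finite
  v <- withr::with_seed(2, sample_levy(2, 1000))
  expect_true(all(is.finite(v)))
  expect_lt(var(v), 1)
  expect_error(sample_levy(0, 5), class = "ecmpa_error_config")
})

test_that("movement phases implement the update equations", {
  prey <- matrix(c(0.2, 0.4), 2, 1)
  elite <- 0.8

  # zero Brownian step freezes phase 1
  expect_equal(ecmpa:::phase1_step(prey, elite, RB = prey * 0, R = prey + 1,
                                   P = 0.5), prey)
  # zero Levy step sends phase 3 onto the elite
  p3 <- ecmpa:::phase3_step(prey, elite, RL = prey * 0, P = 0.5, CF = 0.7)
  expect_true(all(p3 == elite))

  # phase 2 predator half, hand-evaluated in 1-d:
  # step = RB*(elite - RB*prey); new = elite + P*CF*step
  CF <- compute_cf(20, 30)
  got <- ecmpa:::phase2_brownian_step(matrix(0.2, 1, 1), 0.8,
                                      RB = matrix(1, 1, 1), P = 0.5, CF = CF)
  expect_equal(got[1, 1], 0.8 + 0.5 * CF * (0.8 - 0.2))

  # phase schedule splits iterations into thirds
  expect_equal(sapply(c(0, 9, 10, 19, 20, 29), ecmpa:::mpa_phase, IMax = 30),
               c(1, 1, 2, 2, 3, 3))
})

test_that("FADs perturbation branches behave as specified", {
  p <- mpa_params(d = 3, N = 4, FADs = 0.2, lb = 0, ub = 1, seed = 1)
  prey <- matrix(0.5, 4, 3)
  pos <- prey[1, ]

  # long-jump branch with a zeroed binary mask leaves the agent in place
  out <- ecmpa:::fads_step_agent(pos, prey, r = 0.1, R = runif(3),
                                 U = rep(0, 3), r1 = NA, r2 = NA,
                                 CF = 0.9, params = p)
  expect_equal(out, pos)
  # difference branch with r1 == r2 leaves the agent in place
  out <- ecmpa:::fads_step_agent(pos, prey, r = 0.9, R = NULL, U = NULL,
                                 r1 = 2, r2 = 2, CF = 0.9, params = p)
  expect_equal(out, pos)
  # long-jump branch adds CF * (lb + R*(ub-lb)) * U
  out <- ecmpa:::fads_step_agent(rep(0, 3), prey, r = 0.1, R = rep(0.5, 3),
                                 U = rep(1, 3), r1 = NA, r2 = NA,
                                 CF = 0.5, params = p)
  expect_equal(out, rep(0.5 * 0.5, 3))

  # with FADs = 0 and identical agents, apply_fads is a fixed point
  p0 <- mpa_params(d = 3, N = 4, FADs = 0, lb = 0, ub = 1, seed = 1)
  same <- matrix(0.3, 4, 3)
  expect_equal(withr::with_seed(5, ecmpa:::apply_fads(same, 1, p0)), same)
})

test_that("memory saving keeps the agent-wise better position", {
  prev <- matrix(1:6, 3, 2)
  curr <- prev + 10
  all_worse <- ecmpa:::memory_save(prev, c(1, 2, 3), curr, c(2, 3, 4))
  expect_equal(all_worse$positions, prev)
  all_better <- ecmpa:::memory_save(prev, c(5, 5, 5), curr, c(1, 2, 3))
  expect_equal(all_better$positions, curr)
  mixed <- ecmpa:::memory_save(prev, c(1, 5, 3), curr, c(2, 2, 3))
  expect_equal(mixed$positions, rbind(prev[1, ], curr[2, ], prev[3, ]))
  expect_equal(mixed$fitness, c(1, 2, 3))   # tie keeps previous
  expect_error(ecmpa:::memory_save(prev, 1:3, curr[1:2, ], 1:2),
               class = "ecmpa_error_dim_mismatch")
})

test_that("the optimizer minimizes a smooth unimodal objective", {
  p <- mpa_params(d = 5, N = 20, IMax = 100, lb = -1, ub = 1, seed = 1)
  res <- optimize_mpa(function(x) sum(x^2), p)
  expect_lte(res$best_cost, 1e-2)
  expect_true(all(res$best >= -1 & res$best <= 1))
})

test_that("optimizer trace is complete, non-increasing and seed-stable", {
  p <- mpa_params(d = 2, N = 2, IMax = 3, lb = 0, ub = 1, seed = 3)
  res <- optimize_mpa(function(x) sum(x), p)
  expect_equal(nrow(res$trace), 3)
  expect_true(all(diff(res$trace$best_cost) <= 0))
  expect_equal(res$evaluations, 2 * 4)

  for (s in c(1, 7)) {
    p <- mpa_params(d = 4, N = 8, IMax = 15, lb = -2, ub = 2, seed = s)
    r1 <- optimize_mpa(function(x) sum(abs(x)), p)
    r2 <- optimize_mpa(function(x) sum(abs(x)), p)
    expect_identical(r1$trace, r2$trace)
    expect_identical(r1$best, r2$best)
    expect_true(all(diff(r1$trace$best_cost) <= 0))
  }
})

test_that("non-finite costs are reported with the offending agent", {
  p <- mpa_params(d = 2, N = 4, IMax = 3, lb = 0, ub = 1, seed = 1)
  expect_error(optimize_mpa(function(x) NaN, p), class = "ecmpa_error_cost")
  expect_error(optimize_mpa(function(x) NaN, p), "agent 1")
})
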