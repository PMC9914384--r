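#' Marine predators algorithm parameters
#'
#' Tunables of the marine predators optimizer over the continuous box
#' \eqn{[lb, ub]^d}. Defaults follow the reference formulation: step
#' constant `P = 0.5`, FADs (fish aggregating devices) perturbation
#' probability `0.2`, and Levy index `beta = 1.5`.
#'
#' @param d Dimension of the search space (number of variables per agent).
#' @param N Population size (>= 2).
#' @param IMax Number of iterations (>= 3, so all three movement phases run).
#' @param P Step-size constant multiplying every movement update.
#' @param FADs Probability of the long-jump perturbation per agent per
#'   iteration, in \[0, 1\].
#' @param beta Levy stability index in (0, 2].
#' @param lb,ub Scalar lower/upper bound applied to every dimension.
#' @param seed Integer RNG seed; every random draw of the optimizer flows
#'   from it.
#' @return A validated list of class `mpa_params`.
#' @export
mpa_params <- function(d, N = 20, IMax = 50, P = 0.5, FADs = 0.2,
                       beta = 1.5, lb = 0, ub = 1, seed = 1) {
  p <- list(d = as.integer(d), N = as.integer(N), IMax = as.integer(IMax),
            P = P, FADs = FADs, beta = beta, lb = lb, ub = ub,
            seed = as.integer(seed))
  if (p$d < 1) abort("d must be >= 1", class = "ecmpa_error_config")
  if (p$N < 2) abort("N must be >= 2", class = "ecmpa_error_config")
  if (p$IMax < 3) abort("IMax must be >= 3", class = "ecmpa_error_config")
  if (p$FADs < 0 || p$FADs > 1) {
    abort("FADs must be in [0, 1]", class = "ecmpa_error_config")
  }
  if (!(p$lb < p$ub)) abort("need lb < ub", class = "ecmpa_error_config")
  if (p$beta <= 0 || p$beta > 2) {
    abort("beta must be in (0, 2]", class = "ecmpa_error_config")
  }
  structure(p, class = "mpa_params")
}

#' Adaptive predator step scale
#'
#' The step-control factor \eqn{CF = (1 - I/I_{max})^{2 I / I_{max}}},
#' decaying from 1 at the first iteration to 0 at the last; it shrinks the
#' elite-guided moves as the search turns from exploration to exploitation.
#'
#' @param I Current iteration, `0 <= I <= IMax`.
#' @param IMax Maximum number of iterations.
#' @return Scalar in \[0, 1\].
#' @examples
#' compute_cf(0, 50)    # 1
#' compute_cf(25, 50)   # 0.5
#' compute_cf(50, 50)   # 0
#' @export
compute_cf <- function(I, IMax) {
  if (I < 0 || I > IMax) abort("need 0 <= I <= IMax",
                               class = "ecmpa_error_config")
  frac <- I / IMax
  if (frac >= 1) return(0)
  (1 - frac)^(2 * frac)
}

#' Levy-flight step sampler (Mantegna's algorithm)
#'
#' Draws heavy-tailed step lengths \eqn{x = u / |v|^{1/\beta}} with
#' \eqn{u \sim N(0, \sigma_u^2)}, \eqn{v \sim N(0, 1)} and Mantegna's
#' closed-form scale
#' \deqn{\sigma_u = \left[\frac{\Gamma(1+\beta)\,\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right]^{1/\beta}.}
#' Draws come from R's global RNG stream, so results are deterministic under
#' `set.seed()`.
#'
#' @param beta Stability index in (0, 2].
#' @param d Number of draws.
#' @return Numeric vector of length `d`.
#' @export
sample_levy <- function(beta, d) {
  if (beta <= 0 || beta > 2) {
    abort("beta must be in (0, 2]", class = "ecmpa_error_config")
  }
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- rnorm(d, 0, sigma_u)
  v <- rnorm(d)
  u / abs(v)^(1 / beta)
}

#' Initialize the search population
#'
#' Each entry is `lb + u * (ub - lb)` with `u ~ Uniform[0,1]` from the
#' global RNG stream (seed the stream before calling for reproducibility).
#'
#' @param params An [mpa_params()] object.
#' @return `N x d` matrix of positions, all inside \[lb, ub\].
#' @export
init_population <- function(params) {
  u <- matrix(runif(params$N * params$d), params$N, params$d)
  params$lb + u * (params$ub - params$lb)
}

# ---- pure movement steps (randomness injected; used by update_prey and by
# the unit tests that pin the update equations) -------------------------------

# Phase 1 (exploration, Brownian): step = RB*(elite - RB*prey);
# prey <- prey + P * R * step.
phase1_step <- function(prey, elite, RB, R, P) {
  step <- RB * (sweep(-RB * prey, 2, elite, "+"))
  prey + P * R * step
}

# Phase 2 first half (Levy prey moves): step = RL*(elite - RL*prey);
# prey <- prey + P * R * step.
phase2_levy_step <- function(prey, elite, RL, R, P) {
  step <- RL * (sweep(-RL * prey, 2, elite, "+"))
  prey + P * R * step
}

# Phase 2 second half / predator moves (Brownian, elite-based):
# step = RB*(elite - RB*prey); prey <- elite + P * CF * step.
phase2_brownian_step <- function(prey, elite, RB, P, CF) {
  step <- RB * (sweep(-RB * prey, 2, elite, "+"))
  sweep(P * CF * step, 2, elite, "+")
}

# Phase 3 (exploitation, Levy): step = RL*(elite - prey);
# prey <- elite + P * CF * step.
phase3_step <- function(prey, elite, RL, P, CF) {
  step <- RL * (sweep(-prey, 2, elite, "+"))
  sweep(P * CF * step, 2, elite, "+")
}

clamp_box <- function(x, lb, ub) {
  x[x < lb] <- lb
  x[x > ub] <- ub
  x
}

# Movement phase index for 0-based iteration I: boundaries at
# floor(IMax/3) and floor(2*IMax/3).
mpa_phase <- function(I, IMax) {
  if (I < floor(IMax / 3)) 1L else if (I < floor(2 * IMax / 3)) 2L else 3L
}

#' One prey-matrix movement update
#'
#' Applies the movement rule of the current phase to the whole population:
#' Brownian exploration steps in the first third of the iterations, a mixed
#' Levy/Brownian regime in the middle third (Levy for the first half of the
#' agents, elite-based Brownian scaled by `P * CF` for the second half), and
#' elite-based Levy exploitation scaled by `P * CF` in the final third.
#' Positions are clamped to \[lb, ub\] afterwards. Levy steps are drawn as
#' `0.05 * sample_levy(beta, d)`, the scaling used by the reference
#' implementation of the optimizer; Brownian steps are standard normal.
#'
#' @param prey `N x d` matrix of current positions.
#' @param elite Length-`d` best-so-far position.
#' @param I Current iteration (0-based, `0 <= I < IMax`).
#' @param params An [mpa_params()] object.
#' @return Updated `N x d` position matrix.
#' @keywords internal
update_prey <- function(prey, elite, I, params) {
  N <- params$N; d <- params$d; P <- params$P
  phase <- mpa_phase(I, params$IMax)
  CF <- compute_cf(I, params$IMax)
  out <- if (phase == 1L) {
    RB <- matrix(rnorm(N * d), N, d)
    R <- matrix(runif(N * d), N, d)
    phase1_step(prey, elite, RB, R, P)
  } else if (phase == 2L) {
    half <- floor(N / 2)
    top <- seq_len(half)
    bottom <- setdiff(seq_len(N), top)
    RL <- matrix(0.05 * sample_levy(params$beta, half * d), half, d)
    R <- matrix(runif(half * d), half, d)
    RB <- matrix(rnorm(length(bottom) * d), length(bottom), d)
    rbind(phase2_levy_step(prey[top, , drop = FALSE], elite, RL, R, P),
          phase2_brownian_step(prey[bottom, , drop = FALSE], elite, RB, P, CF))
  } else {
    RL <- matrix(0.05 * sample_levy(params$beta, N * d), N, d)
    phase3_step(prey, elite, RL, P, CF)
  }
  clamp_box(out, params$lb, params$ub)
}

# FADs long-jump perturbation for a single agent position (pure; randomness
# injected). If r <= FADs: pos + CF * (lb + R*(ub-lb)) * U, with U a binary
# vector; else: pos + (FADs*(1-r)+r) * (prey[r1,] - prey[r2,]).
fads_step_agent <- function(pos, prey, r, R, U, r1, r2, CF, params) {
  if (r <= params$FADs) {
    pos + CF * (params$lb + R * (params$ub - params$lb)) * U
  } else {
    pos + (params$FADs * (1 - r) + r) * (prey[r1, ] - prey[r2, ])
  }
}

#' FADs perturbation of the population
#'
#' With probability `FADs` per agent, add a `CF`-scaled random jump inside
#' the box masked by a random binary vector; otherwise add a scaled
#' difference of two randomly chosen agents. Escapes stagnation in local
#' optima. Positions are clamped to the box.
#'
#' @inheritParams update_prey
#' @keywords internal
apply_fads <- function(prey, I, params) {
  CF <- compute_cf(I, params$IMax)
  out <- prey
  for (i in seq_len(params$N)) {
    r <- runif(1)
    if (r <= params$FADs) {
      R <- runif(params$d)
      U <- as.numeric(runif(params$d) < params$FADs)
      out[i, ] <- fads_step_agent(prey[i, ], prey, r, R, U, NA, NA, CF, params)
    } else {
      r1 <- sample.int(params$N, 1)
      r2 <- sample.int(params$N, 1)
      out[i, ] <- fads_step_agent(prey[i, ], prey, r, NULL, NULL, r1, r2,
                                  CF, params)
    }
  }
  clamp_box(out, params$lb, params$ub)
}

# Agent-wise memory saving: keep whichever of (previous, current) position
# has the strictly lower cost; ties keep the previous position.
memory_save <- function(prev_pos, prev_fit, curr_pos, curr_fit) {
  if (!all(dim(prev_pos) == dim(curr_pos))) {
    abort("population shapes differ", class = "ecmpa_error_dim_mismatch")
  }
  better <- curr_fit < prev_fit
  pos <- prev_pos
  pos[better, ] <- curr_pos[better, , drop = FALSE]
  list(positions = pos, fitness = ifelse(better, curr_fit, prev_fit))
}

eval_population <- function(cost_fn, positions) {
  fit <- vapply(seq_len(nrow(positions)),
                function(i) cost_fn(positions[i, ]), numeric(1))
  bad <- !is.finite(fit)
  if (any(bad)) {
    abort(sprintf("cost function returned a non-finite value for agent %d",
                  which(bad)[1]),
          class = "ecmpa_error_cost")
  }
  fit
}

#' Run the marine predators optimizer
#'
#' Minimizes `cost_fn` over the box \eqn{[lb, ub]^d}: random initialization,
#' then `IMax` iterations of movement update ([update_prey()]), FADs
#' perturbation ([apply_fads()]), evaluation, agent-wise memory saving, and
#' elite update. Fully deterministic under `params$seed` (the global RNG
#' state is left untouched).
#'
#' @param cost_fn Function mapping a length-`d` numeric vector to a finite
#'   scalar cost.
#' @param params An [mpa_params()] object.
#' @return Object of class `mpa_result`: list with `best` (length-`d`
#'   vector), `best_cost`, `trace` (tibble with `iteration`, `best_cost`,
#'   `cum_evals`), `evaluations`, and `params`.
#' @examples
#' p <- mpa_params(d = 2, N = 10, IMax = 20, lb = -1, ub = 1, seed = 7)
#' res <- optimize_mpa(function(x) sum(x^2), p)
#' res$best_cost
#' @export
optimize_mpa <- function(cost_fn, params) {
  stopifnot(inherits(params, "mpa_params"))
  withr::with_seed(params$seed, {
    prey <- init_population(params)
    fit <- eval_population(cost_fn, prey)
    evals <- params$N
    best_i <- which.min(fit)
    elite <- prey[best_i, ]
    elite_cost <- fit[best_i]
    trace <- numeric(params$IMax)
    cum <- numeric(params$IMax)
    for (iter in seq_len(params$IMax)) {
      I <- iter - 1L
      moved <- update_prey(prey, elite, I, params)
      moved <- apply_fads(moved, I, params)
      new_fit <- eval_population(cost_fn, moved)
      evals <- evals + params$N
      kept <- memory_save(prey, fit, moved, new_fit)
      prey <- kept$positions
      fit <- kept$fitness
      best_i <- which.min(fit)
      if (fit[best_i] < elite_cost) {
        elite <- prey[best_i, ]
        elite_cost <- fit[best_i]
      }
      trace[iter] <- elite_cost
      cum[iter] <- evals
    }
    structure(list(best = elite, best_cost = elite_cost,
                   trace = tibble(iteration = seq_len(params$IMax),
                                  best_cost = trace, cum_evals = cum),
                   evaluations = evals, params = params),
              class = "mpa_result")
  })
}
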