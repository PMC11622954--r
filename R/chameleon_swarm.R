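#' Chameleon swarm optimizer configuration
#'
#' Bound-constrained continuous minimizer mimicking chameleon foraging:
#' a prey-search position update, an eye-rotation update about the swarm
#' centroid, and a velocity-based tongue launch, with elitist tracking of
#' personal and global bests.
#'
#' @param pop_size number of chameleons (at least 2).
#' @param dims search-space dimensionality.
#' @param lower,upper finite bound vectors (recycled to `dims`).
#' @param iterations iteration budget R (at least 1).
#' @param delta,alpha_decay,beta exploration-decay controls of the shrinking
#'   step scale `rho = delta * exp(-alpha_decay * t / R)`; `beta` is kept for
#'   interface completeness and reserved for decay variants.
#' @param lambda inertia exponent of the weight
#'   `W = (1 - r/R)^(lambda * sqrt(r/R))` (default 1).
#' @param p1,p2 attraction coefficients toward global and personal bests.
#' @param P perception probability splitting the prey-search branches.
#' @param seed RNG seed.
#' @return object of class `csa_config`.
#' @export
csa_config <- function(pop_size = 30L, dims, lower, upper, iterations = 100L,
                       delta = 1, alpha_decay = 3.5, beta = 3, lambda = 1,
                       p1 = 2, p2 = 1.8, P = 0.1, seed = 1L) {
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (pop_size < 2) abort("pop_size must be >= 2")
  if (iterations < 1) abort("iterations must be >= 1")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    abort("bounds must be finite with lower < upper")
  structure(list(pop_size = as.integer(pop_size), dims = as.integer(dims),
                 lower = lower, upper = upper,
                 iterations = as.integer(iterations), delta = delta,
                 alpha_decay = alpha_decay, beta = beta, lambda = lambda,
                 p1 = p1, p2 = p2, P = P, seed = as.integer(seed)),
            class = "csa_config")
}

#' Iteration-decaying step scale
#' @param t iteration (0-based for the analytic boundary `rho(0) = delta`).
#' @param R iteration budget.
#' @param delta initial scale.
#' @param alpha_decay decay rate.
#' @return `delta * exp(-alpha_decay * t / R)`.
#' @export
csa_rho <- function(t, R, delta = 1, alpha_decay = 3.5)
  delta * exp(-alpha_decay * t / R)

#' Inertia weight
#' @param r iteration, `0 < r <= R`.
#' @param R iteration budget.
#' @param lambda inertia exponent.
#' @return `(1 - r/R)^(lambda * sqrt(r/R))`; 0 at `r = R`, tends to 1 as
#'   `r -> 0`.
#' @export
csa_inertia <- function(r, R, lambda = 1) (1 - r / R)^(lambda * sqrt(r / R))

#' Acceleration rate
#' @param r iteration (at least 1).
#' @return `2590 * (1 - exp(-log(r)))`, i.e. `2590 * (1 - 1/r)`; 0 at
#'   `r = 1`, saturating at 2590.
#' @export
csa_acceleration <- function(r) 2590 * (1 - exp(-log(r)))

csa_clip <- function(x, config) pmin(pmax(x, config$lower), config$upper)

# evaluate one candidate; non-finite fitness -> resample once in the box
csa_eval <- function(x, objective, config) {
  f <- objective(x)
  if (!is.finite(f)) {
    x <- config$lower + runif(config$dims) * (config$upper - config$lower)
    f <- objective(x)
    if (!is.finite(f)) f <- Inf
  }
  list(x = x, f = f)
}

#' Initialize a chameleon swarm
#'
#' Positions are drawn uniformly in the box
#' (`a = L + rand * (U - L)` per coordinate), velocities start at zero, and
#' personal/global bests are set from the initial fitness.
#'
#' @param objective function of a numeric vector returning a scalar.
#' @param config a [csa_config()].
#' @return state list with `positions`, `velocities`, `fitness`,
#'   `pbest`/`pbest_f`, `gbest`/`gbest_f`, `iter`, `evaluations`.
#' @export
csa_initialize <- function(objective, config) {
  C <- config$pop_size; D <- config$dims
  pos <- matrix(runif(C * D), C, D)
  pos <- sweep(sweep(pos, 2L, config$upper - config$lower, "*"),
               2L, config$lower, "+")
  fit <- numeric(C)
  for (i in seq_len(C)) {
    ev <- csa_eval(pos[i, ], objective, config)
    pos[i, ] <- ev$x; fit[i] <- ev$f
  }
  best <- which.min(fit)
  list(positions = pos, velocities = matrix(0, C, D), fitness = fit,
       pbest = pos, pbest_f = fit,
       gbest = pos[best, ], gbest_f = fit[best],
       iter = 0L, evaluations = C)
}

# update fitness bookkeeping for a full population evaluation
csa_absorb <- function(state, objective, config) {
  C <- config$pop_size
  for (i in seq_len(C)) {
    ev <- csa_eval(state$positions[i, ], objective, config)
    state$positions[i, ] <- ev$x
    state$fitness[i] <- ev$f
    state$evaluations <- state$evaluations + 1L
    if (ev$f < state$pbest_f[i]) {
      state$pbest_f[i] <- ev$f
      state$pbest[i, ] <- ev$x
    }
    if (ev$f < state$gbest_f) {
      state$gbest_f <- ev$f
      state$gbest <- ev$x
    }
  }
  state
}

#' One chameleon swarm iteration
#'
#' Applies, in order: the prey-search update (attraction toward the personal
#' and global bests, or a `rho`-scaled random exploration step with
#' probability `P`), a random planar (Givens) rotation of each position about
#' the swarm centroid, and the velocity-based launch
#' `x <- x + (v_new^2 - v_old^2) / (2 y)` with inertia-weighted velocity
#' `v_new = W v + p1 (G - x) rand + p2 (Pbest - x) rand`. Positions are
#' clipped to the bounds and bests updated after every phase. The launch is
#' skipped at `r = 1`, where the acceleration `y` is zero.
#'
#' @param state state list from [csa_initialize()] or a previous step.
#' @param objective scalar objective function.
#' @param config a [csa_config()].
#' @return updated state.
#' @export
csa_step <- function(state, objective, config) {
  C <- config$pop_size; D <- config$dims
  r <- state$iter + 1L
  R <- config$iterations
  rho <- csa_rho(r, R, config$delta, config$alpha_decay)
  W <- csa_inertia(r, R, config$lambda)
  y <- csa_acceleration(r)

  # phase 1: prey search
  for (i in seq_len(C)) {
    a <- state$positions[i, ]
    if (runif(1) >= config$P) {
      a <- a + config$p1 * (state$pbest[i, ] - state$gbest) * runif(D) +
        config$p2 * (state$gbest - a) * runif(D)
    } else {
      a <- a + rho * (config$upper - config$lower) * runif(D) *
        sign(runif(D) - 0.5)
    }
    state$positions[i, ] <- csa_clip(a, config)
  }
  state <- csa_absorb(state, objective, config)

  # phase 2: eye rotation about the swarm centroid
  if (D >= 2) {
    centroid <- colMeans(state$positions)
    for (i in seq_len(C)) {
      pl <- sample.int(D, 2L)
      theta <- runif(1, -pi, pi)
      a <- state$positions[i, ] - centroid
      rot <- a
      rot[pl[1L]] <- cos(theta) * a[pl[1L]] - sin(theta) * a[pl[2L]]
      rot[pl[2L]] <- sin(theta) * a[pl[1L]] + cos(theta) * a[pl[2L]]
      state$positions[i, ] <- csa_clip(centroid + rot, config)
    }
    state <- csa_absorb(state, objective, config)
  }

  # phase 3: velocity launch (guarded at r = 1 where y = 0)
  vold <- state$velocities
  for (i in seq_len(C)) {
    x <- state$positions[i, ]
    vnew <- W * vold[i, ] +
      config$p1 * (state$gbest - x) * runif(D) +
      config$p2 * (state$pbest[i, ] - x) * runif(D)
    state$velocities[i, ] <- vnew
    if (r > 1L)
      state$positions[i, ] <- csa_clip(x + (vnew^2 - vold[i, ]^2) / (2 * y),
                                       config)
  }
  if (r > 1L) state <- csa_absorb(state, objective, config)

  state$iter <- r
  state
}

#' Minimize an objective with the chameleon swarm
#'
#' @param objective scalar function on the box.
#' @param config a [csa_config()].
#' @return list with `best_x`, `best_f`, `history` (best fitness per
#'   iteration, non-increasing) and `evaluations`. Deterministic for a fixed
#'   seed.
#' @export
csa_minimize <- function(objective, config) {
  withr::with_seed(config$seed, {
    state <- csa_initialize(objective, config)
    history <- numeric(config$iterations)
    for (r in seq_len(config$iterations)) {
      state <- csa_step(state, objective, config)
      history[r] <- state$gbest_f
    }
  })
  list(best_x = state$gbest, best_f = state$gbest_f, history = history,
       evaluations = state$evaluations)
}
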