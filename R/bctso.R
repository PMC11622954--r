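#' Binary chaotic transient-search selector configuration
#'
#' Wrapper feature selection driven by transient search optimization with
#' optional chaotic (logistic-map) streams for population initialization and
#' the `C1` coefficient, a sigmoid binarization of the continuous positions,
#' and a cross-validated classifier accuracy fitness.
#'
#' @param pop_size population size (at least 2).
#' @param iterations iteration budget `L_max`.
#' @param k constant scaling the `C1` coefficient (`C1 = k z r3 + 1`).
#' @param w1,w2 fitness weights for accuracy and feature-ratio terms; must
#'   sum to 1 (defaults 0.6 and 0.4).
#' @param logistic_r logistic-map control parameter (default 4, the fully
#'   chaotic regime).
#' @param chaotic_init draw the initial population from the chaotic stream
#'   instead of uniform variates.
#' @param chaotic_C1 draw the `r3` stream of `C1` chaotically (the improved
#'   variant).
#' @param folds stratified cross-validation folds (at least 2).
#' @param knn_k neighbors of the wrapped k-nearest-neighbour classifier.
#' @param fitness_ratio_sign `"reward_fewer"` (default) scores
#'   `w1 * Acc + w2 * (1 - n/N)` so smaller subsets win the tie;
#'   `"literal"` scores `w1 * Acc + w2 * n/N`.
#' @param position_bound continuous positions live in
#'   `[-position_bound, position_bound]` per dimension.
#' @param seed RNG seed.
#' @return object of class `tso_config`.
#' @export
tso_config <- function(pop_size = 20L, iterations = 100L, k = 1,
                       w1 = 0.6, w2 = 0.4, logistic_r = 4,
                       chaotic_init = TRUE, chaotic_C1 = TRUE,
                       folds = 5L, knn_k = 5L,
                       fitness_ratio_sign = c("reward_fewer", "literal"),
                       position_bound = 4, seed = 1L) {
  if (abs(w1 + w2 - 1) > 1e-9) abort("w1 + w2 must equal 1")
  if (pop_size < 2) abort("pop_size must be >= 2")
  if (folds < 2) abort("folds must be >= 2")
  structure(list(pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations), k = k,
                 w1 = w1, w2 = w2, logistic_r = logistic_r,
                 chaotic_init = isTRUE(chaotic_init),
                 chaotic_C1 = isTRUE(chaotic_C1),
                 folds = as.integer(folds), knn_k = as.integer(knn_k),
                 fitness_ratio_sign = match.arg(fitness_ratio_sign),
                 position_bound = position_bound, seed = as.integer(seed)),
            class = "tso_config")
}

#' Logistic-map sequence
#'
#' Iterates `x_{t+1} = r x_t (1 - x_t)` from `x0` and returns the orbit
#' `x_1, ..., x_length`. For `r <= 4` and `x0` in `(0, 1)` all values stay
#' in `[0, 1]`.
#'
#' @param x0 seed value in `(0, 1)`.
#' @param r control parameter (4 is fully chaotic).
#' @param length number of iterates to return.
#' @return numeric vector of length `length`.
#' @export
logistic_sequence <- function(x0, r = 4, length = 1L) {
  if (x0 <= 0 || x0 >= 1) abort("x0 must lie strictly in (0, 1)")
  out <- numeric(length)
  x <- x0
  for (t in seq_len(length)) {
    x <- r * x * (1 - x)
    out[t] <- x
  }
  out
}

#' Transient-search coefficients
#'
#' \deqn{z = 2 - 2 l / L_{max}, \quad T = 2 z r_2 - z, \quad C_1 = k z r_3 + 1}
#' so `z` decays linearly from 2 to 0 and `T` spans `[-z, z]`, a subset of
#' `[-2, 2]`.
#'
#' @param l iteration, `0 <= l <= L_max`.
#' @param L_max iteration budget.
#' @param k constant of the `C1` coefficient.
#' @param r2,r3 random (or chaotic) draws in `[0, 1]`; drawn uniformly when
#'   missing.
#' @return list with `T`, `C1`, `z`.
#' @export
tso_coefficients <- function(l, L_max, k = 1, r2 = runif(1), r3 = runif(1)) {
  if (l < 0 || l > L_max) abort("l must lie in [0, L_max]")
  z <- 2 - 2 * (l / L_max)
  list(T = 2 * z * r2 - z, C1 = k * z * r3 + 1, z = z)
}

#' Transient-search position update
#'
#' With the exploitation branch (`r1 < 0.5`) the position decays
#' exponentially toward the best solution,
#' `Y* + (Y - C1 Y*) exp(-T)`; otherwise the oscillatory exploration branch
#' `Y* + exp(-T) (cos(2 pi T) + sin(2 pi T)) |Y - C1 Y*|` is taken.
#' All arguments may be scalars or per-dimension vectors; the selector draws
#' `r1`, `T` and `C1` per dimension, which keeps the population diverse
#' around the elitist best (a single scalar draw per individual collapses
#' every coordinate onto the same transient and stalls the search).
#'
#' @param Y current position vector.
#' @param Y_star best-known position vector.
#' @param T,C1 coefficients from [tso_coefficients()], scalar or vector.
#' @param r1 branch draw(s) in `[0, 1]`.
#' @return updated position vector.
#' @export
tso_update <- function(Y, Y_star, T, C1, r1 = runif(1)) {
  decay <- Y_star + (Y - C1 * Y_star) * exp(-T)
  oscil <- Y_star + exp(-T) * (cos(2 * pi * T) + sin(2 * pi * T)) *
    abs(Y - C1 * Y_star)
  ifelse(rep_len(r1 < 0.5, length(Y)), decay, oscil)
}

#' Sigmoid binarization of a continuous position
#'
#' Bit d is set iff `1 / (1 + exp(-x_d)) > r_d` with `r_d ~ U(0, 1)` drawn
#' per dimension. An all-zero draw is resampled (at most 10 times), after
#' which the maximum-sigmoid bit is forced so the mask is never empty.
#'
#' @param position numeric vector.
#' @param rd optional fixed threshold draws (for reproducible examples).
#' @return logical feature-inclusion vector with at least one bit set.
#' @export
binarize <- function(position, rd = NULL) {
  s <- 1 / (1 + exp(-position))
  for (try in 1:10) {
    r <- if (is.null(rd)) runif(length(position)) else rd
    bits <- s > r
    if (any(bits)) return(bits)
    if (!is.null(rd)) break
  }
  bits <- logical(length(position))
  bits[which.max(s)] <- TRUE
  bits
}

#' Cross-validated fitness of a feature subset
#'
#' `Acc` is the mean stratified k-fold accuracy of a k-nearest-neighbour
#' classifier restricted to the selected columns;
#' `Fit = w1 * Acc + w2 * (1 - n/N)` by default (see
#' [tso_config()]'s `fitness_ratio_sign`). The classifier's tie-breaking is
#' seeded from the mask itself, so a mask's fitness is a pure function of
#' the mask and the fold assignment.
#'
#' @param mask logical feature-inclusion vector (nonempty).
#' @param table a [generate_feature_table()] result, or a list with
#'   `matrix` and `labels`.
#' @param config a [tso_config()].
#' @param folds optional precomputed fold assignment from
#'   [stratified_kfold()]; computed from `config$seed` when missing.
#' @return list with `fit` and `acc`.
#' @export
subset_fitness <- function(mask, table, config = tso_config(), folds = NULL) {
  if (!any(mask)) abort("mask selects no features")
  X <- table$matrix[, mask, drop = FALSE]
  y <- factor(table$labels)
  if (is.null(folds)) folds <- stratified_kfold(table$labels, config$folds,
                                                seed = config$seed)
  sel <- which(mask)
  mask_seed <- child_seed(config$seed,
                          sum(sel * seq_along(sel)) %% 1000003L)
  acc <- withr::with_seed(mask_seed, {
    correct <- 0L
    for (f in sort(unique(folds))) {
      te <- folds == f
      pred <- class::knn(X[!te, , drop = FALSE], X[te, , drop = FALSE],
                         y[!te], k = config$knn_k)
      correct <- correct + sum(pred == y[te])
    }
    correct / length(y)
  })
  ratio <- sum(mask) / length(mask)
  fit <- if (config$fitness_ratio_sign == "literal")
    config$w1 * acc + config$w2 * ratio
  else
    config$w1 * acc + config$w2 * (1 - ratio)
  list(fit = fit, acc = acc)
}

#' Select features with binary chaotic transient search
#'
#' Initializes a population of continuous positions (chaotic logistic stream
#' or uniform), and per iteration recomputes the transient coefficients,
#' moves every position toward the elitist best, binarizes, and scores the
#' mask with the cross-validated wrapper fitness. The best mask is kept
#' across iterations (maximization), so the fitness history is
#' non-decreasing.
#'
#' @param table a [generate_feature_table()] result or compatible list.
#' @param config a [tso_config()].
#' @return list with `best_mask`, `best_fitness`, `cv_accuracy`, `history`
#'   (best fitness per iteration), `evaluations` and the `folds` assignment
#'   used by every fitness evaluation.
#' @export
bctso_select <- function(table, config = tso_config()) {
  if (length(unique(table$labels)) < 2) abort("table must contain >= 2 classes")
  N <- ncol(table$matrix)
  lb <- -config$position_bound; ub <- config$position_bound
  withr::with_seed(config$seed, {
    folds <- stratified_kfold(table$labels, config$folds,
                              seed = child_seed(config$seed, 2L))
    # chaotic stream shared by initialization and the C1 coefficient
    x0 <- runif(1, 0.05, 0.45)
    chaos_state <- x0
    next_chaos <- function(n) {
      s <- logistic_sequence(chaos_state, config$logistic_r, n)
      chaos_state <<- s[n]
      s
    }
    pop <- if (config$chaotic_init)
      matrix(lb + next_chaos(config$pop_size * N) * (ub - lb),
             config$pop_size, N)
    else
      matrix(lb + runif(config$pop_size * N) * (ub - lb),
             config$pop_size, N)

    cache <- new.env(parent = emptyenv())
    score <- function(mask) {
      key <- paste(which(mask), collapse = ",")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      res <- subset_fitness(mask, table, config, folds)
      cache[[key]] <- res
      res
    }

    best_fit <- -Inf; best_acc <- NA_real_
    best_mask <- NULL; best_pos <- NULL
    evals <- 0L
    for (i in seq_len(config$pop_size)) {
      mask <- binarize(pop[i, ])
      res <- score(mask); evals <- evals + 1L
      if (res$fit > best_fit) {
        best_fit <- res$fit; best_acc <- res$acc
        best_mask <- mask; best_pos <- pop[i, ]
      }
    }
    history <- numeric(config$iterations)
    for (l in seq_len(config$iterations)) {
      for (i in seq_len(config$pop_size)) {
        r2 <- runif(N)
        r3 <- if (config$chaotic_C1) next_chaos(N) else runif(N)
        co <- tso_coefficients(l, config$iterations, config$k, r2, r3)
        pos <- tso_update(pop[i, ], best_pos, co$T, co$C1, runif(N))
        pop[i, ] <- pmin(pmax(pos, lb), ub)
        mask <- binarize(pop[i, ])
        res <- score(mask); evals <- evals + 1L
        if (res$fit > best_fit) {
          best_fit <- res$fit; best_acc <- res$acc
          best_mask <- mask; best_pos <- pop[i, ]
        }
      }
      history[l] <- best_fit
    }
  })
  list(best_mask = best_mask, best_fitness = best_fit,
       cv_accuracy = best_acc, history = history, evaluations = evals,
       folds = folds)
}
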