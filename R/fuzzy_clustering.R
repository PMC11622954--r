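#' LWIFCM configuration
#'
#' Settings of the local-information intuitionistic fuzzy c-means engine.
#'
#' @param c number of clusters (at least 2 for multi-cluster runs; 1 is
#'   allowed and degenerates to a weighted mean).
#' @param m fuzzifier exponent, greater than 1.
#' @param alpha uncertainty parameter of the Yager complement, in `(0, 1]`.
#'   Values above 1 would make the hesitation degree negative.
#' @param rho variance stabilizer of the local information weight
#'   `k_j = (sigma_j^2 + rho) / (mean(sigma^2) + rho)`, positive.
#' @param window_radius half-width of the square spatial neighborhood
#'   (1 gives 3x3).
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the maximum center shift.
#' @param local_term logical; include the spatial penalty (only meaningful
#'   for image input).
#' @param membership_exponent logical; raise the modified memberships to `m`
#'   in the objective's data term (consistent with the center update) rather
#'   than using them linearly.
#' @param seed RNG seed used only when a center must be re-seeded.
#' @return object of class `lwifcm_config`.
#' @export
lwifcm_config <- function(c = 4L, m = 2, alpha = 0.85, rho = 1e-3,
                          window_radius = 1L, max_iter = 100L, tol = 1e-5,
                          local_term = TRUE, membership_exponent = TRUE,
                          seed = 1L) {
  if (m <= 1) abort("m must be > 1")
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
  if (rho <= 0) abort("rho must be > 0")
  if (c < 1) abort("c must be >= 1")
  structure(list(c = as.integer(c), m = m, alpha = alpha, rho = rho,
                 window_radius = as.integer(window_radius),
                 max_iter = as.integer(max_iter), tol = tol,
                 local_term = isTRUE(local_term),
                 membership_exponent = isTRUE(membership_exponent),
                 seed = as.integer(seed)),
            class = "lwifcm_config")
}

# squared Euclidean distances, c x n, between rows of V (c x d) and rows of
# X (n x d)
sq_dist <- function(X, V) {
  cx <- rowSums(X^2)
  cv <- rowSums(V^2)
  pmax(outer(cv, cx, "+") - 2 * V %*% t(X), 0)
}

as_data_matrix <- function(data) {
  if (is.null(dim(data))) matrix(as.numeric(data), ncol = 1L)
  else matrix(as.numeric(data), nrow(data), ncol(data))
}

as_center_matrix <- function(V, d) {
  if (is.null(dim(V))) matrix(as.numeric(V), ncol = d)
  else matrix(as.numeric(V), nrow(V), ncol(V))
}

#' Fuzzy membership update
#'
#' The standard c-means membership update
#' \deqn{u_{ij} = 1 / \sum_k (d_{ij} / d_{kj})^{2/(m-1)}}
#' over squared Euclidean distances, optionally with an additive per-entry
#' penalty on the squared distances (the spatial information term). A data
#' point at zero distance from a center receives a crisp column; ties go to
#' the lowest cluster index.
#'
#' @param data numeric vector (1-D) or matrix (`n x d`).
#' @param V centers: numeric vector or `c x d` matrix with distinct rows.
#' @param m fuzzifier, greater than 1.
#' @param penalty optional `c x n` nonnegative matrix added to the squared
#'   distances.
#' @return `c x n` membership matrix with columns summing to 1.
#' @export
update_memberships <- function(data, V, m, penalty = NULL) {
  X <- as_data_matrix(data)
  V <- as_center_matrix(V, ncol(X))
  if (nrow(V) >= 2) {
    dmin <- min(dist(V))
    if (dmin < 1e-12) abort("duplicate centers")
  }
  if (m <= 1) abort("m must be > 1")
  e <- sq_dist(X, V)
  if (!is.null(penalty)) e <- e + penalty
  zero_cols <- which(colSums(e < 1e-15) > 0L)
  inv <- e^(-1 / (m - 1))
  U <- sweep(inv, 2L, colSums(inv), "/")
  if (length(zero_cols)) {
    for (j in zero_cols) {
      U[, j] <- 0
      U[which(e[, j] < 1e-15)[1L], j] <- 1
    }
  }
  U
}

#' Intuitionistic modification of a fuzzy partition
#'
#' From memberships `u`, the Yager-complement non-membership
#' \eqn{\gamma = (1 - u^\alpha)^{1/\alpha}} and hesitation
#' \eqn{\pi = 1 - u - \gamma} are computed elementwise; the modified
#' membership is \eqn{u^* = u + \pi}, renormalized per column.
#'
#' @param U `c x n` membership matrix (columns sum to 1).
#' @param alpha uncertainty parameter in `(0, 1]`.
#' @return object of class `intuitionistic_partition`: list with `U_star`,
#'   `gamma`, `pi`, `alpha`.
#' @export
intuitionify <- function(U, alpha) {
  if (alpha <= 0 || alpha > 1)
    abort("alpha must lie in (0, 1]: hesitation would be negative")
  gamma <- (1 - U^alpha)^(1 / alpha)
  pi_ <- 1 - U - gamma
  if (min(pi_) < -1e-9) abort("negative hesitation degree")
  pi_ <- pmax(pi_, 0)
  Ustar <- U + pi_
  cs <- colSums(Ustar)
  Ustar <- sweep(Ustar, 2L, cs, "/")
  structure(list(U_star = Ustar, gamma = gamma, pi = pi_, alpha = alpha),
            class = "intuitionistic_partition")
}

#' Intuitionistic fuzzy entropy
#'
#' \deqn{IFE = \sum \pi \exp(1 - \pi)}
#'
#' @param pi hesitation degrees in `[0, 1]` (any shape).
#' @return nonnegative scalar.
#' @export
ife <- function(pi) {
  if (min(pi) < 0 || max(pi) > 1) abort("hesitation degrees must lie in [0, 1]")
  sum(pi * exp(1 - pi))
}

#' Weighted center update
#'
#' Each center is the `u*^m`-weighted mean of the data:
#' \deqn{v_i = \sum_j u^{*m}_{ij} x_j / \sum_j u^{*m}_{ij}}
#'
#' @param data numeric vector or `n x d` matrix.
#' @param U_star `c x n` modified membership matrix.
#' @param m fuzzifier exponent (weights are `U_star^m`).
#' @return `c x d` matrix of centers.
#' @export
update_centers <- function(data, U_star, m) {
  X <- as_data_matrix(data)
  W <- U_star^m
  tot <- rowSums(W)
  if (any(tot < 1e-12)) abort("empty cluster")
  (W %*% X) / tot
}

#' Local information weights
#'
#' Per-pixel ratio of local to average variance:
#' \deqn{k_j = (\sigma_j^2 + \rho) / (\bar\sigma^2 + \rho)}
#' where \eqn{\sigma_j^2} is the intensity variance over the square window of
#' half-width `window_radius` at pixel j and \eqn{\bar\sigma^2} its mean over
#' all pixels.
#'
#' @param image numeric matrix.
#' @param window_radius neighborhood half-width.
#' @param rho positive variance stabilizer.
#' @return strictly positive matrix, same shape as `image`.
#' @export
local_weights <- function(image, window_radius = 1L, rho = 1e-3) {
  if (rho <= 0) abort("rho must be > 0")
  r <- as.integer(window_radius)
  npix <- (2 * r + 1)^2
  s1 <- window_sum(image, r)
  s2 <- window_sum(image^2, r)
  sigma2 <- pmax(s2 / npix - (s1 / npix)^2, 0)
  (sigma2 + rho) / (mean(sigma2) + rho)
}

#' Spatial disagreement penalty (fuzzy local information factor)
#'
#' \deqn{G_{ij} = \sum_{r \in N_j, r \ne j} \frac{1}{1 + d_{jr}}
#'   (1 - u_{ir})^m \| x_r - v_i \|^2}
#' where \eqn{d_{jr}} is the Euclidean pixel distance between j and its
#' neighbor r; neighbors beyond the border are mirror-reflected.
#'
#' @param image numeric matrix of intensities.
#' @param U `c x n` membership matrix, columns in raster (column-major) order.
#' @param V centers (length-c vector or `c x 1` matrix of intensities).
#' @param m fuzzifier exponent.
#' @param window_radius neighborhood half-width.
#' @return `c x n` nonnegative penalty matrix.
#' @export
local_penalty <- function(image, U, V, m, window_radius = 1L) {
  r <- as.integer(window_radius)
  n <- nrow(image); mm <- ncol(image)
  cc <- nrow(U)
  v <- as.numeric(V)
  xp <- pad_reflect(image, r)
  offsets <- expand.grid(di = -r:r, dj = -r:r)
  offsets <- offsets[offsets$di != 0 | offsets$dj != 0, ]
  # precompute the shifted intensity slices once (cluster-independent)
  xs_list <- lapply(seq_len(nrow(offsets)), function(o) {
    di <- offsets$di[o]; dj <- offsets$dj[o]
    xp[(1 + r + di):(n + r + di), (1 + r + dj):(mm + r + dj)]
  })
  wts <- 1 / (1 + sqrt(offsets$di^2 + offsets$dj^2))
  G <- matrix(0, cc, n * mm)
  for (i in seq_len(cc)) {
    comp <- pad_reflect((1 - matrix(U[i, ], n, mm))^m, r)
    acc <- matrix(0, n, mm)
    for (o in seq_len(nrow(offsets))) {
      di <- offsets$di[o]; dj <- offsets$dj[o]
      us <- comp[(1 + r + di):(n + r + di), (1 + r + dj):(mm + r + dj)]
      acc <- acc + wts[o] * us * (xs_list[[o]] - v[i])^2
    }
    G[i, ] <- acc
  }
  G
}

#' LWIFCM objective value
#'
#' \deqn{\hat J = \sum_i \sum_j u^{*m}_{ij} d^2(x_j, v_i) +
#'   \sum \pi \exp(1 - \pi) + \sum_i \sum_j k_j G_{ij}}
#' With `alpha = 1` (zero hesitation) and no local term this reduces exactly
#' to the plain fuzzy c-means objective.
#'
#' @param data numeric vector or `n x d` matrix.
#' @param U_star modified memberships, `c x n`.
#' @param pi hesitation matrix, `c x n`.
#' @param V centers.
#' @param m fuzzifier exponent.
#' @param k optional per-point local weights (length n).
#' @param G optional `c x n` spatial penalty.
#' @param membership_exponent raise `U_star` to `m` in the data term.
#' @return scalar objective.
#' @export
lwifcm_objective <- function(data, U_star, pi, V, m, k = NULL, G = NULL,
                             membership_exponent = TRUE) {
  X <- as_data_matrix(data)
  V <- as_center_matrix(V, ncol(X))
  d2 <- sq_dist(X, V)
  uw <- if (membership_exponent) U_star^m else U_star
  J <- sum(uw * d2) + ife(pi)
  if (!is.null(G)) {
    if (is.null(k)) k <- rep(1, ncol(G))
    J <- J + sum(sweep(G, 2L, as.numeric(k), "*"))
  }
  J
}

#' Run LWIFCM clustering
#'
#' Alternates the membership update (with the spatial penalty folded into
#' the squared distances when the local term is enabled), the intuitionistic
#' modification, and the center update until the maximum center shift drops
#' below `tol` or `max_iter` is reached. Hard labels are the per-point
#' argmax of the modified memberships (lowest index on ties).
#'
#' @param data numeric vector, `n x d` feature matrix, or an image matrix
#'   when `image = TRUE`.
#' @param config an [lwifcm_config()].
#' @param V0 initial centers: length-`c` vector or `c x d` matrix with
#'   distinct rows.
#' @param image logical; treat `data` as a 2-D intensity raster (enables the
#'   spatial local-information term).
#' @return list with `model` (centers `V`, fuzzifier `m`, final `objective`),
#'   `partition` (the [intuitionify()] result), `U` (raw memberships),
#'   `labels` (integer vector, or raster when `image = TRUE`), `history`
#'   (objective per iteration) and `iterations`.
#' @details If a cluster loses all weight its center is re-seeded at the
#'   point worst fit by the remaining centers, with a warning.
#' @export
run_lwifcm <- function(data, config, V0, image = FALSE) {
  stopifnot(inherits(config, "lwifcm_config"))
  img <- NULL
  if (image) {
    img <- data
    X <- matrix(as.vector(data), ncol = 1L)
  } else {
    X <- as_data_matrix(data)
  }
  V <- as_center_matrix(V0, ncol(X))
  if (nrow(V) != config$c) abort("V0 must provide c initial centers")
  if (config$c >= 2 && min(dist(V)) < 1e-12) abort("V0 has coincident centers")
  use_local <- config$local_term && !is.null(img)
  k <- if (use_local)
    as.vector(local_weights(img, config$window_radius, config$rho))
  history <- numeric(0)
  IP <- NULL; U <- NULL
  penalty <- NULL
  for (it in seq_len(config$max_iter)) {
    U <- update_memberships(X, V, config$m, penalty)
    IP <- intuitionify(U, config$alpha)
    newV <- tryCatch(update_centers(X, IP$U_star, config$m),
                     error = function(e) e)
    if (inherits(newV, "error")) {
      # re-seed the starved center at the worst-fit point
      warning("empty cluster: re-seeding center")
      w <- rowSums(IP$U_star^config$m)
      bad <- which(w < 1e-12)
      d2 <- sq_dist(X, V)
      worst <- which.max(apply(d2, 2L, min))
      V[bad, ] <- X[worst, ] + seq_along(bad) * 1e-8
      penalty <- NULL
      next
    }
    Gcur <- NULL
    if (use_local) {
      # one spatial-penalty evaluation per iteration: it scores this
      # iteration's objective and feeds the next membership update
      Gcur <- local_penalty(img, IP$U_star, newV, config$m,
                            config$window_radius)
      penalty <- sweep(Gcur, 2L, k, "*")
    }
    history <- c(history,
                 lwifcm_objective(X, IP$U_star, IP$pi, newV, config$m,
                                  k = k, G = Gcur,
                                  membership_exponent = config$membership_exponent))
    shift <- max(abs(newV - V))
    V <- newV
    if (shift < config$tol) break
  }
  lab <- max.col(t(IP$U_star), ties.method = "first")
  if (!is.null(img)) lab <- matrix(lab, nrow(img), ncol(img))
  list(model = list(V = V, m = config$m, objective = history[length(history)]),
       partition = IP, U = U, labels = lab, history = history,
       iterations = length(history))
}
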