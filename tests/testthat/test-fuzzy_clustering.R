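test_that("membership update matches direct evaluation and normalizes", {
  U <- update_memberships(c(0, 2), c(0, 1), m = 2)
  expect_equal(U[, 2], c(0.2, 0.8), tolerance = 1e-12)
  # point coincident with a center gets a crisp column
  expect_equal(U[, 1], c(1, 0))
  expect_equal(colSums(U), c(1, 1), tolerance = 1e-12)
  X <- withr::with_seed(4, runif(50))
  U2 <- update_memberships(X, c(0.2, 0.5, 0.9), m = 1.7)
  expect_equal(colSums(U2), rep(1, 50), tolerance = 1e-9)
  expect_error(update_memberships(X, c(0.3, 0.3), 2), "duplicate")
})

test_that("intuitionistic modification follows the Yager complement", {
  U <- matrix(c(0.5, 0.5), 2, 1)
  ip <- intuitionify(U, 0.5)
  expect_equal(ip$gamma[1, 1], (1 - sqrt(0.5))^2, tolerance = 1e-12)
  expect_equal(ip$pi[1, 1], 1 - 0.5 - (1 - sqrt(0.5))^2, tolerance = 1e-12)
  # alpha = 1 reduces to the plain fuzzy partition
  ip1 <- intuitionify(U, 1)
  expect_equal(ip1$gamma, 1 - U)
  expect_equal(max(abs(ip1$pi)), 0)
  expect_equal(ip1$U_star, U)
  # boundary: u = 0 gives full non-membership, no hesitation
  ip0 <- intuitionify(matrix(c(0, 1), 2, 1), 0.7)
  expect_equal(ip0$gamma[1, 1], 1)
  expect_equal(ip0$pi[1, 1], 0)
  expect_error(intuitionify(U, 1.5), "alpha")
})

test_that("hesitation stays nonnegative and u + gamma + pi = 1 over alpha", {
  U <- withr::with_seed(8, {
    raw <- matrix(runif(3 * 40), 3)
    sweep(raw, 2, colSums(raw), "/")
  })
  for (alpha in c(0.2, 0.5, 0.85, 1)) {
    ip <- intuitionify(U, alpha)
    expect_gte(min(ip$pi), 0)
    expect_equal(U + ip$gamma + ip$pi, matrix(1, 3, 40), tolerance = 1e-9)
    expect_equal(colSums(ip$U_star), rep(1, 40), tolerance = 1e-9)
  }
})

test_that("intuitionistic fuzzy entropy matches direct sums", {
  expect_equal(ife(c(0, 0, 0)), 0)
  expect_equal(ife(1), 1)
  expect_equal(ife(c(0.5, 0.5)), 2 * 0.5 * exp(0.5), tolerance = 1e-12)
})

test_that("center update is the weighted mean", {
  # m = 1 hand instance: v1 = (1*0 + 0.5*1) / 1.5
  Ustar <- matrix(c(1, 0, 0.5, 0.5), 2, 2)
  expect_error(update_centers(c(0, 1), Ustar, 1), NA)
  V <- update_centers(c(0, 1), Ustar, 1)
  expect_equal(V[1, 1], 1 / 3, tolerance = 1e-12)
  # crisp memberships on separated groups recover group means
  x <- c(0.1, 0.2, 0.8, 0.9)
  Uc <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(as.numeric(update_centers(x, Uc, 2)), c(0.15, 0.85))
  # uniform memberships collapse every center to the global mean
  Uu <- matrix(0.5, 2, 4)
  expect_equal(as.numeric(update_centers(x, Uu, 2)), rep(mean(x), 2))
  expect_error(update_centers(x, matrix(0, 2, 4), 2), "empty cluster")
})

test_that("local information weights behave as variance ratios", {
  const <- matrix(0.5, 16, 16)
  expect_equal(local_weights(const, 1, 1e-3), matrix(1, 16, 16))
  chk <- outer(1:16, 1:16, function(i, j) (i + j) %% 2 * 1.0)
  k <- local_weights(chk, 1, 1e-3)
  inner <- k[3:14, 3:14]
  expect_lt(diff(range(inner)), 1e-12)  # symmetric interior, single value
  expect_gt(min(k), 0)
  img <- withr::with_seed(2, matrix(runif(32 * 32), 32))
  expect_equal(mean(local_weights(img, 1, 1e-6)), 1, tolerance = 1e-2)
})

test_that("spatial penalty matches a brute-force neighbor sum", {
  img <- withr::with_seed(7, matrix(runif(25), 5))
  U <- withr::with_seed(9, {
    raw <- matrix(runif(2 * 25), 2)
    sweep(raw, 2, colSums(raw), "/")
  })
  V <- c(0.3, 0.7)
  G <- local_penalty(img, U, V, m = 2, window_radius = 1)
  for (i in 1:2) {
    ui <- matrix(U[i, ], 5, 5)
    for (cell in list(c(3, 3), c(1, 1), c(5, 2))) {
      expected <- g_bruteforce(img, U, V[i], ui, 2, cell[1], cell[2])
      expect_equal(G[i, (cell[2] - 1) * 5 + cell[1]], expected,
                   tolerance = 1e-12)
    }
  }
  # crisp agreement or zero residual kill the penalty
  Ucrisp <- rbind(rep(1, 25), rep(0, 25))
  expect_equal(max(local_penalty(img, Ucrisp, V, 2, 1)[1, ]), 0)
  flat <- matrix(0.7, 5, 5)
  expect_equal(max(local_penalty(flat, U, V, 2, 1)[2, ]), 0)
})

test_that("objective reduces to plain FCM when hesitation and penalty vanish", {
  x <- withr::with_seed(12, runif(30))
  V <- c(0.25, 0.75)
  U <- update_memberships(x, V, 2)
  ip <- intuitionify(U, 1)
  J <- lwifcm_objective(x, ip$U_star, ip$pi, V, 2)
  d2 <- rbind((x - 0.25)^2, (x - 0.75)^2)
  expect_equal(J, sum(U^2 * d2), tolerance = 1e-10)
  # perfect crisp fit: data and hesitation terms are zero
  xc <- c(0.25, 0.75)
  Uc <- diag(2)
  ipc <- intuitionify(Uc, 1)
  expect_equal(lwifcm_objective(xc, ipc$U_star, ipc$pi, V, 2), 0)
})

test_that("objective matches an independent term-by-term sum on a hand instance", {
  x <- c(0.1, 0.2, 0.8, 0.9)
  V <- c(0.15, 0.85)
  U <- update_memberships(x, V, 2)
  ip <- intuitionify(U, 0.8)
  k <- c(1, 1.2, 0.9, 1)
  G <- withr::with_seed(3, matrix(runif(8), 2))
  J <- lwifcm_objective(x, ip$U_star, ip$pi, V, 2, k = k, G = G)
  manual <- 0
  for (i in 1:2) for (j in 1:4) {
    manual <- manual + ip$U_star[i, j]^2 * (x[j] - V[i])^2 + k[j] * G[i, j]
  }
  manual <- manual + sum(ip$pi * exp(1 - ip$pi))
  expect_equal(J, manual, tolerance = 1e-12)
})

test_that("the engine with alpha 1 and no local term equals independent FCM", {
  for (s in 1:5) {
    x <- withr::with_seed(100 + s, c(runif(100, 0, 0.4), runif(100, 0.6, 1)))
    V0 <- withr::with_seed(200 + s, sort(runif(2)))
    cfg <- lwifcm_config(c = 2, m = 2, alpha = 1, local_term = FALSE,
                         max_iter = 100, tol = 1e-6)
    fit <- run_lwifcm(x, cfg, V0)
    orc <- fcm_oracle(x, 2, 2, V0, max_iter = 100, tol = 1e-6)
    expect_identical(as.integer(fit$labels), as.integer(orc$labels))
    expect_equal(fit$model$objective, orc$objective, tolerance = 1e-10)
    expect_equal(as.numeric(fit$model$V), orc$V, tolerance = 1e-10)
  }
})

test_that("plain FCM objective is non-increasing across iterations", {
  x <- withr::with_seed(31, c(rnorm(150, 0.3, 0.07), rnorm(150, 0.7, 0.07)))
  x <- pmin(pmax(x, 0), 1)
  cfg <- lwifcm_config(c = 2, alpha = 1, local_term = FALSE, max_iter = 60)
  fit <- run_lwifcm(x, cfg, c(0.45, 0.55))
  expect_true(all(diff(fit$history) <= 1e-12))
})

test_that("two-gaussian centers are recovered within 0.02", {
  x <- withr::with_seed(5, c(rnorm(200, 0.2, 0.02), rnorm(200, 0.8, 0.02)))
  cfg <- lwifcm_config(c = 2, local_term = FALSE)
  fit <- run_lwifcm(x, cfg, c(0.4, 0.6))
  expect_lt(max(abs(sort(as.numeric(fit$model$V)) - c(0.2, 0.8))), 0.02)
})

test_that("a single cluster converges to the weighted global mean", {
  x <- withr::with_seed(6, runif(80))
  cfg <- lwifcm_config(c = 1, alpha = 1, local_term = FALSE)
  fit <- run_lwifcm(x, cfg, 0.1)
  expect_equal(as.numeric(fit$model$V), mean(x), tolerance = 1e-6)
})

test_that("noiseless two-tissue phantom labels reproduce ground truth", {
  ph <- generate_phantom(phantom_config(image_size = 128, seed = 6))
  img <- ph$image * ph$brain_mask
  cfg <- lwifcm_config(c = 4, local_term = FALSE, max_iter = 60)
  fit <- run_lwifcm(img, cfg, c(0.05, 0.3, 0.6, 0.9), image = TRUE)
  perm <- match_labels(fit$labels, ph$labels + 1L)
  relabeled <- matrix(perm[as.character(fit$labels)], 128, 128)
  expect_identical(as.integer(relabeled), as.integer(ph$labels + 1L))
})

test_that("partitions stay column-stochastic throughout a spatial run", {
  ph <- generate_phantom(phantom_config(image_size = 64, rician_sigma = 0.05,
                                        seed = 8))
  cfg <- lwifcm_config(c = 3, max_iter = 15)
  fit <- run_lwifcm(ph$image, cfg, c(0.1, 0.45, 0.8), image = TRUE)
  expect_equal(colSums(fit$U), rep(1, 64 * 64), tolerance = 1e-9)
  expect_equal(colSums(fit$partition$U_star), rep(1, 64 * 64),
               tolerance = 1e-9)
  expect_gte(min(fit$partition$pi), 0)
  expect_true(all(is.finite(fit$history)))
})
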