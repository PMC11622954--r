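test_that("logistic map orbits match direct iteration", {
  s <- logistic_sequence(0.3, 4, 2)
  expect_equal(s[1], 0.84, tolerance = 1e-12)
  expect_equal(s[2], 0.5376, tolerance = 1e-12)
  # algebraic fixed point of the r = 4 map
  expect_equal(logistic_sequence(0.75, 4, 10), rep(0.75, 10))
  long <- logistic_sequence(0.3, 4, 1000)
  expect_gte(min(long), 0)
  expect_lte(max(long), 1)
  expect_error(logistic_sequence(1.2, 4, 5), "x0")
})

test_that("transient coefficients decay linearly and bound T", {
  expect_equal(tso_coefficients(0, 100, r2 = 0.3, r3 = 0.3)$z, 2)
  co_end <- tso_coefficients(100, 100, r2 = 0.9, r3 = 0.1)
  expect_equal(co_end$z, 0)
  expect_equal(co_end$T, 0)
  # printed extremes of T at l = 0
  expect_equal(tso_coefficients(0, 50, r2 = 1)$T, 2)
  expect_equal(tso_coefficients(0, 50, r2 = 0)$T, -2)
  for (l in c(0, 10, 37, 50)) {
    co <- tso_coefficients(l, 50, r2 = runif(1), r3 = runif(1))
    expect_lte(abs(co$T), 2)
  }
})

test_that("position update matches its two branches", {
  Ys <- c(1, -2)
  # zero transient term returns the best exactly
  expect_equal(tso_update(1.3 * Ys, Ys, T = 0.7, C1 = 1.3, r1 = 0.2), Ys)
  # T = 0 exploit branch is a plain offset
  Y <- c(0.5, 0.5)
  expect_equal(tso_update(Y, Ys, T = 0, C1 = 2, r1 = 0.1), Ys + (Y - 2 * Ys))
  # large T contracts toward the best
  upd <- tso_update(Y, Ys, T = 2, C1 = 1, r1 = 0.3)
  expect_true(all(abs(upd - Ys) <= exp(-2) * abs(Y - Ys) + 1e-12))
})

test_that("binarization thresholds the sigmoid and never empties the mask", {
  expect_identical(binarize(c(2, -2), rd = c(0.5, 0.5)), c(TRUE, FALSE))
  expect_identical(binarize(c(50, 50), rd = c(0.99, 0.99)), c(TRUE, TRUE))
  # strongly negative positions still yield at least one bit
  b <- withr::with_seed(3, binarize(rep(-50, 8)))
  expect_gte(sum(b), 1)
})

test_that("subset fitness combines accuracy and the feature ratio", {
  tab <- generate_feature_table(feature_table_config(seed = 3))
  cfg <- tso_config(seed = 5)
  folds <- stratified_kfold(tab$labels, 5, seed = 1)
  mask <- tab$informative_mask
  res <- subset_fitness(mask, tab, cfg, folds)
  expect_equal(res$fit, 0.6 * res$acc + 0.4 * (1 - 5 / 30), tolerance = 1e-12)
  # literal printed form rewards the kept-feature ratio instead
  cfg_lit <- tso_config(fitness_ratio_sign = "literal", seed = 5)
  res_lit <- subset_fitness(mask, tab, cfg_lit, folds)
  expect_equal(res_lit$fit, 0.6 * res_lit$acc + 0.4 * (5 / 30),
               tolerance = 1e-12)
  # w2 = 0 reduces fitness to accuracy; full masks drop the ratio term
  cfg0 <- tso_config(w1 = 1, w2 = 0, seed = 5)
  res0 <- subset_fitness(mask, tab, cfg0, folds)
  expect_equal(res0$fit, res0$acc)
  full <- subset_fitness(rep(TRUE, 30), tab, cfg, folds)
  expect_equal(full$fit, 0.6 * full$acc, tolerance = 1e-12)
  expect_error(subset_fitness(rep(FALSE, 30), tab, cfg, folds), "mask")
})

test_that("selection is elitist, deterministic, and stays in bounds", {
  tab <- generate_feature_table(
    feature_table_config(n_samples = 120, n_features = 12, n_informative = 3,
                         seed = 8))
  cfg <- tso_config(pop_size = 8, iterations = 12, seed = 14)
  res <- bctso_select(tab, cfg)
  expect_true(all(diff(res$history) >= 0))
  expect_gte(sum(res$best_mask), 1)
  expect_identical(bctso_select(tab, cfg), res)
  # chaotic and uniform initialization both work
  cfg_u <- tso_config(pop_size = 8, iterations = 12, seed = 14,
                      chaotic_init = FALSE, chaotic_C1 = FALSE)
  res_u <- bctso_select(tab, cfg_u)
  expect_true(all(diff(res_u$history) >= 0))
})

test_that("informative features are recovered across seeds", {
  recalls <- vapply(1:5, function(s) {
    tab <- generate_feature_table(feature_table_config(seed = 10 + s))
    res <- bctso_select(tab, tso_config(pop_size = 20, iterations = 100,
                                        seed = 100 + s))
    sum(res$best_mask & tab$informative_mask) / sum(tab$informative_mask)
  }, numeric(1))
  expect_gte(median(recalls), 0.8)
})

test_that("pure-accuracy search matches the exhaustive oracle", {
  hits <- 0
  for (s in 1:5) {
    tab <- generate_feature_table(
      feature_table_config(n_samples = 120, n_features = 10,
                           n_informative = 3, seed = 20 + s))
    cfg <- tso_config(pop_size = 20, iterations = 50, w1 = 1, w2 = 0,
                      seed = 200 + s)
    res <- bctso_select(tab, cfg)
    folds <- res$folds
    oracle <- 0
    for (mcode in 1:1023) {
      mask <- as.logical(intToBits(mcode)[1:10])
      acc <- subset_fitness(mask, tab, cfg, folds)$acc
      if (acc > oracle) oracle <- acc
    }
    expect_lte(res$cv_accuracy, oracle + 1e-12)  # oracle upper-bounds search
    if (res$cv_accuracy >= oracle - 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("pure-noise tables stay near the chance-fitness envelope", {
  tab <- generate_feature_table(
    feature_table_config(n_samples = 300, effect_size = 0, seed = 55))
  cfg <- tso_config(pop_size = 10, iterations = 20, seed = 56)
  res <- bctso_select(tab, cfg)
  n <- sum(res$best_mask)
  envelope <- 0.6 * 0.25 + 0.4 * (1 - n / 30)
  se <- 3 * sqrt(0.25 * 0.75 / 300)
  # winner's-curse slack on top of the binomial standard error
  expect_lt(res$best_fitness, envelope + 0.6 * (3 * se + 0.06))
})
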