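test_that("the printed architecture reproduces every published tensor size", {
  st <- propagate_shapes(ercp_net_spec(38), c(3, 416, 416))
  expect_identical(st[["Conv"]], c(16L, 208L, 208L))
  expect_identical(st[["MaxPool"]], c(16L, 104L, 104L))
  expect_identical(st[["CER_Block_1"]], c(48L, 52L, 52L))
  expect_identical(st[["ACA_Block_1"]], c(48L, 52L, 52L))
  expect_identical(st[["CER_Block_2"]], c(144L, 26L, 26L))
  expect_identical(st[["ACA_Block_2"]], c(144L, 26L, 26L))
  expect_identical(st[["CER_Block_3"]], c(432L, 13L, 13L))
  expect_identical(st[["ACA_Block_3"]], c(432L, 13L, 13L))
  expect_identical(st[["BIF_Block"]], c(1296L, 13L, 13L))
  expect_identical(st[["Global average pool"]], c(1296L, 1L, 1L))
  expect_identical(st[["Fully connected layer"]], 1296L)
  expect_identical(st[["Softmax"]], 38L)
})

test_that("shape propagation flags indivisible dims and empty nets", {
  empty <- structure(list(layers = list(), num_classes = 2L),
                     class = "arch_spec")
  expect_identical(propagate_shapes(empty, c(3, 50, 50)), list())
  expect_error(propagate_shapes(ercp_net_spec(4), c(3, 415, 415)),
               "Conv")
})

test_that("channel-expansion block triples channels and halves space", {
  x <- withr::with_seed(3, array(runif(16 * 104 * 104), c(16, 104, 104)))
  y <- cer_block_forward(x)
  expect_identical(dim(y), c(48L, 52L, 52L))
  # constant input: max-pools preserve the constant, residual doubles it
  const <- array(0.3, c(4, 8, 8))
  expect_equal(cer_block_forward(const), array(0.6, c(12, 4, 4)))
  # max-pool dominance: (out - tiled entry) >= stride-2-pooled input
  small <- withr::with_seed(4, array(runif(2 * 8 * 8), c(2, 8, 8)))
  ys <- cer_block_forward(small)
  pooled <- ys[1:2, , ] * 0
  for (i in 1:4) for (j in 1:4)
    pooled[, i, j] <- apply(small[, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                                  drop = FALSE], 1, max)
  for (b in 1:3)
    expect_true(all(ys[(2 * b - 1):(2 * b), , ] - pooled >= pooled - 1e-12))
  expect_error(cer_block_forward(array(0, c(2, 7, 7))), "even")
})

test_that("the reciprocal Gaussian transform inverts the density exactly", {
  v <- withr::with_seed(5, rnorm(32))
  out <- igpdf(v)
  expect_lt(max(abs(out * dnorm(v, mean(v), sd(v)) - 1)), 1e-9)
  # at the mean the value is sigma * sqrt(2 pi)
  v2 <- c(0, 1, 2)  # mean 1, sd 1
  expect_equal(igpdf(v2)[2], sqrt(2 * pi), tolerance = 1e-12)
  expect_error(igpdf(rep(0.7, 10)), "degenerate")
})

test_that("attention block preserves shape and adds bounded maps", {
  f <- withr::with_seed(6, array(runif(8 * 16 * 16), c(8, 16, 16)))
  out <- aca_block_forward(f, seed = 2)
  expect_identical(dim(out), dim(f))
  resid <- out - f  # channel gate + spatial map, each a sigmoid in (0, 1)
  expect_gt(min(resid), 0)
  expect_lt(max(resid), 2)
  expect_identical(aca_block_forward(f, seed = 2), out)
  mult <- aca_block_forward(f, combine = "multiplicative", seed = 2)
  expect_identical(dim(mult), dim(f))
  expect_true(all(mult <= f + 1e-12))  # two gates in (0,1) shrink the map
})

test_that("fusion pools, projects and concatenates to the printed shape", {
  taps <- withr::with_seed(7, list(
    array(runif(48 * 52 * 52), c(48, 52, 52)),
    array(runif(144 * 26 * 26), c(144, 26, 26)),
    array(runif(432 * 13 * 13), c(432, 13, 13))))
  fused <- bif_fuse(taps, seed = 1)
  expect_identical(dim(fused), c(1296L, 13L, 13L))
  single <- bif_fuse(taps[3], seed = 1)
  expect_identical(single, taps[[3]])
  expect_error(bif_fuse(list(array(0, c(4, 10, 10)), array(0, c(4, 7, 7)))),
               "divisible")
})

test_that("multi-scale residual block splits channels and keeps shape", {
  x <- withr::with_seed(8, array(runif(16 * 12 * 12), c(16, 12, 12)))
  for (s in c(1, 2, 4)) {
    y <- res2net_block_forward(x, s = s, seed = 3)
    expect_identical(dim(y), dim(x))
  }
  # s = 1 degenerates to the 1 x 1 convolution alone
  y1 <- res2net_block_forward(x, s = 1, seed = 3)
  w1 <- brainseg:::random_weights(16, 16, 1,
                                  brainseg:::child_seed(3, 0L))
  expect_equal(y1, brainseg:::conv2d_fm(x, w1), tolerance = 1e-12)
  expect_error(res2net_block_forward(x, s = 3), "divisible")
})

test_that("feature extraction is seeded and discriminates tumor intensity", {
  ph <- generate_phantom(phantom_config(image_size = 64, seed = 1))
  v1 <- extract_features(ph$image, seed = 9)
  expect_length(v1, 32)
  expect_identical(extract_features(ph$image, seed = 9), v1)
  hits <- 0
  for (t in 1:20) {
    pa <- generate_phantom(phantom_config(image_size = 64, tumor_mean = 0.8,
                                          tumor_radius_frac = 0.3,
                                          rician_sigma = 0.02, seed = 800 + t))
    pb <- generate_phantom(phantom_config(image_size = 64, tumor_mean = 0.5,
                                          tumor_radius_frac = 0.3,
                                          rician_sigma = 0.02, seed = 800 + t))
    # same anatomy and tumor, fresh noise realization
    base <- generate_phantom(phantom_config(image_size = 64, tumor_mean = 0.8,
                                            tumor_radius_frac = 0.3,
                                            seed = 800 + t))
    noise2 <- add_rician_noise(base$image, 0.02, seed = 900 + t)
    fa <- extract_features(pa$image, seed = 9)
    fb <- extract_features(pb$image, seed = 9)
    fn <- extract_features(noise2, seed = 9)
    if (sqrt(sum((fa - fb)^2)) > sqrt(sum((fa - fn)^2))) hits <- hits + 1
  }
  expect_gte(hits, 16)
})
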