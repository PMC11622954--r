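#' Phantom slice configuration
#'
#' Parameters of the simulated 2-D brain slice: an axis-aligned elliptical
#' brain (semi-axes 0.8 and 0.7 of the half image size) partitioned into
#' concentric tissue bands, a bright skull ring separated from the brain by a
#' dark gap, a randomly placed tumor disc with a low-order sinusoidal boundary
#' perturbation, a smooth unit-mean multiplicative bias field (sum of two
#' low-frequency cosines) and Rician magnitude noise.
#'
#' @param image_size pixels per side (square), at least 64.
#' @param n_tissues number of tissue classes (at least 2).
#' @param tissue_means intensity of each tissue in `[0, 1]`, strictly
#'   increasing, one per tissue.
#' @param tumor_mean tumor intensity in `[0, 1]`, distinct from every tissue
#'   mean.
#' @param tumor_radius_frac tumor radius as a fraction of the effective brain
#'   radius (geometric mean of the semi-axes), in `(0, 1)`.
#' @param bias_amplitude peak multiplicative bias-field deviation (unitless,
#'   nonnegative).
#' @param rician_sigma Rician noise scale in intensity units (nonnegative).
#' @param seed RNG seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L, n_tissues = 2L,
                           tissue_means = c(0.35, 0.55), tumor_mean = 0.8,
                           tumor_radius_frac = 0.2, bias_amplitude = 0,
                           rician_sigma = 0, seed = 1L) {
  if (image_size < 64) abort("invalid phantom config: image_size must be >= 64")
  if (n_tissues < 2) abort("invalid phantom config: n_tissues must be >= 2")
  if (length(tissue_means) != n_tissues)
    abort("invalid phantom config: tissue_means must have n_tissues entries")
  if (any(diff(tissue_means) <= 0))
    abort("invalid phantom config: tissue_means must be strictly increasing")
  if (any(tissue_means < 0) || any(tissue_means > 1) ||
      tumor_mean < 0 || tumor_mean > 1)
    abort("invalid phantom config: tissue_means/tumor_mean must lie in [0, 1]")
  if (any(abs(tissue_means - tumor_mean) < 1e-9))
    abort("invalid phantom config: tumor_mean must differ from tissue_means")
  if (tumor_radius_frac <= 0 || tumor_radius_frac >= 1)
    abort("invalid phantom config: tumor_radius_frac must lie in (0, 1)")
  if (bias_amplitude < 0)
    abort("invalid phantom config: bias_amplitude must be >= 0")
  if (rician_sigma < 0)
    abort("invalid phantom config: rician_sigma must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_tissues = as.integer(n_tissues),
                 tissue_means = as.numeric(tissue_means),
                 tumor_mean = as.numeric(tumor_mean),
                 tumor_radius_frac = tumor_radius_frac,
                 bias_amplitude = bias_amplitude,
                 rician_sigma = rician_sigma,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# geometry constants of the phantom: brain semi-axis fractions and the skull
# ring placement (scale factors of the brain ellipse)
.brain_ax <- 0.8
.brain_bx <- 0.7
.skull_inner <- 1.18
.skull_outer <- 1.26
.skull_intensity <- 0.95

#' Generate a ground-truthed phantom slice
#'
#' @param config a [phantom_config()].
#' @return object of class `labeled_phantom`: list with `image` (numeric
#'   matrix in `[0, 1]`), `labels` (integer raster: 0 background/skull,
#'   `1..n_tissues` tissues, `n_tissues + 1` tumor), `brain_mask` (logical
#'   raster, `TRUE` exactly where `labels > 0`) and the `config`.
#' @details With `rician_sigma = 0` and `bias_amplitude = 0` the image is
#'   exactly piecewise constant at the configured intensities. Output is
#'   bit-identical for a fixed seed.
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  n <- config$image_size
  half <- n / 2
  a <- .brain_ax * half
  b <- .brain_bx * half
  cx <- half + 0.5
  cy <- half + 0.5
  xs <- matrix(rep(seq_len(n), each = n), n)   # column coordinate
  ys <- matrix(rep(seq_len(n), times = n), n)  # row coordinate
  # normalized elliptical radius (1 on the brain boundary)
  er <- sqrt(((xs - cx) / a)^2 + ((ys - cy) / b)^2)
  brain <- er <= 1
  skull <- er > .skull_inner & er <= .skull_outer

  labels <- matrix(0L, n, n)
  # concentric tissue bands, innermost band is tissue 1
  band <- pmin(config$n_tissues, 1L + floor(er * config$n_tissues))
  labels[brain] <- band[brain]

  r_eff <- sqrt(a * b)
  r0 <- config$tumor_radius_frac * r_eff
  withr::with_seed(config$seed, {
    tumor <- .place_tumor(xs, ys, cx, cy, a, b, r0)
    labels[tumor & brain] <- config$n_tissues + 1L

    image <- matrix(0, n, n)
    values <- c(config$tissue_means, config$tumor_mean)
    inside <- labels > 0L
    image[inside] <- values[labels[inside]]
    image[skull] <- .skull_intensity

    if (config$bias_amplitude > 0) {
      bias <- .bias_field(n, config$bias_amplitude)
      image <- clip01(image * bias)
    }
    noise_seed <- child_seed(config$seed, 1L)
  })
  if (config$rician_sigma > 0)
    image <- add_rician_noise(image, config$rician_sigma, seed = noise_seed)

  structure(list(image = image, labels = labels, brain_mask = brain,
                 config = config),
            class = "labeled_phantom")
}

# sample a tumor center such that the perturbed disc stays inside the brain
# ellipse, then rasterize the disc with a low-order sinusoidal boundary
.place_tumor <- function(xs, ys, cx, cy, a, b, r0) {
  rmax <- r0 * 1.15  # maximum boundary perturbation is 13%
  for (try in 1:200) {
    tx <- cx + runif(1, -a, a)
    ty <- cy + runif(1, -b, b)
    # center must lie inside the ellipse shrunk by rmax on both axes
    if (((tx - cx) / (a - rmax))^2 + ((ty - cy) / (b - rmax))^2 <= 1) break
  }
  ph1 <- runif(1, 0, 2 * pi)
  ph2 <- runif(1, 0, 2 * pi)
  theta <- atan2(ys - ty, xs - tx)
  rb <- r0 * (1 + 0.08 * sin(3 * theta + ph1) + 0.05 * sin(5 * theta + ph2))
  sqrt((xs - tx)^2 + (ys - ty)^2) <= rb
}

# unit-mean multiplicative bias surface: sum of two low-frequency cosines
# with random phase, rescaled so the peak deviation equals `amplitude`
.bias_field <- function(n, amplitude) {
  u <- seq(0, 1, length.out = n)
  p1 <- runif(1, 0, 2 * pi)
  p2 <- runif(1, 0, 2 * pi)
  g <- outer(cos(2 * pi * 0.7 * u + p1), cos(2 * pi * 0.9 * u + p2), "+") / 2
  g <- g - mean(g)
  1 + amplitude * g / max(abs(g))
}

#' Add Rician magnitude noise to an image
#'
#' Models MRI magnitude noise: the image is treated as the real channel,
#' independent Gaussian noise of scale `sigma` is added to real and imaginary
#' channels, and the magnitude is taken:
#' \deqn{out = \sqrt{(x + \sigma g_1)^2 + (\sigma g_2)^2}}
#' with standard normal fields \eqn{g_1, g_2}, clipped to `[0, 1]`.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param sigma noise scale in intensity units (nonnegative). `sigma = 0`
#'   returns the input unchanged.
#' @param seed RNG seed.
#' @return noisy image, same shape, values in `[0, 1]`.
#' @export
add_rician_noise <- function(image, sigma, seed = 1L) {
  check_gray_image(image)
  if (sigma < 0) abort("sigma must be >= 0")
  if (sigma == 0) return(image)
  withr::with_seed(seed, {
    g1 <- matrix(rnorm(length(image)), nrow(image))
    g2 <- matrix(rnorm(length(image)), nrow(image))
  })
  clip01(sqrt((image + sigma * g1)^2 + (sigma * g2)^2))
}

#' Feature table configuration
#'
#' Class-structured tabular data with a known informative feature subset,
#' emulating the shape/texture feature tables a wrapper selector operates
#' on. Each informative column is a class marker: samples of one class (the
#' classes are covered cyclically in shuffled order) are shifted so that the
#' marked class is `effect_size` feature standard deviations away from the
#' rest, with the column mean centered. Markers for different classes are
#' complementary rather than redundant copies of one signal, as real shape,
#' texture and intensity descriptors are. Non-informative columns are
#' standard normal regardless of class. The default is the four-class
#' tumor-typing setting.
#'
#' @param n_samples,n_features table dimensions.
#' @param n_informative number of informative features (at least 1, at most
#'   `n_features`).
#' @param n_classes number of classes.
#' @param class_proportions nonnegative, sums to 1; one entry per class.
#' @param effect_size mean shift between adjacent classes on informative
#'   features, in units of the feature standard deviation.
#' @param seed RNG seed.
#' @return object of class `feature_table_config`.
#' @export
feature_table_config <- function(n_samples = 300L, n_features = 30L,
                                 n_informative = 5L, n_classes = 4L,
                                 class_proportions = NULL, effect_size = 2,
                                 seed = 1L) {
  if (is.null(class_proportions))
    class_proportions <- rep(1 / n_classes, n_classes)
  if (n_informative < 1) abort("invalid config: n_informative must be >= 1")
  if (n_informative > n_features)
    abort("invalid config: n_informative exceeds n_features")
  if (length(class_proportions) != n_classes)
    abort("invalid config: class_proportions must have n_classes entries")
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9)
    abort("invalid config: class_proportions must be nonnegative and sum to 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 n_classes = as.integer(n_classes),
                 class_proportions = as.numeric(class_proportions),
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "feature_table_config")
}

#' Generate a class-structured feature table
#'
#' @param config a [feature_table_config()].
#' @return object of class `feature_table`: list with `matrix`
#'   (`n_samples x n_features`), `labels` (integer classes `1..n_classes`),
#'   `informative_mask` (logical per feature) and the `config`.
#' @export
generate_feature_table <- function(config) {
  if (!inherits(config, "feature_table_config"))
    config <- do.call(feature_table_config, config)
  withr::with_seed(config$seed, {
    labels <- sample.int(config$n_classes, config$n_samples, replace = TRUE,
                         prob = config$class_proportions)
    mask <- logical(config$n_features)
    mask[sample.int(config$n_features, config$n_informative)] <- TRUE
    X <- matrix(rnorm(config$n_samples * config$n_features),
                config$n_samples, config$n_features)
    # each informative column marks one class (cyclic shuffled coverage):
    # marked class mean - rest mean = effect_size, column centered
    K <- config$n_classes
    e <- config$effect_size
    coverage <- rep_len(sample.int(K), config$n_informative)
    fi <- which(mask)
    for (i in seq_along(fi)) {
      X[, fi[i]] <- X[, fi[i]] +
        ifelse(labels == coverage[i], e * (K - 1) / K, -e / K)
    }
  })
  colnames(X) <- sprintf("f%03d", seq_len(config$n_features))
  structure(list(matrix = X, labels = labels, informative_mask = mask,
                 config = config),
            class = "feature_table")
}
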