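#' Layer specification
#'
#' One layer of the channel-expansion residual attention network, identified
#' by `kind`:
#' \describe{
#'   \item{conv}{`out_channels`, `kernel` (odd), `stride`.}
#'   \item{maxpool}{`window`, `stride`.}
#'   \item{cer_block}{channel-expansion residual block: stride-2 entry
#'     max-pool, three parallel same-padded max-pools (windows 3/5/7)
#'     concatenated, plus the entry tensor tiled threefold along channels.
#'     Triples channels, halves spatial size, parameter-free.}
#'   \item{aca_block}{attention block; shape-preserving. `kernel` is the
#'     spatial-attention convolution size.}
#'   \item{bif_block}{multi-stage fusion: `taps` names earlier layers whose
#'     outputs are pooled to the deepest tap's spatial size, projected 1x1
#'     to its channel count and concatenated.}
#'   \item{res2net_block}{multi-scale residual block with `s` channel
#'     subsets; shape-preserving.}
#'   \item{gap}{global average pool to `(C, 1, 1)`.}
#'   \item{fc}{fully connected; `width` (defaults to incoming channels).}
#'   \item{softmax}{terminal class scores; `width` = number of classes.}
#' }
#'
#' @param name unique layer name.
#' @param kind one of the kinds above.
#' @param ... kind-specific parameters.
#' @return object of class `layer_spec`.
#' @export
layer_spec <- function(name, kind, ...) {
  kinds <- c("conv", "maxpool", "cer_block", "aca_block", "bif_block",
             "res2net_block", "gap", "fc", "softmax")
  if (!kind %in% kinds) abort("unknown layer kind: ", kind)
  params <- list(...)
  if (kind == "conv") {
    params$kernel <- params$kernel %||% 3L
    params$stride <- params$stride %||% 1L
    if (params$stride < 1) abort("stride must be >= 1")
    if (params$stride == 1 && params$kernel %% 2 == 0)
      abort("kernel must be odd for same-padding layers")
  }
  structure(c(list(name = name, kind = kind), params), class = "layer_spec")
}

#' Architecture of the printed channel-expansion residual classifier
#'
#' Stem (3x3 conv, stride 2, 16 filters; 2x2 max-pool, stride 2), three
#' channel-expansion residual blocks each followed by an attention block,
#' a fusion block over the three attention outputs, global average pooling,
#' a fully connected layer and a softmax head.
#'
#' @param num_classes softmax width (default 38, matching the printed
#'   configuration; use 4 for a four-class brain-tumor task).
#' @return object of class `arch_spec`: list of [layer_spec()]s plus
#'   `num_classes`.
#' @export
ercp_net_spec <- function(num_classes = 38L) {
  layers <- list(
    layer_spec("Conv", "conv", out_channels = 16L, kernel = 3L, stride = 2L),
    layer_spec("MaxPool", "maxpool", window = 2L, stride = 2L),
    layer_spec("CER_Block_1", "cer_block"),
    layer_spec("ACA_Block_1", "aca_block", kernel = 7L),
    layer_spec("CER_Block_2", "cer_block"),
    layer_spec("ACA_Block_2", "aca_block", kernel = 7L),
    layer_spec("CER_Block_3", "cer_block"),
    layer_spec("ACA_Block_3", "aca_block", kernel = 7L),
    layer_spec("BIF_Block", "bif_block",
               taps = c("ACA_Block_1", "ACA_Block_2", "ACA_Block_3")),
    layer_spec("Global average pool", "gap"),
    layer_spec("Fully connected layer", "fc"),
    layer_spec("Softmax", "softmax", width = as.integer(num_classes))
  )
  structure(list(layers = layers, num_classes = as.integer(num_classes)),
            class = "arch_spec")
}

#' Propagate tensor shapes through an architecture
#'
#' Pure integer arithmetic per layer kind; no weights are involved.
#'
#' @param arch an `arch_spec` (e.g. [ercp_net_spec()]).
#' @param input_shape integer triple `(channels, height, width)`.
#' @return named list mapping layer name to its output shape (triples for
#'   spatial layers, single widths for `fc`/`softmax`).
#' @export
propagate_shapes <- function(arch, input_shape) {
  shp <- as.integer(input_shape)
  out <- list()
  get_tap <- function(nm) {
    if (is.null(out[[nm]])) abort("fusion tap '", nm, "' must precede the fusion layer")
    out[[nm]]
  }
  for (ly in arch$layers) {
    shp <- switch(ly$kind,
      conv = {
        if (any(shp[2:3] %% ly$stride != 0))
          abort("layer '", ly$name, "': spatial dims not divisible by stride")
        c(ly$out_channels, shp[2:3] %/% ly$stride)
      },
      maxpool = {
        if (any(shp[2:3] %% ly$stride != 0))
          abort("layer '", ly$name, "': spatial dims not divisible by stride")
        c(shp[1], shp[2:3] %/% ly$stride)
      },
      cer_block = {
        if (any(shp[2:3] %% 2L != 0))
          abort("layer '", ly$name, "': spatial dims must be even")
        c(3L * shp[1], shp[2:3] %/% 2L)
      },
      aca_block = shp,
      res2net_block = {
        if (shp[1] %% ly$s != 0)
          abort("layer '", ly$name, "': channels not divisible by s")
        shp
      },
      bif_block = {
        taps <- lapply(ly$taps, get_tap)
        spat <- vapply(taps, function(t) t[2], numeric(1))
        deepest <- taps[[which.min(spat)]]
        for (t in taps)
          if (any(t[2:3] %% deepest[2:3] != 0))
            abort("layer '", ly$name, "': tap not divisible to deepest size")
        c(length(taps) * deepest[1], deepest[2:3])
      },
      gap = c(shp[1], 1L, 1L),
      fc = ly$width %||% prod(shp),
      softmax = ly$width,
      abort("unknown layer kind: ", ly$kind)
    )
    shp <- as.integer(shp)
    out[[ly$name]] <- shp
  }
  out
}

# --- tensor helpers: feature maps are arrays (C, H, W) -----------------------

as_feature_map <- function(x) {
  if (is.matrix(x)) array(x, c(1L, dim(x))) else x
}

# stride-s max pool with window w (w == s for entry pools)
maxpool_fm <- function(x, window, stride = window) {
  d <- dim(x)
  if (any(d[2:3] %% stride != 0)) abort("spatial dims not divisible by stride")
  H <- d[2] %/% stride; W <- d[3] %/% stride
  out <- array(-Inf, c(d[1], H, W))
  for (di in seq_len(window)) for (dj in seq_len(window)) {
    ri <- pmin((seq_len(H) - 1L) * stride + di, d[2])
    ci <- pmin((seq_len(W) - 1L) * stride + dj, d[3])
    out <- pmax(out, x[, ri, ci, drop = FALSE])
  }
  out
}

# same-padded stride-1 max pool, odd window, mirror padding
maxpool_same <- function(x, window) {
  r <- (window - 1L) %/% 2L
  d <- dim(x)
  out <- array(-Inf, d)
  ridx <- reflect_index(d[2], r)
  cidx <- reflect_index(d[3], r)
  for (di in 0:(window - 1L)) for (dj in 0:(window - 1L)) {
    out <- pmax(out, x[, ridx[(1 + di):(d[2] + di)],
                       cidx[(1 + dj):(d[3] + dj)], drop = FALSE])
  }
  out
}

# zero-padded 2-D convolution: weights (Cout, Cin, k, k), odd k, stride 1
conv2d_fm <- function(x, w, bias = NULL) {
  d <- dim(x); k <- dim(w)[3]; r <- (k - 1L) %/% 2L
  Cout <- dim(w)[1]
  xp <- array(0, c(d[1], d[2] + 2L * r, d[3] + 2L * r))
  xp[, (r + 1):(r + d[2]), (r + 1):(r + d[3])] <- x
  out <- array(0, c(Cout, d[2], d[3]))
  for (o in seq_len(Cout)) {
    acc <- matrix(0, d[2], d[3])
    for (ci in seq_len(d[1])) for (di in seq_len(k)) for (dj in seq_len(k)) {
      acc <- acc + w[o, ci, di, dj] *
        xp[ci, (di):(di + d[2] - 1L), (dj):(dj + d[3] - 1L)]
    }
    out[o, , ] <- acc + if (is.null(bias)) 0 else bias[o]
  }
  out
}

# strided conv: apply same-padded conv then subsample
conv2d_strided <- function(x, w, stride, bias = NULL) {
  full <- conv2d_fm(x, w, bias)
  if (stride == 1L) return(full)
  d <- dim(full)
  full[, seq(1L, d[2], by = stride), seq(1L, d[3], by = stride), drop = FALSE]
}

# seeded He-style random weights (Cout, Cin, k, k)
random_weights <- function(Cout, Cin, k, seed) {
  withr::with_seed(seed, {
    array(rnorm(Cout * Cin * k * k, sd = 1 / sqrt(Cin * k * k)),
          c(Cout, Cin, k, k))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Channel-expansion residual block forward pass
#'
#' Entry stride-2 max-pool (spatial halving), three parallel same-padded
#' max-pools with windows 3, 5 and 7, channel concatenation (tripling the
#' channel count) and a residual addition of the entry tensor tiled three
#' times along channels. Parameter-free by construction.
#'
#' @param x feature map array `(C, H, W)` with even `H`, `W`.
#' @return feature map `(3C, H/2, W/2)`.
#' @export
cer_block_forward <- function(x) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (any(d[2:3] %% 2L != 0)) abort("spatial dims must be even")
  entry <- maxpool_fm(x, 2L, 2L)
  pooled <- lapply(c(3L, 5L, 7L), function(w) maxpool_same(entry, w))
  cat_ <- array(0, c(3L * d[1], d[2] %/% 2L, d[3] %/% 2L))
  for (b in 1:3)
    cat_[((b - 1L) * d[1] + 1L):(b * d[1]), , ] <- pooled[[b]]
  tiled <- array(0, dim(cat_))
  for (b in 1:3)
    tiled[((b - 1L) * d[1] + 1L):(b * d[1]), , ] <- entry
  cat_ + tiled
}

#' Reciprocal Gaussian density transform
#'
#' The pointwise inverse of the Gaussian likelihood density with mean and
#' standard deviation estimated from the vector itself:
#' \deqn{IGPDF(v) = \sigma \sqrt{2\pi} \exp((v - \mu)^2 / (2 \sigma^2))}
#' so that `igpdf(v) * dnorm(v, mu, sigma) = 1` elementwise. Values far from
#' the channel mean are amplified, which is the attention block's saliency
#' signal.
#'
#' @param v numeric vector of pooled channel statistics.
#' @return transformed vector.
#' @export
igpdf <- function(v) {
  mu <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 1e-8) abort("degenerate channel statistics")
  s * sqrt(2 * pi) * exp((v - mu)^2 / (2 * s^2))
}

#' Attention block forward pass
#'
#' Channel branch: global average-pool and max-pool vectors are transformed
#' by [igpdf()], summed and squashed by a sigmoid, giving one gate per
#' channel. Spatial branch: channelwise mean and max maps are stacked and
#' convolved (`kernel x kernel`, seeded random weights) into a single
#' sigmoid map. In the default `"additive"` mode the output is
#' `F + channel_gate + spatial_map`; `"multiplicative"` gates `F` by both
#' maps instead. Shape-preserving either way.
#'
#' @param x feature map `(C, H, W)`.
#' @param kernel spatial-attention convolution size (odd).
#' @param combine `"additive"` or `"multiplicative"`.
#' @param seed RNG seed for the spatial convolution weights.
#' @return feature map with the input's shape.
#' @export
aca_block_forward <- function(x, kernel = 7L, combine = c("additive", "multiplicative"),
                              seed = 1L) {
  combine <- match.arg(combine)
  x <- as_feature_map(x)
  d <- dim(x)
  avg <- apply(x, 1L, mean)
  mx <- apply(x, 1L, max)
  gate <- sigmoid(igpdf(avg) + igpdf(mx))
  mean_map <- apply(x, c(2L, 3L), mean)
  max_map <- apply(x, c(2L, 3L), max)
  stacked <- array(0, c(2L, d[2], d[3]))
  stacked[1L, , ] <- mean_map
  stacked[2L, , ] <- max_map
  w <- random_weights(1L, 2L, kernel, seed)
  ms <- sigmoid(conv2d_fm(stacked, w)[1L, , ])
  out <- array(0, d)
  for (ci in seq_len(d[1])) {
    out[ci, , ] <- if (combine == "additive")
      x[ci, , ] + gate[ci] + ms
    else
      x[ci, , ] * gate[ci] * ms
  }
  out
}

#' Multi-stage feature fusion forward pass
#'
#' Each shallow tap is max-pooled down to the deepest tap's spatial size and
#' projected by a seeded random 1x1 convolution to the deepest tap's channel
#' count; all taps are then concatenated along channels. A single tap passes
#' through unchanged.
#'
#' @param taps list of feature maps, shallowest first.
#' @param seed RNG seed for the projection weights.
#' @return fused feature map `(n_taps * C_deep, H_deep, W_deep)`.
#' @export
bif_fuse <- function(taps, seed = 1L) {
  taps <- lapply(taps, as_feature_map)
  if (length(taps) == 1L) return(taps[[1L]])
  spat <- vapply(taps, function(t) dim(t)[2], numeric(1))
  deep <- taps[[which.min(spat)]]
  dd <- dim(deep)
  proj <- vector("list", length(taps))
  for (i in seq_along(taps)) {
    t <- taps[[i]]
    ratio <- dim(t)[2] / dd[2]
    if (ratio != round(ratio) || dim(t)[3] / dd[3] != ratio)
      abort("tap ", i, " not divisible to the deepest spatial size")
    if (ratio > 1) t <- maxpool_fm(t, as.integer(ratio), as.integer(ratio))
    if (dim(t)[1] != dd[1]) {
      w <- random_weights(dd[1], dim(t)[1], 1L, child_seed(seed, i))
      t <- conv2d_fm(t, w)
    }
    proj[[i]] <- t
  }
  out <- array(0, c(length(taps) * dd[1], dd[2], dd[3]))
  for (i in seq_along(proj))
    out[((i - 1L) * dd[1] + 1L):(i * dd[1]), , ] <- proj[[i]]
  out
}

#' Multi-scale residual block forward pass
#'
#' A 1x1 convolution followed by an equal split into `s` channel subsets
#' `x_1..x_s`; `y_1 = x_1` and `y_i = conv3x3(x_i + y_{i-1})` for `i >= 2`;
#' the `y_i` are concatenated. Shape-preserving.
#'
#' @param x feature map `(C, H, W)` with `C` divisible by `s`.
#' @param s number of channel subsets.
#' @param seed RNG seed for the convolution weights.
#' @return feature map with the input's shape.
#' @export
res2net_block_forward <- function(x, s = 4L, seed = 1L) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] %% s != 0) abort("channels not divisible by s")
  g <- d[1] %/% s
  w1 <- random_weights(d[1], d[1], 1L, child_seed(seed, 0L))
  x <- conv2d_fm(x, w1)
  out <- array(0, d)
  yprev <- NULL
  for (i in seq_len(s)) {
    idx <- ((i - 1L) * g + 1L):(i * g)
    xi <- x[idx, , , drop = FALSE]
    if (i == 1L) {
      yi <- xi
    } else {
      w <- random_weights(g, g, 3L, child_seed(seed, i))
      yi <- conv2d_fm(xi + yprev, w)
    }
    out[idx, , ] <- yi
    yprev <- yi
  }
  out
}

#' Multi-scale feature extraction configuration
#' @param input_size square input side the image is resized to.
#' @param stem_channels channels of the stride-2 stem convolution.
#' @param stage_channels channel count per stage; each stage is a 1x1
#'   channel projection, a 2x2 stride-2 max-pool and a multi-scale residual
#'   block. The final entry is the feature vector length.
#' @param s channel subsets per residual block.
#' @return list configuration.
#' @export
res2net_config <- function(input_size = 64L, stem_channels = 8L,
                           stage_channels = c(16L, 32L), s = 4L) {
  list(input_size = as.integer(input_size),
       stem_channels = as.integer(stem_channels),
       stage_channels = as.integer(stage_channels), s = as.integer(s))
}

#' Extract a multi-scale feature vector from an image
#'
#' A deterministic, untrained multiscale feature bank: the image is resized
#' to the configured input size and passed through a seeded random-weight
#' stem plus multi-scale residual stages; the global-average-pooled
#' activations of the last stage are returned.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param config a [res2net_config()].
#' @param seed RNG seed for all weights.
#' @return numeric vector of length `tail(config$stage_channels, 1)`.
#' @export
extract_features <- function(image, config = res2net_config(), seed = 1L) {
  check_gray_image(image)
  img <- EBImage::resize(EBImage::Image(image),
                         w = config$input_size, h = config$input_size)
  x <- array(matrix(EBImage::imageData(img), config$input_size),
             c(1L, config$input_size, config$input_size))
  wstem <- random_weights(config$stem_channels, 1L, 3L, child_seed(seed, 100L))
  x <- tanh(conv2d_strided(x, wstem, 2L))
  for (st in seq_along(config$stage_channels)) {
    ch <- config$stage_channels[st]
    wproj <- random_weights(ch, dim(x)[1], 1L, child_seed(seed, 200L + st))
    x <- conv2d_fm(x, wproj)
    x <- maxpool_fm(x, 2L, 2L)
    x <- tanh(res2net_block_forward(x, config$s, child_seed(seed, 300L + st)))
  }
  apply(x, 1L, mean)
}
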