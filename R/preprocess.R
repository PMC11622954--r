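#' Skull stripping by thresholding and morphology
#'
#' Removes the skull ring and background from a slice: Otsu threshold,
#' binary closing (disc of radius 3), largest connected foreground component,
#' then erosion (disc of radius 2). The returned image is the input with
#' everything outside the brain mask zeroed.
#'
#' @param image numeric matrix in `[0, 1]` with `max > min`.
#' @return list with `image` (masked slice) and `brain_mask` (logical raster).
#' @export
strip_skull <- function(image) {
  check_gray_image(image)
  if (max(image) <= min(image)) abort("no foreground")
  thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  fg <- EBImage::Image(image > thr)
  fg <- EBImage::closing(fg, EBImage::makeBrush(7, "disc"))
  lab <- EBImage::bwlabel(fg)
  counts <- tabulate(as.integer(lab))
  if (length(counts) == 0) abort("no foreground")
  keep <- which.max(counts)
  comp <- EBImage::Image(as.integer(lab) == keep, dim = dim(image))
  comp <- EBImage::erode(comp, EBImage::makeBrush(5, "disc"))
  mask <- matrix(as.logical(EBImage::imageData(comp)), nrow(image))
  out <- image
  out[!mask] <- 0
  list(image = out, brain_mask = mask)
}

#' Median filter with mirror padding
#'
#' Each pixel is replaced by the median of the odd `window` x `window`
#' neighborhood; borders are handled by mirror-reflection padding.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param window odd integer window side, at least 3.
#' @return filtered image, same shape; output range within input range.
#' @export
median_filter <- function(image, window = 3L) {
  check_gray_image(image)
  if (window %% 2 != 1 || window < 3) abort("window must be an odd integer >= 3")
  r <- (window - 1L) %/% 2L
  xp <- pad_reflect(image, r)
  n <- nrow(image); m <- ncol(image)
  stack <- matrix(0, n * m, window * window)
  k <- 0L
  for (di in -r:r) for (dj in -r:r) {
    k <- k + 1L
    stack[, k] <- xp[(1 + r + di):(n + r + di), (1 + r + dj):(m + r + dj)]
  }
  matrix(apply(stack, 1L, median), n, m)
}

#' Entropy-adaptive contrast-limited histogram equalization
#'
#' Tile-wise CLAHE in which each tile's clip limit is scaled by that tile's
#' normalized histogram entropy: `clip(tile) = base_clip * (0.5 +
#' H(tile) / log2(nbins))`, so busier (higher-entropy) tiles get more
#' equalization headroom. Per-tile mappings are blended by bilinear
#' interpolation between tile centers.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param tiles integer vector `c(rows, cols)` of the tile grid, each at
#'   least 2.
#' @param base_clip base clip limit as a fraction of tile pixels per bin
#'   pool, in `(0, 1]`.
#' @param nbins number of histogram bins.
#' @return enhanced image in `[0, 1]`. A constant image is returned
#'   unchanged with a warning.
#' @export
acclahe <- function(image, tiles = c(8L, 8L), base_clip = 0.01, nbins = 64L) {
  check_gray_image(image)
  if (length(tiles) == 1L) tiles <- rep(tiles, 2L)
  if (any(tiles < 2)) abort("tiles must be at least 2 x 2")
  if (base_clip <= 0 || base_clip > 1) abort("base_clip must lie in (0, 1]")
  if (max(image) - min(image) < 1e-12) {
    warning("constant image: returned unchanged")
    return(image)
  }
  n <- nrow(image); m <- ncol(image)
  ty <- tiles[1L]; tx <- tiles[2L]
  # tile boundaries (pixels assigned to nearest tile by index arithmetic)
  row_edges <- round(seq(0, n, length.out = ty + 1))
  col_edges <- round(seq(0, m, length.out = tx + 1))
  bin <- pmin(floor(image * nbins), nbins - 1L) + 1L  # bin index 1..nbins

  # per-tile clipped-CDF mappings: maps array [ty, tx, nbins] -> [0,1]
  maps <- array(0, c(ty, tx, nbins))
  centers_r <- numeric(ty); centers_c <- numeric(tx)
  for (i in seq_len(ty)) {
    rows <- (row_edges[i] + 1L):row_edges[i + 1L]
    centers_r[i] <- mean(rows)
    for (j in seq_len(tx)) {
      cols <- (col_edges[j] + 1L):col_edges[j + 1L]
      if (i == 1L) centers_c[j] <- mean(cols)
      h <- tabulate(bin[rows, cols], nbins)
      npix <- sum(h)
      p <- h / npix
      nz <- p > 0
      entropy <- -sum(p[nz] * log2(p[nz]))
      clip_frac <- base_clip * (0.5 + entropy / log2(nbins))
      cap <- max(1, round(clip_frac * npix))
      excess <- sum(pmax(h - cap, 0))
      h <- pmin(h, cap) + excess / nbins
      cdf <- cumsum(h) / sum(h)
      maps[i, j, ] <- cdf
    }
  }

  # bilinear blend of the four surrounding tile mappings at each pixel
  ri <- row(image); ci <- col(image)
  i0 <- pmin(pmax(findInterval(ri, centers_r), 1L), ty - 1L)
  j0 <- pmin(pmax(findInterval(ci, centers_c), 1L), tx - 1L)
  wr <- (ri - centers_r[i0]) / (centers_r[i0 + 1L] - centers_r[i0])
  wc <- (ci - centers_c[j0]) / (centers_c[j0 + 1L] - centers_c[j0])
  wr <- pmin(pmax(wr, 0), 1); wc <- pmin(pmax(wc, 0), 1)
  idx <- function(ii, jj) maps[cbind(as.vector(ii), as.vector(jj), as.vector(bin))]
  v00 <- idx(i0, j0); v01 <- idx(i0, j0 + 1L)
  v10 <- idx(i0 + 1L, j0); v11 <- idx(i0 + 1L, j0 + 1L)
  out <- (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
  matrix(clip01(out), n, m)
}

#' Peak signal-to-noise ratio and RMS contrast
#'
#' `psnr = 10 log10(peak^2 / MSE)` with peak 1; `contrast` is the RMS
#' (population standard deviation) of the test image's intensities, times 100.
#'
#' @param reference,test numeric matrices of identical shape in `[0, 1]`.
#' @return list with `psnr` (dB) and `contrast`.
#' @export
enhancement_metrics <- function(reference, test) {
  check_gray_image(reference, "reference")
  check_gray_image(test, "test")
  if (!identical(dim(reference), dim(test))) abort("image shapes differ")
  mse <- mean((reference - test)^2)
  if (mse == 0) abort("infinite PSNR: images are identical")
  list(psnr = 10 * log10(1 / mse), contrast = 100 * rms_contrast(test))
}

# population standard deviation of pixel intensities
rms_contrast <- function(image) sqrt(mean((image - mean(image))^2))
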