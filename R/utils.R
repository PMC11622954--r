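#' @importFrom stats runif rnorm sd median var dist setNames
#' @importFrom withr with_seed
NULL

# Stop with the caller's message, no call in the condition.
abort <- function(...) stop(..., call. = FALSE)

# Validate a 2-D grayscale raster in [0, 1].
check_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    abort(arg, " must be a numeric matrix")
  if (any(!is.finite(image)))
    abort(arg, " contains non-finite values")
  if (min(image) < 0 || max(image) > 1)
    abort(arg, " must have values in [0, 1]")
  invisible(image)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Mirror-reflection pad of a matrix by `p` on all sides (edge not repeated).
# The reflection path is cyclic, so pads deeper than the raster and 1-row
# ("1-D") inputs stay legal.
pad_reflect <- function(x, p) {
  n <- nrow(x); m <- ncol(x)
  ridx <- reflect_index(n, p)
  cidx <- reflect_index(m, p)
  x[ridx, cidx, drop = FALSE]
}

reflect_index <- function(n, p) {
  if (n == 1L) return(rep(1L, n + 2L * p))
  # mirror path 1..n..1..n.. gives symmetric reflection of any depth
  cycle <- c(seq_len(n), seq(n - 1L, 2L))
  pos <- seq(-p, n - 1L + p) %% length(cycle) + 1L
  cycle[pos]
}

# Sum over the square window of half-width r at each pixel (reflect padding).
window_sum <- function(x, r) {
  xp <- pad_reflect(x, r)
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (di in -r:r) for (dj in -r:r)
    out <- out + xp[(1 + r + di):(n + r + di), (1 + r + dj):(m + r + dj)]
  out
}

# Derive a bounded child seed from a base seed and a stream index.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
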