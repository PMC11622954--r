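# Independent oracles, coded without reusing package internals.

# Plain fuzzy c-means on a 1-D vector, mirroring the alternating schedule:
# memberships from centers, centers from memberships, objective with the
# updated centers; stop on max center shift < tol.
fcm_oracle <- function(x, cc, m, V0, max_iter = 100, tol = 1e-5) {
  V <- as.numeric(V0)
  n <- length(x)
  U <- matrix(0, cc, n)
  J <- NA_real_
  for (it in seq_len(max_iter)) {
    d2 <- sapply(x, function(xx) (xx - V)^2)   # cc x n
    for (j in seq_len(n)) {
      z <- which(d2[, j] < 1e-15)
      if (length(z)) {
        U[, j] <- 0
        U[z[1], j] <- 1
      } else {
        for (i in seq_len(cc))
          U[i, j] <- 1 / sum((d2[i, j] / d2[, j])^(1 / (m - 1)))
      }
    }
    W <- U^m
    newV <- as.numeric((W %*% x) / rowSums(W))
    d2new <- sapply(x, function(xx) (xx - newV)^2)
    J <- sum(W * d2new)
    shift <- max(abs(newV - V))
    V <- newV
    if (shift < tol) break
  }
  labels <- apply(U, 2, which.max)
  list(V = V, labels = labels, objective = J)
}

# Brute-force spatial penalty for one pixel (row r0, col c0), mirror padding.
g_bruteforce <- function(image, U, v_i, u_i_raster, m, r0, c0, radius = 1) {
  n <- nrow(image); mm <- ncol(image)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  g <- 0
  for (di in -radius:radius) for (dj in -radius:radius) {
    if (di == 0 && dj == 0) next
    rr <- refl(r0 + di, n); cc <- refl(c0 + dj, mm)
    w <- 1 / (1 + sqrt(di^2 + dj^2))
    g <- g + w * (1 - u_i_raster[rr, cc])^m * (image[rr, cc] - v_i)^2
  }
  g
}

# matched tumor Dice of a 0-based predicted label raster against phantom truth
tumor_dice <- function(label_map, truth_labels) {
  tl <- max(truth_labels)
  perm <- match_labels(label_map, truth_labels)
  pl <- as.integer(names(perm)[!is.na(perm) & perm == tl])
  if (length(pl) == 0) return(0)
  dice_iou(label_map == pl, truth_labels == tl)$dice
}

# phantom with impulse ("salt") noise at a given pixel fraction
salt_phantom <- function(seed, image_size = 128, frac = 0.02) {
  ph <- generate_phantom(phantom_config(image_size = image_size, seed = seed))
  img <- ph$image * ph$brain_mask
  withr::with_seed(seed + 5000L, {
    idx <- sample(length(img), round(frac * length(img)))
  })
  img[idx] <- 1.0
  list(image = img, phantom = ph)
}
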