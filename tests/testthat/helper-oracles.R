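# Independent brute-force oracles used across the suite. These are written
# as plain loops over the defining formulas, deliberately sharing no code
# with the implementation they check.

# 3D convolution by direct summation, double precision.
ref_conv3d <- function(x, w, b, k, stride = 1, dil = 1) {
  d <- dim(x); C <- d[1]; D <- d[2]; H <- d[3]; W <- d[4]; B <- d[5]
  pad <- dil * (k - 1) / 2
  oD <- (D + 2 * pad - dil * (k - 1) - 1) %/% stride + 1
  oH <- (H + 2 * pad - dil * (k - 1) - 1) %/% stride + 1
  oW <- (W + 2 * pad - dil * (k - 1) - 1) %/% stride + 1
  Co <- nrow(w)
  y <- array(0, c(Co, oD, oH, oW, B))
  for (s in 1:B) for (ox in 1:oW) for (oy in 1:oH) for (oz in 1:oD) {
    acc <- b
    for (kx in 0:(k - 1)) for (ky in 0:(k - 1)) for (kz in 0:(k - 1)) {
      iz <- (oz - 1) * stride - pad + kz * dil + 1
      iy <- (oy - 1) * stride - pad + ky * dil + 1
      ix <- (ox - 1) * stride - pad + kx * dil + 1
      if (iz < 1 || iz > D || iy < 1 || iy > H || ix < 1 || ix > W) next
      t <- kz + k * (ky + k * kx)
      acc <- acc + w[, t * C + 1:C, drop = FALSE] %*% x[, iz, iy, ix, s]
    }
    y[, oz, oy, ox, s] <- acc
  }
  y
}

# Batch normalization with explicit per-channel loops (training mode).
ref_batchnorm <- function(x, gamma, beta, eps) {
  d <- dim(x); C <- d[1]
  y <- array(0, d)
  n <- length(x) / C
  for (cc in 1:C) {
    v <- x[cc, , , , ]
    mu <- sum(v) / n
    va <- sum((v - mu)^2) / n
    y[cc, , , , ] <- gamma[cc] * (v - mu) / sqrt(va + eps) + beta[cc]
  }
  y
}

# Dice coefficient by explicit voxel counting.
ref_dsc <- function(pred, gt, class_id) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(pred)) {
    a <- pred[i] == class_id
    b <- gt[i] == class_id
    if (a && b) inter <- inter + 1
    if (a) na <- na + 1
    if (b) nb <- nb + 1
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

# ASD by enumerating boundary voxels (6-connectivity, array border counts)
# and all-pairs distances.
ref_surface <- function(mask, spacing) {
  d <- dim(mask)
  pts <- NULL
  for (ix in 1:d[3]) for (iy in 1:d[2]) for (iz in 1:d[1]) {
    if (!mask[iz, iy, ix]) next
    edge <- iz == 1 || iz == d[1] || iy == 1 || iy == d[2] ||
      ix == 1 || ix == d[3]
    if (!edge) {
      nb <- c(mask[iz - 1, iy, ix], mask[iz + 1, iy, ix],
              mask[iz, iy - 1, ix], mask[iz, iy + 1, ix],
              mask[iz, iy, ix - 1], mask[iz, iy, ix + 1])
      if (all(nb)) next
    }
    pts <- rbind(pts, c(iz, iy, ix) * spacing)
  }
  pts
}

ref_asd <- function(pred, gt, class_id, spacing) {
  sp <- ref_surface(pred == class_id, spacing)
  sg <- ref_surface(gt == class_id, spacing)
  if (is.null(sp) || is.null(sg)) return(NA_real_)
  mind <- function(A, B) {
    vapply(seq_len(nrow(A)), function(i)
      sqrt(min(colSums((t(B) - A[i, ])^2))), numeric(1))
  }
  mean(c(mind(sp, sg), mind(sg, sp)))
}

# Small random label volumes for metric tests.
random_mask_pair <- function(n = 8, p = 0.3) {
  a <- array(as.integer(runif(n^3) < p), c(n, n, n))
  b <- array(as.integer(runif(n^3) < p), c(n, n, n))
  list(a = a, b = b)
}

# Tiny phantom spec / network config used by fast unit tests.
tiny_spec <- function(seed = 1)
  phantom_spec(grid_size = c(8, 16, 16), seed = seed)

tiny_net <- function(...) phantom_net_config(...)

tiny_batch <- function(C, D = 4, H = 4, W = 4, B = 2, seed = 1)
  with_seed(seed, array(rnorm(C * D * H * W * B), c(C, D, H, W, B)))
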