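# Primitive layers of the network: convolution wrappers around the compiled
# im2col/GEMM kernels, ReLU, squeeze-and-excitation channel recalibration,
# and the Conv-D block (convolution + DSBN + ReLU). All forward functions
# take the shared ctx environment (par = parameters, bn = running stats,
# domain, training, update_stats, G = gradient accumulator) and return
# list(y, cache); the paired *_bwd functions consume (ctx, dy, cache),
# accumulate parameter gradients into ctx$G, and return dx.

par_conv_init <- function(par, name, cin, cout, k) {
  fan_in <- cin * k^3
  par[[paste0(name, ".w")]] <-
    matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), nrow = cout)
  par[[paste0(name, ".b")]] <- rep(0, cout)
  par
}

par_bn_init <- function(par, bn, name, channels, shared = FALSE,
                        domains = c("source", "target"),
                        eps = 1e-5, momentum = 0.1) {
  doms <- if (shared) "shared" else domains
  for (dom in doms) {
    par[[paste0(name, ".g.", dom)]] <- rep(1, channels)
    par[[paste0(name, ".b.", dom)]] <- rep(0, channels)
  }
  bn[[name]] <- list(
    shared = shared, eps = eps, momentum = momentum,
    mean = setNames(lapply(doms, function(d) rep(0, channels)), doms),
    var  = setNames(lapply(doms, function(d) rep(1, channels)), doms)
  )
  list(par = par, bn = bn)
}

conv_fwd <- function(ctx, x, name, k = 3, stride = 1, dil = 1) {
  w <- ctx$par[[paste0(name, ".w")]]
  b <- ctx$par[[paste0(name, ".b")]]
  y <- cpp_conv3d_fwd(x, w, b, k, stride, dil)
  list(y = y, cache = list(x = x, name = name, k = k, stride = stride,
                           dil = dil))
}

conv_bwd <- function(ctx, dy, cache, need_dx = TRUE) {
  w <- ctx$par[[paste0(cache$name, ".w")]]
  r <- cpp_conv3d_bwd(cache$x, w, dy, cache$k, cache$stride, cache$dil,
                      need_dx)
  g_add(ctx$G, paste0(cache$name, ".w"), r$dw)
  g_add(ctx$G, paste0(cache$name, ".b"), as.numeric(r$db))
  if (need_dx) r$dx else NULL
}

relu_fwd <- function(x) {
  list(y = pmax(x, 0), cache = x > 0)
}

relu_bwd <- function(dy, mask) dy * mask

# Conv-D: convolution whose normalization layer is DSBN, followed by ReLU.
convd_fwd <- function(ctx, x, name, k = 3, stride = 1, dil = 1, act = TRUE) {
  cv <- conv_fwd(ctx, x, paste0(name, ".conv"), k, stride, dil)
  bn <- nn_bn_fwd(ctx, cv$y, paste0(name, ".bn"))
  if (act) {
    rl <- relu_fwd(bn$y)
    y <- rl$y; mask <- rl$cache
  } else {
    y <- bn$y; mask <- NULL
  }
  list(y = y, cache = list(conv = cv$cache, bn = bn$cache, mask = mask))
}

convd_bwd <- function(ctx, dy, cache, need_dx = TRUE) {
  if (!is.null(cache$mask)) dy <- relu_bwd(dy, cache$mask)
  dy <- nn_bn_bwd(ctx, dy, cache$bn)
  conv_bwd(ctx, dy, cache$conv, need_dx)
}

convd_init <- function(par, bn, name, cin, cout, k = 3, shared = FALSE) {
  par <- par_conv_init(par, paste0(name, ".conv"), cin, cout, k)
  r <- par_bn_init(par, bn, paste0(name, ".bn"), cout, shared = shared)
  r
}

# ---- squeeze-and-excitation channel recalibration ----

par_se_init <- function(par, name, channels, reduction) {
  cr <- max(1L, channels %/% reduction)
  par[[paste0(name, ".w1")]] <-
    matrix(rnorm(cr * channels, sd = sqrt(2 / channels)), nrow = cr)
  par[[paste0(name, ".b1")]] <- rep(0, cr)
  par[[paste0(name, ".w2")]] <-
    matrix(rnorm(channels * cr, sd = sqrt(1 / cr)), nrow = channels)
  par[[paste0(name, ".b2")]] <- rep(0, channels)
  par
}

#' Squeeze-and-excitation channel recalibration
#'
#' Scales each channel of each sample by a weight in (0, 1) computed from the
#' channel's global average: global average pooling, a bottleneck linear
#' layer with ReLU, an expansion linear layer, and a sigmoid. Used inside
#' each dilated branch of the scale-aware block to reinforce informative
#' channels.
#'
#' @param x feature array `(C, D, H, W, B)`
#' @param params SE parameter list from [se_init()]
#' @return array of the same shape, `x` scaled per channel and sample
#' @export
se_recalibrate <- function(x, params) {
  ctx <- new.env(parent = emptyenv())
  ctx$par <- params
  se_fwd(ctx, x, "se")$y
}

#' Initialize a standalone squeeze-and-excitation block
#'
#' @param channels feature channel count
#' @param reduction bottleneck reduction factor (channels/reduction units)
#' @param seed integer seed for weight initialization
#' @return named parameter list usable with [se_recalibrate()]
#' @export
se_init <- function(channels, reduction = 4, seed = 1) {
  with_seed(seed, par_se_init(list(), "se", channels, reduction))
}

se_fwd <- function(ctx, x, name) {
  d <- dim(x)
  C <- d[1]; B <- d[5]; nvox <- prod(d[2:4])
  x3 <- x; dim(x3) <- c(C, nvox, B)
  pooled <- vapply(seq_len(B), function(s) rowMeans(x3[, , s, drop = FALSE]),
                   numeric(C))
  pooled <- matrix(pooled, nrow = C)
  w1 <- ctx$par[[paste0(name, ".w1")]]; b1 <- ctx$par[[paste0(name, ".b1")]]
  w2 <- ctx$par[[paste0(name, ".w2")]]; b2 <- ctx$par[[paste0(name, ".b2")]]
  hpre <- w1 %*% pooled + b1
  h <- pmax(hpre, 0)
  spre <- w2 %*% h + b2
  wgt <- 1 / (1 + exp(-spre))                       # C x B
  scale <- wgt[, rep(seq_len(B), each = nvox), drop = FALSE]
  y <- as.numeric(x) * as.numeric(scale)
  dim(y) <- d
  list(y = y, cache = list(x = x, pooled = pooled, hpre = hpre, h = h,
                           wgt = wgt, name = name, dims = d))
}

se_bwd <- function(ctx, dy, cache) {
  d <- cache$dims
  C <- d[1]; B <- d[5]; nvox <- prod(d[2:4])
  name <- cache$name
  w1 <- ctx$par[[paste0(name, ".w1")]]
  w2 <- ctx$par[[paste0(name, ".w2")]]
  wgt <- cache$wgt
  prod3 <- dy * cache$x; dim(prod3) <- c(C, nvox, B)
  dwgt <- vapply(seq_len(B), function(s) rowSums(prod3[, , s, drop = FALSE]),
                 numeric(C))
  dwgt <- matrix(dwgt, nrow = C)
  ds <- dwgt * wgt * (1 - wgt)
  g_add(ctx$G, paste0(name, ".w2"), ds %*% t(cache$h))
  g_add(ctx$G, paste0(name, ".b2"), rowSums(ds))
  dh <- t(w2) %*% ds
  dh1 <- dh * (cache$hpre > 0)
  g_add(ctx$G, paste0(name, ".w1"), dh1 %*% t(cache$pooled))
  g_add(ctx$G, paste0(name, ".b1"), rowSums(dh1))
  dpooled <- t(w1) %*% dh1                          # C x B
  scale <- wgt[, rep(seq_len(B), each = nvox), drop = FALSE]
  dx <- as.numeric(dy) * as.numeric(scale)
  dx <- dx + as.numeric(dpooled[, rep(seq_len(B), each = nvox),
                                drop = FALSE]) / nvox
  dim(dx) <- d
  dx
}
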