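# Global-local fusion (GLF) bottleneck.
#
# Two parallel paths over the bottleneck feature map: a local path (3x3x3
# conv -> ReLU -> 1x1x1 conv, width d = C_in/2) keeping fine spatial detail,
# and a global path that projects to width d, unfolds the map into 2x2x2
# patches, runs L pre-norm transformer layers over the N patch positions
# (no positional embeddings; the P within-patch indices are handled
# batch-like), and folds back. The two d-channel maps are concatenated and
# fused by a 3x3x3 then 1x1x1 convolution into C_out channels.
#
# Internal token layout is (d, P, N, B), feature axis fastest; the public
# patch-tensor layout (P, N, d, B) of unfold_patches() is converted at the
# module boundary.

#' GLF bottleneck configuration
#'
#' @param in_channels bottleneck input channels `C_in`
#' @param out_channels output channels (default `C_in`)
#' @param d internal width of both paths (default `C_in / 2`)
#' @param patch per-axis patch dims, all 2 by default
#' @param n_layers transformer depth L (default 4); `0` degenerates the
#'   global path to its projection, i.e. a purely convolutional bottleneck
#' @param d_head dimension per self-attention head (default 8); the head
#'   count is derived as `d / d_head`
#' @param mlp_ratio hidden-width expansion of the transformer MLP
#' @return a `glf_config` list
#' @export
glf_config <- function(in_channels, out_channels = in_channels,
                       d = in_channels / 2, patch = c(2, 2, 2),
                       n_layers = 4, d_head = 8, mlp_ratio = 2) {
  if (d %% d_head != 0)
    stop("token width d = ", d, " is not divisible by d_head = ", d_head)
  stopifnot(n_layers >= 0, all(patch >= 1))
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 d = as.integer(d), patch = as.integer(patch),
                 n_layers = as.integer(n_layers),
                 d_head = as.integer(d_head),
                 n_head = as.integer(d / d_head),
                 mlp_ratio = mlp_ratio),
            class = "glf_config")
}

# ---- token-space primitives ----

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

ln_fwd <- function(z, g, b, eps = 1e-5) {
  d <- dim(z)[1]
  m <- matrix(z, nrow = d)
  mu <- colMeans(m)
  va <- colMeans(m * m) - mu^2
  invstd <- 1 / sqrt(pmax(va, 0) + eps)
  xhat <- (m - rep(mu, each = d)) * rep(invstd, each = d)
  y <- xhat * g + b
  dim(y) <- dim(z)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, g = g,
                           dims = dim(z)))
}

ln_bwd <- function(dy, cache) {
  d <- cache$dims[1]
  dm <- matrix(dy, nrow = d)
  xhat <- cache$xhat
  dg <- rowSums(dm * xhat)
  db <- rowSums(dm)
  dxhat <- dm * cache$g
  cm1 <- colMeans(dxhat)
  cm2 <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(cm1, each = d) - xhat * rep(cm2, each = d)) *
    rep(cache$invstd, each = d)
  dim(dx) <- cache$dims
  list(dx = dx, dg = dg, db = db)
}

# Multi-head self-attention over the N patch positions, separately per
# (sample, within-patch index). Softmax over the key axis, scaled by
# 1/sqrt(d_head); heads concatenated and mixed by the output projection.
mha_fwd <- function(par, z, name, d_head) {
  dz <- dim(z)
  d <- dz[1]; P <- dz[2]; N <- dz[3]; B <- dz[4]
  H <- d %/% d_head
  m <- matrix(z, nrow = d)
  Qa <- par[[paste0(name, ".wq")]] %*% m
  Ka <- par[[paste0(name, ".wk")]] %*% m
  Va <- par[[paste0(name, ".wv")]] %*% m
  dim(Qa) <- dz; dim(Ka) <- dz; dim(Va) <- dz
  O <- array(0, dz)
  Aarr <- array(0, c(N, N, H, P, B))
  sc <- 1 / sqrt(d_head)
  for (b in seq_len(B)) for (p in seq_len(P)) {
    Qm <- Qa[, p, , b]; Km <- Ka[, p, , b]; Vm <- Va[, p, , b]
    if (is.null(dim(Qm))) { Qm <- matrix(Qm, nrow = d); Km <- matrix(Km, nrow = d); Vm <- matrix(Vm, nrow = d) }
    for (h in seq_len(H)) {
      idx <- ((h - 1) * d_head + 1):(h * d_head)
      S <- crossprod(Qm[idx, , drop = FALSE], Km[idx, , drop = FALSE]) * sc
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A <- E / rowSums(E)
      O[idx, p, , b] <- Vm[idx, , drop = FALSE] %*% t(A)
      Aarr[, , h, p, b] <- A
    }
  }
  out <- par[[paste0(name, ".wo")]] %*% matrix(O, nrow = d) +
    par[[paste0(name, ".bo")]]
  dim(out) <- dz
  list(y = out, cache = list(m = m, Qa = Qa, Ka = Ka, Va = Va, A = Aarr,
                             O = O, dims = dz, d_head = d_head,
                             name = name))
}

mha_bwd <- function(ctx, dy, cache) {
  dz <- cache$dims
  d <- dz[1]; P <- dz[2]; N <- dz[3]; B <- dz[4]
  d_head <- cache$d_head
  H <- d %/% d_head
  name <- cache$name
  sc <- 1 / sqrt(d_head)
  dmo <- matrix(dy, nrow = d)
  g_add(ctx$G, paste0(name, ".wo"), dmo %*% t(matrix(cache$O, nrow = d)))
  g_add(ctx$G, paste0(name, ".bo"), rowSums(dmo))
  dO <- t(ctx$par[[paste0(name, ".wo")]]) %*% dmo
  dim(dO) <- dz
  dQ <- array(0, dz); dK <- array(0, dz); dV <- array(0, dz)
  for (b in seq_len(B)) for (p in seq_len(P)) {
    for (h in seq_len(H)) {
      idx <- ((h - 1) * d_head + 1):(h * d_head)
      dOh <- matrix(dO[idx, p, , b], nrow = d_head)
      A <- cache$A[, , h, p, b]
      Vh <- matrix(cache$Va[idx, p, , b], nrow = d_head)
      Qh <- matrix(cache$Qa[idx, p, , b], nrow = d_head)
      Kh <- matrix(cache$Ka[idx, p, , b], nrow = d_head)
      dV[idx, p, , b] <- dOh %*% A
      dA <- crossprod(dOh, Vh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[idx, p, , b] <- Kh %*% t(dS) * sc
      dK[idx, p, , b] <- Qh %*% dS * sc
    }
  }
  m <- cache$m
  dQm <- matrix(dQ, nrow = d); dKm <- matrix(dK, nrow = d)
  dVm <- matrix(dV, nrow = d)
  g_add(ctx$G, paste0(name, ".wq"), dQm %*% t(m))
  g_add(ctx$G, paste0(name, ".wk"), dKm %*% t(m))
  g_add(ctx$G, paste0(name, ".wv"), dVm %*% t(m))
  dmi <- t(ctx$par[[paste0(name, ".wq")]]) %*% dQm +
    t(ctx$par[[paste0(name, ".wk")]]) %*% dKm +
    t(ctx$par[[paste0(name, ".wv")]]) %*% dVm
  dim(dmi) <- dz
  dmi
}

# One pre-norm residual transformer layer:
#   z' = MHA(LN(z)) + z ;  z = MLP(LN(z')) + z'
tf_layer_fwd <- function(ctx, z, name, cfg) {
  par <- ctx$par
  l1 <- ln_fwd(z, par[[paste0(name, ".ln1.g")]], par[[paste0(name, ".ln1.b")]])
  at <- mha_fwd(par, l1$y, name, cfg$d_head)
  z2 <- z + at$y
  l2 <- ln_fwd(z2, par[[paste0(name, ".ln2.g")]], par[[paste0(name, ".ln2.b")]])
  d <- dim(z)[1]
  m2 <- matrix(l2$y, nrow = d)
  h1 <- par[[paste0(name, ".w1")]] %*% m2 + par[[paste0(name, ".b1")]]
  g1 <- gelu(h1)
  f <- par[[paste0(name, ".w2")]] %*% g1 + par[[paste0(name, ".b2")]]
  dim(f) <- dim(z)
  z3 <- z2 + f
  list(y = z3, cache = list(l1 = l1$cache, at = at$cache, l2 = l2$cache,
                            m2 = m2, h1 = h1, g1 = g1, name = name,
                            dims = dim(z)))
}

tf_layer_bwd <- function(ctx, dy, cache) {
  name <- cache$name
  d <- cache$dims[1]
  dmy <- matrix(dy, nrow = d)
  g_add(ctx$G, paste0(name, ".w2"), dmy %*% t(cache$g1))
  g_add(ctx$G, paste0(name, ".b2"), rowSums(dmy))
  dg1 <- t(ctx$par[[paste0(name, ".w2")]]) %*% dmy
  dh1 <- dg1 * gelu_grad(cache$h1)
  g_add(ctx$G, paste0(name, ".w1"), dh1 %*% t(cache$m2))
  g_add(ctx$G, paste0(name, ".b1"), rowSums(dh1))
  dl2y <- t(ctx$par[[paste0(name, ".w1")]]) %*% dh1
  dim(dl2y) <- cache$dims
  l2b <- ln_bwd(dl2y, cache$l2)
  g_add(ctx$G, paste0(name, ".ln2.g"), l2b$dg)
  g_add(ctx$G, paste0(name, ".ln2.b"), l2b$db)
  dz2 <- dy + l2b$dx
  dat <- mha_bwd(ctx, dz2, cache$at)
  l1b <- ln_bwd(dat, cache$l1)
  g_add(ctx$G, paste0(name, ".ln1.g"), l1b$dg)
  g_add(ctx$G, paste0(name, ".ln1.b"), l1b$db)
  dz2 + l1b$dx
}

# ---- internal unfold/fold in token layout (d, P, N, B) ----

iunfold <- function(x, patch) {
  dd <- dim(x)
  d <- dd[1]; sp <- dd[2:4]; B <- dd[5]
  dim(x) <- c(d, patch[1], sp[1] / patch[1], patch[2], sp[2] / patch[2],
              patch[3], sp[3] / patch[3], B)
  y <- aperm(x, c(1, 2, 4, 6, 3, 5, 7, 8))
  dim(y) <- c(d, prod(patch), prod(sp) / prod(patch), B)
  y
}

ifold <- function(z, spatial, patch) {
  dd <- dim(z)
  d <- dd[1]; B <- dd[4]
  dim(z) <- c(d, patch[1], patch[2], patch[3],
              spatial[1] / patch[1], spatial[2] / patch[2],
              spatial[3] / patch[3], B)
  y <- aperm(z, c(1, 2, 5, 3, 6, 4, 7, 8))
  dim(y) <- c(d, spatial, B)
  y
}

# ---- parameter construction ----

tf_init <- function(par, name, cfg) {
  d <- cfg$d
  dm <- as.integer(d * cfg$mlp_ratio)
  for (l in seq_len(cfg$n_layers)) {
    nm <- paste0(name, ".t", l)
    par[[paste0(nm, ".ln1.g")]] <- rep(1, d)
    par[[paste0(nm, ".ln1.b")]] <- rep(0, d)
    for (w in c(".wq", ".wk", ".wv", ".wo"))
      par[[paste0(nm, w)]] <- matrix(rnorm(d * d, sd = sqrt(1 / d)), nrow = d)
    par[[paste0(nm, ".bo")]] <- rep(0, d)
    par[[paste0(nm, ".ln2.g")]] <- rep(1, d)
    par[[paste0(nm, ".ln2.b")]] <- rep(0, d)
    par[[paste0(nm, ".w1")]] <- matrix(rnorm(dm * d, sd = sqrt(1 / d)), nrow = dm)
    par[[paste0(nm, ".b1")]] <- rep(0, dm)
    par[[paste0(nm, ".w2")]] <- matrix(rnorm(d * dm, sd = sqrt(1 / dm)), nrow = d)
    par[[paste0(nm, ".b2")]] <- rep(0, d)
  }
  par
}

glf_init <- function(par, name, cfg) {
  d <- cfg$d
  par <- par_conv_init(par, paste0(name, ".loc1"), cfg$in_channels, d, 3)
  par <- par_conv_init(par, paste0(name, ".loc2"), d, d, 1)
  par <- par_conv_init(par, paste0(name, ".projg"), cfg$in_channels, d, 1)
  par <- tf_init(par, name, cfg)
  par <- par_conv_init(par, paste0(name, ".fuse1"), 2 * d, cfg$out_channels, 3)
  par <- par_conv_init(par, paste0(name, ".fuse2"), cfg$out_channels,
                       cfg$out_channels, 1)
  par
}

tf_run_fwd <- function(ctx, z, name, cfg) {
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    st <- tf_layer_fwd(ctx, z, paste0(name, ".t", l), cfg)
    z <- st$y
    caches[[l]] <- st$cache
  }
  list(y = z, caches = caches)
}

tf_run_bwd <- function(ctx, dz, caches) {
  for (l in rev(seq_along(caches))) dz <- tf_layer_bwd(ctx, dz, caches[[l]])
  dz
}

glf_fwd <- function(ctx, x, name, cfg) {
  sp <- dim(x)[2:4]
  for (ax in 1:3) if (sp[ax] %% cfg$patch[ax] != 0)
    stop("bottleneck spatial axis ", ax, " (size ", sp[ax],
         ") is not divisible by patch dim ", cfg$patch[ax])
  lc1 <- conv_fwd(ctx, x, paste0(name, ".loc1"), k = 3)
  lr <- relu_fwd(lc1$y)
  lc2 <- conv_fwd(ctx, lr$y, paste0(name, ".loc2"), k = 1)
  pg <- conv_fwd(ctx, x, paste0(name, ".projg"), k = 1)
  z <- iunfold(pg$y, cfg$patch)
  tr <- tf_run_fwd(ctx, z, name, cfg)
  xG <- ifold(tr$y, sp, cfg$patch)
  cat <- concat_channels(lc2$y, xG)
  f1 <- conv_fwd(ctx, cat, paste0(name, ".fuse1"), k = 3)
  fr <- relu_fwd(f1$y)
  f2 <- conv_fwd(ctx, fr$y, paste0(name, ".fuse2"), k = 1)
  list(y = f2$y,
       cache = list(lc1 = lc1$cache, lr = lr$cache, lc2 = lc2$cache,
                    pg = pg$cache, tr = tr$caches, f1 = f1$cache,
                    fr = fr$cache, f2 = f2$cache, sp = sp, cfg = cfg))
}

glf_bwd <- function(ctx, dy, cache, need_dx = TRUE) {
  cfg <- cache$cfg
  dfr <- conv_bwd(ctx, dy, cache$f2)
  df1 <- relu_bwd(dfr, cache$fr)
  dcat <- conv_bwd(ctx, df1, cache$f1)
  halves <- split_channels(dcat)
  # local path
  dlc2 <- conv_bwd(ctx, halves[[1]], cache$lc2)
  dlr <- relu_bwd(dlc2, cache$lr)
  dxa <- conv_bwd(ctx, dlr, cache$lc1, need_dx)
  # global path: fold gradient = unfold (pure index permutation)
  dz <- iunfold(halves[[2]], cfg$patch)
  dz <- tf_run_bwd(ctx, dz, cache$tr)
  dpg <- ifold(dz, cache$sp, cfg$patch)
  dxb <- conv_bwd(ctx, dpg, cache$pg, need_dx)
  if (need_dx) dxa + dxb else NULL
}

# ---- public module surfaces ----

#' Initialize a standalone transformer stack
#'
#' @param d token feature width
#' @param n_layers transformer depth
#' @param d_head per-head dimension; `d` must be divisible by it
#' @param mlp_ratio MLP expansion factor
#' @param seed weight-init seed
#' @return list with `par` (parameters) and `cfg`
#' @export
transformer_init <- function(d, n_layers = 4, d_head = 8, mlp_ratio = 2,
                             seed = 1) {
  cfg <- glf_config(in_channels = 2 * d, d = d, n_layers = n_layers,
                    d_head = d_head, mlp_ratio = mlp_ratio)
  par <- with_seed(seed, tf_init(list(), "tf", cfg))
  list(par = par, cfg = cfg)
}

#' Run the patch transformer on a patch tensor
#'
#' Applies `L` pre-norm residual transformer layers to a patch tensor in the
#' public `(P, N, d, B)` layout. Attention runs over the `N` patch
#' positions with softmax over the key axis scaled by `1/sqrt(d_head)`;
#' there are no positional embeddings, so the map is permutation-equivariant
#' over patch positions.
#'
#' @param xU patch tensor `(P, N, d, B)`, e.g. from [unfold_patches()]
#' @param tr transformer state from [transformer_init()]
#' @param return_attention if `TRUE`, attach the per-layer attention maps
#'   (arrays `(N, N, n_head, P, B)`) as attribute `"attention"`
#' @return patch tensor `(P, N, d, B)`
#' @export
transformer_forward <- function(xU, tr, return_attention = FALSE) {
  z <- aperm(xU, c(3, 1, 2, 4))            # -> (d, P, N, B)
  ctx <- new.env(parent = emptyenv())
  ctx$par <- tr$par
  run <- tf_run_fwd(ctx, z, "tf", tr$cfg)
  y <- aperm(run$y, c(2, 3, 1, 4))
  if (return_attention)
    attr(y, "attention") <- lapply(run$caches, function(cc) cc$at$A)
  y
}

#' Initialize a standalone GLF block
#'
#' @param cfg a [glf_config()]
#' @param seed weight-init seed
#' @return list with `par` and `cfg`
#' @export
glf_block_init <- function(cfg, seed = 1) {
  list(par = with_seed(seed, glf_init(list(), "glf", cfg)), cfg = cfg)
}

#' Run a standalone GLF bottleneck forward
#'
#' @param x feature array `(C_in, D, H, W, B)`; spatial dims divisible by
#'   the patch dims
#' @param domain domain tag (accepted for interface symmetry; the GLF block
#'   contains no domain-specific normalization)
#' @param cfg a [glf_config()]
#' @param block optional state from [glf_block_init()]
#' @return output feature array `(C_out, D, H, W, B)`
#' @export
glf_forward <- function(x, domain = "target", cfg, block = NULL) {
  if (is.null(block)) block <- glf_block_init(cfg, seed = 1)
  ctx <- new.env(parent = emptyenv())
  ctx$par <- block$par
  glf_fwd(ctx, x, "glf", cfg)$y
}
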