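#' Domain-specific batch normalization (DSBN)
#'
#' DSBN keeps one full set of batch-normalization statistics and affine
#' parameters per imaging domain. A feature batch is normalized with the
#' statistics of its own domain only, so the shared convolution weights see
#' comparably distributed activations from both domains while the intensity
#' shift between domains is absorbed by the normalization layer:
#' `y_d = kappa_d * (x_d - mu_d) / sqrt(sigma_d + delta) + theta_d`.
#'
#' `dsbn_init()` creates the state; [dsbn_forward()] applies it.
#'
#' @param channels number of feature channels
#' @param domains character vector of domain tags (default source/target)
#' @param eps small positive constant `delta` preventing division by zero
#' @param momentum running-statistics update rate in training mode
#' @return a `dsbn_state` list with per-domain running means/variances and
#'   per-domain affine parameters `gamma` (scale) and `beta` (shift)
#' @export
dsbn_init <- function(channels, domains = c("source", "target"),
                      eps = 1e-5, momentum = 0.1) {
  stopifnot(eps > 0, length(domains) >= 1)
  one_dom <- function(v) setNames(lapply(domains, function(d) rep(v, channels)),
                                  domains)
  structure(list(
    channels = channels, domains = domains, eps = eps, momentum = momentum,
    mean = one_dom(0), var = one_dom(1),
    gamma = one_dom(1), beta = one_dom(0)
  ), class = "dsbn_state")
}

#' Apply domain-specific batch normalization
#'
#' In training mode the batch is normalized with its own per-channel
#' mini-batch mean and (biased) variance, and the running statistics of the
#' sample's domain are updated; statistics and parameters of every other
#' domain are untouched. In eval mode the stored running statistics are used
#' and the call is side-effect free. Mixed-domain batches must be split by
#' the caller: all samples in `x` share the one `domain` tag.
#'
#' @param x feature array `(C, D, H, W, B)`
#' @param domain a single domain tag present in `state$domains`
#' @param state a `dsbn_state` from [dsbn_init()]
#' @param training logical; batch statistics + running update if `TRUE`
#' @return `list(y = normalized array, state = possibly updated state)`
#' @export
dsbn_forward <- function(x, domain, state, training = FALSE) {
  if (!domain %in% state$domains)
    stop("unknown domain tag '", domain, "'; known: ",
         paste(state$domains, collapse = ", "))
  d <- dim(x)
  if (d[1] != state$channels)
    stop("channel mismatch: got ", d[1], ", state has ", state$channels)
  B <- d[length(d)]
  if (training && B < 2)
    stop("training-mode batch normalization needs batch size >= 2, got ", B)
  if (training) {
    st <- bn_batch_stats(x)
    mom <- state$momentum
    state$mean[[domain]] <- (1 - mom) * state$mean[[domain]] + mom * st$mean
    state$var[[domain]]  <- (1 - mom) * state$var[[domain]] + mom * st$var
    mu <- st$mean; va <- st$var
  } else {
    mu <- state$mean[[domain]]; va <- state$var[[domain]]
  }
  y <- bn_apply(x, mu, va, state$gamma[[domain]], state$beta[[domain]],
                state$eps)
  list(y = y, state = state)
}

# Per-channel mean and biased variance over all batch and spatial positions.
bn_batch_stats <- function(x) {
  C <- dim(x)[1]
  m <- matrix(x, nrow = C)
  mu <- rowMeans(m)
  va <- rowMeans(m * m) - mu^2
  list(mean = mu, var = pmax(va, 0))
}

bn_apply <- function(x, mu, va, gamma, beta, eps) {
  C <- dim(x)[1]
  invstd <- 1 / sqrt(va + eps)
  m <- matrix(x, nrow = C)
  y <- (m - mu) * (gamma * invstd) + beta   # length-C vectors recycle by row
  dim(y) <- dim(x)
  y
}

# ---- internal forward/backward used inside the network ----
# Running stats live in ctx$bn[[name]]; affine parameters in ctx$par under
# "<name>.g.<dom>" / "<name>.b.<dom>". dom is "shared" for plain BN layers.

nn_bn_fwd <- function(ctx, x, name) {
  dom <- if (isTRUE(ctx$bn[[name]]$shared)) "shared" else ctx$domain
  g <- ctx$par[[paste0(name, ".g.", dom)]]
  b <- ctx$par[[paste0(name, ".b.", dom)]]
  rs <- ctx$bn[[name]]
  C <- dim(x)[1]
  if (ctx$training) {
    if (dim(x)[length(dim(x))] < 2)
      stop("training-mode batch normalization needs batch size >= 2")
    st <- bn_batch_stats(x)
    if (isTRUE(ctx$update_stats)) {
      mom <- rs$momentum
      rs$mean[[dom]] <- (1 - mom) * rs$mean[[dom]] + mom * st$mean
      rs$var[[dom]]  <- (1 - mom) * rs$var[[dom]] + mom * st$var
      ctx$bn[[name]] <- rs
    }
    mu <- st$mean; va <- st$var
  } else {
    mu <- rs$mean[[dom]]; va <- rs$var[[dom]]
  }
  invstd <- 1 / sqrt(va + rs$eps)
  m <- matrix(x, nrow = C)
  xhat <- (m - mu) * invstd
  y <- xhat * g + b
  dim(y) <- dim(x)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, g = g,
                           name = name, dom = dom, dims = dim(x),
                           training = ctx$training))
}

nn_bn_bwd <- function(ctx, dy, cache) {
  C <- cache$dims[1]
  dm <- matrix(dy, nrow = C)
  xhat <- cache$xhat
  g_add(ctx$G, paste0(cache$name, ".g.", cache$dom), rowSums(dm * xhat))
  g_add(ctx$G, paste0(cache$name, ".b.", cache$dom), rowSums(dm))
  dxhat <- dm * cache$g
  if (cache$training) {
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
      cache$invstd
  } else {
    dx <- dxhat * cache$invstd
  }
  dim(dx) <- cache$dims
  dx
}

# Accumulate a gradient into the gradient environment.
g_add <- function(G, name, val) {
  if (is.null(G[[name]])) G[[name]] <- val else G[[name]] <- G[[name]] + val
  invisible(NULL)
}
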