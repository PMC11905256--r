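# 3D encoder-decoder segmentation network: UNet whose encoder stages are
# scale-aware SAD blocks (or plain Conv-D double convolutions when the
# scale-aware block is disabled), with the GLF global-local fusion block in
# the bottleneck, a conv decoder with skip connections, and a softmax head.
# Downsampling is by strided convolution, upsampling by factor-2 trilinear
# interpolation followed by a 1x1x1 channel-reduction convolution.

#' Network configuration
#'
#' @param n_stages number of encoder stages (each halves resolution after
#'   its block); the bottleneck sits below the deepest stage
#' @param base_width channels of the first stage; widths double per stage,
#'   the bottleneck has twice the deepest stage's width
#' @param n_classes output classes (background + 4 organs = 5)
#' @param in_channels input image channels
#' @param use_sad scale-aware blocks in the encoder; plain Conv-D double
#'   convolutions otherwise (DSBN in either case)
#' @param use_glf GLF block in the bottleneck; plain Conv-D double
#'   convolution otherwise
#' @param dilation_rates branch dilation rates of the SAD blocks
#' @param se_reduction,shuffle_groups SAD block internals
#' @param glf_layers,glf_d_head,glf_mlp_ratio GLF transformer depth,
#'   per-head width and MLP expansion
#' @param patch GLF patch dims; the deepest feature map must be divisible
#'   by them
#' @param dsbn_decoder if `TRUE` the decoder also uses domain-specific
#'   normalization; by default decoder normalization is shared across
#'   domains
#' @param domains domain tags known to the normalization layers
#' @return a `net_config` list
#' @export
net_config <- function(n_stages = 4, base_width = 16, n_classes = 5,
                       in_channels = 1, use_sad = TRUE, use_glf = TRUE,
                       dilation_rates = c(1, 3), se_reduction = 4,
                       shuffle_groups = 2, glf_layers = 4, glf_d_head = 8,
                       glf_mlp_ratio = 2, patch = c(2, 2, 2),
                       dsbn_decoder = FALSE,
                       domains = c("source", "target")) {
  widths <- base_width * 2^(seq_len(n_stages) - 1)
  bott <- 2 * widths[n_stages]
  structure(list(
    n_stages = n_stages, widths = widths, bottleneck_width = bott,
    n_classes = n_classes, in_channels = in_channels,
    use_sad = use_sad, use_glf = use_glf,
    dilation_rates = dilation_rates, se_reduction = se_reduction,
    shuffle_groups = shuffle_groups,
    glf = glf_config(bott, bott, d = bott / 2, patch = patch,
                     n_layers = glf_layers, d_head = glf_d_head,
                     mlp_ratio = glf_mlp_ratio),
    dsbn_decoder = dsbn_decoder, domains = domains
  ), class = "net_config")
}

#' Desk-scale network preset
#'
#' A small configuration (2 encoder stages, widths 8/16, bottleneck 32)
#' sized so full training runs complete in minutes on one CPU with
#' 32x32x16 phantom volumes. Identical topology family to the default
#' configuration, just narrower and shallower.
#'
#' @param ... overrides passed to [net_config()]
#' @export
phantom_net_config <- function(...) {
  net_config(n_stages = 2, base_width = 8, ...)
}

#' Build the segmentation network
#'
#' Initializes all parameters (shared across domains) and all per-domain
#' normalization statistics. Two models built with the same config and seed
#' are identical, which is how the teacher is created from the student.
#'
#' @param cfg a [net_config()]
#' @param seed weight-initialization seed
#' @return a `segnet` model list with elements `cfg`, `par` (named flat
#'   parameter list), `bn` (per-layer normalization states) and `n_par`
#' @export
build_network <- function(cfg, seed = 1) {
  with_seed(seed, {
    par <- list(); bn <- list()
    cin <- cfg$in_channels
    for (s in seq_len(cfg$n_stages)) {
      w <- cfg$widths[s]
      nm <- paste0("enc", s)
      if (cfg$use_sad) {
        scfg <- sad_config(cin, w, cfg$dilation_rates, cfg$se_reduction,
                           cfg$shuffle_groups)
        r <- sad_init(par, bn, nm, scfg)
      } else {
        r <- convd_init(par, bn, paste0(nm, ".cd1"), cin, w)
        r <- convd_init(r$par, r$bn, paste0(nm, ".cd2"), w, w)
      }
      par <- r$par; bn <- r$bn
      wnext <- if (s < cfg$n_stages) cfg$widths[s + 1] else cfg$bottleneck_width
      r <- convd_init(par, bn, paste0("down", s), w, wnext)
      par <- r$par; bn <- r$bn
      cin <- wnext
    }
    bw <- cfg$bottleneck_width
    if (cfg$use_glf) {
      par <- glf_init(par, "bott", cfg$glf)
    } else {
      r <- convd_init(par, bn, "bott.cd1", bw, bw)
      r <- convd_init(r$par, r$bn, "bott.cd2", bw, bw)
      par <- r$par; bn <- r$bn
    }
    shared_dec <- !cfg$dsbn_decoder
    cup <- bw
    for (s in rev(seq_len(cfg$n_stages))) {
      w <- cfg$widths[s]
      r <- convd_init(par, bn, paste0("up", s), cup, w, k = 1,
                      shared = shared_dec)
      r <- convd_init(r$par, r$bn, paste0("dec", s, ".c1"), 2 * w, w,
                      k = 1, shared = shared_dec)
      r <- convd_init(r$par, r$bn, paste0("dec", s, ".c2"), w, w,
                      shared = shared_dec)
      par <- r$par; bn <- r$bn
      cup <- w
    }
    par <- par_conv_init(par, "head", cfg$widths[1], cfg$n_classes, 1)
    structure(list(cfg = cfg, par = par, bn = bn,
                   n_par = sum(vapply(par, length, numeric(1)))),
              class = "segnet")
  })
}

make_ctx <- function(model, domain, training, update_stats = training) {
  if (is.null(domain) || !domain %in% model$cfg$domains)
    stop("domain tag must be one of: ",
         paste(model$cfg$domains, collapse = ", "),
         " (domain-specific normalization requires it)")
  ctx <- new.env(parent = emptyenv())
  ctx$par <- model$par
  ctx$bn <- model$bn
  ctx$domain <- domain
  ctx$training <- training
  ctx$update_stats <- update_stats
  ctx$G <- new.env(parent = emptyenv())
  ctx
}

stage_fwd <- function(ctx, x, nm, cfg, width, cin) {
  if (cfg$use_sad) {
    scfg <- sad_config(cin, width, cfg$dilation_rates, cfg$se_reduction,
                       cfg$shuffle_groups)
    sad_fwd(ctx, x, nm, scfg)
  } else {
    c1 <- convd_fwd(ctx, x, paste0(nm, ".cd1"))
    c2 <- convd_fwd(ctx, c1$y, paste0(nm, ".cd2"))
    list(y = c2$y, cache = list(plain = TRUE, c1 = c1$cache, c2 = c2$cache))
  }
}

stage_bwd <- function(ctx, dy, cache, need_dx = TRUE) {
  if (isTRUE(cache$plain)) {
    dy <- convd_bwd(ctx, dy, cache$c2)
    convd_bwd(ctx, dy, cache$c1, need_dx)
  } else {
    sad_bwd(ctx, dy, cache, need_dx)
  }
}

# Full forward pass. Returns probabilities, logits, the cache needed for
# backward, and the (possibly updated) normalization states.
net_fwd <- function(model, x, domain, training = FALSE,
                    update_stats = training, ctx = NULL) {
  cfg <- model$cfg
  if (is.null(ctx)) ctx <- make_ctx(model, domain, training, update_stats)
  skips <- vector("list", cfg$n_stages)
  caches <- list(stages = vector("list", cfg$n_stages),
                 downs = vector("list", cfg$n_stages),
                 ups = vector("list", cfg$n_stages),
                 decs = vector("list", cfg$n_stages))
  h <- x
  cin <- cfg$in_channels
  for (s in seq_len(cfg$n_stages)) {
    st <- stage_fwd(ctx, h, paste0("enc", s), cfg, cfg$widths[s], cin)
    caches$stages[[s]] <- st$cache
    skips[[s]] <- st$y
    dn <- convd_fwd(ctx, st$y, paste0("down", s), stride = 2)
    caches$downs[[s]] <- dn$cache
    h <- dn$y
    cin <- if (s < cfg$n_stages) cfg$widths[s + 1] else cfg$bottleneck_width
  }
  if (cfg$use_glf) {
    bt <- glf_fwd(ctx, h, "bott", cfg$glf)
  } else {
    b1 <- convd_fwd(ctx, h, "bott.cd1")
    b2 <- convd_fwd(ctx, b1$y, "bott.cd2")
    bt <- list(y = b2$y, cache = list(plain = TRUE, c1 = b1$cache,
                                      c2 = b2$cache))
  }
  caches$bott <- bt$cache
  h <- bt$y
  for (s in rev(seq_len(cfg$n_stages))) {
    hu <- cpp_upsample2_fwd(h)
    up <- convd_fwd(ctx, hu, paste0("up", s), k = 1)
    cat <- concat_channels(up$y, skips[[s]])
    d1 <- convd_fwd(ctx, cat, paste0("dec", s, ".c1"), k = 1)
    d2 <- convd_fwd(ctx, d1$y, paste0("dec", s, ".c2"))
    caches$ups[[s]] <- list(up = up$cache, in_dim = dim(h))
    caches$decs[[s]] <- list(d1 = d1$cache, d2 = d2$cache)
    h <- d2$y
  }
  hd <- conv_fwd(ctx, h, "head", k = 1)
  caches$head <- hd$cache
  probs <- channel_softmax(hd$y)
  list(probs = probs, logits = hd$y, cache = caches, ctx = ctx)
}

# Backward pass from dlogits; accumulates parameter gradients into ctx$G.
net_bwd <- function(model, ctx, caches, dlogits) {
  cfg <- model$cfg
  dh <- conv_bwd(ctx, dlogits, caches$head)
  for (s in seq_len(cfg$n_stages)) {
    dec <- caches$decs[[s]]
    dd <- convd_bwd(ctx, dh, dec$d2)
    dcat <- convd_bwd(ctx, dd, dec$d1)
    halves_w <- cfg$widths[s]
    m <- matrix(dcat, nrow = dim(dcat)[1])
    dup <- m[seq_len(halves_w), , drop = FALSE]
    dskip <- m[(halves_w + 1):(2 * halves_w), , drop = FALSE]
    dim(dup) <- c(halves_w, dim(dcat)[-1])
    dim(dskip) <- c(halves_w, dim(dcat)[-1])
    upc <- caches$ups[[s]]
    dhu <- convd_bwd(ctx, dup, upc$up)
    dh <- cpp_upsample2_bwd(dhu, upc$in_dim)
    caches$skipgrads[[s]] <- dskip
  }
  if (cfg$use_glf) {
    dh <- glf_bwd(ctx, dh, caches$bott)
  } else {
    dh <- convd_bwd(ctx, dh, caches$bott$c2)
    dh <- convd_bwd(ctx, dh, caches$bott$c1)
  }
  for (s in rev(seq_len(cfg$n_stages))) {
    dstage <- convd_bwd(ctx, dh, caches$downs[[s]]) + caches$skipgrads[[s]]
    dh <- stage_bwd(ctx, dstage, caches$stages[[s]], need_dx = (s > 1))
  }
  invisible(ctx$G)
}

#' Forward pass of the segmentation network
#'
#' Runs a preprocessed volume batch through the network in eval mode
#' (stored normalization statistics; deterministic and side-effect free).
#' Optional input noise is applied before the network, as used by the
#' mean-teacher consistency branch.
#'
#' @param model a `segnet` from [build_network()]
#' @param x volume batch `(1, D, H, W, B)` with values in `[0, 1]`, or a
#'   single `(D, H, W)` volume array
#' @param domain domain tag selecting the normalization statistics
#' @param noise optional `list(sd =, seed =)` additive Gaussian input noise
#' @return per-voxel class probabilities `(n_classes, D, H, W, B)`
#' @export
net_forward <- function(model, x, domain, noise = NULL) {
  if (length(dim(x)) == 3) dim(x) <- c(1, dim(x), 1)
  if (!is.null(noise) && noise$sd > 0) {
    eps <- with_seed(noise$seed %||% 0,
                     array(rnorm(length(x), sd = noise$sd), dim(x)))
    x <- x + eps
  }
  net_fwd(model, x, domain, training = FALSE)$probs
}

#' Predict a label map for a single volume
#'
#' @param model a `segnet`
#' @param vol `(D, H, W)` volume array in `[0, 1]`
#' @param domain domain tag
#' @return integer `(D, H, W)` array of class labels `0..n_classes-1`
#' @export
predict_labels <- function(model, vol, domain) {
  probs <- net_forward(model, vol, domain)
  C <- dim(probs)[1]
  m <- matrix(probs, nrow = C)
  lab <- max.col(t(m)) - 1L
  array(lab, dim(probs)[2:4])
}
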