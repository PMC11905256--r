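# Scale-aware block with DSBN (SAD).
#
# Structure: Conv-D -> [dilated branch r1 + SE || dilated branch r2 + SE]
# -> channel concatenation -> channel shuffle -> Conv-D. Both branches use
# 3x3x3 kernels; the differing dilation rates (1 and 3 by default) give the
# two branches different receptive fields so organs of different scales are
# seen at matched feature depth. Each branch outputs C/2 channels so the
# concatenation restores C. Every normalization inside the block is
# domain-specific (DSBN), so the block is domain-aware through its
# normalization only: convolution and SE weights are shared across domains.

#' Scale-aware block configuration
#'
#' @param in_channels,out_channels channel counts entering/leaving the block
#' @param dilation_rates two distinct dilation rates for the parallel
#'   branches (default 1 and 3)
#' @param se_reduction squeeze-and-excitation bottleneck reduction
#' @param shuffle_groups channel-shuffle group count (one group per branch)
#' @return a `sad_config` list
#' @export
sad_config <- function(in_channels, out_channels, dilation_rates = c(1, 3),
                       se_reduction = 4, shuffle_groups = 2) {
  stopifnot(length(dilation_rates) == 2, all(dilation_rates >= 1),
            out_channels %% 2 == 0, out_channels %% shuffle_groups == 0)
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 dilation_rates = as.integer(dilation_rates),
                 se_reduction = se_reduction,
                 shuffle_groups = shuffle_groups),
            class = "sad_config")
}

sad_init <- function(par, bn, name, cfg) {
  C <- cfg$out_channels
  r <- convd_init(par, bn, paste0(name, ".cd1"), cfg$in_channels, C)
  r <- convd_init(r$par, r$bn, paste0(name, ".br1"), C, C / 2)
  r$par <- par_se_init(r$par, paste0(name, ".se1"), C / 2, cfg$se_reduction)
  r <- convd_init(r$par, r$bn, paste0(name, ".br2"), C, C / 2)
  r$par <- par_se_init(r$par, paste0(name, ".se2"), C / 2, cfg$se_reduction)
  r <- convd_init(r$par, r$bn, paste0(name, ".cd2"), C, C)
  r
}

sad_fwd <- function(ctx, x, name, cfg) {
  cd1 <- convd_fwd(ctx, x, paste0(name, ".cd1"))
  b1 <- convd_fwd(ctx, cd1$y, paste0(name, ".br1"),
                  dil = cfg$dilation_rates[1])
  s1 <- se_fwd(ctx, b1$y, paste0(name, ".se1"))
  b2 <- convd_fwd(ctx, cd1$y, paste0(name, ".br2"),
                  dil = cfg$dilation_rates[2])
  s2 <- se_fwd(ctx, b2$y, paste0(name, ".se2"))
  cat <- concat_channels(s1$y, s2$y)
  shuf <- channel_shuffle(cat, cfg$shuffle_groups)
  cd2 <- convd_fwd(ctx, shuf, paste0(name, ".cd2"))
  list(y = cd2$y,
       cache = list(cd1 = cd1$cache, b1 = b1$cache, s1 = s1$cache,
                    b2 = b2$cache, s2 = s2$cache, cd2 = cd2$cache,
                    cfg = cfg))
}

sad_bwd <- function(ctx, dy, cache, need_dx = TRUE) {
  cfg <- cache$cfg
  dshuf <- convd_bwd(ctx, dy, cache$cd2)
  C <- dim(dshuf)[1]
  perm <- shuffle_permutation(C, cfg$shuffle_groups)
  m <- matrix(dshuf, nrow = C)
  dcat <- m[inverse_permutation(perm), , drop = FALSE]
  dim(dcat) <- dim(dshuf)
  halves <- split_channels(dcat)
  db1 <- se_bwd(ctx, halves[[1]], cache$s1)
  db2 <- se_bwd(ctx, halves[[2]], cache$s2)
  dcd1 <- convd_bwd(ctx, db1, cache$b1) + convd_bwd(ctx, db2, cache$b2)
  convd_bwd(ctx, dcd1, cache$cd1, need_dx)
}

#' Run a standalone scale-aware block forward
#'
#' Builds (or reuses) a self-contained SAD block and applies it to a feature
#' batch. Mainly a module surface for experimentation and testing; inside
#' the full network the block is wired by [build_network()].
#'
#' @param x feature array `(C_in, D, H, W, B)`
#' @param domain domain tag, `"source"` or `"target"`
#' @param cfg a [sad_config()]
#' @param block optional block state from [sad_block_init()]; created fresh
#'   (seed 1) when omitted
#' @param training logical, training-mode normalization
#' @return `list(y = output array (C_out, D, H, W, B), block = state)`
#' @export
sad_forward <- function(x, domain, cfg, block = NULL, training = FALSE) {
  if (is.null(block)) block <- sad_block_init(cfg, seed = 1)
  ctx <- new.env(parent = emptyenv())
  ctx$par <- block$par; ctx$bn <- block$bn
  ctx$domain <- domain; ctx$training <- training
  ctx$update_stats <- training
  out <- sad_fwd(ctx, x, "sad", cfg)
  block$bn <- ctx$bn
  list(y = out$y, block = block)
}

#' Initialize a standalone scale-aware block
#'
#' @param cfg a [sad_config()]
#' @param seed integer seed for weight initialization
#' @return list with `par` (parameters) and `bn` (per-domain running stats)
#' @export
sad_block_init <- function(cfg, seed = 1) {
  with_seed(seed, sad_init(list(), list(), "sad", cfg))
}
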