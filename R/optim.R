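# AdamW optimizer with decoupled weight decay and a stepwise exponential
# learning-rate schedule.

#' Optimizer and training-loop configuration
#'
#' Defaults follow the training recipe: AdamW with initial learning rate
#' 0.0009 and weight decay 0.00005, learning rate decayed by 0.95 every 250
#' iterations, batches of 4 labeled-source + 2 labeled-target + 2
#' unlabeled-target samples, EMA decay 0.99, and gradient clipping at
#' global norm 5.
#'
#' @param steps number of training iterations
#' @param lr initial learning rate
#' @param weight_decay decoupled weight-decay rate
#' @param lr_decay,lr_decay_every exponential decay factor and interval
#'   (iterations)
#' @param batch_sl,batch_tl,batch_tu per-step sample counts from the
#'   labeled-source, labeled-target and unlabeled-target pools
#' @param ema_decay teacher EMA coefficient
#' @param clip_norm global gradient-norm clip
#' @param noise_sd additive Gaussian input-noise sd for the consistency
#'   branch
#' @param augment apply online augmentation to training samples
#' @param use_semt use the mean-teacher consistency branch (unlabeled data)
#' @param subsets labeled pools used for the supervised loss
#' @return an `optim_config` list
#' @export
optim_config <- function(steps = 200, lr = 0.0009, weight_decay = 0.00005,
                         lr_decay = 0.95, lr_decay_every = 250,
                         batch_sl = 4, batch_tl = 2, batch_tu = 2,
                         ema_decay = 0.99, clip_norm = 5, noise_sd = 0.05,
                         augment = TRUE, use_semt = TRUE,
                         subsets = c("SL", "TL")) {
  structure(list(steps = steps, lr = lr, weight_decay = weight_decay,
                 lr_decay = lr_decay, lr_decay_every = lr_decay_every,
                 batch_sl = batch_sl, batch_tl = batch_tl,
                 batch_tu = batch_tu, ema_decay = ema_decay,
                 clip_norm = clip_norm, noise_sd = noise_sd,
                 augment = augment, use_semt = use_semt, subsets = subsets),
            class = "optim_config")
}

adamw_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0)
}

adamw_step <- function(par, grads, opt, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mh <- opt$m[[nm]] / bc1
    vh <- opt$v[[nm]] / bc2
    par[[nm]] <- par[[nm]] - lr * (mh / (sqrt(vh) + eps) + wd * par[[nm]])
  }
  list(par = par, opt = opt)
}

# Stepwise exponential schedule: lr * decay^floor(k / every).
lr_at <- function(cfg, k) cfg$lr * cfg$lr_decay^(k %/% cfg$lr_decay_every)
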