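# Self-ensembling mean-teacher training engine.
#
# Each step samples a mixed batch (4 SL + 2 TL + 2 TU by default), runs the
# student on the source sub-batch with domain = "source" and on the target
# sub-batches with domain = "target", computes the composite supervised loss
# on SL and TL, the MSE consistency loss between student and teacher
# predictions on TU (same augmented input, independent additive Gaussian
# noise draws), backpropagates to the student only, applies AdamW with the
# stepwise-exponential learning-rate schedule, and finally updates the
# teacher as an EMA of the student. The consistency weight follows the
# Gaussian warm-up, normalized so its final value is the tuned lambda.

#' Train the segmentation network with the mean-teacher scheme
#'
#' @param data a `split_dataset` from [generate_dataset()] or
#'   [load_manifest()]
#' @param net_cfg a [net_config()]; [phantom_net_config()] is the
#'   desk-scale default
#' @param w a [loss_weights()]; its `k_max` is set to the step count if
#'   left at the default
#' @param opt_cfg an [optim_config()]
#' @param seed integer seed governing weight init, batch sampling,
#'   augmentation and noise
#' @param verbose print a progress line every 25 steps
#' @return list with `model` (the trained student, the deliverable),
#'   `teacher` (or `NULL` when the consistency branch is off), `history`
#'   (one row per step: all loss terms, the effective consistency weight
#'   and the learning rate) and `config` (the fully resolved configuration)
#' @export
train <- function(data, net_cfg = phantom_net_config(), w = loss_weights(),
                  opt_cfg = optim_config(), seed = 1, verbose = FALSE) {
  stopifnot(inherits(data, "split_dataset"))
  w$k_max <- opt_cfg$steps
  use_cons <- opt_cfg$use_semt && w$lambda > 0 && opt_cfg$batch_tu > 0
  if (use_cons && length(data$TU) == 0) {
    warning("TU is empty: consistency term disabled, training is purely supervised")
    use_cons <- FALSE
  }
  pools <- list()
  if ("SL" %in% opt_cfg$subsets && opt_cfg$batch_sl > 0)
    pools$SL <- data$SL
  if ("TL" %in% opt_cfg$subsets && opt_cfg$batch_tl > 0)
    pools$TL <- data$TL
  if (length(pools) == 0 || any(vapply(pools, length, 1L) == 0))
    stop("no labeled samples available for the supervised loss")

  student <- build_network(net_cfg, seed = mix_seed(seed, 77))
  teacher <- if (use_cons) student else NULL   # copy of student at step 0
  opt <- adamw_init(student$par)
  hist <- vector("list", opt_cfg$steps)

  for (k in seq_len(opt_cfg$steps)) {
    set.seed(mix_seed(seed, 1000, k))
    G <- new.env(parent = emptyenv())
    sup <- 0; dice <- 0; ce <- 0

    run_labeled <- function(pool, n, domain) {
      idx <- sample.int(length(pool), n, replace = TRUE)
      vols <- vector("list", n); labs <- vector("list", n)
      for (i in seq_len(n)) {
        smp <- pool[[idx[i]]]
        if (opt_cfg$augment) {
          a <- augment(smp$volume, smp$label,
                       seed = sample.int(2^30, 1))
          vols[[i]] <- a$volume; labs[[i]] <- a$label
        } else {
          vols[[i]] <- smp$volume; labs[[i]] <- smp$label
        }
      }
      x <- stack_batch(vols)
      y <- array(unlist(labs), c(dim(labs[[1]]), n))
      fw <- net_fwd(student, x, domain, training = TRUE)
      fw$ctx$G <- G
      lg <- sup_loss_grad(fw$probs, y, w)
      net_bwd(student, fw$ctx, fw$cache, lg$dlogits)
      student$bn <<- fw$ctx$bn
      sup <<- sup + lg$loss; dice <<- dice + lg$dice; ce <<- ce + lg$ce
      invisible(NULL)
    }

    if (!is.null(pools$SL)) run_labeled(pools$SL, opt_cfg$batch_sl, "source")
    if (!is.null(pools$TL)) run_labeled(pools$TL, opt_cfg$batch_tl, "target")

    un <- 0; lam_eff <- 0
    if (use_cons) {
      lam_eff <- effective_lambda(w, k)
      n <- opt_cfg$batch_tu
      idx <- sample.int(length(data$TU), n, replace = TRUE)
      vols <- vector("list", n)
      for (i in seq_len(n)) {
        smp <- data$TU[[idx[i]]]
        vols[[i]] <- if (opt_cfg$augment)
          augment(smp$volume, NULL, seed = sample.int(2^30, 1))$volume
        else smp$volume
      }
      x <- stack_batch(vols)
      noise_s <- with_seed(sample.int(2^30, 1),
                           array(rnorm(length(x), sd = opt_cfg$noise_sd), dim(x)))
      noise_t <- with_seed(sample.int(2^30, 1),
                           array(rnorm(length(x), sd = opt_cfg$noise_sd), dim(x)))
      # batch statistics for the forward, but running stats are not
      # updated from noise-perturbed inputs: they track clean data only
      fs <- net_fwd(student, x + noise_s, "target", training = TRUE,
                    update_stats = FALSE)
      fs$ctx$G <- G
      ft <- net_fwd(teacher, x + noise_t, "target", training = TRUE,
                    update_stats = FALSE)
      cg <- cons_loss_grad(fs$probs, ft$probs)
      un <- cg$loss
      net_bwd(student, fs$ctx, fs$cache, lam_eff * cg$dlogits)
    }

    total <- sup + lam_eff * un
    if (!is.finite(total))
      stop("training diverged at step ", k, ": total loss = ", total,
           " (sup = ", sup, ", cons = ", un, ")")

    grads <- clip_gradients(as.list(G), opt_cfg$clip_norm)
    lr_k <- lr_at(opt_cfg, k)
    upd <- adamw_step(student$par, grads, opt, lr_k, opt_cfg$weight_decay)
    student$par <- upd$par; opt <- upd$opt
    if (use_cons) teacher <- ema_update(teacher, student, opt_cfg$ema_decay)

    hist[[k]] <- data.frame(step = k, loss_total = total, loss_sup = sup,
                            loss_dice = dice, loss_ce = ce, loss_cons = un,
                            lambda_eff = lam_eff, lr = lr_k)
    if (verbose && k %% 25 == 0)
      message(sprintf("step %d | total %.4f sup %.4f cons %.4f lr %.2e",
                      k, total, sup, un, lr_k))
  }

  list(model = student, teacher = teacher,
       history = do.call(rbind, hist),
       config = resolved_config(net_cfg, w, opt_cfg, seed))
}

stack_batch <- function(vols) {
  d <- dim(vols[[1]])
  x <- array(unlist(vols), c(d, length(vols)))
  dim(x) <- c(1, d, length(vols))
  x
}

# Full resolved-configuration echo: every operative default appears here.
resolved_config <- function(net_cfg, w, opt_cfg, seed) {
  list(
    seed = seed,
    lambda = w$lambda, lambda_dice = w$lambda_dice, lambda_ce = w$lambda_ce,
    ramp_amplitude = w$ramp_amplitude, ramp_sharpness = w$ramp_sharpness,
    k_max = w$k_max,
    ema_decay = opt_cfg$ema_decay,
    lr = opt_cfg$lr, weight_decay = opt_cfg$weight_decay,
    lr_decay = opt_cfg$lr_decay, lr_decay_every = opt_cfg$lr_decay_every,
    batch_sl = opt_cfg$batch_sl, batch_tl = opt_cfg$batch_tl,
    batch_tu = opt_cfg$batch_tu,
    steps = opt_cfg$steps, clip_norm = opt_cfg$clip_norm,
    noise_sd = opt_cfg$noise_sd, augment = opt_cfg$augment,
    use_semt = opt_cfg$use_semt, subsets = opt_cfg$subsets,
    n_stages = net_cfg$n_stages, widths = net_cfg$widths,
    bottleneck_width = net_cfg$bottleneck_width,
    n_classes = net_cfg$n_classes,
    use_sad = net_cfg$use_sad, use_glf = net_cfg$use_glf,
    dilation_rates = net_cfg$dilation_rates,
    se_reduction = net_cfg$se_reduction,
    shuffle_groups = net_cfg$shuffle_groups,
    patch = net_cfg$glf$patch, glf_layers = net_cfg$glf$n_layers,
    glf_d_head = net_cfg$glf$d_head, glf_mlp_ratio = net_cfg$glf$mlp_ratio,
    dsbn_decoder = net_cfg$dsbn_decoder
  )
}
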