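# Composite supervised loss (soft Dice + cross-entropy), the mean-teacher
# consistency loss, the Gaussian consistency-weight ramp, and the EMA
# teacher update.

#' Loss weighting configuration
#'
#' @param lambda consistency trade-off weight; the final (fully ramped)
#'   weight of the unsupervised loss term (default 2.0)
#' @param lambda_dice,lambda_ce weights of the Dice and cross-entropy parts
#'   of the supervised loss; must sum to 1 (defaults 0.7 / 0.3)
#' @param ramp_amplitude,ramp_sharpness amplitude (0.1) and sharpness (5) of
#'   the time-dependent Gaussian warm-up
#' @param k_max final training iteration for the ramp
#' @return a `loss_weights` list
#' @export
loss_weights <- function(lambda = 2.0, lambda_dice = 0.7, lambda_ce = 0.3,
                         ramp_amplitude = 0.1, ramp_sharpness = 5,
                         k_max = 1000) {
  stopifnot(abs(lambda_dice + lambda_ce - 1) < 1e-12, lambda >= 0)
  structure(list(lambda = lambda, lambda_dice = lambda_dice,
                 lambda_ce = lambda_ce, ramp_amplitude = ramp_amplitude,
                 ramp_sharpness = ramp_sharpness, k_max = k_max),
            class = "loss_weights")
}

#' Soft Dice coefficient of one class
#'
#' `(2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` for a probability map
#' `p` and binary target `t` of the same shape.
#'
#' @param p predicted probabilities for the class
#' @param t binary (0/1) target indicator
#' @param eps smoothing constant
#' @export
soft_dice <- function(p, t, eps = 1e-7) {
  (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

#' Composite supervised segmentation loss
#'
#' Per sample: `lambda_dice * (1 - mean multi-class soft Dice) +
#' lambda_ce * (mean voxel-wise cross-entropy)`, summed over the samples in
#' the batch (labeled source and labeled target samples both enter this
#' way). The Dice mean runs over all classes including background.
#'
#' @param pred class probabilities `(C, D, H, W, B)`
#' @param target integer label array `(D, H, W, B)` (or `(D, H, W)` for a
#'   single sample), classes `0..C-1`
#' @param w a [loss_weights()]
#' @return scalar loss with attributes `dice` and `ce` holding the two
#'   batch-summed components (before their lambda weights)
#' @export
supervised_loss <- function(pred, target, w = loss_weights()) {
  r <- sup_loss_grad(pred, target, w, grad = FALSE)
  structure(r$loss, dice = r$dice, ce = r$ce)
}

sup_loss_grad <- function(pred, target, w, grad = TRUE, eps = 1e-7) {
  if (length(pred) == 0) stop("empty batch")
  dp <- dim(pred)
  if (length(dp) == 4) { dim(pred) <- c(dp, 1); dp <- dim(pred) }
  C <- dp[1]; B <- dp[5]; nvox <- prod(dp[2:4])
  if (B < 1 || length(pred) == 0) stop("empty batch")
  if (length(dim(target)) == 3) dim(target) <- c(dim(target), 1)
  stopifnot(all(dim(target) == dp[2:5]))
  tmin <- min(target); tmax <- max(target)
  if (tmin < 0 || tmax > C - 1) stop("target classes outside 0..", C - 1)
  pm <- matrix(pred, nrow = C)            # columns: voxel-within-sample
  dice_sum <- 0; ce_sum <- 0
  gp <- if (grad) matrix(0, C, ncol(pm)) else NULL   # dL/dp
  for (s in seq_len(B)) {
    cols <- ((s - 1) * nvox + 1):(s * nvox)
    ps <- pm[, cols, drop = FALSE]
    ts <- as.integer(target[, , , s])
    # cross-entropy of the true class
    pick <- ps[cbind(ts + 1L, seq_len(nvox))]
    ce_s <- -mean(log(pmax(pick, 1e-12)))
    ce_sum <- ce_sum + ce_s
    dice_cl <- numeric(C)
    for (cc in seq_len(C)) {
      tc <- as.numeric(ts == cc - 1L)
      pc <- ps[cc, ]
      A <- 2 * sum(pc * tc) + eps
      Bden <- sum(pc) + sum(tc) + eps
      dice_cl[cc] <- A / Bden
      if (grad) {
        # d(1 - mean dice)/dp_c = -(2 t B - A)/(C B^2)
        gp[cc, cols] <- gp[cc, cols] +
          w$lambda_dice * (-(2 * tc * Bden - A) / (C * Bden^2))
      }
    }
    dice_sum <- dice_sum + (1 - mean(dice_cl))
    if (grad) {
      # CE gradient folded later through softmax directly via (p - onehot)
      NULL
    }
  }
  loss <- w$lambda_dice * dice_sum + w$lambda_ce * ce_sum
  out <- list(loss = loss, dice = dice_sum, ce = ce_sum)
  if (grad) {
    # chain the dice part through the softmax: dlogit = p * (g - sum(g*p))
    inner <- colSums(gp * pm)
    dlog_dice <- pm * (gp - rep(inner, each = C))
    # CE through softmax has the closed form (p - onehot)/nvox per sample
    onehot <- matrix(0, C, ncol(pm))
    tall <- as.integer(target)
    onehot[cbind(tall + 1L, seq_along(tall))] <- 1
    dlog_ce <- w$lambda_ce * (pm - onehot) / nvox
    dlogits <- dlog_dice + dlog_ce
    dim(dlogits) <- dp
    out$dlogits <- dlogits
  }
  out
}

#' Mean-teacher consistency loss
#'
#' Mean squared error between student and teacher class-probability maps on
#' the same unlabeled inputs: per sample the mean over voxels and classes,
#' summed over the samples. Symmetric in its arguments; the teacher
#' prediction carries no gradient.
#'
#' @param student_pred,teacher_pred probability arrays of identical shape
#'   `(C, D, H, W, B)`
#' @return scalar loss
#' @export
consistency_loss <- function(student_pred, teacher_pred) {
  if (!identical(dim(student_pred), dim(teacher_pred)))
    stop("student/teacher prediction shapes differ")
  d <- dim(student_pred)
  B <- d[length(d)]
  sum((student_pred - teacher_pred)^2) / (length(student_pred) / B)
}

cons_loss_grad <- function(sprob, tprob) {
  d <- dim(sprob)
  B <- d[length(d)]
  per <- length(sprob) / B
  diff <- sprob - tprob
  loss <- sum(diff^2) / per
  # d/dprob then through softmax
  gp <- 2 * diff / per
  C <- d[1]
  gm <- matrix(gp, nrow = C); pmat <- matrix(sprob, nrow = C)
  inner <- colSums(gm * pmat)
  dlog <- pmat * (gm - rep(inner, each = C))
  dim(dlog) <- d
  list(loss = loss, dlogits = dlog)
}

#' Time-dependent Gaussian consistency-weight ramp
#'
#' `amplitude * exp(-sharpness * (1 - k/k_max)^2)`: near zero at the start
#' of training and rising monotonically to `amplitude` at `k = k_max`, so
#' the unsupervised term only gains influence once the student produces
#' meaningful predictions.
#'
#' @param k current iteration(s), `0 <= k <= k_max`
#' @param k_max final iteration (> 0)
#' @param amplitude ramp amplitude (default 0.1)
#' @param sharpness ramp sharpness (default 5)
#' @return the ramp value(s)
#' @export
consistency_weight <- function(k, k_max, amplitude = 0.1, sharpness = 5) {
  if (k_max <= 0) stop("k_max must be positive")
  if (any(k < 0) || any(k > k_max)) stop("k must lie in [0, k_max]")
  amplitude * exp(-sharpness * (1 - k / k_max)^2)
}

# Effective consistency weight: the tuned trade-off lambda modulated by the
# warm-up ramp normalized to end at 1, i.e. lambda * ramp(k)/ramp(k_max).
effective_lambda <- function(w, k) {
  w$lambda * exp(-w$ramp_sharpness * (1 - k / w$k_max)^2)
}

#' Total training loss
#'
#' `L_total = L_sup + lambda_eff(k) * L_un` with `lambda_eff(k) =
#' lambda * exp(-sharpness (1 - k/k_max)^2)`, the warm-up-modulated
#' trade-off that equals `lambda` at `k = k_max`.
#'
#' @param sup supervised loss value
#' @param un consistency loss value
#' @param w a [loss_weights()]
#' @param k current iteration
#' @export
total_loss <- function(sup, un, w, k) {
  sup + effective_lambda(w, k) * un
}

#' Exponential-moving-average teacher update
#'
#' Every teacher parameter is updated in place of the returned copy as
#' `p' <- eta * p' + (1 - eta) * p` from the matching student parameter;
#' per-domain normalization running statistics follow the same rule. The
#' teacher is never updated by gradients.
#'
#' @param teacher,student `segnet` models of identical topology
#' @param eta EMA decay coefficient in `[0, 1]` (default 0.99)
#' @return the updated teacher model
#' @export
ema_update <- function(teacher, student, eta = 0.99) {
  stopifnot(eta >= 0, eta <= 1)
  if (!identical(names(teacher$par), names(student$par)))
    stop("teacher/student parameter topology mismatch")
  for (nm in names(teacher$par))
    teacher$par[[nm]] <- eta * teacher$par[[nm]] +
      (1 - eta) * student$par[[nm]]
  for (nm in names(teacher$bn)) {
    for (dom in names(teacher$bn[[nm]]$mean)) {
      teacher$bn[[nm]]$mean[[dom]] <- eta * teacher$bn[[nm]]$mean[[dom]] +
        (1 - eta) * student$bn[[nm]]$mean[[dom]]
      teacher$bn[[nm]]$var[[dom]] <- eta * teacher$bn[[nm]]$var[[dom]] +
        (1 - eta) * student$bn[[nm]]$var[[dom]]
    }
  }
  teacher
}
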