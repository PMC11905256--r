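# Losses, consistency ramp, EMA update, and the training engine.

test_that("a perfect one-hot prediction has zero supervised loss", {
  target <- array(sample(0:4, 3 * 3 * 3, TRUE), c(3, 3, 3, 1))
  pred <- array(0, c(5, 3, 3, 3, 1))
  for (cc in 0:4) pred[cc + 1, , , , 1] <- target[, , , 1] == cc
  L <- supervised_loss(pred, target)
  expect_equal(as.numeric(L), 0, tolerance = 1e-5)
  expect_equal(attr(L, "ce"), 0, tolerance = 1e-10)
  expect_equal(attr(L, "dice"), 0, tolerance = 1e-5)
})

test_that("a uniform 5-class prediction has cross-entropy ln 5 per voxel", {
  target <- array(sample(0:4, 4 * 4 * 2, TRUE), c(4, 4, 2, 1))
  pred <- array(0.2, c(5, 4, 4, 2, 1))
  L <- supervised_loss(pred, target)
  expect_equal(attr(L, "ce"), log(5), tolerance = 1e-6)
  expect_equal(log(5), 1.609, tolerance = 1e-3)
})

test_that("the two-voxel soft-dice toy matches the hand computation", {
  # pred class-1 probabilities (1, 0), target (1, 1):
  # dice = 2*1 / (1 + 2) = 2/3, dice loss 1/3
  expect_equal(soft_dice(c(1, 0), c(1, 1)), 2 / 3, tolerance = 1e-6)
  expect_equal(1 - soft_dice(c(1, 0), c(1, 1)), 1 / 3, tolerance = 1e-6)
})

test_that("supervised loss rejects bad inputs", {
  expect_error(supervised_loss(array(0.2, c(5, 2, 2, 2, 1)),
                               array(7L, c(2, 2, 2, 1))), "target classes")
  expect_error(sadglf:::sup_loss_grad(numeric(0), integer(0),
                                      loss_weights()), "empty")
})

test_that("consistency loss: zero at equality, closed form, symmetric", {
  p <- with_seed(1, array(runif(5 * 3 * 3 * 3 * 2), c(5, 3, 3, 3, 2)))
  expect_equal(consistency_loss(p, p), 0)
  q <- p + 0.1
  # per-sample MSE 0.01, summed over the 2 samples
  expect_equal(consistency_loss(p, q), 0.02, tolerance = 1e-12)
  r <- with_seed(2, array(runif(length(p)), dim(p)))
  expect_equal(consistency_loss(p, r), consistency_loss(r, p))
  expect_error(consistency_loss(p, array(0, c(5, 2, 2, 2, 1))),
               "shapes differ")
})

test_that("the Gaussian warm-up ramp has its stated endpoints and shape", {
  expect_identical(consistency_weight(1000, 1000), 0.1)
  expect_equal(consistency_weight(0, 1000), 0.1 * exp(-5),
               tolerance = 1e-12)
  ks <- seq(0, 500, by = 0.5)
  vals <- consistency_weight(ks, 500)
  expect_true(all(diff(vals) > 0))
  expect_error(consistency_weight(0, 0), "positive")
  expect_error(consistency_weight(-1, 10))
})

test_that("total loss combines supervised and ramped consistency terms", {
  w <- loss_weights(lambda = 2.0, k_max = 100)
  expect_equal(total_loss(1, 0.5, w, k = 100), 1 + 2 * 0.5)
  w0 <- loss_weights(lambda = 0, k_max = 100)
  expect_equal(total_loss(1.3, 9, w0, k = 50), 1.3)
  expect_equal(total_loss(1.3, 0, w, k = 50), 1.3)
  expect_error(loss_weights(lambda_dice = 0.5, lambda_ce = 0.4))
})

test_that("EMA endpoints and the m-step closed form hold", {
  cfg <- tiny_net()
  student <- build_network(cfg, seed = 1)
  teacher0 <- build_network(cfg, seed = 2)
  t0 <- ema_update(teacher0, student, eta = 0)
  expect_equal(t0$par, student$par)
  t1 <- ema_update(teacher0, student, eta = 1)
  expect_equal(t1$par, teacher0$par)
  for (eta in c(0, 0.5, 0.99, 1)) {
    m <- 7
    teach <- teacher0
    for (i in 1:m) teach <- ema_update(teach, student, eta)
    for (nm in c("enc1.cd1.conv.w", "head.w")) {
      closed <- eta^m * teacher0$par[[nm]] + (1 - eta^m) * student$par[[nm]]
      expect_equal(teach$par[[nm]], closed, tolerance = 1e-10)
    }
  }
  bad <- student; names(bad$par)[1] <- "renamed"
  expect_error(ema_update(bad, student), "topology")
})

test_that("a short mean-teacher run satisfies its bookkeeping contracts", {
  data <- generate_dataset(tiny_spec(), 3, 4, 0.5, seed = 1, n_test = 1)
  steps <- 6
  fit <- train(data, tiny_net(), loss_weights(),
               optim_config(steps = steps, batch_sl = 2, batch_tl = 2,
                            batch_tu = 2), seed = 3)
  h <- fit$history
  expect_equal(nrow(h), steps)
  expect_true(all(is.finite(unlist(h))))
  # loss decomposition identity at every step
  expect_equal(h$loss_total, h$loss_sup + h$lambda_eff * h$loss_cons,
               tolerance = 1e-10)
  expect_equal(h$lambda_eff,
               2 * exp(-5 * (1 - h$step / steps)^2), tolerance = 1e-12)
  expect_false(is.null(fit$teacher))
  expect_false(identical(fit$teacher$par, fit$model$par))
})

test_that("the stepwise exponential learning-rate schedule is honored", {
  cfg <- optim_config()
  expect_equal(sadglf:::lr_at(cfg, 1), 0.0009)
  expect_equal(sadglf:::lr_at(cfg, 249), 0.0009)
  expect_equal(sadglf:::lr_at(cfg, 250), 0.0009 * 0.95)
  expect_equal(sadglf:::lr_at(cfg, 500), 0.0009 * 0.95^2)
})

test_that("teacher stays gradient-isolated: eta = 1 freezes it at init", {
  data <- generate_dataset(tiny_spec(), 2, 4, 0.5, seed = 2, n_test = 1)
  fit <- train(data, tiny_net(), loss_weights(),
               optim_config(steps = 3, batch_sl = 2, batch_tl = 2,
                            batch_tu = 2, ema_decay = 1), seed = 4)
  init <- build_network(tiny_net(), seed = mix_seed(4, 77))
  expect_equal(fit$teacher$par, init$par, tolerance = 1e-14)
  expect_false(identical(fit$model$par, init$par))
})

test_that("lambda = 0 reproduces the plain supervised trajectory exactly", {
  data <- generate_dataset(tiny_spec(), 2, 4, 0.5, seed = 5, n_test = 1)
  f1 <- train(data, tiny_net(), loss_weights(lambda = 0),
              optim_config(steps = 4, batch_sl = 2, batch_tl = 2,
                           batch_tu = 2), seed = 6)
  f2 <- train(data, tiny_net(), loss_weights(),
              optim_config(steps = 4, batch_sl = 2, batch_tl = 2,
                           batch_tu = 2, use_semt = FALSE), seed = 6)
  expect_identical(f1$model$par, f2$model$par)
  expect_null(f1$teacher)
  expect_null(f2$teacher)
})

test_that("an empty TU pool disables consistency with a warning", {
  data <- generate_dataset(tiny_spec(), 2, 2, 1, seed = 7, n_test = 1)
  expect_warning(
    fit <- train(data, tiny_net(), loss_weights(),
                 optim_config(steps = 2, batch_sl = 2, batch_tl = 2),
                 seed = 8),
    "TU is empty")
  expect_true(all(fit$history$loss_cons == 0))
})

test_that("the resolved config echoes every operative default", {
  data <- generate_dataset(tiny_spec(), 2, 4, 0.5, seed = 9, n_test = 1)
  fit <- train(data, tiny_net(), loss_weights(),
               optim_config(steps = 2, batch_tl = 2, batch_tu = 2), seed = 1)
  cf <- fit$config
  expect_equal(cf$lambda, 2.0)
  expect_equal(cf$lambda_dice, 0.7)
  expect_equal(cf$lambda_ce, 0.3)
  expect_equal(cf$ema_decay, 0.99)
  expect_equal(cf$lr, 0.0009)
  expect_equal(cf$weight_decay, 0.00005)
  expect_equal(cf$lr_decay, 0.95)
  expect_equal(cf$lr_decay_every, 250)
  expect_equal(cf$batch_sl, 4)
  expect_equal(cf$dilation_rates, c(1, 3))
  expect_equal(cf$patch, c(2L, 2L, 2L))
  expect_equal(cf$glf_layers, 4L)
  expect_equal(cf$glf_d_head, 8L)
  expect_equal(cf$ramp_amplitude, 0.1)
  expect_equal(cf$ramp_sharpness, 5)
})
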