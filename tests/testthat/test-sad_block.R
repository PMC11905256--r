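# Scale-aware block: SE recalibration, channel shuffle, dilated branches.

test_that("SE with saturated sigmoid is the identity", {
  par <- se_init(channels = 4, reduction = 2, seed = 1)
  par$se.w2[] <- 0
  par$se.b2[] <- 50            # sigmoid(50) == 1 to double precision
  x <- tiny_batch(4, seed = 2)
  expect_equal(se_recalibrate(x, par), x, tolerance = 1e-12)
})

test_that("SE scales channel c by its computed weight w_c elementwise", {
  par <- se_init(channels = 3, reduction = 1, seed = 2)
  x <- tiny_batch(3, B = 2, seed = 3)
  y <- se_recalibrate(x, par)
  # recompute the weights independently per sample
  for (s in 1:2) {
    pooled <- apply(x[, , , , s, drop = FALSE], 1, mean)
    h <- pmax(par$se.w1 %*% pooled + par$se.b1, 0)
    wgt <- 1 / (1 + exp(-(par$se.w2 %*% h + par$se.b2)))
    for (cc in 1:3)
      expect_equal(y[cc, , , , s], x[cc, , , , s] * wgt[cc],
                   tolerance = 1e-12)
    expect_true(all(wgt > 0 & wgt < 1))
  }
})

test_that("SE of an all-zero input is all-zero", {
  par <- se_init(channels = 4, seed = 3)
  x <- array(0, c(4, 3, 3, 3, 2))
  expect_equal(se_recalibrate(x, par), x)
})

test_that("channel shuffle realizes the reshape-transpose permutation", {
  x <- array(0, c(6, 1, 1, 1, 1))
  x[, 1, 1, 1, 1] <- 0:5
  y <- channel_shuffle(x, groups = 2)
  expect_equal(as.numeric(y), c(0, 3, 1, 4, 2, 5))
  expect_equal(channel_shuffle(x, groups = 1), x)
  # applying the inverse permutation restores the tensor
  z <- tiny_batch(8, seed = 4)
  perm <- sadglf:::shuffle_permutation(8, 2)
  shuffled <- channel_shuffle(z, 2)
  m <- matrix(shuffled, nrow = 8)[sadglf:::inverse_permutation(perm), ]
  dim(m) <- dim(z)
  expect_identical(m, z)
  expect_error(channel_shuffle(tiny_batch(5), 2), "not divisible")
})

test_that("dilated branches have the dilation-dictated impulse footprints", {
  cfg <- sad_config(in_channels = 1, out_channels = 4,
                    dilation_rates = c(1, 3))
  block <- sad_block_init(cfg, seed = 5)
  # strip normalization/SE nonlinearity out of the picture by probing the
  # raw branch convolutions on an impulse
  D <- 9; imp <- array(0, c(4, D, D, D, 1)); imp[1, 5, 5, 5, 1] <- 1
  r1 <- sadglf:::cpp_conv3d_fwd(imp, block$par$sad.br1.conv.w,
                                rep(0, 2), 3L, 1L, 1L)
  r3 <- sadglf:::cpp_conv3d_fwd(imp, block$par$sad.br2.conv.w,
                                rep(0, 2), 3L, 1L, 3L)
  nz <- function(y) which(apply(abs(y[, , , , 1]) > 1e-12, 2:4, any),
                          arr.ind = TRUE)
  off1 <- abs(nz(r1) - 5); off3 <- abs(nz(r3) - 5)
  expect_equal(max(off1), 1)                 # dilation 1: +/- 1 voxel
  expect_equal(max(off3), 3)                 # dilation 3: +/- 3 voxels
  expect_true(all(off3 %in% c(0, 3)))        # and nothing in between
  # dilation-3 branch responds at offset 3 where dilation-1 is zero
  expect_gt(max(abs(r3[, 8, 5, 5, 1])), 0)
  expect_equal(max(abs(r1[, 8, 5, 5, 1])), 0)
})

test_that("identical branch weights with equal dilations duplicate halves", {
  cfg <- sad_config(in_channels = 2, out_channels = 4,
                    dilation_rates = c(1, 1))
  block <- sad_block_init(cfg, seed = 6)
  for (suffix in c("conv.w", "conv.b", "bn.g.source", "bn.b.source"))
    block$par[[paste0("sad.br2.", suffix)]] <-
      block$par[[paste0("sad.br1.", suffix)]]
  for (suffix in c("w1", "b1", "w2", "b2"))
    block$par[[paste0("sad.se2.", suffix)]] <-
      block$par[[paste0("sad.se1.", suffix)]]
  x <- tiny_batch(2, D = 6, H = 6, W = 6, seed = 7)
  ctx <- new.env(parent = emptyenv())
  ctx$par <- block$par; ctx$bn <- block$bn
  ctx$domain <- "source"; ctx$training <- TRUE; ctx$update_stats <- FALSE
  cd1 <- sadglf:::convd_fwd(ctx, x, "sad.cd1")
  b1 <- sadglf:::convd_fwd(ctx, cd1$y, "sad.br1", dil = 1)
  s1 <- sadglf:::se_fwd(ctx, b1$y, "sad.se1")
  b2 <- sadglf:::convd_fwd(ctx, cd1$y, "sad.br2", dil = 1)
  s2 <- sadglf:::se_fwd(ctx, b2$y, "sad.se2")
  expect_equal(s1$y, s2$y, tolerance = 1e-12)
})

test_that("sad_forward obeys the declared shape contract", {
  cfg <- sad_config(in_channels = 8, out_channels = 16)
  x <- tiny_batch(8, D = 16, H = 16, W = 8, B = 2, seed = 8)
  out <- sad_forward(x, "source", cfg, training = TRUE)
  expect_equal(dim(out$y), c(16, 16, 16, 8, 2))
})

test_that("the domain tag changes only normalization, never branch weights", {
  cfg <- sad_config(in_channels = 2, out_channels = 4)
  block <- sad_block_init(cfg, seed = 9)
  x <- tiny_batch(2, D = 6, H = 6, W = 6, seed = 10)
  par_before <- block$par
  o1 <- sad_forward(x, "source", cfg, block, training = TRUE)
  o2 <- sad_forward(x, "target", cfg, o1$block, training = TRUE)
  expect_identical(o2$block$par, par_before)
  # with batch statistics and identical per-domain affines the outputs agree
  expect_equal(o1$y, o2$y, tolerance = 1e-10)
})
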