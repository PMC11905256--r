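# Global-local fusion: unfold/fold, patch transformer, fused bottleneck.

test_that("unfold obeys the N = D*H*W/P shape rule", {
  x <- tiny_batch(4, D = 4, H = 4, W = 4, B = 1, seed = 1)
  u <- unfold_patches(x, c(2, 2, 2))
  expect_equal(dim(u), c(8, 8, 4, 1))        # P = 8, N = 64/8 = 8, d = 4
  expect_error(unfold_patches(tiny_batch(2, D = 3), c(2, 2, 2)),
               "not divisible")
})

test_that("fold is the exact inverse of unfold", {
  for (rep in 1:10) {
    dims <- 2 * sample(1:3, 3, replace = TRUE)
    x <- with_seed(rep, array(rnorm(3 * prod(dims) * 2), c(3, dims, 2)))
    u <- unfold_patches(x)
    expect_identical(fold_patches(u, dims), x)
  }
})

test_that("a constant input yields constant patch slices", {
  x <- array(2.5, c(3, 4, 4, 2, 1))
  u <- unfold_patches(x)
  expect_true(all(u == 2.5))
})

test_that("unfold places within-patch voxels and patches coherently", {
  # tag every voxel with its global linear index; each column n of the
  # patch tensor must hold exactly the 8 voxels of one 2x2x2 block
  x <- array(seq_len(4 * 4 * 4), c(1, 4, 4, 4, 1))
  u <- unfold_patches(x)
  for (n in seq_len(dim(u)[2])) {
    vox <- sort(u[, n, 1, 1])
    coords <- arrayInd(vox, c(4, 4, 4))
    expect_equal(max(coords[, 1]) - min(coords[, 1]), 1)
    expect_equal(max(coords[, 2]) - min(coords[, 2]), 1)
    expect_equal(max(coords[, 3]) - min(coords[, 3]), 1)
  }
})

test_that("attention rows are normalized to 1", {
  tr <- transformer_init(d = 8, n_layers = 2, d_head = 4, seed = 2)
  xU <- with_seed(3, array(rnorm(4 * 6 * 8 * 2), c(4, 6, 8, 2)))
  y <- transformer_forward(xU, tr, return_attention = TRUE)
  for (A in attr(y, "attention")) {
    sums <- apply(A, 3:5, rowSums)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-6)
  }
})

test_that("a zero query gives uniform attention equal to the value mean", {
  tr <- transformer_init(d = 4, n_layers = 1, d_head = 4, seed = 4)
  tr$par$tf.t1.wq[] <- 0
  xU <- with_seed(5, array(rnorm(2 * 5 * 4 * 1), c(2, 5, 4, 1)))
  y <- transformer_forward(xU, tr, return_attention = TRUE)
  A <- attr(y, "attention")[[1]]
  expect_equal(as.numeric(A), rep(1 / 5, length(A)), tolerance = 1e-12)
  # head output at every position is the mean over positions of the value
  # projections of the layer-normalized input
  z <- aperm(xU, c(3, 1, 2, 4))
  l1 <- sadglf:::ln_fwd(z, tr$par$tf.t1.ln1.g, tr$par$tf.t1.ln1.b)
  at <- sadglf:::mha_fwd(tr$par, l1$y, "tf.t1", 4)
  V <- tr$par$tf.t1.wv %*% matrix(l1$y, nrow = 4)
  dim(V) <- dim(z)
  for (p in 1:2) {
    vmean <- rowMeans(matrix(V[, p, , 1], nrow = 4))
    for (n in 1:5)
      expect_equal(at$cache$O[, p, n, 1], vmean, tolerance = 1e-5)
  }
})

test_that("the transformer is permutation-equivariant over patch positions", {
  tr <- transformer_init(d = 8, n_layers = 3, d_head = 4, seed = 6)
  xU <- with_seed(7, array(rnorm(4 * 10 * 8 * 2), c(4, 10, 8, 2)))
  perm <- with_seed(8, sample(10))
  y1 <- transformer_forward(xU, tr)[, perm, , , drop = FALSE]
  y2 <- transformer_forward(xU[, perm, , , drop = FALSE], tr)
  expect_equal(y1, y2, tolerance = 1e-5)
})

test_that("glf_forward preserves shape and reduces to conv-only at L = 0", {
  cfg <- glf_config(in_channels = 8, out_channels = 8, d_head = 4,
                    n_layers = 2)
  x <- tiny_batch(8, D = 8, H = 8, W = 4, B = 2, seed = 9)
  y <- glf_forward(x, "target", cfg)
  expect_equal(dim(y), dim(x))
  cfg0 <- glf_config(in_channels = 8, out_channels = 8, d_head = 4,
                     n_layers = 0)
  y0 <- glf_forward(x, "target", cfg0, block = glf_block_init(cfg0, seed = 1))
  expect_equal(dim(y0), dim(x))
  expect_error(glf_config(in_channels = 8, d_head = 3), "divisible")
})

test_that("the global path propagates an impulse to distant voxels", {
  cfg <- glf_config(in_channels = 2, out_channels = 2, d = 2, d_head = 2,
                    n_layers = 1)
  block <- glf_block_init(cfg, seed = 10)
  # silence the local path so only the global (transformer) path remains
  block$par$glf.loc1.w[] <- 0; block$par$glf.loc1.b[] <- 0
  x0 <- array(0, c(2, 8, 8, 8, 1))
  x1 <- x0; x1[1, 1, 1, 1, 1] <- 10
  y0 <- glf_forward(x1 * 0, "target", cfg, block)
  y1 <- glf_forward(x1, "target", cfg, block)
  dd <- abs(y1 - y0)
  # a voxel far outside any local receptive field (opposite corner)
  expect_gt(max(dd[, 7:8, 7:8, 7:8, 1]), 1e-8)
})
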