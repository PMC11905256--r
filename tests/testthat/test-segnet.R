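# Network assembly: shape/softmax contracts, determinism, domain behaviour,
# numeric stability, and the compiled conv kernels against a brute-force
# oracle.

test_that("compiled conv kernels match the brute-force oracle", {
  for (cse in list(list(C = 3, Co = 4, k = 3, stride = 1, dil = 1),
                   list(C = 3, Co = 4, k = 3, stride = 1, dil = 3),
                   list(C = 4, Co = 6, k = 3, stride = 2, dil = 1),
                   list(C = 5, Co = 2, k = 1, stride = 1, dil = 1))) {
    x <- with_seed(cse$C, array(rnorm(cse$C * 6 * 8 * 10 * 2),
                                c(cse$C, 6, 8, 10, 2)))
    w <- with_seed(cse$Co, matrix(rnorm(cse$Co * cse$C * cse$k^3), cse$Co))
    b <- rnorm(cse$Co)
    y <- sadglf:::cpp_conv3d_fwd(x, w, b, cse$k, cse$stride, cse$dil)
    y0 <- ref_conv3d(x, w, b, cse$k, cse$stride, cse$dil)
    expect_lt(max(abs(y - y0)), 1e-5)
    # adjoint identities: <conv(x), dy> = <x, dx> = <w, dw> (b = 0)
    yl <- sadglf:::cpp_conv3d_fwd(x, w, rep(0, cse$Co), cse$k, cse$stride,
                                  cse$dil)
    dy <- with_seed(99, array(rnorm(length(yl)), dim(yl)))
    g <- sadglf:::cpp_conv3d_bwd(x, w, dy, cse$k, cse$stride, cse$dil, TRUE)
    ip <- sum(yl * dy)
    expect_equal(sum(g$dx * x), ip, tolerance = 1e-4)
    expect_equal(sum(g$dw * w), ip, tolerance = 1e-4)
  }
})

test_that("trilinear upsampling is value-conserving and adjoint-consistent", {
  x <- tiny_batch(3, D = 4, H = 4, W = 2, seed = 1)
  y <- sadglf:::cpp_upsample2_fwd(x)
  expect_equal(dim(y), c(3, 8, 8, 4, 2))
  expect_equal(sum(y), 8 * sum(x), tolerance = 1e-8)   # interpolation mass
  dy <- with_seed(2, array(rnorm(length(y)), dim(y)))
  dx <- sadglf:::cpp_upsample2_bwd(dy, dim(x))
  expect_equal(sum(dx * x), sum(y * dy), tolerance = 1e-8)
})

test_that("forward yields a proper softmax field of the declared shape", {
  model <- build_network(tiny_net(), seed = 1)
  x <- with_seed(1, array(runif(1 * 16 * 32 * 32 * 2), c(1, 16, 32, 32, 2)))
  p <- net_forward(model, x, "source")
  expect_equal(dim(p), c(5, 16, 32, 32, 2))
  sums <- colSums(matrix(p, nrow = 5))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-10)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("a teacher built as a copy reproduces the student exactly", {
  student <- build_network(tiny_net(), seed = 3)
  teacher <- student
  x <- with_seed(2, array(runif(1 * 8 * 16 * 16), c(1, 8, 16, 16, 1)))
  expect_identical(net_forward(student, x, "target"),
                   net_forward(teacher, x, "target"))
})

test_that("eval forwards are deterministic; zero noise equals no noise", {
  model <- build_network(tiny_net(), seed = 4)
  x <- with_seed(3, array(runif(1 * 8 * 16 * 16), c(1, 8, 16, 16, 1)))
  expect_identical(net_forward(model, x, "target"),
                   net_forward(model, x, "target"))
  expect_equal(net_forward(model, x, "target",
                           noise = list(sd = 0, seed = 1)),
               net_forward(model, x, "target"), tolerance = 1e-15)
  n1 <- net_forward(model, x, "target", noise = list(sd = 0.05, seed = 9))
  n2 <- net_forward(model, x, "target", noise = list(sd = 0.05, seed = 9))
  expect_identical(n1, n2)
  expect_false(identical(n1, net_forward(model, x, "target")))
})

test_that("probabilities stay finite and normalized under extreme inputs", {
  model <- build_network(tiny_net(), seed = 5)
  x <- with_seed(4, array(runif(1 * 8 * 16 * 16) * 1e3, c(1, 8, 16, 16, 1)))
  p <- net_forward(model, x, "target")
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
  sums <- colSums(matrix(p, nrow = 5))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-8)
})

test_that("a missing or unknown domain tag is rejected", {
  model <- build_network(tiny_net(), seed = 6)
  x <- array(0.5, c(1, 8, 16, 16, 1))
  expect_error(net_forward(model, x, NULL), "domain tag")
  expect_error(net_forward(model, x, "cohort3"), "domain tag")
})

test_that("with forced-shared statistics the domain tag has no effect", {
  model <- build_network(tiny_net(), seed = 7)
  # force source parameters/statistics equal to target everywhere
  for (nm in names(model$par)) {
    if (grepl("\\.g\\.source$|\\.b\\.source$", nm)) {
      tgt <- sub("source$", "target", nm)
      model$par[[nm]] <- model$par[[tgt]]
    }
  }
  for (nm in names(model$bn)) {
    doms <- names(model$bn[[nm]]$mean)
    if (all(c("source", "target") %in% doms)) {
      model$bn[[nm]]$mean$source <- model$bn[[nm]]$mean$target
      model$bn[[nm]]$var$source <- model$bn[[nm]]$var$target
    }
  }
  x <- with_seed(5, array(runif(1 * 8 * 16 * 16), c(1, 8, 16, 16, 1)))
  expect_identical(net_forward(model, x, "source"),
                   net_forward(model, x, "target"))
})

test_that("construction reports a parameter count and honors flags", {
  m1 <- build_network(tiny_net(), seed = 1)
  m0 <- build_network(tiny_net(use_sad = FALSE, use_glf = FALSE), seed = 1)
  expect_gt(m1$n_par, m0$n_par)
  expect_true(any(grepl("^bott\\.t1\\.", names(m1$par))))
  expect_false(any(grepl("^bott\\.t1\\.", names(m0$par))))
  expect_error(net_config(n_stages = 2, base_width = 8, glf_d_head = 5),
               "divisible")
})
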