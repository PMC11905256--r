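# Two-domain phantom generator: determinism, geometry, intensity model,
# dataset partitioning.

test_that("noiseless two-level phantom has exactly the two values 0 and 1", {
  spec <- phantom_spec(
    grid_size = c(16, 16, 16), n_organs = 1,
    organ_scale_ranges = matrix(c(0.2, 0.2), 1),
    organ_centers = matrix(c(0.5, 0.5, 0.5), 1),
    center_jitter = 0,
    domain_intensity_maps = list(
      source = list(mean = c(0.2, 0.8), sd = c(0, 0)),
      target = list(mean = c(0.3, 0.6), sd = c(0, 0))),
    noise_sd = 0)
  ph <- generate_phantom(spec, "source", 1)
  expect_setequal(unique(as.numeric(ph$volume)), c(0, 1))
  expect_setequal(unique(as.integer(ph$label)), c(0L, 1L))
})

test_that("phantom generation is deterministic per (spec, domain, seed)", {
  spec <- tiny_spec()
  a <- generate_phantom(spec, "target", 7)
  b <- generate_phantom(spec, "target", 7)
  expect_identical(a$volume, b$volume)
  expect_identical(a$label, b$label)
  c <- generate_phantom(spec, "source", 7)
  expect_false(identical(a$volume, c$volume))
})

test_that("organ voxel count matches the analytic ellipsoid volume", {
  # radius fraction 0.25 on a 32^3 grid: a sphere of radius 8 voxels,
  # expected count (4/3) * pi * 8^3, checked within 20%
  spec <- phantom_spec(
    grid_size = c(32, 32, 32), n_organs = 1,
    organ_scale_ranges = matrix(c(0.25, 0.25), 1),
    organ_centers = matrix(c(0.5, 0.5, 0.5), 1),
    center_jitter = 0, noise_sd = 0,
    domain_intensity_maps = list(
      source = list(mean = c(0, 1), sd = c(0, 0)),
      target = list(mean = c(1, 0), sd = c(0, 0))))
  ph <- generate_phantom(spec, "source", 3)
  expected <- 4 / 3 * pi * 8^3
  expect_lt(abs(sum(ph$label == 1L) - expected) / expected, 0.2)
})

test_that("default phantoms contain all organ classes with disjoint labels", {
  ph <- generate_phantom(phantom_spec(seed = 2), "target", 5)
  expect_setequal(sort(unique(as.integer(ph$label))), 0:4)
  expect_true(all(ph$volume >= 0 & ph$volume <= 1))
  expect_true(all(is.finite(ph$volume)))
})

test_that("grid and placement failures raise explicit errors", {
  expect_error(phantom_spec(grid_size = c(4, 16, 16)), ">= 8")
  expect_error(phantom_spec(grid_size = c(9, 16, 16)), "divisible")
  overlap <- phantom_spec(
    grid_size = c(16, 16, 16), n_organs = 2,
    organ_scale_ranges = matrix(0.4, 2, 2),
    organ_centers = rbind(c(0.5, 0.45, 0.5), c(0.5, 0.55, 0.5)),
    center_jitter = 0)
  expect_error(generate_phantom(overlap, "source", 1), "placement failed")
  expect_error(generate_phantom(tiny_spec(), "nope", 1), "unknown domain")
})

test_that("dataset split arithmetic and invariants hold", {
  data <- generate_dataset(tiny_spec(), n_source = 3, n_target = 10,
                           labeled_ratio = 0.2, seed = 1, n_test = 2)
  expect_length(data$TL, 2)
  expect_length(data$TU, 8)
  expect_length(data$SL, 3)
  expect_length(data$test, 2)
  ids <- c(vapply(data$TL, `[[`, "", "case_id"),
           vapply(data$TU, `[[`, "", "case_id"),
           vapply(data$test, `[[`, "", "case_id"))
  expect_length(unique(ids), length(ids))       # no overlap in the partition
  expect_true(all(vapply(data$TU, function(s) is.null(s$label), TRUE)))
  rng <- range(unlist(lapply(c(data$SL, data$TL), `[[`, "volume")))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("labeled_ratio = 1 empties TU; invalid ratios error", {
  data <- generate_dataset(tiny_spec(), 2, 4, labeled_ratio = 1, seed = 1,
                           n_test = 1)
  expect_length(data$TU, 0)
  expect_length(data$TL, 4)
  expect_error(generate_dataset(tiny_spec(), 2, 2, labeled_ratio = 0.1),
               "zero TL")
  expect_error(generate_dataset(tiny_spec(), 2, 2, labeled_ratio = 0))
})

test_that("different dataset seeds change voxel data but not split sizes", {
  d1 <- generate_dataset(tiny_spec(), 2, 5, 0.2, seed = 1, n_test = 1)
  d2 <- generate_dataset(tiny_spec(), 2, 5, 0.2, seed = 2, n_test = 1)
  expect_equal(lengths(d1[c("SL", "TL", "TU", "test")]),
               lengths(d2[c("SL", "TL", "TU", "test")]))
  expect_false(identical(d1$SL[[1]]$volume, d2$SL[[1]]$volume))
})

test_that("domain intensity shift exceeds 5x the standard error per class", {
  spec <- tiny_spec()
  n <- 6
  class_means <- function(domain) {
    vapply(seq_len(n), function(i) {
      ph <- generate_phantom(spec, domain, i)
      vapply(0:4, function(cc) mean(ph$volume[ph$label == cc]), numeric(1))
    }, numeric(5))
  }
  ma <- class_means("source"); mb <- class_means("target")
  for (cc in 1:5) {
    se <- sqrt(sd(ma[cc, ])^2 / n + sd(mb[cc, ])^2 / n)
    expect_gt(abs(mean(ma[cc, ]) - mean(mb[cc, ])), 5 * se)
  }
})

test_that("identical intensity maps for both domains are rejected", {
  im <- list(mean = c(0.1, 0.5, 0.6, 0.7, 0.8), sd = rep(0.01, 5))
  expect_error(phantom_spec(domain_intensity_maps = list(source = im,
                                                         target = im)),
               "no domain shift")
})

test_that("dataset round-trips through NIfTI files and a manifest", {
  dir <- withr::local_tempdir()
  data <- generate_dataset(tiny_spec(), 1, 2, 0.5, seed = 3, n_test = 1)
  manifest <- write_dataset(data, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- load_manifest(file.path(dir, "manifest.csv"))
  expect_length(back$TU, 1)
  expect_equal(back$TL[[1]]$volume, data$TL[[1]]$volume, tolerance = 1e-6)
  expect_identical(back$TL[[1]]$label, data$TL[[1]]$label)
  expect_equal(back$labeled_ratio, 0.5)
})
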