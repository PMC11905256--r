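# Two-domain 3D abdominal phantom generator.
#
# Each phantom is a (D, H, W) grid containing four axis-aligned ellipsoidal
# "organs" (stand-ins for liver, right kidney, left kidney, spleen) on a
# background, at anatomically inspired anchor positions with per-case
# jittered centers and per-case sampled scales. The two domains share the
# geometry model but map classes to disjoint intensity distributions
# (contrast-inverted between domains, emulating CT vs T2-SPIR MRI), so the
# dataset exhibits the two properties the adaptation method targets:
# organ-scale variation across patients and an intensity-distribution
# mismatch across modalities.

#' Phantom specification
#'
#' @param grid_size `(D, H, W)` voxels; every dim must be at least 8 and
#'   divisible by 2 (the GLF patch edge)
#' @param n_organs number of foreground organs (default 4)
#' @param organ_scale_ranges per-organ `[min, max]` fractional-radius
#'   intervals (fraction of each grid dimension), a `n_organs x 2` matrix
#' @param organ_centers per-organ anchor centers as fractions of
#'   `(D, H, W)`, a `n_organs x 3` matrix
#' @param center_jitter uniform jitter (fraction of grid) on each center
#' @param domain_intensity_maps per-domain per-class intensity model:
#'   `list(source = list(mean =, sd =), target = ...)`, vectors of length
#'   `n_organs + 1` (background first)
#' @param noise_sd additive scanner-noise sd (on top of per-class texture)
#' @param spacing_mm voxel spacing `(dz, dy, dx)` in mm
#' @param seed base seed of the specification
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(grid_size = c(16, 32, 32), n_organs = 4,
                         organ_scale_ranges = NULL, organ_centers = NULL,
                         center_jitter = 0.03,
                         domain_intensity_maps = NULL,
                         noise_sd = 0.02, spacing_mm = c(7, 1.5, 1.5),
                         seed = 1) {
  if (any(grid_size < 8))
    stop("grid dims must all be >= 8, got ", paste(grid_size, collapse = "x"))
  if (any(grid_size %% 2 != 0))
    stop("grid dims must be divisible by the patch edge 2")
  if (is.null(organ_scale_ranges))
    organ_scale_ranges <- rbind(liver = c(0.16, 0.22),
                                r_kidney = c(0.07, 0.10),
                                l_kidney = c(0.07, 0.10),
                                spleen = c(0.10, 0.14))[seq_len(n_organs), ,
                                                        drop = FALSE]
  if (is.null(organ_centers))
    organ_centers <- rbind(liver = c(0.50, 0.32, 0.30),
                           r_kidney = c(0.50, 0.72, 0.30),
                           l_kidney = c(0.50, 0.70, 0.70),
                           spleen = c(0.50, 0.32, 0.74))[seq_len(n_organs), ,
                                                         drop = FALSE]
  if (is.null(domain_intensity_maps))
    domain_intensity_maps <- list(
      source = list(mean = c(0.10, 0.55, 0.70, 0.70, 0.60)[1:(n_organs + 1)],
                    sd = rep(0.02, n_organs + 1)),
      target = list(mean = c(0.15, 0.80, 0.35, 0.35, 0.60)[1:(n_organs + 1)],
                    sd = rep(0.05, n_organs + 1)))
  for (dmn in names(domain_intensity_maps)) {
    im <- domain_intensity_maps[[dmn]]
    stopifnot(length(im$mean) == n_organs + 1, length(im$sd) == n_organs + 1)
  }
  if (length(domain_intensity_maps) >= 2) {
    mm <- vapply(domain_intensity_maps, function(m) m$mean,
                 numeric(n_organs + 1))
    if (all(apply(mm, 1, function(r) max(r) - min(r)) == 0))
      stop("domain intensity maps are identical for every class: no domain shift")
  }
  structure(list(grid_size = as.integer(grid_size), n_organs = n_organs,
                 organ_scale_ranges = organ_scale_ranges,
                 organ_centers = organ_centers,
                 center_jitter = center_jitter,
                 domain_intensity_maps = domain_intensity_maps,
                 noise_sd = noise_sd, spacing_mm = spacing_mm, seed = seed),
            class = "phantom_spec")
}

#' Generate one phantom case
#'
#' Deterministic for fixed `(spec, domain, case_seed)`. The label map is
#' built first (ellipsoids with per-case scale and center draws); the
#' volume is the domain-specific intensity map of the labels plus additive
#' noise, min-max normalized to `[0, 1]`.
#'
#' @param spec a [phantom_spec()]
#' @param domain domain tag naming an entry of `spec$domain_intensity_maps`
#' @param case_seed per-case seed (see [mix_seed()])
#' @return `list(volume = (D,H,W) array in [0,1], label = (D,H,W) integer
#'   array with classes 0..n_organs, spacing_mm, domain, case_seed)`
#' @export
generate_phantom <- function(spec, domain, case_seed) {
  if (!domain %in% names(spec$domain_intensity_maps))
    stop("unknown domain '", domain, "'")
  gs <- spec$grid_size
  with_seed(mix_seed(spec$seed, case_seed, match(domain,
                                                 names(spec$domain_intensity_maps))), {
    lab <- array(0L, gs)
    coords <- list(z = slice.index(lab, 1), y = slice.index(lab, 2),
                   x = slice.index(lab, 3))
    for (org in seq_len(spec$n_organs)) {
      rng <- spec$organ_scale_ranges[org, ]
      frac <- runif(1, rng[1], rng[2])
      ctr <- spec$organ_centers[org, ] +
        runif(3, -spec$center_jitter, spec$center_jitter)
      semi <- pmax(frac * gs, 1)            # semi-axes in voxels per axis
      cz <- ctr[1] * gs[1]; cy <- ctr[2] * gs[2]; cx <- ctr[3] * gs[3]
      inside <- ((coords$z - 0.5 - cz) / semi[1])^2 +
        ((coords$y - 0.5 - cy) / semi[2])^2 +
        ((coords$x - 0.5 - cx) / semi[3])^2 <= 1
      if (!any(inside))
        stop("organ ", org, " placement failed: empty label on grid ",
             paste(gs, collapse = "x"))
      if (any(lab[inside] != 0L))
        stop("organ ", org, " placement failed: overlaps an earlier organ; ",
             "grid too small for the requested scale ranges")
      lab[inside] <- org
    }
    im <- spec$domain_intensity_maps[[domain]]
    v <- im$mean[lab + 1L] +
      rnorm(length(lab), sd = im$sd[lab + 1L]) +
      rnorm(length(lab), sd = spec$noise_sd)
    dim(v) <- gs
    rng <- range(v)
    v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
    list(volume = v, label = lab, spacing_mm = spec$spacing_mm,
         domain = domain, case_seed = case_seed)
  })
}

#' Generate a partitioned two-domain phantom dataset
#'
#' Produces `n_source` labeled source cases (SL), `n_target` target
#' training cases split into labeled (TL) and unlabeled (TU) by
#' `labeled_ratio`, and `n_test` held-out labeled target cases. Per-case
#' seeds are derived from `(seed, case index)` so the dataset is
#' reproducible element-wise; TL, TU and test partition the target cases
#' with no overlap.
#'
#' @param spec a [phantom_spec()]
#' @param n_source labeled source training cases
#' @param n_target target training cases (TL + TU)
#' @param labeled_ratio fraction of target training cases that are labeled,
#'   in `(0, 1]`
#' @param seed dataset seed
#' @param n_test held-out labeled target cases
#' @return a `split_dataset`: lists `SL`, `TL`, `TU`, `test` of case
#'   samples (`volume`, `label` (absent in TU), `domain`, `case_id`) plus
#'   `labeled_ratio` and `spec`
#' @export
generate_dataset <- function(spec, n_source, n_target, labeled_ratio,
                             seed = 1, n_test = 4) {
  stopifnot(n_source >= 1, n_target >= 1)
  if (labeled_ratio <= 0 || labeled_ratio > 1)
    stop("labeled_ratio must lie in (0, 1]")
  n_tl <- round(labeled_ratio * n_target)
  if (n_tl < 1)
    stop("labeled_ratio ", labeled_ratio, " yields zero TL cases; ",
         "need n_target >= ", ceiling(0.5 / labeled_ratio))
  spec$seed <- mix_seed(spec$seed, seed)
  mk <- function(domain, case_id, keep_label) {
    ph <- generate_phantom(spec, domain, case_id)
    list(volume = ph$volume,
         label = if (keep_label) ph$label else NULL,
         spacing_mm = ph$spacing_mm, domain = domain,
         case_id = paste0(domain, "_", case_id))
  }
  SL <- lapply(seq_len(n_source), function(i) mk("source", i, TRUE))
  # target training cases: the first n_tl (by mixed case seed order) are TL
  tgt_ids <- seq_len(n_target)
  TL <- lapply(tgt_ids[seq_len(n_tl)], function(i) mk("target", i, TRUE))
  TU <- if (n_tl < n_target)
    lapply(tgt_ids[(n_tl + 1):n_target], function(i) mk("target", i, FALSE))
  else list()
  test <- lapply(n_target + seq_len(n_test),
                 function(i) mk("target", i, TRUE))
  structure(list(SL = SL, TL = TL, TU = TU, test = test,
                 labeled_ratio = labeled_ratio, spec = spec),
            class = "split_dataset")
}

#' Write a phantom dataset as NIfTI pairs with a manifest
#'
#' Writes `<case>_img.nii.gz` (and `<case>_lab.nii.gz` for labeled cases)
#' with voxel spacing in the header, plus `manifest.csv` listing path,
#' label path, domain and subset (SL/TL/TU/test).
#'
#' @param data a `split_dataset`
#' @param dir output directory (created if needed)
#' @return the manifest data frame, invisibly
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (subset in c("SL", "TL", "TU", "test")) {
    for (smp in data[[subset]]) {
      base <- file.path(dir, paste0(subset, "_", smp$case_id))
      img <- paste0(base, "_img.nii.gz")
      write_nifti_volume(smp$volume, img, smp$spacing_mm)
      labp <- ""
      if (!is.null(smp$label)) {
        labp <- paste0(base, "_lab.nii.gz")
        write_nifti_volume(smp$label, labp, smp$spacing_mm)
      }
      rows[[length(rows) + 1]] <- data.frame(
        case_id = smp$case_id, subset = subset, domain = smp$domain,
        image = img, label = labp)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset from a manifest written by [write_dataset()]
#'
#' @param path path to `manifest.csv`
#' @return a `split_dataset`
#' @export
load_manifest <- function(path) {
  manifest <- read.csv(path, stringsAsFactors = FALSE)
  out <- list(SL = list(), TL = list(), TU = list(), test = list())
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    vol <- read_nifti_volume(row$image)
    lab <- if (nzchar(row$label)) read_nifti_volume(row$label) else NULL
    out[[row$subset]][[length(out[[row$subset]]) + 1]] <- list(
      volume = vol$values,
      label = if (!is.null(lab)) array(as.integer(round(lab$values)),
                                       dim(lab$values)) else NULL,
      spacing_mm = vol$spacing_mm, domain = row$domain,
      case_id = row$case_id)
  }
  n_tl <- length(out$TL); n_tu <- length(out$TU)
  structure(c(out, list(labeled_ratio = if (n_tl + n_tu > 0)
    n_tl / (n_tl + n_tu) else NA_real_)),
    class = "split_dataset")
}
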