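# NIfTI input/output, the preprocessing chain (clip -> crop -> resample ->
# normalize) and online augmentation (in-plane rotation + shear, gamma
# contrast).

#' Construct a volume object
#'
#' @param values finite 3D numeric array `(D, H, W)`
#' @param spacing_mm voxel spacing `(dz, dy, dx)`, strictly positive
#' @param modality one of `"CT"`, `"MRI"`, `"synthetic-source"`,
#'   `"synthetic-target"`
#' @return a `volume` list
#' @export
volume <- function(values, spacing_mm = c(1, 1, 1), modality = "MRI") {
  if (!all(is.finite(values))) stop("volume contains non-finite voxels")
  if (any(spacing_mm <= 0)) stop("spacing must be strictly positive")
  structure(list(values = values, spacing_mm = spacing_mm,
                 modality = modality), class = "volume")
}

#' Write a 3D array as NIfTI with spacing in the header
#' @param arr `(D, H, W)` array
#' @param path output path (`.nii` or `.nii.gz`)
#' @param spacing_mm voxel spacing written to pixdim
#' @export
write_nifti_volume <- function(arr, path, spacing_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file into a plain array plus spacing
#' @param path NIfTI path
#' @return `list(values = array, spacing_mm = numeric(3))`
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim(img)),
       spacing_mm = as.numeric(RNifti::pixdim(img)))
}

#' Preprocess a volume (and aligned label map)
#'
#' The chain is: CT intensity clipping to `ct_clip`, cropping to the
#' targeted organs (the union bounding box of foreground labels plus a
#' margin; for unlabeled volumes an intensity-threshold body-mask box),
#' resampling to `target_dims` (trilinear for the image,
#' nearest-neighbour for labels so no new class values appear), and min-max
#' normalization to `[0, 1]`. A degenerate intensity range yields a
#' constant-zero volume with a warning rather than NaN.
#'
#' @param vol a [volume()] (or plain `(D, H, W)` array, treated as MRI)
#' @param label optional integer label array aligned to `vol`
#' @param target_dims output dims `(D, H, W)`
#' @param ct_clip clip bounds applied to CT volumes before normalization
#' @param crop logical, crop to the organ/body box first
#' @param margin crop margin in voxels
#' @return `list(volume = volume object, label = array or NULL)`
#' @export
preprocess <- function(vol, label = NULL, target_dims = c(32, 256, 256),
                       ct_clip = c(-350, 350), crop = TRUE, margin = 2) {
  if (!inherits(vol, "volume")) vol <- volume(vol)
  v <- vol$values
  if (!all(is.finite(v))) stop("volume contains non-finite voxels")
  if (identical(vol$modality, "CT"))
    v <- pmin(pmax(v, ct_clip[1]), ct_clip[2])
  d <- dim(v)
  if (crop) {
    mask <- if (!is.null(label)) label > 0
    else v > min(v) + 0.1 * (max(v) - min(v))
    if (any(mask)) {
      idx <- which(mask, arr.ind = TRUE)
      lo <- pmax(apply(idx, 2, min) - margin, 1)
      hi <- pmin(apply(idx, 2, max) + margin, d)
      v <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      if (!is.null(label))
        label <- label[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    }
  }
  src_dims <- dim(v)
  v <- resample_array(v, target_dims, "trilinear")
  if (!is.null(label)) {
    label <- resample_array(label, target_dims, "nearest")
    label <- array(as.integer(round(label)), target_dims)
  }
  rng <- range(v)
  if (rng[2] > rng[1]) {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("degenerate intensity range (max = min): returning constant 0")
    v <- array(0, dim(v))
  }
  new_spacing <- vol$spacing_mm * src_dims / target_dims
  list(volume = volume(v, new_spacing, vol$modality), label = label)
}

#' Resample a 3D array to target dimensions
#'
#' Center-aligned resampling: output voxel centers map linearly onto input
#' voxel centers. `"trilinear"` interpolates; `"nearest"` picks the closest
#' voxel (no new values introduced, suitable for label maps).
#'
#' @param arr `(D, H, W)` array
#' @param target target dims `(D, H, W)`
#' @param method `"trilinear"` or `"nearest"`
#' @export
resample_array <- function(arr, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  if (all(d == target)) return(arr)
  ax <- lapply(1:3, function(a) {
    sc <- d[a] / target[a]
    (seq_len(target[a]) - 0.5) * sc - 0.5   # 0-based input coordinate
  })
  if (method == "nearest") {
    iz <- pmin(pmax(round(ax[[1]]), 0), d[1] - 1) + 1
    iy <- pmin(pmax(round(ax[[2]]), 0), d[2] - 1) + 1
    ix <- pmin(pmax(round(ax[[3]]), 0), d[3] - 1) + 1
    return(arr[iz, iy, ix, drop = FALSE])
  }
  lohi <- lapply(1:3, function(a) {
    lo <- floor(ax[[a]]); f <- ax[[a]] - lo
    lo2 <- pmin(pmax(lo, 0), d[a] - 1)
    hi2 <- pmin(lo + 1, d[a] - 1)
    list(lo = lo2 + 1, hi = pmax(hi2, 0) + 1, f = f)
  })
  out <- array(0, target)
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    wz <- if (bz == 0) 1 - lohi[[1]]$f else lohi[[1]]$f
    wy <- if (by == 0) 1 - lohi[[2]]$f else lohi[[2]]$f
    wx <- if (bx == 0) 1 - lohi[[3]]$f else lohi[[3]]$f
    iz <- if (bz == 0) lohi[[1]]$lo else lohi[[1]]$hi
    iy <- if (by == 0) lohi[[2]]$lo else lohi[[2]]$hi
    ix <- if (bx == 0) lohi[[3]]$lo else lohi[[3]]$hi
    w <- outer(outer(wz, wy), wx)
    out <- out + arr[iz, iy, ix, drop = FALSE] * w
  }
  out
}

#' Online augmentation
#'
#' Applies one random in-plane (H, W) rotation in `rotation_deg`, one shear
#' in `shear_rad` (radians), and one gamma contrast adjustment with gamma
#' in `gamma_range` to a volume in `[0, 1]`. The geometric transform is
#' applied identically to image (bilinear) and label (nearest neighbour);
#' gamma applies to the image only; the image is clipped back to `[0, 1]`.
#' Deterministic for a fixed seed.
#'
#' @param vol `(D, H, W)` array in `[0, 1]` (or a [volume()])
#' @param label optional integer label array of the same shape
#' @param seed integer seed for the three parameter draws
#' @param rotation_deg,shear_rad,gamma_range augmentation parameter ranges
#' @return `list(volume = array, label = array or NULL, params = draws)`
#' @export
augment <- function(vol, label = NULL, seed = 1,
                    rotation_deg = c(-30, 30), shear_rad = c(-0.1, 0.1),
                    gamma_range = c(1.5, 2)) {
  if (inherits(vol, "volume")) vol <- vol$values
  pars <- with_seed(mix_seed(seed, 4242), list(
    theta = runif(1, rotation_deg[1], rotation_deg[2]) * pi / 180,
    shear = runif(1, shear_rad[1], shear_rad[2]),
    gamma = runif(1, gamma_range[1], gamma_range[2])))
  d <- dim(vol)
  H <- d[2]; W <- d[3]
  # forward map p' = M (p - c) + c with M = rotation %*% shear; we sample
  # the output grid through the inverse map.
  R <- matrix(c(cos(pars$theta), sin(pars$theta),
                -sin(pars$theta), cos(pars$theta)), 2)
  Sh <- matrix(c(1, 0, pars$shear, 1), 2)
  M <- R %*% Sh
  Minv <- solve(M)
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  gy <- rep(seq_len(H) - 1, times = W)
  gx <- rep(seq_len(W) - 1, each = H)
  src <- Minv %*% rbind(gy - ctr[1], gx - ctr[2])
  sy <- src[1, ] + ctr[1]
  sx <- src[2, ] + ctr[2]
  out <- warp_planes(vol, sy, sx, bilinear = TRUE)
  out <- pmin(pmax(out, 0), 1)^pars$gamma
  lab_out <- NULL
  if (!is.null(label))
    lab_out <- array(as.integer(warp_planes(label, sy, sx, bilinear = FALSE)),
                     d)
  list(volume = array(out, d), label = lab_out, params = pars)
}

# Apply the same in-plane coordinate lookup (sy, sx; 0-based, length H*W)
# to every depth slice at once. Out-of-range coordinates map to 0.
warp_planes <- function(vol, sy, sx, bilinear = TRUE) {
  d <- dim(vol)
  D <- d[1]; H <- d[2]; W <- d[3]
  Vm <- matrix(vol, nrow = D)              # columns indexed (y + H*x)
  out <- matrix(0, D, H * W)
  if (bilinear) {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    for (by in 0:1) for (bx in 0:1) {
      yy <- y0 + by; xx <- x0 + bx
      wt <- (if (by == 0) 1 - fy else fy) * (if (bx == 0) 1 - fx else fx)
      ok <- yy >= 0 & yy <= H - 1 & xx >= 0 & xx <= W - 1 & wt > 0
      if (!any(ok)) next
      colidx <- yy[ok] + H * xx[ok] + 1
      out[, ok] <- out[, ok] + Vm[, colidx, drop = FALSE] *
        rep(wt[ok], each = D)
    }
  } else {
    yy <- round(sy); xx <- round(sx)
    ok <- yy >= 0 & yy <= H - 1 & xx >= 0 & xx <= W - 1
    colidx <- yy[ok] + H * xx[ok] + 1
    out[, ok] <- Vm[, colidx, drop = FALSE]
  }
  array(out, d)
}
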