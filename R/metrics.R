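# Evaluation: per-organ Dice similarity coefficient (DSC) and average
# symmetric surface distance (ASD), case-level aggregation, and the paired
# two-sided t-test used for method comparisons.

#' Dice similarity coefficient for one class
#'
#' `2 |A intersect B| / (|A| + |B|)` on the binarized class. Conventions:
#' both masks empty -> 1; one empty -> 0.
#'
#' @param pred,gt integer label arrays of identical shape
#' @param class_id class to binarize on
#' @return a fraction in `[0, 1]`
#' @export
dsc <- function(pred, gt, class_id) {
  stopifnot(identical(dim(pred), dim(gt)))
  a <- pred == class_id
  b <- gt == class_id
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Average symmetric surface distance for one class, in mm
#'
#' Surface voxels are 6-connectivity boundary voxels (a foreground voxel
#' with a background face-neighbour, or on the array border). The ASD is
#' the mean, over the union of both surfaces, of each surface voxel's
#' nearest distance to the other surface, computed in physical millimetres
#' using the voxel spacing. Symmetric by construction. If either surface
#' is empty the metric is undefined and `NA` is returned with attribute
#' `undefined = TRUE` (never silently zero).
#'
#' @param pred,gt integer label arrays of identical shape
#' @param class_id class to binarize on
#' @param spacing_mm voxel spacing `(dz, dy, dx)`
#' @return distance in mm, or flagged `NA`
#' @export
asd <- function(pred, gt, class_id, spacing_mm = c(1, 1, 1)) {
  stopifnot(identical(dim(pred), dim(gt)))
  sp <- surface_coords(pred == class_id, spacing_mm)
  sg <- surface_coords(gt == class_id, spacing_mm)
  if (nrow(sp) == 0 || nrow(sg) == 0)
    return(structure(NA_real_, undefined = TRUE))
  d1 <- cpp_min_dists(sp, sg)
  d2 <- cpp_min_dists(sg, sp)
  mean(c(d1, d2))
}

# Boundary voxels of a logical mask under 6-connectivity; voxels on the
# array border count as boundary. Returns physical coordinates (n x 3).
surface_coords <- function(mask, spacing_mm) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, dir) {
    idx <- lapply(d, seq_len)
    src <- lapply(d, seq_len)
    if (dir > 0) { idx[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { idx[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    nb <- array(FALSE, d)
    nb[idx[[1]], idx[[2]], idx[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    acc & nb
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- shift_and(interior, ax, dir)
  boundary <- mask & !interior
  idx <- which(boundary, arr.ind = TRUE)
  if (length(idx) == 0) return(matrix(0, 0, 3))
  sweep(matrix(as.numeric(idx), ncol = 3), 2, spacing_mm, `*`)
}

#' Two-sided paired t-test on per-case scores
#'
#' Used to compare methods on case-level organ-averaged scores. Zero
#' variance of the paired differences makes the statistic undefined; the
#' p-value is then `NaN` with `flag = "zero_variance"`.
#'
#' @param a,b equal-length (>= 2) per-case score vectors, paired by case
#' @return `list(statistic, df, p.value, flag)`
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0)
    return(list(statistic = NaN, df = length(a) - 1, p.value = NaN,
                flag = "zero_variance"))
  tt <- t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, flag = NULL)
}

#' Evaluate a model on labeled cases
#'
#' Predicts each case and computes per-class DSC and ASD.
#'
#' @param model a `segnet`
#' @param cases list of samples with `volume`, `label`, `spacing_mm`
#' @param domain domain tag for the forward passes
#' @param class_names names of the foreground classes
#' @return data frame: one row per case per foreground class, with columns
#'   `case_id`, `class_id`, `class_name`, `dsc`, `asd_mm`
#' @export
evaluate_cases <- function(model, cases, domain = "target",
                           class_names = c("liver", "r_kidney", "l_kidney",
                                           "spleen")) {
  rows <- list()
  for (smp in cases) {
    pred <- predict_labels(model, smp$volume, domain)
    for (cc in seq_along(class_names)) {
      a <- asd(pred, smp$label, cc, smp$spacing_mm %||% c(1, 1, 1))
      rows[[length(rows) + 1]] <- data.frame(
        case_id = smp$case_id %||% NA_character_, class_id = cc,
        class_name = class_names[cc],
        dsc = dsc(pred, smp$label, cc),
        asd_mm = as.numeric(a))
    }
  }
  do.call(rbind, rows)
}

#' Summarize case metrics per organ and overall
#'
#' Mean and sd of DSC/ASD per organ plus the all-organ average row,
#' mirroring the usual multi-organ results-table layout.
#'
#' @param df output of [evaluate_cases()]
#' @return data frame with one row per organ plus `"average"`
#' @export
summarize_metrics <- function(df) {
  per <- do.call(rbind, lapply(split(df, df$class_name), function(g)
    data.frame(class_name = g$class_name[1],
               dsc_mean = mean(g$dsc), dsc_sd = sd(g$dsc),
               asd_mean = mean(g$asd_mm, na.rm = TRUE),
               asd_sd = sd(g$asd_mm, na.rm = TRUE))))
  case_avg <- vapply(split(df, df$case_id), function(g) mean(g$dsc),
                     numeric(1))
  case_asd <- vapply(split(df, df$case_id),
                     function(g) mean(g$asd_mm, na.rm = TRUE), numeric(1))
  rbind(per, data.frame(class_name = "average",
                        dsc_mean = mean(case_avg), dsc_sd = sd(case_avg),
                        asd_mean = mean(case_asd), asd_sd = sd(case_asd)))
}

#' Case-level organ-averaged DSC
#'
#' @param df output of [evaluate_cases()]
#' @return named vector, one organ-averaged DSC per case
#' @export
case_average_dsc <- function(df) {
  vapply(split(df, df$case_id), function(g) mean(g$dsc), numeric(1))
}
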