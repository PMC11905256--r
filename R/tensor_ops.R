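#' Channel shuffle
#'
#' Permutes the channels of a feature tensor by the reshape--transpose
#' permutation used after grouped or multi-branch convolutions: channels are
#' viewed as a `(groups, C/groups)` grid and read out column-wise, so that
#' channels originating from different branches interleave. For `C = 6`,
#' `groups = 2` the channel order `0..5` becomes `0,3,1,4,2,5`.
#'
#' @param x array whose first axis is the channel axis, e.g. `(C, D, H, W, B)`
#' @param groups number of groups; `C` must be divisible by `groups`
#' @return array of the same shape with channels permuted; voxel data within
#'   each channel is untouched
#' @export
channel_shuffle <- function(x, groups) {
  C <- dim(x)[1]
  if (C %% groups != 0)
    stop("channel count ", C, " is not divisible by groups = ", groups)
  perm <- shuffle_permutation(C, groups)
  m <- matrix(x, nrow = C)
  y <- m[perm, , drop = FALSE]
  dim(y) <- dim(x)
  y
}

# The shuffle permutation: y[i] = x[perm[i]].
shuffle_permutation <- function(C, groups) {
  as.vector(t(matrix(seq_len(C), ncol = groups)))
}

inverse_permutation <- function(perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  inv
}

#' Unfold a feature tensor into non-overlapping patches
#'
#' Losslessly rearranges a `(d, D, H, W, B)` feature tensor into a patch
#' tensor of shape `(P, N, d, B)`, where `P = p_d * p_h * p_w` is the number
#' of voxels per patch and `N = D*H*W / P` the number of patches. Position
#' `(q, n)` holds the q-th within-patch voxel of the n-th patch; within-patch
#' voxels and patches are both ordered depth-fastest. This is the token
#' layout consumed by the bottleneck transformer: attention runs over the N
#' patch positions, separately for each within-patch index q.
#'
#' @param x array `(d, D, H, W, B)`; each spatial dim must be divisible by
#'   the corresponding patch dim
#' @param patch integer vector `(p_d, p_h, p_w)`, all 2 by default
#' @return array `(P, N, d, B)`
#' @seealso [fold_patches()]
#' @export
unfold_patches <- function(x, patch = c(2, 2, 2)) {
  d <- dim(x)
  stopifnot(length(d) == 5)
  sp <- d[2:4]
  for (ax in 1:3) {
    if (sp[ax] %% patch[ax] != 0)
      stop("spatial axis ", ax, " (size ", sp[ax],
           ") is not divisible by patch dim ", patch[ax])
  }
  ch <- d[1]; B <- d[5]
  dim(x) <- c(ch, patch[1], sp[1] / patch[1], patch[2], sp[2] / patch[2],
              patch[3], sp[3] / patch[3], B)
  y <- aperm(x, c(2, 4, 6, 3, 5, 7, 1, 8))
  dim(y) <- c(prod(patch), prod(sp) / prod(patch), ch, B)
  y
}

#' Fold a patch tensor back into a feature tensor
#'
#' Exact inverse of [unfold_patches()]: `fold_patches(unfold_patches(x),
#' dim(x)[2:4])` reproduces `x` bit-exactly.
#'
#' @param u array `(P, N, d, B)` as produced by [unfold_patches()]
#' @param spatial integer vector `(D, H, W)` of the original feature tensor
#' @param patch integer vector `(p_d, p_h, p_w)`
#' @return array `(d, D, H, W, B)`
#' @export
fold_patches <- function(u, spatial, patch = c(2, 2, 2)) {
  du <- dim(u)
  stopifnot(length(du) == 4)
  ch <- du[3]; B <- du[4]
  dim(u) <- c(patch[1], patch[2], patch[3],
              spatial[1] / patch[1], spatial[2] / patch[2],
              spatial[3] / patch[3], ch, B)
  y <- aperm(u, c(7, 1, 4, 2, 5, 3, 6, 8))
  dim(y) <- c(ch, spatial, B)
  y
}
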