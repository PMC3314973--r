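#' Reparameterize weights against a reference class
#'
#' The softmax likelihood is invariant to adding a common vector to every
#' class column, so the weight matrix can equivalently be expressed with one
#' class fixed to zero: `w'_j = w_j - w_ref`. Predictions are unchanged;
#' the reference column becomes identically zero. With the placebo class as
#' reference, the remaining columns read directly as each drug's
#' discriminating pattern relative to placebo.
#'
#' @param W Weight matrix (`d x m`) with class column names, or an
#'   `smlr_fit`.
#' @param reference Reference class label (must be a column of `W`).
#' @return Weight matrix of the same shape with the reference column zero.
#' @export
reparameterize_weights <- function(W, reference) {
  if (inherits(W, "smlr_fit")) W <- W$weights
  if (is.null(colnames(W)) || !(reference %in% colnames(W))) {
    abort(sprintf("Unknown reference class '%s'.", reference))
  }
  W - W[, reference]
}

#' Map weight-vector coefficients back to the voxel grid
#'
#' Places each class's coefficients at their grid coordinates via the
#' feature matrix's voxel index; voxels outside the analysis mask are `NA`.
#'
#' @param fit An `smlr_fit` (or a weight matrix with class column names).
#' @param features The [asl_features()] the model was trained on.
#' @param reference Optional reference class; when given, weights are first
#'   passed through [reparameterize_weights()].
#' @return Named list of 3-D arrays, one per class.
#' @export
discrimination_maps <- function(fit, features, reference = NULL) {
  W <- if (inherits(fit, "smlr_fit")) fit$weights else fit
  stopifnot(inherits(features, "asl_features"))
  if (nrow(W) != ncol(features$X)) {
    abort("Weight rows must match the feature matrix's voxel count.")
  }
  if (!is.null(reference)) W <- reparameterize_weights(W, reference)
  idx <- which(features$mask)
  lapply(setNames(colnames(W), colnames(W)), function(cl) {
    vol <- array(NA_real_, dim(features$mask))
    vol[idx] <- W[, cl]
    vol
  })
}

#' Overlap of nonzero coefficients between two discrimination maps
#'
#' Classifies every in-mask voxel by the exact-zero pattern of its
#' coefficients in two maps: both zero, nonzero only in the first, only in
#' the second, or in both. "Nonzero" is an exact test — the L1 path produces
#' exact zeros, so no epsilon threshold is used.
#'
#' @param mapA,mapB 3-D coefficient arrays on the same grid (`NA` outside
#'   the mask).
#' @return List with `map` (integer array: 0 neither, 1 only A, 2 only B,
#'   3 both; `NA` outside mask) and `legend` (named vector).
#' @export
compute_overlap_map <- function(mapA, mapB) {
  check_same_grid(mapA, mapB, "overlap inputs")
  mask <- is.finite(mapA) & is.finite(mapB)
  out <- array(NA_integer_, dim(mapA))
  a <- mapA[mask] != 0
  b <- mapB[mask] != 0
  out[mask] <- ifelse(a & b, 3L, ifelse(a, 1L, ifelse(b, 2L, 0L)))
  list(map = out,
       legend = c(neither = 0L, only_A = 1L, only_B = 2L, both = 3L))
}

#' Voxelwise unpaired t-statistic map
#'
#' Two-sample pooled-variance (Student) t-statistic at every voxel for one
#' binary contrast, computed from the same images used to train the
#' classifier. The map is returned unthresholded; voxels where the pooled
#' variance is zero get `NaN`. Swapping the groups negates the map.
#'
#' @param groupA,groupB Lists of [cbf_map()] objects (or 3-D arrays), at
#'   least two per group, on a common grid.
#' @return List with `t` (3-D array), `nA`, `nB`, `df`.
#' @export
unpaired_t_map <- function(groupA, groupB) {
  as_flow <- function(x) if (inherits(x, "cbf_map")) x$flow else x
  A <- lapply(groupA, as_flow)
  B <- lapply(groupB, as_flow)
  nA <- length(A); nB <- length(B)
  if (nA < 2L || nB < 2L) abort("Each group needs at least 2 volumes.")
  for (v in c(A, B)) check_same_grid(v, A[[1]], "t-map inputs")
  dims <- dim(A[[1]])
  MA <- vapply(A, as.numeric, numeric(prod(dims)))
  MB <- vapply(B, as.numeric, numeric(prod(dims)))
  mA <- rowMeans(MA); mB <- rowMeans(MB)
  ssA <- rowSums((MA - mA)^2); ssB <- rowSums((MB - mB)^2)
  df <- nA + nB - 2L
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se  # 0/0 -> NaN where pooled variance vanishes
  list(t = array(t, dims), nA = nA, nB = nB, df = df)
}

#' Sign concordance between a discrimination map and a t-map
#'
#' Among voxels with nonzero coefficients in the discrimination map and a
#' defined t-statistic, the fraction where the coefficient and the
#' t-statistic share a sign. Returns `NA` when no voxel qualifies.
#'
#' @param map 3-D coefficient array.
#' @param t_map 3-D t-statistic array (or the list from
#'   [unpaired_t_map()]).
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
sign_concordance <- function(map, t_map) {
  if (is.list(t_map)) t_map <- t_map$t
  check_same_grid(map, t_map, "map and t-map")
  sel <- is.finite(map) & map != 0 & is.finite(t_map)
  if (!any(sel)) return(NA_real_)
  mean(sign(map[sel]) == sign(t_map[sel]))
}
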