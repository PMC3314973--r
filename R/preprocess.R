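#' Smooth a flow map with an isotropic Gaussian kernel
#'
#' Separable Gaussian convolution with full width at half maximum given in mm
#' (the SPM convention), i.e. per-axis standard deviation
#' `fwhm / (2 sqrt(2 log 2))` converted to voxels through the map's voxel
#' size. The kernel is truncated at 4 standard deviations and normalized to
#' unit sum; boundaries are handled by half-sample symmetric reflection, so a
#' constant volume is reproduced exactly and the total in-volume sum is
#' preserved.
#'
#' @param map A [cbf_map()] (must carry voxel-size metadata).
#' @param fwhm_mm Kernel full width at half maximum in mm (> 0).
#' @return A smoothed [cbf_map()] on the same grid.
#' @export
smooth_volume <- function(map, fwhm_mm = 8) {
  stopifnot(inherits(map, "cbf_map"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0) {
    abort("`fwhm_mm` must be a single positive number.")
  }
  if (is.null(map$voxel_size_mm) || any(!is.finite(map$voxel_size_mm))) {
    abort("Voxel-size metadata is required for smoothing in mm units.")
  }
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- map$flow
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / map$voxel_size_mm[axis]
    if (sigma_vox < 1e-8) next
    h <- as.integer(ceiling(4 * sigma_vox))
    w <- dnorm(seq(-h, h), sd = sigma_vox)
    w <- w / sum(w)
    out <- convolve_axis(out, w, axis)
  }
  cbf_map(out, map$voxel_size_mm, mask = map$mask)
}

# 1-D convolution along one axis of a 3-D array with half-sample symmetric
# (mirror) padding; kernel w has odd length 2h+1 and sums to 1
convolve_axis <- function(arr, w, axis) {
  d <- dim(arr)
  h <- (length(w) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  x <- matrix(x, nrow = dp[1])
  n <- dp[1]
  # mirror indices: position 0 -> 1, -1 -> 2, n+1 -> n, n+2 -> n-1 ...
  refl <- function(i) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  pad_idx <- refl(seq.int(1L - h, n + h))
  xp <- x[pad_idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(x))
  for (t in seq_along(w)) {
    out <- out + w[t] * xp[seq.int(t, t + n - 1L), , drop = FALSE]
  }
  out <- array(out, dp)
  aperm(out, order(perm))
}

#' Average the first k scans of a scan list
#'
#' Voxelwise arithmetic mean of the first `k` maps in acquisition order; the
#' output mask is the intersection of the input masks.
#'
#' @param maps List of [cbf_map()] objects on a common grid, in acquisition
#'   order.
#' @param k Number of leading scans to average (default: all).
#' @return A [cbf_map()].
#' @export
average_scans <- function(maps, k = length(maps)) {
  if (length(maps) == 0L) abort("Cannot average an empty list of maps.")
  if (k < 1L || k > length(maps)) {
    abort(sprintf("`k` must be between 1 and %d.", length(maps)))
  }
  maps <- maps[seq_len(k)]
  for (mp in maps) {
    stopifnot(inherits(mp, "cbf_map"))
    check_same_grid(mp$flow, maps[[1]]$flow, "scans being averaged")
  }
  flow <- Reduce(`+`, lapply(maps, `[[`, "flow")) / k
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  cbf_map(flow, maps[[1]]$voxel_size_mm, mask = mask)
}

#' Feature matrix of vectorized, centered perfusion images
#'
#' Container for the classifier input: an `n x d` matrix with one row per
#' averaged subject-condition image and one column per in-mask voxel, plus
#' the row metadata and the voxel-to-grid index map.
#'
#' @param X Numeric matrix, rows = scans/images, columns = in-mask voxels.
#' @param row_meta Tibble with columns `subject` and `condition`, one row per
#'   row of `X`.
#' @param voxel_index Tibble with columns `col`, `i`, `j`, `k` mapping matrix
#'   columns to grid coordinates.
#' @param mask Logical 3-D array; `sum(mask)` must equal `ncol(X)`.
#' @param voxel_size_mm Voxel size in mm.
#' @param centered Logical; whether rows have been mean-centered within
#'   subject.
#' @return An object of class `asl_features`.
#' @export
asl_features <- function(X, row_meta, voxel_index, mask,
                         voxel_size_mm = c(3, 3, 3), centered = FALSE) {
  if (nrow(row_meta) != nrow(X)) abort("`row_meta` must have one row per row of `X`.")
  if (sum(mask) != ncol(X)) abort("`ncol(X)` must equal the mask cardinality.")
  structure(
    list(X = X, row_meta = tibble::as_tibble(row_meta),
         voxel_index = tibble::as_tibble(voxel_index), mask = mask,
         voxel_size_mm = voxel_size_mm, centered = centered),
    class = "asl_features"
  )
}

#' @export
print.asl_features <- function(x, ...) {
  cat(sprintf("<asl_features> %d images x %d voxels (%s, %scentered)\n",
              nrow(x$X), ncol(x$X),
              paste(dim(x$mask), collapse = "x"),
              if (x$centered) "" else "not "))
  invisible(x)
}

#' Mean-center feature rows within each subject
#'
#' Basal perfusion differs between participants; subtracting each subject's
#' mean image removes that offset. For every subject, the mean of that
#' subject's rows is subtracted from each of its rows, so per-subject column
#' sums become zero. Centering only makes sense over the rows entering one
#' classification problem, which is why [build_feature_matrix()] centers
#' after condition selection.
#'
#' @param features An [asl_features()] object; every subject must contribute
#'   at least two rows (centering a single row would zero it).
#' @return The centered [asl_features()].
#' @export
mean_center_within_subject <- function(features) {
  stopifnot(inherits(features, "asl_features"))
  subj <- features$row_meta$subject
  counts <- table(subj)
  if (any(counts < 2L)) {
    abort(sprintf(
      "Subject(s) %s have a single row; within-subject centering would erase them.",
      paste(names(counts)[counts < 2L], collapse = ", ")
    ))
  }
  X <- features$X
  for (s in unique(subj)) {
    rows <- which(subj == s)
    X[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                       colMeans(X[rows, , drop = FALSE]))
  }
  features$X <- X
  features$centered <- TRUE
  features
}

#' Build the classifier feature matrix from a scan set
#'
#' Runs the preprocessing pipeline in order: smooth every scan, average the
#' first `k_scans` scans per subject-condition, mean-center within subject
#' over exactly the selected conditions, and vectorize in-mask voxels. The
#' analysis mask is the set of voxels finite and nonzero in every input map
#' (intersected with the maps' own masks).
#'
#' @param scans Tibble with columns `subject`, `condition`, `scan` and a
#'   `map` list-column of [cbf_map()] objects (e.g.
#'   `generate_phantom_dataset()$scans` or [read_scan_set()] output).
#' @param conditions Character vector of condition labels to include (3 for
#'   the multi-class problem, 2 for a binary contrast).
#' @param k_scans Number of leading scans to average per subject-condition.
#' @param fwhm_mm Smoothing kernel FWHM in mm; `NULL` or 0 skips smoothing.
#' @param center Center within subject (default `TRUE`).
#' @return An [asl_features()] object with one row per subject-condition.
#' @export
build_feature_matrix <- function(scans, conditions = NULL, k_scans = NULL,
                                 fwhm_mm = 8, center = TRUE) {
  stopifnot(is.data.frame(scans), all(c("subject", "condition", "scan", "map")
                                      %in% names(scans)))
  if (is.null(conditions)) conditions <- unique(scans$condition)
  if (!all(conditions %in% scans$condition)) {
    abort("Some requested `conditions` are absent from the scan set.")
  }
  sel <- scans |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::arrange(.data$subject, match(.data$condition, conditions),
                   .data$scan)
  dims <- dim(sel$map[[1]]$flow)
  vox <- sel$map[[1]]$voxel_size_mm
  for (mp in sel$map) check_same_grid(mp$flow, sel$map[[1]]$flow, "scan set maps")

  mask <- Reduce(`&`, lapply(sel$map, function(mp) {
    mp$mask & is.finite(mp$flow) & mp$flow != 0
  }))

  if (!is.null(fwhm_mm) && fwhm_mm > 0) {
    sel$map <- lapply(sel$map, smooth_volume, fwhm_mm = fwhm_mm)
  }

  groups <- sel |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(avg = list(average_scans(
      map[order(scan)],
      k = if (is.null(k_scans)) length(map) else k_scans
    )), .groups = "drop") |>
    dplyr::arrange(.data$subject, match(.data$condition, conditions))

  idx <- which(mask)
  coords <- arrayInd(idx, dims)
  voxel_index <- tibble::tibble(col = seq_along(idx), i = coords[, 1],
                                j = coords[, 2], k = coords[, 3])
  X <- do.call(rbind, lapply(groups$avg, function(mp) mp$flow[idx]))
  feats <- asl_features(
    X, row_meta = groups |> dplyr::select("subject", "condition"),
    voxel_index = voxel_index, mask = mask, voxel_size_mm = vox
  )
  if (center) feats <- mean_center_within_subject(feats)
  feats
}
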