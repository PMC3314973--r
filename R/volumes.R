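#' Quantified cerebral blood flow volume
#'
#' A `cbf_map` wraps a 3-D array of flow values in ml/100 g/min together with
#' its voxel size (mm) and a logical analysis mask. Voxels outside the mask
#' carry `NA`.
#'
#' @param flow 3-D numeric array of flow values (ml/100 g/min).
#' @param voxel_size_mm Numeric length-3, voxel edge lengths in mm.
#' @param mask Logical array of the same dimension; default marks finite
#'   voxels.
#' @return An object of class `cbf_map` with elements `flow`, `mask`,
#'   `voxel_size_mm`.
#' @export
cbf_map <- function(flow, voxel_size_mm = c(3, 3, 3), mask = NULL) {
  if (!is.array(flow) || length(dim(flow)) != 3L) {
    abort("`flow` must be a 3-D array.")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    abort("`voxel_size_mm` must be 3 positive numbers.")
  }
  if (is.null(mask)) {
    mask <- is.finite(flow)
  }
  if (!identical(dim(mask), dim(flow))) {
    abort("`mask` dimensions must match `flow`.")
  }
  structure(
    list(flow = flow, mask = mask, voxel_size_mm = voxel_size_mm),
    class = "cbf_map"
  )
}

#' @export
print.cbf_map <- function(x, ...) {
  d <- dim(x$flow)
  cat(sprintf(
    "<cbf_map> %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d in mask\n",
    d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
    x$voxel_size_mm[3], sum(x$mask)
  ))
  v <- x$flow[x$mask]
  if (length(v)) {
    cat(sprintf("  flow range: [%.4g, %.4g] ml/100 g/min\n",
                min(v), max(v)))
  }
  invisible(x)
}

#' Control/label ASL signal pair
#'
#' One pulsed-continuous ASL acquisition: a control volume and a label volume
#' of raw signal intensities on a common grid. The control-minus-label
#' difference is the perfusion-weighted signal.
#'
#' @param control,label 3-D numeric arrays of signal intensities (scanner
#'   units), same dimensions.
#' @param voxel_size_mm Numeric length-3, voxel size in mm.
#' @return An object of class `asl_pair`.
#' @export
asl_pair <- function(control, label, voxel_size_mm = c(3, 3, 3)) {
  if (!is.array(control) || !is.array(label) ||
      !identical(dim(control), dim(label))) {
    abort("`control` and `label` must be arrays with identical dimensions.")
  }
  if (!all(is.finite(control)) || !all(is.finite(label))) {
    abort("ASL signal volumes must be finite everywhere.")
  }
  structure(
    list(control = control, label = label,
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "asl_pair"
  )
}

#' Coil sensitivity map
#'
#' The calibration volume `C`: the fully relaxed MRI signal produced by 1 g of
#' water per ml of brain, used to convert perfusion-weighted signal into
#' absolute flow.
#'
#' @param C 3-D numeric array; must be strictly positive inside `mask`.
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @param mask Logical array; default all `TRUE`.
#' @return An object of class `sensitivity_map`.
#' @export
sensitivity_map <- function(C, voxel_size_mm = c(3, 3, 3), mask = NULL) {
  if (!is.array(C) || length(dim(C)) != 3L) {
    abort("`C` must be a 3-D array.")
  }
  if (is.null(mask)) mask <- array(TRUE, dim(C))
  if (any(!is.finite(C[mask])) || any(C[mask] <= 0)) {
    abort("Sensitivity `C` must be finite and strictly positive inside the mask.")
  }
  structure(
    list(C = C, mask = mask, voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "sensitivity_map"
  )
}

# shared grid check used across modules
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("Grid mismatch: %s have dimensions %s vs %s.", what,
                  paste(dim(a), collapse = "x"),
                  paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}
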