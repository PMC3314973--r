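#' Specify a spherical effect cluster
#'
#' A cluster plants an additive, condition-specific flow change inside a
#' sphere, standing in for a region where one drug raises or lowers perfusion
#' relative to another.
#'
#' @param center_voxel Integer length-3, cluster center in voxel indices
#'   (1-based).
#' @param radius_voxels Positive number; a voxel belongs to the cluster if the
#'   Euclidean distance from its center to `center_voxel` (in voxel units) is
#'   `<= radius_voxels`, boundary ties included.
#' @param effect_by_condition Numeric vector, one additive flow change
#'   (ml/100 g/min) per condition; at least two entries must differ for the
#'   cluster to be discriminative.
#' @return An object of class `effect_cluster`.
#' @export
effect_cluster <- function(center_voxel, radius_voxels, effect_by_condition) {
  center_voxel <- as.numeric(center_voxel)
  if (length(center_voxel) != 3L || any(!is.finite(center_voxel))) {
    abort("`center_voxel` must be 3 finite numbers.")
  }
  if (!is.numeric(radius_voxels) || length(radius_voxels) != 1L ||
      radius_voxels <= 0) {
    abort("`radius_voxels` must be a single positive number.")
  }
  structure(
    list(center_voxel = center_voxel, radius_voxels = radius_voxels,
         effect_by_condition = as.numeric(effect_by_condition)),
    class = "effect_cluster"
  )
}

#' Specify a synthetic perfusion phantom
#'
#' Defines the study design a phantom dataset emulates: a voxel grid, a
#' subjects-by-conditions-by-scans layout, spherical effect clusters, a global
#' baseline flow, spatially constant per-subject offsets, and i.i.d. Gaussian
#' voxel noise per scan.
#'
#' @param grid_shape Integer length-3, voxels per axis (each >= 4).
#' @param voxel_size_mm Numeric length-3, voxel size in mm.
#' @param n_subjects,n_conditions,scans_per_condition Design counts;
#'   `n_conditions >= 2`, `scans_per_condition >= 1`.
#' @param clusters List of [effect_cluster()] objects; every
#'   `effect_by_condition` must have length `n_conditions` and every sphere
#'   must lie fully inside the grid.
#' @param baseline_cbf Baseline flow, ml/100 g/min (> 0).
#' @param subject_offset_sd SD of the per-subject constant flow offset
#'   (ml/100 g/min, >= 0); this is exactly what within-subject mean-centering
#'   removes.
#' @param noise_sd SD of i.i.d. per-voxel, per-scan Gaussian noise
#'   (ml/100 g/min, >= 0).
#' @param condition_labels Optional character vector of condition names.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(14, 14, 8),
                         voxel_size_mm = c(3, 3, 3),
                         n_subjects = 15,
                         n_conditions = 3,
                         scans_per_condition = 6,
                         clusters = list(),
                         baseline_cbf = 50,
                         subject_offset_sd = 8,
                         noise_sd = 4,
                         condition_labels = NULL,
                         seed = 0L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    abort("`grid_shape` must be 3 integers, each >= 4.")
  }
  if (n_conditions < 2L) abort("`n_conditions` must be >= 2.")
  if (scans_per_condition < 1L) abort("`scans_per_condition` must be >= 1.")
  if (n_subjects < 1L) abort("`n_subjects` must be >= 1.")
  if (baseline_cbf <= 0) abort("`baseline_cbf` must be > 0.")
  if (subject_offset_sd < 0 || noise_sd < 0) {
    abort("`subject_offset_sd` and `noise_sd` must be >= 0.")
  }
  if (is.null(condition_labels)) {
    condition_labels <- if (n_conditions == 3L) {
      c("MPH", "ATX", "PLC")
    } else {
      sprintf("cond%02d", seq_len(n_conditions))
    }
  }
  if (length(condition_labels) != n_conditions) {
    abort("`condition_labels` must have one entry per condition.")
  }
  for (cl in clusters) {
    if (!inherits(cl, "effect_cluster")) {
      abort("Every element of `clusters` must be an `effect_cluster`.")
    }
    if (length(cl$effect_by_condition) != n_conditions) {
      abort("`effect_by_condition` length must equal `n_conditions`.")
    }
    lo <- cl$center_voxel - cl$radius_voxels
    hi <- cl$center_voxel + cl$radius_voxels
    if (any(lo < 1) || any(hi > grid_shape)) {
      abort(sprintf(
        "Cluster at (%s) with radius %.3g extends outside the %s grid.",
        paste(cl$center_voxel, collapse = ", "), cl$radius_voxels,
        paste(grid_shape, collapse = "x")
      ))
    }
  }
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
         n_subjects = as.integer(n_subjects),
         n_conditions = as.integer(n_conditions),
         scans_per_condition = as.integer(scans_per_condition),
         clusters = clusters, baseline_cbf = baseline_cbf,
         subject_offset_sd = subject_offset_sd, noise_sd = noise_sd,
         condition_labels = condition_labels, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default phantom: three drug-like conditions with four planted clusters
#'
#' Emulates a 15-subject, 3-condition (two active drugs plus placebo),
#' 6-scans-per-condition resting perfusion study. Four spherical clusters
#' mimic the kinds of differential regions such studies report: one region
#' where only the first drug raises flow, two where the drugs move flow in
#' opposite directions, and one where only the second drug raises flow.
#' Cluster effect magnitudes are at least three times the per-scan voxel
#' noise SD.
#'
#' @param ... Overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(...) {
  clusters <- list(
    # caudate-like: drug A only
    effect_cluster(c(5, 5, 4), 2.2, c(15, 0, 0)),
    # midbrain-like: opposite drug effects
    effect_cluster(c(10, 5, 5), 2.2, c(12, -12, 0)),
    # thalamus-like: opposite drug effects
    effect_cluster(c(5, 10, 5), 2.2, c(12, -12, 0)),
    # cerebellum-like: drug B only
    effect_cluster(c(10, 10, 4), 2.5, c(0, 15, 0))
  )
  args <- list(...)
  if (is.null(args$clusters)) args$clusters <- clusters
  do.call(phantom_spec, args)
}

#' Reduced phantom design for scan-count learning curves
#'
#' A smaller companion design to [default_phantom_spec()] used to study how
#' classification accuracy grows with the number of scans averaged: 6
#' subjects on a 10 x 10 x 6 grid with four clusters of the same geometry as
#' the default phantom and a per-scan voxel noise SD (30 ml/100 g/min)
#' calibrated so that single-scan accuracy sits mid-range between chance and
#' ceiling — the regime where averaging visibly helps.
#'
#' @param ... Overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
learning_curve_phantom_spec <- function(...) {
  clusters <- list(
    effect_cluster(c(4, 4, 3), 2, c(12, 0, 0)),
    effect_cluster(c(7, 4, 4), 2, c(10, -10, 0)),
    effect_cluster(c(4, 7, 4), 2, c(10, -10, 0)),
    effect_cluster(c(7, 7, 3), 2, c(0, 12, 0))
  )
  args <- list(...)
  defaults <- list(grid_shape = c(10, 10, 6), n_subjects = 6,
                   scans_per_condition = 6, clusters = clusters,
                   noise_sd = 30, subject_offset_sd = 8)
  for (nm in names(defaults)) {
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  }
  do.call(phantom_spec, args)
}

# logical sphere membership volume for one cluster
sphere_mask <- function(grid_shape, center, radius) {
  dx <- (seq_len(grid_shape[1]) - center[1])^2
  dy <- (seq_len(grid_shape[2]) - center[2])^2
  dz <- (seq_len(grid_shape[3]) - center[3])^2
  d2 <- outer(outer(dx, dy, `+`), dz, `+`)
  d2 <= radius^2 + 1e-12
}

#' Generate a phantom dataset
#'
#' Draws one dataset from a [phantom_spec()]: each scan equals
#' `baseline_cbf` + a per-subject constant offset + the condition's cluster
#' effects + i.i.d. Gaussian voxel noise. The truth mask marks the union of
#' spheres whose effect vectors are not constant across conditions, i.e. the
#' voxels a condition classifier can legitimately use.
#'
#' @param spec A `phantom_spec`.
#' @return An object of class `phantom_dataset` with elements
#'   \describe{
#'     \item{scans}{tibble with columns `subject`, `condition`, `scan`, and a
#'       `map` list-column of [cbf_map()] objects.}
#'     \item{truth_mask}{logical array marking discriminative voxels.}
#'     \item{spec}{the generating spec.}
#'   }
#' @export
generate_phantom_dataset <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  m <- spec$n_conditions

  effect_vol <- lapply(seq_len(m), function(j) array(0, gs))
  truth <- array(FALSE, gs)
  for (cl in spec$clusters) {
    memb <- sphere_mask(gs, cl$center_voxel, cl$radius_voxels)
    for (j in seq_len(m)) {
      effect_vol[[j]][memb] <- effect_vol[[j]][memb] + cl$effect_by_condition[j]
    }
    if (diff(range(cl$effect_by_condition)) > 0) truth <- truth | memb
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  offsets <- rnorm(spec$n_subjects, 0, spec$subject_offset_sd)
  rows <- vector("list", spec$n_subjects * m * spec$scans_per_condition)
  idx <- 0L
  subj_ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  for (s in seq_len(spec$n_subjects)) {
    for (j in seq_len(m)) {
      base <- spec$baseline_cbf + offsets[s] + effect_vol[[j]]
      for (sc in seq_len(spec$scans_per_condition)) {
        noise <- if (spec$noise_sd > 0) {
          array(rnorm(prod(gs), 0, spec$noise_sd), gs)
        } else {
          array(0, gs)
        }
        idx <- idx + 1L
        rows[[idx]] <- tibble::tibble(
          subject = subj_ids[s],
          condition = spec$condition_labels[j],
          scan = sc,
          map = list(cbf_map(base + noise, spec$voxel_size_mm))
        )
      }
    }
  }
  structure(
    list(scans = dplyr::bind_rows(rows), truth_mask = truth, spec = spec),
    class = "phantom_dataset"
  )
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "<phantom_dataset> %d subjects x %d conditions x %d scans on a %s grid\n",
    x$spec$n_subjects, x$spec$n_conditions, x$spec$scans_per_condition,
    paste(x$spec$grid_shape, collapse = "x")
  ))
  cat(sprintf("  %d discriminative voxels in truth mask\n", sum(x$truth_mask)))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Writes one NIfTI-1 volume per scan plus a CSV manifest
#' (`subject`, `condition`, `scan`, `path`) and the truth mask.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- dataset$spec$voxel_size_mm
  manifest <- dataset$scans |>
    dplyr::mutate(path = sprintf("%s_%s_scan%02d.nii.gz",
                                 .data$subject, .data$condition, .data$scan))
  for (i in seq_len(nrow(manifest))) {
    write_volume(manifest$map[[i]]$flow, file.path(dir, manifest$path[i]), vox)
  }
  write_volume(dataset$truth_mask * 1, file.path(dir, "truth_mask.nii.gz"), vox)
  out <- manifest |> dplyr::select(!"map")
  readr::write_csv(out, file.path(dir, "manifest.csv"))
  invisible(out)
}

#' Read a scan set from a manifest
#'
#' Reads the NIfTI + CSV layout produced by [write_phantom_dataset()] (or any
#' co-registered data arranged the same way) into a scan tibble.
#'
#' @param manifest_path Path to a `manifest.csv` with columns `subject`,
#'   `condition`, `scan`, `path` (paths relative to the manifest).
#' @return A tibble with a `map` list-column of `cbf_map` objects.
#' @export
read_scan_set <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  dir <- dirname(manifest_path)
  man$map <- lapply(man$path, function(p) {
    img <- RNifti::readNifti(file.path(dir, p))
    cbf_map(array(as.numeric(img), dim(img)),
            voxel_size_mm = RNifti::pixdim(img)[1:3])
  })
  man |> dplyr::select(!"path")
}

write_volume <- function(arr, path, voxel_size_mm) {
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
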