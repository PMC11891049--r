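#' Write a synthetic cohort as NIfTI volumes with sidecars
#'
#' Serializes each lesion as a 4D NIfTI (a toy x-by-y-by-1-by-n_b layout:
#' voxels are laid out row-major on a square slice and padded with zeros;
#' ROI geometry is not simulated, so the layout is only a container), an
#' FSL-style `.bval` sidecar (one space-separated line), a binary ROI mask
#' NIfTI, plus a cohort-level CSV.
#'
#' @param cohort An `ivim_cohort`.
#' @param dir Output directory.
#' @return Data frame manifest (patient_id, dwi, bval, mask), invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ivim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort$lesions), function(i) {
    les <- cohort$lesions[[i]]
    sig <- cohort$signals[[i]]
    id <- les$patient_id
    nb <- ncol(sig)
    side <- ceiling(sqrt(les$n_voxels))
    vol <- array(0, dim = c(side, side, 1, nb))
    mask <- array(0L, dim = c(side, side, 1))
    for (v in seq_len(les$n_voxels)) {
      x <- ((v - 1) %% side) + 1
      y <- ((v - 1) %/% side) + 1
      vol[x, y, 1, ] <- sig[v, ]
      mask[x, y, 1] <- 1L
    }
    dwi_path <- file.path(dir, paste0(id, "_dwi.nii.gz"))
    mask_path <- file.path(dir, paste0(id, "_mask.nii.gz"))
    bval_path <- file.path(dir, paste0(id, ".bval"))
    RNifti::writeNifti(RNifti::asNifti(vol), dwi_path)
    RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
    writeLines(paste(les$scheme$b_values, collapse = " "), bval_path)
    data.frame(patient_id = id, dwi = dwi_path, bval = bval_path,
               mask = mask_path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(cbind(cohort$patients, seed = cohort$seed),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Import one externally acquired case
#'
#' Validates and loads a 4D diffusion volume with its `.bval` sidecar and ROI
#' mask: the mask must match the volume grid, the scheme must contain b = 0,
#' and the ROI must contain at least 3 voxels.
#'
#' @param dwi_path 4D NIfTI with one volume per b-value.
#' @param bval_path FSL-style `.bval` (whitespace-separated values).
#' @param mask_path 3D NIfTI ROI mask (nonzero = in ROI).
#' @param site_tag Site tag to attach to the returned scheme (default "X").
#' @return List: `signals` (n_voxels x n_b matrix), `scheme`
#'   (`bvalue_scheme`), `n_voxels`.
#' @export
import_external_case <- function(dwi_path, bval_path, mask_path,
                                 site_tag = "X") {
  vol <- RNifti::readNifti(dwi_path)
  d <- dim(vol)
  if (length(d) != 4L) stop("expected a 4D diffusion volume, got ",
                            length(d), "D")
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  if (length(bvals) != d[4]) {
    stop("shape mismatch: .bval has ", length(bvals), " entries but volume has ",
         d[4], " diffusion volumes")
  }
  if (!any(bvals == 0)) stop("scheme must contain b = 0")
  mask <- RNifti::readNifti(mask_path)
  md <- dim(mask)
  if (length(md) == 4L && md[4] == 1L) md <- md[1:3]
  if (length(md) == 2L) md <- c(md, 1L) # trailing singleton dim dropped on read
  if (!identical(as.integer(md), as.integer(d[1:3]))) {
    stop("grid mismatch: mask is ", paste(md, collapse = "x"),
         " but volume is ", paste(d[1:3], collapse = "x"))
  }
  idx <- which(array(mask, dim = md) != 0)
  if (length(idx) < 3L) {
    stop("ROI mask has ", length(idx),
         " voxels; at least 3 voxels are required")
  }
  ord <- order(bvals)
  flat <- matrix(as.numeric(vol), prod(d[1:3]), d[4])
  signals <- flat[idx, ord, drop = FALSE]
  scheme <- structure(list(site_tag = site_tag, variant = 1L,
                           b_values = bvals[ord]), class = "bvalue_scheme")
  assert_scheme(scheme)
  list(signals = signals, scheme = scheme, n_voxels = length(idx))
}

#' Write fitted parameter maps as NIfTI
#'
#' One 3D NIfTI per parameter (units mm^2/s for the diffusivities, the
#' perfusion fraction dimensionless) in the same toy layout as
#' [write_cohort_nifti()], plus a per-voxel CSV with the validity flags.
#'
#' @param map A `parameter_map` from [fit_roi()].
#' @param prefix Output path prefix.
#' @return Character vector of written files, invisibly.
#' @export
write_parameter_map <- function(map, prefix) {
  stopifnot(inherits(map, "parameter_map"))
  V <- nrow(map)
  side <- ceiling(sqrt(V))
  files <- character()
  for (p in c("f_p", "D_p", "D_t")) {
    vol <- array(NA_real_, dim = c(side, side, 1))
    vol[seq_len(V)] <- map[[p]]
    path <- paste0(prefix, "_", p, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(vol), path)
    files <- c(files, path)
  }
  csv <- paste0(prefix, "_voxels.csv")
  utils::write.csv(as.data.frame(map), csv, row.names = FALSE)
  invisible(c(files, csv))
}
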