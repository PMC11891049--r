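#' Published cohort reference tables
#'
#' Per-site, per-class summary statistics of the three-site breast-lesion
#' cohort that the synthetic generator emulates: lesion counts and ROI voxel
#' counts (mean +/- SD), and ROI-mean IVIM parameter distributions
#' (mean +/- SD across patients) as estimated by the reference segmented
#' least-squares package ("software a"). `f_p` is stored as a fraction
#' (converted from percent); diffusivities in mm^2/s (converted from
#' 10^-3 mm^2/s).
#'
#' @return A list with data frames `lesions` (site, label, n_patients,
#'   roi_voxels_mean, roi_voxels_sd) and `ivim` (site, label, parameter,
#'   mean, sd in internal units).
#' @export
cohort_reference_tables <- function() {
  lesions <- data.frame(
    site = rep(c("A", "B", "C"), each = 2),
    label = rep(c("benign", "malignant"), times = 3),
    n_patients = c(12L, 46L, 70L, 19L, 38L, 117L),
    roi_voxels_mean = c(201, 1363, 51, 34, 33, 56),
    roi_voxels_sd = c(143, 1644, 101, 28, 40, 69),
    stringsAsFactors = FALSE
  )
  # ROI-mean parameter distributions, software-a columns.
  # f_p in %, D in 1e-3 mm^2/s as published; converted below.
  raw <- rbind(
    data.frame(site = "A", label = "benign",    f_p = 15.79, f_p_sd = 9.87,
               D_p = 10.57, D_p_sd = 3.83, D_t = 1.26, D_t_sd = 0.29),
    data.frame(site = "A", label = "malignant", f_p = 13.85, f_p_sd = 5.02,
               D_p = 12.02, D_p_sd = 3.12, D_t = 1.20, D_t_sd = 0.39),
    data.frame(site = "B", label = "benign",    f_p = 18.62, f_p_sd = 7.49,
               D_p = 6.07,  D_p_sd = 2.34, D_t = 1.04, D_t_sd = 0.33),
    data.frame(site = "B", label = "malignant", f_p = 20.66, f_p_sd = 7.15,
               D_p = 7.06,  D_p_sd = 2.02, D_t = 0.88, D_t_sd = 0.29),
    data.frame(site = "C", label = "benign",    f_p = 12.77, f_p_sd = 6.95,
               D_p = 18.02, D_p_sd = 8.47, D_t = 1.36, D_t_sd = 0.40),
    data.frame(site = "C", label = "malignant", f_p = 11.41, f_p_sd = 4.91,
               D_p = 16.23, D_p_sd = 5.94, D_t = 0.93, D_t_sd = 0.29)
  )
  ivim <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    data.frame(
      site = r$site, label = r$label,
      parameter = c("f_p", "D_p", "D_t"),
      mean = c(r$f_p / 100, r$D_p * 1e-3, r$D_t * 1e-3),
      sd = c(r$f_p_sd / 100, r$D_p_sd * 1e-3, r$D_t_sd * 1e-3),
      stringsAsFactors = FALSE
    )
  }))
  rownames(ivim) <- NULL
  list(lesions = lesions, ivim = ivim)
}

# Physiological truncation ranges for ground-truth parameters.
truth_ranges <- function() {
  list(f_p = c(0, 1), D_p = c(0, 0.1), D_t = c(0, 0.003))
}
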