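#' Synthetic cohort generator settings
#'
#' Defaults reproduce the composition of the three-site breast study: 58/89/155
#' patients at Sites A/B/C with 46/19/117 malignant lesions (one lesion per
#' patient), ROI sizes matched to the published mean +/- SD per site and class,
#' and ground-truth IVIM parameter distributions drawn from the published
#' per-site, per-class ROI-mean statistics.
#'
#' @param counts Data frame with columns `site`, `label`, `n_patients`
#'   (defaults to the published cohort composition).
#' @param snr Signal-to-noise ratio at b = 0 (default 40, typical for breast
#'   DWI at 3 T).
#' @param variability Intra-lesion variability fraction: voxel values are
#'   `center * (1 + variability * z)` with independent standard-normal `z`
#'   per parameter (default 0.10).
#' @param s0 Unweighted signal amplitude assigned to every voxel (arbitrary
#'   units, default 100).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(counts = NULL, snr = 40, variability = 0.10,
                          s0 = 100) {
  if (is.null(counts)) counts <- cohort_reference_tables()$lesions[
    , c("site", "label", "n_patients")]
  stopifnot(all(c("site", "label", "n_patients") %in% names(counts)))
  if (any(counts$n_patients < 1L)) stop("patient counts must be >= 1")
  if (snr <= 0) stop("snr must be > 0")
  if (variability < 0) stop("variability must be >= 0")
  structure(list(counts = counts, snr = snr, variability = variability,
                 s0 = s0),
            class = "cohort_config")
}

# Truncated-normal draws by rejection; falls back to clamping if the
# acceptance region is pathologically small.
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  for (it in 1:1000) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
    if (!length(todo)) break
  }
  if (length(todo)) out[todo] <- pmin(pmax(mean, lower), upper)
  out
}

#' Draw one synthetic lesion
#'
#' Draws a patient-level parameter center `(f_p, D_p, D_t)` from a truncated
#' normal with the published per-(site, label) ROI-mean statistics (rejection
#' resampling enforces the physical ordering `D_p >= D_t`), then per-voxel
#' values `center * (1 + variability * z)` re-truncated to the physiological
#' ranges. The voxel count is lognormal, moment-matched to the published ROI
#' sizes for that site and class and floored at 3 voxels.
#'
#' @param site_tag Site, `"A"`, `"B"` or `"C"`.
#' @param label `"benign"` or `"malignant"`.
#' @param stream Optional RNG stream (see [rng_streams()]).
#' @param config A [cohort_config()].
#' @param scheme Optional [site_bvalue_scheme()] to attach; defaults to the
#'   site's variant 1.
#' @param patient_id Optional identifier string.
#' @return A list of class `lesion_spec` with fields `patient_id`, `site_tag`,
#'   `label`, `n_voxels`, `center`, `truth` (data frame of per-voxel
#'   parameters), `scheme`, `snr`.
#' @export
sample_lesion <- function(site_tag, label, stream = NULL,
                          config = cohort_config(), scheme = NULL,
                          patient_id = NA_character_) {
  if (is.null(stream)) return(.sample_lesion(site_tag, label, config, scheme,
                                             patient_id))
  with_rng_stream(stream, .sample_lesion(site_tag, label, config, scheme,
                                         patient_id))
}

.sample_lesion <- function(site_tag, label, config, scheme, patient_id) {
  tabs <- cohort_reference_tables()
  ivim <- tabs$ivim
  les <- tabs$lesions
  sel <- ivim$site == site_tag & ivim$label == label
  if (!any(sel)) stop("no reference entry for site ", site_tag,
                      ", label ", label)
  stat <- function(p) {
    r <- ivim[sel & ivim$parameter == p, ]
    c(mean = r$mean, sd = r$sd)
  }
  rng <- truth_ranges()
  fp <- stat("f_p"); dp <- stat("D_p"); dt <- stat("D_t")

  # patient-level center with D_p >= D_t by rejection
  for (it in 1:1000) {
    c_dp <- rtruncnorm1(1, dp["mean"], dp["sd"], rng$D_p[1], rng$D_p[2])
    c_dt <- rtruncnorm1(1, dt["mean"], dt["sd"], rng$D_t[1], rng$D_t[2])
    if (c_dp >= c_dt) break
  }
  if (c_dp < c_dt) c_dp <- c_dt
  c_fp <- rtruncnorm1(1, fp["mean"], fp["sd"], rng$f_p[1], rng$f_p[2])

  # lognormal voxel count moment-matched to the published ROI sizes
  lr <- les[les$site == site_tag & les$label == label, ]
  sdlog2 <- log(1 + (lr$roi_voxels_sd / lr$roi_voxels_mean)^2)
  meanlog <- log(lr$roi_voxels_mean) - sdlog2 / 2
  n_vox <- max(3L, as.integer(round(stats::rlnorm(1, meanlog, sqrt(sdlog2)))))

  v <- config$variability
  perturb <- function(center, range) {
    if (v == 0) return(rep(center, n_vox))
    x <- center * (1 + v * stats::rnorm(n_vox))
    bad <- x < range[1] | x > range[2]
    for (it in 1:100) {
      if (!any(bad)) break
      x[bad] <- center * (1 + v * stats::rnorm(sum(bad)))
      bad <- x < range[1] | x > range[2]
    }
    pmin(pmax(x, range[1]), range[2])
  }
  t_fp <- perturb(c_fp, rng$f_p)
  t_dp <- perturb(c_dp, rng$D_p)
  t_dt <- perturb(c_dt, rng$D_t)
  swap <- t_dp < t_dt
  t_dp[swap] <- pmax(t_dp[swap], t_dt[swap])

  if (is.null(scheme)) scheme <- site_bvalue_scheme(site_tag, 1L)
  structure(list(
    patient_id = patient_id, site_tag = site_tag, label = label,
    n_voxels = n_vox,
    center = c(f_p = unname(c_fp), D_p = unname(c_dp), D_t = unname(c_dt)),
    truth = data.frame(f_p = t_fp, D_p = t_dp, D_t = t_dt, S0 = config$s0),
    scheme = scheme, snr = config$snr
  ), class = "lesion_spec")
}

# Largest-remainder apportionment of n patients over the Site A sub-scheme
# usage proportions; returns a variant index per patient.
apportion_variants <- function(n, weights = site_a_variant_counts()) {
  p <- weights / sum(weights)
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * p - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(seq_along(weights), times = base)
}

#' Generate a seeded multi-site synthetic cohort
#'
#' Builds the full synthetic study: per-patient lesion ground truth, a b-value
#' scheme per site (Site A sub-schemes apportioned by their published usage
#' counts), clean biexponential decays and Rician magnitude noise. The result
#' is a pure function of `(config, seed)`: every lesion draws from its own
#' counter-based RNG substream.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return An object of class `ivim_cohort`: list with `patients` (data frame:
#'   patient_id, site, label, variant, n_voxels, snr), `lesions` (list of
#'   `lesion_spec`), `signals` (list of n_voxels x n_b noisy magnitude
#'   matrices), `config`, `seed`.
#' @examples
#' coh <- generate_cohort(cohort_config(data.frame(
#'   site = c("A", "A"), label = c("benign", "malignant"),
#'   n_patients = c(1L, 1L))), seed = 1)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  counts <- config$counts
  plan <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(site = counts$site[i], label = counts$label[i],
               idx = seq_len(counts$n_patients[i]), stringsAsFactors = FALSE)
  }))
  # fixed enumeration: by site, label, index (independent of iteration order)
  plan <- plan[order(plan$site, plan$label, plan$idx), , drop = FALSE]
  n <- nrow(plan)
  plan$patient_id <- sprintf("%s-%s-%03d", plan$site,
                             substr(plan$label, 1, 1), plan$idx)

  # Site A variant apportionment across its patients (benign then malignant,
  # in enumeration order)
  plan$variant <- 1L
  a_rows <- which(plan$site == "A")
  if (length(a_rows)) plan$variant[a_rows] <- apportion_variants(length(a_rows))

  streams <- rng_streams(seed, 2L * n)
  lesions <- vector("list", n)
  signals <- vector("list", n)
  for (i in seq_len(n)) {
    scheme <- site_bvalue_scheme(plan$site[i], plan$variant[i])
    les <- sample_lesion(plan$site[i], plan$label[i], stream = streams[[i]],
                         config = config, scheme = scheme,
                         patient_id = plan$patient_id[i])
    clean <- vapply(scheme$b_values, function(b)
      ivim_signal(list(f_p = les$truth$f_p, D_p = les$truth$D_p,
                       D_t = les$truth$D_t, S0 = les$truth$S0), b),
      numeric(les$n_voxels))
    clean <- matrix(clean, nrow = les$n_voxels)
    noisy <- with_rng_stream(streams[[n + i]], {
      sigma <- config$s0 / config$snr
      n1 <- matrix(stats::rnorm(length(clean), 0, sigma), nrow = nrow(clean))
      n2 <- matrix(stats::rnorm(length(clean), 0, sigma), nrow = nrow(clean))
      sqrt((clean + n1)^2 + n2^2)
    })
    colnames(noisy) <- paste0("b", scheme$b_values)
    lesions[[i]] <- les
    signals[[i]] <- noisy
  }
  patients <- data.frame(
    patient_id = plan$patient_id, site = plan$site, label = plan$label,
    variant = plan$variant,
    n_voxels = vapply(lesions, function(l) l$n_voxels, integer(1)),
    snr = config$snr, stringsAsFactors = FALSE
  )
  structure(list(patients = patients, lesions = lesions, signals = signals,
                 config = config, seed = as.integer(seed)),
            class = "ivim_cohort")
}

#' @export
print.ivim_cohort <- function(x, ...) {
  tab <- table(x$patients$site, x$patients$label)
  cat(sprintf("<ivim_cohort> %d patients, seed %d, SNR %g\n",
              nrow(x$patients), x$seed, x$config$snr))
  print(tab)
  invisible(x)
}
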