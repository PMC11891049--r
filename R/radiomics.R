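#' Fixed-range histogram specification
#'
#' The shared histogram module: 100 equal-width bins over a fixed,
#' parameter-specific range (`f_p` 0-1, `D_p` 0-0.1 mm^2/s, `D_t` 0-0.003
#' mm^2/s). Values outside the range are excluded and counted as unused, so
#' feature extraction is identical for every fitting method.
#'
#' @param parameter `"f_p"`, `"D_p"` or `"D_t"` (fills in the default range),
#'   or `NULL` to give `range_min`/`range_max` explicitly.
#' @param range_min,range_max Histogram range in parameter units.
#' @param n_bins Number of equal-width bins (default 100).
#' @return A list of class `histogram_spec`.
#' @export
histogram_spec <- function(parameter = NULL, range_min = NULL,
                           range_max = NULL, n_bins = 100L) {
  if (!is.null(parameter)) {
    parameter <- match.arg(parameter, c("f_p", "D_p", "D_t"))
    r <- histogram_ranges()[[parameter]]
    if (is.null(range_min)) range_min <- r[1]
    if (is.null(range_max)) range_max <- r[2]
  }
  if (is.null(range_min) || is.null(range_max) || range_max <= range_min) {
    stop("need range_max > range_min")
  }
  if (n_bins < 1) stop("n_bins must be >= 1")
  structure(list(parameter = parameter, range_min = range_min,
                 range_max = range_max, n_bins = as.integer(n_bins)),
            class = "histogram_spec")
}

#' Build a fixed-range histogram
#'
#' Bins are half-open `[edge_i, edge_{i+1})` with the last bin closed at
#' `range_max`. Values outside `[range_min, range_max]` (and non-finite
#' values) are excluded and reported in `n_excluded`.
#'
#' @param values Numeric vector.
#' @param spec A [histogram_spec()].
#' @return List of class `ivim_histogram`: `counts`, `bin_centers`,
#'   `bin_width`, `n_used`, `n_excluded`, `n_total`, `spec`.
#' @export
build_histogram <- function(values, spec) {
  stopifnot(inherits(spec, "histogram_spec"))
  values <- as.numeric(values)
  n_total <- length(values)
  finite <- is.finite(values)
  inr <- finite & values >= spec$range_min & values <= spec$range_max
  used <- values[inr]
  width <- (spec$range_max - spec$range_min) / spec$n_bins
  idx <- pmin(floor((used - spec$range_min) / width), spec$n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = spec$n_bins)
  centers <- spec$range_min + (seq_len(spec$n_bins) - 0.5) * width
  structure(list(counts = counts, bin_centers = centers, bin_width = width,
                 n_used = length(used), n_excluded = n_total - length(used),
                 n_total = n_total, spec = spec),
            class = "ivim_histogram")
}

#' First-order features of a binned parameter distribution
#'
#' Computes minimum, maximum, mean, variance, skewness and kurtosis from the
#' binned representation (bin centers weighted by counts), honoring the fixed
#' shared histogram module. Moments are population moments (count-weighted;
#' no n-1 correction, which is ill-defined under binning); kurtosis is
#' non-excess (`m4/m2^2`) by default.
#'
#' @param hist An [build_histogram()] result (or `values` plus `spec`).
#' @param excess If `TRUE` report excess kurtosis (`m4/m2^2 - 3`).
#' @return A one-row data frame: `minimum`, `maximum`, `mean`, `variance`,
#'   `skewness`, `kurtosis`, `utilization`, `n_used`, `flag`
#'   (`"ok"`, `"degenerate"` when the binned variance is zero, `"empty"` when
#'   no voxel fell inside the range).
#' @export
first_order_features <- function(hist, excess = FALSE) {
  stopifnot(inherits(hist, "ivim_histogram"))
  n_used <- hist$n_used
  util <- if (hist$n_total > 0) n_used / hist$n_total else NA_real_
  if (n_used == 0L) {
    return(data.frame(minimum = NA_real_, maximum = NA_real_, mean = NA_real_,
                      variance = NA_real_, skewness = NA_real_,
                      kurtosis = NA_real_, utilization = util, n_used = 0L,
                      flag = "empty", stringsAsFactors = FALSE))
  }
  cnt <- hist$counts
  ctr <- hist$bin_centers
  occ <- which(cnt > 0)
  m <- sum(cnt * ctr) / n_used
  m2 <- sum(cnt * (ctr - m)^2) / n_used
  if (m2 > 0) {
    m3 <- sum(cnt * (ctr - m)^3) / n_used
    m4 <- sum(cnt * (ctr - m)^4) / n_used
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - if (excess) 3 else 0
    flag <- "ok"
  } else {
    skew <- 0
    kurt <- 0
    flag <- "degenerate"
  }
  data.frame(minimum = ctr[occ[1]], maximum = ctr[occ[length(occ)]],
             mean = m, variance = m2, skewness = skew, kurtosis = kurt,
             utilization = util, n_used = n_used, flag = flag,
             stringsAsFactors = FALSE)
}

#' First-order features of a fitted parameter map
#'
#' For each IVIM parameter, filters the map's voxels by that parameter's
#' validity flag and histogram range (exclusion is per parameter: a voxel can
#' contribute to `D_t` but not to `D_p`), builds the fixed-range histogram
#' and extracts the first-order features.
#'
#' @param map A `parameter_map` from [fit_roi()].
#' @param excess Passed to [first_order_features()].
#' @return A data frame with one row per parameter (`parameter` column plus
#'   the feature columns).
#' @export
features_for_map <- function(map, excess = FALSE) {
  stopifnot(inherits(map, "parameter_map"))
  out <- lapply(c("f_p", "D_p", "D_t"), function(p) {
    flag <- map[[paste0("in_range_", p)]]
    vals <- map[[p]]
    vals[!flag | is.na(flag)] <- NA_real_
    h <- build_histogram(vals, histogram_spec(p))
    cbind(parameter = p, first_order_features(h, excess = excess),
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# The 16 reported metrics (minimum only for D_t, mirroring the reported
# feature set).
reported_metrics <- function() {
  c("D_t_min", "D_t_max", "D_t_mean", "D_t_variance", "D_t_skew", "D_t_kurt",
    "f_p_max", "f_p_mean", "f_p_variance", "f_p_skew", "f_p_kurt",
    "D_p_max", "D_p_mean", "D_p_variance", "D_p_skew", "D_p_kurt")
}

#' Build the tidy per-patient feature table
#'
#' Runs [features_for_map()] for every (patient, method) parameter map and
#' returns the long feature table used by the agreement and diagnostic
#' stages: one row per (patient, method, metric).
#'
#' @param cohort An `ivim_cohort`.
#' @param maps Named list (one element per method tag) of lists of
#'   `parameter_map`s, one per patient, in cohort order.
#' @param metrics Metric names to keep (default [reported_metrics()]).
#' @return Data frame of class `feature_table` with columns `patient_id`,
#'   `site`, `label`, `method`, `metric`, `value`, plus a `utilization`
#'   attribute table (patient, method, parameter, utilization).
#' @export
feature_table <- function(cohort, maps, metrics = reported_metrics()) {
  stopifnot(inherits(cohort, "ivim_cohort"))
  pts <- cohort$patients
  rows <- list()
  util <- list()
  feat_name <- c(minimum = "min", maximum = "max", mean = "mean",
                 variance = "variance", skewness = "skew", kurtosis = "kurt")
  for (m in names(maps)) {
    stopifnot(length(maps[[m]]) == nrow(pts))
    for (i in seq_len(nrow(pts))) {
      ff <- features_for_map(maps[[m]][[i]])
      util[[length(util) + 1L]] <- data.frame(
        patient_id = pts$patient_id[i], method = m,
        parameter = ff$parameter, utilization = ff$utilization,
        stringsAsFactors = FALSE)
      metric <- as.vector(t(outer(ff$parameter, feat_name,
                                  function(p, f) paste0(p, "_", f))))
      value <- as.vector(t(as.matrix(ff[, names(feat_name)])))
      keep <- metric %in% metrics
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pts$patient_id[i], site = pts$site[i],
        label = pts$label[i], method = m, metric = metric[keep],
        value = value[keep], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "utilization") <- do.call(rbind, util)
  class(out) <- c("feature_table", class(out))
  out
}
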