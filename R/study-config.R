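#' End-to-end study configuration
#'
#' Bundles every tunable of the pipeline: cohort generator settings, fitter
#' settings, histogram bin count, statistics toggles and the output
#' directory. Serializable to/from JSON and YAML; unknown keys are rejected.
#'
#' @param cohort List of [cohort_config()] arguments (`counts`, `snr`,
#'   `variability`, `s0`).
#' @param fit List: `b_threshold` (s/mm^2), `dp_init`, `bayes_grid`
#'   (nodes per axis for the cohort-scale Bayesian grid), `methods`
#'   (the three software stand-ins).
#' @param histogram List: `n_bins`.
#' @param statistics List: `shared_slope`, `lou`.
#' @param seed Master seed.
#' @param out_dir Output directory for [run_study()].
#' @return List of class `study_config`.
#' @export
study_config <- function(cohort = list(), fit = list(), histogram = list(),
                         statistics = list(), seed = 1L,
                         out_dir = "ivim-study") {
  defaults <- list(
    cohort = list(counts = NULL, snr = 40, variability = 0.10, s0 = 100),
    fit = list(b_threshold = 200, dp_init = 0.01, bayes_grid = 32L,
               methods = c("seg_a", "seg_b", "bayes")),
    histogram = list(n_bins = 100L),
    statistics = list(shared_slope = FALSE, lou = TRUE),
    seed = 1L, out_dir = "ivim-study"
  )
  merge_cfg <- function(def, user, path) {
    extra <- setdiff(names(user), names(def))
    if (length(extra)) stop("unknown config key(s) in ", path, ": ",
                            paste(extra, collapse = ", "))
    def[names(user)] <- user
    def
  }
  cfg <- defaults
  cfg$cohort <- merge_cfg(defaults$cohort, cohort, "cohort")
  cfg$fit <- merge_cfg(defaults$fit, fit, "fit")
  cfg$histogram <- merge_cfg(defaults$histogram, histogram, "histogram")
  cfg$statistics <- merge_cfg(defaults$statistics, statistics, "statistics")
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  class(cfg) <- "study_config"
  cfg
}

#' Read/write a study configuration (JSON or YAML)
#'
#' @param path File path; format chosen from the extension (`.json`, `.yaml`
#'   or `.yml`).
#' @param config A [study_config()] (for writing).
#' @return `read_study_config()` returns a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$cohort$counts) && !is.data.frame(raw$cohort$counts)) {
    raw$cohort$counts <- as.data.frame(raw$cohort$counts)
  }
  study_config(cohort = raw$cohort %||% list(),
               fit = raw$fit %||% list(),
               histogram = raw$histogram %||% list(),
               statistics = raw$statistics %||% list(),
               seed = raw$seed %||% 1L,
               out_dir = raw$out_dir %||% "ivim-study")
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
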