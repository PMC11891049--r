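#' Pearson correlation with validity checks
#'
#' Product-moment correlation between two paired vectors; pairs with missing
#' values are dropped. Returns `NA` (with a warning) when fewer than 3
#' complete pairs remain or either side has zero variance, so that undefined
#' cells can be excluded from averaging rather than imputed.
#'
#' @param x,y Paired numeric vectors.
#' @return Scalar correlation in \[-1,1\], or `NA`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    warning("pearson_r: fewer than 3 complete pairs; returning NA")
    return(NA_real_)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson_r: zero variance; returning NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Mean and coefficient of variation
#'
#' @param values Numeric vector (length >= 2); `NA`s are dropped.
#' @return List with `mean` and `cv_pct` = 100 * sample SD (n-1) / mean
#'   (`NA` with a warning when the mean is zero).
#' @export
average_and_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) {
    warning("average_and_cv: mean is zero; CV undefined")
    return(list(mean = m, cv_pct = NA_real_))
  }
  list(mean = m, cv_pct = 100 * stats::sd(values) / m)
}

#' Two-way random-effects absolute-agreement ICC, single measurement
#'
#' ICC(2,1): `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`,
#' where `MS_R`, `MS_C`, `MS_E` are the rows (subjects), columns (raters)
#' and error mean squares of the two-way ANOVA decomposition. Absolute
#' agreement penalizes systematic offsets between raters, matching the
#' question of whether three software packages deliver interchangeable
#' values.
#'
#' @param mat Numeric matrix, subjects x raters (>= 5 complete rows,
#'   >= 2 columns; rows with missing cells are dropped).
#' @return Scalar ICC, or `NA` when the decomposition is singular.
#' @export
icc_absolute_agreement <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 5L) stop("need at least 5 complete subjects")
  grand <- mean(mat)
  rowm <- rowMeans(mat)
  colm <- colMeans(mat)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (!is.finite(denom) || denom <= 0) {
    warning("icc_absolute_agreement: singular decomposition")
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Bland-Altman method-comparison summary
#'
#' Differences `d_i = x_i - y_i` summarized as the mean and SD (n-1) of the
#' absolute differences, and a within-subject coefficient of variation
#' `100 * (SD(d)/sqrt(2)) / mean(all 2n measurements)`. The classic signed
#' bias and 95% limits of agreement (`mean(d) +/- 1.96 SD(d)`) are included
#' for plotting. An alternative CV based on the mean absolute difference is
#' reported alongside (`cv_meanabs_pct`).
#'
#' @param x,y Paired measurements (length >= 3; incomplete pairs dropped).
#' @return List: `mean_abs_diff`, `sd_abs_diff`, `cv_pct`, `cv_meanabs_pct`,
#'   `bias`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  d <- x - y
  grand <- mean(c(x, y))
  sd_d <- stats::sd(d)
  cv <- if (grand > 0) 100 * (sd_d / sqrt(2)) / grand else {
    warning("bland_altman: non-positive grand mean; CV undefined")
    NA_real_
  }
  cv2 <- if (grand > 0) 100 * mean(abs(d)) / grand else NA_real_
  list(mean_abs_diff = mean(abs(d)), sd_abs_diff = stats::sd(abs(d)),
       cv_pct = cv, cv_meanabs_pct = cv2, bias = mean(d),
       loa_lower = mean(d) - 1.96 * sd_d, loa_upper = mean(d) + 1.96 * sd_d,
       n = length(x))
}

#' Cross-software agreement study
#'
#' For every metric, computes the Pearson correlation and Bland-Altman
#' summary for each software pair within each site (never pooling across
#' sites), the three-rater ICC(2,1) per site, and per-metric averages: mean
#' correlation over all (pair, site) cells and its coefficient of variation.
#' Metrics are ranked by mean correlation. Cells with fewer than 3 patients
#' or zero variance are skipped with a warning and excluded from averages.
#'
#' @param ft A [feature_table()].
#' @return List of class `agreement_summary`: `pairs` (per pair x site x
#'   metric records), `icc` (site x metric), `summary` (per metric: `mean_r`,
#'   `cv_r_pct`, `n_cells`, `rank`).
#' @export
agreement_study <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  methods <- sort(unique(ft$method))
  if (length(methods) < 2L) stop("need at least 2 methods")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  sites <- sort(unique(ft$site))
  metrics <- unique(ft$metric)

  wide <- function(metric, site) {
    sub <- ft[ft$metric == metric & ft$site == site, ]
    stats::reshape(sub[, c("patient_id", "method", "value")],
                   idvar = "patient_id", timevar = "method",
                   direction = "wide")
  }

  pair_rows <- list()
  icc_rows <- list()
  for (metric in metrics) {
    for (site in sites) {
      w <- wide(metric, site)
      cols <- paste0("value.", methods)
      for (pr in pairs) {
        x <- w[[paste0("value.", pr[1])]]
        y <- w[[paste0("value.", pr[2])]]
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3L) {
          warning("agreement_study: skipping ", metric, " at site ", site,
                  " pair ", paste(pr, collapse = "-"), " (<3 patients)")
          next
        }
        r <- suppressWarnings(pearson_r(x[ok], y[ok]))
        ba <- bland_altman(x[ok], y[ok])
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          metric = metric, site = site, pair = paste(pr, collapse = "-"),
          n = sum(ok), r = r, ba_mean_abs_diff = ba$mean_abs_diff,
          ba_sd_abs_diff = ba$sd_abs_diff, ba_cv_pct = ba$cv_pct,
          bias = ba$bias, stringsAsFactors = FALSE)
      }
      mat <- as.matrix(w[, cols, drop = FALSE])
      icc <- tryCatch(suppressWarnings(icc_absolute_agreement(mat)),
                      error = function(e) NA_real_)
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        metric = metric, site = site, icc = icc, n = nrow(mat),
        stringsAsFactors = FALSE)
    }
  }
  pair_df <- do.call(rbind, pair_rows)
  icc_df <- do.call(rbind, icc_rows)

  summ <- do.call(rbind, lapply(metrics, function(metric) {
    rs <- pair_df$r[pair_df$metric == metric]
    rs <- rs[is.finite(rs)]
    if (length(rs) >= 2L) {
      ac <- average_and_cv(rs)
      data.frame(metric = metric, mean_r = ac$mean, cv_r_pct = ac$cv_pct,
                 n_cells = length(rs), stringsAsFactors = FALSE)
    } else {
      data.frame(metric = metric, mean_r = NA_real_, cv_r_pct = NA_real_,
                 n_cells = length(rs), stringsAsFactors = FALSE)
    }
  }))
  summ <- summ[order(-summ$mean_r), ]
  summ$rank <- seq_len(nrow(summ))
  rownames(summ) <- NULL
  structure(list(pairs = pair_df, icc = icc_df, summary = summ),
            class = "agreement_summary")
}
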