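#' Site-adjusted logistic regression for malignancy
#'
#' Maximum-likelihood logistic fit of
#' `logit P(malignant) = alpha_site + beta_site * x`, i.e. a site-specific
#' intercept and slope per site (full interaction), which absorbs between-site
#' differences in acquisition and cohort mix. The metric is z-scored over the
#' pooled sample before fitting. Complete separation is detected (diverging
#' coefficients or non-convergence of IRLS) and resolved by a
#' ridge-stabilized Newton solve (penalty 1e-4), which leaves predicted ranks
#' unchanged.
#'
#' @param scores Metric values, one per patient.
#' @param site_tags Site of each patient.
#' @param labels 0/1 (or `"benign"`/`"malignant"`) outcome per patient.
#' @param shared_slope If `TRUE`, fit one common slope with site-specific
#'   intercepts instead of the full interaction.
#' @param standardize Z-score `scores` before fitting (default `TRUE`).
#' @return Object of class `ivim_logit`: coefficients, design metadata,
#'   `converged`, `separation_flag`.
#' @export
fit_site_adjusted_logistic <- function(scores, site_tags, labels,
                                       shared_slope = FALSE,
                                       standardize = TRUE) {
  y <- as_binary_label(labels)
  stopifnot(length(scores) == length(y), length(site_tags) == length(y))
  if (length(unique(y)) < 2L) stop("need both classes present")
  if (sum(y == 0) < 2L || sum(y == 1) < 2L) {
    stop("need at least 2 patients per class")
  }
  center <- if (standardize) mean(scores) else 0
  scale <- if (standardize) stats::sd(scores) else 1
  if (!is.finite(scale) || scale == 0) scale <- 1
  x <- (scores - center) / scale
  site <- factor(site_tags)
  X <- logit_design(x, site, shared_slope)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  coefs <- fit$coefficients
  sep <- !fit$converged || any(!is.finite(coefs)) || any(abs(coefs) > 15)
  if (sep) coefs <- ridge_irls(X, y, lambda = 1e-4)
  structure(list(coefficients = coefs, sites = levels(site),
                 shared_slope = shared_slope, center = center, scale = scale,
                 converged = fit$converged, separation_flag = sep),
            class = "ivim_logit")
}

as_binary_label <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  l <- as.character(labels)
  stopifnot(all(l %in% c("benign", "malignant")))
  as.integer(l == "malignant")
}

logit_design <- function(x, site, shared_slope) {
  # one-hot site indicators built directly (model.matrix needs >= 2 levels)
  M <- vapply(levels(site), function(l) as.numeric(site == l),
              numeric(length(site)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  colnames(M) <- paste0("site", levels(site))
  if (shared_slope) {
    X <- cbind(M, x = x)
  } else {
    X <- cbind(M, M * x)
    colnames(X) <- c(colnames(M), paste0(colnames(M), ":x"))
  }
  X
}

# Newton iterations for the ridge-penalized logistic log-likelihood.
ridge_irls <- function(X, y, lambda = 1e-4, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * W) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * beta
    beta <- beta + solve(H, g)
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1p(exp(eta))) - lambda * sum(beta^2) / 2
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  stats::setNames(drop(beta), colnames(X))
}

#' Predicted malignancy probabilities
#'
#' Inverse-logit of the fitted linear predictor; within one site this is a
#' strictly monotone transform of the metric whenever that site's slope is
#' nonzero.
#'
#' @param model An `ivim_logit` fit.
#' @param scores,site_tags New data (raw metric scale; the training
#'   standardization constants are applied).
#' @return Probabilities in (0,1).
#' @export
predict_prob <- function(model, scores, site_tags) {
  stopifnot(inherits(model, "ivim_logit"))
  site_tags <- as.character(site_tags)
  unseen <- setdiff(unique(site_tags), model$sites)
  if (length(unseen)) stop("unseen site tag(s): ", paste(unseen, collapse = ", "))
  x <- (scores - model$center) / model$scale
  site <- factor(site_tags, levels = model$sites)
  X <- logit_design(x, site, model$shared_slope)
  stats::plogis(drop(X %*% model$coefficients[colnames(X)]))
}

# DeLong structural components: placements of positives against negatives.
delong_components <- function(scores, labels) {
  y <- as_binary_label(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) stop("need both classes present")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- sum(v10) / m
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong standard error
#'
#' Area under the ROC curve as the Mann-Whitney statistic (ties weighted
#' 1/2), with the nonparametric DeLong variance
#' `S10/m + S01/n` computed from the structural components.
#'
#' @param scores Continuous classifier scores.
#' @param labels 0/1 or benign/malignant labels (malignant = positive).
#' @param kind Label for the estimate (`"apparent"` or `"lou"`).
#' @return List of class `auc_result`: `auc`, `se`, `kind`, `m`, `n`.
#' @export
auc_delong <- function(scores, labels, kind = "apparent") {
  cmp <- delong_components(scores, labels)
  s10 <- if (cmp$m > 1) stats::var(cmp$v10) else 0
  s01 <- if (cmp$n > 1) stats::var(cmp$v01) else 0
  structure(list(auc = cmp$auc, se = sqrt(s10 / cmp$m + s01 / cmp$n),
                 kind = kind, m = cmp$m, n = cmp$n),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC (%s) = %.4f (SE %.4f); %d positives / %d negatives\n",
              x$kind, x$auc, x$se, x$m, x$n))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided z-test on the AUC difference of two score sets evaluated on the
#' same patients, using the paired DeLong covariance of the structural
#' components.
#'
#' @param scores_1,scores_2 Score vectors over the same patients.
#' @param labels Shared labels.
#' @return List: `auc_1`, `auc_2`, `z`, `p`, `degenerate` (`TRUE` when the
#'   difference has zero variance, in which case `p = 1`).
#' @export
delong_paired_test <- function(scores_1, scores_2, labels) {
  stopifnot(length(scores_1) == length(scores_2))
  c1 <- delong_components(scores_1, labels)
  c2 <- delong_components(scores_2, labels)
  m <- c1$m; n <- c1$n
  s10 <- stats::var(cbind(c1$v10, c2$v10))
  s01 <- stats::var(cbind(c1$v01, c2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(v) || v <= 1e-16) {
    return(list(auc_1 = c1$auc, auc_2 = c2$auc, z = 0, p = 1,
                degenerate = TRUE))
  }
  z <- (c1$auc - c2$auc) / sqrt(v)
  list(auc_1 = c1$auc, auc_2 = c2$auc, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Leave-one-patient-out cross-validated AUC
#'
#' For each patient, refits the site-adjusted logistic model on the remaining
#' patients and predicts the held-out probability; the pooled out-of-sample
#' probabilities are scored with [auc_delong()]. Standardization constants
#' from the full sample are reused across folds. A fold whose training set
#' loses a class entirely is flagged and that patient's prediction is the
#' training prevalence.
#'
#' @inheritParams fit_site_adjusted_logistic
#' @return An `auc_result` (kind `"lou"`) with the out-of-sample
#'   probabilities in `$probs` and the number of degenerate folds in
#'   `$n_flagged_folds`.
#' @export
lou_cv_auc <- function(scores, site_tags, labels, shared_slope = FALSE) {
  y <- as_binary_label(labels)
  n <- length(y)
  if (n < 10L) stop("need at least 10 patients for leave-one-out")
  center <- mean(scores); scale <- stats::sd(scores)
  if (!is.finite(scale) || scale == 0) scale <- 1
  probs <- numeric(n)
  flagged <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2L) {
      probs[i] <- mean(y[tr])
      flagged <- flagged + 1L
      next
    }
    fit <- fit_site_adjusted_logistic(
      (scores[tr] - center) / scale, site_tags[tr], y[tr],
      shared_slope = shared_slope, standardize = FALSE)
    probs[i] <- predict_prob(fit, (scores[i] - center) / scale, site_tags[i])
  }
  out <- auc_delong(probs, y, kind = "lou")
  out$probs <- probs
  out$n_flagged_folds <- flagged
  out
}

#' Diagnostic performance study
#'
#' For every metric and every method: apparent AUC(SE) from the site-adjusted
#' logistic model and leave-one-patient-out AUC(SE). Per metric: the mean of
#' the three methods' AUCs with its CV%, and all pairwise DeLong p-values on
#' the apparent predicted probabilities. Metrics are ranked by mean AUC,
#' separately for the apparent and cross-validated analyses. Patients whose
#' metric value is missing are dropped for that (metric, method) cell;
#' DeLong pairs use the patients common to both methods.
#'
#' @param ft A [feature_table()].
#' @param shared_slope Passed to the logistic fits.
#' @param lou Compute leave-one-out AUCs (default `TRUE`).
#' @return List of class `diagnostic_summary`: `auc` (metric x method rows
#'   with AUC/SE/LOU columns), `summary` (per metric: mean/CV, apparent and
#'   LOU, with ranks), `delong` (pairwise p-values).
#' @export
diagnostic_study <- function(ft, shared_slope = FALSE, lou = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  methods <- sort(unique(ft$method))
  metrics <- unique(ft$metric)
  auc_rows <- list()
  delong_rows <- list()
  probs_store <- list()
  for (metric in metrics) {
    for (m in methods) {
      sub <- ft[ft$metric == metric & ft$method == m, ]
      ok <- is.finite(sub$value)
      sub <- sub[ok, ]
      fit <- fit_site_adjusted_logistic(sub$value, sub$site, sub$label,
                                        shared_slope = shared_slope)
      p_hat <- predict_prob(fit, sub$value, sub$site)
      ap <- auc_delong(p_hat, sub$label)
      lo <- if (lou) lou_cv_auc(sub$value, sub$site, sub$label,
                                shared_slope = shared_slope) else NULL
      auc_rows[[length(auc_rows) + 1L]] <- data.frame(
        metric = metric, method = m, n = nrow(sub),
        auc = ap$auc, se = ap$se,
        lou_auc = if (lou) lo$auc else NA_real_,
        lou_se = if (lou) lo$se else NA_real_,
        separation = fit$separation_flag, stringsAsFactors = FALSE)
      probs_store[[paste(metric, m, sep = "|")]] <-
        stats::setNames(p_hat, sub$patient_id)
    }
    for (pr in utils::combn(methods, 2, simplify = FALSE)) {
      p1 <- probs_store[[paste(metric, pr[1], sep = "|")]]
      p2 <- probs_store[[paste(metric, pr[2], sep = "|")]]
      common <- intersect(names(p1), names(p2))
      lab <- ft$label[match(common, ft$patient_id)]
      dl <- delong_paired_test(p1[common], p2[common], lab)
      delong_rows[[length(delong_rows) + 1L]] <- data.frame(
        metric = metric, pair = paste(pr, collapse = "-"),
        auc_1 = dl$auc_1, auc_2 = dl$auc_2, z = dl$z, p = dl$p,
        stringsAsFactors = FALSE)
    }
  }
  auc_df <- do.call(rbind, auc_rows)
  delong_df <- do.call(rbind, delong_rows)
  summ <- do.call(rbind, lapply(metrics, function(metric) {
    a <- auc_df[auc_df$metric == metric, ]
    ap <- average_and_cv(a$auc)
    lo <- if (lou) average_and_cv(a$lou_auc) else list(mean = NA, cv_pct = NA)
    data.frame(metric = metric, mean_auc = ap$mean, cv_auc_pct = ap$cv_pct,
               mean_lou_auc = lo$mean, cv_lou_auc_pct = lo$cv_pct,
               stringsAsFactors = FALSE)
  }))
  summ$rank_apparent <- rank(-summ$mean_auc, ties.method = "first")
  summ$rank_lou <- if (lou) rank(-summ$mean_lou_auc, ties.method = "first")
                   else NA_integer_
  summ <- summ[order(summ$rank_apparent), ]
  rownames(summ) <- NULL
  structure(list(auc = auc_df, summary = summ, delong = delong_df),
            class = "diagnostic_summary")
}
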