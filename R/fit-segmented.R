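#' One voxel's diffusion decay
#'
#' @param signals Positive magnitudes, one per b-value of `scheme`.
#' @param scheme A [site_bvalue_scheme()] object.
#' @return A list of class `voxel_decay`.
#' @export
voxel_decay <- function(signals, scheme) {
  assert_scheme(scheme)
  signals <- as.numeric(signals)
  if (length(signals) != length(scheme$b_values)) {
    stop("signals length (", length(signals), ") does not match scheme length (",
         length(scheme$b_values), ")")
  }
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    stop("signals must be finite and strictly positive")
  }
  structure(list(signals = signals, scheme = scheme), class = "voxel_decay")
}

# Fit/report bounds. Fit bounds are deliberately wider than the histogram
# ranges so that out-of-range voxels can occur.
fit_bounds <- function() {
  list(f_p = c(0, 1), D_p = c(0, 0.3), D_t = c(0, 0.01))
}

histogram_ranges <- function() {
  list(f_p = c(0, 1), D_p = c(0, 0.1), D_t = c(0, 0.003))
}

#' Log-linear monoexponential fit of the high-b regime
#'
#' Ordinary least squares of `log(S)` on `b`, restricted to `b >= b_threshold`
#' (above the pseudo-diffusion regime). This is Step 1 of segmented IVIM
#' fitting: the slope gives the tissue diffusivity and the back-extrapolated
#' intercept, as a fraction of the measured b = 0 signal, carries the
#' perfusion fraction.
#'
#' @param decay A [voxel_decay()] object.
#' @param b_threshold Threshold in s/mm^2 (default 200); points with
#'   `b >= b_threshold` enter the fit.
#' @return List with `D_t` (= -slope, mm^2/s), `intercept_fraction`
#'   (= exp(intercept)/S(b=0)), `n_high` (points used).
#' @export
fit_monoexp_loglinear <- function(decay, b_threshold = 200) {
  stopifnot(inherits(decay, "voxel_decay"))
  r <- monoexp_block(matrix(decay$signals, nrow = 1),
                     decay$scheme$b_values, b_threshold)
  list(D_t = r$D_t[1], intercept_fraction = r$intercept_fraction[1],
       n_high = r$n_high)
}

# Vectorized Step 1 for a voxel block (rows = voxels).
monoexp_block <- function(Y, b, b_threshold) {
  hi <- which(b >= b_threshold)
  if (length(hi) < 2L) {
    stop("scheme [", paste(b, collapse = ","), "] has fewer than 2 b-values >= ",
         b_threshold, " s/mm^2; cannot fit the monoexponential step")
  }
  s0 <- Y[, 1]
  Yh <- pmax(Y[, hi, drop = FALSE], 1e-6 * s0)
  L <- log(Yh)
  x <- b[hi]
  xc <- x - mean(x)
  denom <- sum(xc^2)
  ybar <- rowMeans(L)
  slope <- as.vector((L - ybar) %*% xc) / denom
  intercept <- ybar - slope * mean(x)
  list(D_t = -slope, intercept_fraction = exp(intercept) / s0,
       n_high = length(hi))
}

# Vectorized golden-section minimization over one bounded scalar per voxel.
# Fixed iteration count makes the result a deterministic function of the
# objective alone (identical for any block size).
gss_min_vec <- function(fn, lower, upper, n, iters = 60L) {
  inv_phi <- (sqrt(5) - 1) / 2
  a <- rep(lower, n); b <- rep(upper, n)
  for (it in seq_len(iters)) {
    h <- b - a
    c1 <- b - inv_phi * h
    d1 <- a + inv_phi * h
    left <- fn(c1) < fn(d1)
    b <- ifelse(left, d1, b)
    a <- ifelse(left, a, c1)
  }
  (a + b) / 2
}

# Vectorized segmented fit for a voxel block sharing one scheme.
# Returns a list of numeric vectors (one entry per voxel).
seg_fit_block <- function(Y, b, variant, b_threshold = 200, dp_init = 0.01) {
  V <- nrow(Y)
  bounds <- fit_bounds()
  s0 <- Y[, 1]
  Yn <- Y / s0

  step1 <- monoexp_block(Y, b, b_threshold)
  D_t <- pmin(pmax(step1$D_t, bounds$D_t[1]), bounds$D_t[2])
  f_p <- pmin(pmax(1 - step1$intercept_fraction, 0), 1)

  Et <- exp(-outer(D_t, b))                      # V x n_b tissue term
  tissue <- (1 - f_p) * Et
  sse_at <- function(dp_vec) {
    r <- Yn - (f_p * exp(-outer(dp_vec, b)) + tissue)
    rowSums(r * r)
  }

  converged <- rep(TRUE, V)
  dp_at_bound <- rep(FALSE, V)
  if (variant == "seg_a") {
    D_p <- gss_min_vec(sse_at, bounds$D_p[1], bounds$D_p[2], V)
    # a pinned minimum converges to the upper endpoint; snap and flag it
    pin <- D_p > bounds$D_p[2] * 0.995 &
      sse_at(rep(bounds$D_p[2], V)) <= sse_at(D_p)
    D_p[pin] <- bounds$D_p[2]
    dp_at_bound <- D_p >= bounds$D_p[2] * 0.995
    fixed <- f_p < 1e-6                          # D_p unidentifiable
    D_p[fixed] <- dp_init
    dp_at_bound[fixed] <- FALSE
  } else { # seg_b: joint (f_p, D_p) refinement per voxel, D_t frozen
    D_p <- numeric(V)
    for (v in seq_len(V)) {
      yv <- Yn[v, ]; etv <- Et[v, ]
      fn <- function(p) {
        r <- yv - (p[1] * exp(-b * p[2]) + (1 - p[1]) * etv)
        sum(r * r)
      }
      gr <- function(p) {
        ep <- exp(-b * p[2])
        r <- yv - (p[1] * ep + (1 - p[1]) * etv)
        c(-2 * sum(r * (ep - etv)), 2 * p[1] * sum(r * b * ep))
      }
      opt <- stats::optim(c(f_p[v], dp_init), fn, gr, method = "L-BFGS-B",
                          lower = c(bounds$f_p[1], bounds$D_p[1]),
                          upper = c(bounds$f_p[2], bounds$D_p[2]),
                          control = list(maxit = 200))
      f_p[v] <- opt$par[1]
      D_p[v] <- opt$par[2]
      converged[v] <- opt$convergence == 0L
    }
  }
  rss <- {
    r <- Yn - (f_p * exp(-outer(D_p, b)) + (1 - f_p) * Et)
    rowSums(r * r) * s0^2
  }
  list(f_p = f_p, D_p = D_p, D_t = D_t, S0 = s0, residual_norm = rss,
       converged = converged, dp_at_bound = dp_at_bound)
}

# Assemble fit rows with per-parameter validity flags against the histogram
# ranges (vectorized; `dp_at_bound` additionally invalidates D_p).
fit_result_frame <- function(method, f_p, D_p, D_t, S0, residual_norm,
                             converged, dp_at_bound = FALSE,
                             f_p_sd = NA_real_, D_p_sd = NA_real_,
                             D_t_sd = NA_real_) {
  hr <- histogram_ranges()
  n <- length(f_p)
  out <- data.frame(
    method = rep(method, n), f_p = f_p, D_p = D_p, D_t = D_t, S0 = S0,
    residual_norm = residual_norm, converged = converged,
    in_range_f_p = !is.na(f_p) & f_p >= hr$f_p[1] & f_p <= hr$f_p[2],
    in_range_D_p = !is.na(D_p) & D_p >= hr$D_p[1] & D_p <= hr$D_p[2] &
      !dp_at_bound,
    in_range_D_t = !is.na(D_t) & D_t >= hr$D_t[1] & D_t <= hr$D_t[2],
    f_p_sd = f_p_sd, D_p_sd = D_p_sd, D_t_sd = D_t_sd,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fit_result", class(out))
  out
}

fit_result_row <- fit_result_frame

#' Segmented least-squares IVIM fit
#'
#' Two-step estimation emulating the segmented least-squares software family.
#' Step 1 fits the high-b (`b >= b_threshold`) log-linear decay for `D_t` and
#' the back-extrapolated intercept; Step 2 sets `f_p = 1 - intercept_fraction`
#' (clipped to \[0,1\]). Step 3 differs between the two variants:
#' \describe{
#'   \item{`seg_a`}{1-D bounded least squares for `D_p` over all b-values with
#'     `f_p` and `D_t` frozen (golden-section search). Voxels whose fitted
#'     `D_p` hits the fit bound are flagged out of range for `D_p`: this
#'     variant rejects more pseudo-diffusion voxels, as its reference
#'     software family does.}
#'   \item{`seg_b`}{joint bounded refinement of `(f_p, D_p)` over all
#'     b-values with `D_t` frozen, initialized from Steps 1-2.}
#' }
#' Fit bounds are `f_p` \[0,1\], `D_p` \[0,0.3\] mm^2/s, `D_t` \[0,0.01\]
#' mm^2/s (wider than the histogram ranges, so out-of-range voxels occur).
#' With a vanishing perfusion fraction (`f_p < 1e-6` after Step 2) `D_p` is
#' unidentifiable and is reported at its initialization value.
#'
#' @param decay A [voxel_decay()] object.
#' @param variant `"seg_a"` or `"seg_b"`.
#' @param b_threshold Segmentation threshold, s/mm^2 (default 200).
#' @param dp_init Initialization for `D_p` (default 0.01 mm^2/s).
#' @return One-row data frame (class `fit_result`): `method`, `f_p`, `D_p`,
#'   `D_t`, `S0`, `residual_norm`, `converged`, per-parameter `in_range_*`
#'   flags.
#' @export
fit_segmented_lsq <- function(decay, variant = c("seg_a", "seg_b"),
                              b_threshold = 200, dp_init = 0.01) {
  variant <- match.arg(variant)
  stopifnot(inherits(decay, "voxel_decay"))
  r <- seg_fit_block(matrix(decay$signals, nrow = 1), decay$scheme$b_values,
                     variant, b_threshold, dp_init)
  fit_result_frame(variant, r$f_p, r$D_p, r$D_t, r$S0, r$residual_norm,
                   r$converged, dp_at_bound = r$dp_at_bound)
}
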