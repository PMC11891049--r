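#' Bayesian grid prior/posterior specification
#'
#' Defines the deterministic tensor grid on which the voxelwise posterior is
#' evaluated. Priors are uniform on the supports `f_p` in \[0,1\], `D_p` in
#' \[`dp_range`\], `D_t` in \[`dt_range`\] with the physical constraint
#' `D_p >= D_t`; `D_p` and `D_t` nodes are log-spaced (uniformity is restored
#' through trapezoidal quadrature weights), `f_p` nodes are linear. The
#' amplitude `S0` (flat prior) and the noise standard deviation (Jeffreys
#' prior) are marginalized analytically, so the grid covers only the three
#' decay parameters.
#'
#' @param n_f,n_dp,n_dt Nodes per axis (default 64 each).
#' @param dp_range Support of `D_p` in mm^2/s; the lower edge must be
#'   positive for log spacing (default `c(1e-3, 0.1)`).
#' @param dt_range Support of `D_t` in mm^2/s (default `c(2e-4, 3e-3)`).
#' @return A list of class `bayes_priors` with node vectors and quadrature
#'   weights.
#' @export
bayes_priors <- function(n_f = 64L, n_dp = 64L, n_dt = 64L,
                         dp_range = c(1e-3, 0.1), dt_range = c(2e-4, 3e-3)) {
  stopifnot(dp_range[1] > 0, dt_range[1] > 0,
            dp_range[2] > dp_range[1], dt_range[2] > dt_range[1],
            n_f >= 4, n_dp >= 4, n_dt >= 4)
  f <- seq(0, 1, length.out = n_f)
  dp <- exp(seq(log(dp_range[1]), log(dp_range[2]), length.out = n_dp))
  dt <- exp(seq(log(dt_range[1]), log(dt_range[2]), length.out = n_dt))
  trap_w <- function(x) {
    n <- length(x)
    w <- numeric(n)
    w[1] <- (x[2] - x[1]) / 2
    w[n] <- (x[n] - x[n - 1]) / 2
    if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
    w
  }
  structure(list(f = f, dp = dp, dt = dt,
                 wf = trap_w(f), wdp = trap_w(dp), wdt = trap_w(dt)),
            class = "bayes_priors")
}

# Vectorized Bayesian fit for a voxel block sharing one b-value scheme.
# Y: V x n_b matrix of magnitudes. Returns a data frame of posterior means
# and SDs. The per-(f, D_p, D_t) weight is
#   prior_w * (g'g)^(-1/2) * max(RSSmin, eps*y'y)^(-(n-1)/2),
# the analytic marginal over S0 (flat) and sigma (Jeffreys), with
# RSSmin = y'y - (y'g)^2 / g'g for unit-amplitude model g.
fit_bayes_block <- function(Y, b, priors, eps = 1e-12, chunk = NULL) {
  V <- nrow(Y); n_b <- length(b)
  stopifnot(ncol(Y) == n_b)
  k <- (n_b - 1) / 2
  f <- priors$f; dp <- priors$dp; dt <- priors$dt

  Ep <- exp(-outer(b, dp))            # n_b x n_dp
  Et <- exp(-outer(b, dt))            # n_b x n_dt
  pp <- colSums(Ep * Ep)
  tt <- colSums(Et * Et)
  Cpt <- crossprod(Ep, Et)            # n_dp x n_dt

  n_dp <- length(dp); n_dt <- length(dt)
  pair_ip <- rep(seq_len(n_dp), times = n_dt)
  pair_it <- rep(seq_len(n_dt), each = n_dp)
  keep <- dp[pair_ip] >= dt[pair_it]  # physical ordering constraint
  pair_ip <- pair_ip[keep]; pair_it <- pair_it[keep]
  n_pair <- length(pair_ip)
  ppP <- pp[pair_ip]; ttP <- tt[pair_it]
  cP <- Cpt[cbind(pair_ip, pair_it)]
  prior_pair <- priors$wdp[pair_ip] * priors$wdt[pair_it]
  dpP <- dp[pair_ip]; dtP <- dt[pair_it]

  if (is.null(chunk)) chunk <- max(1L, floor(2^21 / n_pair))
  res <- matrix(NA_real_, V, 9)
  colnames(res) <- c("f_p", "D_p", "D_t", "S0", "f_p_sd", "D_p_sd", "D_t_sd",
                     "W", "zero")
  for (start in seq(1L, V, by = chunk)) {
    idx <- start:min(V, start + chunk - 1L)
    Yc <- Y[idx, , drop = FALSE]
    Vc <- length(idx)
    # column-wise products avoid BLAS so results are identical for any block size
    Apt <- matrix(0, n_dp, Vc)
    for (j in seq_len(n_dp)) {
      Apt[j, ] <- rowSums(Yc * matrix(Ep[, j], Vc, n_b, byrow = TRUE))
    }
    Att <- matrix(0, n_dt, Vc)
    for (j in seq_len(n_dt)) {
      Att[j, ] <- rowSums(Yc * matrix(Et[, j], Vc, n_b, byrow = TRUE))
    }
    Mp <- Apt[pair_ip, , drop = FALSE]  # n_pair x Vc
    Mt <- Att[pair_it, , drop = FALSE]
    Syy <- rowSums(Yc * Yc)
    SyyM <- matrix(Syy, n_pair, Vc, byrow = TRUE)
    W <- Sf <- Sf2 <- Sdp <- Sdp2 <- Sdt <- Sdt2 <- Ss0 <- numeric(Vc)
    for (fi in seq_along(f)) {
      fv <- f[fi]
      sg2 <- fv^2 * ppP + 2 * fv * (1 - fv) * cP + (1 - fv)^2 * ttP
      amp <- priors$wf[fi] * prior_pair / sqrt(sg2)
      G <- fv * Mp + (1 - fv) * Mt
      rss <- pmax(SyyM - (G * G) / sg2, eps * SyyM)
      w <- amp * rss^(-k)
      cw <- colSums(w)
      W <- W + cw
      Sf <- Sf + fv * cw
      Sf2 <- Sf2 + fv^2 * cw
      Sdp <- Sdp + colSums(w * dpP)
      Sdp2 <- Sdp2 + colSums(w * dpP^2)
      Sdt <- Sdt + colSums(w * dtP)
      Sdt2 <- Sdt2 + colSums(w * dtP^2)
      Ss0 <- Ss0 + colSums(w * G / sg2)
    }
    m_f <- Sf / W; m_dp <- Sdp / W; m_dt <- Sdt / W
    res[idx, "f_p"] <- m_f
    res[idx, "D_p"] <- m_dp
    res[idx, "D_t"] <- m_dt
    res[idx, "S0"] <- Ss0 / W
    res[idx, "f_p_sd"] <- sqrt(pmax(Sf2 / W - m_f^2, 0))
    res[idx, "D_p_sd"] <- sqrt(pmax(Sdp2 / W - m_dp^2, 0))
    res[idx, "D_t_sd"] <- sqrt(pmax(Sdt2 / W - m_dt^2, 0))
    res[idx, "W"] <- W
    res[idx, "zero"] <- apply(Yc, 1, function(r) max(r) == min(r))
  }
  res
}

# Prior means under the constrained uniform prior (used for zero-decay voxels).
bayes_prior_mean <- function(priors) {
  n_dp <- length(priors$dp); n_dt <- length(priors$dt)
  ip <- rep(seq_len(n_dp), times = n_dt)
  it <- rep(seq_len(n_dt), each = n_dp)
  keep <- priors$dp[ip] >= priors$dt[it]
  w <- (priors$wdp[ip] * priors$wdt[it])[keep]
  c(f_p = sum(priors$f * priors$wf) / sum(priors$wf),
    D_p = sum(priors$dp[ip][keep] * w) / sum(w),
    D_t = sum(priors$dt[it][keep] * w) / sum(w))
}

#' Bayesian IVIM fit (deterministic grid posterior)
#'
#' Voxelwise Bayesian estimation emulating the Bayesian software family.
#' The likelihood is Gaussian with the noise standard deviation analytically
#' marginalized under a Jeffreys prior and the amplitude `S0` under a flat
#' prior; the posterior over `(f_p, D_p, D_t)` is evaluated on the
#' deterministic grid of [bayes_priors()] (uniform priors with `D_p >= D_t`)
#' and summarized by marginal posterior means and SDs. Estimates always lie
#' inside the prior support, so the in-range flags are true by construction.
#'
#' @param decay A [voxel_decay()] object.
#' @param priors A [bayes_priors()] specification.
#' @return One-row `fit_result` data frame (see [fit_segmented_lsq()]), with
#'   posterior SDs in `f_p_sd`, `D_p_sd`, `D_t_sd`. A zero-decay voxel (all
#'   signals equal) is returned at the prior mean with `converged = FALSE`.
#' @export
fit_bayesian <- function(decay, priors = bayes_priors()) {
  stopifnot(inherits(decay, "voxel_decay"), inherits(priors, "bayes_priors"))
  fit_roi_bayes(matrix(decay$signals, nrow = 1), decay$scheme$b_values,
                priors)
}
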