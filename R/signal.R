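#' IVIM parameter set
#'
#' Bundles the biexponential IVIM parameters: perfusion fraction `f_p`
#' (dimensionless, in \[0,1\]), pseudo-diffusion `D_p` (mm^2/s), tissue
#' diffusivity `D_t` (mm^2/s) and unweighted amplitude `S0` (arbitrary
#' units, > 0). For physical ground truth `D_p >= D_t`; fitted values may
#' violate the ordering and carry validity flags instead.
#'
#' @param f_p Perfusion fraction in \[0,1\].
#' @param D_p Pseudo-diffusion coefficient, mm^2/s.
#' @param D_t Tissue diffusivity, mm^2/s.
#' @param S0 Signal amplitude at b = 0; must be positive.
#' @param check If `TRUE` (default) enforce the ground-truth invariants
#'   (including `D_p >= D_t`).
#' @return A list of class `ivim_params`.
#' @export
ivim_params <- function(f_p, D_p, D_t, S0 = 1, check = TRUE) {
  p <- list(f_p = as.numeric(f_p), D_p = as.numeric(D_p),
            D_t = as.numeric(D_t), S0 = as.numeric(S0))
  if (check) {
    if (is.na(p$f_p) || p$f_p < 0 || p$f_p > 1) stop("f_p must lie in [0,1]")
    if (p$D_t < 0 || p$D_p < p$D_t) stop("need D_p >= D_t >= 0")
    if (p$S0 <= 0) stop("S0 must be positive")
  }
  structure(p, class = "ivim_params")
}

#' Biexponential IVIM signal decay
#'
#' Evaluates the IVIM model
#' `S(b) = S0 * (f_p * exp(-b * D_p) + (1 - f_p) * exp(-b * D_t))`,
#' the sum of a fast pseudo-diffusion compartment (capillary flow) and a slow
#' tissue-water compartment.
#'
#' @param params An [ivim_params()] object (or list with fields `f_p`, `D_p`,
#'   `D_t`, `S0`).
#' @param b Diffusion weighting(s), s/mm^2; non-negative, vectorized.
#' @return Signal magnitude(s), same units as `S0`; monotone non-increasing
#'   in `b`.
#' @examples
#' ivim_signal(ivim_params(0.1, 0.01, 0.001), b = c(0, 800))
#' @export
ivim_signal <- function(params, b) {
  if (any(b < 0)) stop("b-values must be non-negative")
  params$S0 * (params$f_p * exp(-b * params$D_p) +
               (1 - params$f_p) * exp(-b * params$D_t))
}

#' Add Rician magnitude noise to a clean signal
#'
#' Magnitude MRI noise: the clean signal is placed on the real channel and
#' independent zero-mean Gaussian noise of standard deviation `s0 / snr` is
#' added to both quadrature channels before taking the complex modulus. This
#' produces the characteristic positive noise floor (Rayleigh-distributed
#' where the clean signal is zero).
#'
#' @param clean_signal Non-negative clean magnitudes (vector or matrix).
#' @param snr Signal-to-noise ratio at b = 0; must be positive.
#' @param s0 Reference amplitude defining the noise level `sigma = s0/snr`.
#'   Defaults to the first element of `clean_signal` (the b = 0 signal).
#' @param stream Optional RNG stream (a `.Random.seed` vector from
#'   [rng_streams()]); if `NULL` the current RNG state is used.
#' @return Noisy magnitudes, strictly positive, same shape as `clean_signal`.
#' @export
add_rician_noise <- function(clean_signal, snr, s0 = NULL, stream = NULL) {
  if (length(snr) != 1L || is.na(snr) || snr <= 0) stop("snr must be > 0")
  if (any(clean_signal < 0)) stop("clean_signal must be non-negative")
  if (is.null(s0)) s0 <- clean_signal[1]
  if (s0 <= 0) stop("reference amplitude s0 must be positive")
  sigma <- s0 / snr
  draw <- function() {
    n <- length(clean_signal)
    n1 <- stats::rnorm(n, 0, sigma)
    n2 <- stats::rnorm(n, 0, sigma)
    out <- sqrt((clean_signal + n1)^2 + n2^2)
    attributes(out) <- attributes(clean_signal)
    out
  }
  if (is.null(stream)) draw() else with_rng_stream(stream, draw())
}
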