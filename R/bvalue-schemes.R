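#' Site-specific diffusion-weighting schemes
#'
#' Returns the b-value scheme used at one of the three acquisition sites of the
#' multi-site breast cohort. Site A acquired with five different sub-schemes
#' over the course of the study (selected by `variant`); Sites B and C each
#' used a single fixed scheme.
#'
#' @param site_tag One of `"A"`, `"B"`, `"C"`.
#' @param variant Sub-scheme index. Site A has variants 1 to 5; Sites B and C
#'   only variant 1.
#' @return An object of class `bvalue_scheme`: a list with elements `site_tag`,
#'   `variant` and `b_values` (strictly increasing, starting at 0, in s/mm^2).
#' @examples
#' site_bvalue_scheme("B")$b_values
#' site_bvalue_scheme("A", 2)
#' @export
site_bvalue_scheme <- function(site_tag, variant = 1L) {
  schemes <- .bvalue_scheme_table()
  if (!is.character(site_tag) || length(site_tag) != 1L ||
      !site_tag %in% names(schemes)) {
    stop("unknown site '", paste(site_tag, collapse = ","),
         "'; valid sites are: ", paste(names(schemes), collapse = ", "))
  }
  site <- schemes[[site_tag]]
  variant <- as.integer(variant)
  if (length(variant) != 1L || is.na(variant) ||
      variant < 1L || variant > length(site)) {
    stop("invalid variant ", variant, " for site ", site_tag,
         "; valid variants are 1..", length(site))
  }
  structure(
    list(site_tag = site_tag, variant = variant, b_values = site[[variant]]),
    class = "bvalue_scheme"
  )
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat(sprintf("<bvalue_scheme> site %s, variant %d: %s s/mm^2\n",
              x$site_tag, x$variant, paste(x$b_values, collapse = ",")))
  invisible(x)
}

# b-value lists per site; Site A sub-schemes ordered as acquired, with
# per-sub-scheme patient usage counts 9/24/10/14/1 (see site_a_variant_counts).
.bvalue_scheme_table <- function() {
  list(
    A = list(
      c(0, 30, 60, 90, 120, 250, 400, 600, 800),
      c(0, 30, 60, 90, 120, 400, 600, 800, 1000),
      c(0, 30, 60, 90, 120, 250, 450, 600, 800, 1000),
      c(0, 30, 60, 90, 120, 250, 400, 600, 800, 1000),
      c(0, 10, 30, 60, 90, 120, 200, 400, 600, 800, 1000)
    ),
    B = list(c(0, 100, 600, 800, 1000)),
    C = list(c(0, 5, 10, 20, 30, 50, 70, 100, 200, 400, 600, 800, 1000))
  )
}

#' Number of Site A patients acquired with each sub-scheme
#'
#' @return Integer vector of length 5 (one count per Site A variant).
#' @export
site_a_variant_counts <- function() c(9L, 24L, 10L, 14L, 1L)

n_scheme_variants <- function(site_tag) {
  length(.bvalue_scheme_table()[[site_tag]])
}

assert_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  b <- scheme$b_values
  if (length(b) < 4L || b[1] != 0 || any(diff(b) <= 0) || any(b < 0)) {
    stop("malformed b-value scheme: must start at 0, be strictly increasing, ",
         "length >= 4")
  }
  invisible(scheme)
}
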