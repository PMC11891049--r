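#' Reproducible counter-based RNG streams
#'
#' Derives `n` independent L'Ecuyer-CMRG substreams from a single master seed.
#' Stream `k` is a fixed function of `(seed, k)`, so consumers that are each
#' given their own stream produce the same draws regardless of the order in
#' which they run.
#'
#' @param seed Integer master seed.
#' @param n Number of streams.
#' @return A list of `n` `.Random.seed` vectors.
#' @export
rng_streams <- function(seed, n) {
  state <- local_rng_state()
  on.exit(restore_rng_state(state))
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  out <- vector("list", n)
  for (k in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[k]] <- s
  }
  out
}

#' Evaluate an expression under a given RNG stream
#'
#' Temporarily installs `stream` as the global RNG state, evaluates `expr`,
#' then restores the previous state.
#'
#' @param stream A `.Random.seed` vector (e.g. from [rng_streams()]).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_rng_stream <- function(stream, expr) {
  state <- local_rng_state()
  on.exit(restore_rng_state(state))
  assign(".Random.seed", stream, envir = globalenv())
  expr
}

local_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
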