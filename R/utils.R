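## Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one user seed, kept below 2^31.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

td_log <- function(...) {
  if (isTRUE(getOption("trajdiff.verbose", FALSE)))
    message("[trajdiff] ", sprintf(...))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment; `NA` p-values are passed through unchanged and do
#' not count toward the number of tests.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return numeric vector of FDR (q-) values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}
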