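#' B-spline basis on \[0, 1\] with K + 1 functions
#'
#' Constructs the spline basis used throughout the expression and density
#' models. `K` is the knot-count parameter: the basis always contains exactly
#' `K + 1` functions that are nonnegative and sum to one at every point of
#' \[0, 1\] (partition of unity), so a constant fitted curve corresponds to
#' equal coefficients on all basis functions.
#'
#' Convention: `K = 0` gives the single constant function; for `1 <= K <= 3`
#' the basis is the degree-`K` Bernstein basis (no interior knots); for
#' `K >= 4` it is the cubic B-spline basis with `K - 3` equidistant interior
#' knots. All choices yield `K + 1` functions.
#'
#' @param K integer knot-count parameter, `K >= 0`.
#' @return an object of class `spline_basis` with elements `K`, `degree`,
#'   `knots` (full knot vector) and `eval(t)`, a function returning the
#'   `length(t) x (K+1)` evaluation matrix.
#' @export
make_basis <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 0) stop("K must be a nonnegative integer")
  if (K == 0L) {
    b <- list(K = 0L, degree = 0L, knots = c(0, 1),
              eval = function(t) {
                stopifnot(all(t >= 0 & t <= 1))
                matrix(1, length(t), 1L)
              })
    class(b) <- "spline_basis"
    return(b)
  }
  degree <- min(3L, K)
  n_interior <- K - degree                    # K+1 = n_interior + degree + 1
  interior <- if (n_interior > 0) seq_len(n_interior) / (n_interior + 1) else numeric(0)
  knots <- c(rep(0, degree + 1L), interior, rep(1, degree + 1L))
  ev <- function(t) {
    stopifnot(all(t >= 0 & t <= 1))
    # splineDesign is open on the right boundary; fold t = 1 in explicitly
    M <- splines::splineDesign(knots, pmin(t, 1 - 1e-12), ord = degree + 1L)
    at1 <- t >= 1 - 1e-12
    if (any(at1)) {
      last <- numeric(K + 1L)
      last[K + 1L] <- 1
      M[at1, ] <- rep(last, each = sum(at1))
    }
    M
  }
  b <- list(K = K, degree = degree, knots = knots, eval = ev)
  class(b) <- "spline_basis"
  b
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("B-spline basis on [0,1]: K = %d (%d functions, degree %d)\n",
              x$K, x$K + 1L, x$degree))
  invisible(x)
}

# Evaluate basis for a pseudotime vector, with caching-friendly signature.
basis_matrix <- function(basis, t) basis$eval(t)
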