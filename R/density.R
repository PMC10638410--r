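## Cell density along pseudotime: interval counts per sample, and the
## TCD/XCD tests obtained by feeding interval count ratios through the
## expression-model machinery (intervals act as pseudo-cells at interval
## midpoints).

#' Interval cell-density matrix along a branch
#'
#' Divides pseudotime (rescaled to \[0, 1\]) into `n_intervals` half-open
#' equal-length intervals (last interval closed) and counts cells per
#' sample and interval. Ratios are counts over the per-sample total on the
#' branch.
#'
#' @param pseudotime named pseudotime vector (or `td_branch`).
#' @param sample_of_cell named sample assignment.
#' @param n_intervals number of intervals (default 100).
#' @param min_cells samples contributing fewer cells are flagged (ratio
#'   estimates unstable); default 20.
#' @return list of class `density_matrix`: `counts` (samples x intervals),
#'   `ratio`, `totals`, `midpoints`, `flagged`.
#' @export
density_matrix <- function(pseudotime, sample_of_cell, n_intervals = 100,
                           min_cells = 20) {
  if (n_intervals < 2) stop("n_intervals must be at least 2")
  pt <- as_pseudotime(pseudotime)
  sv <- sample_of_cell[names(pt)]
  samp <- if (is.factor(sv)) sv else factor(sv)
  empty <- levels(samp)[tabulate(samp, nlevels(samp)) == 0L]
  if (length(empty)) {
    warning("sample(s) with zero cells on branch dropped: ",
            paste(empty, collapse = ", "))
    samp <- droplevels(samp)
  }
  iv <- pmin(floor(pt * n_intervals), n_intervals - 1L) + 1L
  counts <- table(samp, factor(iv, levels = seq_len(n_intervals)))
  counts <- matrix(as.numeric(counts), nrow = nlevels(samp),
                   dimnames = list(levels(samp), NULL))
  totals <- rowSums(counts)
  out <- list(counts = counts, ratio = counts / totals, totals = totals,
              midpoints = (seq_len(n_intervals) - 0.5) / n_intervals,
              flagged = names(totals)[totals < min_cells],
              n_intervals = n_intervals)
  class(out) <- "density_matrix"
  out
}

#' @export
print.density_matrix <- function(x, ...) {
  cat(sprintf("density_matrix: %d samples x %d intervals (totals %s)\n",
              nrow(x$counts), x$n_intervals,
              paste(x$totals, collapse = ", ")))
  if (length(x$flagged))
    cat("  flagged (few cells): ", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

# Build the pseudo-expression matrix for the density tests: one "gene"
# whose "cells" are the intervals, expression = ratio, pseudotime =
# interval midpoint.
density_pseudo_data <- function(density) {
  S <- nrow(density$counts)
  n <- density$n_intervals
  y <- as.numeric(t(density$ratio))
  t <- rep(density$midpoints, S)
  samp <- rep(rownames(density$counts), each = n)
  ids <- paste0(samp, "_iv", rep(seq_len(n), S))
  list(y = stats::setNames(y, ids), t = stats::setNames(t, ids),
       samp = stats::setNames(samp, ids))
}

#' Temporal cell-density (TCD) test
#'
#' Tests whether cell density changes along pseudotime by modeling the
#' interval count ratios `r_st / L_s` exactly like gene expression and
#' applying the TDE machinery; the permutation null shuffles the interval
#' order within each sample.
#'
#' @param density a [density_matrix()].
#' @param mode "pm" or "chisq".
#' @param n_perm permutations (pm mode).
#' @param K_max BIC cap for the basis.
#' @param seed RNG seed.
#' @return one-row data.frame (`llr`, `p_value`, `K`).
#' @export
tcd_test <- function(density, mode = c("pm", "chisq"), n_perm = 100,
                     K_max = 10, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(density, "density_matrix"))
  if (nrow(density$counts) < 2L) stop("need at least 2 samples")
  pd <- density_pseudo_data(density)
  samp <- droplevels(factor(pd$samp))
  X <- matrix(1, nlevels(samp), 1L,
              dimnames = list(levels(samp), "intercept"))
  expr <- matrix(pd$y, nrow = 1L, dimnames = list("density", names(pd$y)))
  t_list <- split(as.numeric(pd$t), samp)
  Ks <- select_K_all(expr, pd$t, samp, K_max = K_max)
  res <- tde_core(expr, t_list, samp, X, Ks, mode, n_perm,
                  prescreen_p = NULL, seed = seed, tol = 1e-4,
                  max_iter = 200, shuffle_only = TRUE)
  data.frame(llr = res$llr, p_value = res$p_value, K = res$K)
}

#' Covariate cell-density (XCD) test
#'
#' Tests whether a sample covariate changes the pseudotemporal cell-density
#' curve, by running the overall XDE machinery on the interval count
#' ratios. The permutation null shuffles the covariate across samples
#' (intervals are kept intact).
#'
#' @param density a [density_matrix()].
#' @param sample_design samples x (V+1) design matrix.
#' @param covariate tested covariate (name or index, non-intercept).
#' @param mode "pm" or "chisq".
#' @param n_perm permutations.
#' @param K_max BIC cap.
#' @param seed RNG seed.
#' @return one-row data.frame (`llr`, `p_value`, `K`).
#' @export
xcd_test <- function(density, sample_design, covariate,
                     mode = c("pm", "chisq"), n_perm = 100, K_max = 10,
                     seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(density, "density_matrix"))
  pd <- density_pseudo_data(density)
  samp <- droplevels(factor(pd$samp))
  X <- as.matrix(sample_design)[levels(samp), , drop = FALSE]
  v <- covariate_index(X, covariate)
  t_list <- split(as.numeric(pd$t), samp)
  y_list <- split(as.numeric(pd$y), samp)
  expr <- matrix(pd$y, nrow = 1L, dimnames = list("density", names(pd$y)))
  K <- select_K_all(expr, pd$t, samp, K_max = K_max)[1L]
  S <- nlevels(samp)
  scalar <- S <= (ncol(X) - 1L) + K + 2
  basis <- make_basis(K)
  Phi_list <- lapply(t_list, function(tt) basis_matrix(basis, tt))
  f0 <- fit_nested_one(y_list, Phi_list, X, K, v, "M0", scalar, 1e-4, 200)
  f2 <- fit_nested_one(y_list, Phi_list, X, K, v, "M2", scalar, 1e-4, 200)
  llr <- f2$loglik - f0$loglik
  if (mode == "chisq") {
    p <- chisq_pvalue(llr, K + 1L)
  } else {
    seeds <- child_seeds(seed, 1L)
    nulls <- with_seed(seeds[[1L]], vapply(seq_len(n_perm), function(i) {
      Xp <- X
      Xp[, v + 1L] <- X[sample.int(S), v + 1L]
      g0 <- fit_nested_one(y_list, Phi_list, Xp, K, v, "M0", scalar,
                           1e-4, 200)
      g2 <- fit_nested_one(y_list, Phi_list, Xp, K, v, "M2", scalar,
                           1e-4, 200)
      g2$loglik - g0$loglik
    }, numeric(1)))
    p <- kde_tail_p(llr, nulls)
  }
  data.frame(llr = llr, p_value = p, K = K)
}
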