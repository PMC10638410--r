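## Benchmark metrics: FDR calibration curves, sensitivity-realFDR AUC, and
## the top-N gold-set overlap permutation test.

#' Realized-vs-reported FDR calibration curve
#'
#' For each cutoff on the sorted grid of reported FDR values, computes the
#' realized FDR (false discoveries / discoveries; 0 when there are no
#' discoveries) among genes with reported FDR at or below the cutoff. The
#' FDR difference is the trapezoid area under the realized-vs-reported
#' curve on \[0, 1\] minus 0.5 (the diagonal's area); positive values mean
#' anticonservative reporting.
#'
#' @param reported_fdr reported FDR per gene, in \[0, 1\].
#' @param truth logical per gene: TRUE for genuinely differential genes.
#' @return list of class `calibration_curve`: `reported` grid, `realized`,
#'   `fdr_difference`, `sensitivity`, `auc` (see
#'   [sensitivity_realfdr_auc()]).
#' @export
fdr_curve_difference <- function(reported_fdr, truth) {
  stopifnot(length(reported_fdr) == length(truth))
  ok <- !is.na(reported_fdr)
  reported_fdr <- reported_fdr[ok]; truth <- as.logical(truth[ok])
  if (any(reported_fdr < 0 | reported_fdr > 1))
    stop("reported FDR must lie in [0, 1]")
  grid <- sort(unique(c(0, reported_fdr, 1)))
  realized <- sens <- numeric(length(grid))
  n_true <- sum(truth)
  for (i in seq_along(grid)) {
    disc <- reported_fdr <= grid[i]
    realized[i] <- if (any(disc)) sum(disc & !truth) / sum(disc) else 0
    sens[i] <- if (n_true > 0) sum(disc & truth) / n_true else NA_real_
  }
  area <- sum(diff(grid) * (utils::head(realized, -1) +
                              utils::tail(realized, -1)) / 2)
  out <- list(reported = grid, realized = realized,
              fdr_difference = area - 0.5, sensitivity = sens,
              auc = if (n_true > 0)
                sensitivity_realfdr_auc(reported_fdr, truth) else NA_real_)
  class(out) <- "calibration_curve"
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: FDR difference = %.4f, AUC = %.4f\n",
              x$fdr_difference, x$auc))
  invisible(x)
}

#' Area under the sensitivity vs realized-FDR curve
#'
#' Sweeps cutoffs over the score grid (ascending scores / reported FDRs),
#' records (realized FDR, sensitivity) pairs, and integrates sensitivity
#' over realized FDR in \[0, 1\] by trapezoid, extending the final
#' sensitivity to realized FDR = 1.
#'
#' @param scores_or_fdrs per-gene scores, small = more significant.
#' @param truth logical per gene.
#' @return scalar AUC in \[0, 1\].
#' @export
sensitivity_realfdr_auc <- function(scores_or_fdrs, truth) {
  truth <- as.logical(truth)
  n_true <- sum(truth)
  if (n_true == 0) stop("no true genes: AUC undefined")
  ord <- order(scores_or_fdrs)
  cum_false <- cumsum(!truth[ord])
  cum_true <- cumsum(truth[ord])
  n_disc <- seq_along(ord)
  # collapse tied scores to a single cutoff
  last_of_tie <- c(scores_or_fdrs[ord][-1L] !=
                     utils::head(scores_or_fdrs[ord], -1L), TRUE)
  realized <- (cum_false / n_disc)[last_of_tie]
  sens <- (cum_true / n_true)[last_of_tie]
  ord2 <- order(realized, sens)
  realized <- realized[ord2]
  sens <- cummax(sens[ord2])
  # right-extend at the final sensitivity; left of the smallest attained
  # realized FDR the curve contributes nothing (no interpolated credit)
  realized <- c(realized, 1)
  sens <- c(sens, sens[length(sens)])
  sum(diff(realized) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

#' Top-N overlap permutation test against a gold gene set
#'
#' Counts the overlap with the gold set among the top N genes of the
#' ranking for each N on the grid; the observed statistic is the mean
#' overlap across Ns. The null is built by permuting the gene order;
#' one-sided p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param ranked_genes gene ids ordered by increasing FDR (best first).
#' @param gold_set gold-standard gene ids (subset of the universe).
#' @param n_grid vector of Ns (default seq(10, 500, 10), clipped).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list: `observed`, `null` draws, `p_value`, `n_grid`.
#' @export
topn_overlap_test <- function(ranked_genes, gold_set,
                              n_grid = seq(10, 500, by = 10),
                              n_perm = 10000, seed = 1) {
  if (!length(gold_set)) stop("empty gold set")
  if (!all(gold_set %in% ranked_genes))
    stop("gold_set must be a subset of the ranked gene universe")
  n_grid <- n_grid[n_grid <= length(ranked_genes)]
  if (!length(n_grid)) stop("n_grid exceeds the gene universe")
  mean_overlap <- function(genes) {
    hits <- cumsum(genes %in% gold_set)
    mean(hits[n_grid])
  }
  observed <- mean_overlap(ranked_genes)
  nulls <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    mean_overlap(sample(ranked_genes)), numeric(1)))
  list(observed = observed, null = nulls,
       p_value = (1 + sum(nulls >= observed)) / (n_perm + 1),
       n_grid = n_grid)
}
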