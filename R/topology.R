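## Branch uncertainty (bootstrap detection rates with Jaccard matching) and
## differential topology (branch-proportion regression).

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Null-calibrated Jaccard cutoff for branch matching
#'
#' Draws `n_draws` random cell sets of the branch's size from the cell
#' universe and computes their Jaccard index with the branch; the `q`
#' quantile of this null distribution is the detection cutoff.
#'
#' @param branch_cells character vector of branch member cells.
#' @param all_cells cell universe.
#' @param n_draws number of null draws (default 1000).
#' @param q quantile (default 0.99).
#' @param seed RNG seed.
#' @return scalar cutoff in (0, 1\].
#' @export
jaccard_cutoff <- function(branch_cells, all_cells, n_draws = 1000,
                           q = 0.99, seed = 1) {
  if (!length(branch_cells)) stop("empty branch")
  if (length(branch_cells) > length(all_cells))
    stop("branch larger than cell universe")
  if (!all(branch_cells %in% all_cells))
    stop("branch cells must be a subset of the universe")
  nulls <- with_seed(seed, vapply(seq_len(n_draws), function(i)
    jaccard(sample(all_cells, length(branch_cells)), branch_cells),
    numeric(1)))
  as.numeric(stats::quantile(nulls, q))
}

#' Bootstrap branch detection rates
#'
#' For each bootstrap sample (cells resampled with replacement; duplicates
#' collapsed to unique identities for the overlap computation), the
#' trajectory is rebuilt with the original cluster number, rooted at the
#' cluster with the smallest mean original pseudotime, and every original
#' branch is matched against the bootstrap branches by Jaccard index. A
#' branch is detected when any bootstrap branch reaches its null-calibrated
#' cutoff (computed once from the original data). The detection rate is the
#' fraction of bootstrap samples in which the branch is detected.
#'
#' @param dataset an `msd` dataset with embedding.
#' @param tree the original `trajectory_tree`.
#' @param n_bootstraps number of bootstrap samples (default 1000).
#' @param seed RNG seed.
#' @param n_null_draws draws for the Jaccard null (default 1000).
#' @return data.frame (`branch_id`, `jaccard_cutoff`, `detection_rate`,
#'   `n_bootstraps`).
#' @export
detection_rates <- function(dataset, tree, n_bootstraps = 1000, seed = 1,
                            n_null_draws = 1000) {
  stopifnot(inherits(tree, "trajectory_tree"))
  if (n_bootstraps < 1) stop("n_bootstraps must be >= 1")
  cells <- dataset$cell_ids
  branches <- tree$branches
  cutoffs <- vapply(seq_along(branches), function(i)
    jaccard_cutoff(branches[[i]]$cells, cells, n_draws = n_null_draws,
                   seed = seed + i), numeric(1))
  gp <- global_pseudotime(tree)
  detected <- matrix(FALSE, n_bootstraps, length(branches))
  emb <- dataset$embedding
  seeds <- child_seeds(seed, n_bootstraps)
  for (b in seq_len(n_bootstraps)) {
    res <- NULL
    attempt <- 0L
    while (is.null(res) && attempt < 10L) {
      attempt <- attempt + 1L
      res <- tryCatch({
        boot_cells <- with_seed(seeds[[b]] + attempt - 1L,
                                sample(cells, replace = TRUE))
        ucells <- unique(boot_cells)
        cl <- cluster_cells(emb[ucells, , drop = FALSE], k = tree$n_clusters,
                            seed = seeds[[b]])
        mst <- build_mst(cl$centers)
        org <- which.min(vapply(seq_len(cl$k), function(k)
          mean(gp[names(cl$cluster_of_cell)[cl$cluster_of_cell == k]]),
          numeric(1)))
        seqs <- root_and_enumerate(mst, cl$k, org)
        lapply(seqs, function(p)
          names(cl$cluster_of_cell)[cl$cluster_of_cell %in% p])
      }, error = function(e) {
        td_log("bootstrap %d failed (%s); redrawn", b, conditionMessage(e))
        NULL
      })
    }
    if (is.null(res)) next
    for (i in seq_along(branches)) {
      js <- vapply(res, jaccard, numeric(1), b = branches[[i]]$cells)
      detected[b, i] <- any(js >= cutoffs[i])
    }
  }
  data.frame(branch_id = names(branches) %||% seq_along(branches),
             jaccard_cutoff = cutoffs,
             detection_rate = colMeans(detected),
             n_bootstraps = n_bootstraps)
}

#' Branch cell proportions per sample
#'
#' For each sample and branch: cells of the sample on the branch divided by
#' the sample's total cell count. Branches sharing pre-branch-point cells
#' count those cells in every branch containing them. Samples with zero
#' cells are excluded with a warning.
#'
#' @param tree a `trajectory_tree` (or a named list of cell-id vectors).
#' @param sample_of_cell named sample assignment for all cells.
#' @return list of class `branch_proportions`: `proportions` and `counts`
#'   (samples x branches), `totals`, per-branch `mean` and `variance`.
#' @export
branch_proportions <- function(tree, sample_of_cell) {
  branch_cells <- if (inherits(tree, "trajectory_tree"))
    lapply(tree$branches, `[[`, "cells") else tree
  f <- factor(sample_of_cell)
  totals <- table(f)
  if (any(totals == 0L)) {
    warning("sample(s) with zero cells excluded: ",
            paste(names(totals)[totals == 0L], collapse = ", "))
    f <- droplevels(f)
    totals <- table(f)
  }
  counts <- vapply(branch_cells, function(cl)
    as.numeric(table(f[names(sample_of_cell) %in% cl])),
    numeric(nlevels(f)))
  counts <- matrix(counts, nrow = nlevels(f),
                   dimnames = list(levels(f), names(branch_cells)))
  props <- counts / as.numeric(totals)
  out <- list(proportions = props, counts = counts,
              totals = as.numeric(totals),
              mean = colMeans(props),
              variance = apply(props, 2L, stats::var))
  class(out) <- "branch_proportions"
  out
}

#' @export
print.branch_proportions <- function(x, ...) {
  cat("branch cell proportions (mean, SD across samples):\n")
  for (b in colnames(x$proportions))
    cat(sprintf("  %s: %.3f (%.3f)\n", b, x$mean[[b]],
                sqrt(x$variance[[b]])))
  invisible(x)
}

#' Differential topology test (binomial logistic regression per branch)
#'
#' Models each branch's per-sample cell count as binomial with the sample's
#' total count, `log(p/(1-p))` linear in the sample covariates; Wald test
#' per covariate coefficient, BH FDR across branches within covariate.
#' Complete separation (all-zero or all-one proportions within a level) is
#' flagged with `NA` p-values rather than penalized.
#'
#' @param proportions a `branch_proportions` object.
#' @param sample_design samples x (V+1) design matrix (leading intercept).
#' @return data.frame (`branch_id`, `covariate`, `estimate`, `se`,
#'   `statistic`, `p_value`, `fdr`).
#' @export
test_topology_binomial <- function(proportions, sample_design) {
  stopifnot(inherits(proportions, "branch_proportions"))
  X <- as.matrix(sample_design)
  samples <- rownames(proportions$proportions)
  X <- X[samples, , drop = FALSE]
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (qr(X)$rank < ncol(X)) stop("design is rank deficient")
  covs <- colnames(X)[-1L]
  res <- list()
  for (b in colnames(proportions$counts)) {
    cnt <- proportions$counts[, b]
    tot <- proportions$totals
    fit <- suppressWarnings(
      stats::glm.fit(X, cnt / tot, weights = tot,
                     family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 100)))
    sep <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
    # Wald: vcov from the weighted information matrix
    w <- fit$weights
    info <- crossprod(X * sqrt(w))
    vc <- tryCatch(solve(info), error = function(e) NULL)
    for (j in seq_along(covs)) {
      est <- fit$coefficients[j + 1L]
      se <- if (!is.null(vc)) sqrt(vc[j + 1L, j + 1L]) else NA_real_
      bad <- sep || !is.finite(est) || !is.finite(se) || abs(est) > 20
      z <- if (bad) NA_real_ else est / se
      res[[length(res) + 1L]] <- data.frame(
        branch_id = b, covariate = covs[j], estimate = est, se = se,
        statistic = z,
        p_value = if (bad) NA_real_ else 2 * stats::pnorm(-abs(z)))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  for (cv in covs)
    out$fdr[out$covariate == cv] <- bh_adjust(out$p_value[out$covariate == cv])
  out
}

# ---- multinomial baseline-category logit (hand ML + Wald) -------------------

# counts: S x L nonnegative matrix; X: S x (V+1). Reference category = ref.
# Newton-Raphson on the multinomial log-likelihood; returns coefficients
# ((L-1) x (V+1)) and the inverse observed information.
multinom_ml <- function(counts, X, ref, max_iter = 100, tol = 1e-10) {
  S <- nrow(counts); L <- ncol(counts); P <- ncol(X)
  nonref <- setdiff(seq_len(L), ref)
  nb <- length(nonref)
  beta <- matrix(0, nb, P)
  n_s <- rowSums(counts)
  npar <- nb * P
  for (it in seq_len(max_iter)) {
    eta <- X %*% t(beta)                      # S x nb
    denom <- 1 + rowSums(exp(eta))
    pi_nb <- exp(eta) / denom                 # S x nb
    grad <- numeric(npar)
    H <- matrix(0, npar, npar)
    for (s in seq_len(S)) {
      y <- counts[s, nonref]
      mu <- n_s[s] * pi_nb[s, ]
      grad <- grad + as.numeric(kronecker(y - mu, X[s, ]))  # v fastest
      W <- n_s[s] * (diag(pi_nb[s, ], nb) - tcrossprod(pi_nb[s, ]))
      H <- H + kronecker(W, tcrossprod(X[s, ]))
    }
    step <- tryCatch(solve(H + diag(1e-10, npar), grad),
                     error = function(e) rep(NA_real_, npar))
    if (anyNA(step)) break
    # step halving against overshoot
    mll <- function(b) {
      e <- X %*% t(b)
      sum(counts[, nonref] * e) - sum(n_s * log(1 + rowSums(exp(e))))
    }
    ll_old <- mll(beta)
    fac <- 1
    repeat {
      cand <- beta + fac * matrix(step, nb, P, byrow = TRUE)
      if (mll(cand) >= ll_old - 1e-12 || fac < 1e-4) break
      fac <- fac / 2
    }
    beta <- cand
    if (max(abs(step)) * fac < tol) break
  }
  eta <- X %*% t(beta)
  denom <- 1 + rowSums(exp(eta))
  pi_nb <- exp(eta) / denom
  H <- matrix(0, npar, npar)
  for (s in seq_len(S)) {
    W <- n_s[s] * (diag(pi_nb[s, ], nb) - tcrossprod(pi_nb[s, ]))
    H <- H + kronecker(W, tcrossprod(X[s, ]))
  }
  vcov <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, npar, npar))
  list(beta = beta, vcov = vcov, nonref = nonref, ref = ref,
       loglik = sum(counts[, nonref] * (X %*% t(beta))) -
         sum(n_s * log(denom)) +
         sum(lgamma(n_s + 1)) - sum(lgamma(counts + 1)))
}

#' Differential topology test (multinomial logistic regression)
#'
#' Joint baseline-category logit over all branches: per-sample branch counts
#' follow a multinomial; `log(p_l / p_ref)` is linear in the covariates, the
#' reference being the most abundant branch. Wald tests per (branch,
#' covariate). Note that branch counts may double-count shared pre-branch
#' cells; for the joint multinomial model the counts should partition cells
#' (use terminal-segment counts) — results with overlapping counts are a
#' pragmatic approximation.
#'
#' @param counts samples x branches count matrix (or `branch_proportions`).
#' @param sample_design samples x (V+1) design matrix.
#' @return data.frame (`branch_id`, `covariate`, `estimate`, `se`,
#'   `statistic`, `p_value`, `fdr`), non-reference branches only.
#' @export
test_topology_multinomial <- function(counts, sample_design) {
  if (inherits(counts, "branch_proportions")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 branches")
  X <- as.matrix(sample_design)[rownames(counts) %||%
                                  seq_len(nrow(counts)), , drop = FALSE]
  ref <- which.max(colSums(counts))
  fit <- multinom_ml(counts, X, ref)
  covs <- colnames(X)[-1L]
  P <- ncol(X)
  res <- list()
  for (li in seq_along(fit$nonref)) {
    for (j in seq_along(covs)) {
      pos <- (li - 1L) * P + j + 1L
      est <- fit$beta[li, j + 1L]
      se <- sqrt(fit$vcov[pos, pos])
      bad <- !is.finite(est) || !is.finite(se) || abs(est) > 20
      z <- if (bad) NA_real_ else est / se
      res[[length(res) + 1L]] <- data.frame(
        branch_id = colnames(counts)[fit$nonref[li]] %||% fit$nonref[li],
        covariate = covs[j], estimate = est, se = se, statistic = z,
        p_value = if (bad) NA_real_ else 2 * stats::pnorm(-abs(z)))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  for (cv in covs)
    out$fdr[out$covariate == cv] <- bh_adjust(out$p_value[out$covariate == cv])
  attr(out, "reference_branch") <- colnames(counts)[ref] %||% ref
  out
}
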