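## XDE and TDE tests over all genes of a dataset, on one pseudotemporal
## branch, plus XDE classification and DE-pattern clustering.

as_pseudotime <- function(x) {
  if (inherits(x, "td_branch"))
    return(stats::setNames(x$pseudotime, x$cells))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("pseudotime must be a named numeric vector or a td_branch")
}

covariate_index <- function(design, covariate) {
  covs <- colnames(design)[-1L]
  if (is.character(covariate)) {
    v <- match(covariate, covs)
    if (is.na(v)) stop("unknown covariate: ", covariate)
  } else {
    v <- as.integer(covariate)
    if (v < 1L || v > length(covs)) stop("covariate index out of range")
  }
  v
}

split_by_sample <- function(values, f) split(as.numeric(values), f)

xde_category <- function(fdr_overall, fdr_mean, fdr_trend, cutoff) {
  ifelse(is.na(fdr_overall) | fdr_overall > cutoff, "nonXDE",
    ifelse(fdr_mean <= cutoff & fdr_trend <= cutoff, "bothSig",
      ifelse(fdr_mean <= cutoff, "meanSig",
        ifelse(fdr_trend <= cutoff, "trendSig", "otherSig"))))
}

#' Differential expression associated with a sample covariate (XDE)
#'
#' For every gene, fits the nested models M0 (no covariate effect), M1
#' (constant curve shift) and M2 (free effect) along the branch and computes
#' three log-likelihood-ratio tests: overall (M2:M0), mean (M1:M0) and trend
#' (M2:M1). P-values come either from a permutation null (cells
#' bootstrapped within sample, then the tested covariate permuted across
#' samples; Gaussian-KDE tail mass) or from the asymptotic chi-squared
#' reference. FDRs are Benjamini-Hochberg within each test across genes, and
#' each gene is classified as `nonXDE`, `meanSig`, `trendSig`, `bothSig` or
#' `otherSig` at `fdr_cutoff`.
#'
#' `prescreen_p` (permutation mode only) skips permutations for genes whose
#' chi-squared overall p-value exceeds the threshold; such genes keep their
#' chi-squared p-values, which cannot reach significance at usual cutoffs.
#'
#' @param dataset an `msd` dataset.
#' @param pseudotime named pseudotime vector in \[0, 1\] (or a `td_branch`).
#' @param covariate tested covariate (name or index among non-intercept
#'   design columns).
#' @param mode "pm" (permutation) or "chisq".
#' @param n_perm permutations per gene (pm mode).
#' @param fdr_cutoff significance cutoff for classification.
#' @param K_max maximum knot parameter for per-gene BIC selection.
#' @param prescreen_p optional chi-squared pre-screen threshold (e.g. 0.1).
#' @param genes optional subset of gene ids.
#' @param seed RNG seed for the permutation null.
#' @param tol,max_iter EM controls.
#' @return data.frame with per-gene statistics, p-values, FDRs, `category`
#'   and the estimated mean shift per unit covariate.
#' @export
xde_test <- function(dataset, pseudotime, covariate, mode = c("pm", "chisq"),
                     n_perm = 100, fdr_cutoff = 0.05, K_max = 20,
                     prescreen_p = NULL, genes = NULL, seed = 1,
                     tol = 1e-4, max_iter = 150) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "msd"))
  pt <- as_pseudotime(pseudotime)
  cells <- intersect(names(pt), dataset$cell_ids)
  if (!length(cells)) stop("pseudotime covers no cells of the dataset")
  pt <- pt[cells]
  genes <- genes %||% dataset$gene_ids
  expr <- get_expression(dataset, genes)[, cells, drop = FALSE]
  samp <- droplevels(dataset$sample_of_cell[cells])
  X <- dataset$sample_design[levels(samp), , drop = FALSE]
  v <- covariate_index(X, covariate)
  lv <- table(X[, v + 1L])
  if (any(lv < 2L))
    warning("fewer than 2 samples in some covariate level")
  S <- nrow(X)
  t_list <- split_by_sample(pt, samp)
  Ks <- select_K_all(expr, pt, samp, K_max = K_max)
  basis_cache <- list(); Phi_cache <- list()
  get_bp <- function(K) {
    key <- as.character(K)
    if (is.null(basis_cache[[key]])) {
      b <- make_basis(K)
      basis_cache[[key]] <<- b
      Phi_cache[[key]] <<- lapply(t_list, function(tt) basis_matrix(b, tt))
    }
    list(basis = basis_cache[[key]], Phi = Phi_cache[[key]])
  }
  G <- length(genes)
  out <- data.frame(gene = genes, K = Ks,
                    llr_overall = NA_real_, p_overall = NA_real_,
                    fdr_overall = NA_real_,
                    llr_mean = NA_real_, p_mean = NA_real_,
                    fdr_mean = NA_real_,
                    llr_trend = NA_real_, p_trend = NA_real_,
                    fdr_trend = NA_real_, mean_shift = NA_real_,
                    stringsAsFactors = FALSE)
  seeds <- child_seeds(seed, G)
  for (g in seq_len(G)) {
    y <- expr[g, ]
    if (stats::var(y) < 1e-12) next        # zero-variance gene: reported NA
    K <- Ks[g]
    bp <- get_bp(K)
    y_list <- split_by_sample(y, samp)
    scalar <- S <= (ncol(X) - 1L) + K + 2
    fits <- tryCatch(lapply(c("M0", "M1", "M2"), function(mod)
      fit_nested_one(y_list, bp$Phi, X, K, v, mod, scalar, tol, max_iter)),
      error = function(e) NULL)
    if (is.null(fits)) next
    ll <- vapply(fits, `[[`, numeric(1), "loglik")
    llr <- c(overall = ll[3] - ll[1], mean = ll[2] - ll[1],
             trend = ll[3] - ll[2])
    out$llr_overall[g] <- llr[["overall"]]
    out$llr_mean[g] <- llr[["mean"]]
    out$llr_trend[g] <- llr[["trend"]]
    # mean shift per unit covariate: average effect of beta_.v on the curve
    B2 <- matrix(fits[[3]]$theta, nrow = K + 1L, byrow = TRUE)
    out$mean_shift[g] <- mean(B2[, v + 1L])
    pchi <- c(chisq_pvalue(llr[["overall"]], K + 1L),
              chisq_pvalue(llr[["mean"]], 1L),
              if (K >= 1L) chisq_pvalue(llr[["trend"]], K) else 1)
    if (mode == "chisq") {
      out$p_overall[g] <- pchi[1]; out$p_mean[g] <- pchi[2]
      out$p_trend[g] <- pchi[3]
    } else {
      if (!is.null(prescreen_p) && pchi[1] > prescreen_p) {
        out$p_overall[g] <- pchi[1]; out$p_mean[g] <- pchi[2]
        out$p_trend[g] <- pchi[3]
      } else {
        nulls <- with_seed(seeds[[g]],
          perm_llrs_xde(y_list, t_list, X, v, K, n_perm, scalar,
                        tol, max_iter, bp$basis))
        out$p_overall[g] <- kde_tail_p(llr[["overall"]], nulls[, 1L])
        out$p_mean[g] <- kde_tail_p(llr[["mean"]], nulls[, 2L])
        out$p_trend[g] <- if (K >= 1L)
          kde_tail_p(llr[["trend"]], nulls[, 3L]) else 1
      }
    }
  }
  out$fdr_overall <- bh_adjust(out$p_overall)
  out$fdr_mean <- bh_adjust(out$p_mean)
  out$fdr_trend <- bh_adjust(out$p_trend)
  out$category <- xde_category(out$fdr_overall, out$fdr_mean,
                               out$fdr_trend, fdr_cutoff)
  attr(out, "mode") <- mode
  attr(out, "n_permutations") <- if (mode == "pm") n_perm else 0L
  out
}

#' Differential expression along pseudotime (TDE)
#'
#' Tests, for every gene, whether the pseudotemporal curve is constant: H0
#' constrains every column of the fixed-effect matrix `B` to a shared scalar
#' (so the population curve is flat), H1 is unconstrained. The permutation
#' null bootstraps cells within sample and permutes pseudotime within
#' sample.
#'
#' @inheritParams xde_test
#' @param design optional design matrix override; defaults to the dataset's
#'   design (use an intercept-only matrix for covariate-free TDE).
#' @return data.frame with `gene`, `K`, `llr`, `p_value`, `fdr`.
#' @export
tde_test <- function(dataset, pseudotime, mode = c("pm", "chisq"),
                     n_perm = 100, fdr_cutoff = 0.05, K_max = 20,
                     prescreen_p = NULL, genes = NULL, design = NULL,
                     seed = 1, tol = 1e-4, max_iter = 150) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "msd"))
  pt <- as_pseudotime(pseudotime)
  cells <- intersect(names(pt), dataset$cell_ids)
  pt <- pt[cells]
  genes <- genes %||% dataset$gene_ids
  expr <- get_expression(dataset, genes)[, cells, drop = FALSE]
  samp <- droplevels(dataset$sample_of_cell[cells])
  X <- if (is.null(design)) dataset$sample_design[levels(samp), , drop = FALSE]
       else as.matrix(design)[levels(samp), , drop = FALSE]
  S <- nrow(X)
  t_list <- split_by_sample(pt, samp)
  Ks <- select_K_all(expr, pt, samp, K_max = K_max)
  res <- tde_core(expr, t_list, samp, X, Ks, mode, n_perm, prescreen_p,
                  seed, tol, max_iter, shuffle_only = FALSE)
  res$fdr <- bh_adjust(res$p_value)
  attr(res, "mode") <- mode
  res
}

# Shared TDE engine (also used by the density TCD test, where permutations
# shuffle interval order without bootstrap).
tde_core <- function(expr, t_list, samp, X, Ks, mode, n_perm, prescreen_p,
                     seed, tol, max_iter, shuffle_only = FALSE) {
  genes <- rownames(expr)
  S <- nrow(X)
  G <- length(genes)
  out <- data.frame(gene = genes, K = Ks, llr = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  seeds <- child_seeds(seed, G)
  basis_cache <- list(); Phi_cache <- list()
  for (g in seq_len(G)) {
    y <- expr[g, ]
    if (stats::var(y) < 1e-12) next
    K <- Ks[g]
    if (K == 0L) { out$llr[g] <- 0; out$p_value[g] <- 1; next }
    key <- as.character(K)
    if (is.null(basis_cache[[key]])) {
      basis_cache[[key]] <- make_basis(K)
      Phi_cache[[key]] <- lapply(t_list, function(tt)
        basis_matrix(basis_cache[[key]], tt))
    }
    basis <- basis_cache[[key]]; Phi_list <- Phi_cache[[key]]
    y_list <- split(as.numeric(y), samp)
    scalar <- S <= (ncol(X) - 1L) + K + 2
    res <- tryCatch({
      f0 <- fit_nested_one(y_list, Phi_list, X, K, NULL, "H0", scalar,
                           tol, max_iter)
      f1 <- fit_nested_one(y_list, Phi_list, X, K, NULL, "M2", scalar,
                           tol, max_iter)
      f1$loglik - f0$loglik
    }, error = function(e) NA_real_)
    if (!is.finite(res)) next
    out$llr[g] <- res
    df <- K * ncol(X)
    pchi <- chisq_pvalue(res, df)
    if (mode == "chisq") {
      out$p_value[g] <- pchi
    } else if (!is.null(prescreen_p) && pchi > prescreen_p) {
      out$p_value[g] <- pchi
    } else {
      nulls <- with_seed(seeds[[g]],
        perm_llrs_tde(y_list, t_list, X, K, n_perm, scalar, tol,
                      max_iter, basis, shuffle_only = shuffle_only))
      out$p_value[g] <- kde_tail_p(res, nulls)
    }
  }
  out
}

# ---- DE pattern clustering --------------------------------------------------

#' Fitted-curve features for DE-pattern clustering
#'
#' Row-standardized population fitted curves (TDE patterns) or standardized
#' covariate trend-difference curves plus the mean-shift sign (XDE patterns)
#' on a pseudotime grid.
#'
#' @param dataset an `msd` dataset.
#' @param pseudotime named pseudotime vector (or `td_branch`).
#' @param genes gene ids to featurize (typically the significant genes).
#' @param what "tde_curves" or "xde_difference".
#' @param covariate tested covariate (required for `xde_difference`).
#' @param grid_n grid resolution (default 100).
#' @param K_max BIC cap for the per-gene basis.
#' @return numeric matrix genes x features.
#' @export
de_pattern_features <- function(dataset, pseudotime, genes,
                                what = c("tde_curves", "xde_difference"),
                                covariate = NULL, grid_n = 100, K_max = 20) {
  what <- match.arg(what)
  pt <- as_pseudotime(pseudotime)
  cells <- intersect(names(pt), dataset$cell_ids)
  pt <- pt[cells]
  expr <- get_expression(dataset, genes)[, cells, drop = FALSE]
  samp <- droplevels(dataset$sample_of_cell[cells])
  X <- dataset$sample_design[levels(samp), , drop = FALSE]
  grid <- seq(0, 1, length.out = grid_n)
  Ks <- select_K_all(expr, pt, samp, K_max = K_max)
  feats <- matrix(0, length(genes), grid_n + (what == "xde_difference"),
                  dimnames = list(genes, NULL))
  for (g in seq_along(genes)) {
    obs <- gene_observations(expr[g, ], pt, samp)
    fit <- fit_em(obs, X, K = Ks[g], tol = 1e-4, max_iter = 200)
    if (what == "tde_curves") {
      cur <- predict_curves(fit, grid, "population")
      feats[g, ] <- standardize_row(cur)
    } else {
      v <- covariate_index(X, covariate)
      diffcur <- as.numeric(basis_matrix(fit$basis, grid) %*% fit$B[, v + 1L])
      feats[g, ] <- c(standardize_row(diffcur - mean(diffcur)),
                      sign(mean(diffcur)))
    }
  }
  feats
}

standardize_row <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

elbow_k <- function(wss, threshold = 0.1) {
  # smallest k >= 2 after which one more cluster explains less than
  # `threshold` of the total (k = 1) within-cluster sum of squares
  total <- max(wss[1L], 1e-12)
  for (k in 2:(length(wss) - 1L)) {
    if (wss[k] < 1e-12) return(k)
    if ((wss[k] - wss[k + 1L]) / total < threshold) return(k)
  }
  length(wss) - 1L
}

#' Cluster differential-expression patterns
#'
#' Unsupervised clustering of DE genes by their fitted-pattern features
#' (see [de_pattern_features()]). K-means by default; a diagonal Gaussian
#' mixture model and Louvain graph clustering are provided as options. When
#' `k` is absent it is chosen by the elbow rule on within-cluster sum of
#' squares (identical rows collapse to a single cluster).
#'
#' @param features genes x features numeric matrix.
#' @param method "kmeans", "gmm" or "louvain".
#' @param k number of clusters (optional; ignored by louvain).
#' @param seed RNG seed.
#' @return integer cluster labels named by gene.
#' @export
cluster_patterns <- function(features, method = c("kmeans", "gmm", "louvain"),
                             k = NULL, seed = 1) {
  method <- match.arg(method)
  features <- as.matrix(features)
  G <- nrow(features)
  if (!is.null(k) && k > G) stop("fewer genes than clusters requested")
  if (method == "louvain") {
    nn <- min(10L, G - 1L)
    d <- as.matrix(stats::dist(features))
    adj <- matrix(0, G, G)
    for (i in seq_len(G)) {
      ord <- order(d[i, ])[-1L][seq_len(nn)]
      adj[i, ord] <- 1
    }
    adj <- pmax(adj, t(adj))
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    lab <- with_seed(seed, igraph::membership(igraph::cluster_louvain(gr)))
    return(stats::setNames(as.integer(lab), rownames(features)))
  }
  if (is.null(k)) {
    if (max(stats::dist(features[seq_len(min(G, 200L)), , drop = FALSE]))
        < 1e-10)
      return(stats::setNames(rep(1L, G), rownames(features)))
    kmax <- min(10L, G - 1L)
    wss <- with_seed(seed, vapply(seq_len(kmax + 1L), function(kk)
      stats::kmeans(features, kk, nstart = 5)$tot.withinss, numeric(1)))
    k <- elbow_k(wss)
  }
  if (method == "kmeans") {
    km <- with_seed(seed, stats::kmeans(features, k, nstart = 10))
    return(stats::setNames(km$cluster, rownames(features)))
  }
  # diagonal-covariance Gaussian mixture, k-means initialized
  lab <- with_seed(seed, gmm_diag(features, k))
  stats::setNames(lab, rownames(features))
}

gmm_diag <- function(X, k, max_iter = 100, tol = 1e-6) {
  G <- nrow(X); p <- ncol(X)
  km <- stats::kmeans(X, k, nstart = 5)
  mu <- km$centers
  sig <- matrix(stats::var(as.numeric(X)) + 1e-6, k, p)
  pi_k <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / G
  ll_old <- -Inf
  resp <- matrix(0, G, k)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      lg <- -0.5 * rowSums(sweep(X, 2, mu[j, ])^2 /
                             rep(sig[j, ], each = G)) -
        0.5 * sum(log(2 * pi * sig[j, ]))
      resp[, j] <- log(pi_k[j] + 1e-12) + lg
    }
    mx <- apply(resp, 1, max)
    pr <- exp(resp - mx)
    ll <- sum(mx + log(rowSums(pr)))
    pr <- pr / rowSums(pr)
    nk <- colSums(pr) + 1e-10
    pi_k <- nk / G
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(pr[, j] * X) / nk[j]
      sig[j, ] <- pmax(colSums(pr[, j] * sweep(X, 2, mu[j, ])^2) / nk[j],
                       1e-6)
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  max.col(pr)
}
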