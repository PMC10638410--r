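## Nested model definitions and likelihood-ratio machinery for the XDE and
## TDE tests. All nested fits share the spline basis (K chosen once per gene)
## and the random-effect structure; only the coefficient-space mean design
## A_s differs:
##   M2 / H1 : b_s = B x_s + u_s                (free B)
##   M0      : column beta_.v = 0               (covariate v removed)
##   M1      : beta_.v = c 1                    (pure mean shift: since the
##             basis sums to one, c x_sv shifts the whole curve)
##   H0      : every column of B constant       (b_s = 1 (x_s' c) + u_s)

nested_A <- function(X, K, v = NULL,
                     model = c("M2", "M0", "M1", "H0")) {
  model <- match.arg(model)
  Vp1 <- ncol(X)
  ones <- rep(1, K + 1L)
  lapply(seq_len(nrow(X)), function(s) {
    x <- X[s, ]
    full <- design_full(x, K)          # columns ordered (k, v) with v fastest
    switch(model,
      M2 = full,
      M0 = full[, (seq_len((K + 1L) * Vp1) - 1L) %% Vp1 != v, drop = FALSE],
      M1 = cbind(full[, (seq_len((K + 1L) * Vp1) - 1L) %% Vp1 != v,
                      drop = FALSE], x[v + 1L] * ones),
      H0 = ones %*% t(x))
  })
}

n_mean_params <- function(K, Vp1, model) {
  switch(model,
         M2 = (K + 1L) * Vp1,
         M0 = (K + 1L) * (Vp1 - 1L),
         M1 = (K + 1L) * (Vp1 - 1L) + 1L,
         H0 = Vp1)
}

# Fit one nested model given precomputed per-sample y and Phi.
fit_nested_one <- function(y_list, Phi_list, X, K, v, model, scalar_omega,
                           tol, max_iter) {
  A <- nested_A(X, K, v, model)
  femm_fit_core(y_list, Phi_list, A, scalar_omega,
                tol = tol, max_iter = max_iter)
}

#' Fit the nested XDE models M0, M1, M2 for one gene
#'
#' M0 removes covariate `v` entirely; M1 constrains its spline coefficients
#' to a single shared scalar (a constant curve shift); M2 is unconstrained.
#' Other covariates (e.g. batch dummies) remain free in all three models.
#' All fits share the basis `K` and the random-effect constraint determined
#' from the full model (`Omega = omega^2 I` iff `S <= V + K + 2`).
#'
#' @param gene_obs a [gene_observations()] object.
#' @param design S x (V+1) design matrix (leading intercept column).
#' @param v index of the tested covariate among the non-intercept columns
#'   (1 = first covariate).
#' @param K knot parameter (select once with [select_K()]).
#' @param tol,max_iter EM controls.
#' @return list with fits `m0`, `m1`, `m2`, log-likelihoods and the LLR
#'   statistics `llr_overall` (M2:M0), `llr_mean` (M1:M0), `llr_trend`
#'   (M2:M1), plus parameter-count differences.
#' @export
fit_nested_models <- function(gene_obs, design, v, K, tol = 1e-4,
                              max_iter = 150) {
  stopifnot(inherits(gene_obs, "gene_obs"))
  X <- align_design(design, gene_obs)
  V <- ncol(X) - 1L
  if (v < 1L || v > V) stop("v must index a non-intercept covariate")
  if (length(unique(X[, v + 1L])) < 2L)
    stop("tested covariate is constant across samples (non-identifiable)")
  S <- gene_obs$S
  scalar <- S <= V + K + 2
  basis <- make_basis(K)
  Phi_list <- lapply(gene_obs$t, function(tt) basis_matrix(basis, tt))
  fits <- lapply(c(M0 = "M0", M1 = "M1", M2 = "M2"), function(mod)
    fit_nested_one(gene_obs$y, Phi_list, X, K, v, mod, scalar, tol, max_iter))
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  list(m0 = fits$M0, m1 = fits$M1, m2 = fits$M2,
       loglik = ll,
       llr_overall = ll[["M2"]] - ll[["M0"]],
       llr_mean = ll[["M1"]] - ll[["M0"]],
       llr_trend = ll[["M2"]] - ll[["M1"]],
       df = c(overall = as.integer(K) + 1L, mean = 1L,
              trend = as.integer(K)),
       K = K, scalar_omega = scalar)
}

#' Chi-squared p-value for a likelihood-ratio statistic
#'
#' The statistic stored throughout the package is the raw log-likelihood
#' ratio; the asymptotic reference distribution applies to twice that value,
#' so this function computes `P(chisq_df >= 2 * llr)`. Negative inputs
#' (optimizer slack) are clipped to zero.
#'
#' @param llr raw log-likelihood ratio (alternative minus null).
#' @param df degrees of freedom (parameter-count difference).
#' @return upper-tail p-value.
#' @export
chisq_pvalue <- function(llr, df) {
  stopifnot(all(df >= 1))
  stats::pchisq(2 * pmax(llr, 0), df = df, lower.tail = FALSE)
}

# Analytic tail mass of the Gaussian-KDE fit to the permutation nulls:
# sum of kernel upper tails, floored at 1e-300.
kde_tail_p <- function(observed, null_llrs, floor = 1e-300) {
  null_llrs <- null_llrs[is.finite(null_llrs)]
  if (!length(null_llrs)) return(NA_real_)
  bw <- stats::bw.nrd0(null_llrs)
  if (!is.finite(bw) || bw <= 0)
    bw <- max(1e-8, abs(mean(null_llrs)) * 1e-6)
  p <- mean(stats::pnorm(observed, mean = null_llrs, sd = bw,
                         lower.tail = FALSE))
  max(min(p, 1), floor)
}

#' Permutation p-value from a refit callable
#'
#' Generic permutation-null engine: calls `refit_callable(i)` for
#' permutations `i = 1..n_perm` (each call must perform the scheme's
#' resampling/shuffling and return a null LLR), fits a Gaussian kernel
#' density with rule-of-thumb bandwidth to the null LLRs and returns the
#' analytic tail mass above `observed_llr`, floored at 1e-300. A failed
#' refit (error or non-finite value) is redrawn up to a 3x call budget.
#'
#' @param observed_llr observed log-likelihood ratio.
#' @param refit_callable function(i) -> numeric null LLR.
#' @param n_perm number of permutations (>= 20).
#' @return p-value.
#' @export
permutation_null_pvalue <- function(observed_llr, refit_callable,
                                    n_perm = 100) {
  if (n_perm < 20) stop("n_perm must be at least 20")
  nulls <- numeric(0)
  i <- 0L
  budget <- 3L * n_perm
  while (length(nulls) < n_perm && i < budget) {
    i <- i + 1L
    val <- tryCatch(refit_callable(i), error = function(e) {
      td_log("permutation refit failed (%s); redrawn", conditionMessage(e))
      NA_real_
    })
    if (is.finite(val)) nulls <- c(nulls, val)
  }
  if (length(nulls) < n_perm)
    warning("only ", length(nulls), " of ", n_perm,
            " permutations succeeded")
  kde_tail_p(observed_llr, nulls)
}

# ---- internal fast permutation loops ---------------------------------------
# These operate on pre-split per-sample y/t lists and return a matrix of
# null LLRs (n_perm x 3 for XDE: overall/mean/trend; n_perm x 1 for TDE).

perm_llrs_xde <- function(y_list, t_list, X, v, K, n_perm, scalar,
                          tol, max_iter, basis) {
  S <- length(y_list)
  out <- matrix(NA_real_, n_perm, 3L)
  for (i in seq_len(n_perm)) {
    ok <- FALSE
    for (attempt in 1:3) {
      yb <- vector("list", S); Pb <- vector("list", S)
      for (s in seq_len(S)) {
        idx <- sample.int(length(y_list[[s]]), replace = TRUE)
        yb[[s]] <- y_list[[s]][idx]
        Pb[[s]] <- basis_matrix(basis, t_list[[s]][idx])
      }
      Xp <- X
      Xp[, v + 1L] <- X[sample.int(S), v + 1L]
      res <- tryCatch({
        f0 <- fit_nested_one(yb, Pb, Xp, K, v, "M0", scalar, tol, max_iter)
        f1 <- fit_nested_one(yb, Pb, Xp, K, v, "M1", scalar, tol, max_iter)
        f2 <- fit_nested_one(yb, Pb, Xp, K, v, "M2", scalar, tol, max_iter)
        c(f2$loglik - f0$loglik, f1$loglik - f0$loglik,
          f2$loglik - f1$loglik)
      }, error = function(e) NULL)
      if (!is.null(res) && all(is.finite(res))) {
        out[i, ] <- res; ok <- TRUE; break
      }
    }
    if (!ok) td_log("permutation %d failed after 3 attempts", i)
  }
  out
}

perm_llrs_tde <- function(y_list, t_list, X, K, n_perm, scalar,
                          tol, max_iter, basis, shuffle_only = FALSE) {
  S <- length(y_list)
  out <- rep(NA_real_, n_perm)
  for (i in seq_len(n_perm)) {
    for (attempt in 1:3) {
      yb <- vector("list", S); Pb <- vector("list", S)
      for (s in seq_len(S)) {
        n <- length(y_list[[s]])
        idx <- if (shuffle_only) seq_len(n) else sample.int(n, replace = TRUE)
        yb[[s]] <- y_list[[s]][idx]
        # permute pseudotime within the sample
        Pb[[s]] <- basis_matrix(basis, sample(t_list[[s]][idx]))
      }
      res <- tryCatch({
        f0 <- fit_nested_one(yb, Pb, X, K, NULL, "H0", scalar, tol, max_iter)
        f1 <- fit_nested_one(yb, Pb, X, K, NULL, "M2", scalar, tol, max_iter)
        f1$loglik - f0$loglik
      }, error = function(e) NULL)
      if (!is.null(res) && is.finite(res)) { out[i] <- res; break }
    }
  }
  out
}
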