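#' Per-gene observations grouped by sample
#'
#' Bundles one gene's expression values and pseudotimes, split by sample, in
#' the layout expected by the functional mixed-effects model. Pseudotime must
#' already be rescaled to \[0, 1\] (per branch).
#'
#' @param y numeric vector of log-normalized expression values, one per cell.
#' @param t numeric vector of pseudotimes in \[0, 1\], aligned with `y`.
#' @param sample sample label per cell (character or factor).
#' @return object of class `gene_obs`: lists `y` and `t` split by sample,
#'   plus `samples`, `S` and `C` (cells per sample).
#' @export
gene_observations <- function(y, t, sample) {
  stopifnot(length(y) == length(t), length(y) == length(sample))
  if (any(!is.finite(y))) stop("missing or non-finite expression values")
  if (any(t < 0 | t > 1)) stop("pseudotime must be rescaled to [0, 1]")
  f <- factor(sample)
  f <- droplevels(f)
  obs <- list(y = split(as.numeric(y), f), t = split(as.numeric(t), f),
              samples = levels(f), S = nlevels(f),
              C = as.integer(table(f)))
  if (any(obs$C == 0L)) stop("every sample must contribute at least one cell")
  class(obs) <- "gene_obs"
  obs
}

#' @export
print.gene_obs <- function(x, ...) {
  cat(sprintf("gene_obs: %d samples, %d cells\n", x$S, sum(x$C)))
  invisible(x)
}

# ---- K selection by BIC -----------------------------------------------------

# Gaussian MLE log-likelihood of an OLS fit with residual sum of squares rss.
ols_loglik <- function(rss, n) {
  sig2 <- max(rss / n, 1e-300)
  -n / 2 * (log(2 * pi * sig2) + 1)
}

#' Select the spline knot parameter K by BIC
#'
#' For each candidate `K` in `0:K_max`, fits an ordinary least-squares spline
#' regression per sample and scores `K * S * log(sum(C_s)) - 2 * sum(l_K_s)`
#' where `l_K_s` is the per-sample Gaussian log-likelihood. Candidates with
#' any sample having `C_s <= K + 1` are skipped. Returns the minimizing `K`
#' (smallest on ties).
#'
#' @param gene_obs a [gene_observations()] object.
#' @param K_max maximum candidate K (default 20).
#' @param details if TRUE, return a list with the BIC table.
#' @export
select_K <- function(gene_obs, K_max = 20, details = FALSE) {
  stopifnot(inherits(gene_obs, "gene_obs"))
  S <- gene_obs$S
  ctot <- sum(gene_obs$C)
  bics <- rep(NA_real_, K_max + 1L)
  for (K in 0:K_max) {
    if (any(gene_obs$C <= K + 1L)) next
    basis <- make_basis(K)
    ll <- 0
    for (s in seq_len(S)) {
      Phi <- basis_matrix(basis, gene_obs$t[[s]])
      fit <- stats::lm.fit(Phi, gene_obs$y[[s]])
      ll <- ll + ols_loglik(sum(fit$residuals^2), length(fit$residuals))
    }
    bics[K + 1L] <- K * S * log(ctot) - 2 * ll
  }
  if (all(is.na(bics))) stop("no feasible K: too few cells per sample")
  K_star <- which.min(bics) - 1L
  if (details) list(K = K_star, bic = bics) else K_star
}

# Fast vectorized K selection for all genes sharing one set of cells:
# expr is genes x cells; t, sample aligned to columns.
select_K_all <- function(expr, t, sample, K_max = 20) {
  f <- droplevels(factor(sample))
  S <- nlevels(f)
  idx <- split(seq_along(t), f)
  Cs <- lengths(idx)
  ctot <- sum(Cs)
  G <- nrow(expr)
  y2 <- matrix(0, G, S)
  for (s in seq_len(S)) y2[, s] <- rowSums(expr[, idx[[s]], drop = FALSE]^2)
  bics <- matrix(NA_real_, G, K_max + 1L)
  for (K in 0:K_max) {
    if (any(Cs <= K + 1L)) next
    basis <- make_basis(K)
    ll <- matrix(0, G, S)
    for (s in seq_len(S)) {
      Phi <- basis_matrix(basis, t[idx[[s]]])
      Q <- qr.Q(qr(Phi))
      proj <- expr[, idx[[s]], drop = FALSE] %*% Q     # G x (K+1)
      rss <- pmax(y2[, s] - rowSums(proj^2), 0)
      n <- Cs[[s]]
      sig2 <- pmax(rss / n, 1e-300)
      ll[, s] <- -n / 2 * (log(2 * pi * sig2) + 1)
    }
    bics[, K + 1L] <- K * S * log(ctot) - 2 * rowSums(ll)
  }
  apply(bics, 1L, which.min) - 1L
}

# ---- core fit over coefficient-space designs --------------------------------

# A_list: per-sample (K+1) x p matrices mapping free parameters to spline
# coefficients (mean structure b_s = A_s theta + u_s). Used directly by the
# nested-model machinery; fit_em() builds the standard covariate design.
femm_fit_core <- function(y_list, Phi_list, A_list, scalar_omega,
                          tol = 1e-6, max_iter = 1000, fix_omega = NULL) {
  S <- length(y_list)
  d <- ncol(Phi_list[[1L]])
  p <- ncol(A_list[[1L]])
  # init: per-sample ridge OLS spline coefficients
  b0 <- matrix(0, S, d)
  s20 <- numeric(S)
  for (s in seq_len(S)) {
    Phi <- Phi_list[[s]]
    G <- crossprod(Phi)
    diag(G) <- diag(G) + 1e-8
    b0[s, ] <- solve(G, crossprod(Phi, y_list[[s]]))
    r <- y_list[[s]] - Phi %*% b0[s, ]
    s20[s] <- sum(r^2) / max(length(r) - d, 1L)
  }
  AtA <- matrix(0, p, p); Atb <- numeric(p)
  for (s in seq_len(S)) {
    AtA <- AtA + crossprod(A_list[[s]])
    Atb <- Atb + crossprod(A_list[[s]], b0[s, ])
  }
  diag(AtA) <- diag(AtA) + 1e-8
  theta0 <- as.numeric(solve(AtA, Atb))
  resid0 <- b0 - do.call(rbind, lapply(A_list, function(A)
    as.numeric(A %*% theta0)))
  if (S >= 2) {
    Om0 <- crossprod(resid0) / S / mean(s20)
  } else {
    Om0 <- diag(0.1, d)
  }
  Om0 <- Om0 + diag(1e-6, d)
  if (scalar_omega) Om0 <- diag(mean(diag(Om0)), d)
  # method-of-moments init for (alpha, eta) on per-sample residual variances
  mv <- mean(s20); vv <- stats::var(s20)
  if (!is.finite(vv) || vv <= 0 || S < 3) {
    a0 <- 3
  } else {
    a0 <- max(mv^2 / vv + 2, 1.05)
  }
  a0 <- min(a0, 1e3)
  e0 <- max(mv, 1e-8) * (a0 - 1)
  fixed <- !is.null(fix_omega)
  if (fixed) Om0 <- fix_omega + diag(1e-12, d)
  fit <- .femm_em_cpp(y_list, Phi_list, A_list, scalar_omega,
                      tol, as.integer(max_iter), a0, e0, Om0,
                      theta0, fixed)
  fit$scalar_omega <- scalar_omega
  fit
}

# ---- user-facing model fit --------------------------------------------------

# Align a design matrix to the sample order of a gene_obs object. Sample
# order inside gene_obs follows factor-level (lexicographic) order, which
# need not match the caller's row order, so rownames are authoritative.
align_design <- function(sample_design, gene_obs) {
  X <- as.matrix(sample_design)
  if (nrow(X) != gene_obs$S)
    stop("sample_design must have one row per sample")
  if (!is.null(rownames(X))) {
    missing_s <- setdiff(gene_obs$samples, rownames(X))
    if (length(missing_s))
      stop("design missing sample(s): ", paste(missing_s, collapse = ", "))
    X <- X[gene_obs$samples, , drop = FALSE]
  }
  X
}

# Coefficient-space design for the full covariate model: b_s = B x_s + u_s,
# vectorized theta = (beta_00,...,beta_0V, beta_10, ...): A_s = I_{K+1} (x) x_s'.
design_full <- function(x_s, K) kronecker(diag(K + 1L), t(x_s))

#' Fit the functional mixed-effects model for one gene
#'
#' Fits `y_s = Phi_s (B x_s + u_s) + eps_s` with sample random effects
#' `u_s ~ N(0, sigma_s^2 Omega)` and cell noise variance
#' `sigma_s^2 ~ IG(alpha, eta)` by EM, maximizing the marginal likelihood
#' over `Theta = (B, Omega, alpha, eta)`. The E-step is closed form
#' (normal-inverse-gamma conjugacy); the M-step solves weighted least squares
#' for `B`, a moment update for `Omega` and a profiled 1-D search for
#' `(alpha, eta)`.
#'
#' When `constrain_omega = "auto"`, the scalar constraint
#' `Omega = omega^2 I` is applied iff `S <= V + K + 2` (too few samples to
#' identify a full covariance).
#'
#' @param gene_obs a [gene_observations()] object.
#' @param sample_design S x (V+1) numeric design matrix, first column ones,
#'   rows ordered as `gene_obs$samples`.
#' @param K knot parameter (see [make_basis()]); choose with [select_K()].
#' @param constrain_omega "auto", "full" or "scalar".
#' @param tol absolute convergence tolerance on the marginal log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param fix_omega optional fixed covariance matrix (skips the Omega update);
#'   mainly for testing degenerate limits.
#' @return object of class `femm_fit`: `B` ((K+1) x (V+1)), `Omega`, `alpha`,
#'   `eta`, `loglik`, `trace`, `converged`, posterior summaries and the basis.
#' @export
fit_em <- function(gene_obs, sample_design, K,
                   constrain_omega = c("auto", "full", "scalar"),
                   tol = 1e-6, max_iter = 1000, fix_omega = NULL) {
  stopifnot(inherits(gene_obs, "gene_obs"))
  constrain_omega <- match.arg(constrain_omega)
  X <- align_design(sample_design, gene_obs)
  if (any(X[, 1L] != 1)) stop("first design column must be the intercept")
  V <- ncol(X) - 1L
  S <- gene_obs$S
  if (qr(X)$rank < ncol(X)) stop("sample_design is rank deficient")
  scalar <- switch(constrain_omega,
                   auto = S <= V + K + 2,
                   full = FALSE,
                   scalar = TRUE)
  basis <- make_basis(K)
  Phi_list <- lapply(gene_obs$t, function(tt) basis_matrix(basis, tt))
  A_list <- lapply(seq_len(S), function(s) design_full(X[s, ], K))
  core <- femm_fit_core(gene_obs$y, Phi_list, A_list, scalar,
                        tol = tol, max_iter = max_iter, fix_omega = fix_omega)
  if (!core$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  B <- matrix(core$theta, nrow = K + 1L, byrow = TRUE)
  dimnames(B) <- list(paste0("phi", 0:K), colnames(X) %||% paste0("x", 0:V))
  fit <- list(B = B, theta = core$theta, Omega = core$Omega,
              alpha = core$alpha, eta = core$eta, K = K, V = V,
              basis = basis, loglik = core$loglik, trace = core$trace,
              converged = core$converged, n_iter = core$n_iter,
              scalar_omega = core$scalar_omega,
              post = list(mean_u = core$post_mean_u, V = core$post_V,
                          q = core$q, E_inv_sigma2 = core$E_inv_sigma2,
                          E_sigma2 = core$E_sigma2),
              samples = gene_obs$samples, design = X)
  class(fit) <- "femm_fit"
  fit
}

#' @export
print.femm_fit <- function(x, ...) {
  cat(sprintf(
    "femm_fit: K = %d, V = %d, S = %d samples, loglik = %.4f (%s, %d iter)\n",
    x$K, x$V, length(x$samples), x$loglik,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Marginal log-likelihood of the functional mixed-effects model
#'
#' Evaluates the closed-form marginal likelihood obtained by integrating the
#' random effects and the inverse-gamma noise variance out of the model: each
#' sample contributes a multivariate-t term with location `Phi_s B x_s`,
#' scale `(eta/alpha) (Phi_s Omega Phi_s' + I)` and `2 alpha` degrees of
#' freedom, computed via the Woodbury identity in (K+1)-dimensional space.
#'
#' @param params list with `B`, `Omega`, `alpha`, `eta` (e.g. a `femm_fit`).
#' @param gene_obs a [gene_observations()] object.
#' @param sample_design S x (V+1) design matrix.
#' @param K knot parameter matching `params$B`.
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(params, gene_obs, sample_design, K) {
  stopifnot(inherits(gene_obs, "gene_obs"))
  X <- align_design(sample_design, gene_obs)
  basis <- make_basis(K)
  Phi_list <- lapply(gene_obs$t, function(tt) basis_matrix(basis, tt))
  A_list <- lapply(seq_len(gene_obs$S), function(s) design_full(X[s, ], K))
  theta <- as.numeric(t(params$B))
  .femm_loglik_cpp(gene_obs$y, Phi_list, A_list, theta,
                   params$Omega, params$alpha, params$eta)
}

#' Posterior summaries of sample-level effects
#'
#' Closed-form posterior moments of the latent `(u_s, sigma_s^2)` under the
#' fitted model: `E[u_s]`, `E[u_s u_s']` and `E[1/sigma_s^2]`.
#'
#' @param fit a `femm_fit`.
#' @return list with per-sample matrices/vectors `E_u` (S x (K+1)),
#'   `E_uu` (list of (K+1)^2 matrices), `E_inv_sigma2`, `E_sigma2`.
#' @export
posterior_effects <- function(fit) {
  stopifnot(inherits(fit, "femm_fit"))
  S <- length(fit$samples)
  E_u <- t(vapply(fit$post$mean_u, as.numeric, numeric(fit$K + 1L)))
  rownames(E_u) <- fit$samples
  E_uu <- lapply(seq_len(S), function(s) {
    m <- as.numeric(fit$post$mean_u[[s]])
    tcrossprod(m) + fit$post$E_sigma2[s] * fit$post$V[[s]]
  })
  list(E_u = E_u, E_uu = E_uu,
       E_inv_sigma2 = fit$post$E_inv_sigma2,
       E_sigma2 = fit$post$E_sigma2)
}

#' Fitted expression curves along pseudotime
#'
#' @param fit a `femm_fit`.
#' @param t_grid pseudotimes in \[0, 1\] at which to evaluate.
#' @param level "population" evaluates `phi(t)' B x`; "sample" evaluates
#'   `phi(t)' (B x_s + E[u_s])` for every sample.
#' @param x covariate vector (length V+1, leading 1) for the population
#'   curve; ignored at sample level.
#' @return numeric vector (population) or matrix samples x grid (sample).
#' @export
predict_curves <- function(fit, t_grid, level = c("population", "sample"),
                           x = NULL) {
  stopifnot(inherits(fit, "femm_fit"))
  level <- match.arg(level)
  Phi <- basis_matrix(fit$basis, t_grid)
  if (level == "population") {
    if (is.null(x)) x <- c(1, rep(0, fit$V))
    if (length(x) != fit$V + 1L) stop("x must have length V + 1")
    as.numeric(Phi %*% (fit$B %*% x))
  } else {
    E_u <- posterior_effects(fit)$E_u
    out <- t(Phi %*% (fit$B %*% t(fit$design) + t(E_u)))
    rownames(out) <- fit$samples
    out
  }
}
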