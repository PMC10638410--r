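# Independent oracles used across the suite. Each reimplements the target
# quantity from first principles, sharing no code with the package paths it
# checks.

# Cox-de Boor recursion for B-spline basis functions over a full knot
# vector (degree d, naive textbook recursion).
oracle_bspline <- function(t, knots, degree) {
  nb <- length(knots) - degree - 1L
  N <- function(i, d, x) {
    if (d == 0) {
      lo <- knots[i]; hi <- knots[i + 1L]
      # right-closed at the final interval
      if (hi >= max(knots) - 1e-14)
        return(as.numeric(x >= lo & x <= hi))
      return(as.numeric(x >= lo & x < hi))
    }
    left <- 0
    if (knots[i + d] > knots[i])
      left <- (x - knots[i]) / (knots[i + d] - knots[i]) * N(i, d - 1L, x)
    right <- 0
    if (knots[i + d + 1L] > knots[i + 1L])
      right <- (knots[i + d + 1L] - x) / (knots[i + d + 1L] - knots[i + 1L]) *
        N(i + 1L, d - 1L, x)
    left + right
  }
  vapply(seq_len(nb), function(i) N(i, degree, t), numeric(length(t)))
}

# Step-up Benjamini-Hochberg written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Logistic regression by hand-rolled IRLS (binomial counts successes/total).
oracle_irls_logistic <- function(X, successes, totals, max_iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- totals * mu * (1 - mu)
    z <- eta + (successes - totals * mu) / pmax(w, 1e-12)
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  vc <- solve(crossprod(X, as.numeric(totals * mu * (1 - mu)) * X))
  list(coef = as.numeric(beta), se = sqrt(diag(vc)))
}

# Full C x C multivariate-t marginal log-likelihood of the functional
# mixed-effects model, computed directly (no Woodbury): integrates
# u ~ N(0, s2 Omega), s2 ~ IG(alpha, eta) out of y ~ N(Phi(Bx + u), s2 I).
oracle_femm_loglik <- function(y_list, Phi_list, x_list, B, Omega,
                               alpha, eta) {
  ll <- 0
  for (s in seq_along(y_list)) {
    y <- y_list[[s]]; Phi <- Phi_list[[s]]
    C <- length(y)
    mu <- as.numeric(Phi %*% (B %*% x_list[[s]]))
    M <- Phi %*% Omega %*% t(Phi) + diag(C)
    q <- as.numeric(t(y - mu) %*% solve(M, y - mu))
    ll <- ll + lgamma(alpha + C / 2) - lgamma(alpha) + alpha * log(eta) -
      C / 2 * log(2 * pi) - 0.5 * determinant(M)$modulus -
      (alpha + C / 2) * log(eta + q / 2)
  }
  as.numeric(ll)
}

# Brute-force 2-D quadrature of the same marginal for K = 0 (scalar u).
oracle_femm_loglik_quad <- function(y, mu0, omega2, alpha, eta) {
  C <- length(y)
  integrand <- function(s2) {
    vapply(s2, function(v) {
      f_u <- function(u)
        vapply(u, function(uu)
          prod(stats::dnorm(y, mu0 + uu, sqrt(v))) *
            stats::dnorm(uu, 0, sqrt(v * omega2)), numeric(1))
      stats::integrate(f_u, -12 * sqrt(v * omega2) - 3,
                       12 * sqrt(v * omega2) + 3,
                       rel.tol = 1e-10)$value *
        eta^alpha / gamma(alpha) * v^(-alpha - 1) * exp(-eta / v)
    }, numeric(1))
  }
  log(stats::integrate(integrand, 1e-4, 60, rel.tol = 1e-9)$value)
}

# Random gene_obs fixture from the generative model.
make_obs_fixture <- function(S = 4, C = 40, K = 2, V = 0, seed = 1,
                             omega2 = 0.1, alpha = 3, eta = 2,
                             beta_v = 0) {
  withr::with_seed(seed, {
    samples <- paste0("s", seq_len(S))
    tt <- runif(S * C)
    samp <- rep(samples, each = C)
    basis <- make_basis(K)
    Phi <- basis$eval(tt)
    X <- matrix(1, S, 1L)
    if (V >= 1)
      X <- cbind(X, matrix(rep(c(1, 0), length.out = S * V), S, V))
    dimnames(X) <- list(samples,
                        c("intercept", if (V >= 1) paste0("x", seq_len(V))))
    B <- matrix(rnorm((K + 1) * (V + 1)), K + 1, V + 1)
    if (V >= 1) B[, 2] <- beta_v
    sig2 <- eta / rgamma(S, alpha)
    y <- numeric(S * C)
    for (s in seq_len(S)) {
      idx <- which(samp == samples[s])
      u <- rnorm(K + 1, 0, sqrt(sig2[s] * omega2))
      y[idx] <- Phi[idx, , drop = FALSE] %*% (B %*% X[s, ] + u) +
        rnorm(C, 0, sqrt(sig2[s]))
    }
    list(obs = gene_observations(y, tt, samp), X = X, B = B, K = K,
         t = tt, samp = samp, y = y)
  })
}

# Small multi-gene dataset for end-to-end tests.
make_sim_dataset <- function(G = 20, S = 6, cells = c(40, 60), seed = 1,
                             beta_effect = 0, K_true = 3) {
  simulate_femm_data(sim_config(S = S, G = G, cells_per_sample = cells,
                                K_true = K_true, beta_effect = beta_effect,
                                seed = seed))
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
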