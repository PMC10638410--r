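intercept_design <- function(samples)
  matrix(1, length(samples), 1L, dimnames = list(samples, "intercept"))

test_that("BIC selects K = 0 for a constant gene and tracks the true K", {
  # constant gene + small noise
  obs <- withr::with_seed(11, gene_observations(
    2 + rnorm(600, 0, 0.2), runif(600), rep(paste0("s", 1:3), each = 200)))
  expect_identical(select_K(obs, K_max = 8), 0L)
  # strongly curved gene generated from a K = 5 basis, low noise
  hits <- vapply(1:20, function(i) withr::with_seed(100 + i, {
    tt <- runif(600)
    Phi <- make_basis(5)$eval(tt)
    beta <- c(0, 2, -2, 2, -2, 0) * 2
    y <- as.numeric(Phi %*% beta) + rnorm(600, 0, 0.1)
    select_K(gene_observations(y, tt, rep(paste0("s", 1:3), each = 200)),
             K_max = 10)
  }), integer(1))
  expect_gte(mean(hits %in% 4:6), 0.9)
})

test_that("single-sample fit with Omega fixed at zero matches OLS", {
  fx <- make_obs_fixture(S = 1, C = 80, K = 3, seed = 3)
  fit <- suppressWarnings(
    fit_em(fx$obs, intercept_design("s1"), K = 3,
           fix_omega = matrix(0, 4, 4), tol = 1e-10, max_iter = 2000))
  Phi <- make_basis(3)$eval(fx$obs$t[[1]])
  ols <- as.numeric(stats::lm.fit(Phi, fx$obs$y[[1]])$coefficients)
  expect_lt(max(abs(as.numeric(fit$B) - ols)), 1e-6)
})

test_that("near-noiseless data is interpolated by the fitted curves", {
  withr::with_seed(5, {
    tt <- runif(200)
    Phi <- make_basis(2)$eval(tt)
    beta <- c(1, 3, 0.5)
    y <- as.numeric(Phi %*% beta) + rnorm(200, 0, 1e-7)
  })
  obs <- gene_observations(y, tt, rep(c("s1", "s2"), each = 100))
  fit <- suppressWarnings(fit_em(obs, intercept_design(c("s1", "s2")),
                                 K = 2, tol = 1e-12, max_iter = 3000))
  # sample-level fitted values (population + posterior sample effect);
  # only sigma^2 * Omega is identified in the noiseless limit, so a common
  # shift may sit in E[u] rather than in B
  basis <- make_basis(2)
  E_u <- posterior_effects(fit)$E_u
  for (s in 1:2) {
    pred <- as.numeric(basis$eval(obs$t[[s]]) %*%
                         (fit$B[, 1] + E_u[s, ]))
    expect_lt(max(abs(pred - obs$y[[s]])), 1e-5)
  }
})

test_that("marginal log-likelihood agrees with the direct C x C oracle", {
  for (seed in 1:8) {
    fx <- make_obs_fixture(S = 3, C = 25, K = 2, V = 0, seed = seed)
    params <- list(B = fx$B[, 1, drop = FALSE],
                   Omega = crossprod(matrix(rnorm(9), 3)) / 3 + diag(0.05, 3),
                   alpha = 2.5, eta = 1.5)
    got <- marginal_loglik(params, fx$obs, fx$X[, 1, drop = FALSE], K = 2)
    want <- oracle_femm_loglik(
      fx$obs$y, lapply(fx$obs$t, function(tt) make_basis(2)$eval(tt)),
      lapply(seq_len(3), function(s) fx$X[s, 1]),
      params$B, params$Omega, params$alpha, params$eta)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("marginal log-likelihood matches 2-D quadrature (K = 0)", {
  y <- c(0.4, -0.2, 0.9, 0.1)
  params <- list(B = matrix(0.3), Omega = matrix(0.5), alpha = 3, eta = 2)
  obs <- gene_observations(y, rep(0.5, 4), rep("s1", 4))
  got <- marginal_loglik(params, obs, matrix(1, 1, 1), K = 0)
  want <- oracle_femm_loglik_quad(y, 0.3, 0.5, 3, 2)
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("marginal log-likelihood is invariant to within-sample cell order", {
  fx <- make_obs_fixture(S = 2, C = 30, K = 2, seed = 9)
  params <- list(B = fx$B[, 1, drop = FALSE], Omega = diag(0.2, 3),
                 alpha = 3, eta = 2)
  X1 <- fx$X[, 1, drop = FALSE]
  ll1 <- marginal_loglik(params, fx$obs, X1, K = 2)
  perm_obs <- withr::with_seed(1, {
    idx <- lapply(fx$obs$C, sample)
    gene_observations(
      unlist(Map(function(y, i) y[i], fx$obs$y, idx)),
      unlist(Map(function(t, i) t[i], fx$obs$t, idx)),
      rep(fx$obs$samples, fx$obs$C))
  })
  expect_equal(marginal_loglik(params, perm_obs, X1, K = 2), ll1,
               tolerance = 1e-10)
})

test_that("EM trace is monotone and its final value equals the closed form", {
  for (seed in 1:20) {
    fx <- make_obs_fixture(S = sample(2:6, 1), C = 30, K = sample(0:3, 1),
                           seed = 200 + seed)
    fit <- suppressWarnings(fit_em(fx$obs, fx$X[, 1, drop = FALSE],
                                   K = fx$K, tol = 1e-6, max_iter = 300))
    expect_true(all(diff(fit$trace) > -1e-8))
    direct <- marginal_loglik(fit, fx$obs, fx$X[, 1, drop = FALSE], K = fx$K)
    expect_equal(fit$loglik, direct, tolerance = 1e-6)
  }
})

test_that("scalar-Omega constraint engages exactly when S <= V + K + 2", {
  fx_small <- make_obs_fixture(S = 5, C = 25, K = 2, V = 1, seed = 31)
  fit_small <- suppressWarnings(fit_em(fx_small$obs, fx_small$X, K = 2))   # 5 <= 1 + 2 + 2
  expect_true(fit_small$scalar_omega)
  fx_big <- make_obs_fixture(S = 8, C = 25, K = 2, V = 1, seed = 32)
  fit_big <- suppressWarnings(fit_em(fx_big$obs, fx_big$X, K = 2))         # 8 > 5
  expect_false(fit_big$scalar_omega)
  fit_forced <- suppressWarnings(
    fit_em(fx_big$obs, fx_big$X, K = 2, constrain_omega = "scalar"))
  expect_true(fit_forced$scalar_omega)
})

test_that("posterior moments follow the conjugate updates", {
  fx <- make_obs_fixture(S = 3, C = 40, K = 1, seed = 41)
  X1 <- fx$X[, 1, drop = FALSE]
  fit <- suppressWarnings(fit_em(fx$obs, X1, K = 1, tol = 1e-8,
                                 max_iter = 500))
  post <- posterior_effects(fit)
  basis <- make_basis(1)
  for (s in 1:3) {
    Phi <- basis$eval(fx$obs$t[[s]])
    r <- fx$obs$y[[s]] - as.numeric(Phi %*% (fit$B %*% X1[s, ]))
    Vs <- solve(crossprod(Phi) + solve(fit$Omega))
    m <- as.numeric(Vs %*% crossprod(Phi, r))
    q <- sum(r^2) - sum(crossprod(Phi, r) * m)
    Cs <- length(r)
    expect_equal(post$E_u[s, ], m, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(post$E_inv_sigma2[s],
                 (fit$alpha + Cs / 2) / (fit$eta + q / 2), tolerance = 1e-6)
  }
  # degenerate prior: Omega -> 0 forces E[u] -> 0
  fit0 <- suppressWarnings(
    fit_em(fx$obs, X1, K = 1, fix_omega = matrix(0, 2, 2)))
  expect_lt(max(abs(posterior_effects(fit0)$E_u)), 1e-6)
})

test_that("a constant covariate column shifts population curves uniformly", {
  fx <- make_obs_fixture(S = 6, C = 30, K = 2, V = 1, seed = 51)
  fit <- suppressWarnings(fit_em(fx$obs, fx$X, K = 2))
  cshift <- 1.7
  fit$B[, 2] <- cshift
  grid <- seq(0, 1, length.out = 50)
  c0 <- predict_curves(fit, grid, "population", x = c(1, 0))
  c1 <- predict_curves(fit, grid, "population", x = c(1, 1))
  expect_equal(c1 - c0, rep(cshift, 50), tolerance = 1e-10)
  # K = 0 fits are constant in t
  fit0 <- suppressWarnings(fit_em(fx$obs, fx$X, K = 0))
  expect_equal(diff(range(predict_curves(fit0, grid, "population"))), 0)
})

test_that("sample-level curves track the sample random effects", {
  fx <- make_obs_fixture(S = 6, C = 60, K = 2, seed = 61, omega2 = 0.6)
  X1 <- fx$X[, 1, drop = FALSE]
  fit <- suppressWarnings(fit_em(fx$obs, X1, K = 2, tol = 1e-8,
                                 max_iter = 1000))
  grid <- seq(0, 1, length.out = 30)
  sc <- predict_curves(fit, grid, "sample")
  expect_identical(dim(sc), c(6L, 30L))
  # per-sample curves fit each sample's cells better than the population curve
  pop <- predict_curves(fit, grid, "population")
  basis <- make_basis(2)
  rs_sample <- rs_pop <- 0
  for (s in 1:6) {
    Phi <- basis$eval(fx$obs$t[[s]])
    E_u <- posterior_effects(fit)$E_u[s, ]
    rs_sample <- rs_sample +
      sum((fx$obs$y[[s]] - Phi %*% (fit$B %*% X1[s, ] + E_u))^2)
    rs_pop <- rs_pop + sum((fx$obs$y[[s]] - Phi %*% (fit$B %*% X1[s, ]))^2)
  }
  expect_lt(rs_sample, rs_pop)
})
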