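test_that("Jaccard cutoff matches the hypergeometric enumeration oracle", {
  cells <- paste0("c", 1:1000)
  branch <- cells[1:50]
  # exact null: overlap X ~ Hypergeometric(50, 950, 50); J = X/(100 - X)
  xs <- 0:50
  pmf <- stats::dhyper(xs, 50, 950, 50)
  jvals <- xs / (100 - xs)
  exact_q99 <- jvals[min(which(cumsum(pmf) >= 0.99))]
  got <- jaccard_cutoff(branch, cells, n_draws = 4000, q = 0.99, seed = 7)
  # allow one overlap unit of Monte-Carlo slack on the discrete grid
  lo <- jvals[max(min(which(cumsum(pmf) >= 0.99)) - 1L, 1L)]
  hi <- jvals[min(min(which(cumsum(pmf) >= 0.99)) + 1L, length(jvals))]
  expect_gte(got, lo)
  expect_lte(got, hi)
  expect_gte(got, 0)
  # degenerate: branch = universe -> cutoff 1
  expect_equal(jaccard_cutoff(cells, cells, n_draws = 50, seed = 1), 1)
  expect_error(jaccard_cutoff(paste0("x", 1:5), cells), "subset")
})

test_that("branch proportions: trivial cases and shared-cell counting", {
  soc <- stats::setNames(rep(c("a", "b"), each = 10), paste0("c", 1:20))
  branches <- list(b1 = paste0("c", 1:10), b2 = paste0("c", 11:20))
  bp <- branch_proportions(branches, soc)
  expect_equal(bp$proportions["a", "b1"], 1)
  expect_equal(bp$proportions["a", "b2"], 0)
  expect_equal(unname(bp$variance["b1"]), 0.5)
  # identical samples -> zero variance
  branches2 <- list(b1 = paste0("c", c(1:5, 11:15)))
  bp2 <- branch_proportions(branches2, soc)
  expect_equal(unname(bp2$variance["b1"]), 0)
  # branches sharing early cells double-count them per branch
  shared <- list(b1 = paste0("c", 1:15), b2 = paste0("c", c(1:5, 16:20)))
  bp3 <- branch_proportions(shared, soc)
  expect_equal(sum(bp3$counts["a", ]), 15)   # c1..c5 counted in both
})

test_that("binomial topology test matches the IRLS oracle", {
  counts <- c(30, 35, 28, 33, 60, 55, 62, 58)
  totals <- rep(100, 8)
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = 4))
  rownames(X) <- paste0("s", 1:8)
  soc <- stats::setNames(rep(paste0("s", 1:8), totals),
                         paste0("c", 1:800))
  branch_cells <- unlist(lapply(1:8, function(s)
    paste0("c", (s - 1) * 100 + seq_len(counts[s]))))
  bp <- branch_proportions(list(br = branch_cells), soc)
  res <- test_topology_binomial(bp, X)
  oracle <- oracle_irls_logistic(X, counts, totals)
  expect_equal(res$estimate, unname(oracle$coef[2]), tolerance = 1e-6)
  expect_equal(res$se, unname(oracle$se[2]), tolerance = 1e-6)
  expect_equal(res$p_value,
               unname(2 * pnorm(-abs(oracle$coef[2] / oracle$se[2]))),
               tolerance = 1e-6)
})

test_that("identical group proportions give a null binomial test", {
  counts <- rep(40, 6); totals <- rep(100, 6)
  X <- cbind(intercept = 1, group = rep(c(0, 1), 3))
  rownames(X) <- paste0("s", 1:6)
  soc <- stats::setNames(rep(paste0("s", 1:6), totals), paste0("c", 1:600))
  branch_cells <- unlist(lapply(1:6, function(s)
    paste0("c", (s - 1) * 100 + 1:40)))
  bp <- branch_proportions(list(br = branch_cells), soc)
  res <- test_topology_binomial(bp, X)
  expect_lt(abs(res$estimate), 1e-8)
  expect_gt(res$p_value, 0.99)
  # complete separation is flagged, not estimated
  sep_counts <- c(0, 0, 0, 100, 100, 100)
  bc <- unlist(lapply(4:6, function(s)
    paste0("c", (s - 1) * 100 + 1:100)))
  bp_sep <- branch_proportions(list(br = bc), soc)
  X_sep <- cbind(intercept = 1, group = rep(c(0, 1), each = 3))
  rownames(X_sep) <- paste0("s", 1:6)
  res_sep <- test_topology_binomial(bp_sep, X_sep)
  expect_true(is.na(res_sep$p_value))
})

test_that("multinomial logit reduces to binomial when L = 2", {
  counts <- cbind(b1 = c(30, 35, 28, 33, 60, 55, 62, 58),
                  b2 = c(70, 65, 72, 67, 40, 45, 38, 42))
  rownames(counts) <- paste0("s", 1:8)
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = 4))
  rownames(X) <- paste0("s", 1:8)
  mn <- test_topology_multinomial(counts, X)
  orc <- oracle_irls_logistic(X, counts[, 1], rowSums(counts))
  expect_identical(attr(mn, "reference_branch"), "b2")
  expect_equal(mn$estimate, unname(orc$coef[2]), tolerance = 1e-6)
  expect_equal(mn$se, unname(orc$se[2]), tolerance = 1e-6)
})

test_that("multinomial logit recovers simulated coefficients", {
  # 3 branches, known baseline-category coefficients vs reference branch 3
  beta <- rbind(c(0.2, 0.8), c(-0.4, -0.6))   # (branch, intercept/group)
  S <- 40
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = S / 2))
  rownames(X) <- paste0("s", 1:S)
  cover <- vapply(1:30, function(rep_i) {
    counts <- withr::with_seed(900 + rep_i, {
      t(vapply(1:S, function(s) {
        eta <- as.numeric(beta %*% X[s, ])
        p <- c(exp(eta), 1); p <- p / sum(p)
        as.numeric(stats::rmultinom(1, 400, p))
      }, numeric(3)))
    })
    rownames(counts) <- rownames(X)
    colnames(counts) <- paste0("b", 1:3)
    fit <- test_topology_multinomial(counts, X)
    # group log-odds per branch in the generator (vs implicit ref b3),
    # re-expressed against the fitted reference branch
    g <- c(b1 = 0.8, b2 = -0.6, b3 = 0)
    ref <- attr(fit, "reference_branch")
    truth <- g[fit$branch_id] - g[ref]
    all(abs(fit$estimate - truth) <= 2 * fit$se)
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("bootstrap detection: clean branches are redetected", {
  # three well-separated arms emanating from an origin blob
  withr::with_seed(17, {
    n <- 80
    arm <- function(dx, dy) cbind(runif(n, 0.5, 3) * dx + rnorm(n, 0, 0.05),
                                  runif(n, 0.5, 3) * dy + rnorm(n, 0, 0.05))
    emb <- rbind(cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05)),
                 arm(1, 0), arm(-1, 0.3), arm(0, 1))
    rownames(emb) <- paste0("c", seq_len(4 * n))
    expr <- matrix(rnorm(2 * 4 * n), 2,
                   dimnames = list(c("g1", "g2"), rownames(emb)))
  })
  soc <- stats::setNames(rep(c("sA", "sB"), 2 * n), rownames(emb))
  ds <- multisample_dataset(expr, soc, embedding = emb)
  tr <- infer_trajectory(ds, origin = which.min(
    rowSums(cluster_cells(emb, k = 4, seed = 1)$centers^2)), k = 4, seed = 1)
  dr <- detection_rates(ds, tr, n_bootstraps = 30, seed = 5,
                        n_null_draws = 300)
  expect_true(all(dr$detection_rate >= 0.9))
  expect_true(all(dr$jaccard_cutoff > 0 & dr$jaccard_cutoff <= 1))
})

test_that("detection rate does not rise when a branch is subsampled away", {
  withr::with_seed(23, {
    n <- 60
    emb <- rbind(cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05)),
                 cbind(runif(n, 0.5, 3), rnorm(n, 0, 0.05)),
                 cbind(-runif(n, 0.5, 3), rnorm(n, 0, 0.05)))
    rownames(emb) <- paste0("c", seq_len(3 * n))
    expr <- matrix(rnorm(3 * n), 1,
                   dimnames = list("g1", rownames(emb)))
  })
  soc <- stats::setNames(rep(c("sA", "sB"), length.out = 3 * n),
                         rownames(emb))
  ds <- multisample_dataset(expr, soc, embedding = emb)
  tr <- infer_trajectory(ds, origin = 1L, k = 3, seed = 1)
  # find the branch holding the positive-x arm, then subsample it
  arm_cells <- rownames(emb)[(n + 1):(2 * n)]
  overlap <- vapply(tr$branches, function(b)
    length(intersect(b$cells, arm_cells)), numeric(1))
  target <- tr$branches[[which.max(overlap)]]
  rate0 <- detection_rates(ds, tr, n_bootstraps = 20, seed = 9,
                           n_null_draws = 200)
  ds_red <- simulate_branch_reduction(ds, intersect(target$cells, arm_cells),
                                      fraction = 0.9, seed = 3)
  tr_red <- infer_trajectory(ds_red, origin = 1L, k = 3, seed = 1)
  expect_lt(length(ds_red$cell_ids), length(ds$cell_ids))
  expect_identical(nrow(tr_red$mst_edges), 2L)
})
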