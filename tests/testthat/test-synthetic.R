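test_that("generator is reproducible and honors its stated world", {
  cfg <- sim_config(S = 4, G = 6, cells_per_sample = c(30, 40), seed = 9)
  sim1 <- simulate_femm_data(cfg)
  sim2 <- simulate_femm_data(cfg)
  expect_identical(get_expression(sim1$dataset), get_expression(sim2$dataset))
  expect_identical(sim1$truth$pseudotime, sim2$truth$pseudotime)
  ds <- sim1$dataset
  expect_identical(length(ds$gene_ids), 6L)
  expect_identical(nlevels(ds$sample_of_cell), 4L)
  expect_true(all(ds$sample_design[, 1] == 1))
  expect_true(all(sim1$truth$pseudotime >= 0 & sim1$truth$pseudotime <= 1))
})

test_that("zero random effect makes sample curves identical up to noise", {
  sim <- simulate_femm_data(sim_config(S = 4, G = 3, omega2 = 0,
                                       cells_per_sample = c(200, 200),
                                       alpha = 50, eta = 49, seed = 4))
  # per-sample spline fits of one gene should nearly coincide
  ds <- sim$dataset
  pt <- sim$truth$pseudotime
  y <- get_expression(ds)[1, ]
  basis <- make_basis(3)
  grid <- seq(0.05, 0.95, length.out = 20)
  curves <- t(vapply(levels(ds$sample_of_cell), function(s) {
    idx <- ds$cell_ids[ds$sample_of_cell == s]
    co <- stats::lm.fit(basis$eval(pt[idx]), y[idx])$coefficients
    as.numeric(basis$eval(grid) %*% co)
  }, numeric(20)))
  expect_lt(max(apply(curves, 2, stats::sd)), 0.25)
})

test_that("per-sample noise variances follow the inverse-gamma law", {
  # large-sample check of the generator's noise layer
  sim <- simulate_femm_data(sim_config(S = 60, G = 1, omega2 = 0,
                                       cells_per_sample = c(150, 150),
                                       K_true = 0, curve_sd = 0,
                                       alpha = 3, eta = 2, seed = 21))
  ds <- sim$dataset
  y <- get_expression(ds)[1, ]
  s2 <- vapply(levels(ds$sample_of_cell), function(s)
    stats::var(y[ds$cell_ids[ds$sample_of_cell == s]]), numeric(1))
  ref <- withr::with_seed(22, 2 / rgamma(10000, 3))
  expect_gt(stats::ks.test(s2, ref)$p.value, 0.01)
})

test_that("median matching is a fixed point on identical groups, exact on a toy", {
  # toy: 2 intervals; group medians (1, 3) vs (2, 5) -> shifts +1, +2
  expr <- matrix(c(1, 1, 2, 2, 3, 3, 5, 5), 1,
                 dimnames = list("g1", paste0("c", 1:8)))
  soc <- stats::setNames(rep(c("sA", "sB", "sA", "sB"), each = 2),
                         colnames(expr))
  pt <- stats::setNames(c(0.1, 0.2, 0.15, 0.25, 0.7, 0.8, 0.75, 0.85),
                        colnames(expr))
  ds <- multisample_dataset(expr, soc)
  grp <- c(sA = "g0", sB = "g1")
  nulled <- make_null_by_median_matching(ds, grp, pt, n_intervals = 2)
  out <- get_expression(nulled)[1, ]
  expect_equal(unname(out[1:2]), c(2, 2))   # +1 in interval 1
  expect_equal(unname(out[5:6]), c(5, 5))   # +2 in interval 2
  expect_equal(unname(out[c(3, 4, 7, 8)]), c(2, 2, 5, 5))  # untouched
  # identical groups: fixed point (every interval has the same values in
  # both groups, so no shift is applied)
  expr_same <- matrix(rep(c(1, 3), 4), 1,
                      dimnames = list("g1", paste0("c", 1:8)))
  ds_same <- multisample_dataset(expr_same, soc)
  pt_same <- stats::setNames(rep(c(0.1, 0.6), 4), colnames(expr_same))
  same <- make_null_by_median_matching(ds_same, grp, pt_same, 2)
  expect_identical(get_expression(same), expr_same)
})

test_that("median matching equalizes group medians and is idempotent", {
  sim <- make_sim_dataset(G = 15, S = 6, cells = c(60, 80), seed = 31)
  ds <- sim$dataset
  pt <- sim$truth$pseudotime
  grp <- stats::setNames(rep(c("g0", "g1"), 3),
                         levels(ds$sample_of_cell))
  n1 <- make_null_by_median_matching(ds, grp, pt, n_intervals = 20)
  # recomputation oracle: group medians agree per gene x interval
  gl <- grp[as.character(n1$sample_of_cell)]
  iv <- pmin(floor(pt[n1$cell_ids] * 20), 19) + 1
  ex <- get_expression(n1)
  for (i in unique(iv)) {
    i0 <- which(iv == i & gl == "g0"); i1 <- which(iv == i & gl == "g1")
    if (!length(i0) || !length(i1)) next
    m0 <- apply(ex[, i0, drop = FALSE], 1, median)
    m1 <- apply(ex[, i1, drop = FALSE], 1, median)
    expect_lt(max(abs(m0 - m1)), 1e-12)
  }
  n2 <- make_null_by_median_matching(n1, grp, pt, n_intervals = 20)
  expect_equal(get_expression(n2), get_expression(n1), tolerance = 1e-12)
})

test_that("source-gene selection stratifies by dynamic strength", {
  withr::with_seed(41, {
    G <- 60; n <- 400
    tt <- runif(n)
    expr <- matrix(rnorm(G * n, 1, 0.3), G,
                   dimnames = list(sprintf("g%03d", 1:G),
                                   sprintf("c%04d", 1:n)))
    # plant 10 strongly dynamic genes (high SD and high F)
    for (g in 1:10)
      expr[g, ] <- expr[g, ] + 3 * sin(2 * pi * tt + g)
  })
  soc <- stats::setNames(rep(c("sA", "sB"), n / 2), colnames(expr))
  ds <- multisample_dataset(expr, soc)
  pt <- stats::setNames(tt, colnames(expr))
  src <- select_source_genes(ds, c("sA", "sB"), pt, n_gold = 7,
                             n_strengths = 4, seed = 1)
  strata <- src$stratum[!is.na(src$stratum)]
  expect_identical(length(strata), 7L)
  expect_true(max(table(strata)) - min(table(strata)) <= 1)
  top <- src$gene[!is.na(src$stratum) & src$stratum == 4]
  expect_true(all(top %in% sprintf("g%03d", 1:10)))
  expect_error(select_source_genes(ds, c("sA", "sB"), pt, n_gold = 1000),
               "gs_fraction")
})

test_that("spike-in types create the intended contrasts", {
  sim <- make_sim_dataset(G = 60, S = 6, cells = c(80, 100), seed = 51)
  ds <- sim$dataset
  pt <- sim$truth$pseudotime
  grp <- stats::setNames(rep(c("g0", "g1"), 3), levels(ds$sample_of_cell))
  nulled <- make_null_by_median_matching(ds, grp, pt)
  labels <- gold_standard_labels(nulled$gene_ids, gs_fraction = 0.2,
                                 seed = 3)
  expect_identical(sum(labels$truth != "null"), 12L)
  src <- select_source_genes(nulled, names(grp)[grp == "g0"], pt,
                             candidate_genes =
                               labels$gene[labels$truth == "null"],
                             n_gold = 12, seed = 3)
  sp0 <- spike_in(nulled, labels, src, strength_level = 2, grp,
                  multiplier = 0, seed = 7)
  expect_identical(get_expression(sp0$dataset), get_expression(nulled))
  sp <- spike_in(nulled, labels, src, strength_level = 2, grp, seed = 7)
  expect_identical(sum(!is.na(sp$labels$source_gene)), 12L)
  gl <- grp[as.character(ds$sample_of_cell)]
  base <- get_expression(nulled); spiked <- get_expression(sp$dataset)
  # mean-type: group-0 mean rises, and monotonically with the multiplier
  mean_genes <- labels$gene[labels$truth == "mean"]
  shift1 <- rowMeans((spiked - base)[mean_genes, gl == "g0", drop = FALSE])
  expect_true(all(shift1 > 0))
  expect_true(all((spiked - base)[mean_genes, gl == "g1"] == 0))
  sp2 <- spike_in(nulled, labels, src, strength_level = 2, grp,
                  multiplier = 2, seed = 7)
  shift2 <- rowMeans((get_expression(sp2$dataset) -
                        base)[mean_genes, gl == "g0", drop = FALSE])
  expect_true(all(shift2 > shift1))
  # trend-type: near-zero group mean contrast but nonzero trend contrast
  trend_genes <- labels$gene[labels$truth == "trend"]
  for (g in trend_genes) {
    d <- spiked[g, ] - base[g, ]
    m0 <- mean(d[gl == "g0"]); m1 <- mean(d[gl == "g1"])
    expect_lt(abs(m0 - m1), 0.35)
    # added signal correlates with pseudotime structure only in group 0
    src_g <- sp$labels$source_gene[sp$labels$gene == g]
    sig <- base[src_g, ]
    c0 <- stats::cor(d[gl == "g0"], sig[gl == "g0"])
    c1 <- abs(stats::cor(d[gl == "g1"], sig[gl == "g1"]))
    expect_gt(c0, 0.99)
    expect_lt(c1, 0.5)
  }
  # both-type: group 0 only, uncentered
  both_genes <- labels$gene[labels$truth == "both"]
  expect_true(all((spiked - base)[both_genes, gl == "g1"] == 0))
  expect_true(all(rowMeans((spiked - base)[both_genes, gl == "g0",
                                           drop = FALSE]) > 0))
})

test_that("branch reduction subsamples only the requested cells", {
  sim <- make_sim_dataset(G = 4, S = 4, cells = c(50, 50), seed = 61)
  ds <- sim$dataset
  branch_cells <- ds$cell_ids[1:100]
  expect_identical(simulate_branch_reduction(ds, branch_cells, 0), ds)
  red <- simulate_branch_reduction(ds, branch_cells, 0.8, seed = 2)
  kept <- intersect(red$cell_ids, branch_cells)
  expect_identical(length(kept), 20L)
  expect_true(all(setdiff(ds$cell_ids, branch_cells) %in% red$cell_ids))
  expect_error(simulate_branch_reduction(ds, branch_cells, 1), "fraction")
  # half-samples designation
  half <- simulate_branch_reduction(ds, ds$cell_ids, 0.5,
                                    samples = c("s01", "s02"), seed = 3)
  tab <- table(half$sample_of_cell)
  expect_true(all(tab[c("s03", "s04")] == table(ds$sample_of_cell)[c("s03", "s04")]))
  expect_true(all(tab[c("s01", "s02")] < table(ds$sample_of_cell)[c("s01", "s02")]))
})

test_that("multinomial branch-count generator is seeded and conserves totals", {
  cnt <- simulate_branch_counts(8, c(200, 300), c(0.5, 0.3, 0.2), seed = 5)
  cnt2 <- simulate_branch_counts(8, c(200, 300), c(0.5, 0.3, 0.2), seed = 5)
  expect_identical(cnt, cnt2)
  expect_true(all(rowSums(cnt) >= 200 & rowSums(cnt) <= 300))
  expect_identical(dim(cnt), c(8L, 3L))
})
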