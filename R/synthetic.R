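## Simulation generators: sampling from the generative functional
## mixed-effects model, the median-matching null construction, spike-in
## benchmarks with gold-standard labels, and branch-subsampling topology
## simulations.

#' Simulation configuration
#'
#' Defaults describe the standard benchmark world: 8 samples split into two
#' equal groups, 1000 genes, roughly 300 cells per sample, cubic-scale
#' curves (K_true = 3), scalar random-effect covariance and inverse-gamma
#' noise with finite mean (alpha = 3, eta = 2, so E\[sigma_s^2\] = 1).
#'
#' @param S number of samples.
#' @param G number of genes.
#' @param cells_per_sample integer range (min, max), drawn uniformly.
#' @param K_true knot parameter of the generating basis.
#' @param V number of covariates (V = 1: balanced binary group).
#' @param beta_effect (V) vector or scalar: effect size on covariate
#'   columns of B (0 = global null).
#' @param omega2 scalar random-effect variance (Omega = omega2 * I).
#' @param alpha,eta inverse-gamma noise hyperparameters.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline level.
#' @param curve_sd spread of the per-gene spline coefficients around the
#'   baseline (controls how dynamic curves are).
#' @param gs_fraction gold-standard fraction for spike-ins (default 0.2).
#' @param n_strengths number of spike-in strength strata (default 4).
#' @param n_source_clusters source-gene clusters recorded (default 5).
#' @param n_intervals intervals for the median-matching null (default 100).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(S = 8, G = 1000, cells_per_sample = c(250, 350),
                       K_true = 3, V = 1, beta_effect = 0, omega2 = 0.05,
                       alpha = 3, eta = 2, baseline_mean = 1.5,
                       baseline_sd = 0.5, curve_sd = 1,
                       gs_fraction = 0.2, n_strengths = 4,
                       n_source_clusters = 5, n_intervals = 100, seed = 1) {
  stopifnot(S >= 1, G >= 1, gs_fraction > 0, gs_fraction < 1,
            n_strengths >= 1, all(cells_per_sample >= 1))
  if (alpha <= 1) warning("alpha <= 1: noise variance has no finite mean")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate multi-sample expression from the generative model
#'
#' Draws, per gene and sample, `sigma_s^2 ~ IG(alpha, eta)`,
#' `u_s ~ N(0, sigma_s^2 omega2 I)`, pseudotimes uniform on \[0, 1\] and
#' `y_sc = phi(t_sc)' (B x_s + u_s) + eps_sc`. The per-gene fixed effects B
#' have a random smooth intercept column (baseline + spread `curve_sd`) and
#' covariate columns equal to `beta_effect` times a random unit-pattern.
#' A 2-D embedding (curve position plus noise) is attached so trajectory
#' code can run on the simulated data.
#'
#' @param config a [sim_config()].
#' @return list: `dataset` (an `msd`), `truth` (pseudotime, group, per-gene
#'   B, and the generator parameters).
#' @export
simulate_femm_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    pool <- seq(cf$cells_per_sample[1L], cf$cells_per_sample[2L])
    Cs <- pool[sample.int(length(pool), cf$S, replace = TRUE)]
    samples <- sprintf("s%02d", seq_len(cf$S))
    samp <- factor(rep(samples, Cs), levels = samples)
    ncell <- sum(Cs)
    cells <- sprintf("c%05d", seq_len(ncell))
    t_all <- stats::runif(ncell)
    # design: balanced binary group in column 2 (when V >= 1)
    X <- cbind(intercept = rep(1, cf$S))
    if (cf$V >= 1) {
      grp <- rep(c(1, 0), length.out = cf$S)
      X <- cbind(X, group = grp)
      if (cf$V > 1)
        for (v in 2:cf$V)
          X <- cbind(X, stats::rnorm(cf$S))
      colnames(X) <- c("intercept", "group",
                       if (cf$V > 1) paste0("x", 2:cf$V))
    }
    rownames(X) <- samples
    basis <- make_basis(cf$K_true)
    Kp1 <- cf$K_true + 1L
    Phi <- basis_matrix(basis, t_all)
    genes <- sprintf("g%04d", seq_len(cf$G))
    beta_eff <- rep(cf$beta_effect, length.out = max(cf$V, 1L))
    expr <- matrix(0, cf$G, ncell, dimnames = list(genes, cells))
    B_all <- vector("list", cf$G)
    sidx <- split(seq_len(ncell), samp)
    for (g in seq_len(cf$G)) {
      B <- matrix(0, Kp1, cf$V + 1L)
      B[, 1L] <- stats::rnorm(1, cf$baseline_mean, cf$baseline_sd) +
        stats::rnorm(Kp1, 0, cf$curve_sd)
      if (cf$V >= 1)
        for (v in seq_len(cf$V))
          if (beta_eff[v] != 0) {
            pat <- stats::rnorm(Kp1)
            B[, v + 1L] <- beta_eff[v] * pat / sqrt(mean(pat^2))
          }
      sig2 <- cf$eta / stats::rgamma(cf$S, shape = cf$alpha, rate = 1)
      y <- numeric(ncell)
      for (s in seq_len(cf$S)) {
        u <- stats::rnorm(Kp1, 0, sqrt(sig2[s] * cf$omega2))
        idx <- sidx[[s]]
        y[idx] <- Phi[idx, , drop = FALSE] %*% (B %*% X[s, ] + u) +
          stats::rnorm(length(idx), 0, sqrt(sig2[s]))
      }
      expr[g, ] <- y
      B_all[[g]] <- B
    }
    embedding <- cbind(pc1 = t_all + stats::rnorm(ncell, 0, 0.05),
                       pc2 = 0.5 * t_all^2 + stats::rnorm(ncell, 0, 0.05))
    rownames(embedding) <- cells
    ds <- multisample_dataset(expr, stats::setNames(as.character(samp), cells),
                              embedding = embedding, sample_design = X)
    list(dataset = ds,
         truth = list(pseudotime = stats::setNames(t_all, cells),
                      B = stats::setNames(B_all, genes),
                      config = cf))
  })
}

#' Median-matching null construction
#'
#' Removes any covariate-group signal gene by gene: pseudotime is divided
#' into equal-length intervals; within each interval, the group with the
#' lower median expression has the between-group median difference added to
#' its cells, so both groups end with equal per-interval medians. Intervals
#' empty in either group are skipped. The operation is idempotent.
#'
#' @param dataset an `msd` dataset.
#' @param group_labels named per-sample group labels (two groups).
#' @param pseudotime named pseudotime vector in \[0, 1\].
#' @param n_intervals number of intervals (default 100).
#' @return the dataset with matched expression.
#' @export
make_null_by_median_matching <- function(dataset, group_labels, pseudotime,
                                         n_intervals = 100) {
  stopifnot(inherits(dataset, "msd"))
  pt <- as_pseudotime(pseudotime)[dataset$cell_ids]
  if (anyNA(pt)) stop("pseudotime must cover all cells")
  gl <- group_labels[as.character(dataset$sample_of_cell)]
  ug <- sort(unique(as.character(group_labels)))
  if (length(ug) != 2L) stop("exactly two groups required")
  iv <- pmin(floor(pt * n_intervals), n_intervals - 1L) + 1L
  expr <- get_expression(dataset)
  for (i in seq_len(n_intervals)) {
    i0 <- which(iv == i & gl == ug[1L])
    i1 <- which(iv == i & gl == ug[2L])
    if (!length(i0) || !length(i1)) next
    m0 <- apply(expr[, i0, drop = FALSE], 1L, stats::median)
    m1 <- apply(expr[, i1, drop = FALSE], 1L, stats::median)
    d <- m1 - m0
    lower0 <- d > 0
    expr[lower0, i0] <- expr[lower0, i0, drop = FALSE] + d[lower0]
    lower1 <- d < 0
    expr[lower1, i1] <- expr[lower1, i1, drop = FALSE] - d[lower1]
  }
  out <- dataset
  out$expression <- expr
  out$backing <- "memory"
  out$h5_path <- NULL
  out
}

#' Select and stratify spike-in source genes
#'
#' From the candidate (non-gold-standard) genes, selects highly variable
#' genes as those whose expression SD lies above a spline fit of SD against
#' mean across the group-0 cells; clusters them (k-means on standardized
#' interval-averaged profiles; cluster ids recorded); scores each by the
#' F-statistic comparing a spline fit against a constant fit along
#' pseudotime; orders by increasing F and splits the top `n_gold` genes
#' into `n_strengths` equal strata from weakest (1) to strongest.
#'
#' @param dataset an `msd` dataset.
#' @param group0_samples sample ids forming group 0.
#' @param pseudotime named pseudotime vector.
#' @param candidate_genes genes eligible as sources (non-gold genes).
#' @param n_gold number of gold-standard genes needing sources.
#' @param n_strengths number of strength strata (default 4).
#' @param n_clusters source-gene clusters (default 5).
#' @param spline_K basis K for the SD~mean and F-statistic fits (default 5).
#' @param seed RNG seed.
#' @return data.frame (`gene`, `f_stat`, `cluster`, `stratum`) for the
#'   selected source genes, ordered by increasing F; `stratum` in
#'   1..n_strengths.
#' @export
select_source_genes <- function(dataset, group0_samples, pseudotime,
                                candidate_genes = NULL, n_gold,
                                n_strengths = 4, n_clusters = 5,
                                spline_K = 5, seed = 1) {
  stopifnot(inherits(dataset, "msd"))
  candidate_genes <- candidate_genes %||% dataset$gene_ids
  pt <- as_pseudotime(pseudotime)
  cells0 <- dataset$cell_ids[as.character(dataset$sample_of_cell) %in%
                               group0_samples]
  expr <- get_expression(dataset, candidate_genes)[, cells0, drop = FALSE]
  mu <- rowMeans(expr)
  sd_g <- apply(expr, 1L, stats::sd)
  # HV selection: SD above its spline-predicted value given the mean
  mu01 <- (mu - min(mu)) / max(diff(range(mu)), 1e-12)
  Phi_mu <- basis_matrix(make_basis(spline_K), mu01)
  resid <- sd_g - stats::lm.fit(Phi_mu, sd_g)$fitted.values
  hv <- candidate_genes[resid > 0]
  if (length(hv) < n_gold)
    stop("only ", length(hv), " highly variable source genes for ",
         n_gold, " gold genes; lower gs_fraction")
  # F-statistic: spline vs constant fit along pseudotime in group 0
  t0 <- pt[cells0]
  Phi_t <- basis_matrix(make_basis(spline_K), t0)
  Q <- qr.Q(qr(Phi_t))
  E <- expr[hv, , drop = FALSE]
  rss1 <- pmax(rowSums(E^2) - rowSums((E %*% Q)^2), 1e-12)
  rss0 <- rowSums((E - rowMeans(E))^2)
  df1 <- spline_K
  df2 <- length(cells0) - spline_K - 1L
  f_stat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  # cluster standardized interval-mean profiles
  n_iv <- 20L
  ivt <- pmin(floor(t0 * n_iv), n_iv - 1L) + 1L
  prof <- t(apply(E, 1L, function(y)
    tapply(y, factor(ivt, levels = seq_len(n_iv)), mean)))
  prof[is.na(prof)] <- 0
  prof <- t(apply(prof, 1L, standardize_row))
  cl <- with_seed(seed,
                  stats::kmeans(prof, min(n_clusters, nrow(prof) - 1L),
                                nstart = 5)$cluster)
  ord <- order(f_stat)
  tail_idx <- utils::tail(ord, n_gold)
  stratum <- rep(NA_integer_, length(hv))
  stratum[tail_idx] <- rep(seq_len(n_strengths),
                           each = ceiling(n_gold / n_strengths),
                           length.out = n_gold)
  out <- data.frame(gene = hv, f_stat = f_stat, cluster = cl,
                    stratum = stratum, stringsAsFactors = FALSE)
  out[order(out$f_stat), ]
}

#' Assign gold-standard labels for a spike-in benchmark
#'
#' Randomly selects `gs_fraction` of genes as gold standard and assigns
#' them uniformly to the truth types `trend`, `mean` and `both`; all other
#' genes are labeled `null`.
#'
#' @param gene_ids all gene ids.
#' @param gs_fraction gold fraction (default 0.2).
#' @param seed RNG seed.
#' @return data.frame (`gene`, `truth`).
#' @export
gold_standard_labels <- function(gene_ids, gs_fraction = 0.2, seed = 1) {
  with_seed(seed, {
    n_gold <- round(length(gene_ids) * gs_fraction)
    gold <- sample(gene_ids, n_gold)
    truth <- stats::setNames(rep("null", length(gene_ids)), gene_ids)
    truth[gold] <- sample(rep(c("trend", "mean", "both"),
                              length.out = n_gold))
    data.frame(gene = gene_ids, truth = unname(truth[gene_ids]),
               stringsAsFactors = FALSE)
  })
}

#' Spike differential signals into a null dataset
#'
#' Adds, per gold-standard gene, a matched source gene's per-sample
#' expression profile according to the gene's truth type:
#' * `trend`: the source profile is added to group-0 cells as is, and
#'   permuted within each sample before being added to group-1 cells
#'   (trend contrast, approximately equal means);
#' * `mean`: the source profile is permuted within each sample and added
#'   to group-0 cells only (mean shift, no coherent trend);
#' * `both`: the source profile is added to group-0 cells only, uncentered.
#' Null genes are untouched. Signals are scaled by `multiplier`.
#'
#' @param null_dataset the median-matched `msd` dataset.
#' @param labels data.frame (`gene`, `truth`) from [gold_standard_labels()].
#' @param source_strata data.frame from [select_source_genes()].
#' @param strength_level stratum to draw source genes from (1..4).
#' @param group_labels named per-sample group labels; group 0 = the
#'   lexicographically first label.
#' @param multiplier scalar signal multiplier (default 1; e.g. 0.5--4).
#' @param seed RNG seed.
#' @return list: `dataset` (spiked), `labels` (with `strength` and
#'   `source_gene` columns).
#' @export
spike_in <- function(null_dataset, labels, source_strata, strength_level,
                     group_labels, multiplier = 1, seed = 1) {
  stopifnot(inherits(null_dataset, "msd"))
  if (multiplier < 0) stop("multiplier must be nonnegative")
  gold <- labels$gene[labels$truth != "null"]
  pool <- source_strata$gene[!is.na(source_strata$stratum) &
                               source_strata$stratum == strength_level]
  if (!length(pool)) stop("no source genes in stratum ", strength_level)
  gl <- group_labels[as.character(null_dataset$sample_of_cell)]
  g0 <- sort(unique(as.character(group_labels)))[1L]
  expr <- get_expression(null_dataset)
  samp <- null_dataset$sample_of_cell
  sidx <- split(seq_along(samp), samp)
  src_of <- with_seed(seed, stats::setNames(
    sample(pool, length(gold), replace = length(pool) < length(gold)), gold))
  perm_within <- function(v) {
    out <- v
    for (idx in sidx) out[idx] <- v[idx][sample.int(length(idx))]
    out
  }
  seeds <- child_seeds(seed + 1L, length(gold))
  for (gi in seq_along(gold)) {
    g <- gold[gi]
    type <- labels$truth[labels$gene == g]
    sig <- multiplier * expr[src_of[[g]], ]
    if (multiplier == 0) next
    with_seed(seeds[[gi]], {
      if (type == "both") {
        expr[g, gl == g0] <- expr[g, gl == g0] + sig[gl == g0]
      } else if (type == "mean") {
        ps <- perm_within(sig)
        expr[g, gl == g0] <- expr[g, gl == g0] + ps[gl == g0]
      } else {                      # trend
        ps <- perm_within(sig)
        expr[g, gl == g0] <- expr[g, gl == g0] + sig[gl == g0]
        expr[g, gl != g0] <- expr[g, gl != g0] + ps[gl != g0]
      }
    })
  }
  out <- null_dataset
  out$expression <- expr
  lab <- labels
  lab$strength <- ifelse(lab$truth == "null", NA_integer_, strength_level)
  lab$source_gene <- src_of[lab$gene]
  lab$source_gene[lab$truth == "null"] <- NA_character_
  list(dataset = out, labels = lab)
}

#' Subsample a branch's cells (topology power simulations)
#'
#' Removes a uniform fraction of the branch's cells in the designated
#' samples, leaving other cells untouched.
#'
#' @param dataset an `msd` dataset.
#' @param branch_cells cell ids of the branch (or a `td_branch`).
#' @param fraction fraction of branch cells to remove, in \[0, 1).
#' @param samples "all", or a character vector of sample ids to reduce.
#' @param seed RNG seed.
#' @return the reduced `msd` dataset.
#' @export
simulate_branch_reduction <- function(dataset, branch_cells, fraction,
                                      samples = "all", seed = 1) {
  stopifnot(inherits(dataset, "msd"))
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1); for absent branches use topology tools")
  if (inherits(branch_cells, "td_branch")) branch_cells <- branch_cells$cells
  if (fraction == 0) return(dataset)
  target <- branch_cells
  if (!identical(samples, "all"))
    target <- target[as.character(dataset$sample_of_cell[target]) %in% samples]
  drop <- with_seed(seed, sample(target, round(length(target) * fraction)))
  keep <- setdiff(dataset$cell_ids, drop)
  expr <- get_expression(dataset)[, keep, drop = FALSE]
  multisample_dataset(expr, dataset$sample_of_cell[keep],
                      embedding = if (!is.null(dataset$embedding))
                        dataset$embedding[keep, , drop = FALSE] else NULL,
                      sample_design = dataset$sample_design)
}

#' Simulate per-sample branch cell counts under a multinomial model
#'
#' Light-weight generator for topology-test calibration studies: each
#' sample's cells are allocated to branches by a multinomial draw.
#'
#' @param S number of samples.
#' @param size_range per-sample total cell count range.
#' @param prob branch probabilities (sums to 1).
#' @param seed RNG seed.
#' @return samples x branches count matrix.
#' @export
simulate_branch_counts <- function(S, size_range = c(250, 350),
                                   prob = c(0.4, 0.4, 0.2), seed = 1) {
  with_seed(seed, {
    n <- sample(seq(size_range[1L], size_range[2L]), S, replace = TRUE)
    counts <- t(vapply(n, function(ni)
      as.numeric(stats::rmultinom(1, ni, prob)), numeric(length(prob))))
    dimnames(counts) <- list(sprintf("s%02d", seq_len(S)),
                             sprintf("branch%d", seq_along(prob)))
    counts
  })
}

#' Assemble the median-matched null / spike-in benchmark
#'
#' Convenience wrapper chaining the benchmark construction: simulate from
#' the generative model (no covariate effect), split samples into the two
#' design groups, equalize the groups by per-interval median matching and,
#' optionally, spike differential signals into a gold-standard gene subset.
#'
#' @param config a [sim_config()] (V must be >= 1; column 2 is the group).
#' @param spike if FALSE, return the pure null benchmark.
#' @param strength_level source stratum for the spike-ins.
#' @param multiplier spike-in signal multiplier.
#' @return list: `dataset`, `labels` (NULL when `spike = FALSE`),
#'   `pseudotime`, `group` (named per-sample labels).
#' @export
build_spikein_benchmark <- function(config = sim_config(), spike = TRUE,
                                    strength_level = 2, multiplier = 1) {
  stopifnot(config$V >= 1)
  sim <- simulate_femm_data(config)
  ds <- sim$dataset
  pt <- sim$truth$pseudotime
  grp <- stats::setNames(
    ifelse(ds$sample_design[, 2L] == 1, "g1", "g0"),
    rownames(ds$sample_design))
  nulled <- make_null_by_median_matching(ds, grp, pt,
                                         n_intervals = config$n_intervals)
  if (!spike)
    return(list(dataset = nulled, labels = NULL, pseudotime = pt,
                group = grp))
  labels <- gold_standard_labels(nulled$gene_ids,
                                 gs_fraction = config$gs_fraction,
                                 seed = config$seed)
  src <- select_source_genes(
    nulled, names(grp)[grp == "g0"], pt,
    candidate_genes = labels$gene[labels$truth == "null"],
    n_gold = sum(labels$truth != "null"),
    n_strengths = config$n_strengths,
    n_clusters = config$n_source_clusters, seed = config$seed)
  sp <- spike_in(nulled, labels, src, strength_level, grp,
                 multiplier = multiplier, seed = config$seed)
  list(dataset = sp$dataset, labels = sp$labels, pseudotime = pt,
       group = grp)
}
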