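# trajdiff

Differential pseudotime analysis across multiple single-cell RNA-seq
samples.

Most pseudotime differential-expression tools pool all cells as if they came
from a single sample, so a gene that merely varies between donors can look
"dynamic", and condition effects cannot be separated from donor-to-donor
noise. trajdiff treats the *sample* as the unit of replication throughout:

* **Trajectory + uncertainty** — cluster-based minimum-spanning-tree
  pseudotime on a harmonized embedding (k-means + MST over cluster centers,
  TSCAN-style), with per-branch bootstrap **detection rates** calibrated by
  a null Jaccard-overlap distribution.
* **Differential topology** — per-branch binomial logistic regression of
  branch cell proportions on sample covariates (joint multinomial logit
  optional), Wald tests, BH correction.
* **Differential expression** — a functional mixed-effects model per gene:

  $$y_{sc} = \phi(t_{sc})^T (B x_s + u_s) + \epsilon_{sc}, \quad
    u_s \sim N(0, \sigma_s^2 \Omega), \quad
    \epsilon_{sc} \sim N(0, \sigma_s^2), \quad
    \sigma_s^2 \sim \mathrm{IG}(\alpha, \eta)$$

  with B-spline bases $\phi$ on branch-rescaled pseudotime (K chosen per
  gene by BIC) and EM fitting (conjugate E-step; C++ core). Permutation
  likelihood-ratio tests detect **TDE** (expression changes along
  pseudotime), **XDE** (expression changes associated with a sample
  covariate, decomposed into *mean shift* and *trend difference*), and the
  cell-density analogues **TCD/XCD** on interval count ratios
  $r_{st}/L_s$. Batch covariates are adjusted through the design matrix.
* **Benchmark generators + metrics** — sampling from the generative model,
  per-interval median-matching nulls, strength-stratified signal spike-ins
  with gold-standard labels, branch-subsampling simulations, FDR-calibration
  curves, sensitivity–realFDR AUC, and a top-N overlap permutation test.

## Worked example

```r
library(trajdiff)

# a fully synthetic 8-sample dataset from the generative model,
# median-matched between the two sample groups, with differential signals
# spiked into 20% of genes
bm <- build_spikein_benchmark(
  sim_config(S = 8, G = 200, cells_per_sample = c(250, 350), seed = 1),
  spike = TRUE, strength_level = 2)

res <- xde_test(bm$dataset, bm$pseudotime, covariate = "group",
                mode = "pm", n_perm = 50, prescreen_p = 0.1, seed = 2)
table(res$category)
#>
#>  bothSig  meanSig   nonXDE otherSig trendSig
#>        3        7      182        1        7

truth <- bm$labels$truth[match(res$gene, bm$labels$gene)] != "null"
disc  <- !is.na(res$fdr_overall) & res$fdr_overall <= 0.05
c(discoveries = sum(disc), false = sum(disc & !truth))
#> discoveries       false
#>          18           0
```

Eighteen genes are called XDE at 5% FDR, all of them genuinely spiked
(realized FDR 0 here), and each call is classified: `meanSig` genes are
shifted up/down by a constant between the groups, `trendSig` genes change
the *shape* of their pseudotemporal curve, `bothSig` genes do both, and
`otherSig` marks overall-significant genes without a clear attribution.
Trajectory construction, topology tests and density tests follow the same
pattern; see the methods vignette (`vignettes/trajdiff-methods.Rmd`) for
the model, its assumptions and the numerical choices.

A thin CLI wraps the same functions
(`inst/exec/trajdiff.R <subcommand> --flags`, subcommands: trajectory,
detect-rate, topology-test, xde, tde, tcd, xcd, simulate, evaluate).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the realized false
discovery proportion of the overall XDE test at reported FDR 0.05 on the
full-scale synthetic spike-in benchmark (S = 8, G = 1000, median-matched
null, strength-2 spike-ins, 50 permutations with chi-squared pre-screen),
and the type-I error rate of the binomial differential-topology test over
2000 null branch-count replicates. Results are written as JSON.
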