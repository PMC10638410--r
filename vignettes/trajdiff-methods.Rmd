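---
title: "trajdiff: models and methods for multi-sample differential pseudotime analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trajdiff: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell RNA-seq studies increasingly profile *many* biological samples
(donors, patients, conditions) along a shared continuous process —
differentiation, activation, disease progression. Classical pseudotime
differential-expression tools treat all cells as if they came from one
sample, so they cannot ask the questions that actually motivate multi-sample
designs: *does the pseudotemporal program differ between conditions?* and
*is an apparent difference larger than the sample-to-sample variability one
would see between replicates?* trajdiff addresses both, for tree topology,
gene expression, and cell density along pseudotime.

## Trajectory construction and its uncertainty

Cells are clustered by k-means on a harmonized low-dimensional embedding
(the integration itself is upstream and out of scope). When the cluster
number is not given it is chosen by an elbow rule: the smallest $k$ after
which one more cluster explains less than 10% of the total within-cluster
sum of squares. (The drop is measured against the total, $k = 1$, WSS:
measuring it against WSS($k$) never levels off for Gaussian clusters, whose
WSS decays like $1/k$.) A minimum spanning tree over cluster centers, rooted
at a user-specified origin (a cluster id, or the cluster maximizing mean
marker expression), defines the trajectory; every root-to-leaf path is a
branch. A cell's pseudotime is the arc length from the origin to its
orthogonal projection on the nearest flanking tree segment, rescaled to
$[0, 1]$ per branch so that spline knots live on a fixed domain.

Because trees inferred from finite data are unstable, each branch carries a
**detection rate**: cells are resampled with replacement, the trajectory is
rebuilt with the same $k$ (re-running model selection would mix topology
uncertainty with model-selection noise), and the branch counts as detected
when some bootstrap branch overlaps it with a Jaccard index above a
null-calibrated cutoff — the 0.99 quantile of the Jaccard index between the
branch and random cell sets of the same size. Duplicate bootstrap cells are
collapsed to unique identities first; the Jaccard index over multisets is
not well defined.

## Differential topology

Per sample and branch, the **branch cell proportion** is the branch's cell
count over the sample's total. Branches that share pre-branch-point cells
each count those cells — proportions are defined per branch, not as a
partition. The default test fits, per branch, a binomial logistic
regression of the branch count on the sample covariates and reports Wald
p-values with Benjamini–Hochberg correction across branches. A joint
multinomial (baseline-category) logit over all branches is available; its
reference is the most abundant branch, and it is fit by a Newton–Raphson
with analytic Hessian written for this package (no multinomial-logit
fitter is available in the dependency set). Complete separation is flagged
(`NA` p-values), not penalized away.

## The functional mixed-effects model

For one gene on one branch, with sample $s$, cell $c$, pseudotime
$t_{sc} \in [0,1]$ and covariates $x_s = (1, x_{s1}, \dots, x_{sV})^T$:

$$y_{sc} = \phi(t_{sc})^T b_s + \epsilon_{sc}, \qquad
  b_s = B x_s + u_s,\qquad
  \epsilon_{sc} \sim N(0, \sigma_s^2),$$
$$u_s \sim N(0, \sigma_s^2 \Omega), \qquad
  \sigma_s^2 \sim \mathrm{IG}(\alpha, \eta).$$

$\phi$ is a B-spline basis of $K+1$ functions on $[0,1]$ forming a
partition of unity ($\sum_k \phi_k \equiv 1$), so *equal* spline
coefficients describe a flat curve, and a covariate column of $B$ with all
entries equal to $c$ shifts the whole curve by $c$ per unit covariate —
this is what makes the mean/trend decomposition below well defined. The
basis convention is: $K = 0$ the constant function, $1 \le K \le 3$ the
Bernstein basis of degree $K$, $K \ge 4$ cubic B-splines with $K - 3$
equidistant interior knots. $K$ is selected per gene by BIC,
$K S \ln(\sum_s C_s) - 2 \sum_s l_{K,s}$, with $l_{K,s}$ the per-sample OLS
spline log-likelihood, over $K \in \{0, \dots, 20\}$.

The random effect $u_s$ absorbs sample-level curve variability not
explained by covariates; the inverse-gamma layer shares information about
cell-level noise across samples. When $S \le V + K + 2$ a full $\Omega$ is
not identifiable and the scalar constraint $\Omega = \omega^2 I$ engages
automatically.

### Fitting

Integrating $(u_s, \sigma_s^2)$ out gives each sample a multivariate-t
marginal (location $\Phi_s B x_s$, scale
$\tfrac{\eta}{\alpha}(\Phi_s \Omega \Phi_s^T + I)$, $2\alpha$ df),
evaluated via the Woodbury identity in $(K+1)$-space. The EM treats
$(u_s, \sigma_s^2)$ as latent; conjugacy makes the E-step closed form
(normal–inverse-gamma posterior), and the M-step is a weighted least
squares for $B$, a moment update for $\Omega$, and a 1-D golden-section
search for $\alpha$ with $\eta$ profiled out. The marginal log-likelihood
is non-decreasing across iterations (tested), and its final value is
checked against an independent dense $C \times C$ evaluation and against
2-D numerical quadrature on small cases.

Numerical notes, all visible in the tests:

* **$\alpha$ cap.** When per-sample noise variances are homogeneous the
  IG layer degenerates ($\alpha \to \infty$ with $\eta/\alpha \to
  \sigma^2$) and EM inches along a flat ridge. The $\alpha$ search is
  bounded at $10^3$, where the t marginal is numerically Gaussian.
* **Joint identifiability.** Only $\sigma_s^2 \Omega$ is identified as the
  noise vanishes; in that limit a shared offset can sit in $E[u_s]$ rather
  than in $B$. Sample-level fitted curves ($B x_s + E[u_s]$) are the
  stable quantity there.
* **Boundary crawl.** Near $\Omega \to 0$ EM converges linearly with rate
  approaching one. The hypothesis-testing machinery therefore runs EM with
  tol $10^{-4}$ and 150 iterations — enough for log-likelihoods accurate
  to a few hundredths — and uses the *same* budget for observed and
  permuted fits, so likelihood-ratio comparisons are like for like.
  `fit_em()` itself defaults to the stricter tol $10^{-6}$ / 1000.
* $\Omega$ is floored at minimum eigenvalue $10^{-10}$; $\alpha \ge 1.01$
  so the prior mean exists.

## Differential tests

**XDE** (covariate-associated differential expression) compares nested
models for covariate $v$: $M_0$ ($\beta_{\cdot v} = 0$), $M_1$
($\beta_{\cdot v} = c\,\mathbf{1}$, a pure curve shift), $M_2$ (free).
Overall test $M_2{:}M_0$, mean test $M_1{:}M_0$, trend test $M_2{:}M_1$;
all three share the $K$ chosen once per gene and the same random-effect
structure, so the statistics are comparable. Genes significant overall are
classified `meanSig` / `trendSig` / `bothSig` / `otherSig` from the mean
and trend FDRs at the chosen cutoff.

**TDE** (differential expression along pseudotime) compares "every column
of $B$ constant" (flat population curve) against a free $B$. Note the
random effects remain free under the null, so sample-specific wiggles do
not masquerade as pseudotemporal signal — this is precisely the
multi-sample correction, and it costs single-sample power by design.

The test statistic is the log-likelihood ratio. Its null distribution is
built by permutation: cells are bootstrapped within each sample (to
propagate pseudotime variability), then the tested covariate is permuted
across samples (XDE; nuisance covariates such as batch stay attached to
their samples) or pseudotime is permuted within samples (TDE). A Gaussian
kernel density (rule-of-thumb bandwidth) is fitted to the permuted LLRs
and the p-value is its analytic upper-tail mass, floored at $10^{-300}$;
table output renders values under the double-precision floor as
`<2.22e-308`. A chi-squared option ($2 \cdot$LLR against the
parameter-count difference: $K{+}1$, $1$, $K$) is provided for speed, and,
in permutation mode, a *pre-screen*: genes whose chi-squared overall p
exceeds 0.1 skip the permutations and keep their chi-squared p-values —
those can never be discoveries at usual FDR cutoffs (BH rejects only
$p \le 0.05$), so the discovery set is unchanged while runtime drops
several-fold.

**TCD/XCD** (cell-density analogues): pseudotime is cut into 100
equal-length intervals, per-sample counts $r_{st}$ are normalized by the
branch total $L_s$, and the ratios are pushed through the same machinery
with intervals as pseudo-cells at interval midpoints (the abscissa is not
specified upstream; midpoints are the symmetric choice). The count-model
alternative (Poisson/NB with log-link intensity) is deliberately not
implemented. TCD permutations shuffle interval order within sample; XCD
permutations shuffle the covariate across samples.

## The synthetic world

`simulate_femm_data()` draws data from the generative model itself:
uniform pseudotimes; per-gene smooth baseline curves (cubic scale,
$K_{\mathrm{true}} = 3$; baseline level $N(1.5, 0.5^2)$ and coefficient
spread 1, chosen to mimic log-normalized single-cell expression in the
0–4 range); scalar random-effect variance $\omega^2 = 0.05$ (sample curves
visibly but not wildly different); noise $\sigma_s^2 \sim
\mathrm{IG}(3, 2)$ so $E[\sigma_s^2] = 1$ with substantial sample-to-sample
spread. Defaults: $S = 8$ samples in two balanced groups, $G = 1000$
genes, 250–350 cells per sample.

The benchmark pipeline (`build_spikein_benchmark()`) mirrors the standard
construction: (1) a **median-matching null** — within each of 100
pseudotime intervals, the group with the lower per-gene median is shifted
up by the median difference, which provably equalizes group medians and is
idempotent; (2) **spike-ins** — 20% of genes become gold standard, split
evenly among *trend* (source profile added coherently to group 0 and
within-sample-permuted into group 1), *mean* (within-sample-permuted
source added to group 0 only) and *both* (source added to group 0
uncentered). Source genes are highly variable genes (SD above its
spline fit on the mean), ranked by the F-statistic of a spline-vs-constant
fit, with the top genes split into four strength strata.

What a green benchmark test does establish: FDR control and power of the
XDE machinery under realistic sample-level variability with matched group
nulls. What it does not: robustness to trajectory mis-specification (the
benchmark uses the true pseudotime), to non-Gaussian expression noise, or
to unbalanced designs — real data differ in all three ways.

One subtlety worth recording: a spike-in *multiplier* scales the source's
carried-over cell noise along with its signal, so XDE power in the
multiplier saturates once the added noise dominates the gene's intrinsic
noise. The strength *strata* (F-statistic quantiles) are the axis along
which signal-to-noise genuinely grows. The reduced-scale power-ordering
test therefore multiplies sources from the weakest stratum, which keeps
all four multipliers on the rising limb of the power curve.

## Evaluation metrics

Calibration is summarized by the **FDR difference** (trapezoid area under
the realized-vs-reported FDR curve minus the diagonal's 0.5; realized FDR
at a cutoff with zero discoveries is defined as 0, a convention favorable
to the method under test and stated in output metadata) and by the area
under the **sensitivity vs realized-FDR** curve. For the latter,
sensitivity is monotonized over realized FDR, the curve is right-extended
at its final sensitivity, and the region left of the smallest attained
realized FDR contributes nothing — interpolating from the origin would
credit unattained operating points and can rank an inverted ranking above
a random one. The top-N overlap permutation test reports the mean overlap
with a gold gene set over a grid of N (default 10, 20, …, 500, clipped),
against a gene-order permutation null with the $+1$ correction.

## Known limitations

* Power for trend differences at small $S$ is modest — the price of
  honoring sample-level variability; the chi-squared mode is
  anticonservative and kept only as a labeled speed option.
* The multinomial topology test assumes branch counts partition cells;
  with shared pre-branch cells it is a pragmatic approximation (the
  binomial per-branch test is the default for this reason).
* Bootstrap detection rates inherit k-means instability on weakly
  separated embeddings; rates should be read comparatively, not as
  calibrated probabilities.
* Disk-backed mode streams genes from HDF5 but still materializes the
  per-branch slice densely in memory.
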