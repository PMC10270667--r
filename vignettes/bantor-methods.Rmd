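---
title: "Distance regression for repeated brain networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance regression for repeated brain networks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bantor)
```

## The problem

Functional brain networks are usually summarized as an $n_n \times n_n$
connection matrix per scan: the Pearson correlations between regional
fMRI time series, symmetric, unit diagonal, entries in $[-1, 1]$. When
each subject is scanned repeatedly — several tasks, several sessions —
a natural question is whether *distances between subjects' networks*
are related to differences in their phenotypes: do people with similar
IQ have similar connectomes, after controlling for age, sex and other
confounders?

`bantor` implements a regression framework for exactly this question.
The unit of analysis is a pair of scans from two *distinct* subjects on
the *same* task: its response is a network distance, its regressors are
covariate differences, and the correlation induced by reusing subjects
and scans across pairs is handled by a crossed random-effects mixed
model (3M_BANTOR: multitask/multisession BrAin NeTwOrk regression).

## Network distance metrics

All metrics operate on the off-diagonal upper triangle (the diagonal
never carries information):

* **KS** — the natural log of the two-sample Kolmogorov–Smirnov
  statistic between the two scans' edge-weight empirical distributions.
  Only the *distribution* of weights matters, not edge identity. The
  log is taken because, of all the metrics, KS was the only one whose
  inferential behaviour benefits from it; values are $\le 0$. When the
  two edge multisets are identical the statistic is $0$ and its log
  undefined; we floor the value at $\log(1/n_\text{edges})$ — the
  smallest nonzero statistic attainable at that sample size — and flag
  the pair. Between distinct subjects exact ties have probability zero,
  so the floor is a guard, not a modelling device.
* **Jaccard** — scans are first thresholded to binary "key-edge" graphs
  keeping the top fraction of edges by signed weight (exactly
  $k = \mathrm{round}(f \cdot n_\text{edges})$ edges; ties broken by
  row-major edge index so results are bit-reproducible). The distance
  is the fraction of edges, key in either graph, that do not share key
  status. We deliberately rank by *signed* value with no positivity
  filter: this keeps $|$key set$|$ fixed, which the Jaccard denominator
  logic expects; a warning is raised if non-positive edges enter.
* **Euclidean (EUC)** and **Pearson correlation distance (PCD)** —
  $\ell_2$ distance between edge-weight vectors, and $(1 - r)/2$ where
  $r$ is the Pearson correlation between them. The $(1-r)/2$ form is
  the unique affine map of a correlation onto $[0, 1]$, with perfect
  agreement at 0 and perfect anti-agreement at 1.
* **LERM** — the log-Euclidean Riemannian metric
  $\lVert \log C_1 - \log C_2 \rVert_F$ on symmetric positive-definite
  matrices, computed by symmetric eigendecomposition. Any eigenvalue at
  or below $10^{-10}$ is an error naming the offending scan; the
  simulator's smoothing tolerance of $10^{-6}$ leaves a comfortable
  margin above that.

Every metric except LERM also accepts nodal degree vectors (row sums
without the diagonal) in place of full matrices.

## The regression design

`build_design()` emits one row per (distinct-subject pair, task,
repetition combination): with $n_p$ subjects, $n_t$ tasks and $n_r$
repetitions, that is $n_t \binom{n_p}{2} n_r^2$ rows on balanced data
(all $4 \times 4 = 16$ repetition combinations of a pair appear; the
pair itself is unordered). Continuous covariates enter as $|x_a - x_d|$
and categorical ones as the indicator $\mathbf{1}\{x_a \neq x_d\}$ —
for categorical variables with more than two levels the same indicator
is used (any difference counts equally). Within-subject scan pairs are
excluded from the design; they are only assembled for the MDMR
baseline, which requires a complete distance matrix. Each task gets its
own coefficient block and, by default, its own intercept (no global
intercept); a global-intercept and no-intercept variant are available.

## Estimation and inference

Three estimators share this design:

* `fit_f_test()` — ordinary least squares. Rows sharing a subject are
  correlated, so this test is anticonservative; it is kept as the
  comparison baseline and labelled as such.
* `fit_f_test_sle()` — adds a fixed indicator per scan ("scan-level
  effects", two 1s per row), absorbing scan-specific shifts. With one
  scan per subject this was sufficient in the single-task setting; with
  repeated scans the dyad-level correlation remains.
* `fit_bantor()` — the mixed model
  $$\mathrm{Dist} = X\beta + \mathrm{SCANID}\,\alpha + Z b +
  \varepsilon,\qquad b_{(a,d),b} \sim N(0, g_b),\ \varepsilon \sim
  N(0, \sigma^2 I),$$
  with one random intercept per (dyad, task) and a separate variance
  $g_b$ per task (a pooled-variance option exists). The residual
  variance is a single shared $\sigma^2$: the aggregated single-model
  formulation implies one residual term. A per-task residual variance
  is *not* offered — with per-task $g_b$ already absorbing task-level
  dispersion differences we judged the extra parameters not worth the
  loss of the fast profiled solver (a documented limitation).

**REML implementation.** The (dyad, task) groups partition the rows, so
$V_0 = I + \sum_b \gamma_b Z_b Z_b^\top$ (with $\gamma_b = g_b /
\sigma^2$) is block diagonal with the analytic inverse
$I - \frac{\gamma_g}{1 + \gamma_g m_g} J$ per group. One REML
evaluation therefore costs a sparse rank update of $X^\top X$ plus a
single dense Cholesky of $X^\top V_0^{-1} X$ — independent of the row
count — which is what makes 200-replicate simulation studies practical
on one CPU (the same design at full scale has $\sim 2.4\times 10^5$
rows and $\sim 1.5 \times 10^4$ groups). $\beta$ and $\sigma^2$ are
profiled out; the $\gamma_b$ are optimized by bounded quasi-Newton on
the log scale (relative tolerance $10^{-8}$, max 500 iterations), so
$g_b = 0$ is approached smoothly as a boundary (flagged with a
warning), followed by an analytic Newton polish that resolves the
optimum to near machine precision. Identifiability (the scan
indicators are collinear with the task intercepts) is handled by an
order-preserving rank-revealing Cholesky: covariate columns come first
and always survive; trailing scan indicators absorb the redundancy.
Covariate inference is invariant to that identification choice (tested
against an independent implementation that drops different columns).

**Satterthwaite degrees of freedom.** For each coefficient,
$\mathrm{df} = 2 (l^\top \hat C l)^2 / (d^\top \hat V d)$ with $\hat C$
the fixed-effect covariance at the REML optimum, $d$ the gradient of
$l^\top C(\theta) l$ in $\theta = (\gamma_1, \ldots, \gamma_B,
\sigma^2)$, and $\hat V$ twice the inverse observed-information
Hessian of the restricted likelihood. Both $d$ and the Hessian are
computed analytically — the group-partitioned structure reduces every
trace term to per-group scalars plus small dense solves — which is what
lets the balanced-toy check ($\mathrm{df} = J - 2$ for a dyad-level
contrast in a balanced two-level design) hold to $10^{-6}$. The whole
inference path is cross-checked against `lme4`/`lmerTest` (estimates,
standard errors, dfs, variance components, REML log-likelihood) on
small fixtures in the test suite.

**Degenerate case.** With one task and one scan per subject every dyad
contributes one row, the random effects are unidentifiable, and
`fit_bantor()` returns the scan-level-effects F test (flagged
`degenerate`) — the two are the same model there.

**MDMR baseline.** `mdmr_permutation()` implements permutation
multivariate distance matrix regression: Gower-centered
$G = -\tfrac12 H (D \circ D) H$, marginal pseudo-$F$ per predictor,
p-values by jointly permuting rows and columns of $G$ with the add-one
estimator $(1 + \#\{F^\ast \ge F\})/(1 + n_\text{perm})$, default
5000 permutations. It ignores within-subject correlation and is run
separately per task on the complete scan distance matrix
(within-subject pairs included). The mixed-effects extension of MDMR
is out of scope here. The implementation is verified against
`vegan::adonis2` and against a classical univariate permutation test.

No multiple-testing adjustment is applied by default, matching the
framework's exploratory usage; `stats::p.adjust` composes trivially
with the tidy output if wanted.

## The SPD connectome simulator

The simulator generates datasets with *known* covariate dependence so
that type-I error and power can be measured.

* **Covariates.** Fair-coin `SEX` and `TRT`; `IQ` and `AGE` from
  $\mathrm{round}(N(100, 15^2))$. `AGE` and `SEX` never enter the
  generative model — they are the null covariates for type-I error.
  The signal parameter is $a = (IQ - 100) \cdot 0.15 + 2 \cdot
  \mathbf 1\{\mathrm{Trt}\} - 2 \cdot \mathbf 1\{\mathrm{Placebo}\}$,
  clamped to $[-5.95, 5.95]$ so both parameters of
  $\mathrm{Beta}(7 + a, 7 - a)$ stay positive. (That clamp is also why
  the $\mathrm{Beta}(7+a, 7-a)$ parameterization is the right reading
  of the signal distribution: the alternative $\mathrm{Beta}(a, 15)$
  form is undefined for $a \le 0$.)
* **Background.** A random correlation matrix built from a Haar
  orthogonal $Q$ (QR of a Gaussian matrix via `pracma::randortho`),
  $D = \mathrm{diag}(50 \cdot \mathrm{Beta}(34, 2))$,
  $A = Q^\top D Q$ standardized to unit diagonal, then smoothed.
  Its absolute off-diagonal pool is concentrated near zero
  ("low-connectivity noise").
* **Regions.** Three 15-node regions per task; task $j$ has its last
  $j$ regions covariate-dependent (task 1: one, task 2: two, task 3:
  all three), which puts covariate signal in 105/210/315 of the 35,778
  edges at 268 nodes — 0.3%, 0.6%, 0.9%. Each region block is compound
  symmetric: *one* level $r$ fills all off-diagonal cells of the
  $15 \times 15$ block for that scan.
* **Copula coupling.** A subject's 12 per-scan levels for one region
  are coupled through a latent Gaussian with correlation 0.7 within
  task, 0.3 within repetition across tasks, 0 otherwise. That matrix is
  exactly singular (the structure satisfies $1 - 0.7 - 0.3 = 0$), so
  draws use an eigendecomposition square root rather than a Cholesky.
  Marginals: noise regions map the uniform quantile through
  $\mathrm{Beta}(5, 5)$ ("high-connectivity noise"); signal regions
  through the comonotone mixture $(1 - s)\,F^{-1}_\text{pool}(u) +
  s\,F^{-1}_{\mathrm{Beta}(7+a, 7-a)}(u)$, where $F_\text{pool}$ is the
  ECDF of the *absolute* background off-diagonal pool and $s$ is the
  signal fraction. At $s = 0$ signal regions are exchangeable with the
  background pool and covariates carry no information (the basis of the
  type-I experiment); at $s = 1$, $a = 0$ they are
  $\mathrm{Beta}(7, 7)$. Applying the shared quantile through both
  component inverse CDFs (comonotone mixing) preserves the copula's
  rank correlation; inverting the mixture CDF itself is available via
  `mixing = "mixture"`.
* **Scans.** 2,500 (by default) time points of a zero-mean Gaussian
  with the background covariance; each region's columns are overwritten
  with independent draws from its compound-symmetric block; the sample
  Pearson correlation matrix is smoothed to SPD. Drawing the full
  background first and overwriting regions (rather than drawing the
  remainder separately) matches the fact that background entries
  bordering regions are affected by the region series in the sample
  correlation.
* **Smoothing.** Eigenvalue flooring at $10^{-6}$ with rescaling to
  unit diagonal, iterated at most 5 times; positive-semidefinite inputs
  pass through bitwise unchanged. This guarantees every emitted matrix
  is LERM-ready.
* **Seeding.** A master seed spawns per-subject region streams and
  per-scan streams through a small multiplicative hash, so any single
  scan is reproducible in isolation and whole datasets are
  bit-identical across runs.

What the generator does *not* emulate: spatial autocorrelation and
haemodynamics of real BOLD series, motion and physiological artifacts,
atlas misregistration, subject-specific background covariance (one
background matrix is shared within a dataset), or negative-valued
signal regions. Passing tests therefore demonstrate statistical
correctness of the pipeline under this generative model, not robustness
to fMRI preprocessing choices.

## The simulation study and its scale

`run_study()` crosses signal levels (0–100%), metrics, and estimation
methods; each cell simulates a dataset, computes distances, builds the
design, fits, and records per-(task, covariate) rejections at
$\alpha = 0.05$, with binomial Monte-Carlo standard errors.
`power_crossing()` reports the first grid value whose rejection rate
reaches 80% (flagging curves that dip back below after crossing, which
the top-20% Jaccard threshold genuinely does — when the key set is far
larger than the signal-edge set, increasing signal can push all signal
edges inside every key set and erase the contrast; that is why the
0.5% threshold, commensurate with the 0.3–0.9% signal-edge fractions,
is the informative one).

The full-scale design — 100 subjects, 268 nodes, 2,500 replicates per
signal level — is a cluster-scale computation. The package's own
studies run at documented desk-scale profiles chosen once:

* *calibration profile* (type-I error, also used by
  `scripts/acceptance.R`): 30 subjects, 60 nodes, 3 tasks, 4
  repetitions, 300 time points, 200 replicates, Euclidean metric.
  Under the null, the shorter time series only raises distance noise
  and does not affect test calibration.
* *power profile* (test suite): 20 subjects, 60 nodes, 300 time
  points, 8 replicates on a 0/20/.../100% grid, metrics EUC, PCD,
  Jaccard top-0.5% and LERM. At 60 nodes the signal regions cover a
  ~20× larger *fraction* of edges than at 268 nodes, so power rises
  with signal considerably earlier than in the full-scale study; the
  published full-scale crossings are not expected to reproduce at this
  profile, and the corresponding acceptance check documents that
  discrepancy rather than hiding it. A `--paper-scale` switch in the
  CLI restores the full design for cluster runs.

## Numerical choices, degenerate inputs, limitations

* Matrix validation symmetrizes asymmetries up to $10^{-8}$ by
  averaging and rejects anything larger; entries outside $[-1, 1]$
  beyond tolerance are errors.
* Thresholding requires $k \ge 1$ ("empty key set" otherwise); Jaccard
  requires a nonempty union of key sets.
* PCD requires nonconstant edge weights ("constant edge weights"
  error).
* The REML optimizer reports non-convergence with its trace; boundary
  variance estimates ($g_b = 0$) warn and are flagged in `glance()`.
* All estimators are invariant to subject relabeling and row order;
  this is tested.
* Distances are only comparable within a metric; `build_design()`
  refuses mixed-metric input.
* Directed networks, affine-invariant Riemannian metrics beyond LERM,
  geodesic means, and mixed-effects MDMR are out of scope.
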