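---
title: "From in vitro drug response to prognostic gene signatures: methods"
author: "chemosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From in vitro drug response to prognostic gene signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosig)
```

# Overview

`chemosig` implements a complete chain from in vitro chemosensitivity
panels to prognostic gene-expression classifiers for patients:

1. **Dose-response fitting** — four-parameter log-logistic (LL.4) curves
   fitted to viability data give a per-culture, per-drug IC50.
2. **Correlation screening** — per dataset, every gene's expression is
   correlated (Spearman) with IC50; hits must replicate co-directionally
   across independent datasets.
3. **Signature search** — a significance-gated forward beam search grows
   logistic-regression classifiers over the screened genes, pruned at
   each step by repeated cross-validation.
4. **Survival evaluation** — the selected classifier's predicted groups
   are compared by Kaplan-Meier curves, the log-rank test, and a
   multivariate Cox model against clinical covariates.

A seeded synthetic-data module generates panels and cohorts with planted
signal so every stage is testable without external downloads.

# Dose-response model

Viability fractions $y$ at dose $x$ (µM) are modeled as

$$f(x) = \mathrm{lower} + \frac{\mathrm{upper} - \mathrm{lower}}
{1 + (x/e)^{\mathrm{slope}}},$$

fitted by Levenberg-Marquardt least squares with $e$ parameterized on the
log scale so it stays positive. Replicate wells enter as individual
points rather than dose-wise means, which keeps the residual degrees of
freedom honest. The sign convention is `slope > 0` for viability
decreasing with dose; fits whose two asymptotes collapse (constant
responses) or that exhaust the iteration budget are returned with
`converged = FALSE` rather than silently.

`ic50()` returns by default the **relative** IC50 — the inflection $e$,
the half-way point between the two asymptotes, which is the convention of
the widely used dose-response packages. The **absolute** IC50 (where
$f(x) = 0.5$) is available in closed form,
$x = e\,((\mathrm{upper}-0.5)/(0.5-\mathrm{lower}))^{1/\mathrm{slope}}$,
and raises an error when 0.5 lies outside the asymptote range instead of
extrapolating.

Starting values are taken from the data (asymptotes from the response
range, $e$ at the dose nearest mid-response, slope 1); on sigmoid
viability data this initialization is robust, and a grid-search oracle in
the test suite confirms the optimizer reaches the global least-squares
basin on noisy plates.

# Expression normalization

Two count transforms are provided, both monotone within a sample so that
the rank-based screen downstream is unaffected by their details:

* `sizeFactorLogTransform()` — median-of-ratios size factors (per-sample
  median of count / gene-wise geometric mean, genes containing any zero
  excluded from the reference) followed by
  $\log_2(\mathrm{count}/sf + \mathrm{pseudocount})$, pseudocount 1.
  This is a deliberate, documented stand-in for regularized-log
  transforms: it preserves the rank structure that Spearman screening
  uses while avoiding a shrinkage estimator whose details the screen is
  insensitive to. Note that the geometric-mean reference depends on all
  samples, so size factors are meaningful up to a common scale; what is
  exactly invariant is that proportional samples (pure depth differences)
  receive proportional size factors and identical transformed columns.
* `tmmLogCPM()` — trimmed mean of M-values with the conventional
  constants (M-trim 0.30, A-trim 0.05, precision weights, reference =
  sample whose upper quartile is closest to the mean upper quartile),
  factors rescaled to geometric mean 1, followed by $\log_2$ CPM with
  prior count 0.5. This is the cohort-level normalization used before
  classifier training on RNA-seq cohorts.

Replicate libraries from the same culture are collapsed by
`collapseReplicates()` (mean on the normalized scale) because IC50 is a
per-culture quantity; correlating per-library profiles would triple the
apparent sample size without adding information.

# Correlation screening and intersection

For each gene, `spearmanScreen()` computes Spearman's $\rho$ with
mid-ranks for ties against per-sample IC50, after pairwise removal of
missing IC50 values (at least 4 shared samples required). A gene is
significant when $|\rho| > 0.3$ **and** $p < 0.05$, both strict. The
modest $\rho$ threshold reflects that drug response is multifactorial —
no single gene carries a large effect — and reliability is enforced not
by multiple-testing correction but by **co-directional intersection**:
`codirectionalIntersection()` keeps a gene only if it is significant with
the same sign in *every* dataset. With $k$ independent datasets the null
probability of surviving is $2(q/2)^k$ for a per-dataset pass rate $q$,
i.e. about $3\times10^{-5}$ for $q = 0.05$ and $k = 3$, which is why raw
p-values suffice.

Two p-value methods are available:

* `t_approx` (default): $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ against a
  $t_{n-2}$ distribution.
* `exact_permutation` (for $n \le 10$, where the approximation is
  weakest, e.g. a seven-culture organoid panel): the full permutation
  distribution of $\sum_i a_i b_{\pi(i)}$ is computed exactly by a
  bitmask dynamic program over which ranks have been assigned
  ($O(2^n \cdot n \cdot T)$), with mid-rank ties handled by doubling the
  ranks to integers. The two-sided p-value counts permutations with
  $|\rho_{\pi}| \ge |\rho_{\mathrm{obs}}|$.

Constant genes have undefined $\rho$; they are reported as `NaN` and
non-significant, never as an error, so a single flat gene cannot abort a
screen. `crossDrugOverlap()` reports pairwise and all-drug intersections
by direction plus a contradiction list (genes significant in opposite
directions for different drugs).

# The gated beam search

`searchSignatures()` grows logistic classifiers over a gene pool:

* **Size 1**: one model per pool gene; the gene itself must be
  significant (Wald $p < 0.05$). The gate for later steps only
  constrains "all other genes", so requiring the same level for a lone
  gene keeps the rule consistent.
* **Extension**: every survivor of size $s$ is extended by every unused
  pool gene. Gene sets reached through different orders are collapsed to
  one candidate; because the fitted model depends only on the set, the
  coefficients are cached, but the *gate* depends on which gene is new,
  so a set is kept as soon as any parent order passes.
* **Gates**: the new gene must be at least marginally significant
  ($p < 0.15$) and every previously included gene significant
  ($p < 0.05$), from the Wald statistics of the refitted model.
  Non-converged, separated or singular fits fail the gate — the beam
  simply continues without them.
* **CV pruning**: gated candidates are scored by stratified repeated
  3-fold cross-validated AUC (5 repeats by default; the repeat count is
  configurable and mainly stabilizes the cut) and the top 50% survive.
  Ties are broken by training AUC, then by the lexicographically
  smallest gene set, making the whole search bit-reproducible given the
  data and `seed`. Fold assignments are a pure function of the seed and
  are shared by all candidates at a step, so models are compared on the
  same partitions.
* **Stop**: at 12 genes, or earlier when no candidate passes the gates.

All retained models of every size form the registry, with per-step
counts (raw extensions, unique sets, gated, kept) logged so the scale of
the enumeration is visible. `selectBest()` then applies the selection
rule: among models whose training *and* held-out test AUC both exceed a
threshold (0.85 by default), the one with the highest cross-validated
AUC wins. When nothing passes, the result says so explicitly — the
caller may lower the threshold to 0.75, as is appropriate for cohorts
with weaker signal — rather than silently falling back.

ROC AUC is the Mann-Whitney statistic ($U/(n_1 n_0)$, ties counted 1/2).
The logistic fits use iteratively reweighted least squares with the
standard deviance-based stopping rule, implemented in C++ because a
search refits $10^4$–$10^6$ models; the test suite verifies coefficient
and p-value agreement with `stats::glm` to numerical precision.

# Survival evaluation

`definePrognosticStatus()` dichotomizes follow-up at a 5-year horizon:
an event within the horizon is *unfavorable*; surviving past the horizon
is *favorable*; an event-free patient censored before the horizon is
*uncertain*. Uncertain patients are excluded from classifier training
and testing (their 5-year label is unknowable) but are retained, as
censored observations, in complete-dataset Kaplan-Meier analyses. An
event occurring exactly at the horizon counts as within it.

`kaplanMeier()`, `logrankTest()` and `coxPH()` wrap the survival
package's product-limit estimator, $k$-group log-rank statistic and
partial-likelihood Newton-Raphson (Efron ties by default, Breslow
available), with hand-computed fixtures and brute-force O-E/V oracles in
the tests. `coxPH()` reports hazard ratios with 95% Wald intervals,
errors on constant covariates by name, drops aliased (collinear) terms
with a `singular` flag, and flags monotone-likelihood fits.
`evaluatePredictions()` ties the pieces together for a predicted
grouping: per-group KM curves, log-rank p, and a forest-plot-ready Cox
table adjusting for supplied clinical covariates; a single predicted
group degrades gracefully to KM-only with a warning.

# Synthetic data

`simulateInvitroPanel()` emulates the screening inputs: several
independent datasets (7–50 samples) over a shared gene universe,
log-normal counts (per-gene log-mean uniform on $\log 50$–$\log 5000$,
dispersion 0.5 — ties after rounding are rare at these depths), log-IC50
normal around 10 µM with a one-log-unit spread. Planted genes are
generated from a Gaussian copula: the latent Pearson correlation
$r = 2\sin(\pi\rho_s/6)$ is the exact closed form that yields Spearman
$\rho_s$ for bivariate normals, and the monotone count mapping preserves
it up to rounding. Null genes and datasets are mutually independent, so
any cross-dataset reproducibility is the planted signal.

`simulateCohort()` emulates the patient cohorts: per-gene log-normal
expression, a logistic outcome model on the standardized expression of
the signature genes (the intercept is solved so the unfavorable fraction
hits its target, 0.45 by default — close to the roughly balanced
dichotomized cohorts this design targets), and survival times drawn
*conditionally on the binary outcome* from a Weibull hazard scaled by
the same linear predictor: event inside the horizon iff unfavorable,
censoring beyond the horizon for favorable patients, and a 15% early
censoring rate creating uncertain-status patients. The binary outcome is
primary because it is the classifier target; the generated times always
reproduce the intended status labels under `definePrognosticStatus()`.

What the generators deliberately do **not** emulate: library-size and
GC biases, overdispersion structure of real RNA-seq, batch effects,
probe-level microarray artifacts, correlated co-expression modules, or
informative censoring. Green tests therefore demonstrate that the
algorithms recover what they are designed to recover under their own
statistical assumptions — not that a particular clinical dataset will
yield a signature.

# Numerical choices and edge cases

* Strict inequalities everywhere the thresholds appear ($|\rho| > 0.3$,
  $p < 0.05$, AUC $>$ threshold, probability $>$ 0.5 for an unfavorable
  call — a probability of exactly 0.5 is favorable).
* IRLS: deviance-change stopping at $10^{-8}$, 25 iterations, fitted
  probabilities clamped at $10^{-12}$; separation flagged when fitted
  probabilities pin to 0/1 within $10^{-9}$.
* The keep-fraction cut uses `ceiling`, so a lone gated candidate always
  survives.
* Seeds: every generator and the search take explicit integer seeds;
  library code saves and restores the caller's RNG state.
* Time units are years internally; month-scale clinical tables are
  converted on read.

# Problem sizes

The test and acceptance suites run the pipeline at deliberately modest
sizes chosen to exercise every code path with stable Monte-Carlo
margins: screening calibration at 2000 null genes × 20 samples × 200
replicates; intersection recovery at three 30-sample datasets with 10
planted genes among 500 nulls × 100 replicates; the full search at a
60-gene pool, 160 patients, 20 seeded replicates; Cox recovery at
n = 2000 with a true hazard ratio of 2. These are the package's own
simulation conditions and are documented here so they can be scaled up
by users with more patience.

# Limitations

* The screen treats genes independently; co-expression means planted
  and passenger genes can enter the intersection together.
* The beam search explores exhaustively under its gates; with very weak
  gates (`pNew`, `pRetained` near 1) the candidate set can grow
  combinatorially.
* No regularized (lasso/ridge) alternative, nested-CV performance
  estimation, or probability calibration is provided.
* Gene identifiers are matched as exact strings; cross-platform mapping
  is the caller's responsibility.
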