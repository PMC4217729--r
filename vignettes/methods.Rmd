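---
title: "Methods: hierarchical Bayesian mapping of ESRD incidence over small areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian mapping of ESRD incidence over small areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

End-stage renal disease (ESRD) incidence varies strongly over small
administrative areas, but area-level counts are small (a few dozen cases per
area over several years), so raw standardized incidence ratios (SIRs) are
dominated by Poisson noise and spatial autocorrelation. `esrdmap` implements
the standard epidemiological answer: indirect age-sex standardization to get
expected counts, then hierarchical Bayesian smoothing with the
Besag–York–Mollié (BYM) model, optionally with ecological covariates such as
deprivation quintiles, so that each area's relative risk borrows strength
from its neighbours and from the region as a whole.

## Standardization

For each area $i$, sex–age stratum $s$ (two sexes crossed with 5-year age
bands 0–4 … 90+), population $n_{is}$ and duration $T$ years:

* crude rate $= \text{cases}/(\text{population} \cdot T)$, reported per
  million person-years ("pmi");
* internal reference rates $r_s = \sum_i O_{is} / (T \sum_i n_{is})$;
* expected counts $E_i = T \sum_s n_{is} r_s$;
* raw SIR $= O_i / E_i$ with exact Poisson intervals from the gamma-quantile
  formulation, $[\,q_{\gamma}(\alpha/2; O_i)/E_i,\;
  q_{\gamma}(1-\alpha/2; O_i+1)/E_i\,]$.

Internal standardization makes $\sum_i E_i = \sum_i O_i$ exactly, so the
pooled regional SIR is identically 1; this is asserted to machine precision
in the tests. External reference rates can be supplied as a CSV when a
national reference is preferred. Populations are treated as constant over
the study window; no temporal disaggregation is attempted.

## Townsend deprivation index

The index is the sum of four z-standardized census components: % households
not owner-occupied, % unemployment, % household overcrowding, % households
without a car. Two conventions are exposed because the literature is not
uniform: the classical transform (`townsend1988`, default) applies
$\log(x+1)$ to the unemployment and overcrowding components before
z-scoring; `none` skips the transform. z-scores use the population
(n-denominator) standard deviation over the supplied units, so the mean
score is exactly zero — a useful invariant, and the reason the score's mean
is a sharp acceptance check rather than a statistical one. Quintiles are
rank-based with ties broken by unit identifier and remainders allocated to
the lowest quintiles, making the classification deterministic; Q1 (least
deprived) is the reference level of the four dummy covariates.

## The BYM model and its sampler

At the first level $O_i \sim \text{Poisson}(E_i \theta_i)$. At the second,
$\log \theta_i = \alpha + u_i + v_i + x_i^{\mathsf T}\beta$, with
$u_i \sim N(0, \sigma_u^2)$ i.i.d. heterogeneity and $v$ an intrinsic
conditional autoregressive (CAR) field: $v_i \mid v_{-i} \sim
N(\bar v_{\partial i}, \sigma_v^2 / n_i)$ with binary contiguity weights.
The intrinsic CAR is improper; identifiability is restored by constraining
$\sum_i v_i = 0$ and letting $\alpha$ carry the level (the WinBUGS
`car.normal` convention). At the third level both precisions get
$\text{Gamma}(0.5, 0.0005)$ hyperpriors by default — a widely used weakly
informative choice in the Bernardinelli tradition; the exact hyperparameters
are configurable because no single convention is universal. $\alpha$ and
$\beta$ get vague normal priors (sd 1000).

The sampler is Metropolis-within-Gibbs, written for this package:

* univariate random-walk Metropolis updates for $\alpha$, each $\beta_k$
  (touching only the areas where the covariate is non-zero), each $u_i$,
  and each $v_i$ against its CAR full conditional;
* after every full $v$ sweep, $v$ is recentred and the removed mean is
  absorbed into $\alpha$, so the constraint holds exactly at every kept
  draw — this is a reparametrization of the same posterior, not an
  approximation;
* conjugate Gibbs draws for the precisions, with the CAR shape using
  $(n - c)/2$ where $c$ is the number of connected graph components
  (the rank of the intrinsic precision);
* proposal scales adapt toward ~0.44 acceptance in windows of 50 sweeps
  during burn-in only, and are frozen afterwards so the kept chain is a
  valid time-homogeneous Markov chain.

Default run length is 25,000 kept sweeps after 5,000 burn-in. The compiled
(Rcpp) engine is the default; a pure-R reference engine implements the same
sweep through the exported update functions and is used to cross-check the
compiled code. Smoothed SIRs are reported as posterior means of $\theta_i$
(medians are also given); quintile relative risks as
$\exp(\text{posterior mean of } \beta_k)$ with exponentiated quantile
intervals, and the posterior mean of $\exp(\beta_k)$ alongside, since both
conventions appear in applied work. "Significant" means the 95% equal-tailed
credible interval excludes 1.

Areas with no neighbours ("islands") make the CAR conditional variance
undefined; they are rejected by default, or given $v_i = 0$
(heterogeneity-only risk) under an explicit flag.

### Verification strategy

Two independent routes check the sampler. First, a grid-quadrature oracle
for instances of at most 3 units with fixed precisions: $u_i$ is integrated
out on a fine 1-D grid per unit, and the remaining integral over $\alpha$
and the spectral coordinates of the CAR sum-to-zero subspace is evaluated on
a tensor grid. MCMC posterior means must match the oracle within 3
Monte-Carlo standard errors. Second, replicate parameter-recovery studies
against the synthetic generator's ground truth, plus null-calibration
(flat-risk data must yield few "significant" areas) and shrinkage
(smoothed SIRs less variable than raw ones at low expected counts) checks.

## The synthetic registry generator

Because real renal-registry extractions are access-restricted, validation
runs on synthetic registries whose defaults encode the study conditions the
package targets: 169 areas (13×13 rook lattice standing in for canton
geometry), mean area population 23,725 with lognormal dispersion
(`pop_sdlog = 0.6`, giving realistic 5,000–200,000 extremes), 7 years of
follow-up, an age profile shaped like a western-European pyramid with
incidence rising steeply with age and a male/female rate ratio of 1.43,
calibrated so the overall crude rate is 163 cases per million person-years;
quintile log-relative-risks `log(1.18, 1.28, 1.30, 1.44)`; case attributes
with 27.5% diabetic and 24.4% vascular nephropathy, eGFR at initiation
$\sim N(9.05, 1.46^2)$ truncated positive, and Poisson(3) nephrologist
visits. The random-effect scales default to $\sigma_u = 0.1$,
$\sigma_v = 0.2$, chosen once as values that reproduce a realistic smoothed
SIR spread (roughly 0.65–1.65) at these expected counts.

Design choices worth recording:

* The CAR field is drawn **exactly** by eigen-decomposition of the graph
  Laplacian (independent normals with variance $\sigma_v^2/\lambda_k$ on
  the non-null eigenvectors), not by running a chain; its empirical
  covariance equals $\sigma_v^2 (D-W)^{+}$, which makes the generator tests
  sharp. For the 2-node graph this gives $\mathrm{Var}(v_1) =
  \sigma_v^2/4$ (the pseudo-inverse convention).
* The deprivation→risk link routes through the **actual pipeline
  operations**: census components are generated from a latent axis, scored
  and cut into quintiles by the same functions the analysis uses, and the
  quintile dummies multiply risk. The fitted model is therefore correctly
  specified by default; a `continuous` link is provided as a
  misspecification toggle.
* The intercept is calibrated so the population-weighted mean relative risk
  is 1, keeping the realized overall crude rate at its target even when
  deprivation effects are on.
* What the generator does **not** emulate: real geography and irregular
  adjacency, migration and temporal population change, registry
  under-ascertainment, and within-area heterogeneity of deprivation.
  Passing recovery tests therefore demonstrates correctness of the
  machinery under the model's own assumptions, not robustness to the ways
  real registry data violate them.

## Numerical choices

* Exact Poisson SIR intervals use the gamma-quantile identity; tests verify
  them against direct tail-probability root-finding to $10^{-6}$.
* The log posterior drops additive constants consistently; tests compare
  differences between states against a fully normalized independent
  re-derivation.
* Quintile ties break by unit identifier; remainder units go to the lower
  quintiles.
* Degenerate inputs fail loudly: constant census components
  (zero variance), islands passed to the CAR prior, zero expected counts
  with observed cases, asymmetric adjacency files.
* Run manifests contain file hashes, seed, config and package version, and
  deliberately no wall-clock timing, so a rerun with the same inputs and
  seed is byte-identical (timing goes to the log stream instead).

## Problem sizes used by the test suite

The suite exercises the full 169-unit study geometry with shortened chains
(2,000 kept / 500 burn-in) for replicate studies — at these data sizes the
posterior is well explored by such chains, and 50-replicate recovery plus
20-replicate calibration studies complete in well under a minute — and
reserves long chains (20,000 kept) for the small oracle-equivalence
instances where Monte-Carlo error must be tiny. Default production settings
remain 25,000/5,000.

## Known limitations

* Only the intrinsic CAR + heterogeneity (BYM) prior is implemented; no
  Leroux/BYM2/proper-CAR alternatives, and no spatio-temporal extension.
* Adjacency must be supplied (GAL or JSON) or generated as a lattice;
  deriving contiguity from polygon boundaries is out of scope, as is
  cartographic rendering (GeoJSON export uses centroid points).
* Ecological associations (log-SIR vs area covariates) carry the usual
  ecological-fallacy caveat: they are area-level correlations, not
  individual-level effects.
* With internal standardization the covariate relative risks are contrasts
  against the regional age-sex profile; with strong confounding between
  age structure and deprivation the quintile RRs absorb some of it, as in
  any ecological Poisson regression.
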