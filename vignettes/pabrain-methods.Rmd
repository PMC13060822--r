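---
title: "Methods: linking accelerometer-derived physical activity to brain phenotypes"
author: "pabrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking accelerometer-derived physical activity to brain phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pabrain)
```

# The scientific problem

Wrist-worn accelerometers summarize a participant's habitual physical
activity (PA) into a small number of interpretable features — total volume,
intensity-specific minutes, fragmentation of active/sedentary behaviour, and
circadian rhythmicity. Brain MRI pipelines summarize structure and function
into image-derived phenotypes (IDPs): here, Fisher-z-transformed functional
connectivity (FC) edges between network nodes (a 55-node parcellation gives
55·54/2 = 1485 edges) and gray-matter volumes (GMV) for 139 anatomical
regions. `pabrain` implements a three-stage analysis of how these blocks
relate in a middle-aged population cohort, together with a synthetic-cohort
generator that makes every stage testable against known ground truth when
the underlying cohort data are access-restricted.

The three stages are:

1. **Bipartial canonical correlation analysis (CCA)** — symmetric
   multivariate association between the PA block and an IDP block, after
   each block is residualized on its own confounders, with dual
   significance testing (an asymptotic Bartlett chi-square approximation
   and a permutation test), per-mode variance explained, and
   cross-loadings of PA variables on the primary imaging variate.
2. **Mass-univariate importance** — per-phenotype partial F-tests of the
   PA block given confounders with Benjamini–Hochberg (BH) false-discovery
   control, repeated 10-fold cross-validated predictive correlations, and
   three variable-importance engines (coefficient t-tests, bidirectional
   stepwise BIC with forced confounders, random-forest permutation
   importance) combined by consensus ranking.
3. **Nested logistic disease-risk models** — per disease, M0 (confounders
   only), M2 (+PA), M3 (+IDP), M1 (+both), compared by vertically averaged
   ROC curves with numerically integrated AUC and by test-set McFadden
   pseudo-R² over repeated stratified 10-fold cross-validation.

# The PA feature set

Eleven per-participant features are derived from minute-level ENMO traces
(milli-g), via `compute_pa_summaries()`:

| feature | meaning | unit |
|---|---|---|
| TLAC | per-day total of log(1 + ENMO), averaged across days | log-milli-g |
| LIPA | minutes/day with ENMO in [sedentary cut, MVPA cut) | min |
| MVPA | minutes/day with ENMO ≥ 193 milli-g | min |
| SBout / ABout | mean maximal-run length of sedentary / active minutes | min |
| SATP / ASTP | sedentary→active / active→sedentary transition probability | — |
| DARE | daytime (08:00–20:00) share of the daily log-acceleration total | — |
| M10 / L5 | best mean log(1+ENMO) over a contiguous 600-min / worst 300-min window | log-milli-g |
| RA | relative amplitude (M10 − L5)/(M10 + L5) | — |

Conventions this package fixes (each a named argument, since upstream
derivations vary across the actigraphy literature): a minute is *active*
when ENMO ≥ `sedentary_cut` (default 30 milli-g); the LIPA/MVPA boundary is
`mvpa_cut = 193` milli-g; transition denominators exclude the final minute
of each day (it has no successor); M10/L5 windows are contiguous within a
day and do not wrap midnight; per-day values are averaged across days, with
bout runs and transition counts pooled over days before forming
means/ratios; TLAC uses log(1 + x) rather than log x so that zero-activity
minutes contribute zero instead of −∞. Degenerate inputs degrade rather
than fail: a state that never occurs yields `NA` for its transition
probability and bout mean (never a misleading 0), and a constant day has
RA = 0 with a logged warning.

`circadian_summaries()` finds the M10/L5 windows by an O(day-length)
cumulative-sum scan; a brute-force enumeration over all contiguous windows
is kept in the test suite as the oracle, and the two agree exactly.

# Stage 1: bipartial CCA

Given residualized blocks $\tilde X$ (n × p) and $\tilde Y$ (n × q), CCA
finds weight pairs $(a_j, b_j)$ maximizing
$\rho_j = \mathrm{corr}(\tilde X a_j, \tilde Y b_j)$ subject to successive
variates being uncorrelated. `fit_cca()` computes the $\rho_j$ as singular
values of the whitened cross-covariance
$\Sigma_{xx}^{-1/2}\,\Sigma_{xy}\,\Sigma_{yy}^{-1/2}$, with the inverse
square roots formed spectrally and eigenvalues below a relative tolerance
of $10^{-10}$ truncated, so a numerically rank-deficient block degrades to
its numerical rank instead of amplifying noise. Variates are rescaled to
exact unit sample variance, and each mode's sign is fixed so its
largest-magnitude PA-side loading is positive — canonical signs are
arbitrary, and a fixed orientation is needed before loadings can be read.

*Residualization.* `residualize_block()` projects each block onto the
orthogonal complement of its own confounder matrix (intercept always
included) through a rank-revealing QR solve; a rank-deficient confounder
matrix triggers a pseudoinverse projection with a warning rather than a
failure. Residual columns are exactly orthogonal to every confounder, and
therefore so is any linear combination of them — including the canonical
variates, which the test suite verifies to $10^{-8}$.

*Scale.* By default residualized columns are standardized before the fit
(correlation-scale CCA); `standardize = FALSE` gives the covariance-scale
variant. Canonical correlations are invariant to per-column scaling, but
coefficients and variance-explained proportions are easier to interpret on
the standardized scale, hence the default.

*Inference.* Two tests are run per mode $s$:

- `approximation_test()`: Wilks' $\Lambda_s = \prod_{j \ge s}(1-\rho_j^2)$
  with Bartlett's multiplier $-(n - 1 - (p+q+1)/2)$ referred to
  $\chi^2$ with $(p-s+1)(q-s+1)$ degrees of freedom. Bartlett's form is
  the default because the intended regime ($n$ in the thousands,
  $p+q \ll n$) is squarely asymptotic; Rao's F variant — exact in the
  scalar case — is available via `method = "rao"`.
- `permutation_test()`: rows of the residualized PA block (the smaller
  side) are permuted; $p = (1 + \#\{\rho^*_j \ge \hat\rho_j\})/(B+1)$.
  Permuting one block's rows leaves both within-block covariances — and
  hence the whitening operators — unchanged, so the implementation
  precomputes them and refits only the cross-covariance per draw.

Residualization can break the exchangeability that permutation inference
relies on beyond the first mode. The package computes and reports all
modes but attaches an explicit caveat to modes past the primary one
(visible in `summary()` and the pipeline log); interpretation should rest
on mode 1. This is a reporting stance, not a computational restriction.

*Variance explained and loadings.* Mode $j$ explains
$\sum_l \mathrm{corr}(y_l, v_j)^2 \mathrm{var}(y_l) / \sum_l \mathrm{var}(y_l)$
of its own block — the variance-weighted mean squared loading, which
reduces to the plain mean squared loading on standardized blocks and sums
to 1 over a block's full mode set. A large $\rho_1$ with a small
variance-explained share on the imaging side is the expected signature of
a narrow brain subspace aligned with dominant PA dimensions, so the two
quantities are always reported together.

# Stage 2: mass-univariate importance

`screen_responses()` tests, per phenotype column, the PA block's
contribution given confounders with a partial F-test (the
confounders-only model is the reduced model), then applies BH across the
q p-values at level α = 0.05 (configurable). The partial F — rather than
the overall model F — is the default because the scientific question is
the PA block's contribution *after* confounder adjustment; the overall
test is available behind `test = "overall"`.

For selected responses, `cv_predictive_correlation()` reports the mean
over repetitions of the Pearson correlation between the observed response
and its out-of-fold linear prediction (design: confounders + PA, the
default; PA-only is a caller choice by passing a different design).

The three importance engines score each PA variable per response:
−log₁₀ of the coefficient t-test p-value; a 0/1 stepwise-BIC selection
indicator (bidirectional `stats::step()` from the confounders-only model,
confounders forced through the scope's lower bound, k = log n); and
random-forest permutation importance (%IncMSE over out-of-bag
permutations, `randomForest`), which alone can register non-linear or
interaction effects. `consensus_ranking()` rank-normalizes each method's
column-mean scores and averages the ranks.

# Stage 3: nested disease risk

For each disease, `nested_risk()` runs repeated stratified 10-fold
cross-validation (stratification by outcome is essential at 2–12%
prevalence; unstratified folds can lose all events). Within each
repetition every participant receives exactly one out-of-fold probability
per model, and the split is shared across M0–M3 so models are compared on
identical folds.

*Imaging dimensionality.* With 1485 FC edges and rare outcomes,
unpenalized logistic fits of M1/M3 are ill-posed. The package projects a
wide imaging block onto its leading principal components retaining 90% of
variance (configurable), re-learned inside each training fold so the
cross-validation stays honest; M1 and M3 share the reduction, keeping the
models nested. This reduction is an interpretation choice and is flagged
as such; narrow imaging blocks (≤ max(20, n/20) columns) are used as-is.

*ROC and AUC.* Each repetition's pooled out-of-fold probabilities give one
empirical ROC (ties share a vertex, so its trapezoidal area equals the
Mann–Whitney AUC with half-credit for ties). Curves are averaged
vertically on a 1001-point FPR grid and the mean curve is integrated
numerically. Averaging the per-repetition exact AUCs instead agrees with
the mean-curve AUC up to grid interpolation error; the test suite bounds
the discrepancy by 0.005 across a full disease panel.

*Pseudo-R².* McFadden's $R^2 = 1 - \ell(M)/\ell(M_0)$ with Bernoulli
log-likelihoods evaluated out-of-fold per repetition, the null model also
refit per training fold. Boundary probabilities on the correct side
contribute zero log-likelihood exactly; only opposite-label boundary
probabilities are clipped (at $10^{-12}$, with a warning). On training
data the nested ordering $R^2(M_1) \ge R^2(M_2), R^2(M_3)$ holds exactly
and is asserted on every fit; out-of-fold values can be negative for
overfit models, which is informative rather than pathological.

# The synthetic cohort generator

`generate_cohort()` draws cohorts from a linear Gaussian factor model —
chosen because CCA's estimand is a second-moment quantity, which makes
population canonical correlations available in closed form
(`population_canonical_correlations()`), giving every downstream stage a
parameter-recovery oracle.

For each planted mode with target ρ, one standard-normal latent loads on
orthonormalized directions in the PA block and each imaging block, with
loading magnitude $c = \sigma\sqrt{\rho/(1-\rho)}$ against isotropic noise
of scale σ on **both** sides, so the population canonical correlation is
exactly ρ. Confounders (one binary sex-like, continuous age-like and
motion-like) affect every block but are generated independently of the
latents, so residualization removes their contribution without touching
the planted correlation. An extra within-PA common factor (orthogonalized
against the planted directions, hence invisible to the cross-block
spectrum) emulates the strong multicollinearity of real accelerometry
features; its strength is a config choice, as the true PA correlation
structure is not pinned down by published summaries.

Block-specific realism constraints:

- **FC**: edge signals live on the Fisher-z scale, scaled by a fixed 0.25
  so that `tanh` maps them to netmat correlations comfortably inside
  (−0.95, 0.95) (clamped at atanh 0.95, a many-sigma event); netmats are
  exactly symmetric with unit diagonal, and `atanh` of a rebuilt netmat
  reproduces the stored edges bit for bit.
- **GMV**: volumes are the exponential of a small-scale (0.1) Gaussian
  field, hence strictly positive; the planted correlation is exact on the
  log scale and approximate (to first order in the scale) on the observed
  scale, so recovery benchmarks use the FC block.
- **Disease**: labels are Bernoulli draws from a logistic model over
  standardized confounders/PA (and optionally an imaging score), with the
  intercept solved numerically (root-finding on the mean of `plogis`) to
  hit a target prevalence — default 4.5% (diabetes-like), 2.3% (stroke),
  3.3% (coronary heart disease) and 12.5% (cancer), the regime in which
  AUC and pseudo-R² behaviour actually matters. Default risk is driven by
  confounders + PA only.

What the generator does *not* emulate: marginal distributions of specific
real-world IDPs, longitudinal structure, missingness beyond an optional
MCAR mask, or non-linear PA–IDP coupling. Passing tests therefore
demonstrate correctness of the estimators under the factor-model
assumptions, not robustness to real-data pathologies.

# Numerical choices and problem sizes

- Spectral truncation at relative eigenvalue $10^{-10}$ wherever a
  covariance is whitened or inverted.
- Permutation p-values use the add-one convention, so the smallest
  attainable value is $1/(B+1)$ and at least 99 permutations are required.
- Stepwise ties resolve by `step()`'s first-improvement rule in the fixed
  column order; the search space (11 PA variables) is finite, so the
  search always terminates.
- ROC vertical averaging uses 1001 grid points — resolution beyond
  typical per-fold sample sizes without interpolation artifacts.
- Validation benchmarks in the test suite use n = 8000 cohorts with a
  21-node (210-edge) FC-like block for parameter recovery (50
  replicates), 500 simulations × 199 permutations for inference
  calibration, 10⁵ random p-vectors for the BH oracle, and 40 replicates
  for the qualitative risk/importance patterns — sizes at which the
  sampling error of each checked quantity is well below its tolerance.
  At n = 8000 with 221 total block columns, the first sample canonical
  correlation of a ρ = 0.5 cohort carries an upward finite-sample bias of
  about 0.02; the recovery tolerance of 0.03 accommodates exactly this.
  Sample canonical correlations of truly null modes sit at the
  random-matrix floor $\approx (\sqrt p + \sqrt q)/\sqrt n$ rather than
  near zero, so null-mode checks compare against a matched-null
  distribution, never against zero.

# A worked example

```{r example, eval = FALSE}
library(pabrain)

cfg <- cohort_config(2000, n_fc_nodes = 21, n_gmv = 20, seed = 7,
                     latent_spec = list(list(rho = 0.5)))
coh <- generate_cohort(cfg)

fit <- bipartial_cca(coh$pa, coh$fc_edges,
                     confounders_x = coh$confounders,
                     confounders_y = coh$confounders,
                     n_perm = 199, seed = 1)
summary(fit)

scr <- screen_responses(coh$fc_edges, as.matrix(coh$confounders), coh$pa)
scr

nr <- nested_risk(coh$disease[, "diabetes"], coh$confounders, coh$pa,
                  coh$gmv, n_reps = 10, seed = 2)
nr
```

# Known limitations

- The permutation test past mode 1 inherits the exchangeability caveat;
  the package surfaces it but cannot repair it (projection-based
  corrections are out of scope).
- The imaging-block PCA reduction inside the risk stage is a modelling
  choice required to make unpenalized logistic fits well-posed; results
  for wide blocks should be read as "the leading imaging subspace", not
  the full edge set.
- GMV ground-truth correlations are exact only on the log scale.
- The generator's Gaussian linearity means non-linear importance signals
  (the random forest's raison d'être) must be planted explicitly in test
  designs rather than arising from the cohort model itself.
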