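---
title: "Building regression-based normative databases from multi-study control data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building regression-based normative databases from multi-study control data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normforge)
```

## The statistical model

For one test variable, let $y_{ij}$ be the raw score of participant $i$ in
donating study $j$. After transformation (below), scores follow a linear
mixed model

$$ z_{ij} = \beta_0 + \beta_a\,\mathrm{age}_{ij} + \beta_s\,\mathrm{male}_{ij}
          + \beta_e\,\mathrm{edu}_{ij} + u_j + \varepsilon_{ij},
   \qquad u_j \sim N(0, \sigma^2_{study}),\;
          \varepsilon_{ij} \sim N(0, \sigma^2_{resid}). $$

Age is continuous in years; sex is contrast-coded female = 0, male = 1 (any
consistent binary coding yields the same fit — the coding is recorded in
the coefficient name `sexmale`); education is a 7-level ordinal scale
treated as an interval predictor so that one slope is estimated instead of
six separate level effects. The random intercept $u_j$ captures
between-study differences — compensation, inclusion criteria, recruitment —
that make pooled scores non-independent. When a variable was administered
in only one study the model collapses to ordinary least squares with
$\sigma_{study} = 0$.

A new patient belongs to no contributing study, so their expected score
uses the fixed effects only ($E[u] = 0$) and their deviation is judged
against the *total* normative SD $\sqrt{\sigma^2_{study} + \sigma^2_{resid}}$:
between-study variability is part of normative uncertainty for someone
whose hypothetical study is unknown. A within-study comparison
(`sd_type = "residual"`) is available; it gives more extreme z-scores. No
small-sample t-correction is applied to patient z-scores: these norms are
built from thousands of controls, where the normal approximation is
accurate; such corrections matter for the tiny normative samples of
traditional norm tables.

## Pipeline stages and their tunable parameters

| Stage | Parameter | Default | Why |
|---|---|---|---|
| Border cleaning | extreme borders | per-variable config | Curation, not computation: upper = maximum attainable score; lower = worst score compatible with cognitive health (typically a published first percentile of the worst-performing norm group). Border values themselves are attainable, so comparisons are strict. |
| Estimability | cell-count threshold | 5 | An effect is estimable only if its summary cell count (minimum over the 2 sex cells; median over 3 age bands and 7 education levels) is at least 5. |
| Estimability | age bands | 55, 75 | Bands `<55`, `[55, 75]`, `>75` exist **only** for this tabulation; models always use continuous age. |
| Selection | criterion | AIC (ML) | Greedy backward: drop the effect whose removal lowers AIC most; stop when none does. ML (not REML) throughout, so likelihoods are comparable across fixed-effect structures; the AIC counts every estimated parameter, variance components included. |
| Outliers | MAD cutoff | 3.5 | Residual-based (scores abnormal for a 25-year-old may be unremarkable at 85). MAD instead of SD because extreme values inflate the SD and mask themselves; the 1.4826 consistency factor makes "3.5 MAD" commensurate with 3.5 SD under normality while staying deliberately permissive — the database should retain the healthy distribution's genuine spread. |
| Transform | λ grid, step | −3…3, 0.001 | Pure power family; resolution matches the search's intended granularity (selected powers are reported to three decimals). |

### The residual-normalizing power search

Normative comparison assumes normal residuals. The search scans powers
$\lambda$; for each, scores are transformed and the selected demographic
model is fitted, and the winning $\lambda$ maximizes the Box–Cox profile
log-likelihood of the residual model (equivalently: makes the residuals
most normal). Four adjustments adapt the textbook procedure:

1. **Positivity offset.** Powers need positive inputs; when the minimum
   score is $\le 0$, the constant $|\min| + 0.001$ is added first (a
   minimum of −5 becomes +0.001).
2. **Order restoration.** A negative power reverses score order (the worst
   scores become the largest transformed values); multiplying by −1
   restores it. `transform_params` derives the flip from the sign of λ.
3. **Study as predictor.** The grid-search regression includes study as a
   factor, so residuals are normalized *within* every study rather than
   across studies.
4. **Standardization.** The winning transform's scores are standardized to
   mean 0, SD 1 over all post-cleaning observations pooled across studies —
   patient scoring needs one common scale, so study-specific
   standardization was rejected. Tiny or huge powers of raw scores become
   interpretable z-like values.

Two open choices were closed as follows. The normality criterion is the
profile log-likelihood (the classical Box–Cox objective; the procedure is
named but its objective is not universal) — a Shapiro–Francia alternative
(`criterion = "shapiro_francia"`, the squared correlation between sorted
residuals and normal scores) is provided behind a switch, and the test
suite checks both recover a known generating power. Standardization uses
the *marginal* SD of the transformed scores, the plain reading of
standardizing "all transformed scores"; the model's residual SD lives on
separately inside the stored variance components.

$\lambda = 0$ (the log) is outside the pure power family and is skipped
when a grid lands on it. Patient scores are transformed with exactly the
stored parameters — the same procedure, frozen.

## The synthetic generator: study conditions

The generator is the package's ground-truth instrument: a Gaussian latent
score with the same structure the pipeline assumes
($y^* = \beta_0 + \beta_a a + \beta_s s + \beta_e e + u_j + \varepsilon$),
pushed through the inverse transform $y^{*\,1/\lambda_{true}} -
\mathrm{offset}$, then contaminated: a configurable fraction of scores is
replaced by values strictly above the upper border (coding errors) and
strictly below the lower border (pathological outliers), so cleaning
stages have unambiguous truth (recall and false-removal rate are exactly
measurable). Borders are derived to bracket the clean support.

Default conditions emulate a word-list delayed-recall-style variable: 20
studies of 250 participants; age uniform over 17–95 (donated cohorts span
young adults to the very old); sex balanced; education mix peaked at
levels 4–6 with thin tails (a convenience-sample mix; skewed mixes
exercise the estimability screen); latent intercept 13.5, age slope
−0.09/year, male deficit 0.5, education gain 0.8/level, between-study SD
0.6 and residual SD 2.1 — scores decline with age, men score slightly
below women, education helps, and between-study variance is well below
within-study variance. Latent draws below 0.5 are redrawn (truncated
normal): count-like scores have a floor, and the inverse power needs a
positive base. At the defaults this touches well under 0.1 % of draws.
A single RNG stream is seeded once; identical seeds give identical
databases.

What the generator does **not** emulate: discreteness (real recall scores
are integers; the generator is continuous), item-level structure,
floor/ceiling *clumping* (mass exactly at a bound), retest data, and
missingness mechanisms that correlate with demographics. Passing recovery
tests therefore show the pipeline is correct *under its own assumptions*;
they do not certify behaviour on, say, heavily discretized or
ceiling-clumped real variables.

## Numerical choices

- **Grid evaluation.** One QR decomposition of the design matrix is reused
  for the whole λ grid; residuals for a block of powers are obtained in a
  single matrix operation, and the transform matrix is chunked so memory
  stays bounded. A coarse pass at step 0.01 locates the optimum and a fine
  pass at 0.001 refines it within ±0.01 — equivalent to the full fine scan
  because the profile likelihood is smooth and unimodal on this family
  (the test suite pins the single-stage and classical-oracle agreement).
- **Ties.** `which.max` takes the first (smallest-λ) maximizer; at step
  0.001 exact ties are vanishingly rare.
- **Degenerate inputs.** Empty tables, empty grids, all-constant
  demographics, and a zero MAD (at least half the residuals identical) are
  caught explicitly: the zero-MAD case removes nothing and warns rather
  than dividing by zero.
- **Conditional residuals.** Outliers are judged on conditional residuals
  (fixed effects *and* the predicted study intercept subtracted): a score
  should be outlying relative to its own study's level. Marginal residuals
  are available (`residual_type = "marginal"`) and the report records
  which was used. Outliers are detected once, before transformation — no
  iterative refit-and-remove loop.
- **Determinism.** Norm stores are written with full numeric precision and
  no timestamps; rerunning a pipeline on identical input yields
  byte-identical JSON.

## Validation design and problem sizes

The validation suite (and `scripts/acceptance.R`) measures, at sizes chosen
to finish in minutes on one CPU while keeping Monte-Carlo error small
relative to each tolerance:

- the estimability tabulation on the published worked example's printed
  cell counts (exact);
- λ recovery over $\lambda_{true} \in \{0.5, 0.75, 1, 1.5, -1\}$, 20
  replicates each at n = 5000;
- backward-AIC structure recovery, 50 replicates at n = 4000 with a strong
  age effect and null sex/education effects;
- MAD behaviour on clean N(0,1) residuals (n = 100 000) against the
  closed-form tail $2\Phi(-3.5)$, and sensitivity on 5 %-contaminated
  residuals shifted by 8 SD (n = 10 000);
- transform round-trips to 1e−8 over 1000 random parameter draws including
  sign-flip cases;
- between-study variance recovery at a generating share of 0.2
  (30 studies × 200), averaged over 5 replicates because a single
  30-study ICC estimate has sampling SD ≈ 0.04;
- patient percentile calibration at planted conditional percentiles
  {2.5, 16, 50, 84, 97.5}, averaged over 10 independently trained models
  (n = 5000 each) because any single model inherits a location shift from
  the realized mean of its 20 study intercepts
  (SD $\sigma_{study}/\sqrt{20} \approx$ 3.6 percentile points at the
  median) — irreducible finite-study uncertainty, not implementation
  error;
- exact agreement of the single-study fit with ordinary least squares.

## Known limitations

- **AIC retains null effects at a known rate.** A truly-null effect
  survives backward AIC whenever its likelihood-ratio statistic exceeds 2
  — probability $1 - P(\chi^2_1 < 2) \approx 0.157$, independent of sample
  size. Exact recovery of a one-effect truth against two null candidates
  therefore plateaus near $0.843^2 \approx 0.71$. This is a property of
  AIC selection itself, faithfully reproduced here; users wanting stricter
  parsimony should screen effects by a stiffer criterion downstream.
- **λ precision scales with |λ|.** The profile-likelihood estimator is the
  MLE; its SE grows proportionally to $|\lambda|$ (reparameterization of
  the same information), about $0.03\,|\lambda|$ at n = 5000 under the
  default conditions. Recovered powers near ±0.05 of truth are expected
  for $|\lambda| \le 1$; larger magnitudes carry proportionally wider
  uncertainty.
- **Greedy backward is not all-subsets.** The greedy path can in principle
  stop off the global AIC optimum; the suite cross-checks it against an
  exhaustive 8-subset oracle and observes agreement in the overwhelming
  majority of draws, but equality is not guaranteed.
- **Extrapolation.** Patients outside the training demographic ranges are
  scored (flagged `"extrapolated"`), linearly extending the fitted
  effects; norms are only as good as coverage.
- **Single-study variables** carry no between-study variance estimate;
  their total normative SD understates the uncertainty of transporting the
  norm to a new setting.
- **Interval-scaled education and main effects only.** The linear education
  slope and absence of interactions or nonlinear age terms (splines,
  quadratics) follow the construction procedure being modeled; real
  age trajectories that accelerate in the ninth decade will be smoothed.
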