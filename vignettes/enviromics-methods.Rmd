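---
title: "Envirotyping and enviromic prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envirotyping and enviromic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enviromics)
```

## The problem

Multi-environment trials (METs) phenotype a panel of genotypes across
several growing environments. Genomic prediction with a kinship matrix
captures the genetic main effect well, but genotype-by-environment
interaction (G×E) is the main obstacle to predicting performance in
environments where a genotype — or any genotype — has never been tested.
Enviromics addresses this by measuring the environments themselves:
daily weather records are processed into ecophysiologically meaningful
covariates, environments are summarized as quantitative descriptor
vectors or envirotype frequency profiles, and the resulting
environment-by-environment similarity ("enviromic kernel") enters the
prediction model symmetrically to the genomic kinship, turning G×E from
noise into a predictable reaction-norm along environmental gradients.

This package implements the full chain: weather I/O and validation →
ecophysiological processing → environmental characterization →
enviromic kernels → Bayesian genomic×enviromic mixed models with
cross-validation, plus a synthetic-data generator so that every stage is
testable offline.

## Daily weather and its derived covariates

Weather tables are long tibbles keyed by environment and day
(`env_id`, `lat`, `lon`, `date`, `daysFromStart`) carrying NASA
POWER-style variables (`T2M`, `T2M_MAX`, `T2M_MIN`, `T2MDEW`, `RH2M`,
`PRECTOT`, `SRAD_DOWN`, `LWD`, `WS`, `ALT`). `validate_weather()`
enforces physical-range and contiguity invariants; `read_weather()`
resolves provider spellings (including the two dew-point spellings
`T2M_DEW`/`T2MDEW`) through one alias table so that downstream code sees
a single schema.

`process_weather()` composes three steps:

* **Radiation** (`param_radiation()`): photoperiod *N* from the sunset
  hour angle, extraterrestrial radiation from latitude and day of year,
  actual sunshine hours *n* inverted from the Angström–Prescott relation
  (coefficients 0.25/0.50, configurable), and the working global
  radiation `SRAD`.
* **Temperature** (`param_temperature()`): diurnal range; the
  radiation-use-efficiency factor FRUE, a trapezoid over four cardinal
  temperatures (0 below `Tbase1`, linear rise to 1 at `Topt1`, plateau
  to `Topt2`, linear fall to 0 at `Tbase2`), evaluated at the daily mean
  temperature; and growing degree days
  `GDD = max(0, min(Tmean, Topt1) − Tbase1)`. The cap at `Topt1` is the
  simplest rule consistent with cardinal-temperature semantics; users
  wanting an upper-tail penalty can weight thermal time by FRUE
  instead. Cardinal sets for 14 crops ship in
  `species_cardinals()` and load by name (`cardinal_set("maize")`).
* **Atmospheric demand** (`param_atmospheric()`): the saturation
  vapour-pressure slope (Tetens form), vapour pressure deficit from the
  daily extremes against dew point (falling back to relative humidity),
  and Priestley–Taylor potential evapotranspiration
  `ETP = α·Δ/(Δ+γ)·(Rn−G)/λ` with α = 1.26, λ = 2.45 MJ kg⁻¹, and the
  psychrometric constant from barometric pressure at elevation. Net
  radiation is shortwave `(1−0.23)·SRAD` minus net longwave — grey-body
  emission against the observed downward longwave when `LWD` is
  present, otherwise the standard clear-sky-scaled estimate. `PETP`,
  precipitation minus `ETP`, summarizes the daily atmospheric water
  balance. Priestley–Taylor (not Penman–Monteith) is used because α
  already absorbs canopy and vapour-deficit resistance, and it needs no
  wind-speed quality assumptions.

All formulas are unit-tested against independently coded scalar
versions of the same handbook equations on randomized physical inputs.

## Characterizing environments

`time_windows()` defines half-open intervals `[b_i, b_{i+1})` on
`daysFromStart`, typically phenological stages. When one more name than
interval is supplied, the final window is open-ended; this reconciles
the two stage/boundary conventions seen in practice.

Two complementary summaries:

* `env_typing()` discovers **envirotypes**: each day's value is binned
  into `[c_k, c_{k+1})` classes given by crop cardinals (or pooled
  data-driven quantiles 10/25/50/75/90% with ±∞ guards), and each
  environment (× window) is described by the relative frequency of each
  class. Frequencies sum to one per environment, window and variable —
  a property test sweeps random cardinal vectors. Pooled (not
  per-environment) quantile breaks are used so that the same bin means
  the same thing in every environment.
* `w_matrix()` builds the quantitative **W matrix**: environments ×
  `var_stat(_window)` descriptors (mean, sum or quantiles per window),
  mean-centered and scaled by the sample standard deviation. Quality
  control removes zero-variance columns and columns whose standardized
  values exceed `sd_tol` (default 3) in absolute value, logging
  removals. Note that with few environments a single outlier cannot
  exceed the 3-SD screen (the maximum standardized value is
  `(n−1)/√n`), so the screen only bites for moderately sized networks.

The reference configuration used throughout the tests mirrors a
maize trial: 13 daily covariates (`T2M`, `T2M_MAX`, `T2M_MIN`,
`T2MDEW`, `RH2M`, `PRECTOT`, `SRAD`, `N`, `FRUE`, `GDD`, `T2M_RANGE`,
`VPD`, `ETP`) summarized over four development stages (V1–V6, V6–VT,
VT–R1, R1–R3), giving a 52-column W for five environments.

## Enviromic kernels

`env_kernel()` turns W (or an envirotype profile) into an environment ×
environment similarity matrix:

* **Linear**: `K_E = XX′ / (trace(XX′)/q)`, the variance–covariance
  kernel normalized so `trace(K_E) = q` (mean diagonal 1) — the direct
  analogue of a genomic relationship matrix.
* **Gaussian**: `K_E = exp(−h·D²/Q)` with `D²` the squared Euclidean
  distances between environment rows and `Q` the median of the
  *off-diagonal* `D²`. The structural zeros on the diagonal are
  excluded from the median so that `Q` is not dragged down for small
  numbers of environments. The bandwidth `h` defaults to 1;
  `estimate_bandwidth()` offers a data-driven choice by grid search
  (`2^(−3..3)`) over a Gaussian-process profile marginal likelihood of
  environment-mean phenotypes, with intercept and scale profiled out
  analytically.

Degenerate inputs are handled explicitly: identical environments floor
`Q` at a machine-scaled epsilon (with a warning), an all-zero W is an
error for the linear kernel. `psd_repair()` floors eigenvalues at 1e-8
and restores the unit diagonal of Gaussian kernels, for kernels that
lose positive semi-definiteness to rounding. Stage-specific kernels
(`stages =`) select descriptor columns by their window suffix, producing
one kernel per development stage. The centered/scaled W is used as-is
(profiles are used uncentered): centering is the W matrix's job, not
the kernel's.

## The prediction model

Phenotypes follow `y = Xβ + Σ_k u_k + ε` with `u_k ~ N(0, σ²_k K_k)`
and `ε ~ N(0, σ²_e I)`. `get_kernel()` assembles the observation-level
covariance structures for six model families from genomic kernels (G),
the within-environment block structure (GE), enviromic kernels (W) and
their Hadamard interaction (GW = reaction norm):

| family | terms |
|--------|--------------------|
| MM     | G |
| MDs    | G + GE |
| EMM    | W + G |
| EMDs   | W + G + GE |
| RNMM   | W + G + GW |
| RNMDs  | W + G + GE + GW |

For balanced env-major-sorted data the GE term equals
`I_q ⊗ K_G` and the GW term equals `K_E ⊗ K_G` — verified exactly by
brute force at small sizes. Multiple kernels per side cross-multiply,
so four stage kernels under RNMM give 4 W + 1 G + 4 GW terms. Missing
genomic kernels default to identity relatedness.

### Sampler

`kernel_model()` is a Gibbs sampler that eigendecomposes each `K_k`
once (rank-truncated at eigenvalue 1e-8) and samples the random effects
in the rotated basis, where the full conditionals of the coordinates
are independent Gaussians with variance `(1/σ²_e + 1/(σ²_k s_i))⁻¹`;
each sweep is O(n·rank) per term. Variance components get
scaled-inverse-χ² full conditionals via `u′K⁺u = Σ b²_i/s_i`. Priors
are scaled-inverse-χ² with 5 degrees of freedom, scaled so the random
terms jointly take a prior mode of half of `var(y)` split equally and
the residual the other half — weakly informative at MET sample sizes.
Defaults are 1000 sweeps, 200 burn-in, thinning 10; variance reports
are posterior means with equal-tailed 95% credible intervals. Same
seed, same chain, bit for bit.

Missing phenotypes are prediction targets: they are imputed from their
conditional each sweep (data augmentation) and reported in `yHat`. Two
deliberate identifiability choices:

* Fixed effects (flat prior) and the residual variance are conditioned
  on the **observed** records only, and a fixed-effect column with no
  observed records — an entirely held-out environment — is pinned at
  zero. Under full augmentation such a coefficient has an improper
  conditional posterior and random-walks, ruining predictions for
  untested environments.
* When a model carries a W term, per-environment fixed effects would
  absorb all environment levels and leave the enviromic kernel nothing
  to transfer to new environments. `get_kernel(fixed_effects =
  "intercept")` keeps only a global mean so environment levels are
  carried — and predicted — by the enviromic term. The genomic
  baseline (MDs) keeps the conventional per-environment fixed effects.

The sampler is cross-checked against the closed-form
GLS/BLUP solution with fixed variance components (correlation
> 0.999 on the posterior mean predictions) and against
parameter-recovery simulations at the 750-record reference scale.

### Cross-validation

`cv1_split()` holds out whole genotypes (novel genotypes, known
environments); `cv00_split()` holds out genotypes *and* environments,
training only on the sampled genotypes within the sampled environments
and testing on unsampled genotypes in unsampled environments (cells
mixing the two belong to neither set). `run_cv()` masks phenotypes,
refits each model per replicate, and `evaluate_cv()` reports Pearson
correlations on the train/test partitions; `cv_summary()` averages over
replicates with standard deviations.

## The synthetic-data generator

`simulate_weather()` draws daily weather with an environment-specific
mean, one annual temperature sinusoid (amplitude/phase per
environment), Gaussian noise, a Bernoulli–gamma rainfall mixture, and
humidity/dew point/radiation generated consistently with temperature
and latitude; all schema invariants hold by construction. One sinusoid
is the minimal seasonal structure that makes envirotyping and
stage-specific kernels discriminative. `simulate_kinship()` builds a
VanRaden kinship from binomial marker dosages with uniform allele
frequencies. `simulate_met()` draws each phenotypic component (env, G,
GE, W, GW, residual) from its covariance structure using the same
expansions the models fit, and returns the realized components and
generating variances as a truth record that the fitting code never
sees.

The generator's reference conditions are a balanced trial of 150
genotypes in 5 environments (750 records) over a 120-day season, with
variance components σ²_G = 0.5, σ²_GE = 0.3, σ²_e = 0.8 and, for
reaction-norm experiments, σ²_W = 2.7 and σ²_GW = 0.3 — magnitudes
matching a tropical maize MET in which environmental main effects
dominate, genetic effects are moderate and enviromic interaction is
real but modest. What the generator does *not* emulate: unbalanced and
selected trial networks, spatial field trends, non-Gaussian trait
distributions, weather measurement error correlated across
environments, and kinship structure from selection or admixture — so
green tests here demonstrate correctness of the machinery, not
performance guarantees on any particular real MET.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at the reference
scale: 750-record fits with 1000–2000 sweeps, 20-replicate recovery
and cross-validation experiments, and 1000-case property sweeps for
typing normalization. Eigendecompositions are cached per term; a
750-record RNMM fit takes a few seconds on one core. Rank truncation
at 1e-8, the PSD tolerance of −1e-8 before repair, and the symmetric
tolerance 1e-8 are all far below any biologically meaningful signal.
Ties in window assignment cannot occur (half-open intervals);
quantile-based breaks deduplicate before use, so heavily tied variables
(e.g. rainfall zeros) produce fewer, wider bins rather than empty ones.

## Known limitations

* Live weather/elevation retrieval is out of scope; `fetch_weather()`
  takes any backend with the documented signature and ships a
  deterministic synthetic one.
* Raster extraction supports the package's plain-text grid format with
  nearest-cell (never interpolated) lookup; reprojection and
  multi-band rasters are not handled.
* Single-trait models only; no additive+dominance decomposition beyond
  passing multiple genomic kernels; REML is not offered.
* The bandwidth estimator is a grid search, adequate for choosing among
  octave-spaced bandwidths but not a full posterior over `h`.
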