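---
title: "Spatial econometrics of forest cover across jurisdictional levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial econometrics of forest cover across jurisdictional levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestdem)
```

## The model

forestdem operationalizes a cross-sectional, multi-level spatial
econometric analysis of tropical forest cover in nested jurisdictional
units (macro: provinces/regions, meso: districts/counties, micro:
wards/parishes/municipalities). The response is forest cover

$$FC = FA / FA_{pot},$$

a unit's forest area as a share of its *potentially* forested area
(all vegetation classes that could carry forest; water, ice, bare and
built-up surfaces are excluded). Under forest-transition theory, FC
follows a sigmoid trajectory along socioeconomic development, so the
response is linearized logistically,

$$FC^{*} = \ln\!\left(\tfrac{1}{FC} - 1\right),$$

which is unbounded, linear-model-friendly, and strictly *decreasing* in
FC — fitted coefficient signs must be reversed when interpreted on the
forest-cover scale. The seven drivers (total area $A_{TOT}$, potential
vegetation share $PVA$, population pressure $PP_{FA}$, road density
$RD$, flatness $FL$, crop suitability $CSI$, cereal caloric yield $CY$)
are log-transformed — they are ratio-scaled and right-skewed — and
standardized within each sample so coefficient magnitudes are
comparable:

$$\hat X_v = \frac{\ln X_v - \mu(\ln X_v)}{\sigma(\ln X_v)}.$$

The most general model entertained is the spatial Durbin error model
(SDEM)

$$FC^{*} = \beta_0 + \hat X \beta + W \hat X \, \theta + u,
  \qquad u = \lambda W u + \varepsilon,$$

with row-standardized sphere-of-influence (SOI) weights $W$. Setting
$\theta = 0$ gives the spatial error model (SEM), $\lambda = 0$ the
spatially-lagged-X model (SLX), and both zero ordinary least squares.
Because all three restrictions are nested in the SDEM, likelihood-ratio
tests provide a local specification ladder (the LeSage–Pace approach):
the decision rule keeps OLS when the joint restriction is not rejected,
otherwise picks the single acceptable restriction (SEM when $\theta = 0$
is acceptable, SLX when $\lambda = 0$ is), and SDEM when both are
rejected. The 5% level is the default (`alpha = 0.05`). The corner
case — both single restrictions individually acceptable but OLS
rejected — does not arise in typical data; we resolve it toward the
restriction with the larger p-value, a documented house convention.

In SLX and SDEM fits, a variable's *direct* impact is its own-unit
coefficient $\beta_v$, its *indirect* impact is the neighbor coefficient
$\theta_v$, and the *total* impact is their sum, with
$\mathrm{Var}(\beta_v + \theta_v)$ taken from the full coefficient
covariance including the cross term. The decomposition is exact by
construction: total = direct + indirect always.

## The workflow, stage by stage

`run_sample()` executes the stages in a fixed order; each is also an
exported function.

1. **Variable construction** (`compute_variables()`). Ratios follow the
   field definitions; `PP_FA` defaults to persons per hectare of
   *remaining forest* (`P_TOT / FA`), the "pressure on remaining
   forest" reading, with `ppfa_mode = "per_total_area"` switching to a
   per-total-area convention — both appear in applied work, so
   reproduction runs should try both. `RD` converts the area to km²
   (1 km² = 100 ha). Shares (`PVA`, `FL`) are kept as fractions; since
   every variable is log-standardized afterwards, multiplicative unit
   choices only shift $\mu$ and never affect any estimate.
2. **Exclusion filter** (`exclusion_filter()`). The linearization is
   undefined at FC ∈ {0, 1} and the log at zero, so units with nil or
   extreme FC, or nil/missing `PVA`, `CSI` or `RD`, are dismissed with
   per-unit reasons. Zeros in other variables are left for model
   selection to handle. The filter is idempotent and order-independent.
3. **Transform and standardize** (`transform_and_standardize()`).
   Standardization uses the sample (n−1) standard deviation. Pooled
   pantropical samples standardize over the pooled units — the
   standardization index is the *sample*, and a pooled sample is one
   sample. Variables with missing values in a sample (typically `CY`,
   available only where yield series exist) are dropped from that
   sample's design rather than imputed.
4. **Collinearity screen** (`collinearity_screen()`). Any pair with
   |r| ≥ 0.6 (on the transformed variables; standardization leaves
   correlations unchanged) is redundant; the member with the lower
   simple-regression R² against $FC^{*}$ is dropped, iterating until no
   violating pair remains. Ties break by dropping the variable later in
   the canonical order `A_TOT, PVA, PP_FA, RD, FL, CSI, CY`, making the
   screen order-invariant.
5. **Stepwise OLS** (`stepwise_bic()`). Backwards elimination from the
   full screened model, removing at each step the variable whose
   removal most reduces BIC, stopping when no removal reduces it. The
   intercept is always kept. The spatial models are then fit on this
   OLS-stage selection — selection is not re-run per spatial model,
   matching the stated workflow order of the analysis this package
   operationalizes.
6. **SOI weights** (`soi_weights()`). Two units are neighbors when
   circles centered on their centroids, each with radius equal to its
   own nearest-neighbor distance, intersect in two places:
   $|r_i - r_j| < d_{ij} < r_i + r_j$, with strict inequalities —
   tangency is one intersection point, not two. The graph is symmetric,
   contains the mutual nearest-neighbor graph, needs no shared borders
   (it links close islands), and tolerates disconnected country blocks
   in pooled samples. Link counts are reported in the directed-pair
   convention and the non-zero share over all $N^2$ cells, matching the
   reporting conventions of connectivity tables in this literature.
7. **Diagnostics** (`spatial_diagnostics()`). Residual Moran's I with
   the Cliff–Ord regression-residual moments (normal approximation,
   homoskedastic Gaussian variant, one-sided "greater" alternative) and
   the four Lagrange multiplier statistics (error, lag, and their
   robust variants), each against $\chi^2(1)$. The report labels the
   lag tests "SLX"/"R-SLX" for comparability with the diagnostic
   tables of this literature, although they are the classical LM-lag
   statistics.
8. **Specification and fitting** (`specify_model()`). SEM/SDEM are
   estimated by maximum likelihood on the concentrated log-likelihood
   in $\lambda$ (details below); SLX is OLS on the lag-augmented
   design. Degrees of freedom for the ladder: number of lagged terms
   (vs SEM), one (vs SLX), lagged terms + 1 (vs OLS).

## Numerical choices

* **Log-determinant.** For row-standardized weights built from a
  symmetric binary adjacency, $W = D^{-1}A$ is similar to
  $D^{-1/2} A D^{-1/2}$, so its spectrum is real;
  $\ln|I - \lambda W| = \sum_i \ln(1 - \lambda\omega_i)$. The dense
  eigendecomposition is used up to n = 2000 and a sparse LU
  factorization above (`log_det()`); both paths agree to 1e-8 in tests.
  Block-diagonal (disconnected) weights need no special casing.
* **$\lambda$ search.** The admissible interval is
  $(1/\omega_{\min} + 10^{-6},\, 1 - 10^{-6})$. The concentrated
  likelihood is evaluated on a coarse grid (default 200 points, always
  including 0 so nested non-spatial fits are never spuriously beaten),
  then refined by bounded scalar optimization to tolerance 1e-8. A
  maximizer at the interval boundary raises a non-convergence error
  rather than returning a boundary estimate.
* **Standard errors.** Coefficient covariance is the GLS covariance at
  $\hat\lambda$; the $\lambda$ standard error comes from the numerical
  Hessian of the full log-likelihood in
  $(\lambda, \beta, \log\sigma^2)$. Coefficient inference is asymptotic
  normal, two-sided.
* **Parameter counting.** `k_model` counts mean parameters (intercept,
  each variable, each lagged variable) plus one for $\lambda$ when
  present — one degree of freedom per newly introduced spatial
  parameter. Information criteria add one more for $\sigma^2$
  (`AIC = 2k - 2\ell`, `BIC = k\ln n - 2\ell`), which reproduces the
  textbook OLS AIC exactly. The unbiased error variance is
  $e'e/(n - k_{model})$ and SER its square root. For SEM/SDEM the
  R² underlying the adjustment is $\mathrm{cor}(X\hat\beta +
  WX\hat\theta,\, y)^2$, the squared correlation of the fitted trend
  with the response; this definition is not universal across software,
  so cross-package comparisons of spatial adjusted R² deserve care.
* **Moran moments.** The variance uses the homoskedastic Gaussian
  (normal-approximation) expression in $\mathrm{tr}(MWMW')$,
  $\mathrm{tr}((MW)^2)$ and $(\mathrm{tr}\,MW)^2$; a simulation oracle
  in the tests confirms both moments on a small lattice. The
  standard deviate recomputed from the two reference report rows that
  are exactly recoverable from their printed components (4.40 and
  1.64) matches to the printed precision, supporting this variant
  over kurtosis-corrected alternatives.

## What the synthetic generator emulates

`generate_sample()` draws a scenario with known truth so every stage is
testable without any download: uniform-random (or lattice) centroids on
a 100 km square; log-normal covariates with a configurable correlation
matrix (so the log transform yields exactly Gaussian regressors); the
linearized response from the SDEM process; and forest cover by the
inverse logistic. Raw attributes are then *back-solved* (FA from FC and
FA$_{pot}$, population from PP$_{FA}$, and so on) so that the variable
builder reconstructs the generator's standardized design to 1e-10 — a
strong end-to-end inverse check. Random-number consumption order is
fixed (centroids → covariates → innovations), so a seed pins a sample
bit-for-bit across versions.

Default parameters are chosen once to resemble observed jurisdictional
data: population pressure dominates (β = 1.2), crop suitability and
potential vegetation contribute moderately (0.15, 0.2), neighbor
effects are smaller than direct ones, λ = 0.5, innovation σ = 0.5, and
PP$_{FA}$–RD correlate at 0.65 so the collinearity screen has real work
to do. Lognormal shares (`PVA`, `FL`) are capped just below 1 and `CSI`
at 100 to respect their admissible ranges; the caps bind rarely under
the default dispersions and the back-solve uses the capped values, so
the inverse property is exact regardless.

`generate_nested()` builds a macro/meso/micro hierarchy on a nested
rectangular partition: micro units are generated first, parents
aggregate children (sums for extensive attributes, area-weighted means
for CSI and CY, area-weighted centroids), so cross-level conservation
is exact by construction.

What the generator does *not* emulate: real administrative geometries
(units are points in a rectangle, not polygons with shared borders),
spatially autocorrelated covariates, measurement error in land-cover
classification, and the clustered exclusion patterns of real metropoles
or uninhabited areas. Passing tests therefore demonstrate correctness
of the estimators and the pipeline plumbing under the assumed model,
not robustness to the messiness of real deposited data.

## Problem sizes used in the test-suite simulations

Simulation-based checks use sizes chosen to give stable Monte-Carlo
verdicts at interactive runtimes: Moran-moment calibration on a 5 × 5
lattice with 5,000 null replicates; LM-test size on a 10 × 10 lattice
with 4,000 replicates against a 5% ± 1% band; likelihood-ratio type-I
error with 1,000 replicates at n = 200; parameter recovery and 95% CI
coverage (93–97% band per parameter) with 200 replicates at n = 400
under λ = 0.7; SOI/brute-force equivalence on 100 random point sets up
to N = 500. The end-to-end selection check (λ = 0.7, θ ≠ 0, n = 400)
requires the ladder to pick SDEM in at least 90% of replicates.

## Known limitations

* Only the error-family is implemented (OLS/SLX/SEM/SDEM). Spatial-lag
  models for the response (SAR/SDM), GWR and spatial panels are out of
  scope by design; GMM estimation likewise (ML only).
* Geometry ingest is plain text (WKT polygons or centroid columns in
  CSV/Excel); projection is the built-in WGS84 transverse Mercator
  with per-country UTM zone defaults (35S, 17S, 51N). For pooled
  pantropical samples, which no single UTM zone covers, centroids stay
  geographic and SOI distances are geodesic; within-country samples
  use planar UTM distances. Whether the original analyses used
  geodesic or planar distances for pooled samples is not stated in the
  source material, so pooled connectivity counts are a known
  reproduction risk.
* The caloric conversion factors for cereal yields are configuration
  inputs with documented defaults, not authoritative constants.
* The dense Moran/LM diagnostics are O(n²) in memory; they are
  comfortable at the a-few-thousand-units scale this design targets.

## A worked run

```{r example, eval = FALSE}
scenario <- synthetic_scenario(n_units = 300, lambda = 0.6)
sample <- generate_sample(scenario, seed = 2026)
run <- run_sample(sample$units, sample_id = "SYN:micro")
glance(run)
tidy(run$final, "impacts")
autoplot(run$final)
```

The run keeps all 300 units, screens out `RD` (generated collinear
with `PP_FA`), selects `PVA`, `PP_FA`, `CSI` by backwards BIC, detects
residual spatial dependence (Moran SD ≈ 8.6), and specifies an SDEM
with $\hat\lambda \approx 0.51$ — recovering the generating structure.
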