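---
title: "Methods: from external exposure to mixture risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from external exposure to mixture risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixrisk)
```

This vignette describes the models behind `mixrisk`, the assumptions they
carry, the tunable parameters and their defaults, and the numerical choices
made where several reasonable options existed.

## The pipeline

A `mixrisk` analysis connects five stages, each of which can be run and
inspected on its own:

1. **Population simulation.** For each region, `n_per_region` individuals
   are drawn: age from the region's binned age distribution (bin chosen
   proportionally to population count, then uniform on the bin's integer
   ages); obesity status by first drawing a regional prevalence from
   `Normal(prev, (ci_hi - ci_lo)/3.92)` truncated to [0, 100] and then a
   Bernoulli per individual — the 3.92 divisor is the standard conversion
   of a 95% confidence interval width to a standard deviation; inhalation
   rate (m³/day/kg) from a zero-truncated normal whose mean and sd depend
   on the individual's age bracket; and external concentration (µg/m³) per
   chemical from a zero-truncated normal with the region's reported mean
   and sd. Exposure is sampled per individual rather than fixed per region,
   which is consistent with treating exposure as one of the varying inputs
   in the sensitivity analysis.
2. **Dosimetry.** Internal dose rate is
   `D_int = C_ext · IR · t · s` with `t = 1` day by default — the
   downstream plasma concentration is a steady-state quantity, assumed
   reached within a day — and `s = 10⁻³` converting µg to mg, giving
   mg/kg/day. Body weight is already in the denominator of the per-kg
   inhalation rate.
3. **Toxicokinetics.** The steady-state plasma concentration per unit dose
   rate, Css (µM per mg/kg/day), arrives as a table of samples stratified
   by age group × weight status per chemical. Full physiological
   simulation is expensive, so a moderate stored sample (hundreds per
   stratum) is expanded to the population by bootstrap resampling: each
   individual draws uniformly with replacement from their stratum's
   vector. The default age brackets are 0–17, 18–44, 45–64 and 65–100
   years, common strata for population toxicokinetic simulators; they are
   configurable because no single convention exists. Weight status is
   binarized Normal vs Obese, with overweight collapsed into Normal. The
   in-vitro-equivalent concentration is then `C = D_int · Css`.
4. **Concentration-response and mixtures** (below).
5. **Summarization and sensitivity** (below).

## Hill fitting

Each chemical × assay is fit with `E(c) = tp / (1 + (ga/c)^gw)` by maximum
likelihood. Residuals are modelled as iid normal by default; a scaled
Student-t with 4 df is available for robust fits in the style of
high-throughput screening pipelines. Responses are fit on their linear
scale; concentrations enter through `log10(ga)`. Vehicle-control rows
(`conc = 0`) enter the likelihood with a zero-response mean.

The optimizer is bounded quasi-Newton (`L-BFGS-B`) over
`(tp, log10 ga, log gw, log σ)` — the 2-parameter model drops `log gw` and
pins `gw = 1` — from a data-driven start (max response, median log
concentration, unit slope, response sd) plus four jittered restarts, with a
Nelder–Mead polish of the best solution. Bounds follow common screening
practice: `tp ∈ (0, 1.5·max resp]`, `log10 ga` within two decades of the
tested range, `gw ∈ [0.3, 8]`, `σ ∈ (0, 2·sd resp]`. Standard errors come
from the inverse observed information at the optimum (delta method for
`gw`); non-convergence returns the best point with `converged = FALSE`
rather than an error. Fits require at least four distinct positive
concentrations.

Hit-calls are treated as an upstream data attribute: if the
concentration-response table carries a logical `hit` column, non-hit pairs
are excluded before fitting and never reach the mixture stage. The package
does not recompute significance of departure from the null response.

Mixtures are fed by 2-parameter fits by default because the generalized
inverse used by concentration addition is only defined for unit slopes
(below); 3-parameter fits are available wherever a single-curve quantity is
wanted.

## Mixture models

**Generalized concentration addition (GCA)** solves
`Σᵢ Cᵢ / fᵢ⁻¹(E) = 1`. For unit slopes the inverse is extended through the
top, `f⁻¹(E) = ga·E/(tp − E)`, negative above `tp`, which lets a strong
agonist drive the mixture response past a partial agonist's top; the
solution then has the closed form
`E = Σ(tpᵢCᵢ/gaᵢ) / (1 + ΣCᵢ/gaᵢ)`. For non-unit slopes the extension would
need fractional powers of negative numbers, so the equation is solved
numerically with the restricted inverse on `E ∈ (0, min tp)`; a solution
pinned at the bracket edge is flagged (`bracket_limited`) rather than
silently accepted. A numeric route with the extended inverse is kept for
unit-slope mixtures as an internal cross-check of the closed form.

**Independent action (IA)** combines effects as probabilistically
independent: `E = Emax(1 − Π(1 − Eᵢ/Emax))`. `Emax` defaults to the largest
fitted top among the mixture's curves, and can be set to a fixed assay
ceiling (e.g. 100%) instead.

**Hazard quotient (HQ).** The mixture's proportions `wᵢ = Cᵢ/ΣC` are held
fixed; the limiting response `E_lim` as total dose grows is computed under
the chosen model (closed form for unit-slope GCA; `Emax(1 − Π(1 − tpᵢ/Emax))`
for IA, which equals `Emax` at the default ceiling). The benchmark response
is `fraction · E_lim` with `fraction = 0.10` by default, the benchmark dose
is found by monotone root-finding over twelve decades around the observed
total, and `HQ = ΣC / EC_frac`. This makes `HQ = 1` exactly the statement
"this individual sits at the benchmark dose of their own mixture", and HQ
scales linearly with proportional dose changes. Other conventions exist
(absolute activity benchmarks, sums of per-chemical EC10 ratios); the
fraction and the IA/GCA choice are exposed as configuration so the
definition is never implicit.

## Summaries

Regional summaries are empirical quantiles (type 7, the linear
interpolation default in R — fixed so that independent reimplementations
agree bitwise) of a per-individual metric within region × assay. With many
assays, the multi-assay value per region is the `summary_p` quantile across
assays of the per-assay `assay_q` quantile across individuals. Low
`summary_p` (defaults 0.05, 0.10) gives conservative multi-endpoint
estimates that avoid the single lowest assay, which often reflects
cytotoxicity rather than the target mode of action. One population draw
per region is reused across assays, so individuals are matched between
assays; with matched individuals the quantile-of-quantiles is well defined
per region without any assay-alignment ambiguity.

## Sensitivity analysis

The one-at-a-time mode reruns the pipeline with exactly one input
stochastic. Everything else is pinned to a central value: exposure at its
reported mean, age at the region's median simulated age, obesity at the
majority status, inhalation rate at its bracket mean, Css at its stratum
median (median rather than mean because Css samples are right-skewed), and
Hill parameters at their point estimates. When age or obesity vary, the
quantities that depend on them deterministically (inhalation-rate bracket
mean, Css stratum median) follow the varied covariate. `fit_params` is the
exception: the population stays at baseline and the fitted `(tp, log10 ga)`
are perturbed per individual with their standard errors, independently —
parameter covariance is ignored, a simplification that understates joint
uncertainty for strongly correlated parameter pairs. The all-fixed baseline
is degenerate by construction (zero within-region variance), which is the
contract the tests enforce: a varied parameter changes the output iff its
input distribution is non-degenerate.

## Synthetic data

The generator emulates every input with known ground truth: unit-square
grid polygons; concentration-response records `hill(c) + N(0, σ)` on an
11-point log grid from 10⁻³ to 10² µM with 3 replicates and σ = 3% activity
(tops 50–120, log10 AC50 in [−1, 1], slopes 0.8–2 — ranges typical of
active screening curves); exposure means 0.05–2 µg/m³ with sd = 30% of the
mean (the scale of annual-average hazardous air pollutants); a gently
declining decade age pyramid; obesity prevalences 20–45% with ±1.5
percentage-point CIs; per-kg inhalation rates declining from 0.50 (infants)
to 0.18 (seniors) m³/day/kg with 15% CV; and lognormal Css samples
(per-chemical meanlog in [−1, 1], sdlog 0.5, obese strata shifted +0.2 —
obese toxicokinetics tend to yield somewhat higher steady-state levels).
The default shape is 10 regions × 7 chemicals × 1 assay, the size of a
modest single-assay study; the multi-assay configuration uses 20 assays,
which exercises the quantile-of-quantiles machinery at a tractable size.
A `degenerate = TRUE` switch zeroes every variance so the whole pipeline
becomes deterministic and checkable in closed form.

What the fixtures deliberately do not emulate: spatial correlation of
exposures between neighbouring regions, correlation between chemicals'
exposures, assay-to-assay correlation of curve parameters, non-detect
censoring, and heteroscedastic response noise. Passing tests therefore
demonstrate the correctness of the computations and their contracts, not
that real air-toxics data meet these distributional assumptions.

## Numerical choices and limitations

* Truncated normals are sampled by inverse-CDF (exact, deterministic given
  the RNG state, no rejection loop); a zero sd degenerates to the clamped
  mean.
* Default simulation sizes (100 individuals per region in the examples and
  reproduction script) were chosen as the smallest sizes at which regional
  quantiles are stable to a few percent; distributional tests use 40,000
  draws where Monte Carlo error must be below ±0.01.
* GCA root-finding uses `uniroot` to a relative tolerance of 10⁻¹²;
  hazard-quotient brackets span `[10⁻¹², 10¹²]·ΣC` and a failure to bracket
  returns a flagged `NA`, never an exception.
* All randomness flows from a single configuration seed: fitting restarts,
  each region's population in order, and each sensitivity parameter (with a
  fixed per-parameter offset) are seeded deterministically, so a state is
  bit-identical across repeated runs.
* Serialization is CSV + JSON (and GeoJSON for geometries); geometries are
  plain polygon rings in WGS84, validated structurally (closed, ≥ 4
  points) — there is no full planar-validity or reprojection support.
* The state accepts regions without geometry (tabular-only studies); maps
  simply skip such regions.
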