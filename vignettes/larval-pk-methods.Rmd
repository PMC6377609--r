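---
title: "Modelling the pharmacokinetics of waterborne compounds in developing zebrafish larvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the pharmacokinetics of waterborne compounds in developing zebrafish larvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfpk)
```

## The problem

Zebrafish larvae are treated by dissolving a compound in the incubation
medium, but it is the *internal* exposure — the amount of compound inside the
larva over time — that drives pharmacological and toxicological effects. A
larva between 3 and 5 days post fertilisation (dpf) is a rapidly developing
organism: the gastro-intestinal tract opens around 4 dpf, and the liver and
kidneys keep growing and maturing. Absorption and elimination of a compound
therefore change from one experimental day to the next, and experiments run
at different ages are not directly comparable.

`zfpk` quantifies these processes from longitudinal measurements of total
compound amount per larva (pooled samples of several lysed larvae), in two
experimental arms:

* **constant treatment** — larvae stay in treatment medium; samples are drawn
  over 0–180 min;
* **washout** — larvae are treated for 60 min, transferred to drug-free
  medium, and sampled until 240 min.

## Structural model

The core model is a one-compartment turnover with zero-order absorption and
first-order elimination of the internal amount $A$ (pmole/larva):

$$\frac{dA}{dt} = k_a - k_e \, A,$$

where $k_a$ (pmole/min) is a constant uptake rate — justified because the
medium concentration is effectively constant during the experiment (the
medium volume is enormous relative to the larvae) — and $k_e$ (1/min) is the
first-order elimination rate constant, lumping metabolism and excretion. The
model admits closed forms, used throughout for speed and exactness:

* constant treatment: $A(t) = \dfrac{k_a}{k_e}\left(1 - e^{-k_e t}\right)$,
  with plateau $k_a/k_e$ and time to a fraction $f$ of steady state
  $-\ln(1-f)/k_e$;
* washout (treatment ends at $T_d$): $A(t) = A(T_d)\, e^{-k_e (t - T_d)}$ for
  $t \ge T_d$.

Time zero is treatment start in both arms and absorption switches off at
exactly $T_d = 60$ min — the sharp-switch reading of a "treated for 60
minutes, then washed" protocol. The amount is continuous at the switch.

Two richer structural variants are available as competitors in model
selection: a two-compartment model (elimination from the central compartment
only; the *sum* of both compartment amounts is fitted to the observed totals,
since the assay measures whole-larva content) and Michaelis–Menten
(saturable) elimination, $dA/dt = k_a - V_{max} A/(K_m + A)$. Both are
integrated numerically with `deSolve::ode` (lsoda, stiff-capable), relative
tolerance `1e-8` and absolute tolerance `1e-10` — cheap at this problem size
and tight enough that solver error plays no role in model comparison; the
integration is split at $T_d$ so the solver never steps across the input
discontinuity. With exchange rates zero, the two-compartment solution
collapses to the one-compartment closed form; with $K_m \gg A$ and
$V_{max}/K_m = k_e$, Michaelis–Menten linearises to first order. Both limits
are exercised in the test suite.

## Age as a covariate

Development is encoded by letting $k_a$ and $k_e$ depend on age in dpf
through one of three families, parameterised relative to a reference age
(3 dpf, the youngest post-hatching age studied):

* linear: $P = P_{base}\,(1 + slope\,(age - ref))$
* power: $P = P_{base}\,(1 + slope)^{age - ref}$
* discrete: a separate multiplicative step per age level,
  $P = P_{base}(1 + factor_{age})$

The model of primary scientific interest combines a **discrete** step on
$k_a$ (one factor shared by 4 and 5 dpf — the biology being a discrete
event, the opening of the GI tract around 4 dpf) with a **power** function
on $k_e$ (a constant fractional increase per day, matching continuous organ
growth and enzyme maturation). Ages are treated strictly as integer levels
3/4/5; no interpolation at fractional ages is attempted, because the data
contain none.

## Residual error and likelihood

Each pooled sample is lysed to be measured, so it yields a single
observation; between-larva variability cannot be separated from
experimental/analytical noise, and the model therefore carries no random
effects — the pool size is metadata, not a variance divisor. Estimation is
exact Gaussian maximum likelihood with heteroscedastic variance (extended
least squares). Per observation,

$$v_i = \hat{A}_i^2\,\sigma^2_{prop} + \sigma^2_{add},$$

with either term dropped under the pure proportional/additive forms, and the
objective function value (OFV) is

$$\mathrm{OFV} = -2\log L = \sum_i \left[\ln(2\pi v_i) +
  \frac{(A_i^{obs} - \hat{A}_i)^2}{v_i}\right].$$

This is the likelihood a conditional-estimation NLME fit degenerates to when
there are no random effects, so nothing is lost by implementing it directly.

**Optimisation.** Rates and variances are log-transformed; covariate
coefficients use $\log(1+x)$, bounding them above $-1$ on the natural scale.
Each fit runs a primary start (data-driven: the washout log-decline gives a
crude $k_e$, the constant-arm plateau gives $k_a = k_e A_{ss}$) plus
`n_restarts` log-normally jittered restarts (sd 0.5 on the transformed
scale, seeded), each polished with Nelder–Mead followed by BFGS at a
relative tolerance of `1e-10`; the best optimum wins. A non-finite
objective (e.g. a degenerate variance during search) is treated as an
infinite barrier.

**Uncertainty.** The covariance of the estimate is $2 H^{-1}$, where $H$ is
the Hessian of the OFV at the optimum, computed by central finite
differences with a relative step of `1e-4` per coordinate on the estimation
scale and mapped to the reporting scale by the delta method. A
non-positive-definite Hessian flags the covariance step as failed and RSEs
(`100·SE/|estimate|`) are withheld. The published precision criterion of
"3 or more significant digits" is operationalised as the optimiser
tolerance rather than any solver-specific digit diagnostic.

## Model selection

Candidates are compared along a nested ladder (structure → error model →
covariates) with the likelihood ratio test: the drop in OFV between nested
fits is referred to $\chi^2_{\Delta k}$ at significance level 0.01. An
extension is accepted only if, additionally, the fit converged and its
relative standard errors are below 50%. Two deliberate conventions:

* **Negative statistics** (possible numerically when the richer fit stalls)
  are clamped to zero with a warning; a tie at the significance boundary
  keeps the reduced model (parsimony).
* **RSE scope.** By default the 50% bound is applied to the structural
  parameters (rates and covariate coefficients), not to the error-variance
  components (`rse_scope = "all"` restores the stricter gate). The additive
  variance is intrinsically weakly identified whenever proportional noise
  dominates at every sampled amount — its RSE hovers around the 50% mark
  under this design — and letting that single, scientifically peripheral
  quantity veto extensions the likelihood supports at $p < 10^{-40}$ makes
  selection an unstable coin flip. The structural scope keeps the gate
  meaningful where precision actually matters.

Each candidate is warm-started from the currently accepted estimates, which
also enforces nesting monotonicity of the optimised OFV in practice.

## Diagnostics

With no random effects, conditional weighted residuals reduce exactly to
$(A^{obs}_i - \hat{A}_i)/\sqrt{v_i}$; `weighted_residuals()` implements that
identity (and is named "CWRES-equivalent" advisedly). For a correctly
specified model they are standard normal: mean near 0, variance near 1, no
trend against time or predictions, and systematic age-stratified bias when a
real covariate is omitted — all of which the test suite checks. Tables are
the primary artifact; `gof_table()` optionally renders the standard
three-panel plot on top of them.

## The synthetic-data generator

`simulate_dataset()` emulates the study design: ages 3/4/5 dpf; constant
treatment sampled at 10, 20, 30, 60, 90, 120, 150, 180 min; washout (60 min
treatment) sampled at 70, 80, 90, 120, 150, 180, 210, 240 min; triplicate
pooled samples of 5 larvae at every point (144 observations). The published
protocol states the windows (0–180 and 60–240 min) and "at least" triplicate
measurement but not the exact grid; this grid is a faithful reconstruction
with 8 points per arm, dense enough to see both the rise to plateau and the
mono-exponential decline. Time 0 is not sampled: a measurement of an
untreated larva carries information only about the additive noise floor, and
its simulated value would be negative half the time.

Noise is composed as $A^{obs} = \hat{A}(1 + \varepsilon_1) + \varepsilon_2$
with independent $\varepsilon_1 \sim N(0, \sigma^2_{prop})$,
$\varepsilon_2 \sim N(0, \sigma^2_{add})$ — exactly the variance structure
the likelihood assumes. Negative draws (physically impossible amounts) are
truncated at zero and counted; at realistic parameter values fewer than 1%
of observations are affected, so the induced bias is negligible. The same
configuration and seed always reproduce the identical dataset, and the
generator leaves the caller's RNG state untouched.

What the generator does **not** emulate: medium-concentration depletion,
between-larva parameter variability within a pool, below-quantification
censoring, and analytical drift. Passing recovery tests on these data
therefore demonstrates that the estimation machinery is correct and the
design is informative — not that real larvae obey the model.

## Clearance and allometry

Clearance is derived as $CL = k_e \times V_{larva} \times 60$ (nL/h),
assuming the distribution volume equals the total larval volume with
homogeneous distribution (total volumes: 253, 263, 300 nL at 3, 4, 5 dpf).
Bodyweight follows from volume at a tissue density of 0.997 g/mL.

For interspecies comparison, `fit_allometric()` regresses
$\log_{10} CL$ on $\log_{10} BW$ by ordinary least squares **on mature
individuals only**; immature records are retained for plotting but never
enter the fit. The 95% band is the mean-prediction (confidence) interval of
the regression line — the uncertainty of the allometric relationship itself,
not a prediction interval for a new species. Larval values are compared by
extrapolating the band down to larval bodyweight and expressing larval
clearance as a percentage of the band's lower bound; the extrapolation is
flagged as such. Species tables declare their clearance units and are
harmonised to nL/h before fitting (the regression slope is invariant to the
common unit; only the intercept shifts). The species table shipped under
`inst/extdata/` is synthetic, generated from a plausible allometric line for
use in examples — real interspecies values must be supplied by the user.

## Simulation-study sizes

The package's own simulation studies run at sizes chosen to make the checks
sharp but routine on a laptop: 20 replicate simulate-and-refit datasets for
parameter recovery (144 observations each; medians of the recovered
structural parameters are compared with the generating values), 500
replicates for the type-I error of the LRT (on a sparser 54-observation
design with a cheap 3-vs-4-parameter nested pair), and 300 replicates for
the coverage of the allometric confidence band.

## Known limitations

* No random effects, by design: with single observations per lysed pool the
  data cannot identify them. Consequences: RSEs quantify residual-level
  uncertainty only, and the model cannot be ported unchanged to designs with
  repeated measures per individual.
* The additive variance component is weakly identified under designs where
  proportional noise dominates everywhere; expect RSEs near or above 50% for
  it.
* The washout switch is instantaneous; any real transfer/washing transient
  shorter than the sampling resolution is absorbed into residual error.
* Allometric placement of larvae is an extrapolation far below the mature
  bodyweight range; it quantifies distance from the mature relationship, not
  membership in it.
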