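# zfpk — pharmacokinetics of waterborne compounds in developing zebrafish larvae

Zebrafish larvae are a workhorse of early drug discovery and toxicology, but
what drives an observed effect is the *internal* exposure to a waterborne
compound, not its concentration in the incubation medium — and in a larva of
3–5 days post fertilisation (dpf), the processes controlling that exposure
change by the day as the gut opens and the eliminating organs mature. `zfpk`
is for experimentalists and pharmacometricians who need to quantify those
processes from longitudinal internal-exposure data (paradigm compound:
paracetamol) and decide at which larval age an experiment is most
informative.

## The model

Internal amount per larva `A` (pmole) follows a one-compartment turnover
with zero-order absorption and first-order elimination,

    dA/dt = ka − ke · A

with closed forms under constant treatment, `A(t) = (ka/ke)(1 − e^(−ke t))`,
and after washout at `T_d = 60` min, `A(t) = A(T_d) e^(−ke (t − T_d))`.
Development enters through age covariates: a discrete step on the absorption
rate (`ka = ka_base` at 3 dpf, `ka_base (1 + factor_a)` afterwards — the gut
opens as a discrete event) and a power function on the elimination rate
(`ke = ke_base (1 + slope_e)^(age−3)` — continuous organ growth). Fitting is
exact Gaussian maximum likelihood under a combined proportional + additive
residual-error model, with likelihood-ratio-test selection between nested
candidates (two-compartment and Michaelis–Menten variants included),
curvature-based relative standard errors, and CWRES-style diagnostics.
Clearance is derived as `CL = ke × larval volume × 60` (nL/h) and placed
against a log–log allometric regression of clearance on bodyweight fitted to
mature vertebrates. Details and design rationale are in the methods
vignette, `vignettes/larval-pk-methods.Rmd`.

## Worked example

Simulate a design-faithful dataset (ages 3/4/5 dpf, constant-treatment and
washout arms, triplicate pooled samples of 5 larvae) and refit the final
model:

```r
library(zfpk)

design <- default_study_design()
truth <- pk_parameters(ka_base = 0.289, ke_base = 0.0193,
                       factor_a = 1.06, slope_e = 0.175,
                       sigma2_prop = 0.109, sigma2_add = 0.00844)
spec <- model_spec(ka_covariate = "discrete", ke_covariate = "power")

dat <- simulate_dataset(simulation_config(design, truth, spec, seed = 1))
fit <- fit_pk(dat, spec, design, n_restarts = 5, seed = 1)
fit
#> Pharmacokinetic model fit (144 observations, 6 parameters)
#>   OFV (-2 log-likelihood): 543.4372
#>   converged: TRUE
#>
#> Structural parameters
#>          Estimate RSE (%)
#> ka_base    0.2860       5
#> factor_a   1.1900      11
#> ke_base    0.0187       3
#> slope_e    0.2300      12
#>
#> Stochastic parameters
#>             Estimate RSE (%)
#> sigma2_prop  0.07650      14
#> sigma2_add   0.00804      63
```

On this single replicate the absorption rate at 3 dpf is recovered as 0.286
pmole/min (truth 0.289) with a 5% RSE, and the elimination rate as 0.0187
min⁻¹ (truth 0.0193); the discrete absorption step and the per-day
elimination increase are recovered within their reported precision. The
additive variance is the one weakly identified quantity (RSE 63%) — expected,
since 33% proportional noise dominates at every sampled amount.

Derived quantities — age-resolved elimination rates, clearance against the
reported larval volumes, and the time to 90% of steady state:

```r
ke_fit <- covariate_value(covariate_spec("power", fit$par[["ke_base"]],
                                         fit$par[["slope_e"]]), 3:5)
data.frame(age_dpf = 3:5, ke = signif(ke_fit, 3),
           CL_nl_per_h = round(clearance(ke_fit, c(253, 263, 300)), 1))
#>   age_dpf     ke CL_nl_per_h
#> 1       3 0.0187       283.4
#> 2       4 0.0230       362.2
#> 3       5 0.0282       508.1
time_to_steady_state(fit$par[["ke_base"]], 0.9)
#> [1] 123.3  # minutes
```

Allometric placement against mature vertebrates (the bundled species table
is *synthetic*, generated from a plausible allometric line for
demonstration; supply real interspecies values for scientific use):

```r
tab <- read_species_table(system.file("extdata",
        "synthetic_species_clearance.csv", package = "zfpk"))
allo <- fit_allometric(tab)
allo
#> Allometric regression of log10 clearance on log10 bodyweight
#>   fitted on 10 mature species records (0 immature retained for comparison)
#>   log10(CL) = 6.5908 + 0.7597 * log10(BW)   [CL nL/h, BW g]
#>   residual SD (log10): 0.1569 | 95% confidence band
fraction_of_lower_bound(c(283.4, 362.2, 508.1),
                        bodyweight_from_volume(c(253, 263, 300)), allo)
#> [1] 11.1 13.8 17.4   # percent of the extrapolated lower 95% CI bound
```

Larval clearance sits far below the mature-species band and climbs towards
it with age — the quantitative form of the observation that older larvae
resemble higher vertebrates more closely.

A command-line pipeline (`simulate | fit | select | diagnose | allometry`)
over the same functions is available via the wrapper script in
`inst/scripts/zfpk`; see `?pk_cli`.

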