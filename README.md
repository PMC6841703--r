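# primingkit

Quantifying the soil **priming effect** — the change in native soil organic
matter (SOM) decomposition caused by a labile carbon input — from
¹³C-glucose incubation experiments.

Adding fresh carbon to soil can stimulate (or suppress) the microbial
decomposition of the much larger native SOM pool. Measuring this requires
isotope labelling: when the added glucose carries a known ¹³C enrichment,
the respired CO₂ is a two-endmember mixture, and the SOM-derived share of
the treated soil's respiration can be separated from the glucose-derived
share. primingkit implements that pipeline end to end for the standard
design used in continental-scale incubation studies — paired control /
¹³C-glucose treatments in triplicate bottles with shared blanks, measured
over a 65-day schedule — together with the uncertainty, decomposition-model
and driver-screening statistics that accompany it. It is written for soil
biogeochemists analysing such incubations and for methodologists who want a
tested, reproducible reference implementation.

## What it computes

**Source partitioning and priming.** Blank correction of headspace isotope
composition by concentration-weighted mass balance; ideal-gas conversion of
net headspace CO₂ to fluxes (µg CO₂-C g⁻¹ d⁻¹); two-endmember mixing

    f_glucose = (at%_treat − at%_SOM) / (at%_glucose − at%_SOM),   f_SOM = 1 − f_glucose

and the priming effect `PE = C_treat · f_SOM − C_control` with its relative
form (% of basal respiration), integrated over the incubation by
trapezoids plus an optional leading day-0 rectangle.

**Monte-Carlo uncertainty.** Error propagation for the treated SOM-derived
flux, `σ_SOM = F_SOM · sqrt((σ_Ct/C_t)² + (σ_f/f_SOM)²)`, feeding a
1000-draw Monte Carlo that samples per-day fluxes, integrates each draw,
and reports the percentile 95% confidence interval of cumulative priming
per site.

**Two-pool decomposition model.** Control respiration normalised per g SOC
is inverted against `R(t) = k₁f₁C_tot·e^(−k₁t) + k₂(1−f₁)C_tot·e^(−k₂t)`
by adaptive random-walk Metropolis MCMC (uniform priors, k₁ > k₂ enforced,
3 chains, Gelman–Rubin diagnostics, MAP for well-constrained parameters and
posterior means otherwise, R²/RMSE fit checks).

**Driver screening.** Partial correlations (zero-order vs controlled, with
the percent change in coefficient strength), variation partitioning of
priming across the four predictor groups (plant / soil / microbial / SOM
stability; Ezekiel-adjusted R², negative unique fractions reported raw and
truncated to zero), and per-group PC1 extraction.

**Synthetic transect.** A generator with known ground truth — 30 sites (18
steppe, 12 meadow) on a precipitation gradient, realistic covariate ranges,
two-pool kinetics, an exponentially decaying true priming multiplier whose
amplitude is a stated function of SOM-stability covariates — so every stage
is testable without any field data.

## Worked example

```r
library(primingkit)
library(dplyr)

design   <- incubation_design()                 # days 1,3,8,15,35,65 at 15 °C
transect <- generate_transect(n_sites = 30, seed = 42)
records  <- simulate_incubation(transect, design, seed = 42)

partition <- partition_incubation(records, design)
partition |> filter(site_id == "S01") |>
  select(day, c_treat, c_control, f_glucose, priming, relative_priming)
#>     day c_treat c_control f_glucose priming relative_priming
#> 1     1  11.0       5.30     0.602  -0.927            -17.5
#> 2     3   7.47      5.06     0.482  -1.20             -23.6
#> 3     8   4.18      3.76     0.202  -0.425            -11.3
#> 4    15   2.62      2.88     0.0372 -0.351            -12.2
#> 5    35   1.07      1.17     0      -0.0960            -8.23
#> 6    65   0.417     0.473    0      -0.0559           -11.8
```

Site S01 is a *negative* priming site: its treated soil respires less SOM
than the control (priming rates in µg C g⁻¹ d⁻¹; relative priming as % of
basal respiration), with the glucose-derived fraction decaying from 60% of
the treated flux on day 1 to nothing by day 35.

```r
priming_ci(records, design, n_draws = 1000, seed = 42) |> head(3)
#>   site_id cumulative_mean ci_low ci_high n_draws
#> 1 S01               -16.6  -19.9   -13.6    1000
#> 2 S02                25.7   22.4    29.2    1000
#> 3 S03               117.    92.6   143.     1000
```

Cumulative priming over the 65 days (µg C g⁻¹) with percentile 95%
Monte-Carlo intervals: S01 suppresses ~17 µg C g⁻¹ of basal decomposition,
S03 primes ~117 µg C g⁻¹ extra.

```r
soc <- select(transect$truth, site_id, soc_g_kg)
obs <- tibble::tibble(day = design$schedule,
                      rate = filter(partition, site_id == "S01")$c_control /
                             soc$soc_g_kg[1])
fit <- mcmc_fit(obs, n_iter = 10000, seed = 42)
tidy(fit)
#>   parameter      map     mean      q2.5    q97.5 gelman_rubin constraint_class
#> 1 f1        0.0591   0.0576   0.0385    0.0704           1.00 well_constrained
#> 2 k1        0.0500   0.0522   0.0419    0.0739           1.00 well_constrained
#> 3 k2        0.000154 0.000186 0.0000181 0.000498         1.00 well_constrained
```

The inverted two-pool parameters (fast-pool fraction 0.059, fast decay
0.050 d⁻¹) sit within a few percent of this synthetic site's generating
truth (0.061, 0.048 d⁻¹).

The whole pipeline — simulate → partition → priming-ci → fit-twopool →
drivers, with stage CSVs, `summary.json` and a hashed `manifest.json` — runs
as one call:

```r
run_priming_pipeline("results/run1", seed = 42)
```

A thin command-line wrapper with the same stages as subcommands is
installed at `inst/scripts/primingkit.R`
(`Rscript primingkit.R run-all --seed 42 --out-dir results`).

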