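# aqpd

Phase-based variance decomposition and health impact assessment for urban
air-quality time series.

## What problem this solves, and for whom

Air-quality interventions (lockdowns, plant curtailments, traffic schemes)
are usually evaluated by comparing pollutant means before and after. But
weather confounds such comparisons: temperature, wind speed and humidity
move daily concentrations as much as emissions do, and an intervention that
happens to straddle a seasonal transition will look better or worse than it
was. `aqpd` is for air-quality and environmental-health analysts who need
to (1) say how much of the observed pollutant variability a set of
intervention phases explains *beyond* meteorology, and (2) translate the
resulting PM2.5 changes into an attributable cardiovascular mortality
burden with honest uncertainty.

The package ships the 2020 study conditions of Ilo, Peru — a coastal
smelter city whose six decree phases produced a counterintuitive PM2.5
*increase* during early reopening — as its default calendar and synthetic
scenario, but every function is generic over a user-supplied
`phase_calendar()` and hourly CSV input.

## The statistics at the core

Per pollutant, two nested OLS models on the same complete-case daily rows:

    M1:  Y = β₀ + β₁·Temp + β₂·WS + β₃·RH + ε
    M2:  M1 + Σ βᵢ·Phaseᵢ          (reference: baseline phase)

with the explained-variance partition

    R²meteo = R²(M1);   R²phase = R²(M2) − R²(M1)
    %meteo  = 100·R²meteo/R²(M2);   %phase = 100·R²phase/R²(M2)

tested by the nested ANOVA F = ((RSS₁−RSS₂)/q)/(RSS₂/df₂), with
HC3 sandwich standard errors for coefficient inference and a seeded
500-tree random forest (permutation %IncMSE + node-purity importance,
out-of-bag validation) as a linearity-free cross-check. The health impact
chain is the no-threshold log-linear concentration–response model

    RR = exp(β·ΔPM2.5);  AF = (RR−1)/RR;  Deaths = Pop·(Rate/10⁵)·AF

with β = 0.00072 per µg/m³ (95% CI 0.00059–0.00085, GBD 2021
cardiovascular), population 67,167, baseline rate 120/100,000/yr, and
10,000-draw Monte Carlo propagation of the β and baseline-rate
uncertainty. Upstream of all this sit an hourly→daily aggregator with the
75% completeness rule (≥ 18 valid hours), a rolling 8-h ozone maximum,
phase-stratified summaries, Kruskal–Wallis/Dunn/Benjamini–Hochberg
contrasts, Spearman matrices and WHO-2021 guideline exceedances.

## Worked example

```r
library(aqpd)

cfg <- run_config(scenario = default_ilo_config(), seed = 7L)
rep <- run_full_analysis(cfg)
rep$decomposition
#>   pollutant     n r2_full r2_meteo r2_covid pct_meteo pct_covid     f         p
#> 1 pm10        366   0.801   0.264     0.537     33.0       67.0 193.  3.78e- 99
#> 2 pm25        366   0.806   0.0324    0.774      4.02      96.0 285.  2.85e-122
#> 3 no2         366   0.659   0.370     0.289     56.2       43.8  60.6 1.37e- 45
#> 4 o3          289   0.981   0.747     0.234     76.2       23.8 681.  2.39e-154
#> 5 so2         279   0.940   0.692     0.248     73.7       26.3 223.  1.24e- 93
```

Each row splits one pollutant's explained variance: on this synthetic year
ozone loads mostly on meteorology (76% — its configured phase trajectory
follows the seasonal temperature cycle) while PM2.5, whose weather
dependence enters only through wind, loads almost entirely on the phase
structure; the F column confirms the phase increment is significant at the
given sample sizes (n = valid model days; O3 and SO2 lose days to the
simulated end-of-year instrument outages).

```r
rep$hia
#>   phase           mean_pm25  delta pct_change    rr  deaths deaths_lo deaths_hi
#> 1 Pre-Pandemic         12.6  0           0    1      0         0         0
#> 2 Strict Lockdown      14.4  1.81       14.4  1.00   0.105     0.0787    0.135
#> 3 Phase 1              16.7  4.14       32.8  1.00   0.240     0.179     0.307
#> 4 Phase 2              14.7  2.13       16.9  1.00   0.124     0.0926    0.159
#> 5 Phase 3              10.9 -1.66      -13.2  0.999 -0.0964   -0.124    -0.0721
#> 6 Phase 4              12.0 -0.628      -4.98 1.000 -0.0364   -0.0467   -0.0273
```

Each phase's mean PM2.5 is contrasted with the baseline: the ~4 µg/m³
rise during early reopening (Phase 1) carries a relative risk of 1.003 and
about a quarter of an additional cardiovascular death per year in a city
of 67,000 (Monte Carlo 95% interval in the last two columns); the negative
rows are avoided deaths when concentrations dip below baseline.
`sensitivity_suite(cfg)` re-runs everything across completeness thresholds
(12/18/20 h), austral summer/winter strata, 3-SD outlier exclusion and an
extended meteorology set.

## Layout

- `R/` — calendar + scenario generator, ingestion/QC, descriptive
  statistics, nested-model decomposition, forest importance, health impact,
  pipeline orchestration
- `tests/testthat/` — unit, property and end-to-end suites (all fixtures
  generated in code)
- `vignettes/aqpd-methods.Rmd` — the model, its assumptions, every
  numerical convention, and what the synthetic tests do and do not show
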