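# hazeimpact

Health and economic impact assessment of fine particulate (PM2.5) pollution,
as a tested, reproducible R pipeline. The package chains three stages that
are usually run in isolation:

1. **Concentration forecasting** — a grey GM(1,1) model fitted to a short
   annual series, whose residuals are partitioned into states and corrected
   by an empirical Markov chain. The per-state correction
   `h_j = λ_j l_j + (1 − λ_j) u_j` is tuned by a real-coded genetic algorithm
   minimising the in-sample mean squared error instead of the traditional
   midpoint choice `λ = 0.5`.
2. **Health accounting** — log-linear exposure–response functions
   `E = P · I · (1 − e^{−β(C − C₀)})` convert the concentration path into
   attributable premature deaths and seven morbidity outcomes, with 95%
   interval propagation from the coefficient CIs, and aggregate them into
   the two *conducting variables*: the per-mille labor-force loss ratio and
   excess medical expenditure.
3. **Economic simulation** — a social-accounting-matrix-calibrated,
   single-region, closed-economy CGE model (CES production over
   value-added and intermediates, Cobb-Douglas value added, neoclassical
   closure) is solved year by year under recursive dynamics
   (`QLS·(1+g_L)`, `QKS·(1+g_K)`, TFP·(1+g_tfp)) with and without the health
   shock, and reports the macro and sectoral losses.

It is aimed at environmental-health and resource economists who want the
whole chain — short-series forecasting, burden-of-disease accounting, and
general-equilibrium loss estimates — in one scripted, seeded run. The
Beijing 2013–2020 study inputs (concentration series, population table,
exposure-response parameters, aggregate 2012 SAM) ship as plain-text
fixtures; synthetic-data generators mirror every input's statistical
structure so each stage is testable without them.

## Worked example

```r
library(hazeimpact)

pm <- beijing_concentration()                      # 2013-2017, µg/m³
fc <- grey_markov(pm, bounds = c(-4, -2, 2, 4), lambda = "ga",
                  seed = 1, horizon = 3)
fc
#> Grey-Markov forecast
#>   lambda = (0.000, 0.304, 1.000)
#>  year actual gm_fitted corrected residual state
#>  2013   89.5      89.5      89.5      0.0     2
#>  2014   85.9      88.1      86.1     -0.2     1
#>  2015   80.6      78.2      80.2      0.4     3
#>  2016   73.0      69.4      69.4      3.6     3
#>  2017   58.0      61.6      62.6     -4.6     1
#> Forecast:
#>  year value
#>  2018  55.2
#>  2019  49.3
#>  2020  43.7
```

The table shows the GM(1,1) restored values, the residual state of each year
(state 1 = overestimation, 2 = accurate, 3 = underestimation) and the
Markov-corrected series; the GA-tuned coefficients push the corrections to
the informative edges of the state intervals. Diagnostics summarise fit
quality (average relative error 0.0272, grey relational grade 0.699,
posteriori error ratio 0.174, small-error probability 1, MSE 6.861 — the
midpoint correction gives 7.99).

```r
conc <- dplyr::bind_rows(pm, dplyr::mutate(fc$forecast, value = round(value, 1)))
led <- health_impact(conc, beijing_population(2020), beijing_health_outcomes())
led
#> Health-impact ledger, 2013 - 2020
#>   premature deaths: 156600 (43338-248933)
#>   disease cases:    6398067 (3057076-9382319)
#>  year labor_days labor_loss_ratio medical_expense
#>  2013    2343398             0.82         1113.32
#>  2014    2405429             0.83         1088.87
#>  ...
#>  2020    1401584             0.42          597.87
```

Roughly 157 thousand premature deaths and 6.4 million disease cases are
attributable to PM2.5 over 2013–2020; in 2013 the equivalent of 0.82‰ of the
labor force is lost and 1,113 million RMB of excess medical spending is
incurred. These two columns shock the CGE model:

```r
model <- calibrate_cge(rebalance_sam(beijing_sam()))
path <- recursive_simulate(
  model, dplyr::select(led$summary, year, labor_loss_ratio, medical_expense)
)
dplyr::filter(tidy(path), variable == "gdp")$delta
#> -896.0 -966.1 -958.8 -932.9 -792.8 -796.5 -753.5 -707.3   (million RMB)
```

Regional GDP losses are negative every year, peak in 2014 with the
labor-loss ratio, and decline as concentrations fall. With the synthetic
six-sector SAM (`beijing_sam6_synthetic()`), the health-services sector's
output rises under the shock while every other sector contracts.

`run_pipeline(haze_config(...))` wires the three stages together (and
`inst/cli/haze-impact` wraps it for the shell); every result type has
`tidy()`, `glance()` and `autoplot()` methods.

## Package layout

- `R/grey.R`, `R/markov.R`, `R/diagnostics.R`, `R/grey_markov.R` — GM(1,1),
  state chain, GA, model checking
- `R/health.R` — exposure-response accounting and interval propagation
- `R/sam.R`, `R/cge.R` — SAM handling, RAS balancing, CGE calibration,
  Newton equilibrium solver, recursive dynamics, production econometrics
- `R/synthetic.R` — seeded generators for every input type
- `R/pipeline.R`, `inst/cli/haze-impact` — orchestration
- `vignettes/haze-impact-methods.Rmd` — model assumptions, parameter
  choices, numerical notes and limitations
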