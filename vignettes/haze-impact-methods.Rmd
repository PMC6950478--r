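---
title: "Methods: from a PM2.5 series to general-equilibrium losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a PM2.5 series to general-equilibrium losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazeimpact)
```

`hazeimpact` chains three models that jointly translate an annual pollutant
concentration series into macroeconomic losses. This vignette documents the
models, their assumptions, the tunable parameters and the numerical choices;
the README shows the worked pipeline.

# Grey-Markov forecasting

## GM(1,1)

Annual mean concentration series are short — often five observations — which
rules out conventional time-series models. The grey GM(1,1) model instead
fits the *cumulated* series $X^{(1)}(k) = \sum_{i \le k} X^{(0)}(i)$ with a
first-order differential equation
$dX^{(1)}/dt + a X^{(1)} = \mu$, whose parameters (the development
coefficient $a$, per year, and grey control parameter $\mu$) are estimated by
least squares on consecutive-mean pairs of the cumulated sequence. Restored
values on the original scale follow by first differences, with the first
observation kept as the initial condition, so the base year is always fitted
exactly. Fitting requires $n \ge 4$ strictly positive values.

A numerical note worth recording: on an exactly exponential input
$c\,e^{-\alpha (k-1)}$ the least-squares step is *exact* — the
consecutive-mean regression has zero residuals — but the estimated
development coefficient converges to $2\tanh(\alpha/2)$ rather than
$\alpha$, and the continuous-form restoration therefore carries an
$O(\alpha^3)$ discretisation error (about 0.3% relative at $\alpha = 0.2$).
The property tests assert these exact relationships rather than a naive
"reproduces the exponential to machine precision" claim, which the standard
formulation cannot satisfy.

## Residual states and Markov correction

Residuals (actual minus restored) are partitioned into $r \ge 2$ contiguous
intervals $d_i = [l_i, u_i)$ — left-closed, right-open, with the last
interval closed so the maximum residual belongs to a state. Residuals
outside the partition clamp to the nearest state, so late validation years
with unusually large errors remain usable. The one-step transition matrix is
the maximum-likelihood estimate from observed state successions; rows with
no observed departures (possible on short synthetic sequences) default to
uniform with a warning, keeping the matrix row-stochastic. On the Beijing
fixture the state-2 row is estimated from its single observed departure;
that row is unreachable from the forecast origin's state, so no forecast
depends on it.

Each state contributes a representative correction
$h_j = \lambda_j l_j + (1-\lambda_j) u_j$ with whitening coefficients
$\lambda_j \in [0,1]$. The corrected series uses each fitted year's *own*
residual state up to a forecast origin, and the expectation of $h$ under the
$k$-step transition distribution from the origin's state beyond it. The
origin defaults to $n-2$: the last two fitted years are treated as
pseudo-forecast years corrected through the chain rather than their own
states. This is the unique scheme consistent with treating the tail of the
sample as a validation window, and it is configurable (`origin =`).

## The genetic algorithm

The traditional choice $\lambda_j = 0.5$ (interval midpoints) is rarely
optimal. `ga_optimize()` minimises the in-sample MSE of the corrected
series over $[0,1]^r$ with a real-coded GA: population 30, 300 generations,
crossover rate 0.8, mutation rate 0.1, tournament selection of size 2,
arithmetic crossover, per-gene Gaussian mutation (sd 0.1, clipped), elitism
of one, and the midpoint individual seeded into the initial population so
the search can never end below the traditional baseline. Because the
corrected series is linear in $h$, the fitness is a quadratic and the GA
reliably reaches the box-constrained optimum from any seed; a grid oracle in
the test suite confirms this. On the Beijing fixture the fitness is flat in
$\lambda_2$ (state 2 receives zero transition weight from every reachable
state), so reported $\lambda_2$ values are arbitrary — a point worth knowing
when comparing runs.

## Model checking

`forecast_diagnostics()` reports the average relative error, the grey
relational grade (with distinguishing coefficient $\rho = 0.5$; smaller
$\rho$ sharpens discrimination), the posteriori error ratio $C = S_2/S_1$
and the small-error probability
$P = \Pr\{|\Delta_i - \bar\Delta| < 0.6745\,S_1\}$, plus the MSE. Both
standard deviations use the population (divide-by-$n$) form — the sample
form changes the third decimal of $C$ on five observations — and $S_2$ is
taken over the *absolute* error sequence. A perfect match is the $0/0$
limit of the relational coefficient and is defined as grade 1. When
evaluating a forecast whose published form is rounded (concentrations are
reported at 0.1 µg/m³), diagnostics computed from the rounded series
reproduce reported-precision evaluations; full-precision inputs give the
model's own values.

# Exposure-response health accounting

Attributable cases follow $E = P\,I\,(1 - e^{-\beta (C - C_0)})$: exposed
population $P$ (the total resident population, including for pediatric
outcomes — care of sick children costs household working time, and this is
the convention under which the labor-loss ratios are internally consistent),
baseline incidence $I$ (per person-year; for mortality, the year's crude
rate converted from per-mille), exposure-response coefficient $\beta$ per
µg/m³, and baseline concentration $C_0 = 0$ µg/m³ (no evidence of a
no-effect threshold). $E$ is increasing in every argument and saturates at
$P \cdot I$.

Eight outcomes are tracked: all-cause mortality, two hospital-admission
outcomes, two outpatient-visit outcomes, and three *unattended* outcomes
(chronic bronchitis, acute bronchitis, asthma) that are scaled by
$1 - 0.727 = 0.273$ — the complement of the national care-seeking share — to
avoid double counting cases already captured by visits. Key accounting
rules, frozen at 2013 levels:

| parameter | default | units |
|---|---|---|
| care-seeking share | 0.727 | — |
| working-age share of deaths | 0.2244 | — |
| working days per year | 250 | days |
| outpatient unit cost | 393.3 | RMB/visit |
| inpatient unit cost | 18,495.9 | RMB/admission |

Deaths remove whole working years (`0.2244 × 250` days each); morbidity
cases contribute their outcome's per-case work-loss days unscaled by the
working-age share. Lost days divide by 250 and by the labor force to give
the per-mille labor-loss ratio; admissions and visits times the unit costs
give the excess medical expenditure in million RMB. Interval propagation
replaces every $\beta$ by its lower/upper 95% bound simultaneously — a
deterministic, monotone propagation that brackets the central estimate
everywhere, matching how such CIs are conventionally reported (no
resampling).

The population table projects forward with constant growth — residents at
1.23%/yr, labor force at 2.46%/yr (the 2013–2016 averages), mortality frozen
at the last observed rate — with projected rows flagged `estimated`.

# The CGE stage

## Calibration

A social accounting matrix records all income/expenditure flows; each
account's row total must equal its column total. Published SAMs are off by
rounding, so `rebalance_sam()` applies RAS biproportional scaling first.
One numerical subtlety: with sparse SAM topologies (rows or columns with a
single nonzero cell) fixed balancing targets are infeasible — the
factor-account chain pins the household row — so the targets are refreshed
from the current matrix each sweep, which lets the rounding imbalance
diffuse around the account cycle. Zero cells stay zero, preserving the flow
topology.

`calibrate_cge()` reads the benchmark economy off the balanced SAM at unit
prices: per sector, CES technology
$QA = \alpha^q[\delta\,QVA^{\rho} + (1-\delta)\,QINTA^{\rho}]^{1/\rho}$
over value added and aggregate intermediates (Leontief commodity
composition within the aggregate), Cobb-Douglas value added
$QVA = \alpha^{va} QLD^{\eta} QKD^{1-\eta}$, a uniform value-added tax rate
from the activity-to-government flow (sector-level VAT rates are not
separable from an aggregate flow), and household income tax and saving
rates from the institutional flows. Share and efficiency parameters are
chosen so the benchmark satisfies every equation exactly; solving with no
shock reproduces the SAM to numerical precision, which the tests assert for
the Beijing matrix, the synthetic six-sector matrix and randomly generated
matrices. The CES substitution parameter $\rho$ is not identifiable from a
single SAM; it defaults to 0.5 (substitution elasticity 2) and is a
user-facing sensitivity hook.

## Closure, numeraire and shocks

The model is a closed single region: no trade, no enterprise account.
Closure is neoclassical — factor supplies exogenous and fully employed,
government consumption proportional to revenue, savings-driven investment.
The labor wage is the numeraire (a closed model needs exactly one nominal
anchor; no natural alternative presents itself), and exogenous nominal
quantities such as the committed medical expenditure are interpreted at
numeraire prices, which preserves zero-degree homogeneity: rescaling the
numeraire rescales all nominal flows and leaves real allocations unchanged,
an invariant the tests verify.

The two conducting variables enter as: (i) a proportional labor-supply cut
equal to the per-mille loss ratio; (ii) a committed (subsistence-style)
household purchase of the health-services commodity equal to the medical
expenditure, with the remaining disposable income saved and spent by the
calibrated shares. The committed-purchase form is a modelling choice — the
alternative of treating medical spending as a pure income loss would
understate the demand shift toward health services. On a one-sector matrix
the committed purchase is structurally inert (there is no other commodity
to crowd out); the six-sector matrix exists to exhibit it.

## Solving and dynamics

The equilibrium system — zero profit per activity, commodity market
clearing (one market dropped; Walras' law), and factor market clearing — is
solved by damped Newton iteration in log space (positivity for free) with a
forward-difference Jacobian, tolerance $10^{-10}$, starting from the
benchmark rescaled by aggregate factor growth. The dropped market's
relative imbalance is reported as the Walras residual; values above
$10^{-8}$ indicate a solver failure, not an economic result. Recursive
dynamics compound labor supply at $g_L = 2.46\%$, capital at $g_K = 13\%$
and TFP (the CES efficiency parameters) at $g_{tfp} = 2\%$ per year —
regional estimates for the study setting — and each year solves a no-shock
baseline and a shocked equilibrium; deltas are reported in million RMB
(the SAM is in hundred-million RMB) with GDP measured as value added at
benchmark prices.

With these growth rates the economy expands faster than the shock ratios
decline in some adjacent years, so the absolute GDP-loss path can tick up
once mid-window even though its trend falls with the concentration path;
the acceptance checks therefore assert the declining *trend* (negative
slope after the 2014 peak) rather than strict year-over-year monotonicity.

## Production-function econometrics

Where yearly input-output series are available, `estimate_production_params()`
estimates the CES block by the Kmenta second-order log approximation
$\ln QA = u_0 + u_1 \ln QVA + u_2 \ln QINTA + u_3 [\ln(QVA/QINTA)]^2$
(recovering $\delta = u_1$, $\rho = 2u_3/(u_1(1-u_1))$,
$\alpha^q = e^{u_0}$) and the Cobb-Douglas block exactly in logs. The
Kmenta form is an expansion around $QVA = QINTA$: away from that point the
recovered CES parameters carry approximation bias, which is why the
synthetic generator keeps the log input ratio within a configurable band
(default ±0.8 — wide enough to identify the curvature term against noise,
narrow enough to keep the bias within the tested tolerances). A vanishing
curvature term is flagged as Cobb-Douglas degenerate ($\rho = 0$).

# Synthetic data

Each generator emulates the statistical structure one pipeline stage
assumes, under a scoped seed (bit-identical reruns, caller's RNG stream
untouched):

- `gen_concentration()` — exponential decay plus state-conditional uniform
  residuals driven by a supplied Markov chain. Defaults (initial level
  99.3 µg/m³, decay 0.1193/yr, the ±4/±2 µg/m³ state bounds) mirror the
  Beijing fit so the generated trend tracks the observed decline.
- `gen_population()` — geometric growth, constant mortality.
- `gen_balanced_sam()` — random flows on the canonical SAM topology over
  `n_sectors` commodity/activity pairs, balanced exactly by construction
  (demand columns proportional to supply shares) plus a RAS pass.
- `gen_io_timeseries()` — production data from known CES/Cobb-Douglas
  parameters with log-normal disturbances.

What passing tests on synthetic data do and do not show: they establish
that each stage's estimator recovers the generating structure it assumes —
exponential trend, state-structured residuals, balanced flows, log-normal
production noise. Real concentration series have trend breaks and
autocorrelated residuals; real SAMs have measurement error correlated
across accounts; real production data violate the independence of inputs
and disturbances. None of those failure modes are represented, so synthetic
green tests certify the machinery, not the realism of the study
assumptions.

# Problem sizes and determinism

The shipped analyses are small by construction: a five-year series, eight
assessment years, a one-sector (and synthetic six-sector) SAM, GA budgets
of 30×300 evaluations, 28-year synthetic econometric samples. The full test
suite and the acceptance script each run in well under a minute on one
core. All randomness (GA, generators) flows from explicit integer seeds.

# Known limitations

- The exposure-response coefficients, incidence, care-seeking share and
  unit costs are external inputs frozen at base-year levels; no
  age-structure or urban/suburban exposure heterogeneity.
- Premature deaths are not monetised in the CGE stage (only the labor-days
  channel carries them), so economic losses are conservative.
- The CGE model is recursive, not forward-looking; agents do not
  anticipate future shocks.
- The conducting variables are computed outside the CGE model and fed in;
  there is no feedback from equilibrium outcomes to health.
- The six-sector SAM is a synthetic disaggregation for qualitative
  sector-level results; sector-level magnitudes have no empirical standing.
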