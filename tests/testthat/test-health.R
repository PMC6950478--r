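test_that("the exposure-response function behaves as specified", {
  # no excess concentration, no attributable cases
  expect_equal(er_cases(1e6, 0.01, 0.003, 50, baseline_conc = 50), 0)
  # direct evaluation for Beijing 2013 all-cause mortality
  expect_equal(
    er_cases(21.15e6, 4.52 / 1000, 0.00296, 89.5),
    21.15e6 * 0.00452 * (1 - exp(-0.00296 * 89.5))
  )
  # monotone increasing in concentration and coefficient, saturating at P*I
  cs <- er_cases(1e6, 0.01, 0.003, c(10, 50, 100, 500))
  expect_true(all(diff(cs) > 0))
  expect_lt(max(cs), 1e6 * 0.01)
  expect_equal(er_cases(1e6, 0.01, 50, 100), 1e6 * 0.01, tolerance = 1e-9)
  expect_error(er_cases(-1, 0.1, 0.1, 1), "nonnegative")
  expect_error(er_cases(1, 1.1, 0.1, 1), "\\[0, 1\\]")
})

test_that("population projection follows the constant-growth rule", {
  pop <- beijing_population(2020)
  expect_equal(pop$resident_population[pop$year == 2018] / 1e6, 22.27,
    tolerance = 1e-3
  )
  expect_equal(pop$labor_force[pop$year == 2020] / 1e6, 13.45,
    tolerance = 1e-3
  )
  expect_true(all(pop$mortality_rate[pop$year >= 2017] == 5.20))
  expect_true(all(pop$estimated == (pop$year >= 2017)))
  base <- beijing_population(2016)
  expect_equal(nrow(base), 4)
  expect_error(project_population(base, 2014), "precedes")
})

test_that("visit-share scaling applies only to unattended outcomes", {
  outc <- beijing_health_outcomes()
  conc <- annual_series(89.5, start_year = 2013)
  pop <- beijing_population(2016)[1, ]
  full <- annual_impacts(conc, pop, outc, visit_share = 0)
  none <- annual_impacts(conc, pop, outc, visit_share = 1)
  unatt <- outc$category == "unattended"
  expect_equal(none$cases[unatt], rep(0, sum(unatt)))
  expect_equal(none$cases[!unatt], full$cases[!unatt])
  bad <- dplyr::mutate(outc, category = replace(category, 1, "mystery"))
  expect_error(annual_impacts(conc, pop, bad), "unknown outcome category")
})

test_that("vectorised ledger matches a brute-force per-cell recomputation", {
  conc <- bj_conc_path()
  pop <- beijing_population(2020)
  outc <- beijing_health_outcomes()
  led <- health_impact(conc, pop, outc)

  # independent oracle: plain loops, scalar arithmetic, no package helpers
  oracle_cases <- 0
  oracle_days <- numeric(nrow(conc))
  oracle_med <- numeric(nrow(conc))
  oracle_deaths <- 0
  for (i in seq_len(nrow(conc))) {
    yr <- conc$year[i]
    C <- conc$value[i]
    P <- pop$resident_population[pop$year == yr]
    for (j in seq_len(nrow(outc))) {
      I <- if (outc$category[j] == "mortality") {
        pop$mortality_rate[pop$year == yr] / 1000
      } else {
        outc$incidence[j]
      }
      E <- P * I * (1 - exp(-outc$beta[j] * C))
      if (outc$category[j] == "unattended") E <- E * (1 - 0.727)
      if (outc$category[j] == "mortality") {
        oracle_deaths <- oracle_deaths + E
        oracle_days[i] <- oracle_days[i] + E * 0.2244 * 250
      } else {
        oracle_cases <- oracle_cases + E
        oracle_days[i] <- oracle_days[i] + E * outc$work_loss_days[j]
      }
      if (outc$category[j] == "inpatient") oracle_med[i] <- oracle_med[i] + E * 18495.9
      if (outc$category[j] == "outpatient") oracle_med[i] <- oracle_med[i] + E * 393.3
    }
  }
  expect_equal(led$totals$deaths, oracle_deaths, tolerance = 1e-9)
  expect_equal(led$totals$disease_cases, oracle_cases, tolerance = 1e-9)
  expect_equal(led$summary$labor_days, oracle_days, tolerance = 1e-9)
  expect_equal(led$summary$medical_expense, oracle_med / 1e6, tolerance = 1e-9)
})

test_that("interval propagation brackets the central estimate everywhere", {
  led <- health_impact(bj_conc_path(), beijing_population(2020),
    beijing_health_outcomes()
  )
  expect_true(all(led$cases$cases_low <= led$cases$cases + 1e-12))
  expect_true(all(led$cases$cases <= led$cases$cases_high + 1e-12))
  expect_true(all(led$summary$labor_loss_ratio_low <= led$summary$labor_loss_ratio))
  expect_true(all(led$summary$medical_expense <= led$summary$medical_expense_high))
  # degenerate interval collapses onto the central estimate
  outc <- beijing_health_outcomes() |>
    dplyr::mutate(beta_low = beta, beta_high = beta)
  led2 <- health_impact(bj_conc_path(), beijing_population(2020), outc)
  expect_equal(led2$cases$cases_low, led2$cases$cases)
  expect_equal(led2$cases$cases_high, led2$cases$cases)
})

test_that("the labor-loss ratio declines as concentrations fall", {
  led <- health_impact(bj_conc_path(), beijing_population(2020),
    beijing_health_outcomes()
  )
  ratios <- led$summary$labor_loss_ratio[led$summary$year >= 2014]
  expect_true(all(diff(ratios) < 0))
})

test_that("degenerate accounting inputs give zero losses", {
  outc <- beijing_health_outcomes()
  cases0 <- annual_impacts(
    annual_series(0.0 * 1:4, start_year = 2013) |>
      dplyr::mutate(value = 0),
    beijing_population(2016), outc
  )
  expect_equal(cases0$cases, rep(0, nrow(cases0)))
  expect_equal(labor_days_lost(cases0, outc)$labor_days, rep(0, 4))
  expect_equal(medical_expenses(cases0)$medical_expense, rep(0, 4))
  # deaths-only day accounting
  outc_d <- dplyr::mutate(outc, work_loss_days = 0)
  cases <- annual_impacts(
    annual_series(89.5, start_year = 2013),
    beijing_population(2016)[1, ], outc_d
  )
  days <- labor_days_lost(cases, outc_d)
  deaths <- cases$cases[cases$category == "mortality"]
  expect_equal(days$labor_days, deaths * 0.2244 * 250)
})
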