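test_that("noise-free synthetic concentrations are exactly exponential", {
  s <- gen_concentration(n_years = 8, noise = 0, seed = 1)
  expect_equal(s$value, 99.3 * exp(-0.1193 * (0:7)))
  fit <- fit_gm11(s)
  expect_equal(fit$a, 2 * tanh(0.1193 / 2), tolerance = 1e-9)
  # the deterministic trend tracks the observed Beijing decline
  # (the anchored base year is the one structural exception)
  obs <- c(89.5, 85.9, 80.6, 73.0, 58.0)
  expect_lt(max(abs(s$value[2:5] - obs[2:5])), 5)
})

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(
    gen_concentration(seed = 42), gen_concentration(seed = 42)
  )
  expect_identical(
    gen_io_timeseries(seed = 7), gen_io_timeseries(seed = 7)
  )
  expect_identical(
    unclass(gen_balanced_sam(n_sectors = 2, seed = 7)),
    unclass(gen_balanced_sam(n_sectors = 2, seed = 7))
  )
  expect_false(identical(
    gen_concentration(seed = 1)$value, gen_concentration(seed = 2)$value
  ))
})

test_that("generator calls do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(gen_concentration(seed = 9))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("synthetic population compounds geometrically", {
  p <- gen_population(n_years = 6, base_resident = 21.15e6, resident_growth = 0.0123)
  expect_equal(p$resident_population[6] / 1e6, 21.15 * 1.0123^5, tolerance = 1e-9)
  flat <- gen_population(n_years = 4, resident_growth = 0, labor_growth = 0)
  expect_equal(unique(flat$resident_population), flat$resident_population[1])
})

test_that("every generated artifact passes its consumer's preconditions", {
  # concentration -> grey-Markov stage
  s <- gen_concentration(n_years = 10, seed = 3)
  expect_true(all(s$value > 0))
  fc <- grey_markov(s, bounds = c(-4, -2, 2, 4), lambda = 0.5, horizon = 2)
  expect_equal(nrow(fc$forecast), 2)
  # population + concentration -> health stage
  pop <- gen_population(n_years = 10, start_year = min(s$year))
  led <- health_impact(s[, c("year", "value")], pop, beijing_health_outcomes())
  expect_true(all(led$cases$cases >= 0))
  # SAM -> CGE stage (calibrate, solve, shock)
  g <- gen_balanced_sam(n_sectors = 2, seed = 11)
  m <- calibrate_cge(g)
  eq <- solve_equilibrium(m, labor_loss_ratio = led$summary$labor_loss_ratio[1])
  expect_lt(abs(eq$walras), 1e-8)
  # io series -> production econometrics
  est <- estimate_production_params(gen_io_timeseries(seed = 3))
  expect_equal(nrow(est), 5)
})

test_that("synthetic state paths honour the supplied transition matrix", {
  P <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE) # cyclic
  s <- gen_concentration(n_years = 9, transition = P, seed = 5)
  trans <- cbind(s$state[-9], s$state[-1])
  expect_true(all(P[trans] == 1))
  expect_error(
    gen_concentration(transition = matrix(1, 3, 3)),
    "row-stochastic"
  )
})
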