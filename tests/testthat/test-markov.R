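test_that("state partitions parse, validate and label the published states", {
  p <- state_partition(bj_bounds)
  expect_equal(nrow(p), 3)
  expect_equal(p$lower, c(-4, -2, 2))
  p2 <- state_partition("-4:-2,-2:2,2:4")
  expect_equal(p2$upper, p$upper)
  expect_error(state_partition(c(-4, -2)), "at least 2 states")
  expect_error(state_partition(c(-4, -2, -3, 4)), "increasing")
  expect_error(state_partition("-4:-2,0:2"), "contiguous")
})

test_that("residual states match the published assignment, with clamping", {
  p <- state_partition(bj_bounds)
  expect_equal(assign_states(c(0.0, -2.2, 2.4, 3.6, -3.6), p), c(2, 1, 3, 3, 1))
  expect_equal(assign_states(-5.1, p), 1L) # below range clamps to first state
  expect_equal(assign_states(5.0, p), 3L) # above range clamps to last state
  expect_equal(assign_states(2.0, p), 3L) # intervals are left-closed
  expect_equal(assign_states(4.0, p), 3L) # last interval closed at the top
  expect_equal(assign_states(-2.0, p), 2L)
})

test_that("empirical transition matrix matches the published chain", {
  chain <- transition_matrix(c(2, 1, 3, 3, 1), r = 3)
  P <- chain$transition
  expect_equal(P[1, ], c(0, 0, 1))
  expect_equal(P[3, ], c(0.5, 0, 0.5))
  # observed d2 -> d1 transition (the printed chain reports this row
  # differently, but it is unreachable from the forecast origin)
  expect_equal(P[2, ], c(1, 0, 0))
  expect_equal(unname(k_step <- P %*% P)[3, ], c(0.25, 0, 0.75))
})

test_that("transition rows are stochastic, including k-step powers", {
  set.seed(42)
  for (i in 1:20) {
    states <- sample.int(3, 12, replace = TRUE)
    suppressWarnings(chain <- transition_matrix(states, r = 3))
    P <- chain$transition
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
    Pk <- P %*% P %*% P
    expect_equal(rowSums(Pk), rep(1, 3), tolerance = 1e-12)
  }
  expect_warning(transition_matrix(c(1, 1, 1), r = 2), "no observed departures")
})

test_that("whitening values interpolate the state intervals", {
  p <- state_partition(bj_bounds)
  expect_equal(whitening_values(p, c(0.5, 0.5, 0.5)), c(-3, 0, 3))
  expect_equal(whitening_values(p, bj_lambda), c(-2.008, -0.272, 2.014))
  expect_equal(whitening_values(p, c(1, 1, 1)), p$lower)
  expect_equal(whitening_values(p, c(0, 0, 0)), p$upper)
  expect_error(whitening_values(p, c(0.5, 1.2, 0.5)), "\\[0, 1\\]")
  expect_error(whitening_values(p, c(0.5, 0.5)), "one whitening coefficient")
})

test_that("Markov correction reproduces the published corrected series", {
  fc <- grey_markov(bj_pm, bounds = bj_bounds, lambda = bj_lambda, horizon = 3)
  expect_equal(round(fc$table$corrected, 1), c(89.5, 86.1, 80.2, 69.4, 62.6))
  expect_equal(round(fc$forecast$value, 1), c(55.2, 49.3, 43.7))
  expect_equal(fc$forecast$year, 2018:2020)
  # traditional midpoint coefficients
  fc05 <- grey_markov(bj_pm, bounds = bj_bounds, lambda = 0.5, horizon = 0)
  expect_equal(round(fc05$table$corrected, 1), c(89.5, 85.1, 81.2, 69.4, 63.1))
})

test_that("the base year is never corrected, for any whitening choice", {
  for (lam in list(0.5, c(0, 1, 0.3), bj_lambda)) {
    fc <- grey_markov(bj_pm, bounds = bj_bounds, lambda = lam, horizon = 0)
    expect_identical(fc$table$corrected[1], 89.5)
  }
})

test_that("markov_correct validates its arguments", {
  fit <- fit_gm11(bj_pm)
  p <- state_partition(bj_bounds)
  states <- assign_states(residuals(fit), p)
  chain <- transition_matrix(states, 3)
  h <- whitening_values(p, c(0.5, 0.5, 0.5))
  expect_error(markov_correct(fit, chain, h, states, horizon = -1), ">= 0")
  expect_error(markov_correct(fit, chain, h, states, origin = 1), "2..n")
  expect_error(markov_correct(fit, chain, h, states[-1]), "per fitted year")
})

test_that("GA search beats the midpoint baseline and matches a grid oracle", {
  p <- state_partition(bj_bounds)
  base_mse <- grey_markov(bj_pm, bounds = p, lambda = 0.5)$diagnostics$mse
  # independent oracle: exhaustive grid over the two active coefficients
  # (state 2 never receives transition weight from the origin state)
  fit <- fit_gm11(bj_pm)
  r <- residuals(fit)$value
  grid_mse <- function(h1, h3) {
    e <- c(0, r[2] - h1, r[3] - h3, r[4] - 0.5 * (h1 + h3),
      r[5] - (0.25 * h1 + 0.75 * h3))
    mean(e^2)
  }
  g <- expand.grid(h1 = seq(-4, -2, 0.005), h3 = seq(2, 4, 0.005))
  opt <- min(mapply(grid_mse, g$h1, g$h3))
  fits <- lapply(c(11, 97), function(s) ga_optimize(bj_pm, p, seed = s))
  for (ga in fits) {
    expect_lte(ga$mse, base_mse)
    expect_equal(ga$mse, opt, tolerance = 1e-3)
    expect_true(all(ga$lambdas >= 0 & ga$lambdas <= 1))
  }
  # two seeds converge to the same achieved fitness
  expect_equal(fits[[1]]$mse, fits[[2]]$mse, tolerance = 1e-4)
})

test_that("GA results are reproducible under a fixed seed", {
  p <- state_partition(bj_bounds)
  ctrl <- ga_control(pop_size = 20, generations = 40)
  a <- ga_optimize(bj_pm, p, ga_params = ctrl, seed = 3)
  b <- ga_optimize(bj_pm, p, ga_params = ctrl, seed = 3)
  expect_identical(a$lambdas, b$lambdas)
  expect_identical(a$history, b$history)
})
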