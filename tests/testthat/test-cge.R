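bj_model <- calibrate_cge(rebalance_sam(beijing_sam()))

test_that("calibration reads the benchmark economy off the SAM", {
  m <- bj_model
  # household income = labor plus capital earnings at unit factor prices
  expect_equal(m$qls0 + m$qks0, 9117 + 5987, tolerance = 1e-4)
  expect_equal(m$benchmark$qa, 52697, tolerance = 1e-4)
  expect_equal(m$benchmark$qinta, 34632, tolerance = 1e-4)
  p <- m$params
  expect_true(all(p$delta_q > 0 & p$delta_q < 1))
  expect_true(all(p$eta > 0 & p$eta < 1))
  expect_error(calibrate_cge(rebalance_sam(beijing_sam()), rho = 0), "nonzero")
})

test_that("the benchmark equilibrium replicates every SAM flow", {
  for (model in list(
    bj_model,
    calibrate_cge(beijing_sam6_synthetic()),
    calibrate_cge(gen_balanced_sam(n_sectors = 3, seed = 4), rho = 0.4)
  )) {
    eq <- solve_equilibrium(model)
    expect_lt(max(abs(eq$sectors$qa - model$benchmark$qa) / model$benchmark$qa), 1e-6)
    expect_lt(max(abs(eq$sectors$qva - model$benchmark$qva) / model$benchmark$qva), 1e-6)
    expect_lt(max(abs(eq$sectors$qld - model$benchmark$qld) / model$benchmark$qld), 1e-6)
    expect_lt(max(abs(eq$sectors$pa - 1)), 1e-8)
    expect_lt(abs(eq$macro$wk - 1), 1e-8)
    expect_lt(abs(eq$walras), 1e-8)
    # per-sector accounting identity: activity income exhausted by payments
    lhs <- eq$sectors$pa * eq$sectors$qa
    rhs <- eq$sectors$pva * eq$sectors$qva + eq$sectors$pinta * eq$sectors$qinta
    expect_lt(max(abs(lhs - rhs) / lhs), 1e-8)
  }
})

test_that("market clearing and Walras residual hold away from the benchmark", {
  eq <- solve_equilibrium(bj_model,
    qls = bj_model$qls0 * 1.1,
    qks = bj_model$qks0 * 1.3, tfp = 1.05, labor_loss_ratio = 0.8
  )
  expect_lt(abs(eq$walras), 1e-8)
  expect_lt(abs(sum(eq$sectors$qld) - bj_model$qls0 * 1.1 * (1 - 0.8 / 1000)), 1e-6)
  expect_lt(abs(sum(eq$sectors$qkd) - bj_model$qks0 * 1.3), 1e-6)
})

test_that("equilibrium prices are homogeneous of degree one in the numeraire", {
  m6 <- calibrate_cge(beijing_sam6_synthetic())
  base <- solve_equilibrium(m6, labor_loss_ratio = 0.5, medical_expense = 5)
  doubled <- solve_equilibrium(m6,
    labor_loss_ratio = 0.5, medical_expense = 5,
    numeraire = 2
  )
  expect_equal(doubled$sectors$qa, base$sectors$qa, tolerance = 1e-8)
  expect_equal(doubled$sectors$qh, base$sectors$qh, tolerance = 1e-8)
  expect_equal(doubled$sectors$pa, 2 * base$sectors$pa, tolerance = 1e-8)
  expect_equal(doubled$macro$wk, 2 * base$macro$wk, tolerance = 1e-8)
  expect_equal(doubled$macro$yh, 2 * base$macro$yh, tolerance = 1e-8)
})

test_that("shocks validate and map onto the exogenous set", {
  m <- bj_model
  none <- apply_shock(m)
  expect_equal(none$qls, m$qls0)
  expect_equal(none$committed, 0)
  s <- apply_shock(m, labor_loss_ratio = 0.82, medical_expense = 11)
  expect_equal(s$qls, m$qls0 * (1 - 0.00082))
  expect_equal(s$committed, 11)
  expect_error(apply_shock(m, labor_loss_ratio = 1000), "per mille")
  expect_error(apply_shock(m, medical_expense = -1), "nonnegative")
  expect_warning(
    apply_shock(m, medical_expense = m$benchmark$qa[1]),
    "implausibly large"
  )
})

test_that("a labor cut lowers GDP, monotonically in the cut", {
  base <- solve_equilibrium(bj_model)
  losses <- vapply(c(0.4, 0.82, 2), function(r) {
    base$macro$gdp - solve_equilibrium(bj_model, labor_loss_ratio = r)$macro$gdp
  }, numeric(1))
  expect_true(all(losses > 0))
  expect_true(all(diff(losses) > 0))
})

test_that("a committed medical purchase raises health output, lowers income", {
  m6 <- calibrate_cge(beijing_sam6_synthetic())
  base <- solve_equilibrium(m6)
  shocked <- solve_equilibrium(m6,
    labor_loss_ratio = 0.82,
    medical_expense = 11.13
  )
  hi <- match("health_services", m6$sectors)
  expect_gt(shocked$sectors$qa[hi], base$sectors$qa[hi])
  expect_true(all(shocked$sectors$qa[-hi] < base$sectors$qa[-hi]))
  expect_lt(shocked$macro$yh, base$macro$yh)
  expect_lt(shocked$macro$yg, base$macro$yg)
})

test_that("recursive dynamics compound factor supplies and zero shocks give zero deltas", {
  shocks <- tibble::tibble(
    year = 2013:2015, labor_loss_ratio = 0, medical_expense = 0
  )
  path <- recursive_simulate(bj_model, shocks)
  expect_true(all(abs(path$results$delta) < 1e-4))
  expect_true(all(abs(path$log$baseline_walras) < 1e-8))
  # baseline GDP grows with the compounded factor supplies
  gdp <- path$results$baseline[path$results$variable == "gdp"]
  expect_true(all(diff(gdp) > 0))
  # two periods of growth compound exactly on the factor side
  eq2 <- solve_equilibrium(bj_model,
    qls = bj_model$qls0 * 1.0246^2, qks = bj_model$qks0 * 1.13^2,
    tfp = 1.02^2
  )
  expect_equal(sum(eq2$sectors$qld), bj_model$qls0 * 1.0246^2, tolerance = 1e-8)
  expect_equal(sum(eq2$sectors$qkd), bj_model$qks0 * 1.13^2, tolerance = 1e-8)
})

test_that("production parameters are recovered from synthetic data", {
  # exact Cobb-Douglas data: exact recovery
  truth_cd <- list(alpha_q = 1.3, delta_q = 0.55, rho = 0, alpha_va = 1.1, eta = 0.6)
  d0 <- gen_io_timeseries(n = 28, truth = truth_cd, sigma = 0, seed = 2)
  est0 <- estimate_production_params(d0)
  e <- setNames(est0$estimate, est0$term)
  expect_equal(e[["delta_q"]], 0.55, tolerance = 1e-6)
  expect_equal(e[["alpha_q"]], 1.3, tolerance = 1e-6)
  expect_equal(e[["eta"]], 0.6, tolerance = 1e-6)
  expect_equal(e[["alpha_va"]], 1.1, tolerance = 1e-6)
  expect_equal(e[["rho"]], 0, tolerance = 1e-6)
  expect_true(attr(est0, "cd_degenerate"))
  # noisy CES data: approximate recovery (Kmenta approximation bias expected)
  truth <- list(alpha_q = 1.2, delta_q = 0.6, rho = 0.3, alpha_va = 1.1, eta = 0.6)
  d1 <- gen_io_timeseries(n = 28, truth = truth, sigma = 0.01, seed = 2)
  est1 <- estimate_production_params(d1)
  e1 <- setNames(est1$estimate, est1$term)
  expect_equal(e1[["delta_q"]], 0.6, tolerance = 0.05 / 0.6)
  expect_lt(abs(e1[["rho"]] - 0.3), 0.15)
  expect_false(attr(est1, "cd_degenerate"))
  # degenerate variation is rejected
  bad <- dplyr::mutate(d0, qinta = qva)
  expect_error(estimate_production_params(bad), "collinear")
  expect_error(estimate_production_params(d0[1:5, ]), "at least 8")
})
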