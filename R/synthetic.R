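#' Synthetic concentration series
#'
#' Generates an annual series with the structure the grey-Markov stage
#' assumes: a homogeneous exponential decay (which GM(1,1) fits exactly) plus
#' state-structured residuals. The residual state path is drawn from a
#' supplied Markov transition matrix and the residual value uniformly within
#' the state's interval, scaled by `noise`; `noise = 0` returns the pure
#' exponential.
#'
#' @param n_years Series length.
#' @param start_year First calendar year.
#' @param initial_level Level at the first year (µg/m³).
#' @param decay_rate Exponential decay per year.
#' @param partition Residual [state_partition()].
#' @param transition Row-stochastic state transition matrix (defaults to
#'   uniform).
#' @param noise Residual magnitude multiplier in `[0, 1]`.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return Annual-series tibble with a `state` column.
#' @examples
#' gen_concentration(8, noise = 0)
#' @export
gen_concentration <- function(n_years = 8L, start_year = 2013L,
                              initial_level = 99.3, decay_rate = 0.1193,
                              partition = state_partition(c(-4, -2, 2, 4)),
                              transition = NULL, noise = 1, seed = 1L) {
  r <- n_states(partition)
  transition <- transition %||% matrix(1 / r, r, r)
  if (any(abs(rowSums(transition) - 1) > 1e-12)) {
    abort("`transition` must be row-stochastic.")
  }
  draws <- withr::with_seed(seed, {
    states <- integer(n_years)
    states[1] <- sample.int(r, 1)
    for (k in seq_len(n_years - 1L)) {
      states[k + 1L] <- sample.int(r, 1, prob = transition[states[k], ])
    }
    list(states = states, resid = noise * runif(n_years,
      min = partition$lower[states],
      max = partition$upper[states]
    ))
  })
  states <- draws$states
  resid <- draws$resid
  trend <- initial_level * exp(-decay_rate * (seq_len(n_years) - 1))
  out <- annual_series(trend + resid, start_year = start_year)
  out$state <- states
  out
}

#' Synthetic population table
#'
#' Geometric growth from base values with a constant mortality rate — the
#' same structure the projection rule assumes.
#'
#' @param n_years Table length.
#' @param start_year First year.
#' @param base_resident,base_labor Base-year populations (persons).
#' @param mortality_rate Deaths per thousand persons (constant).
#' @param resident_growth,labor_growth Annual growth rates.
#' @return Population tibble consumable by [health_impact()].
#' @export
gen_population <- function(n_years = 8L, start_year = 2013L,
                           base_resident = 21.15e6, base_labor = 11.41e6,
                           mortality_rate = 4.52,
                           resident_growth = 0.0123, labor_growth = 0.0246) {
  k <- seq_len(n_years) - 1
  tibble(
    year = start_year + k,
    resident_population = base_resident * (1 + resident_growth)^k,
    labor_force = base_labor * (1 + labor_growth)^k,
    mortality_rate = mortality_rate,
    estimated = c(FALSE, rep(TRUE, n_years - 1L))
  )
}

#' Synthetic balanced social accounting matrix
#'
#' Draws random positive flows on the flow topology the CGE calibration
#' expects (the aggregate-SAM pattern, generalised to `n_sectors`
#' commodity/activity pairs) and balances by construction plus a final RAS
#' pass. Every generated matrix passes [calibrate_cge()]'s preconditions.
#'
#' @param n_sectors Number of sectors.
#' @param total_output Economy-wide gross output (SAM units).
#' @param seed RNG seed.
#' @return A balanced [sam()].
#' @export
gen_balanced_sam <- function(n_sectors = 1L, total_output = 52697,
                             seed = 1L) {
  M <- n_sectors
  draws <- withr::with_seed(seed, list(
    share = as.numeric(stats::rgamma(M, 2) + 0.2),
    va_rate = runif(M, 0.25, 0.5), # value added share of gross output
    vat_rate = runif(1, 0.1, 0.25), # VAT share of factor payments
    lab_int = runif(M, 0.35, 0.75),
    ti = runif(1, 0.05, 0.15),
    mps = runif(1, 0.3, 0.6)
  ))
  share <- draws$share / sum(draws$share)
  qa <- total_output * share
  va_rate <- draws$va_rate
  vat_rate <- draws$vat_rate
  lab_int <- draws$lab_int
  fac <- qa * va_rate / (1 + vat_rate)
  vat <- fac * vat_rate
  L <- fac * lab_int
  K <- fac - L
  inta <- qa - fac - vat
  ico <- outer(share, inta)
  # income-side totals; with all demand columns proportional to the supply
  # shares the matrix balances exactly by construction (total final demand
  # equals total value added plus indirect tax)
  yh <- sum(L) + sum(K)
  tax <- draws$ti * yh
  sh <- draws$mps * (yh - tax)
  hh <- (yh - tax - sh) * share
  gov <- (sum(vat) + tax) * share
  inv <- sh * share
  sec <- if (M == 1) "" else paste0("_s", seq_len(M))
  acc <- c(
    paste0("commodity", sec), paste0("activity", sec),
    "labor", "capital", "household", "government", "saving_investment"
  )
  S <- matrix(0, length(acc), length(acc), dimnames = list(acc, acc))
  ci <- seq_len(M)
  ai <- M + seq_len(M)
  S[ci, ai] <- ico
  S[cbind(ai, ci)] <- qa
  S["labor", ai] <- L
  S["capital", ai] <- K
  S["household", "labor"] <- sum(L)
  S["household", "capital"] <- sum(K)
  S["government", ai] <- vat
  S["government", "household"] <- tax
  S["saving_investment", "household"] <- sh
  S[ci, "household"] <- hh
  S[ci, "government"] <- gov
  S[ci, "saving_investment"] <- inv
  rebalance_sam(sam(S))
}

#' Synthetic input-output time series from known production parameters
#'
#' Generates yearly production data from the CES and Cobb-Douglas blocks with
#' known ("truth") parameters and log-normal disturbances, for exercising
#' [estimate_production_params()]. Factor inputs follow log-spaced growth
#' paths with independent log-normal spread so the regressors are not
#' collinear; `QVA` follows the Cobb-Douglas block times `exp(e)`, `QA` the
#' CES block times `exp(e)`. With `sigma = 0` and `rho = 0` the generated
#' data satisfies the estimating equations exactly.
#'
#' @param n Number of years (>= 8).
#' @param truth Named list of generator parameters: `alpha_q, delta_q, rho,
#'   alpha_va, eta` (`rho = 0` means Cobb-Douglas technology).
#' @param sigma Disturbance standard deviation on the log scale.
#' @param spread Log-scale spread of the input paths around trend; it also
#'   bounds the log value-added/intermediate ratio, so it trades Kmenta
#'   approximation bias (small spread) against identification of the
#'   curvature term (large spread).
#' @param seed RNG seed.
#' @return Tibble `year, qa, qva, qinta, qld, qkd`.
#' @export
gen_io_timeseries <- function(n = 28L,
                              truth = list(
                                alpha_q = 1.2, delta_q = 0.6, rho = 0.3,
                                alpha_va = 1.1, eta = 0.6
                              ),
                              sigma = 0.01, spread = 0.8, seed = 1L) {
  k <- seq_len(n)
  draws <- withr::with_seed(seed, list(
    qld = 100 * 1.03^k * exp(rnorm(n, 0, spread)),
    qkd = 150 * 1.05^k * exp(rnorm(n, 0, spread)),
    e_va = rnorm(n, 0, sigma),
    d = seq(-spread, spread, length.out = n) + rnorm(n, 0, spread / 3),
    e_qa = rnorm(n, 0, sigma)
  ))
  qld <- draws$qld
  qkd <- draws$qkd
  qva <- truth$alpha_va * qld^truth$eta * qkd^(1 - truth$eta) * exp(draws$e_va)
  # keep the value-added / intermediate mix near balance: the Kmenta
  # regression is a second-order expansion around QVA = QINTA, so the
  # generator holds ln(QVA/QINTA) within +/- spread of zero
  qinta <- qva * exp(-draws$d)
  qa <- if (truth$rho == 0) {
    truth$alpha_q * qva^truth$delta_q * qinta^(1 - truth$delta_q)
  } else {
    truth$alpha_q * (truth$delta_q * qva^truth$rho +
      (1 - truth$delta_q) * qinta^truth$rho)^(1 / truth$rho)
  }
  tibble(
    year = 1984L + k, qa = qa * exp(draws$e_qa),
    qva = qva, qinta = qinta, qld = qld, qkd = qkd
  )
}
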