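# Beijing study values used across tests (observed series, published state
# bounds, published optimal whitening coefficients).
bj_pm <- annual_series(c(89.5, 85.9, 80.6, 73.0, 58.0), start_year = 2013)
bj_bounds <- c(-4, -2, 2, 4)
bj_lambda <- c(0.004, 0.568, 0.993)

# Forecast path used by the health stage: observed 2013-2017 plus the
# grey-Markov 2018-2020 forecast at reported precision.
bj_conc_path <- function() {
  fc <- grey_markov(bj_pm, bounds = bj_bounds, lambda = bj_lambda, horizon = 3)
  dplyr::bind_rows(
    bj_pm,
    dplyr::mutate(fc$forecast, value = round(value, 1))
  )
}
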