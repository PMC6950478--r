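#' Grey-Markov concentration forecast
#'
#' One-call interface to the full forecasting stage: fit GM(1,1), partition
#' the residuals into states, estimate the empirical transition chain, choose
#' whitening coefficients (fixed, traditional midpoints, or a GA search), and
#' produce the corrected in-sample series plus out-of-sample forecast.
#'
#' @param series Annual series tibble (`year`, `value`) or numeric vector.
#' @param bounds State partition break points (or string; see
#'   [state_partition()]).
#' @param lambda Either `"ga"` (default: run [ga_optimize()]), a single number
#'   recycled per state, or a numeric vector of per-state whitening
#'   coefficients.
#' @param horizon Forecast years beyond the data (default 3).
#' @param origin Forecast-origin index; see [markov_correct()].
#' @param ga_params,seed Settings for the GA search when `lambda = "ga"`.
#' @param rho Distinguishing coefficient for the diagnostics.
#' @return A `grey_markov` object: the component fits plus
#'   * `table` — tibble `year, actual, gm_fitted, corrected, residual, state`
#'     over the in-sample years,
#'   * `forecast` — tibble of forecast years,
#'   * `diagnostics` — [forecast_diagnostics()] of corrected vs actual.
#' @examples
#' pm <- annual_series(c(89.5, 85.9, 80.6, 73.0, 58.0), 2013)
#' fc <- grey_markov(pm, bounds = c(-4, -2, 2, 4), lambda = 0.5, horizon = 3)
#' fc$forecast
#' @export
grey_markov <- function(series, bounds, lambda = "ga", horizon = 3L,
                        origin = NULL, ga_params = ga_control(), seed = 1L,
                        rho = 0.5) {
  s <- as_annual_series(series)
  n <- nrow(s)
  origin <- origin %||% max(2L, n - 2L)
  model <- fit_gm11(s)
  partition <- if (inherits(bounds, "state_partition")) bounds else state_partition(bounds)
  res <- residuals(model)
  states <- assign_states(res, partition)
  if (!all(seq_len(n_states(partition)) %in% states)) {
    warn("some states contain no observed residual.")
  }
  chain <- transition_matrix(states, n_states(partition))
  ga <- NULL
  if (identical(lambda, "ga")) {
    ga <- ga_optimize(s, partition,
      ga_params = ga_params, seed = seed,
      origin = origin, model = model
    )
    lambda <- ga$lambdas
  } else if (length(lambda) == 1) {
    lambda <- rep(as.numeric(lambda), n_states(partition))
  }
  h <- whitening_values(partition, lambda)
  corr <- markov_correct(model, chain, h, states, horizon = horizon, origin = origin)
  in_sample <- corr$value[seq_len(n)]
  structure(
    list(
      model = model, partition = partition, chain = chain,
      lambdas = lambda, h = h, ga = ga, origin = origin,
      table = tibble(
        year = s$year, actual = s$value, gm_fitted = model$fitted$value,
        corrected = in_sample, residual = s$value - in_sample, state = states
      ),
      forecast = corr[corr$type == "forecast", c("year", "value")],
      diagnostics = forecast_diagnostics(s, in_sample, rho = rho)
    ),
    class = "grey_markov"
  )
}

#' @export
print.grey_markov <- function(x, ...) {
  cat("Grey-Markov forecast\n")
  cat(sprintf(
    "  lambda = (%s)\n",
    paste(sprintf("%.3f", x$lambdas), collapse = ", ")
  ))
  print(as.data.frame(dplyr::mutate(
    x$table,
    dplyr::across(c("gm_fitted", "corrected", "residual"), \(v) round(v, 1))
  )), row.names = FALSE)
  if (nrow(x$forecast)) {
    cat("Forecast:\n")
    print(as.data.frame(dplyr::mutate(x$forecast, value = round(.data$value, 1))),
      row.names = FALSE
    )
  }
  invisible(x)
}

#' @export
tidy.grey_markov <- function(x, ...) x$table

#' @export
glance.grey_markov <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      a = x$model$a, mu = x$model$mu,
      lambda = paste(sprintf("%.3f", x$lambdas), collapse = ",")
    ),
    x$diagnostics
  )
}

#' Plot a grey-Markov forecast
#'
#' Actual, GM(1,1) fitted, corrected and forecast values as annual lines.
#'
#' @param object A `grey_markov` fit.
#' @param ... Unused.
#' @export
autoplot.grey_markov <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object$table,
      year = .data$year, value = .data$actual, series = "actual"
    ),
    dplyr::transmute(object$table,
      year = .data$year, value = .data$gm_fitted, series = "GM(1,1)"
    ),
    dplyr::transmute(object$table,
      year = .data$year, value = .data$corrected, series = "corrected"
    ),
    dplyr::transmute(object$forecast,
      year = .data$year, value = .data$value, series = "forecast"
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$value, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = NULL, y = expression(PM[2.5] ~ (mu * g / m^3)), colour = NULL
    ) +
    ggplot2::theme_minimal()
}
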