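#' Accumulated generating operator (AGO)
#'
#' Transforms a raw annual series into its running cumulative sum, the
#' smoothed image on which the grey differential model is fitted.
#'
#' @param series An annual series (tibble with `year`, `value`) or numeric
#'   vector.
#' @return A tibble with the same years and cumulated values.
#' @examples
#' ago(annual_series(c(89.5, 85.9, 80.6, 73.0, 58.0), 2013))
#' @export
ago <- function(series) {
  s <- as_annual_series(series)
  tibble(year = s$year, value = cumsum(s$value))
}

#' Fit a GM(1,1) grey model
#'
#' Fits the first-order single-variable grey model: the cumulative (AGO) image
#' of the series is assumed to follow `dX1/dt + a X1 = mu`, and the development
#' coefficient `a` and grey control parameter `mu` are estimated by least
#' squares on consecutive-mean pairs of the AGO sequence. Fitted values on the
#' original scale are restored by inverse AGO with the first observation as
#' initial condition, so `fitted[1]` always equals the first observation
#' exactly.
#'
#' Grey models are designed for very short positive series; at least four
#' observations are required.
#'
#' @param series Annual series (tibble or numeric vector) with `n >= 4`
#'   strictly positive values.
#' @return An object of class `gm11` with elements `a`, `mu`, `x0_1` (first
#'   observation), `fitted` (annual-series tibble of restored values) and
#'   `data` (the input series).
#' @examples
#' fit <- fit_gm11(annual_series(c(89.5, 85.9, 80.6, 73.0, 58.0), 2013))
#' fit$mu / fit$a   # constant of the time-response function
#' @export
fit_gm11 <- function(series) {
  s <- as_annual_series(series)
  n <- nrow(s)
  if (n < 4) abort("GM(1,1) needs at least 4 observations.")
  if (any(s$value <= 0)) abort("GM(1,1) needs strictly positive values.")
  x1 <- cumsum(s$value)
  z <- -0.5 * (x1[-n] + x1[-1])          # consecutive means of the AGO image
  B <- cbind(z, 1)
  yn <- s$value[-1]
  BtB <- crossprod(B)
  if (abs(det(BtB)) < 1e-10 * max(abs(BtB))^2) {
    abort("singular normal equations: the series carries no usable trend.")
  }
  est <- solve(BtB, crossprod(B, yn))
  a <- est[1]
  mu <- est[2]
  structure(
    list(
      a = a, mu = mu, x0_1 = s$value[1],
      fitted = tibble(year = s$year, value = gm11_restored(a, mu, s$value[1], 0:(n - 1))),
      data = s
    ),
    class = "gm11"
  )
}

# Restored (inverse-AGO) values at steps k = 0, 1, 2, ... where k = 0 is the
# base year. k may run beyond the fitting window for extrapolation.
gm11_restored <- function(a, mu, x0_1, k) {
  out <- (1 - exp(a)) * (x0_1 - mu / a) * exp(-a * k)
  out[k == 0] <- x0_1
  out
}

#' @export
print.gm11 <- function(x, ...) {
  cat("GM(1,1) grey model\n")
  cat(sprintf(
    "  a = %.5f  mu = %.4f  mu/a = %.4f\n  fitted over %d-%d (n = %d)\n",
    x$a, x$mu, x$mu / x$a, min(x$fitted$year), max(x$fitted$year),
    nrow(x$fitted)
  ))
  invisible(x)
}

#' Extrapolate a fitted GM(1,1) model
#'
#' @param object A `gm11` fit.
#' @param horizon Number of years beyond the fitting window (0 returns the
#'   in-sample fit only).
#' @param ... Unused.
#' @return Annual-series tibble of fitted plus extrapolated values.
#' @export
predict.gm11 <- function(object, horizon = 0L, ...) {
  n <- nrow(object$fitted)
  k <- 0:(n - 1 + horizon)
  tibble(
    year = seq.int(min(object$fitted$year), by = 1L, length.out = length(k)),
    value = gm11_restored(object$a, object$mu, object$x0_1, k)
  )
}

#' Residuals of a GM(1,1) fit
#'
#' Signed residuals, actual minus restored fitted value, per year. These are
#' the inputs of the Markov state correction.
#'
#' @param object A `gm11` fit.
#' @param ... Unused.
#' @return Annual-series tibble of residuals.
#' @export
residuals.gm11 <- function(object, ...) {
  tibble(year = object$data$year, value = object$data$value - object$fitted$value)
}

#' @rdname residuals.gm11
#' @param series Actual annual series; must align year-by-year with the fitted
#'   series (useful when fitted values come from elsewhere than `object$data`).
#' @param fitted Fitted annual series.
#' @export
series_residuals <- function(series, fitted) {
  s <- as_annual_series(series)
  f <- as_annual_series(fitted)
  if (nrow(s) != nrow(f) || any(s$year != f$year)) {
    abort("actual and fitted series must cover identical years.")
  }
  tibble(year = s$year, value = s$value - f$value)
}

#' @export
tidy.gm11 <- function(x, ...) {
  dplyr::left_join(
    dplyr::rename(x$data, actual = "value"),
    dplyr::rename(x$fitted, fitted = "value"),
    by = "year"
  ) |>
    dplyr::mutate(residual = .data$actual - .data$fitted)
}

#' @export
glance.gm11 <- function(x, ...) {
  r <- x$data$value - x$fitted$value
  tibble(
    a = x$a, mu = x$mu, constant = x$mu / x$a,
    n = nrow(x$data), mse = mean(r^2)
  )
}
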