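#' Construct an annual series
#'
#' The basic container used throughout the forecasting stage: a two-column
#' tibble with one observation per calendar year. Values are typically annual
#' mean concentrations in µg/m³, but any positive annual quantity fits.
#'
#' @param values Numeric vector of observations, one per year.
#' @param start_year First calendar year.
#' @param year Alternatively, an explicit vector of consecutive years.
#' @return A tibble with columns `year` and `value`.
#' @examples
#' annual_series(c(89.5, 85.9, 80.6, 73.0, 58.0), start_year = 2013)
#' @export
annual_series <- function(values, start_year = 1L, year = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0) abort("`values` must be non-empty.")
  if (is.null(year)) {
    year <- seq.int(start_year, by = 1L, length.out = length(values))
  }
  if (length(year) != length(values)) {
    abort("`year` and `values` must have the same length.")
  }
  if (any(diff(year) != 1)) abort("years must be consecutive.")
  tibble(year = as.integer(year), value = values)
}

# Accept either an annual-series tibble or a bare numeric vector; return the
# tibble form. Internal normalisation used by every forecasting entry point.
as_annual_series <- function(x, start_year = 1L) {
  if (is.data.frame(x)) {
    if (!all(c("year", "value") %in% names(x))) {
      abort("a series data frame needs `year` and `value` columns.")
    }
    return(annual_series(x$value, year = x$year))
  }
  annual_series(x, start_year = start_year)
}

# Damped Newton iteration for square nonlinear systems, with a
# forward-difference Jacobian. Deterministic: always starts at `x0` and halves
# the step until the residual norm decreases (up to 30 halvings).
newton_solve <- function(fn, x0, tol = 1e-10, max_iter = 200L) {
  x <- x0
  f <- fn(x)
  if (length(f) != length(x)) abort("system is not square.")
  normf <- function(v) sqrt(sum(v^2))
  iter <- 0L
  while (normf(f) > tol && iter < max_iter) {
    J <- fd_jacobian(fn, x, f)
    step <- tryCatch(solve(J, -f), error = function(e) {
      abort(paste0("singular Jacobian at iteration ", iter))
    })
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      f_new <- fn(x_new)
      if (all(is.finite(f_new)) && normf(f_new) < normf(f)) break
      lambda <- lambda / 2
      if (lambda < 2^-30) {
        abort(paste0(
          "Newton iteration stalled at residual norm ",
          format(normf(f), digits = 4)
        ))
      }
    }
    x <- x_new
    f <- f_new
    iter <- iter + 1L
  }
  if (normf(f) > tol) {
    abort(paste0(
      "no convergence after ", max_iter, " iterations; residual norm ",
      format(normf(f), digits = 4)
    ))
  }
  list(x = x, residual = f, iterations = iter)
}

fd_jacobian <- function(fn, x, f0 = fn(x)) {
  n <- length(x)
  J <- matrix(0, n, n)
  h <- pmax(abs(x), 1) * sqrt(.Machine$double.eps)
  for (j in seq_len(n)) {
    xj <- x
    xj[j] <- xj[j] + h[j]
    J[, j] <- (fn(xj) - f0) / h[j]
  }
  J
}

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
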