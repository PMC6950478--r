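#' Grey-forecast model-checking diagnostics
#'
#' Computes the four standard grey-model checks plus mean squared error for a
#' pair of aligned actual/predicted series:
#'
#' * **average relative error** — mean of `|actual - predicted| / actual`;
#' * **grey relational grade** — mean relational coefficient
#'   `(min D + rho * max D) / (D_i + rho * max D)` over the absolute errors
#'   `D`, with distinguishing coefficient `rho` (default 0.5); equals 1 for a
#'   perfect match;
#' * **posteriori error ratio** `C = S2 / S1` — ratio of the population
#'   standard deviations of the absolute-error sequence and of the original
#'   sequence; smaller is better;
#' * **small error probability** `P` — share of absolute errors within
#'   `0.6745 * S1` of their mean;
#' * **mse** — mean squared prediction error.
#'
#' @param actual,predicted Aligned annual series (tibbles or numeric vectors).
#' @param rho Distinguishing coefficient in (0, 1).
#' @return A `grey_diagnostics` one-row tibble.
#' @examples
#' forecast_diagnostics(c(89.5, 85.9, 80.6), c(89.5, 88.1, 78.2))
#' @export
forecast_diagnostics <- function(actual, predicted, rho = 0.5) {
  a <- as_annual_series(actual)
  p <- as_annual_series(predicted, start_year = a$year[1])
  if (nrow(a) != nrow(p) || any(a$year != p$year)) {
    abort("actual and predicted series must cover identical years.")
  }
  if (any(a$value == 0)) {
    abort("relative error is undefined for zero actual values.")
  }
  if (rho <= 0 || rho >= 1) abort("`rho` must lie in (0, 1).")
  delta <- abs(a$value - p$value)
  s1 <- sd_pop(a$value)
  s2 <- sd_pop(delta)
  out <- tibble(
    avg_relative_error = mean(delta / abs(a$value)),
    # a perfect match is the 0/0 limit of the relational coefficient: grade 1
    relational_grade = if (max(delta) == 0) 1 else
      mean((min(delta) + rho * max(delta)) / (delta + rho * max(delta))),
    posteriori_error_ratio = s2 / s1,
    small_error_probability = mean(abs(delta - mean(delta)) < 0.6745 * s1),
    mse = mean((a$value - p$value)^2)
  )
  class(out) <- c("grey_diagnostics", class(out))
  out
}

#' @export
print.grey_diagnostics <- function(x, ...) {
  cat("Grey forecast diagnostics\n")
  cat(sprintf(
    paste0(
      "  avg relative error      %.4f\n",
      "  relational grade        %.4f\n",
      "  posteriori error ratio  %.4f\n",
      "  small error probability %.4f\n",
      "  MSE                     %.3f\n"
    ),
    x$avg_relative_error, x$relational_grade, x$posteriori_error_ratio,
    x$small_error_probability, x$mse
  ))
  invisible(x)
}
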