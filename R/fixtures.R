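#' Beijing study fixtures
#'
#' Plain-text copies of the published Beijing study inputs, shipped with the
#' package: the observed 2013-2017 annual mean PM2.5 concentration series, the
#' 2013-2016 population/labor-force/mortality table, the eight
#' exposure-response health-outcome parameter rows, and the 2012 aggregate
#' social accounting matrix (hundred-million RMB).
#'
#' `beijing_population()` extends the observed table through `through_year`
#' with the study's projection rule (residents +1.23%/yr, labor force
#' +2.46%/yr, mortality frozen at the 2016 level); projected rows are flagged
#' in the `estimated` column.
#'
#' @return Tibbles matching the schemas consumed by the pipeline stages;
#'   `beijing_sam()` returns a [sam()] matrix.
#' @examples
#' beijing_concentration()
#' beijing_population(through_year = 2020)
#' @name beijing_fixtures
NULL

fixture_path <- function(file) {
  system.file("extdata", file, package = "hazeimpact", mustWork = TRUE)
}

#' @rdname beijing_fixtures
#' @export
beijing_concentration <- function() {
  readr::read_csv(fixture_path("beijing_pm25.csv"), show_col_types = FALSE)
}

#' @rdname beijing_fixtures
#' @param through_year Last year of the projected population table.
#' @export
beijing_population <- function(through_year = 2020L) {
  base <- readr::read_csv(fixture_path("beijing_population.csv"),
    show_col_types = FALSE
  )
  project_population(base, through_year)
}

#' @rdname beijing_fixtures
#' @export
beijing_health_outcomes <- function() {
  readr::read_csv(fixture_path("beijing_health_outcomes.csv"),
    show_col_types = FALSE
  )
}

#' @rdname beijing_fixtures
#' @export
beijing_sam <- function() {
  load_sam(fixture_path("beijing_sam.csv"))
}

#' Synthetic six-sector disaggregation of the Beijing SAM
#'
#' The published study aggregates Beijing's economy to a single activity in
#' its printed SAM; the sector-level matrix behind its six-sector results was
#' never published. This constructor builds a *synthetic* six-sector
#' disaggregation of the printed aggregate matrix — deterministic, exactly
#' balanced, with plausible Beijing-2012 output shares and factor intensities
#' (industry capital-intensive, services labor-intensive, a small
#' health-services sector) — for demonstrating sector-level responses. It is
#' a stand-in, not published data.
#'
#' @return A [sam()] matrix with per-sector commodity/activity accounts.
#' @export
beijing_sam6_synthetic <- function() {
  sectors <- c(
    "agriculture", "industry", "construction",
    "transport_post_telecom", "health_services", "other_services"
  )
  share <- c(0.010, 0.250, 0.070, 0.080, 0.025, 0.565) # gross output shares
  qa <- 52697 * share
  vat <- 2961 * share
  # factor intensities: labor share of factor payments by sector
  lab_int <- c(0.55, 0.40, 0.55, 0.50, 0.75, 0.72)
  fac <- (9117 + 5987) * share
  L <- lab_int * fac
  K <- fac - L
  L <- L * 9117 / sum(L) # rescale so factor rows hit the printed totals
  K <- K * 5987 / sum(K)
  inta <- qa - L - K - vat
  stopifnot(all(inta > 0))
  # intermediate composition: commodity mix of inputs = supply shares
  ico <- outer(share, inta) # commodity n used by activity m
  hh <- 6203 * share
  gov <- 4452 * share
  inv <- 7410 * share
  # tilt household demand toward health services, offset in government demand
  tilt <- min(40, 0.5 * gov[5])
  hh[5] <- hh[5] + tilt
  hh[6] <- hh[6] - tilt
  gov[5] <- gov[5] - tilt
  gov[6] <- gov[6] + tilt
  acc <- c(
    paste0("commodity_", sectors), paste0("activity_", sectors),
    "labor", "capital", "household", "government", "saving_investment"
  )
  S <- matrix(0, length(acc), length(acc), dimnames = list(acc, acc))
  ci <- seq_along(sectors)
  ai <- length(sectors) + seq_along(sectors)
  S[ci, ai] <- ico
  S[cbind(ai, ci)] <- qa
  S["labor", ai] <- L
  S["capital", ai] <- K
  S["household", "labor"] <- 9117
  S["household", "capital"] <- 5987
  S["government", ai] <- vat
  S["government", "household"] <- 1490
  S["saving_investment", "household"] <- 7410
  S[ci, "household"] <- hh
  S[ci, "government"] <- gov
  S[ci, "saving_investment"] <- inv
  rebalance_sam(sam(S))
}
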