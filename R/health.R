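#' Exposure-response attributable cases
#'
#' The log-linear exposure-response function used throughout the health
#' stage: attributable cases `E = P * I * (1 - exp(-beta * (C - C0)))`, where
#' `P` is the exposed population, `I` the baseline annual incidence (a rate in
#' `[0, 1]`), `beta` the exposure-response coefficient per µg/m³ and `C` the
#' annual mean concentration. The baseline concentration `C0` defaults to 0
#' (no evidence of a no-effect threshold for fine particulates). `E` is
#' increasing in every argument and saturates at `P * I`.
#'
#' All arguments are vectorised.
#'
#' @param population Exposed population (persons).
#' @param incidence Baseline incidence rate per person-year.
#' @param beta Exposure-response coefficient (1/(µg/m³)).
#' @param conc Concentration (µg/m³).
#' @param baseline_conc Counterfactual concentration `C0` (µg/m³).
#' @return Attributable cases (persons).
#' @examples
#' er_cases(21.15e6, 0.00452, 0.00296, 89.5)
#' @export
er_cases <- function(population, incidence, beta, conc, baseline_conc = 0) {
  if (any(population < 0) || any(incidence < 0) || any(beta < 0) ||
    any(conc < 0) || any(baseline_conc < 0)) {
    abort("exposure-response inputs must be nonnegative.")
  }
  if (any(incidence > 1)) {
    abort("`incidence` is a per-person rate and must lie in [0, 1].")
  }
  population * incidence * (1 - exp(-beta * (conc - baseline_conc)))
}

#' Project a population table forward
#'
#' Extends an observed population table with constant growth rates: resident
#' population grows at `resident_growth` per year, the labor force at
#' `labor_growth` per year, and the crude mortality rate is frozen at its
#' last observed level. Projected rows carry `estimated = TRUE`.
#'
#' Defaults are the study's Beijing rule: the 2013-2016 average growth rates
#' of 1.23% (residents) and 2.46% (labor force).
#'
#' @param base Tibble with columns `year`, `resident_population`,
#'   `labor_force`, `mortality_rate` (deaths per thousand persons).
#' @param through_year Final projected year.
#' @param resident_growth,labor_growth Annual growth rates.
#' @return The extended tibble, with an `estimated` flag column.
#' @export
project_population <- function(base, through_year,
                               resident_growth = 0.0123,
                               labor_growth = 0.0246) {
  need <- c("year", "resident_population", "labor_force", "mortality_rate")
  if (!all(need %in% names(base))) {
    abort(paste0("`base` needs columns ", paste(need, collapse = ", "), "."))
  }
  if (any(base$labor_force > base$resident_population)) {
    abort("labor force cannot exceed resident population.")
  }
  base <- dplyr::arrange(base, .data$year)
  if (!"estimated" %in% names(base)) base$estimated <- FALSE
  last <- dplyr::slice_tail(base, n = 1)
  if (through_year < last$year) abort("`through_year` precedes the base table.")
  if (through_year == last$year) {
    return(as_tibble(base))
  }
  steps <- seq_len(through_year - last$year)
  proj <- tibble(
    year = last$year + steps,
    resident_population = last$resident_population * (1 + resident_growth)^steps,
    labor_force = last$labor_force * (1 + labor_growth)^steps,
    mortality_rate = last$mortality_rate,
    estimated = TRUE
  )
  dplyr::bind_rows(as_tibble(base), proj)
}

#' Annual attributable cases per health outcome
#'
#' Applies [er_cases()] to every outcome row for one or more years. The
#' exposed population for every outcome is the total resident population; for
#' mortality rows the incidence is the year's crude mortality rate
#' (per-thousand, converted to a rate). Outcomes in the `unattended` category
#' (bronchitis and asthma cases that never reach a clinic) are scaled by
#' `1 - visit_share` to avoid double counting with the visit-based outcomes.
#'
#' @param conc Tibble `year, value` of concentrations (µg/m³).
#' @param population Population table as from [beijing_population()].
#' @param outcomes Outcome parameter tibble as from
#'   [beijing_health_outcomes()]; the `beta_col` argument selects which
#'   coefficient column to use.
#' @param visit_share Share of patients who seek medical care (default
#'   0.727).
#' @param beta_col Coefficient column: `"beta"`, `"beta_low"` or
#'   `"beta_high"`.
#' @param baseline_conc Counterfactual concentration.
#' @return Tibble `year, outcome, category, cases`.
#' @export
annual_impacts <- function(conc, population, outcomes, visit_share = 0.727,
                           beta_col = "beta", baseline_conc = 0) {
  known <- c("mortality", "inpatient", "outpatient", "unattended")
  if (!all(outcomes$category %in% known)) {
    abort(paste0(
      "unknown outcome category: ",
      paste(setdiff(outcomes$category, known), collapse = ", ")
    ))
  }
  joined <- dplyr::inner_join(conc, population, by = "year")
  if (nrow(joined) < nrow(conc)) {
    abort("population table does not cover every concentration year.")
  }
  purrr::pmap_dfr(
    joined[c("year", "value", "resident_population", "mortality_rate")],
    function(year, value, resident_population, mortality_rate) {
      inc <- ifelse(outcomes$category == "mortality",
        mortality_rate / 1000, outcomes$incidence
      )
      cases <- er_cases(
        resident_population, inc, outcomes[[beta_col]], value, baseline_conc
      )
      cases <- ifelse(outcomes$category == "unattended",
        cases * (1 - visit_share), cases
      )
      tibble(
        year = year, outcome = outcomes$outcome,
        category = outcomes$category, cases = cases
      )
    }
  )
}

#' Person-days of labor lost to pollution-attributable ill health
#'
#' Deaths remove whole working years: each death contributes
#' `labor_death_share * annual_workdays` days, where `labor_death_share` is
#' the share of deaths occurring in the working-age (15-64) population.
#' Every morbidity case contributes its outcome's per-case work-loss days,
#' unscaled (care of sick children also costs household working time).
#'
#' @param cases Tibble `year, outcome, category, cases` from
#'   [annual_impacts()].
#' @param outcomes Outcome parameter tibble (for `work_loss_days`).
#' @param labor_death_share Working-age share of all deaths (default 0.2244).
#' @param annual_workdays Working days per person-year (default 250).
#' @return Tibble `year, labor_days` (person-days).
#' @export
labor_days_lost <- function(cases, outcomes, labor_death_share = 0.2244,
                            annual_workdays = 250) {
  cases |>
    dplyr::left_join(outcomes[c("outcome", "work_loss_days")], by = "outcome") |>
    dplyr::mutate(days = dplyr::if_else(
      .data$category == "mortality",
      .data$cases * labor_death_share * annual_workdays,
      .data$cases * .data$work_loss_days
    )) |>
    dplyr::summarise(labor_days = sum(.data$days), .by = "year")
}

#' Labor-force loss ratio
#'
#' Converts lost person-days into the equivalent number of full-time workers
#' (dividing by the annual workday count) and expresses it per thousand of
#' the labor force.
#'
#' @param days Tibble `year, labor_days` from [labor_days_lost()].
#' @param population Population table with `labor_force`.
#' @param annual_workdays Working days per person-year.
#' @return Tibble `year, labor_loss_ratio` (per mille).
#' @export
labor_loss_ratio <- function(days, population, annual_workdays = 250) {
  joined <- dplyr::inner_join(days, population[c("year", "labor_force")],
    by = "year"
  )
  if (any(joined$labor_force <= 0)) abort("labor force must be positive.")
  dplyr::transmute(joined,
    year = .data$year,
    labor_loss_ratio =
      .data$labor_days / annual_workdays / .data$labor_force * 1000
  )
}

#' Excess medical expenditure
#'
#' Hospital admissions are costed at the inpatient per-capita expense and
#' outpatient visits at the outpatient per-capita expense (2013 Beijing
#' levels by default); unattended cases generate no expenditure.
#'
#' @param cases Tibble from [annual_impacts()].
#' @param outpatient_cost,inpatient_cost Per-case costs (RMB).
#' @return Tibble `year, medical_expense` (million RMB).
#' @export
medical_expenses <- function(cases, outpatient_cost = 393.3,
                             inpatient_cost = 18495.9) {
  cases |>
    dplyr::mutate(cost = dplyr::case_when(
      .data$category == "inpatient" ~ .data$cases * inpatient_cost,
      .data$category == "outpatient" ~ .data$cases * outpatient_cost,
      .default = 0
    )) |>
    dplyr::summarise(medical_expense = sum(.data$cost) / 1e6, .by = "year")
}

#' Full health-impact ledger with confidence-interval propagation
#'
#' Runs the whole health accounting — attributable cases per outcome, labor
#' days lost, the labor-force loss ratio and excess medical expenditure — at
#' the central exposure-response coefficients and again with every
#' coefficient replaced by its lower/upper 95% bound simultaneously
#' (deterministic interval propagation; the function is monotone in each
#' coefficient, so the bounds bracket the central estimate everywhere).
#'
#' @inheritParams annual_impacts
#' @inheritParams labor_days_lost
#' @inheritParams medical_expenses
#' @return An `impact_ledger` with
#'   * `cases` — `year, outcome, category, cases, cases_low, cases_high`,
#'   * `summary` — per-year labor days, loss ratio (per mille) and medical
#'     expense (million RMB) with `_low`/`_high` companions,
#'   * `totals` — list of headline aggregates (deaths and disease cases over
#'     the whole window, each with CI).
#' @examples
#' \donttest{
#' conc <- beijing_concentration()
#' led <- health_impact(conc, beijing_population(2017), beijing_health_outcomes())
#' led$summary
#' }
#' @export
health_impact <- function(conc, population, outcomes, visit_share = 0.727,
                          labor_death_share = 0.2244, annual_workdays = 250,
                          outpatient_cost = 393.3, inpatient_cost = 18495.9,
                          baseline_conc = 0) {
  one <- function(beta_col) {
    cases <- annual_impacts(conc, population, outcomes,
      visit_share = visit_share, beta_col = beta_col,
      baseline_conc = baseline_conc
    )
    days <- labor_days_lost(cases, outcomes,
      labor_death_share = labor_death_share,
      annual_workdays = annual_workdays
    )
    list(
      cases = cases,
      summary = days |>
        dplyr::left_join(labor_loss_ratio(days, population, annual_workdays),
          by = "year"
        ) |>
        dplyr::left_join(
          medical_expenses(cases, outpatient_cost, inpatient_cost),
          by = "year"
        )
    )
  }
  central <- one("beta")
  low <- one("beta_low")
  high <- one("beta_high")
  cases <- central$cases |>
    dplyr::mutate(
      cases_low = low$cases$cases,
      cases_high = high$cases$cases
    )
  summary <- central$summary |>
    dplyr::left_join(
      dplyr::rename_with(low$summary, \(x) paste0(x, "_low"), -"year"),
      by = "year"
    ) |>
    dplyr::left_join(
      dplyr::rename_with(high$summary, \(x) paste0(x, "_high"), -"year"),
      by = "year"
    )
  tot <- function(tb, cat, col = "cases") {
    sum(tb[[col]][tb$category %in% cat])
  }
  morb <- c("inpatient", "outpatient", "unattended")
  structure(
    list(
      cases = cases, summary = summary,
      totals = list(
        deaths = tot(cases, "mortality"),
        deaths_low = tot(cases, "mortality", "cases_low"),
        deaths_high = tot(cases, "mortality", "cases_high"),
        disease_cases = tot(cases, morb),
        disease_cases_low = tot(cases, morb, "cases_low"),
        disease_cases_high = tot(cases, morb, "cases_high")
      )
    ),
    class = "impact_ledger"
  )
}

#' @export
print.impact_ledger <- function(x, ...) {
  cat("Health-impact ledger,", min(x$summary$year), "-", max(x$summary$year), "\n")
  cat(sprintf(
    "  premature deaths: %.0f (%.0f-%.0f)\n  disease cases:    %.0f (%.0f-%.0f)\n",
    x$totals$deaths, x$totals$deaths_low, x$totals$deaths_high,
    x$totals$disease_cases, x$totals$disease_cases_low, x$totals$disease_cases_high
  ))
  print(as.data.frame(dplyr::mutate(
    x$summary[c("year", "labor_days", "labor_loss_ratio", "medical_expense")],
    labor_days = round(.data$labor_days),
    labor_loss_ratio = round(.data$labor_loss_ratio, 2),
    medical_expense = round(.data$medical_expense, 2)
  )), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.impact_ledger <- function(x, ...) x$cases

#' @export
glance.impact_ledger <- function(x, ...) as_tibble(x$totals)

#' Plot a health-impact ledger
#'
#' Annual lost working days with the 95% interval band.
#'
#' @param object An `impact_ledger`.
#' @param ... Unused.
#' @export
autoplot.impact_ledger <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$year, .data$labor_days / 1e4)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$labor_days_low / 1e4, ymax = .data$labor_days_high / 1e4),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "lost working time (10,000 person-days)") +
    ggplot2::theme_minimal()
}
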