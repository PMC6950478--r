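#' Calibrate a CGE model from a social accounting matrix
#'
#' Builds a single-region, closed-economy computable general equilibrium
#' model of `M` sectors from a balanced SAM. Each activity produces one
#' commodity with a CES aggregate of value-added and intermediate input;
#' value-added is a Cobb-Douglas composite of labor and capital; households
#' earn all factor income, pay a flat income tax and save at a fixed marginal
#' rate; government income is value-added tax plus income tax and is spent
#' proportionally (the neoclassical closure: government consumption moves
#' with revenue); investment is savings-driven; factor supplies are exogenous
#' and fully employed.
#'
#' Share, efficiency and tax parameters are chosen so that the benchmark
#' equilibrium — all prices 1, quantities read off the SAM — satisfies every
#' model equation exactly; solving the calibrated model with no shock
#' reproduces the SAM.
#'
#' Account naming: factor/institution accounts must be `labor`, `capital`,
#' `household`, `government`, `saving_investment`. A one-sector SAM uses
#' `commodity` and `activity`; a multi-sector SAM uses `commodity_<s>` /
#' `activity_<s>` pairs.
#'
#' @param x A [sam()]; rebalanced automatically if off by more than `1e-8`.
#' @param rho CES substitution parameter per sector (`rho < 1`, `rho != 0`;
#'   substitution elasticity `1 / (1 - rho)`). Default 0.5. Recycled.
#' @return A `cge_model`: per-sector parameter tibble, benchmark quantities,
#'   expenditure shares and tax/saving rates.
#' @examples
#' calibrate_cge(beijing_sam())
#' @export
calibrate_cge <- function(x, rho = 0.5) {
  if (!inherits(x, "sam")) x <- sam(x)
  if (!is_balanced(x)) x <- rebalance_sam(x)
  acc <- rownames(x)
  fixed <- c("labor", "capital", "household", "government", "saving_investment")
  if (!all(fixed %in% acc)) {
    abort(paste0("SAM must contain accounts ", paste(fixed, collapse = ", "), "."))
  }
  com <- grep("^commodity(_|$)", acc, value = TRUE)
  act <- grep("^activity(_|$)", acc, value = TRUE)
  if (length(com) == 0 || length(com) != length(act)) {
    abort("SAM needs matching commodity*/activity* account pairs.")
  }
  sectors <- sub("^commodity_?", "", com)
  sectors[sectors == ""] <- "aggregate"
  M <- length(sectors)
  if (!identical(sub("^activity_?", "", act)[sectors != "aggregate"],
    sectors[sectors != "aggregate"]
  )) {
    abort("commodity and activity accounts must list the same sectors.")
  }
  rho <- rep_len(rho, M)
  if (any(rho >= 1) || any(rho == 0)) abort("`rho` must be < 1 and nonzero.")

  S <- unclass(x)
  qinta0 <- colSums(S[com, act, drop = FALSE])
  if (any(qinta0 <= 0)) abort("every activity needs intermediate input flow.")
  ico <- sweep(S[com, act, drop = FALSE], 2, qinta0, `/`)
  qld0 <- S["labor", act]
  qkd0 <- S["capital", act]
  if (any(qld0 <= 0) || any(qkd0 <= 0)) {
    abort("every activity needs positive labor and capital payments.")
  }
  vat0 <- S["government", act]
  tv <- vat0 / (qld0 + qkd0)
  qva0 <- qld0 + qkd0 + vat0
  qa0 <- qva0 + qinta0
  eta <- qld0 / (qld0 + qkd0)
  alpha_va <- qva0 / (qld0^eta * qkd0^(1 - eta))
  z <- (qva0 / qinta0)^(1 - rho)
  delta_q <- z / (1 + z)
  alpha_q <- qa0 / (delta_q * qva0^rho + (1 - delta_q) * qinta0^rho)^(1 / rho)

  qls0 <- S["household", "labor"]
  qks0 <- S["household", "capital"]
  yh0 <- qls0 + qks0
  ti <- S["government", "household"] / yh0
  mps <- S["saving_investment", "household"] / (yh0 * (1 - ti))
  yg0 <- sum(vat0) + S["government", "household"]
  gov_save_share <- S["saving_investment", "government"] / yg0
  norm_share <- function(v) if (sum(v) > 0) v / sum(v) else rep(0, length(v))
  structure(
    list(
      sectors = sectors,
      params = tibble(
        sector = sectors, alpha_q = alpha_q, delta_q = delta_q, rho = rho,
        alpha_va = unname(alpha_va), eta = unname(eta), tv = unname(tv)
      ),
      ico = ico,
      hh_share = norm_share(S[com, "household"]),
      gov_share = norm_share(S[com, "government"]),
      inv_share = norm_share(S[com, "saving_investment"]),
      ti = unname(ti), mps = unname(mps),
      gov_save_share = unname(gov_save_share),
      qls0 = unname(qls0), qks0 = unname(qks0),
      benchmark = tibble(
        sector = sectors, qa = unname(qa0), qva = unname(qva0),
        qinta = unname(qinta0), qld = unname(qld0), qkd = unname(qkd0)
      ),
      sam = x
    ),
    class = "cge_model"
  )
}

#' @export
print.cge_model <- function(x, ...) {
  cat(
    "CGE model:", length(x$sectors), "sector(s);",
    sprintf(
      "ti = %.4f, mps = %.4f, QLS = %.0f, QKS = %.0f\n",
      x$ti, x$mps, x$qls0, x$qks0
    )
  )
  print(as.data.frame(x$params), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Translate a health shock into the model's exogenous set
#'
#' The two conducting variables enter the economy as (i) a proportional cut
#' of the labor supply — the per-mille labor-loss ratio — and (ii) a
#' committed household purchase of the health-services commodity equal to
#' the excess medical expenditure, valued at benchmark prices, which crowds
#' out discretionary consumption.
#'
#' @param model A `cge_model`.
#' @param labor_loss_ratio Labor loss (per mille of labor supply).
#' @param medical_expense Committed health expenditure in SAM units
#'   (hundred-million RMB).
#' @param health_sector Sector receiving the committed purchase; defaults to
#'   a sector named `health_services`, else the single sector of a one-sector
#'   model.
#' @param qls,qks Pre-shock factor supplies (default: benchmark).
#' @return List with `qls` (post-shock labor supply), `qks`, and `committed`
#'   (per-commodity committed expenditure vector).
#' @export
apply_shock <- function(model, labor_loss_ratio = 0, medical_expense = 0,
                        health_sector = NULL, qls = model$qls0,
                        qks = model$qks0) {
  if (labor_loss_ratio < 0 || labor_loss_ratio >= 1000) {
    abort("`labor_loss_ratio` must lie in [0, 1000) per mille.")
  }
  if (medical_expense < 0) abort("`medical_expense` must be nonnegative.")
  M <- length(model$sectors)
  committed <- rep(0, M)
  if (medical_expense > 0) {
    health_sector <- health_sector %||%
      (if ("health_services" %in% model$sectors) "health_services" else
        if (M == 1) model$sectors else
          abort("specify `health_sector` for a multi-sector model."))
    hi <- match(health_sector, model$sectors)
    if (is.na(hi)) abort(paste0("no sector named '", health_sector, "'."))
    if (medical_expense >= model$benchmark$qa[hi]) {
      warn("committed medical expenditure reaches the sector's benchmark output; the shock is implausibly large.")
    }
    committed[hi] <- medical_expense
  }
  list(qls = qls * (1 - labor_loss_ratio / 1000), qks = qks, committed = committed)
}

#' Solve the general equilibrium
#'
#' Solves the calibrated system — zero profit in every activity, commodity
#' market clearing, and labor/capital market clearing — for prices and
#' activity levels by damped Newton iteration in log space, starting from the
#' benchmark. The labor wage is the numeraire; one commodity market is
#' dropped and its residual value (Walras' law) is reported as a solver
#' check.
#'
#' @param model A `cge_model`.
#' @param qls,qks Factor supplies (default benchmark levels).
#' @param labor_loss_ratio,medical_expense,health_sector Shock, passed to
#'   [apply_shock()]. `medical_expense` in SAM units, valued at numeraire
#'   prices.
#' @param tfp Total-factor-productivity multiplier applied to the CES
#'   efficiency parameters (used by the recursive dynamics).
#' @param numeraire Value at which the labor wage is fixed.
#' @param tol Solver tolerance on the scaled residual norm.
#' @param max_iter Newton iteration cap.
#' @return An `equilibrium`: per-sector tibble of prices/quantities, macro
#'   aggregates, the Walras residual and iteration count.
#' @examples
#' eq <- solve_equilibrium(calibrate_cge(beijing_sam()))
#' eq$macro$gdp
#' @export
solve_equilibrium <- function(model, qls = model$qls0, qks = model$qks0,
                              labor_loss_ratio = 0, medical_expense = 0,
                              health_sector = NULL, tfp = 1, numeraire = 1,
                              tol = 1e-10, max_iter = 200L) {
  shock <- apply_shock(model, labor_loss_ratio, medical_expense,
    health_sector = health_sector, qls = qls, qks = qks
  )
  p <- model$params
  M <- nrow(p)
  sigma <- 1 / (1 - p$rho)
  alpha_q <- p$alpha_q * tfp
  wl <- numeraire
  med <- shock$committed * numeraire # committed value at numeraire prices

  state <- function(x) {
    pa <- exp(x[1:M])
    wk <- exp(x[M + 1])
    qa <- exp(x[M + 1 + (1:M)])
    pinta <- as.numeric(crossprod(model$ico, pa))
    pva <- (1 + p$tv) / p$alpha_va *
      (wl / p$eta)^p$eta * (wk / (1 - p$eta))^(1 - p$eta)
    ratio <- ((p$delta_q / (1 - p$delta_q)) * (pinta / pva))^sigma
    qinta <- qa / (alpha_q * (p$delta_q * ratio^p$rho + (1 - p$delta_q))^(1 / p$rho))
    qva <- ratio * qinta
    qld <- p$eta * pva * qva / ((1 + p$tv) * wl)
    qkd <- (1 - p$eta) * pva * qva / ((1 + p$tv) * wk)
    yh <- wl * shock$qls + wk * shock$qks
    yg <- sum(p$tv * (wl * qld + wk * qkd)) + model$ti * yh
    disp <- (1 - model$ti) * yh - sum(med)
    if (disp <= 0) abort("committed medical expenditure exceeds disposable income.")
    sh <- model$mps * disp
    qh <- model$hh_share * (disp - sh) / pa + med / pa
    gov_cons <- (1 - model$gov_save_share) * yg
    qg <- model$gov_share * gov_cons / pa
    qinv <- model$inv_share * (sh + model$gov_save_share * yg) / pa
    demand <- as.numeric(model$ico %*% qinta) + qh + qg + qinv
    list(
      pa = pa, wk = wk, qa = qa, pinta = pinta, pva = pva, qinta = qinta,
      qva = qva, qld = qld, qkd = qkd, yh = yh, yg = yg, sh = sh, qh = qh,
      qg = qg, qinv = qinv, demand = demand, gov_cons = gov_cons
    )
  }
  resid <- function(x) {
    st <- state(x)
    r_zp <- log(st$pa * st$qa / (st$pva * st$qva + st$pinta * st$qinta))
    r_mc <- if (M > 1) log(st$demand[-M] / st$qa[-M]) else numeric(0)
    c(r_zp, r_mc, log(sum(st$qld) / shock$qls), log(sum(st$qkd) / shock$qks))
  }
  # start at the benchmark, rescaled by aggregate factor growth so far-out
  # years begin near the solution
  gl <- shock$qls / model$qls0
  gk <- shock$qks / model$qks0
  eta_bar <- sum(model$benchmark$qld) /
    (sum(model$benchmark$qld) + sum(model$benchmark$qkd))
  x0 <- log(c(
    rep(numeraire, M), numeraire * gl / gk,
    model$benchmark$qa * tfp * gl^eta_bar * gk^(1 - eta_bar)
  ))
  sol <- newton_solve(resid, x0, tol = tol, max_iter = max_iter)
  st <- state(sol$x)
  # relative imbalance of the dropped commodity market (Walras' law check)
  walras <- (st$demand[M] - st$qa[M]) / st$qa[M]
  structure(
    list(
      sectors = tibble(
        sector = model$sectors, pa = st$pa, pva = st$pva, pinta = st$pinta,
        qa = st$qa, qva = st$qva, qinta = st$qinta, qld = st$qld,
        qkd = st$qkd, qh = st$qh, qg = st$qg, qinv = st$qinv
      ),
      macro = list(
        wl = wl, wk = st$wk, yh = st$yh, yg = st$yg,
        qls = shock$qls, qks = shock$qks,
        gdp = sum(st$qva), # value added at benchmark prices
        household_consumption = sum(st$pa * st$qh),
        government_consumption = st$gov_cons,
        investment = st$sh + model$gov_save_share * st$yg
      ),
      walras = walras, iterations = sol$iterations
    ),
    class = "equilibrium"
  )
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf(
    "Equilibrium (%d iterations, Walras residual %.2e)\n",
    x$iterations, x$walras
  ))
  cat(sprintf(
    "  WK = %.4f  YH = %.1f  YG = %.1f  GDP = %.1f\n",
    x$macro$wk, x$macro$yh, x$macro$yg, x$macro$gdp
  ))
  print(as.data.frame(x$sectors), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.equilibrium <- function(x, ...) x$sectors

#' @export
glance.equilibrium <- function(x, ...) {
  dplyr::bind_cols(as_tibble(x$macro), tibble(
    walras = x$walras,
    iterations = x$iterations
  ))
}

#' Recursive-dynamics growth parameters
#'
#' Between periods the labor supply grows at `gL`, the capital stock at `gK`
#' and total factor productivity (the CES efficiency parameters) at `gtfp`.
#' Defaults are the Beijing study settings: 2.46%, 13% and 2% per year.
#'
#' @param gL,gK,gtfp Annual growth rates (must exceed -1).
#' @export
dynamic_params <- function(gL = 0.0246, gK = 0.13, gtfp = 0.02) {
  if (any(c(gL, gK, gtfp) <= -1)) abort("growth rates must exceed -1.")
  list(gL = gL, gK = gK, gtfp = gtfp)
}

#' Recursive dynamic simulation under a shock path
#'
#' For each year the factor supplies and TFP are compounded forward from the
#' base year, a no-shock baseline equilibrium and a shocked equilibrium are
#' solved, and the differences in the macro aggregates and sector outputs are
#' reported in million RMB (the SAM is kept in hundred-million RMB
#' internally).
#'
#' @param model A `cge_model` calibrated to the base year.
#' @param shocks Tibble `year, labor_loss_ratio` (per mille),
#'   `medical_expense` (million RMB); the first row is the base year.
#' @param dynamics A [dynamic_params()] list.
#' @param health_sector Passed to [apply_shock()].
#' @param currency_scale Million RMB per SAM flow unit (100 for a
#'   hundred-million RMB SAM).
#' @return A `cge_path`: tidy tibble `year, variable, baseline, shocked,
#'   delta` (monetary rows in million RMB) plus a solver log.
#' @export
recursive_simulate <- function(model, shocks, dynamics = dynamic_params(),
                               health_sector = NULL, currency_scale = 100) {
  if (!all(c("year", "labor_loss_ratio", "medical_expense") %in% names(shocks))) {
    abort("`shocks` needs year, labor_loss_ratio, medical_expense columns.")
  }
  shocks <- dplyr::arrange(shocks, .data$year)
  base_year <- shocks$year[1]
  rows <- list()
  log <- list()
  for (i in seq_len(nrow(shocks))) {
    yr <- shocks$year[i]
    t <- yr - base_year
    qls_t <- model$qls0 * (1 + dynamics$gL)^t
    qks_t <- model$qks0 * (1 + dynamics$gK)^t
    tfp_t <- (1 + dynamics$gtfp)^t
    baseline <- solve_equilibrium(model,
      qls = qls_t, qks = qks_t, tfp = tfp_t
    )
    shocked <- solve_equilibrium(model,
      qls = qls_t, qks = qks_t, tfp = tfp_t,
      labor_loss_ratio = shocks$labor_loss_ratio[i],
      medical_expense = shocks$medical_expense[i] / currency_scale,
      health_sector = health_sector
    )
    macro <- c(
      residents_income = "yh", government_revenue = "yg",
      residents_consumption = "household_consumption",
      government_consumption = "government_consumption",
      gdp = "gdp"
    )
    rows[[i]] <- dplyr::bind_rows(
      tibble(
        year = yr, variable = names(macro),
        baseline = unlist(baseline$macro[macro]) * currency_scale,
        shocked = unlist(shocked$macro[macro]) * currency_scale
      ),
      tibble(
        year = yr,
        variable = paste0("output_", model$sectors),
        baseline = baseline$sectors$qa * currency_scale,
        shocked = shocked$sectors$qa * currency_scale
      )
    )
    log[[i]] <- tibble(
      year = yr,
      baseline_iterations = baseline$iterations,
      shocked_iterations = shocked$iterations,
      baseline_walras = baseline$walras, shocked_walras = shocked$walras
    )
  }
  structure(
    list(
      results = dplyr::bind_rows(rows) |>
        dplyr::mutate(delta = .data$shocked - .data$baseline),
      log = dplyr::bind_rows(log)
    ),
    class = "cge_path"
  )
}

#' @export
print.cge_path <- function(x, ...) {
  cat("Recursive CGE simulation\n")
  wide <- x$results |>
    dplyr::filter(!startsWith(.data$variable, "output_")) |>
    dplyr::select("year", "variable", "delta") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "delta")
  print(as.data.frame(dplyr::mutate(
    wide,
    dplyr::across(-"year", \(v) round(v, 2))
  )), row.names = FALSE)
  cat("(deltas, million RMB)\n")
  invisible(x)
}

#' @export
tidy.cge_path <- function(x, ...) x$results

#' Plot a recursive CGE simulation
#'
#' Sector output deltas per year, the qualitative fingerprint of the shock.
#'
#' @param object A `cge_path`.
#' @param ... Unused.
#' @export
autoplot.cge_path <- function(object, ...) {
  df <- object$results |>
    dplyr::filter(startsWith(.data$variable, "output_")) |>
    dplyr::mutate(sector = sub("^output_", "", .data$variable))
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$delta, colour = .data$sector)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "output change (million RMB)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Estimate production-function parameters from input-output time series
#'
#' Least-squares estimation of the two production blocks on yearly data. The
#' CES block uses the second-order (Kmenta) log approximation
#' `ln QA = u0 + u1 ln QVA + u2 ln QINTA + u3 [ln(QVA/QINTA)]^2 + e`, giving
#' `delta_q = u1`, `rho = 2 u3 / (u1 (1 - u1))` and `alpha_q = exp(u0)`; the
#' Cobb-Douglas block `ln QVA = v0 + v1 ln QLD + v2 ln QKD + e` gives
#' `eta = v1` and `alpha_va = exp(v0)`. Standard errors for derived
#' parameters follow by the delta method. When the curvature term `u3`
#' vanishes the technology is flagged as Cobb-Douglas degenerate
#' (`rho = 0`).
#'
#' The Kmenta form is an approximation: away from `rho = 0` the recovered
#' CES parameters carry approximation bias that grows with the spread of
#' `QVA/QINTA`.
#'
#' @param io_series Tibble with columns `qa, qva, qinta, qld, qkd`, one row
#'   per year, at least 8 rows, all positive.
#' @return A `production_params` tibble `term, estimate, std_error` for
#'   `alpha_q, delta_q, rho, alpha_va, eta`, with attribute `cd_degenerate`.
#' @export
estimate_production_params <- function(io_series) {
  need <- c("qa", "qva", "qinta", "qld", "qkd")
  if (!all(need %in% names(io_series))) {
    abort(paste0("`io_series` needs columns ", paste(need, collapse = ", "), "."))
  }
  if (nrow(io_series) < 8) abort("need at least 8 yearly observations.")
  if (any(as.matrix(io_series[need]) <= 0)) abort("all values must be positive.")
  d <- dplyr::mutate(io_series,
    l_qa = log(.data$qa), l_qva = log(.data$qva), l_qinta = log(.data$qinta),
    l_ratio2 = log(.data$qva / .data$qinta)^2,
    l_qld = log(.data$qld), l_qkd = log(.data$qkd)
  )
  ces <- lm(l_qa ~ l_qva + l_qinta + l_ratio2, data = d)
  cd <- lm(l_qva ~ l_qld + l_qkd, data = d)
  if (any(is.na(coef(ces))) || any(is.na(coef(cd)))) {
    abort("collinear regressors; the series has no usable variation.")
  }
  u <- coef(ces)
  v <- coef(cd)
  # vcov emits a spurious warning on numerically perfect fits
  vc <- suppressWarnings(stats::vcov(ces))
  vcd <- suppressWarnings(stats::vcov(cd))
  u0 <- u[1]; u1 <- u[2]; u3 <- u[4]
  cd_degenerate <- abs(u3) < 1e-8
  rho <- if (cd_degenerate) 0 else 2 * u3 / (u1 * (1 - u1))
  # delta-method gradients of rho = 2 u3 / (u1 (1 - u1)) wrt (u1, u3)
  g_rho <- c(-2 * u3 * (1 - 2 * u1) / (u1 * (1 - u1))^2, 2 / (u1 * (1 - u1)))
  se_rho <- sqrt(drop(
    t(g_rho) %*% vc[c("l_qva", "l_ratio2"), c("l_qva", "l_ratio2")] %*% g_rho
  ))
  out <- tibble(
    term = c("alpha_q", "delta_q", "rho", "alpha_va", "eta"),
    estimate = unname(c(exp(u0), u1, rho, exp(v[1]), v[2])),
    std_error = unname(c(
      exp(u0) * sqrt(vc[1, 1]), sqrt(vc[2, 2]), se_rho,
      exp(v[1]) * sqrt(vcd[1, 1]), sqrt(vcd[2, 2])
    ))
  )
  structure(out,
    cd_degenerate = unname(cd_degenerate),
    class = c("production_params", class(out))
  )
}
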