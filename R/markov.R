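#' Residual state partition
#'
#' Splits the residual range into `r >= 2` ordered, contiguous intervals
#' `[l_i, u_i)`. Intervals are left-closed and right-open except the last,
#' which is closed at both ends. State 1 collects the strongest
#' over-estimation residuals, the last state the strongest under-estimation.
#'
#' @param bounds Numeric vector of `r + 1` increasing break points, or a
#'   string `"l1:u1,l2:u2,..."` with contiguous intervals.
#' @return A `state_partition`: tibble with columns `state`, `lower`, `upper`.
#' @examples
#' state_partition(c(-4, -2, 2, 4))
#' state_partition("-4:-2,-2:2,2:4")
#' @export
state_partition <- function(bounds) {
  if (is.character(bounds)) {
    parts <- strsplit(strsplit(bounds, ",")[[1]], ":")
    lo <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    hi <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    if (any(abs(lo[-1] - hi[-length(hi)]) > 1e-12)) {
      abort("state intervals must be contiguous.")
    }
    bounds <- c(lo, hi[length(hi)])
  }
  bounds <- as.numeric(bounds)
  if (length(bounds) < 3) abort("need at least 2 states (3 break points).")
  if (any(diff(bounds) <= 0)) abort("break points must be strictly increasing.")
  structure(
    tibble(
      state = seq_len(length(bounds) - 1L),
      lower = bounds[-length(bounds)],
      upper = bounds[-1]
    ),
    class = c("state_partition", "tbl_df", "tbl", "data.frame")
  )
}

n_states <- function(partition) nrow(partition)

#' Assign residuals to states
#'
#' Each residual is mapped to the interval containing it. Intervals are
#' left-closed, right-open, except the last which is closed; residuals falling
#' outside the partition range are clamped to the nearest (first or last)
#' state, so every value remains usable.
#'
#' @param residuals Annual-series tibble or numeric vector of residuals.
#' @param partition A [state_partition()].
#' @return Integer vector of state labels, one per residual.
#' @examples
#' p <- state_partition(c(-4, -2, 2, 4))
#' assign_states(c(0.0, -2.2, 2.4, 3.6, -3.6), p)
#' @export
assign_states <- function(residuals, partition) {
  r <- if (is.data.frame(residuals)) residuals$value else as.numeric(residuals)
  lo <- partition$lower
  hi <- partition$upper
  vapply(r, function(e) {
    if (e < lo[1]) return(1L)                       # clamp below
    if (e >= hi[length(hi)]) return(nrow(partition)) # clamp above / closed end
    max(which(e >= lo))
  }, integer(1))
}

#' Empirical one-step transition matrix
#'
#' Maximum-likelihood estimate: `p_ij` is the share of observed departures
#' from state `i` that land in state `j`. States never departed from (possible
#' on short or synthetic sequences) receive a uniform row, with a warning, so
#' the matrix stays row-stochastic.
#'
#' @param states Integer vector of consecutive state labels.
#' @param r Number of states.
#' @return A `markov_chain`: list with the `r x r` `transition` matrix and the
#'   observed `state_sequence`.
#' @examples
#' transition_matrix(c(2, 1, 3, 3, 1), r = 3)
#' @export
transition_matrix <- function(states, r) {
  states <- as.integer(states)
  if (length(states) < 2) abort("need at least two states to count transitions.")
  if (any(states < 1 | states > r)) abort("state labels outside 1..r.")
  counts <- matrix(0, r, r)
  for (i in seq_len(length(states) - 1L)) {
    counts[states[i], states[i + 1L]] <- counts[states[i], states[i + 1L]] + 1
  }
  dep <- rowSums(counts)
  P <- counts / ifelse(dep == 0, 1, dep)
  if (any(dep == 0)) {
    warn(paste0(
      "no observed departures from state(s) ",
      paste(which(dep == 0), collapse = ", "),
      "; defaulting those rows to uniform."
    ))
    P[dep == 0, ] <- 1 / r
  }
  structure(list(transition = P, state_sequence = states), class = "markov_chain")
}

#' @export
print.markov_chain <- function(x, ...) {
  cat("Markov residual chain,", nrow(x$transition), "states\n")
  print(round(x$transition, 4))
  invisible(x)
}

# k-step transition matrix.
k_step <- function(chain, k) {
  P <- chain$transition
  out <- diag(nrow(P))
  for (i in seq_len(k)) out <- out %*% P
  out
}

#' Whitening values of a state partition
#'
#' The representative correction `h_j = lambda_j * l_j + (1 - lambda_j) * u_j`
#' locates a point inside each state interval; `lambda_j = 0.5` (the
#' traditional choice) takes the midpoint, while the genetic-algorithm search
#' tunes each `lambda_j` over `[0, 1]`.
#'
#' @param partition A [state_partition()].
#' @param lambdas Numeric vector in `[0, 1]`, one per state.
#' @return Numeric vector `h` of per-state corrections.
#' @examples
#' whitening_values(state_partition(c(-4, -2, 2, 4)), c(0.5, 0.5, 0.5))
#' @export
whitening_values <- function(partition, lambdas) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) != nrow(partition)) {
    abort("need exactly one whitening coefficient per state.")
  }
  if (any(lambdas < 0 | lambdas > 1)) {
    abort("whitening coefficients must lie in [0, 1].")
  }
  lambdas * partition$lower + (1 - lambdas) * partition$upper
}

#' Markov-corrected series and forecast
#'
#' Corrects the GM(1,1) restored values with the residual-state chain. Years
#' 2..`origin` (whose residual state is taken as known) receive their own
#' state's whitening value `h`; years beyond the origin receive the
#' expectation of `h` under the k-step transition distribution started from
#' the origin year's state. The base year is never corrected (its residual is
#' zero by construction).
#'
#' @param model A `gm11` fit.
#' @param chain A `markov_chain` over the fit's residual states.
#' @param h Whitening values from [whitening_values()].
#' @param states Integer state labels of the in-sample residuals.
#' @param horizon Years to forecast beyond the fitted window (`>= 0`).
#' @param origin Index of the forecast-origin year within the fitted series;
#'   in-sample years after it are treated as pseudo-forecasts. Defaults to
#'   `n - 2`, holding the last two fitted years out.
#' @return Annual-series tibble with a `type` column (`"in_sample"` or
#'   `"forecast"`).
#' @export
markov_correct <- function(model, chain, h, states, horizon = 0L,
                           origin = NULL) {
  n <- nrow(model$fitted)
  origin <- origin %||% max(2L, n - 2L)
  if (horizon < 0) abort("`horizon` must be >= 0.")
  if (origin < 2 || origin > n) abort("`origin` must lie in 2..n.")
  if (length(states) != n) abort("need one state label per fitted year.")
  base <- predict(model, horizon = horizon)
  corrected <- base$value
  for (i in 2:origin) corrected[i] <- corrected[i] + h[states[i]]
  steps <- n + horizon - origin
  if (steps > 0) {
    P <- chain$transition
    Pk <- diag(nrow(P))
    for (k in seq_len(steps)) {
      Pk <- Pk %*% P
      corrected[origin + k] <- corrected[origin + k] +
        sum(Pk[states[origin], ] * h)
    }
  }
  tibble(
    year = base$year,
    value = corrected,
    type = rep(c("in_sample", "forecast"), c(n, horizon))
  )
}

#' Genetic-algorithm search for whitening coefficients
#'
#' Real-coded genetic algorithm over `[0, 1]^r` minimising the mean squared
#' error of the Markov-corrected in-sample series (the fitness function).
#' Defaults follow common practice for small continuous problems: population
#' 30, 300 generations, crossover rate 0.8, mutation rate 0.1, tournament
#' selection of size 2, arithmetic crossover, per-gene Gaussian mutation
#' (sd 0.1, clipped to the box) and elitism of one.
#'
#' @param series Annual series the GM(1,1) model was (or will be) fitted to.
#' @param partition Residual [state_partition()].
#' @param ga_params List from [ga_control()].
#' @param seed Integer RNG seed; the search is reproducible given the seed.
#' @param origin Forecast origin passed to [markov_correct()].
#' @param model Optional pre-computed `gm11` fit of `series`.
#' @return A `ga_fit`: list with `lambdas`, `mse`, `convergence_generation`
#'   (first generation attaining the final best fitness) and the best-fitness
#'   `history`.
#' @export
ga_optimize <- function(series, partition, ga_params = ga_control(),
                        seed = 1L, origin = NULL, model = NULL) {
  s <- as_annual_series(series)
  model <- model %||% fit_gm11(s)
  res <- residuals(model)
  states <- assign_states(res, partition)
  chain <- transition_matrix(states, n_states(partition))
  n <- nrow(s)
  origin <- origin %||% max(2L, n - 2L)
  r <- n_states(partition)
  # the corrected series is linear in h: corrected = fitted + A h, with A
  # holding the per-year state indicators / k-step transition rows
  A <- matrix(0, n, r)
  for (i in 2:origin) A[i, states[i]] <- 1
  Pk <- diag(r)
  for (k in seq_len(n - origin)) {
    Pk <- Pk %*% chain$transition
    A[origin + k, ] <- Pk[states[origin], ]
  }
  target <- s$value - model$fitted$value
  fitness <- function(lambda) {
    h <- lambda * partition$lower + (1 - lambda) * partition$upper
    mean((target - A %*% h)^2)
  }
  p <- ga_params
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pop <- matrix(runif(p$pop_size * r), p$pop_size, r)
  pop[1, ] <- 0.5                       # seed the traditional midpoint choice
  fit <- apply(pop, 1, fitness)
  history <- numeric(p$generations)
  for (gen in seq_len(p$generations)) {
    elite_i <- which.min(fit)
    pick <- function() {                # tournament of size 2
      cand <- sample.int(p$pop_size, 2)
      cand[which.min(fit[cand])]
    }
    new_pop <- matrix(0, p$pop_size, r)
    new_pop[1, ] <- pop[elite_i, ]
    for (i in 2:p$pop_size) {
      a <- pop[pick(), ]
      b <- pop[pick(), ]
      child <- if (runif(1) < p$crossover_rate) {
        w <- runif(1)
        w * a + (1 - w) * b             # arithmetic crossover
      } else a
      mut <- runif(r) < p$mutation_rate
      child[mut] <- pmin(1, pmax(0, child[mut] + rnorm(sum(mut), 0, 0.1)))
      new_pop[i, ] <- child
    }
    pop <- new_pop
    fit <- apply(pop, 1, fitness)
    history[gen] <- min(fit)
  }
  best <- which.min(fit)
  best_mse <- fit[best]
  structure(
    list(
      lambdas = pop[best, ],
      mse = best_mse,
      convergence_generation = which(history <= best_mse + 1e-12)[1],
      history = history
    ),
    class = "ga_fit"
  )
}

#' @rdname ga_optimize
#' @param pop_size,generations,crossover_rate,mutation_rate GA settings.
#' @export
ga_control <- function(pop_size = 30L, generations = 300L,
                       crossover_rate = 0.8, mutation_rate = 0.1) {
  list(
    pop_size = as.integer(pop_size), generations = as.integer(generations),
    crossover_rate = crossover_rate, mutation_rate = mutation_rate
  )
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf(
    "GA whitening search: lambda = (%s), MSE = %.4f (generation %d)\n",
    paste(sprintf("%.3f", x$lambdas), collapse = ", "),
    x$mse, x$convergence_generation
  ))
  invisible(x)
}
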