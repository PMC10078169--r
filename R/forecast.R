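#' Simulate future climate paths
#'
#' Gaussian random walk with drift around the fitted long-term trend:
#' `w_{t+1} ~ Normal(w_t + slope, slope_se)`, iterated from the last
#' observed value.  Both the drift and its uncertainty come from the
#' [fit_weighted_trend()] estimate, so parameter uncertainty in the climate
#' trend propagates into the forecasts.
#'
#' @param trend A `climate_trend` (or any list with `slope` and `slope_se`).
#' @param w_last Last observed value (raw units), one per path or length 1.
#' @param horizon Number of future years (>= 1).
#' @param n_paths Number of independent paths.
#' @param seed Optional seed.
#' @return Matrix `n_paths x horizon` of future values.
#' @export
simulate_future_climate <- function(trend, w_last, horizon, n_paths = 1,
                                    seed = NULL) {
  stopifnot(horizon >= 1, n_paths >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- rep_len(w_last, n_paths)
  out <- matrix(NA_real_, n_paths, horizon)
  for (j in seq_len(horizon)) {
    w <- rnorm(n_paths, w + trend$slope, trend$slope_se)
    out[, j] <- w
  }
  out
}

#' Forecast abundance and local extinction risk
#'
#' For every posterior draw, initializes the population from that draw's
#' SY/ASY abundances in the last data year and simulates demographic
#' stochasticity forward to the horizon year: age-specific survival,
#' density-dependent recruitment, and entry of new individuals from a fresh
#' augmented pool of `M_future` candidates with
#' `Pr(entry in t) = (n1 + n2)_{t-1} * gamma_{t-1} / M_future`.  New
#' entrants are SY in their entry year and ASY afterwards; survivors age to
#' ASY.  Climate variants draw one future covariate path per posterior draw
#' ([simulate_future_climate()]); the time variant extends the scaled year
#' index and is independent of any climate input.
#'
#' @param samples A `js_posterior` from [run_mcmc()].
#' @param data The [encounter_data()] the model was fitted to.
#' @param trend The [trend_spec()] used in the fit.
#' @param climate_trend A `climate_trend` (required for climate variants):
#'   long-term trend of the covariate in raw units per year.
#' @param horizon Calendar year to forecast through (e.g. 2040).
#' @param M_future Augmentation bound for future entrants (2,400 by
#'   default).
#' @param seed Seed for the forecast simulation.
#' @return An object of class `js_forecast`: abundance trajectories
#'   (draws x years, first column = last data year), future covariate paths,
#'   extinction indicators, and metadata.
#' @export
forecast_population <- function(samples, data, trend = samples$trend,
                                climate_trend = NULL, horizon = 2040,
                                M_future = 2400, seed = 1) {
  stopifnot(inherits(samples, "js_posterior"))
  last_year <- max(samples$years)
  if (horizon < last_year) stop("horizon precedes the last data year")
  n_future <- horizon - last_year
  m <- posterior_matrix(samples)
  T <- samples$T
  ndraw <- nrow(m)
  n1 <- m[, sprintf("n1[%d]", T)]
  n2 <- m[, sprintf("n2[%d]", T)]

  Nmat <- matrix(NA_real_, ndraw, n_future + 1L)
  Nmat[, 1L] <- n1 + n2
  if (n_future == 0L) {
    return(structure(list(N = Nmat, years = last_year,
                          w_future = NULL,
                          extinct = Nmat[, 1L] == 0,
                          M_future = M_future, area = samples$area),
                     class = "js_forecast"))
  }
  set.seed(seed)

  ## future covariate values on the model's scaled scale, one path per draw
  if (trend$variant == "time") {
    w_fut <- matrix(rep(scale_future_years(T, n_future), each = ndraw),
                    ndraw, n_future)
    w_raw <- NULL
  } else {
    if (is.null(climate_trend))
      stop("climate variants require a fitted climate trend")
    wT <- m[, sprintf("w[%d]", T)]
    w_last_raw <- wT * samples$scaling$scale + samples$scaling$center
    w_raw <- simulate_future_climate(climate_trend, w_last_raw, n_future,
                                     n_paths = ndraw)
    w_fut <- (w_raw - samples$scaling$center) / samples$scaling$scale
  }
  ## trailing covariate value at the last data year (drives the first
  ## forecast transition)
  w_now <- if (trend$variant == "time") rep(scale_years(T)[T], ndraw)
           else m[, sprintf("w[%d]", T)]

  period_of_year <- function(yr) {
    if (is.null(trend$changepoint)) 1L else 1L + (yr >= trend$changepoint)
  }

  pars <- list(alpha = m[, "alpha"], b0_gam = m[, "b0_gam"],
               b2_gam = m[, "b2_gam"],
               b0_phi_sy = m[, "b0_phi_sy"], b0_phi_asy = m[, "b0_phi_asy"])
  b1g <- function(per) {
    if (is.null(trend$changepoint)) m[, "b1_gam"]
    else if (per == 1L) m[, "b1_gam_pre"] else m[, "b1_gam_post"]
  }
  b1p <- function(per) {
    if (is.null(trend$changepoint)) m[, "b1_phi"]
    else if (per == 1L) m[, "b1_phi_pre"] else m[, "b1_phi_post"]
  }

  R_pool <- rep.int(M_future, ndraw)
  cum_pi <- rep(0, ndraw)
  w_prev <- w_now
  for (j in seq_len(n_future)) {
    yr_prev <- last_year + j - 1L
    per <- period_of_year(yr_prev)
    Nprev <- n1 + n2
    ED <- Nprev / samples$area
    eta <- pars$b0_gam + b1g(per) * w_prev -
      pars$b2_gam * ED^samples$dd_power
    gam <- pars$alpha * plogis(eta)
    pi_t <- Nprev * gam / M_future
    rem <- 1 - cum_pi
    if (any(pi_t > rem + 1e-9))
      stop("future augmentation bound exhausted; increase M_future")
    haz <- ifelse(rem > 0, pmin(pi_t / rem, 1), 0)
    entrants <- rbinom(ndraw, R_pool, haz)
    R_pool <- R_pool - entrants
    cum_pi <- cum_pi + pi_t

    phi_sy <- plogis(pars$b0_phi_sy + b1p(per) * w_prev)
    phi_asy <- plogis(pars$b0_phi_asy + b1p(per) * w_prev)
    surv <- rbinom(ndraw, n1, phi_sy) + rbinom(ndraw, n2, phi_asy)
    n1 <- entrants
    n2 <- surv
    Nmat[, j + 1L] <- n1 + n2
    w_prev <- w_fut[, j]
  }

  structure(list(N = Nmat, years = seq(last_year, horizon),
                 w_future = if (trend$variant == "time") NULL else w_raw,
                 extinct = Nmat[, n_future + 1L] == 0,
                 M_future = M_future, area = samples$area,
                 variant = trend$variant),
            class = "js_forecast")
}

#' Local extinction risk
#'
#' Percentage of forecast trajectories whose abundance is zero in the
#' horizon year.
#'
#' @param result A `js_forecast`.
#' @return Extinction risk in percent (0-100).
#' @export
extinction_risk <- function(result) {
  stopifnot(inherits(result, "js_forecast"), length(result$extinct) > 0)
  100 * mean(result$extinct)
}

#' @export
print.js_forecast <- function(x, ...) {
  cat("Population forecast:", min(x$years), "-", max(x$years), "\n")
  cat("  draws:", nrow(x$N), "; M_future:", x$M_future, "\n")
  cat(sprintf("  extinction risk at %d: %.1f%%\n", max(x$years),
              extinction_risk(x)))
  invisible(x)
}

#' Forecast summary table
#'
#' @param result A `js_forecast`.
#' @return Data frame `year, median_density, lower, upper` (females/ha).
#' @export
forecast_summary <- function(result) {
  dens <- result$N / result$area
  qs <- t(apply(dens, 2L, quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  data.frame(year = result$years, median_density = qs[, 2],
             lower = qs[, 1], upper = qs[, 3])
}
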