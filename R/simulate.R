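#' Configuration of the synthetic-data generator
#'
#' Defines one simulated study: years and plot geometry, the true
#' demographic/observation parameters, and the climate scenario from which
#' station series are generated.  Defaults emulate a long-term warbler
#' demography study at a warm-margin mid-elevation plot: 18 breeding seasons
#' on an 18-ha plot with roughly a dozen breeding females, elevation-graded
#' early-breeding temperature warming by 0.07 degC/yr, and annual
#' precipitation with no trend.
#'
#' @param T Number of study years.
#' @param M Augmentation bound for the simulated superpopulation.
#' @param area Plot area (ha).
#' @param EN1 Expected number of females alive in the first year; the
#'   first-year entry probability is `EN1 / M`.
#' @param params True [model_params()] (the generator overrides `pi1` with
#'   `EN1 / M`).  Coefficients are on the centered/scaled covariate scale.
#' @param years Calendar years (length `T`).
#' @param plot_elevation Elevation (m) of the study plot.
#' @param n_stations_temp,n_stations_precip Number of climate stations per
#'   variable, spread across `station_span` m around the plot elevation.
#' @param station_span Half-width (m) of the station elevation band.
#' @param climate Named list of climate-scenario constants: reference value,
#'   per-year trend, per-meter elevation slope, station noise SD, shared
#'   interannual shock SD, and (temperature only) the within-season SD
#'   attached to each station mean (`value_sd`).
#' @param single_day_years Calendar years surveyed on a single day.
#' @param seed Integer seed; identical configurations and seeds yield
#'   identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(T = 18, M = 600, area = 18, EN1 = 12,
                       params = model_params(
                         alpha = 1.5, b0_gam = -0.5, b1_gam = -0.3,
                         b2_gam = 0.5, b0_phi_sy = qlogis(0.40),
                         b0_phi_asy = qlogis(0.55), b1_phi = -0.35,
                         b0_cap = qlogis(0.85), b1_cap = 0,
                         k = 0.7, tau = 0.5, p_eta = 0.9, p_r = 0.61),
                       years = seq(2002, length.out = T),
                       plot_elevation = 1200,
                       n_stations_temp = 3, n_stations_precip = 6,
                       station_span = 150,
                       climate = list(
                         temp_ref = 16.14, temp_year_slope = 0.07,
                         temp_elev_slope = -0.006, temp_noise_sd = 0.35,
                         temp_shock_sd = 0.5, temp_value_sd = 2.0,
                         precip_ref = 2283, precip_year_slope = 0,
                         precip_elev_slope = 0.62, precip_noise_sd = 180,
                         precip_shock_sd = 300),
                       single_day_years = integer(), seed = 1L) {
  stopifnot(T >= 2, M >= 2, area > 0, EN1 > 0, EN1 < M,
            length(years) == T)
  params$pi1 <- EN1 / M
  structure(list(T = T, M = M, area = area, EN1 = EN1, params = params,
                 years = as.integer(years), plot_elevation = plot_elevation,
                 n_stations_temp = n_stations_temp,
                 n_stations_precip = n_stations_precip,
                 station_span = station_span, climate = climate,
                 single_day_years = as.integer(single_day_years),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate climate-station series
#'
#' Station values follow a linear trend surface in year and elevation with a
#' shared interannual shock and independent per-station noise:
#' `value = ref + year_slope * (year - years[1]) + elev_slope *
#' (elevation - plot_elevation) + shock_year + Normal(0, noise_sd)`.
#' Temperature records carry a `value_sd` column (within-season SD of the
#' daily means); precipitation records do not.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns
#'   `station_id, elevation_m, year, variable, value, value_sd`.
#' @export
simulate_climate <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cl <- config$climate
  out <- list()
  truth <- list(years = config$years)
  for (vb in c("early_breeding_temperature", "annual_precipitation")) {
    pre <- if (vb == "early_breeding_temperature") "temp" else "precip"
    n_st <- if (pre == "temp") config$n_stations_temp
            else config$n_stations_precip
    if (n_st < 2) stop("need at least 2 stations per variable")
    elevs <- round(seq(config$plot_elevation - config$station_span,
                       config$plot_elevation + config$station_span,
                       length.out = n_st))
    shocks <- rnorm(config$T, 0, cl[[paste0(pre, "_shock_sd")]])
    plot_true <- cl[[paste0(pre, "_ref")]] +
      cl[[paste0(pre, "_year_slope")]] * (config$years - config$years[1]) +
      shocks
    truth[[vb]] <- plot_true
    for (s in seq_len(n_st)) {
      mu <- plot_true +
        cl[[paste0(pre, "_elev_slope")]] * (elevs[s] - config$plot_elevation)
      val <- mu + rnorm(config$T, 0, cl[[paste0(pre, "_noise_sd")]])
      out[[length(out) + 1L]] <- data.frame(
        station_id = sprintf("%s%02d", substr(pre, 1, 1), s),
        elevation_m = elevs[s], year = config$years, variable = vb,
        value = val,
        value_sd = if (pre == "temp") cl$temp_value_sd else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "true_plot_values") <- truth
  res
}

sy_age_at <- function(b, a1, t) {
  ## TRUE when the individual is SY in year t (alive assumed)
  if (t == 1) b == 1 & a1 == 0L else b == t
}

#' Simulate the latent demographic truth
#'
#' Draws entry years, first-year ages, and survival trajectories from the
#' data-augmented Jolly-Seber process: sequential entry with probability
#' `pi_t = N_{t-1} * gamma_{t-1} / M` (realized-abundance convention),
#' density-dependent recruitment, and age-specific survival.
#'
#' @param config A [sim_config()].
#' @param covariate Covariate value per year on the model (centered/scaled)
#'   scale; defaults to the scaled year index (the "time" variant).
#' @param period Optional changepoint period per year.
#' @return An object of class `js_truth`: entry years `b`, first-year ages
#'   `a1`, alive states `z`, age matrix `a`, yearly abundances `N`, `n1`,
#'   `n2`, realized recruitment rates `gamma`, and the covariate used.
#' @export
simulate_population <- function(config, covariate = scale_years(config$T),
                                period = rep(1L, config$T)) {
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  T <- config$T; M <- config$M; pars <- config$params
  stopifnot(length(covariate) == T)
  b <- rep.int(T + 1L, M)
  a1 <- integer(M)
  z <- matrix(0L, M, T)
  gamma <- rep(NA_real_, T)

  enter1 <- runif(M) < pars$pi1
  b[enter1] <- 1L
  a1[enter1] <- as.integer(runif(M)[enter1] < pars$tau)
  z[enter1, 1] <- 1L
  cum <- pars$pi1

  for (t in 2:T) {
    alive_prev <- z[, t - 1] == 1L
    N_prev <- sum(alive_prev)
    ## survival of those alive in t-1, by age in t-1
    if (N_prev > 0) {
      idx <- which(alive_prev)
      sy <- sy_age_at(b[idx], a1[idx], t - 1L)
      phi <- ifelse(sy,
                    survival_probability(pars, "SY", covariate[t - 1],
                                         period[t - 1]),
                    survival_probability(pars, "ASY", covariate[t - 1],
                                         period[t - 1]))
      z[idx, t] <- as.integer(runif(length(idx)) < phi)
    }
    ## entries at t
    gamma[t - 1] <- recruitment_rate(pars, covariate[t - 1],
                                     N_prev / config$area, period[t - 1])
    pi_t <- N_prev * gamma[t - 1] / M
    rem <- 1 - cum
    if (pi_t > rem + 1e-12)
      stop("augmentation bound exhausted; increase M")
    haz <- if (rem > 0) min(pi_t / rem, 1) else 0
    cand <- which(b == T + 1L)
    if (length(cand) == 0L && pi_t > 0)
      stop("augmentation bound exhausted; increase M")
    newly <- cand[runif(length(cand)) < haz]
    b[newly] <- t
    z[newly, t] <- 1L
    cum <- cum + pi_t
  }
  a <- ages_from_entry(b, a1, T)
  structure(list(b = b, a1 = a1, z = z, a = a,
                 N = colSums(z), n1 = colSums(z * (a == 0L)),
                 n2 = colSums(z * (a == 1L)), gamma = gamma,
                 covariate = covariate, period = period,
                 T = T, M = M, area = config$area, years = config$years),
            class = "js_truth")
}

#' Simulate the observation process
#'
#' Applies the mark-resight observation model to a latent truth: alive
#' unmarked females are captured with the year-varying capture probability
#' and aged to their true class with probability `k` (else AHY); marked
#' females are resighted with probability `p_eta`, degraded by `p_r` in
#' single-day survey years; counts of unmarked females are Binomial draws.
#' Never-captured females contribute only to the counts.
#'
#' @param truth A [simulate_population()] result.
#' @param config The [sim_config()] that produced it.
#' @return An [encounter_data()] object (observed histories augmented to
#'   `M`), with the matching of rows to truth individuals deliberately not
#'   retained.
#' @export
simulate_observations <- function(truth, config) {
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  T <- truth$T; M <- truth$M; pars <- config$params
  s <- scale_years(T)
  p_cap <- plogis(pars$b0_cap + pars$b1_cap * s)
  single <- config$years %in% config$single_day_years
  p_det <- pars$p_eta * ifelse(single, pars$p_r, 1)

  capture <- age_class <- resight <- matrix(0L, M, T)
  marked <- matrix(0L, M, T)
  for (i in seq_len(M)) {
    if (truth$b[i] > T) next
    is_marked <- FALSE
    for (t in seq(truth$b[i], T)) {
      if (truth$z[i, t] == 0L) break
      if (!is_marked && runif(1) < p_cap[t]) {
        capture[i, t] <- 1L
        is_marked <- TRUE
        true_class <- if (truth$a[i, t] == 0L) 1L else 2L
        age_class[i, t] <- if (runif(1) < pars$k) true_class else 3L
      }
      if (is_marked) {
        marked[i, t:T] <- 1L
        resight[i, t] <- as.integer(runif(1) < p_det[t])
      }
    }
  }
  U <- colSums(truth$z * (marked == 0L))
  u <- rbinom(T, U, p_det)

  obs <- which(rowSums(capture) > 0)
  out <- encounter_data(capture[obs, , drop = FALSE],
                        age_class[obs, , drop = FALSE],
                        resight[obs, , drop = FALSE],
                        u, config$years, config$area, M = M,
                        single_day = single, plot_id = "sim")
  ## which truth individual each observed row corresponds to -- used only by
  ## validation code; the model never sees it
  attr(out, "truth_rows") <- obs
  out
}

#' Simulate a complete dataset
#'
#' Climate stations, plot-level covariate estimates, latent demographic
#' truth, and observed encounter data, all from one seed.  For climate
#' variants the covariate driving demography is the true plot-level value
#' (trend plus shared interannual shock), centered and scaled.
#'
#' @param config A [sim_config()].
#' @param trend A [trend_spec()] choosing which covariate drives demography.
#' @return A list of class `js_dataset` with elements `stations`,
#'   `estimates` (plot-level `mu`/`sigma` per year and variable), `truth`,
#'   `data`, `scaling` (covariate center/scale), `trend`, and `config`.
#' @export
simulate_dataset <- function(config, trend = trend_spec("time")) {
  stations <- simulate_climate(config)
  plots <- data.frame(plot_id = "sim", region = "sim",
                      elevation_m = config$plot_elevation,
                      area_ha = config$area,
                      first_year = min(config$years),
                      last_year = max(config$years))
  est <- rbind(
    predict_plot_climate(stations, plots, "early_breeding_temperature"),
    predict_plot_climate(stations, plots, "annual_precipitation"))
  period <- trend_periods(trend, config$years)
  if (trend$variant == "time") {
    w <- scale_years(config$T)
    scaling <- list(center = mean(seq_len(config$T)),
                    scale = sd(seq_len(config$T)))
  } else {
    vb <- if (trend$variant == "temperature") "early_breeding_temperature"
          else "annual_precipitation"
    w_raw <- attr(stations, "true_plot_values")[[vb]]
    scaling <- list(center = mean(w_raw), scale = sd(w_raw))
    w <- (w_raw - scaling$center) / scaling$scale
  }
  truth <- simulate_population(config, covariate = w, period = period)
  data <- simulate_observations(truth, config)
  structure(list(stations = stations, estimates = est, truth = truth,
                 data = data, scaling = scaling, trend = trend,
                 config = config),
            class = "js_dataset")
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits the CSV dialects the model reads (climate stations, plot metadata,
#' encounters, counts) plus the latent truth as JSON.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("stations.csv", "plots.csv", "encounters.csv",
                            "counts.csv", "truth.json"))
  write.csv(dataset$stations, paths[1], row.names = FALSE)
  write.csv(data.frame(plot_id = "sim", region = "sim",
                       elevation_m = dataset$config$plot_elevation,
                       area_ha = dataset$config$area,
                       first_year = min(dataset$config$years),
                       last_year = max(dataset$config$years)),
            paths[2], row.names = FALSE)
  write_encounters(dataset$data, paths[3], paths[4])
  tr <- dataset$truth
  jsonlite::write_json(list(b = tr$b, a1 = tr$a1, N = tr$N, n1 = tr$n1,
                            n2 = tr$n2, gamma = tr$gamma,
                            covariate = tr$covariate, years = tr$years),
                       paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
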