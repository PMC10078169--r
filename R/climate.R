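#' Read climate-station series and plot metadata
#'
#' Station CSV columns: `station_id, elevation_m, year, variable, value,
#' value_sd` (and optionally `region`).  Plot CSV columns: `plot_id, region,
#' elevation_m, area_ha, first_year, last_year`.
#'
#' @param path Path to the CSV file.
#' @return A data frame.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "elevation_m", "year", "variable", "value")
  if (!all(need %in% names(x)))
    stop("station file must have columns: ", paste(need, collapse = ", "))
  if (!"value_sd" %in% names(x)) x$value_sd <- NA_real_
  if (any(x$elevation_m <= 0)) stop("station elevations must be positive")
  if (any(!is.na(x$value_sd) & x$value_sd < 0))
    stop("value_sd must be non-negative")
  if (anyDuplicated(x[c("station_id", "year", "variable")]))
    stop("one record per station x year x variable expected")
  x
}

#' @rdname read_stations
#' @export
read_plots <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "elevation_m", "area_ha")
  if (!all(need %in% names(x)))
    stop("plot file must have columns: ", paste(need, collapse = ", "))
  x
}

#' Filter climate stations by elevation
#'
#' Retains a station record iff its elevation is within `tolerance` meters of
#' the elevation of at least one study plot (boundary inclusive).  Stations
#' far outside the plots' elevation band would extrapolate the
#' elevation-climate regression.
#'
#' @param stations Station data frame (see [read_stations()]).
#' @param plot_elevations Numeric vector of plot elevations (m).
#' @param tolerance Maximum absolute elevation difference (m); 175 m by
#'   default.
#' @return The filtered station data frame.
#' @export
filter_stations <- function(stations, plot_elevations, tolerance = 175) {
  stopifnot(tolerance >= 0, length(plot_elevations) >= 1)
  keep <- vapply(stations$elevation_m, function(e)
    min(abs(e - plot_elevations)) <= tolerance, logical(1))
  out <- stations[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no stations within tolerance (", tolerance, " m) of the plots")
  out
}

station_weights <- function(stations, variable) {
  ## inverse-SD weights for the temperature means; unweighted otherwise
  if (variable == "early_breeding_temperature" &&
      !all(is.na(stations$value_sd))) {
    if (any(is.na(stations$value_sd) | stations$value_sd <= 0))
      stop("inverse-SD weighting requires positive value_sd on every record")
    1 / stations$value_sd
  } else rep(1, nrow(stations))
}

#' Predict plot-level climate from station series
#'
#' Fits, per variable (and per region when a `region` column is present), a
#' linear model with a shared elevation trend and a separate intercept for
#' each year, weighting temperature means by the reciprocal of their
#' within-season SD.  Returns the prediction mean `mu` and the standard
#' error of the fitted mean `sigma` at each plot's elevation for each year
#' with station data.  `sigma` is the SE of the mean (not a prediction
#' interval): the predicted value enters the demographic model as an
#' uncertain mean.
#'
#' @param stations Station data frame.
#' @param plots Plot metadata data frame (see [read_plots()]).
#' @param variable `"early_breeding_temperature"` or
#'   `"annual_precipitation"`.
#' @return Data frame `plot_id, year, variable, mu, sigma`.
#' @export
predict_plot_climate <- function(stations, plots,
                                 variable = c("early_breeding_temperature",
                                              "annual_precipitation")) {
  variable <- match.arg(variable)
  st <- stations[stations$variable == variable, , drop = FALSE]
  if (nrow(st) == 0) stop("no station records for variable ", variable)
  by_region <- "region" %in% names(st) && "region" %in% names(plots)
  groups <- if (by_region) unique(plots$region) else "all"
  out <- list()
  for (g in groups) {
    stg <- if (by_region) st[st$region == g, , drop = FALSE] else st
    plg <- if (by_region) plots[plots$region == g, , drop = FALSE] else plots
    if (nrow(plg) == 0) next
    if (length(unique(stg$elevation_m)) < 2)
      stop("need stations at >= 2 distinct elevations to fit the ",
           "elevation trend")
    el_c <- mean(stg$elevation_m)
    stg$elev_c <- stg$elevation_m - el_c
    stg$fyear <- factor(stg$year)
    wts <- station_weights(stg, variable)
    fit <- lm(value ~ 0 + fyear + elev_c, data = stg, weights = wts)
    years <- sort(unique(stg$year))
    missing_years <- setdiff(seq(min(years), max(years)), years)
    if (length(missing_years))
      warning("no station data for year(s) ",
              paste(missing_years, collapse = ", "),
              "; those plot-years are absent from the output")
    for (p in seq_len(nrow(plg))) {
      nd <- data.frame(fyear = factor(years, levels = levels(stg$fyear)),
                       elev_c = plg$elevation_m[p] - el_c)
      pr <- predict(fit, newdata = nd, se.fit = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        plot_id = plg$plot_id[p], year = years, variable = variable,
        mu = as.numeric(pr$fit), sigma = as.numeric(pr$se.fit))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Long-term climate trend with inverse-SD weighting
#'
#' Linear regression of the climate variable on year (trend effect) with
#' elevation as a covariate, optionally weighting observations by the
#' reciprocal of their within-season SD, and optionally adding a
#' year-by-period interaction around a changepoint year.  Year is centered
#' at its midpoint and elevation at its mean before fitting (slopes are
#' unchanged; the centering only stabilizes the normal equations).
#'
#' @param stations Station data frame (one variable's records are selected).
#' @param variable Climate variable to model.
#' @param weights `"inverse_sd"` (weights proportional to `1/value_sd`) or
#'   `"none"`.
#' @param interaction_period Optional changepoint year; the model then adds
#'   `year x period` (period = before vs. at/after the changepoint) and the
#'   interaction's 95% CI is reported.
#' @param region Label stored on the result.
#' @return An object of class `climate_trend`: `slope` (units/yr),
#'   `slope_se`, `ci95`, `t_stat`, `p_value`, optional `interaction`
#'   (estimate + CI), and the fitted `model`.
#' @export
fit_weighted_trend <- function(stations,
                               variable = c("early_breeding_temperature",
                                            "annual_precipitation"),
                               weights = c("inverse_sd", "none"),
                               interaction_period = NULL,
                               region = "all") {
  variable <- match.arg(variable)
  weights <- match.arg(weights)
  st <- stations[stations$variable == variable, , drop = FALSE]
  if (length(unique(st$year)) < 3) stop("need >= 3 years of data")
  st$year_c <- st$year - mean(range(st$year))
  st$elev_c <- st$elevation_m - mean(st$elevation_m)
  wts <- if (weights == "inverse_sd") {
    if (any(is.na(st$value_sd) | st$value_sd <= 0))
      stop("weights = 'inverse_sd' requires positive value_sd on every record")
    1 / st$value_sd
  } else rep(1, nrow(st))
  interaction <- NULL
  if (is.null(interaction_period)) {
    fit <- lm(value ~ year_c + elev_c, data = st, weights = wts)
  } else {
    st$period <- factor(st$year >= interaction_period,
                        labels = c("before", "after"))
    fit <- lm(value ~ year_c * period + elev_c, data = st, weights = wts)
    ci <- confint(fit)["year_c:periodafter", ]
    interaction <- list(estimate = unname(coef(fit)["year_c:periodafter"]),
                        ci95 = unname(ci))
  }
  sm <- summary(fit)$coefficients
  ci <- confint(fit)["year_c", ]
  structure(list(variable = variable, region = region,
                 slope = unname(coef(fit)["year_c"]),
                 slope_se = unname(sm["year_c", "Std. Error"]),
                 ci95 = unname(ci),
                 t_stat = unname(sm["year_c", "t value"]),
                 p_value = unname(sm["year_c", "Pr(>|t|)"]),
                 interaction = interaction, model = fit),
            class = "climate_trend")
}

#' @export
print.climate_trend <- function(x, ...) {
  cat(sprintf("Climate trend (%s, %s): %.4f per yr (SE %.4f, 95%% CI %.4f to %.4f)\n",
              x$variable, x$region, x$slope, x$slope_se,
              x$ci95[1], x$ci95[2]))
  if (!is.null(x$interaction))
    cat(sprintf("  year x period interaction: %.4f (95%% CI %.4f to %.4f)\n",
                x$interaction$estimate, x$interaction$ci95[1],
                x$interaction$ci95[2]))
  invisible(x)
}

#' Test for increasing interannual variability of precipitation
#'
#' Two-stage test: stage 1 fits annual precipitation with a separate
#' intercept per year and an elevation trend; stage 2 regresses the absolute
#' values of the stage-1 residuals on year (trend) and elevation.  A positive
#' stage-2 year slope indicates precipitation becoming more variable over
#' time.  Two-sided t-test with residual degrees of freedom.
#'
#' @param stations Station data frame (annual-precipitation records are
#'   selected).
#' @return List with `slope` (mm/yr of |residual|), `t_stat`, `p_value`, and
#'   the two fitted models.
#' @export
test_precip_variability <- function(stations) {
  st <- stations[stations$variable == "annual_precipitation", , drop = FALSE]
  if (length(unique(st$year)) < 4) stop("need >= 4 years of data")
  st$elev_c <- st$elevation_m - mean(st$elevation_m)
  st$fyear <- factor(st$year)
  stage1 <- lm(value ~ 0 + fyear + elev_c, data = st)
  st$abs_resid <- abs(residuals(stage1))
  if (max(st$abs_resid) < sqrt(.Machine$double.eps))
    stop("degenerate input: stage-1 residuals are constant (zero)")
  st$year_c <- st$year - mean(range(st$year))
  stage2 <- lm(abs_resid ~ year_c + elev_c, data = st)
  sm <- summary(stage2)$coefficients
  list(slope = unname(coef(stage2)["year_c"]),
       t_stat = unname(sm["year_c", "t value"]),
       p_value = unname(sm["year_c", "Pr(>|t|)"]),
       stage1 = stage1, stage2 = stage2)
}
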