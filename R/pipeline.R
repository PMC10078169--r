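#' Run configuration for the full analysis pipeline
#'
#' Collects the file paths, plot selection, model variant, MCMC settings,
#' and forecast options of one end-to-end run.  Can be read from a YAML file
#' with [read_run_config()].
#'
#' @param stations_file,plots_file,encounter_file,counts_file Input CSVs
#'   (see [read_stations()], [read_plots()], [read_encounters()]).
#' @param plot_id Which plot to analyze.
#' @param variant Trend variant (`"time"`, `"temperature"`,
#'   `"precipitation"`).
#' @param changepoint Optional changepoint year.
#' @param M Augmentation bound.
#' @param chains,iter,adapt MCMC settings.
#' @param horizon Forecast horizon year.
#' @param M_future Forecast augmentation bound.
#' @param single_day_years Years surveyed on a single day.
#' @param station_tolerance Elevation tolerance (m) for station filtering.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stations_file, plots_file, encounter_file,
                       counts_file, plot_id, variant = "time",
                       changepoint = NULL, M = 600, chains = 3,
                       iter = 2000, adapt = 500, horizon = 2040,
                       M_future = 2400, single_day_years = integer(),
                       station_tolerance = 175, seed = 1,
                       out_dir = "js-run") {
  cfg <- structure(list(stations_file = stations_file,
                        plots_file = plots_file,
                        encounter_file = encounter_file,
                        counts_file = counts_file, plot_id = plot_id,
                        variant = variant, changepoint = changepoint,
                        M = M, chains = chains, iter = iter, adapt = adapt,
                        horizon = horizon, M_future = M_future,
                        single_day_years = single_day_years,
                        station_tolerance = station_tolerance,
                        seed = seed, out_dir = out_dir),
                   class = "run_config")
  for (f in c(cfg$stations_file, cfg$plots_file, cfg$encounter_file,
              cfg$counts_file)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  cfg
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys match the [run_config()]
#'   arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

pipeline_log <- function(...) message("[jsclimate] ", ...)

#' Run the full pipeline: climate, model, inference, forecast
#'
#' Executes the stages in order -- station filtering, plot-level climate
#' prediction, long-term climate trend, model fitting, convergence
#' assessment, and forecasting -- and writes all artifacts (posterior
#' summary, convergence table, forecast summary, report JSON, and a manifest
#' with input hashes and seeds) to the output directory.  Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts (`samples`,
#'   `summary`, `convergence`, `forecast`, `report`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  pipeline_log("reading inputs")
  stations <- read_stations(config$stations_file)
  plots <- read_plots(config$plots_file)
  plot <- plots[plots$plot_id == config$plot_id, , drop = FALSE]
  if (nrow(plot) != 1) stop("plot_id not found in plot metadata: ",
                            config$plot_id)

  pipeline_log("building climate covariates")
  stations <- filter_stations(stations, plots$elevation_m,
                              config$station_tolerance)
  trend <- trend_spec(config$variant, config$changepoint)
  climate_trend <- NULL
  covariates <- NULL
  if (config$variant != "time") {
    vb <- if (config$variant == "temperature") "early_breeding_temperature"
          else "annual_precipitation"
    est <- predict_plot_climate(stations, plots, vb)
    covariates <- est[est$plot_id == config$plot_id, , drop = FALSE]
    climate_trend <- fit_weighted_trend(
      stations, vb,
      weights = if (vb == "early_breeding_temperature") "inverse_sd"
                else "none")
    utils::write.csv(est, file.path(config$out_dir, "plot_climate.csv"),
                     row.names = FALSE)
  }

  pipeline_log("reading encounter data")
  data <- read_encounters(config$encounter_file, config$counts_file,
                          area = plot$area_ha, M = config$M,
                          single_day_years = config$single_day_years,
                          plot_id = config$plot_id)

  pipeline_log("fitting the model (", config$chains, " chains x ",
               config$iter, " draws)")
  samples <- run_mcmc(data, covariates = covariates, trend = trend,
                      settings = mcmc_settings(config$chains, config$iter,
                                               config$adapt, config$seed))
  summ <- summarize_posterior(samples)
  conv <- assess_convergence(samples)
  utils::write.csv(summ, file.path(config$out_dir, "posterior_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(conv, file.path(config$out_dir, "convergence.csv"),
                   row.names = FALSE)

  pipeline_log("forecasting to ", config$horizon)
  fc <- forecast_population(samples, data, trend = trend,
                            climate_trend = climate_trend,
                            horizon = config$horizon,
                            M_future = config$M_future,
                            seed = config$seed)
  utils::write.csv(forecast_summary(fc),
                   file.path(config$out_dir, "forecast_summary.csv"),
                   row.names = FALSE)

  report <- make_report(list(samples = samples, summary = summ,
                             convergence = conv, forecast = fc,
                             config = config))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  inputs <- c(config$stations_file, config$plots_file,
              config$encounter_file, config$counts_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("jsclimate")),
    seed = config$seed, variant = config$variant,
    changepoint = config$changepoint,
    mcmc = list(chains = config$chains, iter = config$iter,
                adapt = config$adapt),
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipeline_log("done in ", sprintf("%.1f", manifest$elapsed_s), " s")

  invisible(list(samples = samples, summary = summ, convergence = conv,
                 forecast = fc, report = report, manifest = manifest))
}

#' Build the report tables from run artifacts
#'
#' Mirrors the reporting style of long-term demography studies: per-year
#' density with 95% CrIs, trend coefficients with CrIs, and the extinction
#' risk at the horizon.
#'
#' @param artifacts List with `samples`, `summary`, `convergence`,
#'   `forecast`, and `config` (as assembled by [run_pipeline()]).
#' @return A list (serializable to JSON) with `density`, `parameters`, and
#'   `extinction_risk_percent`.
#' @export
make_report <- function(artifacts) {
  summ <- artifacts$summary
  dens <- summ[grepl("^density\\[", summ$parameter), , drop = FALSE]
  dens$year <- artifacts$samples$years
  pars <- summ[!grepl("^(density|N|n1|n2|w)\\[", summ$parameter), ,
               drop = FALSE]
  risk <- extinction_risk(artifacts$forecast)
  stopifnot(risk >= 0, risk <= 100)
  list(plot_id = artifacts$samples$plot_id,
       variant = artifacts$samples$trend$variant,
       density = dens[, c("year", "median", "lower", "upper")],
       parameters = pars,
       extinction_risk_percent = risk,
       horizon = max(artifacts$forecast$years))
}
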