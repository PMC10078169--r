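## Shared fixtures: toy enumeration machinery for the T = 2 / T = 3 oracle
## checks and the simulation configurations used across test files.

## all (b, d, a1) trajectories of one individual for a study of T years
latent_configs <- function(T) {
  cfg <- list()
  for (b in seq_len(T)) {
    for (d in seq(b + 1, T + 1)) {
      if (b == 1) for (a1 in 0:1) cfg[[length(cfg) + 1L]] <- c(b, d, a1)
      else cfg[[length(cfg) + 1L]] <- c(b, d, 0L)
    }
  }
  cfg[[length(cfg) + 1L]] <- c(T + 1L, T + 1L, 0L)
  cfg
}

z_from_bd <- function(b, d, T) as.integer(b <= seq_len(T) & seq_len(T) < d)

state_from_configs <- function(cfgs_chosen, T, area) {
  b <- vapply(cfgs_chosen, `[`, numeric(1), 1)
  d <- vapply(cfgs_chosen, `[`, numeric(1), 2)
  a1 <- vapply(cfgs_chosen, `[`, numeric(1), 3)
  z <- do.call(rbind, lapply(cfgs_chosen, function(c) z_from_bd(c[1], c[2], T)))
  augmented_state(b = b, a1 = a1, z = z, area = area)
}

## every observation outcome of one individual over T = 2 years:
## never captured / captured in year 1 or 2 with an age class, plus all
## resight patterns over the marked years
obs_options_T2 <- function() {
  opts <- list()
  opts[[1]] <- list(cap = c(0L, 0L), ac = c(0L, 0L), y = c(0L, 0L))
  for (cls in 1:3) for (y1 in 0:1) for (y2 in 0:1)
    opts[[length(opts) + 1L]] <-
      list(cap = c(1L, 0L), ac = c(cls, 0L), y = c(y1, y2))
  for (cls in 1:3) for (y2 in 0:1)
    opts[[length(opts) + 1L]] <-
      list(cap = c(0L, 1L), ac = c(0L, cls), y = c(0L, y2))
  opts
}

toy_params <- function(T = 2) {
  model_params(alpha = 1, b0_gam = -0.5, b1_gam = 0.2, b2_gam = 0.2,
               b0_phi_sy = -0.2, b0_phi_asy = 0.3, b1_phi = 0.1,
               b0_cap = 0.4, b1_cap = 0.1, k = 0.7, tau = 0.4,
               p_eta = 0.8, p_r = 0.6, pi1 = 0.25,
               w = jsclimate:::scale_years(T))
}

## simulation settings for the parameter-recovery studies: an open
## population of roughly 30-60 females on 100 ha observed for 15 years;
## the augmentation bound comfortably exceeds the ~200 cumulative entries
recovery_config <- function(seed, T = 15, M = 300) {
  sim_config(
    T = T, M = M, area = 100, EN1 = 35,
    params = model_params(alpha = 1.5, b0_gam = -1.1, b1_gam = -0.3,
                          b2_gam = 2.0, b0_phi_sy = qlogis(0.50),
                          b0_phi_asy = qlogis(0.70), b1_phi = -0.35,
                          b0_cap = qlogis(0.85), b1_cap = 0,
                          k = 0.7, tau = 0.5, p_eta = 0.9),
    seed = seed)
}

## a small fitted-posterior stand-in for forecast tests: every draw carries
## the same parameter values and terminal age structure
fake_posterior <- function(params, n1_T, n2_T, ndraw = 1, T = 10,
                           area = 25, variant = "time") {
  nm <- c("alpha", "b0_gam", "b1_gam", "b2_gam", "b0_phi_sy", "b0_phi_asy",
          "b1_phi", "b0_cap", "b1_cap", "k", "tau", "p_eta", "p_r", "pi1")
  vals <- c(params$alpha, params$b0_gam, params$b1_gam[1], params$b2_gam,
            params$b0_phi_sy, params$b0_phi_asy, params$b1_phi[1],
            params$b0_cap, params$b1_cap, params$k, params$tau,
            params$p_eta, params$p_r, params$pi1)
  m <- matrix(rep(vals, each = ndraw), ndraw, length(nm),
              dimnames = list(NULL, nm))
  ns <- matrix(0, ndraw, 3 * T)
  colnames(ns) <- c(sprintf("n1[%d]", 1:T), sprintf("n2[%d]", 1:T),
                    sprintf("N[%d]", 1:T))
  ns[, sprintf("n1[%d]", T)] <- n1_T
  ns[, sprintf("n2[%d]", T)] <- n2_T
  ns[, sprintf("N[%d]", T)] <- n1_T + n2_T
  structure(list(chains = list(cbind(m, ns)),
                 settings = mcmc_settings(chains = 1, iter = ndraw,
                                          adapt = 0, seed = 1),
                 trend = trend_spec(variant), years = seq(2001, length.out = T),
                 T = T, M = 300, area = area,
                 variant = if (variant == "time") 0L else 1L,
                 scaling = list(center = mean(seq_len(T)),
                                scale = sd(seq_len(T))),
                 dd_power = 2, plot_id = "fake"),
            class = "js_posterior")
}

## station series lying exactly on a linear surface in year and elevation
exact_station_grid <- function(elevs, years, intercept, year_slope,
                               elev_slope, variable, value_sd = 2) {
  g <- expand.grid(elevation_m = elevs, year = years)
  data.frame(station_id = paste0("s", match(g$elevation_m, elevs)),
             elevation_m = g$elevation_m, year = g$year, variable = variable,
             value = intercept + year_slope * g$year + elev_slope * g$elevation_m,
             value_sd = if (variable == "early_breeding_temperature")
               value_sd else NA_real_)
}
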