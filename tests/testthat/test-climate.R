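test_that("station filtering keeps exactly the stations within tolerance", {
  st <- data.frame(station_id = c("a", "b", "c"),
                   elevation_m = c(900, 1100, 1600),
                   year = 2002, variable = "early_breeding_temperature",
                   value = 15, value_sd = 1)
  kept <- filter_stations(st, c(1050, 1200, 1350), tolerance = 175)
  expect_setequal(kept$station_id, c("a", "b"))

  ## boundary is inclusive, down to zero tolerance
  expect_equal(filter_stations(st, 1100, tolerance = 0)$station_id, "b")
  expect_error(filter_stations(st, 5000, tolerance = 175),
               "no stations within tolerance")
})

test_that("plot-level prediction reproduces a perfect linear surface", {
  st <- exact_station_grid(c(900, 1100, 1300), 2002:2006,
                           intercept = 20, year_slope = 0,
                           elev_slope = -0.005,
                           variable = "early_breeding_temperature")
  plots <- data.frame(plot_id = "p1", elevation_m = 1200, area_ha = 20)
  est <- predict_plot_climate(st, plots, "early_breeding_temperature")
  expect_equal(nrow(est), 5)
  expect_equal(est$mu, rep(20 - 0.005 * 1200, 5), tolerance = 1e-10)
  expect_true(all(est$sigma < 1e-7))
})

test_that("plot-level prediction matches a weighted least-squares oracle", {
  set.seed(4)
  st <- exact_station_grid(c(950, 1150, 1350), 2002:2003,
                           intercept = 18, year_slope = 0.05,
                           elev_slope = -0.004,
                           variable = "early_breeding_temperature")
  st$value <- st$value + rnorm(nrow(st), 0, 0.4)
  st$value_sd <- c(1.2, 0.8, 2.1, 1.5, 0.9, 1.1)
  plots <- data.frame(plot_id = "p1", elevation_m = 1200, area_ha = 20)
  est <- predict_plot_climate(st, plots, "early_breeding_temperature")

  ## weighted normal equations, written out independently of lm()
  el_c <- st$elevation_m - mean(st$elevation_m)
  X <- cbind(st$year == 2002, st$year == 2003, el_c)
  W <- diag(1 / st$value_sd)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% st$value)
  resid <- st$value - X %*% beta
  s2 <- sum(resid^2 / st$value_sd) / (nrow(st) - 3)
  x0 <- rbind(c(1, 0, 1200 - mean(st$elevation_m)),
              c(0, 1, 1200 - mean(st$elevation_m)))
  mu_hat <- as.numeric(x0 %*% beta)
  se_hat <- sqrt(diag(x0 %*% solve(XtWX) %*% t(x0)) * s2)
  expect_equal(est$mu, mu_hat, tolerance = 1e-8)
  expect_equal(est$sigma, se_hat, tolerance = 1e-8)
})

test_that("prediction uncertainty shrinks as residual noise shrinks", {
  plots <- data.frame(plot_id = "p1", elevation_m = 1200, area_ha = 20)
  sig <- vapply(c(1, 0.3, 0.05), function(nsd) {
    set.seed(11)
    st <- exact_station_grid(c(950, 1150, 1350), 2002:2005, 18, 0.05,
                             -0.004, "annual_precipitation")
    st$value <- st$value + rnorm(nrow(st), 0, nsd)
    mean(predict_plot_climate(st, plots, "annual_precipitation")$sigma)
  }, numeric(1))
  expect_true(all(diff(sig) < 0))
})

test_that("predicted early-breeding temperature declines with elevation", {
  set.seed(21)
  st <- exact_station_grid(c(950, 1150, 1350), 2002:2010, 18, 0.05, -0.006,
                           "early_breeding_temperature")
  st$value <- st$value + rnorm(nrow(st), 0, 0.3)
  plots <- data.frame(plot_id = c("lo", "hi"), elevation_m = c(1050, 1350),
                      area_ha = 20)
  est <- predict_plot_climate(st, plots, "early_breeding_temperature")
  lo <- est$mu[est$plot_id == "lo"]; hi <- est$mu[est$plot_id == "hi"]
  expect_true(all(hi < lo))
})

test_that("weighted trend recovers a noiseless slope exactly", {
  st <- exact_station_grid(c(1000, 1200), 2002:2011, intercept = 3,
                           year_slope = 0.07, elev_slope = -0.005,
                           variable = "early_breeding_temperature")
  tr <- suppressWarnings(      # lm warns on an essentially perfect fit
    fit_weighted_trend(st, "early_breeding_temperature", "inverse_sd"))
  expect_equal(tr$slope, 0.07, tolerance = 1e-10)
  expect_lt(diff(tr$ci95), 1e-6)

  ## constant weights give the same slope as no weights
  set.seed(2)
  st$value <- st$value + rnorm(nrow(st), 0, 0.5)
  t1 <- fit_weighted_trend(st, "early_breeding_temperature", "inverse_sd")
  t2 <- fit_weighted_trend(st, "early_breeding_temperature", "none")
  expect_equal(t1$slope, t2$slope, tolerance = 1e-12)
})

test_that("weighted trend equals the weighted normal-equations oracle", {
  set.seed(7)
  st <- exact_station_grid(c(1000, 1150, 1300), 2002:2009, 3, 0.07, -0.005,
                           "early_breeding_temperature")
  st$value <- st$value + rnorm(nrow(st), 0, 0.6)
  st$value_sd <- runif(nrow(st), 0.5, 3)
  tr <- fit_weighted_trend(st, "early_breeding_temperature", "inverse_sd")
  X <- cbind(1, st$year - mean(range(st$year)),
             st$elevation_m - mean(st$elevation_m))
  W <- diag(1 / st$value_sd)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% st$value)
  expect_equal(tr$slope, beta[2], tolerance = 1e-10)
})

test_that("weighted trend needs value_sd and enough years", {
  st <- exact_station_grid(c(1000, 1200), 2002:2011, 1000, 0, 0.6,
                           "annual_precipitation")
  expect_error(fit_weighted_trend(st, "annual_precipitation", "inverse_sd"),
               "value_sd")
  st2 <- st[st$year < 2004, ]
  expect_error(fit_weighted_trend(st2, "annual_precipitation", "none"),
               ">= 3 years")
})

test_that("trend recovery is calibrated: within 2 SE in >= 93 of 100 runs", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(300 + r)
    st <- exact_station_grid(c(1000, 1150, 1300), 2002:2016, 3, 0.07,
                             -0.005, "early_breeding_temperature")
    st$value <- st$value + rnorm(nrow(st), 0, 0.9)
    tr <- fit_weighted_trend(st, "early_breeding_temperature", "inverse_sd")
    if (abs(tr$slope - 0.07) <= 2 * tr$slope_se) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("year-by-period interaction detects a slope change", {
  st <- exact_station_grid(c(1000, 1200), 2002:2019, 3, 0.02, -0.005,
                           "early_breeding_temperature")
  after <- st$year >= 2012
  st$value <- st$value + ifelse(after, 0.08 * (st$year - 2012), 0)
  tr <- suppressWarnings(      # lm warns on an essentially perfect fit
    fit_weighted_trend(st, "early_breeding_temperature", "inverse_sd",
                       interaction_period = 2012))
  expect_equal(tr$interaction$estimate, 0.08, tolerance = 1e-8)
  expect_lt(diff(tr$interaction$ci95), 1e-5)
})

test_that("precipitation-variability test holds its size under the null", {
  rejections <- 0L
  for (r in 1:100) {
    set.seed(500 + r)
    st <- exact_station_grid(c(950, 1050, 1150, 1250, 1350), 1981:2020,
                             2000, 0.5, 0.6, "annual_precipitation")
    st$value <- st$value + rnorm(nrow(st), 0, 300)   # homoscedastic
    res <- test_precip_variability(st)
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 11L)
})

test_that("precipitation-variability test detects increasing spread", {
  set.seed(99)
  st <- exact_station_grid(c(950, 1050, 1150, 1250, 1350), 1981:2020,
                           2000, 0.5, 0.6, "annual_precipitation")
  sdt <- 150 * (1 + (st$year - 1981) / 39)          # SD doubles over time
  st$value <- st$value + rnorm(nrow(st), 0, sdt)
  res <- test_precip_variability(st)
  expect_gt(res$slope, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("precipitation-variability is invariant to a level shift", {
  set.seed(12)
  st <- exact_station_grid(c(1000, 1200), 2002:2015, 2000, 1, 0.6,
                           "annual_precipitation")
  st$value <- st$value + rnorm(nrow(st), 0, 200)
  r1 <- test_precip_variability(st)
  st$value <- st$value + 5000
  r2 <- test_precip_variability(st)
  expect_equal(r1$slope, r2$slope, tolerance = 1e-9)
  expect_equal(r1$t_stat, r2$t_stat, tolerance = 1e-9)

  st$value <- 3000   # constant: no residual variation at all
  expect_error(test_precip_variability(st), "degenerate")
})
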