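test_that("identical configuration and seed give identical outputs", {
  cfg <- sim_config(T = 8, M = 100, area = 20, EN1 = 10, seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$stations$value, d2$stations$value)
  expect_identical(d1$truth$b, d2$truth$b)
  expect_identical(d1$data$capture, d2$data$capture)
  expect_identical(d1$data$u, d2$data$u)

  ## byte-identical CSV fixtures
  f1 <- write_dataset(d1, tempfile()); f2 <- write_dataset(d2, tempfile())
  for (j in seq_along(f1))
    expect_identical(readLines(f1[j]), readLines(f2[j]))
})

test_that("noiseless synthetic climate returns the generating slope", {
  cfg <- sim_config(T = 10, seed = 3,
                    climate = list(temp_ref = 16, temp_year_slope = 0.07,
                                   temp_elev_slope = -0.006,
                                   temp_noise_sd = 0, temp_shock_sd = 0,
                                   temp_value_sd = 2,
                                   precip_ref = 2283, precip_year_slope = 0,
                                   precip_elev_slope = 0.62,
                                   precip_noise_sd = 0, precip_shock_sd = 0))
  st <- simulate_climate(cfg)
  tr <- suppressWarnings(      # lm warns on an essentially perfect fit
    fit_weighted_trend(st, "early_breeding_temperature", "inverse_sd"))
  expect_equal(tr$slope, 0.07, tolerance = 1e-10)
})

test_that("warming-trend recovery is calibrated across seeds", {
  ## independent station noise only: with a shared interannual shock the
  ## observations are correlated within years and the regression SE no
  ## longer estimates the sampling SD of the slope.  The design is kept
  ## large (10 stations x 30 years) so the 2-SE interval attains its
  ## ~95.4% normal coverage rather than the smaller t coverage.
  hits <- 0L
  for (r in 1:100) {
    cfg <- sim_config(T = 30, n_stations_temp = 10, seed = 700 + r)
    cfg$climate$temp_shock_sd <- 0
    cfg$climate$temp_noise_sd <- 0.9
    st <- simulate_climate(cfg)
    tr <- fit_weighted_trend(st, "early_breeding_temperature", "inverse_sd")
    if (abs(tr$slope - 0.07) <= 2 * tr$slope_se) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("population simulation honors degenerate survival/recruitment", {
  base <- model_params(b0_cap = qlogis(0.8), k = 0.7, p_eta = 0.9)
  ## immortal, no recruitment: abundance is constant
  p_live <- base
  p_live$b0_phi_sy <- p_live$b0_phi_asy <- 745; p_live$b0_gam <- -745
  cfg <- sim_config(T = 6, M = 60, area = 10, EN1 = 10, params = p_live,
                    seed = 2)
  tr <- simulate_population(cfg)
  expect_true(all(tr$N == tr$N[1]))

  ## immediate extinction: nobody survives, nobody recruits
  p_dead <- base
  p_dead$b0_phi_sy <- p_dead$b0_phi_asy <- -745; p_dead$b0_gam <- -745
  cfg2 <- sim_config(T = 6, M = 60, area = 10, EN1 = 10, params = p_dead,
                     seed = 2)
  tr2 <- simulate_population(cfg2)
  expect_true(all(tr2$N[-1] == 0))

  ## derived bookkeeping invariants
  expect_equal(tr$N, tr$n1 + tr$n2)
  expect_equal(tr$N, colSums(tr$z))
})

test_that("augmentation exhaustion is reported as an error", {
  p <- model_params(b0_gam = 10, alpha = 3,
                    b0_phi_sy = 745, b0_phi_asy = 745)
  cfg <- sim_config(T = 10, M = 12, area = 100, EN1 = 8, params = p, seed = 1)
  expect_error(simulate_population(cfg), "increase M")
})

test_that("mean second-year abundance matches the expectation oracle", {
  cfg <- sim_config(T = 5, M = 30, area = 10, EN1 = 6,
                    params = model_params(alpha = 1.2, b0_gam = -0.6,
                                          b1_gam = 0.2, b2_gam = 0.3,
                                          b0_phi_sy = -0.2, b0_phi_asy = 0.4,
                                          b1_phi = -0.2, k = 0.7, tau = 0.4,
                                          p_eta = 0.9),
                    seed = 1)
  p <- cfg$params
  w <- jsclimate:::scale_years(5)
  phiS <- survival_probability(p, "SY", w[1])
  phiA <- survival_probability(p, "ASY", w[1])
  ## exact expectation over the generative rules: N1 is Binomial(M, pi1),
  ## survivors mix the age-specific survivals, entrants follow the sequential
  ## entry hazard pi_2 / (1 - pi_1) with pi_2 = N1 * gamma_1(N1) / M
  EN2 <- 0
  for (n in 0:30) {
    pn <- dbinom(n, 30, p$pi1)
    surv <- n * (p$tau * phiA + (1 - p$tau) * phiS)
    gam <- recruitment_rate(p, w[1], n / 10)
    h <- min(n * gam / 30 / (1 - p$pi1), 1)
    EN2 <- EN2 + pn * (surv + (30 - n) * h)
  }
  sims <- vapply(1:10000, function(s) {
    cfg$seed <- s
    simulate_population(cfg)$N[2]
  }, numeric(1))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - EN2), 4 * se)
})

test_that("perfect detection yields complete, correctly aged histories", {
  p <- model_params(alpha = 1.2, b0_gam = -0.8, b2_gam = 0.3,
                    b0_phi_sy = 0, b0_phi_asy = 0.8,
                    b0_cap = 745, k = 1, tau = 0.4, p_eta = 1)
  cfg <- sim_config(T = 7, M = 80, area = 15, EN1 = 10, params = p, seed = 8)
  truth <- simulate_population(cfg)
  dat <- simulate_observations(truth, cfg)
  ## every alive female is captured in her entry year and resighted while
  ## alive; nobody remains unmarked, so all counts are zero
  expect_true(all(dat$u == 0))
  obs <- which(rowSums(dat$capture) > 0)
  expect_equal(length(obs), sum(truth$b <= cfg$T))
  expect_equal(sum(dat$capture), sum(truth$b <= cfg$T))
  expect_equal(sum(dat$resight), sum(truth$z))
  ## ageing is exact: age classifications appear only at captures and are
  ## never the ambiguous class
  expect_true(all(dat$capture[dat$age_class > 0L] == 1L))
  expect_true(all(dat$age_class != 3L))
})

test_that("capture frequency of alive unmarked females matches p_cap", {
  cfg <- recovery_config(31, T = 8)
  cfg$params$b0_cap <- qlogis(0.6); cfg$params$b1_cap <- 0
  truth <- simulate_population(cfg)
  ## replicated observation processes at a fixed truth: every alive year up
  ## to and including first capture is a capture attempt with p_cap = 0.6
  p_hat_num <- p_hat_den <- 0
  for (r in 1:2000) {
    cfg$seed <- 5000 + r
    dat <- simulate_observations(truth, cfg)
    rows <- attr(dat, "truth_rows")
    marked_full <- matrix(0L, truth$M, cfg$T)
    marked_full[rows, ] <- dat$marked[seq_along(rows), ]
    p_hat_num <- p_hat_num + sum(dat$capture)
    p_hat_den <- p_hat_den + sum(truth$z * (1 - marked_full)) +
      sum(dat$capture)
  }
  p_hat <- p_hat_num / p_hat_den
  se <- sqrt(0.6 * 0.4 / p_hat_den)
  expect_lt(abs(p_hat - 0.6), 4 * se)
})

test_that("observed detections never exceed true abundance", {
  for (s in 1:10) {
    cfg <- recovery_config(40 + s, T = 10)
    truth <- simulate_population(cfg)
    dat <- simulate_observations(truth, cfg)
    marked_detected <- colSums(dat$resight == 1L)
    expect_true(all(dat$u + marked_detected <= truth$N))
  }
})

test_that("single-day surveys degrade detection multiplicatively", {
  p <- model_params(b0_cap = qlogis(0.9), k = 1, p_eta = 0.61, p_r = 0.5,
                    b0_phi_sy = 745, b0_phi_asy = 745, b0_gam = -745)
  cfg <- sim_config(T = 4, M = 60, area = 10, EN1 = 30, params = p,
                    single_day_years = 2005, seed = 3)
  truth <- simulate_population(cfg)
  tot <- c(normal = 0, single = 0); alive <- c(normal = 0, single = 0)
  for (r in 1:1500) {
    cfg$seed <- r
    dat <- simulate_observations(truth, cfg)
    rows <- attr(dat, "truth_rows")
    for (t in 1:4) {
      lab <- if (cfg$years[t] == 2005) "single" else "normal"
      idx <- dat$marked[seq_along(rows), t] == 1L & truth$z[rows, t] == 1L
      tot[lab] <- tot[lab] + sum(dat$resight[seq_along(rows), t][idx])
      alive[lab] <- alive[lab] + sum(idx)
    }
  }
  rate <- tot / alive
  expect_lt(abs(rate[["normal"]] - 0.61), 4 * sqrt(0.61 * 0.39 / alive[["normal"]]))
  expect_lt(abs(rate[["single"]] - 0.61 * 0.5),
            4 * sqrt(0.305 * 0.695 / alive[["single"]]))
})
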