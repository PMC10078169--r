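test_that("recruitment rate evaluates the density-dependent logistic", {
  expect_equal(recruitment_rate(model_params(alpha = 1), w = 0, ED = 0), 0.5)
  p <- model_params(alpha = 1.5, b0_gam = 0.2, b1_gam = 0.3, b2_gam = 0.1)
  expect_equal(recruitment_rate(p, w = 1, ED = 2), 1.5 / (1 + exp(-0.1)),
               tolerance = 1e-12)
  ## bounded by alpha, strictly decreasing in density when b2 > 0
  ed <- seq(0, 5, by = 0.5)
  g <- recruitment_rate(p, w = 1, ED = ed)
  expect_true(all(g > 0 & g < p$alpha))
  expect_true(all(diff(g) < 0))
  ## linear density term selectable
  p1 <- model_params(alpha = 1, b2_gam = 0.5, dd_power = 1)
  expect_equal(recruitment_rate(p1, 0, ED = 2), plogis(-1))
})

test_that("survival probability is a shared-trend logit model", {
  expect_equal(survival_probability(model_params(), "SY", w = 0), 0.5)
  p <- model_params(b0_phi_asy = 0.5, b1_phi = -0.4)
  expect_equal(survival_probability(p, "ASY", w = 1), plogis(0.1),
               tolerance = 1e-12)
  w <- seq(-2, 2, by = 0.5)
  expect_true(all(diff(survival_probability(p, "ASY", w)) < 0))
  ## age classes share the trend, differ in intercept
  p2 <- model_params(b0_phi_sy = -0.3, b0_phi_asy = 0.5, b1_phi = -0.4)
  d <- qlogis(survival_probability(p2, "ASY", w)) -
       qlogis(survival_probability(p2, "SY", w))
  expect_equal(d, rep(0.8, length(w)), tolerance = 1e-12)
})

test_that("entry probabilities follow the realized-abundance convention", {
  ## hand evaluation: n1 = 2, n2 = 3, gamma_1 = 0.2, M = 10 -> pi_2 = 0.1
  p <- model_params(alpha = 1, pi1 = 0.3, b0_gam = qlogis(0.2))
  pi <- entry_probabilities(p, n1 = c(2, 0), n2 = c(3, 0), area = 1e9, M = 10)
  expect_equal(pi[2], 0.1, tolerance = 1e-12)
  expect_equal(sum(pi), 1, tolerance = 1e-12)

  ## no recruitment: all later entry probabilities vanish
  p0 <- model_params(alpha = 1e-300, pi1 = 0.4)
  pi0 <- entry_probabilities(p0, n1 = c(5, 5, 5), n2 = c(0, 0, 0),
                             area = 10, M = 50)
  expect_equal(pi0[2:3], c(0, 0), tolerance = 1e-300)
  expect_equal(pi0[4], 0.6)

  ## normalization holds for arbitrary valid inputs
  set.seed(1)
  for (r in 1:20) {
    T <- sample(3:8, 1)
    p <- model_params(alpha = runif(1, 0.5, 2), b0_gam = rnorm(1),
                      b1_gam = rnorm(1, 0, 0.3), b2_gam = runif(1),
                      pi1 = runif(1, 0, 0.3), w = rnorm(T))
    pi <- entry_probabilities(p, n1 = rpois(T, 5), n2 = rpois(T, 5),
                              area = 20, M = 500)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
  }
})

test_that("latent density rejects impossible states and normalizes", {
  T <- 2; area <- 2
  pars <- toy_params(T)
  ## alive before entry
  bad <- augmented_state(b = c(2, 3), a1 = c(0, 0),
                         z = rbind(c(1L, 1L), c(0L, 0L)), area = area)
  expect_identical(latent_log_density(pars, bad), -Inf)
  ## dead in the entry year
  bad2 <- augmented_state(b = c(1, 3), a1 = c(0, 0),
                          z = rbind(c(0L, 0L), c(0L, 0L)), area = area)
  expect_identical(latent_log_density(pars, bad2), -Inf)

  ## exhaustive enumeration sums to one (M = 2, T = 2)
  cfgs <- latent_configs(T)
  tot <- 0
  for (c1 in cfgs) for (c2 in cfgs) {
    st <- state_from_configs(list(c1, c2), T, area)
    lp <- latent_log_density(pars, st)
    if (is.finite(lp)) tot <- tot + exp(lp)
  }
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("survival contributes nothing when apparent survival is one", {
  T <- 3
  pars <- toy_params(T)
  pars$b0_phi_sy <- pars$b0_phi_asy <- 745   # phi = 1 up to rounding
  pars$b1_phi <- 0
  st_live <- augmented_state(b = 1, a1 = 0, z = matrix(1L, 1, T), area = 1)
  st_enter_only <- augmented_state(b = 3, a1 = 0,
                                   z = matrix(c(0L, 0L, 1L), 1), area = 1)
  ## same entry-year probability structure: the difference of densities is
  ## exactly the entry-term difference, with zero survival contribution
  lp_live <- latent_log_density(pars, st_live)
  expect_true(is.finite(lp_live))
  expect_equal(lp_live, log(pars$pi1) + log(1 - pars$tau), tolerance = 1e-9)
})

test_that("observation density matches hand-computed capture terms", {
  T <- 2; area <- 2
  pars <- toy_params(T)
  pars$b0_cap <- qlogis(0.4); pars$b1_cap <- 0; pars$k <- 0.7
  st <- augmented_state(b = c(1, 3), a1 = c(0, 0),
                        z = rbind(c(1L, 1L), c(0L, 0L)), area = area)
  ## SY-aged capture in year 1, resighted both years, no unmarked counts
  dat <- encounter_data(capture = rbind(c(1L, 0L), c(0L, 0L)),
                        age_class = rbind(c(1L, 0L), c(0L, 0L)),
                        resight = rbind(c(1L, 1L), c(0L, 0L)),
                        u = c(0L, 0L), years = 1:2, area = area)
  lp <- observation_log_density(pars, st, dat)
  expect_equal(lp, log(0.4 * 0.7) + 2 * log(pars$p_eta), tolerance = 1e-12)

  ## perfect resighting forces y = z: a missed resight is impossible
  pars2 <- pars; pars2$p_eta <- 1
  dat2 <- encounter_data(capture = rbind(c(1L, 0L), c(0L, 0L)),
                         age_class = rbind(c(1L, 0L), c(0L, 0L)),
                         resight = rbind(c(1L, 0L), c(0L, 0L)),
                         u = c(0L, 0L), years = 1:2, area = area)
  expect_identical(observation_log_density(pars2, st, dat2), -Inf)

  ## counts exceeding the available unmarked females are impossible
  dat3 <- encounter_data(capture = rbind(c(1L, 0L), c(0L, 0L)),
                         age_class = rbind(c(1L, 0L), c(0L, 0L)),
                         resight = rbind(c(1L, 1L), c(0L, 0L)),
                         u = c(5L, 0L), years = 1:2, area = area)
  expect_identical(observation_log_density(pars, st, dat3), -Inf)
})

test_that("observation density normalizes over all data outcomes", {
  T <- 2; area <- 2
  pars <- toy_params(T)
  st <- state_from_configs(list(c(1, 3, 0), c(2, 3, 0)), T, area)
  opts <- obs_options_T2()
  datasets <- list()
  for (o1 in opts) for (o2 in opts) for (u1 in 0:2) for (u2 in 0:2)
    datasets[[length(datasets) + 1L]] <-
      encounter_data(rbind(o1$cap, o2$cap), rbind(o1$ac, o2$ac),
                     rbind(o1$y, o2$y), u = c(u1, u2), years = 1:2,
                     area = area, single_day = c(FALSE, TRUE))
  tot <- 0
  for (dat in datasets) {
    lp <- observation_log_density(pars, st, dat)
    if (is.finite(lp)) tot <- tot + exp(lp)
  }
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("covariate measurement density is a Gaussian in the latent value", {
  p <- model_params(w = 16.1)
  est <- data.frame(mu = 16.1, sigma = 0.9)
  expect_equal(covariate_log_density(p, est), dnorm(16.1, 16.1, 0.9, log = TRUE))
  expect_equal(covariate_log_density(p, est), -log(0.9 * sqrt(2 * pi)),
               tolerance = 1e-12)
  ## location invariance
  p2 <- model_params(w = c(1, 2) + 5)
  e1 <- data.frame(mu = c(1.3, 1.8), sigma = c(0.5, 0.7))
  e2 <- e1; e2$mu <- e2$mu + 5
  expect_equal(covariate_log_density(model_params(w = c(1, 2)), e1),
               covariate_log_density(p2, e2), tolerance = 1e-12)
  expect_error(covariate_log_density(p, data.frame(mu = 1, sigma = 0)),
               "sigma")
  ## a vanishing sigma pins the latent value to the estimate
  lp_near <- covariate_log_density(model_params(w = 16.1001),
                                   data.frame(mu = 16.1, sigma = 1e-4))
  lp_far <- covariate_log_density(model_params(w = 16.2),
                                  data.frame(mu = 16.1, sigma = 1e-4))
  expect_gt(lp_near - lp_far, 1e5)
})

test_that("prior density: moment-matched Beta, support constraints", {
  sh <- beta_moment_match(0.61, 0.27)
  expect_equal(unname(sh["shape1"]), 1.380, tolerance = 1e-3)
  expect_equal(unname(sh["shape2"]), 0.883, tolerance = 1e-3)
  ## the matched Beta reproduces the target moments
  expect_equal(sh[["shape1"]] / sum(sh), 0.61, tolerance = 1e-12)
  v <- prod(sh) / (sum(sh)^2 * (sum(sh) + 1))
  expect_equal(sqrt(v), 0.27, tolerance = 1e-12)

  p <- toy_params()
  expect_true(is.finite(prior_log_density(p)))
  p_bad <- p; p_bad$b2_gam <- -0.1
  expect_identical(prior_log_density(p_bad), -Inf)
  p_bad2 <- p; p_bad2$alpha <- -1
  expect_identical(prior_log_density(p_bad2), -Inf)
})

test_that("with zero trend coefficients the covariate values are inert", {
  T <- 3; area <- 2
  pars <- toy_params(T)
  pars$b1_gam <- 0; pars$b1_phi <- 0
  st <- state_from_configs(list(c(1, 4, 0), c(2, 3, 0), c(4, 4, 0)), T, area)
  pars_t <- pars; pars_t$w <- jsclimate:::scale_years(T)      # time variant
  pars_c <- pars; pars_c$w <- c(1.7, -0.4, 0.9)               # climate values
  expect_equal(latent_log_density(pars_t, st), latent_log_density(pars_c, st),
               tolerance = 1e-12)
})
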