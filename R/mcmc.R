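#' MCMC settings
#'
#' Defaults mirror the reference analysis (3 chains, 1,000 adaptation
#' iterations, 35,000 kept samples per chain).  Reduced profiles
#' (e.g. `iter = 2000, adapt = 500`) are appropriate for simulation studies
#' and tests.
#'
#' @param chains Number of chains.
#' @param iter Kept iterations per chain.
#' @param adapt Adaptation (burn-in) iterations per chain, discarded.
#' @param seed Integer seed; chain `c` uses `seed + 1000 * (c - 1)`.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3, iter = 35000, adapt = 1000, seed = 1) {
  stopifnot(chains >= 1, iter >= 1, adapt >= 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 adapt = as.integer(adapt), seed = as.integer(seed)),
            class = "mcmc_settings")
}

par_layout <- function(T, variant) {
  nm <- c("alpha", "b0_gam", "b1_gam1", "b1_gam2", "b2_gam",
          "b0_phi_sy", "b0_phi_asy", "b1_phi1", "b1_phi2",
          "b0_cap", "b1_cap", "k", "tau", "p_eta", "p_r", "pi1")
  if (variant == 1) nm <- c(nm, paste0("w[", seq_len(T), "]"))
  c(nm, paste0("n1[", seq_len(T), "]"), paste0("n2[", seq_len(T), "]"),
    paste0("N[", seq_len(T), "]"))
}

## overdispersed but moderate starting values; the recruitment block starts
## small so that the entry probabilities of a large augmented population
## cannot exceed 1 at initialization
draw_init_params <- function(T, priors) {
  list(theta = c(alpha = 0.5 + abs(rnorm(1, 0, 0.3)),
                 b0_gam = rnorm(1, -2, 0.5), b1_gam1 = rnorm(1, 0, 0.2),
                 b1_gam2 = rnorm(1, 0, 0.2), b2_gam = abs(rnorm(1, 0, 0.1)),
                 b0_phi_sy = rnorm(1, 0, 0.5), b0_phi_asy = rnorm(1, 0, 0.5),
                 b1_phi1 = rnorm(1, 0, 0.3), b1_phi2 = rnorm(1, 0, 0.3),
                 b0_cap = rnorm(1, 0.5, 0.5), b1_cap = rnorm(1, 0, 0.3),
                 k = runif(1, 0.3, 0.9), tau = runif(1, 0.3, 0.7),
                 p_eta = runif(1, 0.5, 0.95),
                 p_r = rbeta(1, priors$pr_shape1, priors$pr_shape2),
                 pi1 = runif(1, 0.02, 0.2)))
}

init_latent <- function(data) {
  M <- data$M; T <- length(data$years)
  f <- apply(data$capture, 1L, function(x) {
    i <- which(x == 1L); if (length(i)) i[1] else 0L })
  l <- apply(data$capture == 1L | data$resight == 1L, 1L, function(x) {
    i <- which(x); if (length(i)) i[length(i)] else 0L })
  b <- rep.int(T + 1L, M); d <- rep.int(T + 1L, M); a1 <- integer(M)
  obs <- which(f > 0L)
  ## entry at first detection (one year earlier for ASY-aged captures, whose
  ## latent age says they entered before the capture year), death right
  ## after the last detection
  b[obs] <- f[obs]
  asy <- obs[data$age_class[cbind(obs, f[obs])] == 2L]
  b[asy] <- pmax(1L, f[asy] - 1L)
  a1[obs] <- as.integer(data$age_class[cbind(obs, f[obs])] == 2L)
  d[obs] <- pmin(l[obs] + 1L, T + 1L)
  ## alive pseudo-individuals so that every year has positive abundance and
  ## the unmarked counts are feasible
  U_obs <- integer(T)
  for (i in obs) if (b[i] < f[i]) {
    ts <- seq.int(b[i], f[i] - 1L)
    U_obs[ts] <- U_obs[ts] + 1L
  }
  aug <- setdiff(seq_len(M), obs)
  need <- min(max(max(data$u - U_obs) + 2L, 3L), length(aug))
  if (max(data$u - U_obs) > length(aug))
    stop("unmarked counts exceed the augmentation bound; increase M")
  take <- aug[seq_len(need)]
  b[take] <- 1L
  a1[take] <- rbinom(length(take), 1L, 0.5)
  list(b = b, d = d, a1 = a1)
}

#' Fit the integrated Jolly-Seber model by MCMC
#'
#' Samples the joint posterior of the data-augmented Jolly-Seber
#' capture-resight + count model using a Metropolis-within-Gibbs sampler:
#' exact categorical Gibbs draws of every augmented individual's latent
#' trajectory (entry year, death year, first-year age) and adaptive
#' random-walk Metropolis updates of the continuous parameters (and, for
#' climate variants, the latent true covariate values).
#'
#' Climate covariates are centered and scaled (to SD 1) before entering the
#' logit-linear predictors; for the "time" variant the covariate is the
#' centered/scaled year index.  Runs are deterministic given the settings
#' seed.
#'
#' @param data An [encounter_data()].
#' @param covariates For climate variants, a data frame with columns
#'   `year`, `mu`, `sigma` (plot-level covariate estimates in raw units)
#'   covering every study year; ignored for the "time" variant.
#' @param trend A [trend_spec()].
#' @param settings An [mcmc_settings()].
#' @param priors A [prior_spec()].
#' @param init_params Optional [model_params()] fixing the initial (or, with
#'   `fix_params = TRUE`, the permanent) parameter values.
#' @param fix_params If `TRUE`, parameters are held at `init_params` and only
#'   latent states are sampled (used for validation against enumeration).
#' @param record_entry If `TRUE`, per-draw entry years of every augmented
#'   individual are stored (memory-heavy; for toy validation).
#' @param scaling Optional `list(center, scale)` overriding the covariate
#'   standardization.
#' @param dd_power Power on density in the recruitment function (default 2).
#' @param param_passes Parameter-update passes per latent sweep (the
#'   parameter updates are cheap relative to the latent sweep, and the
#'   recruitment block needs the extra movement).
#' @param fix_latent If `TRUE`, the latent states are held at their initial
#'   values and only parameters are sampled (validation use).
#' @param init_state Optional list with elements `b`, `d`, `a1` overriding
#'   the data-driven latent initialization.
#' @return An object of class `js_posterior`.
#' @export
run_mcmc <- function(data, covariates = NULL, trend = trend_spec("time"),
                     settings = mcmc_settings(), priors = prior_spec(),
                     init_params = NULL, fix_params = FALSE,
                     record_entry = FALSE, scaling = NULL, dd_power = 2,
                     param_passes = 10, fix_latent = FALSE,
                     init_state = NULL) {
  stopifnot(inherits(data, "encounter_data"), inherits(trend, "trend_spec"))
  T <- length(data$years); M <- data$M
  if (T < 2) stop("need at least 2 study years")
  variant <- if (trend$variant == "time") 0L else 1L
  period <- trend_periods(trend, data$years) - 1L   # 0-based for C++
  ncp <- if (is.null(trend$changepoint)) 1L else 2L
  syear <- scale_years(T)

  if (variant == 1L) {
    if (is.null(covariates))
      stop("climate variants require plot-level covariate estimates")
    idx <- match(data$years, covariates$year)
    if (anyNA(idx))
      stop("covariate estimates missing for year(s) ",
           paste(data$years[is.na(idx)], collapse = ", "))
    mu_raw <- covariates$mu[idx]; sig_raw <- covariates$sigma[idx]
    if (any(sig_raw <= 0)) stop("sigma must be positive")
    scaling <- scaling %||% list(center = mean(mu_raw), scale = sd(mu_raw))
    mu_s <- (mu_raw - scaling$center) / scaling$scale
    sig_s <- sig_raw / scaling$scale
  } else {
    scaling <- scaling %||% list(center = mean(seq_len(T)),
                                 scale = sd(seq_len(T)))
    mu_s <- numeric(0); sig_s <- numeric(0)
  }

  covs <- list(variant = variant, period = as.integer(period),
               ncp = ncp, dd_power = as.integer(dd_power),
               mu = mu_s, sigma = sig_s, syear = syear)
  cdata <- list(capture = data$capture, age_class = data$age_class,
                resight = data$resight, u = data$u,
                single_day = data$single_day, area = data$area)

  theta_from_params <- function(p) {
    c(p$alpha, p$b0_gam, p$b1_gam[1], p$b1_gam[min(2, length(p$b1_gam))],
      p$b2_gam, p$b0_phi_sy, p$b0_phi_asy,
      p$b1_phi[1], p$b1_phi[min(2, length(p$b1_phi))],
      p$b0_cap, p$b1_cap, p$k, p$tau, p$p_eta, p$p_r, p$pi1)
  }

  chains <- vector("list", settings$chains)
  b_draws <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    set.seed(settings$seed + 1000L * (ch - 1L))
    res <- NULL
    for (attempt in seq_len(100L)) {
      theta <- if (!is.null(init_params)) theta_from_params(init_params)
               else unname(draw_init_params(T, priors)$theta)
      lat <- init_state %||% init_latent(data)
      w0 <- if (variant == 1L) mu_s else syear
      init <- list(theta = theta, w = w0, b = lat$b, d = lat$d, a1 = lat$a1)
      res <- tryCatch(
        cpp_js_chain(cdata, covs, unclass(priors), init,
                     settings$adapt, settings$iter,
                     fix_params, record_entry, as.integer(param_passes),
                     fix_latent),
        error = function(e) {
          if (grepl("non-finite joint density", conditionMessage(e)) &&
              is.null(init_params)) NULL else stop(e)
        })
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop("could not find a finite starting point after 100 attempts")
    dr <- res$draws
    colnames(dr) <- par_layout(T, variant)
    if (ncp == 1L) dr <- dr[, setdiff(colnames(dr), c("b1_gam2", "b1_phi2")),
                            drop = FALSE]
    cn <- colnames(dr)
    cn[cn == "b1_gam1"] <- if (ncp == 1L) "b1_gam" else "b1_gam_pre"
    cn[cn == "b1_phi1"] <- if (ncp == 1L) "b1_phi" else "b1_phi_pre"
    cn[cn == "b1_gam2"] <- "b1_gam_post"
    cn[cn == "b1_phi2"] <- "b1_phi_post"
    colnames(dr) <- cn
    chains[[ch]] <- dr
    if (record_entry) b_draws[[ch]] <- res$b_draws
  }

  structure(list(chains = chains, settings = settings, trend = trend,
                 priors = priors, years = data$years, T = T, M = M,
                 area = data$area, variant = variant, scaling = scaling,
                 dd_power = dd_power, plot_id = data$plot_id,
                 b_draws = if (record_entry) b_draws else NULL),
            class = "js_posterior")
}

#' @export
print.js_posterior <- function(x, ...) {
  cat("Posterior samples: integrated Jolly-Seber model (plot", x$plot_id,
      ")\n")
  cat("  trend variant:", x$trend$variant,
      if (!is.null(x$trend$changepoint))
        paste0("(changepoint ", x$trend$changepoint, ")") else "", "\n")
  cat("  chains:", length(x$chains), "x", nrow(x$chains[[1]]),
      "kept draws;", "M =", x$M, "; years",
      min(x$years), "-", max(x$years), "\n")
  invisible(x)
}

#' Stack all chains into one draw matrix
#'
#' @param samples A `js_posterior`.
#' @return Numeric matrix (draws x parameters).
#' @export
posterior_matrix <- function(samples) {
  do.call(rbind, samples$chains)
}
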