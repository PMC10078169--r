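#' Per-capita recruitment rate
#'
#' Logistic recruitment with negative density dependence,
#' `gamma = alpha / (1 + exp(-(b0 + b1 * w - b2 * ED^dd_power)))`, bounded in
#' `(0, alpha)`.
#'
#' @param params A [model_params()] object.
#' @param w Covariate value (centered/scaled units).
#' @param ED Female density (females/ha), `>= 0`.
#' @param period Changepoint period selecting which trend coefficient
#'   applies (1 or 2).
#' @return Recruitment rate(s), same length as the longest argument.
#' @examples
#' recruitment_rate(model_params(alpha = 1), w = 0, ED = 0)  # 0.5
#' @export
recruitment_rate <- function(params, w, ED, period = 1L) {
  stopifnot(all(ED >= 0))
  b1 <- params$b1_gam[pmin(period, length(params$b1_gam))]
  eta <- params$b0_gam + b1 * w - params$b2_gam * ED^params$dd_power
  params$alpha * plogis(eta)
}

#' Age-specific apparent survival probability
#'
#' `logit(phi_j) = b0_j + b1 * w`; SY and ASY females share the trend
#' coefficient and differ in the intercept.
#'
#' @inheritParams recruitment_rate
#' @param age `"SY"` or `"ASY"` (or 0/1).
#' @return Survival probability/ies.
#' @export
survival_probability <- function(params, age, w, period = 1L) {
  if (is.character(age)) age <- match.arg(age, c("SY", "ASY"))
  b0 <- if (identical(age, "SY") || identical(age, 0) || identical(age, 0L))
    params$b0_phi_sy else params$b0_phi_asy
  b1 <- params$b1_phi[pmin(period, length(params$b1_phi))]
  plogis(b0 + b1 * w)
}

#' Entry probabilities of the data-augmented Jolly-Seber model
#'
#' First-year entry is the free parameter `pi1`; entry in later years follows
#' the realized-abundance convention
#' `pi_t = (n1_{t-1} + n2_{t-1}) * gamma_{t-1} / M`, and
#' `pi_{T+1} = 1 - sum(pi_{1..T})` is the probability of never entering.
#'
#' The returned vector is a valid probability distribution only when
#' `sum(pi_{1..T}) <= 1`; otherwise the final element is negative, which
#' marks an invalid parameter/state combination (the joint density treats it
#' as `-Inf` rather than raising an error).
#'
#' @param params A [model_params()] (supplying `pi1` and the recruitment
#'   parameters; `params$w` supplies the covariate values).
#' @param n1,n2 Realized SY and ASY abundances per year (length `T`).
#' @param area Plot area (ha), used for the density term.
#' @param M Augmentation bound.
#' @param period Changepoint period per year (length `T`).
#' @return Numeric vector of length `T + 1`.
#' @examples
#' p <- model_params(pi1 = 0.3, b0_gam = qlogis(0.2))  # gamma = 0.2
#' entry_probabilities(p, n1 = c(2, 0), n2 = c(3, 0), area = 1, M = 10)
#' @export
entry_probabilities <- function(params, n1, n2, area, M,
                                period = rep(1L, length(n1))) {
  T <- length(n1)
  stopifnot(length(n2) == T, M > 0)
  w <- params$w %||% rep(0, T)
  N <- n1 + n2
  pi <- numeric(T + 1)
  pi[1] <- params$pi1
  if (T > 1) {
    t0 <- seq_len(T - 1)
    gam <- recruitment_rate(params, w[t0], N[t0] / area, period[t0])
    pi[t0 + 1] <- N[t0] * gam / M
  }
  pi[T + 1] <- 1 - sum(pi[seq_len(T)])
  pi
}

ages_from_entry <- function(b, a1, T) {
  M <- length(b)
  a <- matrix(1L, M, T)
  ent <- which(b >= 2 & b <= T)
  a[cbind(ent, b[ent])] <- 0L
  a[b == 1, 1] <- as.integer(a1[b == 1])
  a
}

#' Augmented latent state
#'
#' @param b Entry year per augmented individual (`T + 1` = never enters).
#' @param a1 First-year age indicator (0 = SY, 1 = ASY); used only for
#'   individuals with `b = 1`.
#' @param z Alive-state matrix (`M x T`).
#' @param area Plot area (ha).
#' @return An object of class `augmented_state` with derived yearly
#'   abundances `N`, `n1` (SY), `n2` (ASY).
#' @export
augmented_state <- function(b, a1, z, area) {
  z <- as.matrix(z); storage.mode(z) <- "integer"
  T <- ncol(z)
  stopifnot(length(b) == nrow(z), length(a1) == nrow(z), area > 0,
            all(b >= 1), all(b <= T + 1))
  a <- ages_from_entry(b, a1, T)
  structure(list(b = as.integer(b), a1 = as.integer(a1), z = z, a = a,
                 n1 = colSums(z * (a == 0L)), n2 = colSums(z * (a == 1L)),
                 N = colSums(z), area = area),
            class = "augmented_state")
}

#' Log-density of the latent demographic process
#'
#' Sums the categorical entry-year terms (with entry probabilities computed
#' from the realized abundances of the state itself), the Bernoulli
#' first-year age terms, and the Bernoulli survival transitions.  States that
#' violate the model's deterministic constraints (alive before entry, dead at
#' entry, entry probabilities exceeding 1) have density `-Inf` rather than
#' raising an error.
#'
#' @param params A [model_params()] with `params$w` of length `T`.
#' @param state An [augmented_state()].
#' @param period Changepoint period per year (default: no changepoint).
#' @return Log probability (possibly `-Inf`).
#' @export
latent_log_density <- function(params, state, period = NULL) {
  z <- state$z; b <- state$b; a <- state$a
  M <- nrow(z); T <- ncol(z)
  period <- period %||% rep(1L, T)
  w <- params$w %||% rep(0, T)
  stopifnot(length(w) == T, length(period) == T)

  ## deterministic structure: z = 0 before entry, z = 1 at entry
  for (i in seq_len(M)) {
    if (b[i] <= T) {
      if (b[i] > 1 && any(z[i, seq_len(b[i] - 1)] != 0L)) return(-Inf)
      if (z[i, b[i]] != 1L) return(-Inf)
    } else if (any(z[i, ] != 0L)) return(-Inf)
  }

  pi <- entry_probabilities(params, state$n1, state$n2, state$area, M, period)
  if (pi[T + 1] < 0) return(-Inf)
  lp_entry <- log(pi[b])                      # log(0) = -Inf when impossible
  lp <- sum(lp_entry)
  if (!is.finite(lp)) return(-Inf)

  first <- b == 1
  lp <- lp + sum(dbinom(state$a1[first], 1, params$tau, log = TRUE))

  ## survival transitions (t -> t+1) use the age at t
  for (i in seq_len(M)) {
    if (b[i] > T) next
    if (b[i] < T) {
      for (t in seq(b[i], T - 1)) {
        phi <- survival_probability(params, a[i, t], w[t], period[t])
        p <- z[i, t] * phi
        lp <- lp + dbinom(z[i, t + 1], 1, p, log = TRUE)
        if (!is.finite(lp)) return(-Inf)
      }
    }
  }
  lp
}

#' Log-density of the observation process
#'
#' Capture terms for alive unmarked females (with the age-classification
#' split `k` / `1 - k`), resight terms for marked females, and Binomial
#' count terms for unmarked females, with the single-day detection
#' probability applied where flagged.  Data/state combinations that are
#' impossible under the model (capture or resight of a dead female, an
#' age classification contradicting the latent age, counts exceeding the
#' number of alive unmarked females) have density `-Inf`.
#'
#' @param params A [model_params()].
#' @param state An [augmented_state()] consistent with `data` (same `M`, `T`).
#' @param data An [encounter_data()].
#' @return Log probability (possibly `-Inf`).
#' @export
observation_log_density <- function(params, state, data) {
  z <- state$z; a <- state$a
  M <- nrow(z); T <- ncol(z)
  stopifnot(data$M == M, length(data$years) == T)
  s <- scale_years(T)
  p_cap <- plogis(params$b0_cap + params$b1_cap * s)
  p_det <- params$p_eta * ifelse(data$single_day, params$p_r, 1)

  lp <- 0
  for (i in seq_len(M)) {
    for (t in seq_len(T)) {
      ## capture process: runs while the female has not yet been marked; the
      ## first-capture year carries both the capture term and (once marked)
      ## the resight term below
      if (data$capture[i, t] == 1L) {
        pc <- z[i, t] * p_cap[t]
        ac <- data$age_class[i, t]
        if (ac == 1L) {                        # aged SY: latent age must be SY
          if (z[i, t] == 0L || a[i, t] != 0L) return(-Inf)
          lp <- lp + log(pc * params$k)
        } else if (ac == 2L) {                 # aged ASY
          if (z[i, t] == 0L || a[i, t] != 1L) return(-Inf)
          lp <- lp + log(pc * params$k)
        } else {                               # AHY: ambiguous
          if (z[i, t] == 0L) return(-Inf)
          lp <- lp + log(pc * (1 - params$k))
        }
      } else if (data$marked[i, t] == 0L) {
        if (z[i, t] == 1L) lp <- lp + log(1 - p_cap[t])
      }
      ## resight process: runs from the first capture year onward
      if (data$marked[i, t] == 1L) {
        p <- z[i, t] * p_det[t]
        lp <- lp + dbinom(data$resight[i, t], 1, p, log = TRUE)
      }
      if (!is.finite(lp)) return(-Inf)
    }
  }
  U <- colSums(z * (data$marked == 0L))
  for (t in seq_len(T)) {
    if (data$u[t] > U[t]) return(-Inf)
    lp <- lp + dbinom(data$u[t], U[t], p_det[t], log = TRUE)
  }
  lp
}

#' Log-density of the climate-covariate measurement model
#'
#' `mu_t ~ Normal(w_t, sigma_t)`: the predicted plot-level covariate mean is
#' a noisy measurement of the latent true covariate.  Absent for the "time"
#' variant.
#'
#' @param params A [model_params()] with `params$w` of length `nrow(estimates)`.
#' @param estimates Data frame with columns `mu` and `sigma` (one row per
#'   modeled year), on the same (scaled) units as `params$w`.
#' @return Log probability.
#' @export
covariate_log_density <- function(params, estimates) {
  stopifnot(all(c("mu", "sigma") %in% names(estimates)))
  if (any(estimates$sigma <= 0)) stop("sigma must be positive")
  w <- params$w
  stopifnot(length(w) == nrow(estimates))
  sum(dnorm(estimates$mu, w, estimates$sigma, log = TRUE))
}

#' Log-density of the prior
#'
#' @param params A [model_params()].
#' @param priors A [prior_spec()].
#' @param include_w Whether to include the Gaussian prior on the latent
#'   covariate values (climate variants).
#' @return Log prior density (`-Inf` outside the support).
#' @export
prior_log_density <- function(params, priors = prior_spec(),
                              include_w = !is.null(params$w)) {
  if (params$alpha <= 0 || params$b2_gam < 0) return(-Inf)
  for (p in c(params$k, params$tau, params$p_eta, params$p_r, params$pi1)) {
    if (p < 0 || p > 1) return(-Inf)
  }
  betas <- c(params$b0_gam, params$b1_gam, params$b0_phi_sy,
             params$b0_phi_asy, params$b1_phi, params$b0_cap, params$b1_cap)
  lp <- sum(dnorm(betas, 0, priors$sd_beta, log = TRUE)) +
    dnorm(params$b2_gam, 0, priors$sd_b2, log = TRUE) + log(2) +
    dexp(params$alpha, priors$rate_alpha, log = TRUE) +
    dbeta(params$p_r, priors$pr_shape1, priors$pr_shape2, log = TRUE)
  if (include_w && !is.null(params$w))
    lp <- lp + sum(dnorm(params$w, 0, priors$sd_w, log = TRUE))
  lp
}

#' Joint log-density of the integrated model
#'
#' Latent + observation + (for climate variants) covariate measurement +
#' prior terms; the quantity the MCMC sampler targets.
#'
#' @inheritParams observation_log_density
#' @param estimates Plot-level covariate estimates (`mu`, `sigma`) on the
#'   model's scaled units, or `NULL` for the "time" variant.
#' @param priors A [prior_spec()].
#' @param period Changepoint period per year.
#' @return Log probability (possibly `-Inf`).
#' @export
joint_log_density <- function(params, state, data, estimates = NULL,
                              priors = prior_spec(), period = NULL) {
  lp <- prior_log_density(params, priors, include_w = !is.null(estimates))
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + latent_log_density(params, state, period)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + observation_log_density(params, state, data)
  if (!is.finite(lp)) return(-Inf)
  if (!is.null(estimates)) lp <- lp + covariate_log_density(params, estimates)
  lp
}
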