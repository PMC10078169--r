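#' Demographic and observation parameters for the integrated Jolly-Seber model
#'
#' Bundles one draw (or one configuration) of every parameter of the
#' data-augmented Jolly-Seber capture-resight + count model: per-capita
#' recruitment with negative density dependence, age-specific apparent
#' survival, time-varying capture probability, age-classification and
#' resight/detection probabilities, the first-year entry probability, and the
#' latent true covariate values for climate variants.
#'
#' The trend coefficients `b1_gam` and `b1_phi` may have length 2, in which
#' case the first element applies to years before a changepoint and the
#' second to years at/after it (see [trend_spec()]).
#'
#' @param alpha Upper bound on the per-capita recruitment rate (> 0).
#' @param b0_gam,b1_gam,b2_gam Recruitment intercept, covariate-trend
#'   coefficient(s), and density-dependence coefficient (`b2_gam >= 0`; the
#'   prior only admits negative density dependence).
#' @param b0_phi_sy,b0_phi_asy Apparent-survival intercepts (logit scale) for
#'   second-year (SY) and after-second-year (ASY) females.
#' @param b1_phi Covariate-trend coefficient(s) on apparent survival, shared
#'   between age classes.
#' @param b0_cap,b1_cap Intercept and time-trend (on the centered/scaled year
#'   index) of the capture probability of unmarked females, logit scale.
#' @param k Probability that a captured female is aged to a specific class
#'   (SY/ASY) rather than the ambiguous AHY class.
#' @param tau Probability that a female alive in the first year is ASY.
#' @param p_eta Probability that an alive marked female breeds on (and is
#'   resighted on) the study plot; absorbs temporary emigration.
#' @param p_r Extra detection probability applying in years when the plot was
#'   surveyed on a single day.
#' @param pi1 Entry probability for the first study year.
#' @param w Latent true covariate value per year (centered/scaled units).
#'   For the "time" variant this is the scaled year index.
#' @param dd_power Power on expected density in the recruitment function
#'   (2 by default, i.e. `ED^2`; 1 selects a linear density term).
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(alpha = 1.5, b0_gam = 0.2, b1_gam = 0.3, b2_gam = 0.1)
#' recruitment_rate(p, w = 1, ED = 2)
#' @export
model_params <- function(alpha = 1, b0_gam = 0, b1_gam = 0, b2_gam = 0,
                         b0_phi_sy = 0, b0_phi_asy = 0, b1_phi = 0,
                         b0_cap = 0, b1_cap = 0,
                         k = 0.5, tau = 0.5, p_eta = 0.9, p_r = 0.61,
                         pi1 = 0.1, w = NULL, dd_power = 2) {
  stopifnot(alpha > 0, b2_gam >= 0,
            length(b1_gam) %in% 1:2, length(b1_phi) %in% 1:2,
            dd_power %in% c(1, 2))
  for (p in c(k, tau, p_eta, p_r, pi1)) {
    if (p < 0 || p > 1) stop("probability-type parameters must lie in [0, 1]")
  }
  structure(list(alpha = alpha, b0_gam = b0_gam, b1_gam = b1_gam,
                 b2_gam = b2_gam, b0_phi_sy = b0_phi_sy,
                 b0_phi_asy = b0_phi_asy, b1_phi = b1_phi,
                 b0_cap = b0_cap, b1_cap = b1_cap, k = k, tau = tau,
                 p_eta = p_eta, p_r = p_r, pi1 = pi1, w = w,
                 dd_power = dd_power),
            class = "model_params")
}

#' Trend variant of the demographic model
#'
#' One model fit carries a single trend covariate on recruitment and
#' survival: the year index ("time"), early-breeding temperature, or annual
#' precipitation.  An optional changepoint year splits the trend coefficient
#' into separate values before and at/after the changepoint.
#'
#' @param variant One of `"time"`, `"temperature"`, `"precipitation"`.
#' @param changepoint Optional calendar year at which the trend coefficients
#'   change.
#' @return An object of class `trend_spec`.
#' @export
trend_spec <- function(variant = c("time", "temperature", "precipitation"),
                       changepoint = NULL) {
  variant <- match.arg(variant)
  if (!is.null(changepoint)) stopifnot(is.numeric(changepoint),
                                       length(changepoint) == 1)
  structure(list(variant = variant, changepoint = changepoint),
            class = "trend_spec")
}

#' Map calendar years to changepoint periods
#'
#' @param trend A [trend_spec()].
#' @param years Calendar years.
#' @return Integer vector: 1 before the changepoint, 2 at/after it (all 1
#'   when the trend has no changepoint).
#' @export
trend_periods <- function(trend, years) {
  if (is.null(trend$changepoint)) rep(1L, length(years))
  else 1L + as.integer(years >= trend$changepoint)
}

#' Prior specification
#'
#' Vague Gaussian priors on all regression coefficients, a half-normal on the
#' density-dependence coefficient (restricting it to negative density
#' dependence), an exponential prior on the recruitment bound, Uniform(0, 1)
#' on probability parameters, and a Beta prior on the single-day detection
#' probability moment-matched to a resighting study (mean 0.61, SD 0.27 by
#' default).
#'
#' @param sd_beta SD of the mean-zero Gaussian priors on regression
#'   coefficients.
#' @param sd_b2 Scale of the half-normal prior on the density-dependence
#'   coefficient.  The coefficient multiplies squared density (at most
#'   ~0.4 (females/ha)^2 on these plots), so a scale of 2.5 keeps the
#'   implied density-dependence term weakly informative on the logit scale;
#'   much larger scales effectively assert strong density dependence and
#'   distort the trend coefficient.
#' @param rate_alpha Rate of the exponential prior on the recruitment bound.
#' @param pr_mean,pr_sd Mean and SD to which the Beta prior on the single-day
#'   detection probability is moment-matched.
#' @param sd_w SD of the mean-zero Gaussian prior on the latent true
#'   covariate values (centered/scaled units) in climate variants.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(sd_beta = 10, sd_b2 = 2.5, rate_alpha = 1,
                       pr_mean = 0.61, pr_sd = 0.27, sd_w = 10) {
  sh <- beta_moment_match(pr_mean, pr_sd)
  structure(list(sd_beta = sd_beta, sd_b2 = sd_b2, rate_alpha = rate_alpha,
                 pr_mean = pr_mean, pr_sd = pr_sd,
                 pr_shape1 = sh[["shape1"]], pr_shape2 = sh[["shape2"]],
                 sd_w = sd_w),
            class = "prior_spec")
}

#' Moment-match a Beta distribution
#'
#' Solves `a/(a+b) = mean` and `ab/((a+b)^2 (a+b+1)) = sd^2` for the shape
#' parameters.
#'
#' @param mean,sd Target mean and standard deviation (must satisfy
#'   `sd^2 < mean * (1 - mean)`).
#' @return Named numeric vector `c(shape1, shape2)`.
#' @examples
#' beta_moment_match(0.61, 0.27)
#' @export
beta_moment_match <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) stop("sd too large for a Beta distribution with this mean")
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}
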