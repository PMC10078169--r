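split_chain_halves <- function(chains) {
  out <- list()
  for (x in chains) {
    n <- length(x); h <- n %/% 2L
    out[[length(out) + 1L]] <- x[seq_len(h)]
    out[[length(out) + 1L]] <- x[seq.int(h + 1L, 2L * h)]
  }
  out
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the usual between/within-variance R-hat
#' is computed on the resulting `2 * chains` sequences, so that trends
#' within a chain inflate the diagnostic.
#'
#' @param chains List of numeric vectors (one per chain, equal lengths).
#' @return R-hat, or `NA` for degenerate (zero-variance) draws.
#' @export
split_rhat <- function(chains) {
  stopifnot(length(chains) >= 2)
  halves <- split_chain_halves(chains)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars); B <- n * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat and effective sample size for every scalar parameter and
#' every yearly abundance, with flags for parameters whose R-hat exceeds the
#' threshold and for degenerate (constant) quantities, whose R-hat/ESS are
#' reported as `NA` rather than failing.
#'
#' @param samples A `js_posterior` from [run_mcmc()] (at least two chains).
#' @param rhat_threshold Flag threshold (1.1 by default).
#' @return A data frame with columns `parameter`, `rhat`, `ess`, `flag`.
#' @export
assess_convergence <- function(samples, rhat_threshold = 1.1) {
  if (length(samples$chains) < 2)
    stop("convergence assessment requires at least 2 chains")
  pars <- colnames(samples$chains[[1]])
  out <- data.frame(parameter = pars, rhat = NA_real_, ess = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  for (j in seq_along(pars)) {
    cols <- lapply(samples$chains, function(m) m[, j])
    if (all(vapply(cols, function(x) var(x) == 0, logical(1)))) {
      out$flag[j] <- "degenerate"
      next
    }
    out$rhat[j] <- split_rhat(cols)
    ml <- coda::mcmc.list(lapply(cols, coda::mcmc))
    out$ess[j] <- sum(coda::effectiveSize(ml))
    if (is.na(out$rhat[j])) out$flag[j] <- "degenerate"
    else if (out$rhat[j] > rhat_threshold) out$flag[j] <- "no_convergence"
  }
  out
}

#' Posterior summary table
#'
#' Equal-tailed medians and 95\% credible intervals (2.5/50/97.5
#' percentiles) for every parameter, plus the per-year female density
#' (abundance / plot area, females per ha).
#'
#' @param samples A `js_posterior`.
#' @return Data frame `parameter, median, lower, upper`.
#' @export
summarize_posterior <- function(samples) {
  m <- posterior_matrix(samples)
  if (nrow(m) == 0) stop("no posterior draws")
  qs <- t(apply(m, 2L, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE))
  out <- data.frame(parameter = colnames(m), median = qs[, 2],
                    lower = qs[, 1], upper = qs[, 3],
                    stringsAsFactors = FALSE)
  ncols <- grep("^N\\[", colnames(m))
  if (length(ncols)) {
    dens <- m[, ncols, drop = FALSE] / samples$area
    qd <- t(apply(dens, 2L, quantile, probs = c(0.025, 0.5, 0.975),
                  names = FALSE))
    out <- rbind(out, data.frame(
      parameter = sprintf("density[%d]", seq_along(ncols)),
      median = qd[, 2], lower = qd[, 1], upper = qd[, 3],
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
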