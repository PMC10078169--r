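#' @keywords internal
"_PACKAGE"

#' @useDynLib jsclimate, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm coef confint predict rbinom runif rnorm rexp rbeta
#'   dnorm dbinom dbeta dexp quantile sd plogis qlogis median var pt
#'   residuals setNames
#' @importFrom utils read.csv write.csv
NULL

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

## Centered/scaled year index used for the capture-probability trend and for
## the "time" covariate variant.  sd() rather than a range so that trend
## coefficients are per-SD-of-year, comparable across plots with different T.
scale_years <- function(T) {
  idx <- seq_len(T)
  (idx - mean(idx)) / sd(idx)
}

## Continuation of the scaled year index beyond the data for forecasting.
scale_future_years <- function(T, n_future) {
  idx <- seq_len(T)
  (T + seq_len(n_future) - mean(idx)) / sd(idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
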