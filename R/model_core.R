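## Deterministic kernel: digestion curve, detectability integral, field
## detection probability, and the two Bernoulli log-likelihoods.

#' Numerically stable log(1 + exp(x))
#'
#' Safe for |x| up to the double-precision overflow range; used by the
#' detectability integral.
#' @param x numeric vector.
#' @return log(1 + exp(x)), elementwise.
#' @export
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18          # below this, log1p(exp(x)) is exact and safe
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out                     # above 33.3, log(1+e^x) == x to double precision
}

#' Probability of detecting a prey meal t hours after ingestion
#'
#' The digestion curve: detection probability declines as a logistic
#' function of time since feeding, `logit pi(t) = beta0 - beta1 * t`.
#' `beta0` is the log-odds of detection immediately after the meal and
#' `beta1` (> 0, per hour) the rate at which the molecular signal vanishes.
#'
#' @param beta0 numeric, intercept of the digestion curve (log-odds scale).
#' @param beta1 numeric, strictly positive decay slope (per hour).
#' @param t numeric, non-negative hours since feeding.
#' @return Detection probability in (0, 1), vectorised over the inputs.
#' @examples
#' detection_probability(2, 0.1, c(0, 24, 72))
#' @export
detection_probability <- function(beta0, beta1, t) {
  check_digestion_params(beta0, beta1)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  stats::plogis(beta0 - beta1 * t)
}

#' Detectability integral of a digestion curve
#'
#' The area under the digestion curve, `I = integral_0^Inf pi(t) dt =
#' log(1 + exp(beta0)) / beta1`, in hours. `lambda * I` is the expected
#' number of past meals still detectable at the time of a test, so `I`
#' acts as the effective detection window of the assay.
#'
#' @inheritParams detection_probability
#' @return The integral in hours, vectorised over the inputs.
#' @examples
#' detectability_integral(0, 1)      # log(2)
#' detectability_integral(2, 0.1)    # ~21.27 h
#' @export
detectability_integral <- function(beta0, beta1) {
  check_digestion_params(beta0, beta1)
  log1pexp(beta0) / beta1
}

#' Probability that a field-caught predator tests positive
#'
#' Under a homogeneous Poisson predation process with intensity `lam`
#' (events per hour) and detectability window `I` (hours), the number of
#' still-detectable meals is Poisson(`lam * I`) and a binary test is
#' positive as soon as one meal is detectable:
#' `p(I) = 1 - exp(-lam * I)`.
#'
#' @param lam numeric, non-negative predation rate (events per hour).
#' @param I numeric, non-negative detectability integral (hours).
#' @return Probability in \[0, 1), vectorised.
#' @examples
#' field_positive_probability(0.05, 21.27)
#' @export
field_positive_probability <- function(lam, I) {
  if (any(!is.finite(lam)) || any(lam < 0)) {
    stop("`lam` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(I)) || any(I < 0)) {
    stop("`I` must be finite and >= 0", call. = FALSE)
  }
  -expm1(-lam * I)
}

#' Feeding-trial log-likelihood
#'
#' Bernoulli log-likelihood of laboratory detection results given one
#' digestion curve per predator-prey pair: each test at delay `d` is
#' positive with probability `pi(d)`.
#'
#' @param lab data frame with columns `predator`, `prey`,
#'   `hours_since_feeding`, `detected` (0/1).
#' @param params data frame with columns `predator`, `prey`, `beta0`,
#'   `beta1`; one row per pair.
#' @return Total log-likelihood (scalar).
#' @export
lab_loglik <- function(lab, params) {
  validate_lab_data(lab)
  pr <- match_pair_params(lab, params, c("beta0", "beta1"))
  p <- detection_probability(pr$beta0, pr$beta1, lab$hours_since_feeding)
  sum(stats::dbinom(lab$detected, 1L, p, log = TRUE))
}

#' Field-test log-likelihood
#'
#' Bernoulli log-likelihood of field detection results given a predation
#' rate and a detectability integral per pair; each (individual, prey)
#' outcome is an independent draw with success probability
#' `1 - exp(-lam * I)`.
#'
#' @param field data frame with columns `predator`, `prey`, `detected`.
#' @param params data frame with columns `predator`, `prey`, `lam` and
#'   either `I` or both `beta0` and `beta1` (from which `I` is computed).
#' @return Total log-likelihood (scalar).
#' @export
field_loglik <- function(field, params) {
  validate_field_data(field)
  if (!"I" %in% names(params)) {
    params$I <- detectability_integral(params$beta0, params$beta1)
  }
  pr <- match_pair_params(field, params, c("lam", "I"))
  p <- field_positive_probability(pr$lam, pr$I)
  ## detected = 0 with p = 0 must give log(1) = 0, not NaN
  ll <- ifelse(field$detected == 1L, log(p), -pr$lam * pr$I)
  if (any(field$detected == 1L & p == 0)) {
    return(-Inf)
  }
  sum(ll)
}

check_digestion_params <- function(beta0, beta1) {
  if (any(!is.finite(beta0))) {
    stop("`beta0` must be finite", call. = FALSE)
  }
  if (any(!is.finite(beta1)) || any(beta1 <= 0)) {
    stop("`beta1` must be finite and > 0", call. = FALSE)
  }
  invisible(TRUE)
}

## Align per-observation rows with per-pair parameter rows; unknown pairs
## are an error, never silently dropped.
match_pair_params <- function(obs, params, cols) {
  key_obs <- paste(obs$prey, obs$predator, sep = "\r")
  key_par <- paste(params$prey, params$predator, sep = "\r")
  if (anyDuplicated(key_par)) {
    stop("duplicated (prey, predator) rows in `params`", call. = FALSE)
  }
  idx <- match(key_obs, key_par)
  if (anyNA(idx)) {
    bad <- unique(paste0(obs$predator[is.na(idx)], " / ", obs$prey[is.na(idx)]))
    stop("observations reference unknown pairs: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  params[idx, cols, drop = FALSE]
}
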