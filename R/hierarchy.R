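## Additive decomposition of the pair-level parameters into prey, predator
## and interaction effects, and the hierarchical prior over those effects.
##
## beta0(p, c) = alpha_beta0(p) + delta_beta0(c) + gamma_beta0(p, c)
## ln lam(p,c) = alpha_lam(p)   + delta_lam(c)   + gamma_lam(p, c)
## beta1(p, c) = exp(log_beta1(p, c)),  log_beta1 ~ Normal (shared family)
##
## Predator and interaction effects and log_beta1 are hierarchised at the
## level of the whole taxonomic group; prey effects get fixed priors.

#' Construct an effect decomposition
#'
#' Bundles the additive prey, predator and interaction effects acting on
#' the digestion intercept `beta0` and on `ln lambda`, plus the per-pair
#' `log(beta1)` values. Matrices are indexed prey x predator.
#'
#' @param prey character vector of prey labels.
#' @param predators character vector of predator labels.
#' @param alpha_beta0,alpha_lam numeric vectors, one value per prey.
#' @param delta_beta0,delta_lam numeric vectors, one value per predator.
#' @param gamma_beta0,gamma_lam numeric matrices, prey x predator.
#' @param log_beta1 numeric matrix, prey x predator.
#' @return An object of class `effect_decomposition`.
#' @export
effect_decomposition <- function(prey, predators,
                                 alpha_beta0, delta_beta0, gamma_beta0,
                                 alpha_lam, delta_lam, gamma_lam,
                                 log_beta1) {
  prey <- as.character(prey)
  predators <- as.character(predators)
  np <- length(prey)
  nc <- length(predators)
  stopifnot(length(alpha_beta0) == np, length(alpha_lam) == np,
            length(delta_beta0) == nc, length(delta_lam) == nc,
            all(dim(gamma_beta0) == c(np, nc)),
            all(dim(gamma_lam) == c(np, nc)),
            all(dim(log_beta1) == c(np, nc)))
  vals <- c(alpha_beta0, alpha_lam, delta_beta0, delta_lam,
            gamma_beta0, gamma_lam, log_beta1)
  if (any(!is.finite(vals))) {
    stop("all effects must be finite", call. = FALSE)
  }
  name2 <- function(m) {
    dimnames(m) <- list(prey, predators)
    m
  }
  structure(list(
    prey = prey, predators = predators,
    alpha_beta0 = stats::setNames(alpha_beta0, prey),
    alpha_lam = stats::setNames(alpha_lam, prey),
    delta_beta0 = stats::setNames(delta_beta0, predators),
    delta_lam = stats::setNames(delta_lam, predators),
    gamma_beta0 = name2(gamma_beta0),
    gamma_lam = name2(gamma_lam),
    log_beta1 = name2(log_beta1)
  ), class = "effect_decomposition")
}

check_registered <- function(effects, prey, predator) {
  bad_p <- setdiff(unique(prey), effects$prey)
  bad_c <- setdiff(unique(predator), effects$predators)
  if (length(bad_p) || length(bad_c)) {
    stop("unknown labels: ", paste(c(bad_p, bad_c), collapse = ", "),
         call. = FALSE)
  }
}

#' Assemble the digestion intercept for given pairs
#'
#' @param effects an [effect_decomposition()].
#' @param prey,predator character vectors of equal length (recycled).
#' @return `alpha_beta0(prey) + delta_beta0(predator) + gamma_beta0(prey, predator)`.
#' @export
assemble_beta0 <- function(effects, prey, predator) {
  prey <- as.character(prey)
  predator <- as.character(predator)
  check_registered(effects, prey, predator)
  effects$alpha_beta0[prey] + effects$delta_beta0[predator] +
    effects$gamma_beta0[cbind(prey, predator)]
}

#' Assemble the log predation rate for given pairs
#'
#' @inheritParams assemble_beta0
#' @return `alpha_lam(prey) + delta_lam(predator) + gamma_lam(prey, predator)`,
#'   the log of the hourly predation rate (exponentiation keeps it positive).
#' @export
assemble_log_lambda <- function(effects, prey, predator) {
  prey <- as.character(prey)
  predator <- as.character(predator)
  check_registered(effects, prey, predator)
  effects$alpha_lam[prey] + effects$delta_lam[predator] +
    effects$gamma_lam[cbind(prey, predator)]
}

#' Pair-level parameters implied by an effect decomposition
#'
#' @param effects an [effect_decomposition()].
#' @return data frame with one row per (prey, predator) pair and columns
#'   `prey`, `predator`, `beta0`, `beta1`, `lam` (per hour).
#' @export
pair_parameters <- function(effects) {
  grid <- expand.grid(prey = effects$prey, predator = effects$predators,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    grid,
    beta0 = assemble_beta0(effects, grid$prey, grid$predator),
    beta1 = exp(effects$log_beta1[cbind(grid$prey, grid$predator)]),
    lam = exp(assemble_log_lambda(effects, grid$prey, grid$predator)),
    row.names = NULL
  )
}

#' Default hyperprior configuration
#'
#' Fixed constants of the hierarchical prior. Prey effects are not
#' hierarchised and get independent Normal(location, scale) priors; the
#' hierarchised families (predator effects and interaction effects on
#' `beta0` and `ln lambda`, and `log_beta1`) are Normal with a family-level
#' scale drawn from a half-Normal, and a family-level location that is
#' fixed at zero except for `log_beta1`, whose location gets a Normal
#' hyperprior. Pinning the predator- and interaction-family locations at
#' zero (their level being carried by the prey effects) keeps the additive
#' decomposition identifiable.
#'
#' @param prey_beta0,prey_lam length-2 numeric `c(location, scale)` of the
#'   fixed prey-effect priors.
#' @param log_beta1_location length-2 numeric `c(location, scale)` of the
#'   Normal hyperprior on the `log_beta1` family location.
#' @param scale_halfnormal positive scalar, scale of the half-Normal
#'   hyperprior shared by all family-level scales.
#' @return A named list of class `hyperprior_config`.
#' @export
default_hyperpriors <- function(prey_beta0 = c(0, 2),
                                prey_lam = c(0, 2),
                                log_beta1_location = c(0, 1),
                                scale_halfnormal = 1) {
  stopifnot(length(prey_beta0) == 2, prey_beta0[2] > 0,
            length(prey_lam) == 2, prey_lam[2] > 0,
            length(log_beta1_location) == 2, log_beta1_location[2] > 0,
            length(scale_halfnormal) == 1, scale_halfnormal > 0)
  structure(list(
    prey_beta0 = as.numeric(prey_beta0),
    prey_lam = as.numeric(prey_lam),
    log_beta1_location = as.numeric(log_beta1_location),
    scale_halfnormal = as.numeric(scale_halfnormal)
  ), class = "hyperprior_config")
}

#' Family-level hyperparameters
#'
#' The location and scale of each hierarchised effect family. Locations of
#' the predator and interaction families are structurally zero (see
#' [default_hyperpriors()]); only `log_beta1` carries a free location.
#'
#' @param mu_log_beta1 location of the shared `log_beta1` family.
#' @param sigma_log_beta1,sigma_delta_beta0,sigma_delta_lam,sigma_gamma_beta0,sigma_gamma_lam
#'   strictly positive family scales.
#' @return A named list of class `hyperparameters`.
#' @export
hyperparameters <- function(mu_log_beta1 = 0,
                            sigma_log_beta1 = 1,
                            sigma_delta_beta0 = 1,
                            sigma_delta_lam = 1,
                            sigma_gamma_beta0 = 1,
                            sigma_gamma_lam = 1) {
  sc <- c(sigma_log_beta1, sigma_delta_beta0, sigma_delta_lam,
          sigma_gamma_beta0, sigma_gamma_lam)
  if (any(!is.finite(sc)) || any(sc <= 0)) {
    stop("all scales must be finite and > 0", call. = FALSE)
  }
  structure(list(
    mu_log_beta1 = mu_log_beta1,
    sigma_log_beta1 = sigma_log_beta1,
    sigma_delta_beta0 = sigma_delta_beta0,
    sigma_delta_lam = sigma_delta_lam,
    sigma_gamma_beta0 = sigma_gamma_beta0,
    sigma_gamma_lam = sigma_gamma_lam
  ), class = "hyperparameters")
}

dhalfnorm_log <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) + stats::dnorm(x, 0, scale, log = TRUE))
}

#' Log-density of the hierarchical prior
#'
#' Sums, on the log scale: fixed Normal priors of the prey effects;
#' Normal densities of the hierarchised predator, interaction and
#' `log_beta1` effects given their family location/scale; the Normal
#' hyperprior of the `log_beta1` location; and half-Normal hyperpriors of
#' all family scales.
#'
#' @param effects an [effect_decomposition()].
#' @param hyper a [hyperparameters()] object.
#' @param config a [default_hyperpriors()] configuration.
#' @return Scalar log-density.
#' @export
prior_logdensity <- function(effects, hyper, config = default_hyperpriors()) {
  if (!inherits(hyper, "hyperparameters")) {
    stop("`hyper` must be a hyperparameters object", call. = FALSE)
  }
  sum(
    stats::dnorm(effects$alpha_beta0, config$prey_beta0[1],
                 config$prey_beta0[2], log = TRUE),
    stats::dnorm(effects$alpha_lam, config$prey_lam[1],
                 config$prey_lam[2], log = TRUE),
    stats::dnorm(effects$delta_beta0, 0, hyper$sigma_delta_beta0, log = TRUE),
    stats::dnorm(effects$delta_lam, 0, hyper$sigma_delta_lam, log = TRUE),
    stats::dnorm(effects$gamma_beta0, 0, hyper$sigma_gamma_beta0, log = TRUE),
    stats::dnorm(effects$gamma_lam, 0, hyper$sigma_gamma_lam, log = TRUE),
    stats::dnorm(effects$log_beta1, hyper$mu_log_beta1,
                 hyper$sigma_log_beta1, log = TRUE),
    stats::dnorm(hyper$mu_log_beta1, config$log_beta1_location[1],
                 config$log_beta1_location[2], log = TRUE),
    dhalfnorm_log(c(hyper$sigma_log_beta1, hyper$sigma_delta_beta0,
                    hyper$sigma_delta_lam, hyper$sigma_gamma_beta0,
                    hyper$sigma_gamma_lam), config$scale_halfnormal)
  )
}
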