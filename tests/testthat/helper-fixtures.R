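## Shared fixtures: small effect decompositions, scenarios and datasets
## built in code. All randomness is seeded by the caller.

toy_effects <- function(n_prey = 2, n_pred = 3, seed = 11) {
  set.seed(seed)
  prey <- paste0("p", seq_len(n_prey))
  predators <- paste0("c", seq_len(n_pred))
  effect_decomposition(
    prey, predators,
    alpha_beta0 = rnorm(n_prey, 2, 0.5),
    delta_beta0 = rnorm(n_pred, 0, 0.5),
    gamma_beta0 = matrix(rnorm(n_prey * n_pred, 0, 0.3), n_prey, n_pred),
    alpha_lam = rnorm(n_prey, -3, 0.5),
    delta_lam = rnorm(n_pred, 0, 0.5),
    gamma_lam = matrix(rnorm(n_prey * n_pred, 0, 0.3), n_prey, n_pred),
    log_beta1 = matrix(rnorm(n_prey * n_pred, log(0.12), 0.3),
                       n_prey, n_pred)
  )
}

## single-pair scenario used for small oracle checks
one_pair_scenario <- function(beta0 = 2, beta1 = 0.1, lam = 0.05,
                              field_n = 500, lab_n_per_time = 20,
                              cluster_mean = 1, seed = 7) {
  simulation_scenario(
    prey = "aphid", predators = "PoCu",
    beta0 = matrix(beta0, 1, 1), beta1 = matrix(beta1, 1, 1),
    lam = matrix(lam, 1, 1), field_n = c(PoCu = field_n),
    lab_times = c(2, 8, 16, 24, 48, 72), lab_n_per_time = lab_n_per_time,
    cluster_mean = cluster_mean, seed = seed)
}

## the fixed 4-predator x 2-prey ground truth of the recovery suite:
## additive structure with daily rates spanning [0.2, 3]
recovery_truth <- function() {
  n_prey <- 2; n_pred <- 4
  prey <- c("aphid", "slug")
  predators <- c("AnDo", "BeSc", "PoCu", "TrQu")
  alpha_lam <- log(c(0.8, 1.6) / 24)
  delta_lam <- log(c(0.33, 0.62, 1.2, 1.9) / sqrt(0.8 * 1.6))
  gamma_lam <- matrix(c(0.15, -0.15, 0.1, -0.1, -0.15, 0.15, -0.1, 0.1),
                      n_prey, n_pred)
  alpha_b0 <- c(1.6, 2.2)
  delta_b0 <- c(-0.3, 0.3, 0, 0.2)
  list(prey = prey, predators = predators,
       beta0 = outer(alpha_b0, delta_b0, "+"),
       loglam = outer(alpha_lam, delta_lam, "+") + gamma_lam)
}

## one replicate of the recovery design: known truth, fresh data; with
## `include_unobserved` a fifth predator has feeding-trial data but no
## field captures, so its rate is informed only through the hierarchy
recovery_scenario <- function(rep_seed, field_n = 300, lab_n_per_time = 5,
                              cluster_mean = 1, include_unobserved = FALSE) {
  tr <- recovery_truth()
  predators <- tr$predators
  beta0 <- tr$beta0
  loglam <- tr$loglam
  fn <- setNames(rep(field_n, 4), predators)
  if (include_unobserved) {
    predators <- c(predators, "ZeFi")
    beta0 <- cbind(beta0, c(1.6, 2.2))        # prey effects only
    loglam <- cbind(loglam, log(c(0.8, 1.6) / 24))
    fn <- c(fn, ZeFi = 0)
  }
  set.seed(rep_seed)
  n_pair <- length(tr$prey) * length(predators)
  beta1 <- exp(matrix(rnorm(n_pair, log(0.12), 0.4), 2, length(predators)))
  simulation_scenario(
    prey = tr$prey, predators = predators,
    beta0 = beta0, beta1 = beta1, lam = exp(loglam),
    field_n = fn,
    lab_times = c(2, 8, 16, 24, 48, 72), lab_n_per_time = lab_n_per_time,
    cluster_mean = cluster_mean, seed = rep_seed)
}
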