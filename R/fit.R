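## Joint MCMC over the feeding-trial and field datasets (JAGS), convergence
## diagnostics, posterior summaries, and the posterior-predictive check.

## The sampler works on binomially aggregated data: feeding-trial rows are
## pooled per (pair, delay) and field rows per pair, which leaves the
## likelihood unchanged and keeps the graph small. Predator effects are
## given a sum-to-zero constraint and interaction effects a non-centred
## parameterisation; both remove ridge/funnel geometry that otherwise
## cripples one-at-a-time sampling (see the methods vignette).
jags_model_string <- function() {
"model {
  for (k in 1:n_lab) {
    logit(pi_lab[k]) <- beta0[lab_prey[k], lab_pred[k]] -
      beta1[lab_prey[k], lab_pred[k]] * lab_t[k]
    lab_y[k] ~ dbin(pi_lab[k], lab_n[k])
  }
  for (k in 1:n_field) {
    p_field[k] <- 1 - exp(-lam[field_prey[k], field_pred[k]] *
                           I[field_prey[k], field_pred[k]])
    field_y[k] ~ dbin(p_field[k], field_n[k])
  }
  for (i in 1:n_prey) {
    alpha_b0[i] ~ dnorm(prey_b0_loc, pow(prey_b0_scale, -2))
    alpha_lam[i] ~ dnorm(prey_lam_loc, pow(prey_lam_scale, -2))
  }
  mu_lb1 ~ dnorm(lb1_loc, pow(lb1_scale, -2))
  sig_delta_b0 ~ dnorm(0, pow(hn_scale, -2)) T(0,)
  sig_delta_lam ~ dnorm(0, pow(hn_scale, -2)) T(0,)
  sig_gamma_b0 ~ dnorm(0, pow(hn_scale, -2)) T(0,)
  sig_gamma_lam ~ dnorm(0, pow(hn_scale, -2)) T(0,)
  sig_lb1 ~ dnorm(0, pow(hn_scale, -2)) T(0,)
  for (j in 1:n_pred) {
    delta_b0_raw[j] ~ dnorm(0, pow(sig_delta_b0, -2))
    delta_lam_raw[j] ~ dnorm(0, pow(sig_delta_lam, -2))
    delta_b0[j] <- delta_b0_raw[j] - mean(delta_b0_raw[])
    delta_lam[j] <- delta_lam_raw[j] - mean(delta_lam_raw[])
  }
  for (i in 1:n_prey) {
    for (j in 1:n_pred) {
      z_gamma_b0[i, j] ~ dnorm(0, 1)
      z_gamma_lam[i, j] ~ dnorm(0, 1)
      gamma_b0[i, j] <- sig_gamma_b0 * z_gamma_b0[i, j]
      gamma_lam[i, j] <- sig_gamma_lam * z_gamma_lam[i, j]
      lb1[i, j] ~ dnorm(mu_lb1, pow(sig_lb1, -2))
      beta0[i, j] <- alpha_b0[i] + delta_b0[j] + gamma_b0[i, j]
      beta1[i, j] <- exp(lb1[i, j])
      lam[i, j] <- exp(alpha_lam[i] + delta_lam[j] + gamma_lam[i, j])
      I[i, j] <- (max(beta0[i, j], 0) +
                  log(1 + exp(-abs(beta0[i, j])))) / beta1[i, j]
    }
  }
}"
}

aggregate_lab <- function(lab) {
  agg <- stats::aggregate(detected ~ prey + predator + hours_since_feeding,
                          data = lab,
                          FUN = function(x) c(y = sum(x), n = length(x)))
  data.frame(agg[c("prey", "predator", "hours_since_feeding")],
             y = agg$detected[, "y"], n = agg$detected[, "n"])
}

aggregate_field <- function(field) {
  agg <- stats::aggregate(detected ~ prey + predator, data = field,
                          FUN = function(x) c(y = sum(x), n = length(x)))
  data.frame(agg[c("prey", "predator")],
             y = agg$detected[, "y"], n = agg$detected[, "n"])
}

#' Fit the hierarchical predation-rate model
#'
#' Joint MCMC estimation over a feeding trial (which identifies the
#' digestion curves) and field detection tests (which identify the
#' predation rates given those curves). The predator and prey registries
#' are the union of the labels in either dataset, so species present in
#' only one of them are retained and informed through the hierarchy.
#'
#' Sampling runs `chains` Markov chains in JAGS and, when
#' `extend_until_converged` is `TRUE`, keeps extending them until the
#' rank-normalised split-R-hat of every monitored parameter drops below
#' `rhat_gate` or `max_total_iter` post-warmup iterations have been drawn.
#'
#' @param lab feeding-trial data frame (`predator`, `prey`,
#'   `hours_since_feeding`, `detected`).
#' @param field field-test data frame (`predator`, `prey`, `detected`).
#' @param hyper a [default_hyperpriors()] configuration.
#' @param chains number of Markov chains (3 by default).
#' @param adapt JAGS adaptation iterations.
#' @param warmup burn-in iterations discarded before monitoring.
#' @param iter post-warmup iterations per extension block.
#' @param thin thinning interval of the stored draws.
#' @param seed integer seed; chain RNG seeds are derived from it, making
#'   runs with identical settings bit-reproducible.
#' @param extend_until_converged extend sampling until `rhat_gate` is met.
#' @param rhat_gate convergence threshold on rank-normalised split-R-hat.
#' @param max_total_iter cap on total post-warmup iterations.
#' @param quiet suppress JAGS progress output.
#' @return An object of class `predation_fit`: a list with the `coda`
#'   `mcmc.list` in `$samples`, the registries, the aggregated data, the
#'   settings used, and the convergence diagnostics of the final draws.
#' @export
fit_model <- function(lab, field, hyper = default_hyperpriors(),
                      chains = 3, adapt = 1500, warmup = 4000,
                      iter = 30000, thin = 5, seed = 1,
                      extend_until_converged = TRUE, rhat_gate = 1.01,
                      max_total_iter = 150000, quiet = TRUE) {
  validate_lab_data(lab)
  validate_field_data(field)
  if (nrow(lab) == 0 || nrow(field) == 0) {
    stop("both datasets must be nonempty", call. = FALSE)
  }
  if (all(field$detected == 1L)) {
    warning("all field tests are positive: the detection model is ",
            "saturated and predation rates are only bounded from below",
            call. = FALSE)
  }
  prey <- sort(unique(c(lab$prey, field$prey)))
  predators <- sort(unique(c(lab$predator, field$predator)))

  lab_agg <- aggregate_lab(lab)
  field_agg <- aggregate_field(field)
  dat <- list(
    n_lab = nrow(lab_agg),
    lab_prey = match(lab_agg$prey, prey),
    lab_pred = match(lab_agg$predator, predators),
    lab_t = lab_agg$hours_since_feeding,
    lab_y = lab_agg$y, lab_n = lab_agg$n,
    n_field = nrow(field_agg),
    field_prey = match(field_agg$prey, prey),
    field_pred = match(field_agg$predator, predators),
    field_y = field_agg$y, field_n = field_agg$n,
    n_prey = length(prey), n_pred = length(predators),
    prey_b0_loc = hyper$prey_beta0[1], prey_b0_scale = hyper$prey_beta0[2],
    prey_lam_loc = hyper$prey_lam[1], prey_lam_scale = hyper$prey_lam[2],
    lb1_loc = hyper$log_beta1_location[1],
    lb1_scale = hyper$log_beta1_location[2],
    hn_scale = hyper$scale_halfnormal
  )
  set.seed(seed)
  rng_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  inits <- lapply(rng_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
  monitors <- c("lam", "beta0", "beta1", "I", "alpha_b0", "alpha_lam",
                "delta_b0", "delta_lam", "gamma_b0", "gamma_lam",
                "mu_lb1", "sig_delta_b0", "sig_delta_lam",
                "sig_gamma_b0", "sig_gamma_lam", "sig_lb1")
  pb <- if (quiet) "none" else "text"
  jm <- rjags::jags.model(textConnection(jags_model_string()), data = dat,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = quiet)
  if (warmup > 0) stats::update(jm, warmup, progress.bar = pb)
  samples <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                                 progress.bar = pb)
  total <- iter
  repeat {
    rhat <- rank_rhat_all(samples)
    if (!extend_until_converged || max(rhat) < rhat_gate ||
        total >= max_total_iter) {
      break
    }
    more <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                                progress.bar = pb)
    samples <- coda::as.mcmc.list(lapply(seq_len(chains), function(ch) {
      coda::mcmc(rbind(samples[[ch]], more[[ch]]), thin = thin)
    }))
    total <- total + iter
  }
  structure(list(
    samples = samples, prey = prey, predators = predators,
    lab = lab_agg, field = field_agg, hyper = hyper,
    settings = list(chains = chains, adapt = adapt, warmup = warmup,
                    iter = total, thin = thin, seed = seed,
                    rhat_gate = rhat_gate, sampler = "JAGS 4.x (Gibbs/slice)"),
    rhat = rhat
  ), class = "predation_fit")
}

#' @export
print.predation_fit <- function(x, ...) {
  cat("Hierarchical predation-rate fit\n")
  cat(sprintf("  %d prey x %d predators; %d lab cells, %d field cells\n",
              length(x$prey), length(x$predators), nrow(x$lab),
              nrow(x$field)))
  cat(sprintf("  %d chains x %d kept draws (thin %d); max split-Rhat %.4f\n",
              length(x$samples), nrow(x$samples[[1]]), x$settings$thin,
              max(x$rhat)))
  invisible(x)
}

## rank-normalised split-R-hat of one parameter across chains
rank_rhat_one <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2) * 2
    x <- x[seq_len(n)]
    list(x[seq_len(n / 2)], x[(n / 2 + 1):n])
  }), recursive = FALSE)
  pooled <- unlist(halves)
  z <- stats::qnorm((rank(pooled, ties.method = "average") - 3 / 8) /
                      (length(pooled) + 1 / 4))
  m <- length(halves)
  n <- length(halves[[1]])
  zc <- matrix(z, nrow = n)
  B <- n * stats::var(colMeans(zc))
  W <- mean(apply(zc, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

rank_rhat_all <- function(samples) {
  pars <- colnames(samples[[1]])
  vapply(pars, function(p) {
    rank_rhat_one(lapply(samples, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
}

#' Potential scale reduction factor
#'
#' Convergence diagnostic comparing between- and within-chain variance.
#' The default is the rank-normalised split variant, which is robust to
#' heavy-tailed posteriors such as those of hierarchical scale parameters;
#' `method = "classic"` gives the original Gelman-Rubin statistic (via
#' `coda::gelman.diag`) for comparison against the conventional < 1.01
#' acceptance gate.
#'
#' @param fit a `predation_fit` or a `coda::mcmc.list` with >= 2 chains.
#' @param parameters optional character vector restricting the result.
#' @param method `"rank"` (default) or `"classic"`.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(fit, parameters = NULL,
                         method = c("rank", "classic")) {
  method <- match.arg(method)
  samples <- if (inherits(fit, "predation_fit")) fit$samples else fit
  if (!coda::is.mcmc.list(samples)) {
    stop("`fit` must be a predation_fit or mcmc.list", call. = FALSE)
  }
  if (length(samples) < 2) {
    stop("at least 2 chains are required", call. = FALSE)
  }
  if (nrow(samples[[1]]) < 4) {
    stop("at least 4 iterations per chain are required", call. = FALSE)
  }
  if (!is.null(parameters)) {
    samples <- samples[, parameters, drop = FALSE]
  }
  if (method == "rank") {
    rank_rhat_all(samples)
  } else {
    ## classic Gelman-Rubin: between/within variance ratio of the raw
    ## chains, sqrt(((n-1)/n * W + B/n) / W)
    pars <- colnames(samples[[1]])
    n <- nrow(samples[[1]])
    vapply(pars, function(p) {
      ch <- vapply(samples, function(s) as.numeric(s[, p]),
                   numeric(n))
      B <- n * stats::var(colMeans(ch))
      W <- mean(apply(ch, 2, stats::var))
      if (W == 0) return(1)
      sqrt(((n - 1) / n * W + B / n) / W)
    }, numeric(1))
  }
}

## draws matrix (all chains stacked) for a parameter family, with the
## (prey, predator) labels recovered from the JAGS index names
family_draws <- function(fit, family) {
  m <- as.matrix(fit$samples)
  cols <- grep(paste0("^", family, "\\["), colnames(m))
  if (!length(cols) && family %in% colnames(m)) {
    ## single-pair model: JAGS drops the [1,1] index on scalar nodes
    cols <- match(family, colnames(m))
    sub <- m[, cols, drop = FALSE]
    return(list(draws = sub, prey = fit$prey[1], predator = fit$predators[1]))
  }
  if (!length(cols)) stop("no monitored parameter `", family, "`",
                          call. = FALSE)
  sub <- m[, cols, drop = FALSE]
  idx <- sub("^.*\\[(\\d+),(\\d+)\\]$", "\\1 \\2", colnames(sub))
  ij <- do.call(rbind, lapply(strsplit(idx, " "), as.integer))
  list(draws = sub,
       prey = fit$prey[ij[, 1]],
       predator = fit$predators[ij[, 2]])
}

#' Posterior draws of daily predation rates
#'
#' @param fit a `predation_fit`.
#' @return List with `draws` (matrix, stacked chains x pairs, events per
#'   day) and the `prey`/`predator` labels of each column.
#' @export
posterior_daily_rates <- function(fit) {
  fam <- family_draws(fit, "lam")
  fam$draws <- fam$draws * 24
  fam
}

## lower-interpolation quantile, so summaries are exactly reproducible
quantile_lower <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 1, names = FALSE)
}

#' Summarise a fitted model
#'
#' Per-pair posterior summaries of the daily predation rate and the
#' digestion-curve parameters, plus the convergence diagnostics of all
#' monitored parameters. Quantiles use lower interpolation (type 1).
#'
#' @param fit a `predation_fit`.
#' @param probs quantile probabilities for the rate table.
#' @return List of class `fit_report` with data frames `rates`,
#'   `digestion` and `diagnostics`.
#' @export
fit_report <- function(fit, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  rates <- posterior_daily_rates(fit)
  qs <- t(apply(rates$draws, 2, quantile_lower, probs = probs))
  colnames(qs) <- paste0("q", format(100 * probs, trim = TRUE))
  rate_tab <- data.frame(
    prey = rates$prey, predator = rates$predator,
    mean = colMeans(rates$draws),
    sd = apply(rates$draws, 2, stats::sd),
    median = apply(rates$draws, 2, quantile_lower, probs = 0.5),
    qs, row.names = NULL, check.names = FALSE)
  b0 <- family_draws(fit, "beta0")
  b1 <- family_draws(fit, "beta1")
  digestion <- data.frame(
    prey = b0$prey, predator = b0$predator,
    beta0_mean = colMeans(b0$draws),
    beta0_sd = apply(b0$draws, 2, stats::sd),
    beta1_mean = colMeans(b1$draws),
    beta1_sd = apply(b1$draws, 2, stats::sd),
    half_life = log(2) / colMeans(b1$draws), row.names = NULL)
  diagnostics <- data.frame(parameter = names(fit$rhat),
                            rhat = unname(fit$rhat), row.names = NULL)
  structure(list(rates = rate_tab, digestion = digestion,
                 diagnostics = diagnostics),
            class = "fit_report")
}

#' @export
summary.predation_fit <- function(object, ...) fit_report(object, ...)

#' @export
print.fit_report <- function(x, ...) {
  cat("Daily predation rates (events/day), top pairs by posterior median:\n")
  ord <- order(x$rates$median, decreasing = TRUE)
  print(utils::head(x$rates[ord, ], 10), digits = 3)
  cat(sprintf("\nmax R-hat: %.4f\n", max(x$diagnostics$rhat)))
  invisible(x)
}

## lower-interpolation quantiles of the posterior-predictive frequency:
## a mixture over posterior draws of Binomial(n, p)/n, computed exactly
predictive_freq_quantiles <- function(p_draws, n, probs) {
  if (length(p_draws) > 1000) {
    p_draws <- p_draws[seq(1, length(p_draws), length.out = 1000)]
  }
  ks <- 0:n
  cdf <- rowMeans(vapply(p_draws, function(p) stats::pbinom(ks, n, p),
                         numeric(n + 1)))
  vapply(probs, function(q) ks[which(cdf >= q - 1e-12)[1]] / n, numeric(1))
}

#' Posterior-predictive check of field detection frequencies
#'
#' For every (predator, prey) pair present in the field data, reports the
#' posterior quantiles of the detection probability `p(I)` next to the
#' observed frequency of positive tests, and checks the observed frequency
#' against the central 95% and 50% intervals of the posterior-predictive
#' frequency (`p(I)` plus binomial sampling noise at the pair's sample
#' size — for well-sampled species this is essentially the interval of
#' `p(I)` itself, while for species caught a handful of times the binomial
#' noise dominates).
#'
#' @param fit a `predation_fit`.
#' @param field the field data the model was fitted to.
#' @return data frame with one row per observed pair: `n_obs`,
#'   `observed_freq`, posterior quantiles of `p(I)` (`q2.5` ... `q97.5`),
#'   predictive-frequency interval bounds (`pred_*`), and `inside95` /
#'   `inside50` flags, with attributes `frac_inside95` / `frac_inside50`.
#'   Registered pairs with no field observations are excluded (their
#'   observed frequency is undefined) with a message.
#' @export
posterior_predictive_check <- function(fit, field) {
  validate_field_data(field)
  obs <- aggregate_field(field)
  lamI_lam <- family_draws(fit, "lam")
  lamI_I <- family_draws(fit, "I")
  p_draws <- -expm1(-(lamI_lam$draws * lamI_I$draws))
  key_fit <- paste(lamI_lam$prey, lamI_lam$predator, sep = "\r")
  key_obs <- paste(obs$prey, obs$predator, sep = "\r")
  n_silent <- length(setdiff(key_fit, key_obs))
  if (n_silent > 0) {
    message(n_silent, " registered pair(s) without field observations ",
            "excluded from the check")
  }
  idx <- match(key_obs, key_fit)
  if (anyNA(idx)) {
    stop("field data contain pairs unknown to the fit", call. = FALSE)
  }
  qmat <- t(apply(p_draws[, idx, drop = FALSE], 2, quantile_lower,
                  probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  colnames(qmat) <- c("q2.5", "q25", "q50", "q75", "q97.5")
  pred <- t(vapply(seq_along(idx), function(k) {
    predictive_freq_quantiles(p_draws[, idx[k]], obs$n[k],
                              c(0.025, 0.25, 0.75, 0.975))
  }, numeric(4)))
  colnames(pred) <- c("pred_lo95", "pred_lo50", "pred_hi50", "pred_hi95")
  freq <- obs$y / obs$n
  out <- data.frame(prey = obs$prey, predator = obs$predator,
                    n_obs = obs$n, observed_freq = freq, qmat, pred,
                    inside95 = freq >= pred[, "pred_lo95"] &
                      freq <= pred[, "pred_hi95"],
                    inside50 = freq >= pred[, "pred_lo50"] &
                      freq <= pred[, "pred_hi50"],
                    row.names = NULL, check.names = FALSE)
  attr(out, "frac_inside95") <- mean(out$inside95)
  attr(out, "frac_inside50") <- mean(out$inside50)
  out
}
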