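## One moderately sized fit is shared across the blocks below; the heavy
## recovery suite lives in test-acceptance.R.

fit_cache <- new.env()
shared_fit <- function() {
  if (is.null(fit_cache$fit)) {
    scn <- recovery_scenario(501, field_n = 200)
    fit_cache$scn <- scn
    fit_cache$lab <- simulate_feeding_trial(scn)
    fit_cache$field <- simulate_field_tests(scn, seed = 502)
    fit_cache$fit <- fit_model(fit_cache$lab, fit_cache$field, seed = 1,
                               adapt = 500, warmup = 1500, iter = 8000,
                               thin = 4, extend_until_converged = FALSE)
  }
  fit_cache
}

test_that("single-pair recovery: posterior median near truth, CrI covers", {
  scn <- one_pair_scenario(beta0 = 2, beta1 = 0.1, lam = 0.05,
                           field_n = 500, lab_n_per_time = 17, seed = 301)
  lab <- simulate_feeding_trial(scn)       # ~100 lab tests
  field <- simulate_field_tests(scn, seed = 302)
  fit <- fit_model(lab, field, seed = 2, adapt = 500, warmup = 1500,
                   iter = 10000, thin = 4, extend_until_converged = FALSE)
  rates <- posterior_daily_rates(fit)
  med <- quantile(rates$draws[, 1], 0.5, type = 1)
  truth <- 0.05 * 24
  expect_lt(abs(med - truth) / truth, 0.25)
  cri <- quantile(rates$draws[, 1], c(0.05, 0.95), type = 1)
  expect_gte(truth, cri[[1]])
  expect_lte(truth, cri[[2]])
})

test_that("all-negative field data concentrate lambda near zero", {
  scn <- one_pair_scenario(lam = 0, field_n = 300, lab_n_per_time = 10,
                           seed = 303)
  lab <- simulate_feeding_trial(scn)
  field <- simulate_field_tests(scn, seed = 304)
  expect_true(all(field$detected == 0L))
  fit <- fit_model(lab, field, seed = 3, adapt = 500, warmup = 1000,
                   iter = 5000, thin = 2, extend_until_converged = FALSE)
  rates <- posterior_daily_rates(fit)
  ## prior 95% quantile of daily lambda is on the order of e^{2.5} * 24;
  ## the likelihood must push the posterior far below it
  expect_lt(quantile(rates$draws[, 1], 0.95, type = 1), 1)
})

test_that("saturated (all-positive) field data trigger a warning", {
  lab <- data.frame(predator = "c1", prey = "p1",
                    hours_since_feeding = rep(c(2, 24, 72), each = 5),
                    detected = rep(c(1L, 1L, 0L), each = 5))
  field <- data.frame(predator = "c1", prey = "p1", detected = rep(1L, 30))
  expect_warning(
    fit_model(lab, field, seed = 4, adapt = 200, warmup = 500, iter = 1000,
              extend_until_converged = FALSE),
    "saturat")
})

test_that("empty datasets are rejected", {
  lab <- data.frame(predator = character(), prey = character(),
                    hours_since_feeding = numeric(), detected = integer())
  field <- data.frame(predator = "c", prey = "p", detected = 0L)
  expect_error(fit_model(lab, field), "nonempty")
})

test_that("fits are reproducible under identical seed and settings", {
  scn <- one_pair_scenario(field_n = 100, lab_n_per_time = 5, seed = 305)
  lab <- simulate_feeding_trial(scn)
  field <- simulate_field_tests(scn, seed = 306)
  f1 <- fit_model(lab, field, seed = 7, adapt = 300, warmup = 500,
                  iter = 1200, extend_until_converged = FALSE)
  f2 <- fit_model(lab, field, seed = 7, adapt = 300, warmup = 500,
                  iter = 1200, extend_until_converged = FALSE)
  expect_identical(as.matrix(f1$samples), as.matrix(f2$samples))
})

test_that("gelman_rubin flags divergence and accepts identical chains", {
  set.seed(61)
  ## two long chains from the same Normal: ~ 1 within 0.01
  same <- coda::mcmc.list(coda::mcmc(cbind(x = rnorm(4000))),
                          coda::mcmc(cbind(x = rnorm(4000))))
  expect_lt(abs(gelman_rubin(same)[["x"]] - 1), 0.01)
  expect_lt(abs(gelman_rubin(same, method = "classic")[["x"]] - 1), 0.01)
  ## two copies of one chain: between-chain variance is zero
  ch <- cbind(x = rnorm(500))
  copies <- coda::mcmc.list(coda::mcmc(ch), coda::mcmc(ch))
  expect_lt(gelman_rubin(copies, method = "classic")[["x"]], 1)
  ## chains centred 5 apart must be flagged
  apart <- coda::mcmc.list(coda::mcmc(cbind(x = rnorm(1000))),
                           coda::mcmc(cbind(x = rnorm(1000, 5))))
  expect_gt(gelman_rubin(apart)[["x"]], 1.01)
  expect_gt(gelman_rubin(apart, method = "classic")[["x"]], 1.01)
  ## degenerate inputs
  expect_error(gelman_rubin(coda::mcmc.list(coda::mcmc(ch))), "2 chains")
})

test_that("posterior-predictive check brackets observed frequencies", {
  fc <- shared_fit()
  ppc <- posterior_predictive_check(fc$fit, fc$field)
  expect_equal(nrow(ppc), 8)
  expect_true(all(ppc$q2.5 <= ppc$q25 & ppc$q25 <= ppc$q50 &
                    ppc$q50 <= ppc$q75 & ppc$q75 <= ppc$q97.5))
  expect_equal(ppc$observed_freq,
               with(aggregate_field(fc$field), y / n))
  ## a correctly specified fit should bracket most observed frequencies
  expect_gte(attr(ppc, "frac_inside95"), 0.75)
})

test_that("posterior-predictive check handles single-observation species", {
  fc <- shared_fit()
  one <- fc$field[fc$field$predator == fc$scn$predators[1], ][1, ]
  one$predator <- fc$scn$predators[1]
  ppc1 <- posterior_predictive_check(fc$fit, one)
  expect_equal(nrow(ppc1), 1)
  expect_true(ppc1$observed_freq %in% c(0, 1))
  expect_equal(ppc1$n_obs, 1)
})

test_that("fit report summaries match independent recomputation", {
  fc <- shared_fit()
  rep <- fit_report(fc$fit)
  draws <- posterior_daily_rates(fc$fit)
  k <- 3
  key <- paste(rep$rates$prey[k], rep$rates$predator[k])
  col <- which(paste(draws$prey, draws$predator) == key)
  x <- draws$draws[, col]
  expect_equal(rep$rates$mean[k], mean(x))
  expect_equal(rep$rates$sd[k], sd(x))
  expect_equal(rep$rates$median[k], quantile(x, 0.5, type = 1, names = FALSE))
  expect_equal(rep$rates[k, "q95"], quantile(x, 0.95, type = 1, names = FALSE))
  ## quantile convention: lower interpolation picks an attained value
  expect_true(rep$rates$median[k] %in% x)
})

test_that("constant draws summarise to the constant with zero sd", {
  ## two chains of constant lambda draws: median = mean = constant
  x <- matrix(0.1, nrow = 50, ncol = 1,
              dimnames = list(NULL, "lam[1,1]"))
  fake <- structure(list(
    samples = coda::mcmc.list(coda::mcmc(x), coda::mcmc(x)),
    prey = "p1", predators = "c1",
    rhat = c("lam[1,1]" = 1)), class = "predation_fit")
  rates <- posterior_daily_rates(fake)
  expect_equal(unname(colMeans(rates$draws)), 2.4)
  expect_equal(unname(apply(rates$draws, 2, sd)), 0)
  ## lower-interpolation convention on a two-point posterior
  y <- c(rep(exp(0), 3), rep(exp(1), 3))
  expect_equal(quantile(24 * y, 0.5, type = 1, names = FALSE), 24)
})
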