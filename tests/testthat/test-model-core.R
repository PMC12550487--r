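test_that("detection probability follows the logistic digestion curve", {
  expect_equal(detection_probability(0, 1, 0), 0.5)
  expect_equal(detection_probability(2, 0.1, 20), 0.5)  # exponent exactly 0
  expect_equal(detection_probability(3, 0.05, 72), plogis(-0.6),
               tolerance = 1e-12)
  ## numerically stable at extreme exponents
  expect_equal(detection_probability(700, 1, 0), 1)
  expect_equal(detection_probability(-700, 1, 0), 0)
  expect_false(is.nan(detection_probability(0, 10, 70)))
})

test_that("detection probability is monotone in t, beta0 and beta1", {
  t <- seq(0, 72, by = 1.5)
  p <- detection_probability(2, 0.1, t)
  expect_true(all(diff(p) < 0))
  b0 <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(detection_probability(b0, 0.1, 10)) > 0))
  b1 <- seq(0.02, 2, by = 0.02)
  expect_true(all(diff(detection_probability(1, b1, 10)) < 0))
})

test_that("invalid digestion arguments are rejected", {
  expect_error(detection_probability(0, 0, 1), "beta1")
  expect_error(detection_probability(0, -1, 1), "beta1")
  expect_error(detection_probability(0, 1, -1), "t")
  expect_error(detectability_integral(0, 0), "beta1")
  expect_error(field_positive_probability(-0.1, 1), "lam")
  expect_error(field_positive_probability(0.1, -1), "I")
})

test_that("detectability integral matches adaptive quadrature", {
  ## independent oracle: numerical integration of the digestion curve
  quad <- function(beta0, beta1) {
    integrate(function(t) plogis(beta0 - beta1 * t), 0, Inf,
              rel.tol = 1e-12)$value
  }
  expect_equal(detectability_integral(0, 1), log(2), tolerance = 1e-12)
  expect_equal(detectability_integral(2, 0.1), quad(2, 0.1),
               tolerance = 1e-9)
  for (b0 in c(-5, -1, 0, 1.7, 5)) {
    for (b1 in c(0.01, 0.12, 1, 5)) {
      expect_equal(detectability_integral(b0, b1), quad(b0, b1),
                   tolerance = 1e-8)
    }
  }
  ## exact 1/beta1 scaling
  expect_equal(detectability_integral(1.3, 1), 10 * detectability_integral(1.3, 10))
  ## stable for large |beta0|: I ~ beta0/beta1 for large beta0
  expect_equal(detectability_integral(600, 2), 300, tolerance = 1e-12)
  expect_gt(detectability_integral(-600, 2), 0)
})

test_that("field positive probability is 1 - exp(-lam I) with sane limits", {
  expect_equal(field_positive_probability(0, 21.269), 0)
  expect_equal(field_positive_probability(log(2), 1), 0.5)
  expect_equal(field_positive_probability(0.05, 21.269),
               1 - exp(-0.05 * 21.269), tolerance = 1e-12)
  expect_equal(field_positive_probability(0.1, 0), 0)
  ## monotone in both arguments
  expect_true(all(diff(field_positive_probability(seq(0, 1, 0.01), 5)) > 0))
  expect_true(all(diff(field_positive_probability(0.2, seq(0, 40, 0.5))) > 0))
})

test_that("lab log-likelihood sums Bernoulli terms over observations", {
  params <- data.frame(predator = "c1", prey = "p1", beta0 = 0, beta1 = 1)
  one <- data.frame(predator = "c1", prey = "p1", hours_since_feeding = 0,
                    detected = 1L)
  expect_equal(lab_loglik(one, params), log(0.5))
  one$detected <- 0L
  expect_equal(lab_loglik(one, params), log(0.5))

  ## 8-observation toy set against a brute-force row-wise oracle
  set.seed(3)
  params <- data.frame(predator = rep(c("c1", "c2"), each = 2),
                       prey = rep(c("p1", "p2"), 2),
                       beta0 = c(2, 1.5, 2.5, 1), beta1 = c(0.1, 0.3, 0.05, 0.2))
  lab <- data.frame(predator = sample(c("c1", "c2"), 8, TRUE),
                    prey = sample(c("p1", "p2"), 8, TRUE),
                    hours_since_feeding = runif(8, 0, 72),
                    detected = rbinom(8, 1, 0.5))
  oracle <- 0
  for (i in seq_len(8)) {
    row <- params[params$predator == lab$predator[i] &
                    params$prey == lab$prey[i], ]
    pi_d <- 1 / (1 + exp(-(row$beta0 - row$beta1 * lab$hours_since_feeding[i])))
    oracle <- oracle + log(ifelse(lab$detected[i] == 1, pi_d, 1 - pi_d))
  }
  expect_equal(lab_loglik(lab, params), oracle, tolerance = 1e-12)
})

test_that("field log-likelihood matches a row-wise oracle", {
  params <- data.frame(predator = "c1", prey = "p1", lam = log(2), I = 1)
  one <- data.frame(predator = "c1", prey = "p1", detected = 1L)
  expect_equal(field_loglik(one, params), log(0.5))

  ## lam * I = 0 everywhere and all rows negative -> total loglik 0
  zero <- data.frame(predator = "c1", prey = "p1", lam = 0, I = 5)
  allneg <- data.frame(predator = rep("c1", 6), prey = "p1",
                       detected = rep(0L, 6))
  expect_identical(field_loglik(allneg, zero), 0)

  ## 10-row toy set, I derived from beta0/beta1 when not supplied
  set.seed(4)
  params <- data.frame(predator = c("c1", "c2"), prey = "p1",
                       lam = c(0.05, 0.02), beta0 = c(2, 1), beta1 = c(0.1, 0.2))
  field <- data.frame(predator = sample(c("c1", "c2"), 10, TRUE),
                      prey = "p1", detected = rbinom(10, 1, 0.5))
  oracle <- 0
  for (i in seq_len(10)) {
    row <- params[params$predator == field$predator[i], ]
    I <- log(1 + exp(row$beta0)) / row$beta1
    p <- 1 - exp(-row$lam * I)
    oracle <- oracle + log(ifelse(field$detected[i] == 1, p, 1 - p))
  }
  expect_equal(field_loglik(field, params), oracle, tolerance = 1e-12)
})

test_that("observations referencing unknown pairs raise a key error", {
  params <- data.frame(predator = "c1", prey = "p1", beta0 = 0, beta1 = 1)
  bad <- data.frame(predator = "c9", prey = "p1", hours_since_feeding = 1,
                    detected = 1L)
  expect_error(lab_loglik(bad, params), "unknown pair")
  badf <- data.frame(predator = "c1", prey = "p9", detected = 0L)
  expect_error(field_loglik(badf, cbind(params, lam = 0.1, I = 2)),
               "unknown pair")
})

test_that("log-likelihoods stay finite across a parameter sweep", {
  set.seed(5)
  lab <- data.frame(predator = "c1", prey = "p1",
                    hours_since_feeding = runif(20, 0, 72),
                    detected = rbinom(20, 1, 0.5))
  for (b0 in c(-5, 0, 5)) {
    for (b1 in c(0.01, 0.5, 3)) {
      ll <- lab_loglik(lab, data.frame(predator = "c1", prey = "p1",
                                       beta0 = b0, beta1 = b1))
      expect_true(is.finite(ll))
    }
  }
})
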