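test_that("Schneider-Orelli correction matches the hand formula and edge cases", {
  expect_equal(schneider_orelli(50, 0), 50)
  expect_equal(schneider_orelli(10, 10), 0)
  expect_equal(schneider_orelli(87, 3.3), (87 - 3.3) / (100 - 3.3) * 100)
  expect_error(schneider_orelli(50, 100), class = "epfmix_domain_error")
  expect_warning(neg <- schneider_orelli(5, 10), "below zero")
  expect_lt(neg, 0)
})

test_that("Schneider-Orelli is monotone in both arguments", {
  set.seed(21)
  for (i in 1:50) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 99)
    da <- runif(1, 0, 100 - a); db <- runif(1, 0, 99 - b)
    suppressWarnings({
      expect_gte(schneider_orelli(a + da, b), schneider_orelli(a, b))
      expect_lte(schneider_orelli(a, b + db) - schneider_orelli(a, b), 1e-12)
    })
  }
})

test_that("Bliss independence reproduces the worked survival products", {
  expect_equal(bliss_joint_survival(0.25, 0.25), 0.5625)
  expect_equal(bliss_expected_mortality(0.8, 0.8), 0.96)
  for (m in c(0, 0.3, 0.99)) expect_equal(bliss_expected_mortality(0, m), m)
  expect_error(bliss_joint_survival(-0.1, 0.5), class = "epfmix_domain_error")
  expect_error(bliss_joint_survival(0.5, 1.2), class = "epfmix_domain_error")
})

test_that("Bliss expectation is symmetric, bounded, and dominates each single agent", {
  set.seed(22)
  a <- runif(60); b <- runif(60)
  expect_equal(bliss_joint_survival(a, b), bliss_joint_survival(b, a))
  em <- bliss_expected_mortality(a, b)
  expect_true(all(em >= 0 & em <= 1))
  expect_true(all(em >= pmax(a, b) - 1e-12))
})

test_that("noiseless proportions on a known curve are recovered near-exactly", {
  d <- make_dr_data(ec50 = 100, beta = 2, m0 = 0.03, exact = TRUE)
  fit <- fit_dose_response(d, objective = "least-squares")
  expect_equal(fit$ec50, 100, tolerance = 1e-4)
  expect_equal(fit$beta, 2, tolerance = 1e-4)
  expect_equal(fit$m0, 0.03, tolerance = 1e-3)
})

test_that("the optimizer beats a dense brute-force grid on the same data", {
  d <- make_dr_data(seed = 5)
  fit <- fit_dose_response(d, objective = "binomial-ML")
  # independent oracle: direct grid evaluation of the binomial log-likelihood
  grid_ll <- function(ec50, beta, m0) {
    p <- 1 - (1 - m0) / (1 + ifelse(d$dose > 0, (d$dose / ec50)^beta, 0))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(dbinom(d$n_dead, d$n_exposed, p, log = TRUE))
  }
  best <- -Inf
  for (e in exp(seq(log(10), log(1000), length.out = 50)))
    for (b in exp(seq(log(0.3), log(8), length.out = 50)))
      for (m in seq(0.005, 0.2, length.out = 10)) {
        v <- grid_ll(e, b, m)
        if (v > best) best <- v
      }
  expect_gte(fit$loglik_or_ss, best)
})

test_that("degenerate and invalid inputs raise typed errors", {
  d <- make_dr_data(seed = 1)
  d$n_dead <- 0
  expect_error(fit_dose_response(d), class = "epfmix_identifiability_error")
  d2 <- data.frame(dose = c(0, 10), n_exposed = 70, n_dead = c(1, 30))
  expect_error(fit_dose_response(d2), class = "epfmix_validation_error")
})

test_that("lethal concentrations invert the fitted curve", {
  fit <- structure(list(ec50 = 10, beta = 1, m0 = 0,
                        covariance = matrix(0, 3, 3,
                          dimnames = rep(list(c("ec50", "beta", "m0")), 2))),
                   class = "dose_response_fit")
  expect_equal(lc_x(fit, 0.5)$concentration, 10)
  expect_equal(lc_x(fit, 0.8)$concentration, 40)  # 10 * (0.8/0.2)
  expect_error(lc_x(fit, 1.2), class = "epfmix_domain_error")

  d <- make_dr_data(seed = 9)
  f2 <- fit_dose_response(d)
  for (x in c(0.15, 0.5, 0.8)) {
    conc <- lc_x(f2, x)$concentration
    expect_equal(predict(f2, data.frame(dose = conc), scale = "abbott")[1], x,
                 tolerance = 1e-6)
  }
})

test_that("parameters are recovered across seeded replicate bioassays", {
  set.seed(31)
  hits <- 0; n_runs <- 30
  for (r in 1:n_runs) {
    d <- make_dr_data(ec50 = 100, beta = 2, m0 = 0.03,
                      doses = c(0, 20, 60, 180, 540), n = 70)
    fit <- fit_dose_response(d)
    se <- sqrt(fit$covariance["ec50", "ec50"])
    hits <- hits + (abs(fit$ec50 - 100) <= qnorm(0.975) * se)
  }
  expect_gte(hits, 0.8 * n_runs)
})

test_that("fixing m0 on Abbott-corrected data agrees with the joint fit on raw data", {
  d <- make_dr_data(ec50 = 100, beta = 2, m0 = 0.05,
                    doses = c(0, 20, 60, 180, 540), n = 200, seed = 41)
  raw <- fit_dose_response(d, objective = "least-squares")
  # correct proportions to the Abbott scale, refit with m0 pinned to zero
  ctrl <- sum(d$n_dead[d$dose == 0]) / sum(d$n_exposed[d$dose == 0])
  corr <- d
  corr$n_dead <- pmax(0, (d$n_dead / d$n_exposed - ctrl) / (1 - ctrl)) * d$n_exposed
  abb <- fit_dose_response(corr, objective = "least-squares", fix_m0 = 0)
  expect_equal(abb$ec50, raw$ec50, tolerance = 0.15)
  expect_equal(abb$beta, raw$beta, tolerance = 0.25)
})
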