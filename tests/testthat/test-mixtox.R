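test_that("toxic units and composition follow the dose/EC50 arithmetic", {
  tu <- toxic_units(100, 2, 100, 2)
  expect_equal(tu$z1, 0.5); expect_equal(tu$T, 2)
  tu2 <- toxic_units(50, 0, 100, 2)
  expect_equal(tu2$z1, 1); expect_equal(tu2$z2, 0)
  tu3 <- toxic_units(200, 2, 100, 2)
  expect_equal(tu3$z1, 2 / 3); expect_equal(tu3$T, 3)
  expect_true(is.na(toxic_units(0, 0, 100, 2)$z1))
  expect_error(toxic_units(1, 1, 0, 2), class = "epfmix_domain_error")
})

test_that("deviation G vanishes on edges and recovers the reference at a = 0", {
  for (k in c("NONE", "SA", "DR", "DL"))
    expect_equal(deviation_g(k, a = 2, b = 3, z1 = 0, z2 = 1, T = 1), 0)
  z <- seq(0.1, 0.9, 0.2)
  expect_equal(deviation_g("SA", a = 0, z1 = z, z2 = 1 - z, T = 1), rep(0, 5))
  # DR sign switch solves a + b z1 = 0
  z1 <- c(0.1, 0.2, 0.24, 0.26, 0.5, 0.9)
  g <- deviation_g("DR", a = -1, b = 4, z1 = z1, z2 = 1 - z1, T = 1)
  expect_true(all(g[z1 < 0.25] < 0))
  expect_true(all(g[z1 > 0.25] > 0))
  expect_equal(deviation_g("DR", a = -1, b = 4, z1 = 0.25, z2 = 0.75), 0)
  # DL switches sign at total toxic units T = 1/b
  gdl <- deviation_g("DL", a = 1, b = 0.5, z1 = 0.5, z2 = 0.5, T = c(1, 2, 3))
  expect_true(gdl[1] > 0 && gdl[2] == 0 && gdl[3] < 0)
})

test_that("surface predictions honour the IA reference and the sign map", {
  m <- surface_model(100, 2, 1, 1, m0 = 0, kind = "NONE")
  # q1 = q2 = 0.5 at the EC50s: IA mortality 1 - 0.25
  expect_equal(predict_surface(m, 100, 2), 0.75)
  m2 <- surface_model(100, 2, 2, 2, m0 = 0.03)
  expect_equal(predict_surface(m2, 0, 0), 0.03)
  # SA with a = -4 gives G = -1 at the (EC50, EC50) cell; survival logit drops
  m3 <- surface_model(100, 2, 1, 1, m0 = 0, kind = "SA", a = -4)
  expect_equal(predict_surface(m3, 100, 2),
               1 - plogis(qlogis(0.25) - 1))
  # a < 0 is synergism: more mortality than the reference
  expect_gt(predict_surface(m3, 100, 2), 0.75)
  # a > 0 is antagonism: less mortality
  m4 <- surface_model(100, 2, 1, 1, m0 = 0, kind = "SA", a = 4)
  expect_lt(predict_surface(m4, 100, 2), 0.75)
})

test_that("every deviated surface with zero parameters equals the reference", {
  set.seed(51)
  c1 <- c(0, runif(30, 0, 500)); c2 <- c(runif(30, 0, 10), 0)
  ref <- surface_model(100, 2, 1.5, 2.5, m0 = 0.05, kind = "NONE")
  for (k in c("SA", "DR", "DL")) {
    mk <- surface_model(100, 2, 1.5, 2.5, m0 = 0.05, kind = k, a = 0, b = 0)
    expect_equal(predict_surface(mk, c1, c2), predict_surface(ref, c1, c2),
                 tolerance = 1e-12)
  }
})

test_that("single-agent edges of the surface match the single-agent curves", {
  doses <- c(0, 10^(0:4) / 10)
  for (k in c("NONE", "SA", "DR", "DL")) {
    m <- surface_model(100, 2, 1.5, 2.5, m0 = 0.04, kind = k, a = -2, b = 5)
    edge1 <- predict_surface(m, doses, 0)
    curve1 <- 1 - (1 - 0.04) / (1 + ifelse(doses > 0, (doses / 100)^1.5, 0))
    expect_equal(edge1, curve1, tolerance = 1e-9)
    edge2 <- predict_surface(m, 0, doses)
    curve2 <- 1 - (1 - 0.04) / (1 + ifelse(doses > 0, (doses / 2)^2.5, 0))
    expect_equal(edge2, curve2, tolerance = 1e-9)
  }
})

test_that("the surface optimizer beats a coarse brute-force grid", {
  # tiny instance: 2 doses per agent, 1 mixture cell, NONE kind
  truth <- surface_model(50, 1, 2, 2, m0 = 0.05)
  cells <- data.frame(dose1 = c(0, 25, 100, 0, 0, 25),
                      dose2 = c(0, 0, 0, 0.5, 2, 0.5))
  set.seed(61)
  d <- data.frame(cells, n_exposed = 70,
                  n_dead = rbinom(6, 70, predict_surface(truth, cells$dose1, cells$dose2)))
  fit <- fit_surface(d, "NONE", "binomial-ML")
  # independent oracle: direct grid evaluation
  ll <- function(e1, e2, b1, b2, m0) {
    q1 <- 1 / (1 + ifelse(d$dose1 > 0, (d$dose1 / e1)^b1, 0))
    q2 <- 1 / (1 + ifelse(d$dose2 > 0, (d$dose2 / e2)^b2, 0))
    p <- pmin(pmax(1 - (1 - m0) * q1 * q2, 1e-12), 1 - 1e-12)
    sum(dbinom(d$n_dead, d$n_exposed, p, log = TRUE))
  }
  best <- -Inf
  for (e1 in exp(seq(log(10), log(200), length.out = 6)))
    for (e2 in exp(seq(log(0.2), log(4), length.out = 6)))
      for (b1 in c(0.5, 1, 2, 4))
        for (b2 in c(0.5, 1, 2, 4))
          for (m0 in c(0.01, 0.05, 0.1, 0.2)) {
            v <- ll(e1, e2, b1, b2, m0)
            if (v > best) best <- v
          }
  expect_gte(fit$loglik_or_ss, best)
})

test_that("nested comparisons book-keep df and select the parsimonious model", {
  mk <- function(kind, ll, n_params) {
    m <- surface_model(100, 2, 2, 2, kind = kind, a = 0.1, b = 0.1)
    m$objective <- "binomial-ML"; m$loglik_or_ss <- ll
    m$data <- data.frame(dose1 = 1, dose2 = 1, n_exposed = 1, n_dead = 0)
    m
  }
  # identical fits: statistic 0, p 1, null kept
  cmp <- compare_surface_models(list(mk("NONE", -100), mk("SA", -100)))
  expect_equal(cmp$comparisons$statistic, 0)
  expect_equal(cmp$comparisons$p_value, 1)
  expect_equal(cmp$selected_kind, "NONE")

  cmp2 <- compare_surface_models(list(mk("NONE", -110), mk("SA", -104),
                                      mk("DR", -100)))
  expect_equal(cmp2$comparisons$df, c(1, 1))
  expect_equal(cmp2$comparisons$null, c("NONE", "SA"))
  expect_equal(cmp2$comparisons$statistic, c(12, 8))
  expect_equal(cmp2$selected_kind, "DR")

  # a worse alternative is clamped at zero with a warning
  expect_warning(
    cmp3 <- compare_surface_models(list(mk("NONE", -100), mk("SA", -101))),
    "clamped")
  expect_equal(cmp3$comparisons$statistic, 0)
})

test_that("deviated fits never lose explained variance to their nested null", {
  cfg <- simulation_config(seed = 71, deviation = list(kind = "SA", a = -2))
  g <- generate_bioassay(cfg, n_bioassays = 1)
  f0 <- fit_surface(g$observations, "NONE")
  for (k in c("SA", "DR")) {
    fk <- fit_surface(g$observations, k, null_fit = f0)
    expect_gte(fk$r_squared, f0$r_squared - 1e-8)
    expect_gte(fk$loglik_or_ss, f0$loglik_or_ss - 1e-6)
  }
})

test_that("interaction maps label the plane by the sign of the deviation", {
  grid <- list(dose1 = 10^(0:3), dose2 = 10^(-1:2) / 10)
  none <- surface_model(100, 2, 2, 2, kind = "NONE")
  im0 <- classify_interaction(none, grid = grid)
  expect_true(all(im0$grid$label == "additive"))
  expect_null(im0$switch_ratio)

  ant <- surface_model(100, 2, 2, 2, kind = "SA", a = 1.5)
  im1 <- classify_interaction(ant, grid = grid)
  expect_true(all(im1$grid$label == "antagonism"))

  # label antisymmetry under a sign flip
  syn <- surface_model(100, 2, 2, 2, kind = "SA", a = -1.5)
  im2 <- classify_interaction(syn, grid = grid)
  swap <- c(synergy = "antagonism", antagonism = "synergy", additive = "additive")
  expect_equal(unname(swap[im1$grid$label]), im2$grid$label)
})

test_that("the dose-ratio switch point follows the analytic boundary", {
  m <- surface_model(100, 2, 2, 2, kind = "DR", a = -1, b = 4)
  # boundary at z1* = 1/4; on the toxic-unit scale tu2/tu1 = 3
  expect_equal(classify_interaction(m, grid = list(dose1 = 1, dose2 = 1))$switch_z,
               0.25)
  expect_equal(classify_interaction(m, grid = list(dose1 = 1, dose2 = 1))$switch_ratio,
               (2 / 100) * 3)
  grid <- list(dose1 = 10^seq(0, 3, length.out = 15),
               dose2 = 10^seq(-2, 1, length.out = 15))
  im <- classify_interaction(m, grid = grid)
  g <- im$grid
  z1 <- (g$dose1 / 100) / (g$dose1 / 100 + g$dose2 / 2)
  expect_true(all(g$label[z1 < 0.249] == "synergy"))      # G < 0 below z1*
  expect_true(all(g$label[z1 > 0.251] == "antagonism"))   # G > 0 above z1*
  expect_equal(im$relative_potency, 50)
})

test_that("the exported grid carries isoboles, fit, labels and observations", {
  truth <- surface_model(100, 2, 2, 2, m0 = 0.03)
  set.seed(81)
  d <- data.frame(dose1 = c(0, 50, 200, 0, 0, 50, 200),
                  dose2 = c(0, 0, 0, 1, 4, 1, 4), n_exposed = 70)
  d$n_dead <- rbinom(7, 70, predict_surface(truth, d$dose1, d$dose2))
  fit <- fit_surface(d, "NONE")
  tab <- export_surface_grid(fit, n_grid = 2)
  expect_equal(sum(tab$source == "grid"), 4)
  expect_equal(sum(tab$source == "observed"), 7)
  expect_error(export_surface_grid(fit, n_grid = 0), class = "epfmix_validation_error")

  # expected-IA column on an edge equals the single-agent curve
  edge <- predict_surface(fit, c(10, 100), c(0, 0), component = "reference")
  curve <- 1 - (1 - fit$m0) / (1 + (c(10, 100) / fit$ec50_1)^fit$beta_1)
  expect_equal(edge, curve, tolerance = 1e-9)

  # isobole monotonicity along random dose rays
  set.seed(82)
  for (i in 1:10) {
    dir <- runif(2, 0.1, 1)
    s <- seq(0, 5, length.out = 40)
    ia <- predict_surface(fit, s * dir[1] * 100, s * dir[2] * 2,
                          component = "reference")
    expect_true(all(diff(ia) >= -1e-12))
  }
})
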