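test_that("noiseless time-course data recover the four parameters", {
  d <- make_tm_data(lt50 = 10, slope = 3, lower = 0, upper = 0.9)
  fit <- fit_time_mortality(d)
  expect_equal(fit$lt50, 10, tolerance = 1e-3)
  expect_equal(fit$slope, 3, tolerance = 5e-3)
  expect_equal(fit$upper, 0.9, tolerance = 1e-3)
  expect_lt(fit$lower, 1e-3)
})

test_that("the curve midpoint is the LT50, analytically and after fitting", {
  d <- make_tm_data(lt50 = 8, slope = 2.5, lower = 0.05, upper = 0.8)
  fit <- fit_time_mortality(d)
  mid <- predict(fit, data.frame(day = fit$lt50))
  expect_equal(mid, (fit$lower + fit$upper) / 2, tolerance = 1e-9)
})

test_that("fits are invariant to the time unit up to rescaling of the LT50", {
  set.seed(91)
  cfg <- simulation_config(seed = 91, design = data.frame(lc_fungus = 0.5, lc_chem = 0),
                           lt50 = 10, slope_time = 3)
  d <- generate_time_course(cfg, n_bioassays = 1)
  f_days <- fit_time_mortality(d)
  d_hours <- transform(d, day = day * 24)
  f_hours <- fit_time_mortality(d_hours)
  expect_equal(f_hours$lt50 / 24, f_days$lt50, tolerance = 1e-4)
  expect_equal(f_hours$slope, f_days$slope, tolerance = 1e-4)
  expect_equal(f_hours$loglik, f_days$loglik, tolerance = 1e-6)
})

test_that("degenerate time courses raise typed errors; slow kill is flagged", {
  d0 <- data.frame(day = c(2, 4, 6), n_exposed = 70, n_dead = 0)
  expect_error(fit_time_mortality(d0), class = "epfmix_identifiability_error")
  d1 <- data.frame(day = c(2, 4, 6), n_exposed = 70, n_dead = 35)
  expect_error(fit_time_mortality(d1), class = "epfmix_identifiability_error")
  d2 <- data.frame(day = c(2, 4), n_exposed = 70, n_dead = c(1, 2))
  expect_error(fit_time_mortality(d2), class = "epfmix_validation_error")
  # mortality never reaches the midpoint inside the horizon
  d3 <- make_tm_data(lt50 = 40, slope = 3, lower = 0, upper = 0.9)
  expect_warning(f3 <- fit_time_mortality(d3), "extrapolated")
  expect_true(f3$extrapolated)
  expect_gt(f3$lt50, 14)
})

test_that("binomial and multinomial likelihood options give close estimates", {
  cfg <- simulation_config(seed = 93, design = data.frame(lc_fungus = 0.5, lc_chem = 0),
                           lt50 = 9, slope_time = 3)
  d <- generate_time_course(cfg, n_bioassays = 1)
  fm <- fit_time_mortality(d, likelihood = "multinomial")
  fb <- fit_time_mortality(d, likelihood = "binomial")
  expect_equal(fb$lt50, fm$lt50, tolerance = 0.15)
})

test_that("a duplicated treatment yields a null shared-LT50 statistic", {
  d <- make_tm_data(lt50 = 10, slope = 3, upper = 0.9, n = 500)
  two <- rbind(transform(d, treatment = "A", replicate = 1),
               transform(d, treatment = "B", replicate = 1))
  ct <- suppressWarnings(compare_lt50_constraint(two))
  expect_lt(ct$statistic, 0.02)
  expect_false(ct$constraint_rejected)
  expect_error(compare_lt50_constraint(transform(d, treatment = "A")),
               class = "epfmix_validation_error")
})

test_that("LT50 reductions propagate from a table of printed estimates", {
  # mixture 8.22 +/- 0.62 vs singles 12.51 +/- 1.49 and 12.11 +/- 0.61
  tab <- data.frame(treatment = c("LC50xLC50", "EPF_LC50", "CHEM_LC50"),
                    lt50 = c(8.22, 12.51, 12.11),
                    lt50_se = c(0.62, 1.49, 0.61))
  map <- data.frame(mixture = "LC50xLC50", single1 = "EPF_LC50",
                    single2 = "CHEM_LC50")
  red <- lt50_reduction_table(tab, map)
  expect_equal(red$reduction_days, 12.11 - 8.22)
  expect_equal(red$faster_single, "CHEM_LC50")
  expect_equal(red$se, sqrt(0.62^2 + 0.61^2))

  tab2 <- data.frame(treatment = c("M", "S1", "S2"), lt50 = c(10, 10, 10),
                     lt50_se = 0)
  map2 <- data.frame(mixture = "M", single1 = "S1", single2 = "S2")
  expect_equal(lt50_reduction_table(tab2, map2)$reduction_days, 0)

  tab3 <- tab2; tab3$lt50 <- c(12, 10, 11)  # mixture slower: negative, kept
  expect_equal(lt50_reduction_table(tab3, map2)$reduction_days, -2)

  expect_error(lt50_reduction_table(tab2, data.frame(
    mixture = "M", single1 = "S1", single2 = "missing")),
    class = "epfmix_validation_error")
})
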