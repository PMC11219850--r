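test_that("a well-formed table reads cleanly and round-trips bit-identically", {
  rows <- make_bioassay_rows()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE)
  obs <- read_bioassay_table(path)
  expect_s3_class(obs, "bioassay_data")
  expect_equal(nrow(obs), 3)

  out <- withr::local_tempfile(fileext = ".csv")
  write_bioassay_table(obs, out)
  again <- read_bioassay_table(out)
  expect_identical(as.data.frame(again), as.data.frame(obs))
})

test_that("column mapping through the manifest renames user columns", {
  rows <- make_bioassay_rows()
  names(rows)[names(rows) == "n_dead"] <- "dead_count"
  mf <- bioassay_manifest(columns = c(n_dead = "dead_count"))
  obs <- read_bioassay_table(rows, mf)
  expect_true("n_dead" %in% names(obs))
  expect_equal(obs$n_dead[obs$treatment == "T2"], 12)
})

test_that("dead counts exceeding exposed fail validation naming the row", {
  rows <- make_bioassay_rows()
  rows$n_dead[1] <- 71
  err <- expect_error(read_bioassay_table(rows), class = "epfmix_validation_error")
  expect_match(conditionMessage(err), "row\\(s\\) 1")
})

test_that("a dip in cumulative deaths is caught and names the replicate", {
  rows <- expand.grid(day = c(2, 6, 10), replicate = 1)
  rows <- data.frame(bioassay = 1, treatment = "T1", replicate = 1,
                     dose_fungus = 10, dose_chem = 0, day = c(2, 6, 10),
                     n_exposed = 70, n_dead = c(5, 12, 9))
  err <- expect_error(read_bioassay_table(rows), class = "epfmix_validation_error")
  expect_match(conditionMessage(err), "decrease over time in replicate")
  expect_match(conditionMessage(err), "T1")
})

test_that("incremental death files are converted to cumulative on read", {
  rows <- data.frame(bioassay = 1, treatment = "T1", replicate = 1,
                     dose_fungus = 10, dose_chem = 0, day = c(2, 6, 10),
                     n_exposed = 70, n_dead = c(5, 7, 2))
  obs <- read_bioassay_table(rows, bioassay_manifest(deaths = "incremental"))
  expect_equal(obs$n_dead, c(5, 12, 14))
})

test_that("dose/LC-label mismatches and out-of-horizon days are rejected", {
  rows <- make_bioassay_rows()
  rows$lc_fungus <- c("LC50", "LC50", "LC15")  # T2 has dose_fungus 0
  expect_error(read_bioassay_table(rows), class = "epfmix_validation_error")
  rows2 <- make_bioassay_rows()
  rows2$day <- 20
  expect_error(read_bioassay_table(rows2), class = "epfmix_validation_error")
})

test_that("deposition follows the CFU dilution arithmetic", {
  expect_equal(deposition_from_cfu(0, 100, 0.04, 1), 0)
  # 100 CFU x dilution 100 x (1 mL / 0.04 mL) / 484 mm^2
  expect_equal(deposition_from_cfu(100, 100, 0.04, 1), 100 * 100 * 25 / 484)
  d1 <- deposition_from_cfu(37, 10, 0.1, 2, viability = 0.5)
  d2 <- deposition_from_cfu(37, 10, 0.1, 2, viability = 1)
  expect_equal(d2 / d1, 0.5)
  expect_error(deposition_from_cfu(10, 100, 0, 1), class = "epfmix_domain_error")
  expect_error(deposition_from_cfu(10, 100, 0.04, 1, coverslip_area = 0),
               class = "epfmix_domain_error")
})

test_that("deposition is linear in CFU count and dilution factor", {
  set.seed(11)
  for (i in 1:25) {
    cfu <- runif(1, 1, 500); dil <- runif(1, 1, 1000)
    pv <- runif(1, 0.01, 1); wv <- runif(1, 0.5, 10)
    base <- deposition_from_cfu(cfu, dil, pv, wv)
    expect_equal(deposition_from_cfu(3 * cfu, dil, pv, wv), 3 * base)
    expect_equal(deposition_from_cfu(cfu, 5 * dil, pv, wv), 5 * base)
  }
})

test_that("deposition summaries use the n-1 sample SD and flag singletons", {
  s <- data.frame(treatment = rep(c("A", "B"), c(3, 1)),
                  dose = c(10, 12, 14, 99))
  out <- summarize_deposition(s)
  a <- out[out$treatment == "A", ]
  expect_equal(a$mean_dose, 12)
  expect_equal(a$sd_dose, 2)
  b <- out[out$treatment == "B", ]
  expect_true(is.na(b$sd_dose))
  expect_true(b$single_sample)

  s2 <- data.frame(treatment = rep("A", 3), dose = c(7, 7, 7))
  expect_equal(summarize_deposition(s2)$sd_dose, 0)

  s3 <- data.frame(treatment = factor(rep("A", 2), levels = c("A", "B")),
                   dose = c(1, 2))
  expect_warning(out3 <- summarize_deposition(s3), "no deposition samples")
  expect_false("B" %in% out3$treatment)
})
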