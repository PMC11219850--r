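# fixture builders shared across test files; all data generated in code

# replicate-level binomial counts on an exact log-logistic curve
make_dr_data <- function(ec50 = 100, beta = 2, m0 = 0.03,
                         doses = c(0, 10, 30, 100, 300, 1000),
                         n = 70, reps = 3, seed = NULL, exact = FALSE) {
  d <- expand.grid(dose = doses, rep = seq_len(reps))
  p <- 1 - (1 - m0) / (1 + ifelse(d$dose > 0, (d$dose / ec50)^beta, 0))
  dead <- if (exact) n * p else {
    if (!is.null(seed)) set.seed(seed)
    rbinom(nrow(d), n, p)
  }
  data.frame(dose = d$dose, n_exposed = n, n_dead = dead)
}

# minimal terminal-mortality bioassay table (cumulative deaths, one day)
make_bioassay_rows <- function() {
  data.frame(
    bioassay = 1, treatment = c("T1", "T1", "T2"), replicate = c(1, 2, 1),
    dose_fungus = c(10, 10, 0), dose_chem = c(0, 0, 1),
    day = 14, n_exposed = 70, n_dead = c(30, 28, 12))
}

# exact expected cumulative time-course counts for one cohort
make_tm_data <- function(lt50 = 10, slope = 3, lower = 0, upper = 0.9,
                         days = seq(2, 14, 2), n = 1000) {
  Ft <- lower + (upper - lower) * pnorm(slope * (log(days) - log(lt50)))
  data.frame(day = days, n_exposed = n, n_dead = n * Ft)
}
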