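#' Default 12-treatment mixture design plus control
#'
#' The replicated leaf-cohort layout: LC15/LC50/LC80 singles of each agent,
#' the six mixture cells admissible under a 90% expected-mortality ceiling
#' (LC15 crossed with all three levels of the partner, LC50 x LC15,
#' LC50 x LC50, LC80 x LC15), and the untreated control.
#'
#' @return data frame with columns `lc_fungus`, `lc_chem` (Abbott-scale
#'   mortality fractions; 0 = not applied).
#' @export
default_mixture_design <- function() {
  data.frame(
    lc_fungus = c(0, 0.15, 0.50, 0.80, 0, 0, 0,
                  0.15, 0.15, 0.15, 0.50, 0.50, 0.80),
    lc_chem = c(0, 0, 0, 0, 0.15, 0.50, 0.80,
                0.15, 0.50, 0.80, 0.15, 0.50, 0.15))
}

#' Configuration for the synthetic bioassay generator
#'
#' Bundles the true data-generating state: single-agent log-logistic
#' parameters, per-bioassay background mortality, the deviation truth, the
#' treatment design, replication, deposition scatter and the census
#' schedule. Defaults reproduce the replicated whitefly leaf-cohort design:
#' 3 replicate leaves x 24 nymphs per treatment (at least 70 per
#' treatment), 3 bioassays, background mortality 2.7/14.3/3.3%, lognormal
#' deposition scatter with CV 0.15, 14-day horizon censused every 48 h.
#'
#' @param seed integer seed; identical configurations generate identical data.
#' @param ec50,beta length-2 vectors of true single-agent parameters
#'   (fungus, chemical).
#' @param m0 background mortality per bioassay.
#' @param deviation list with `kind` (`"NONE"`, `"SA"`, `"DR"`, `"DL"`) and
#'   parameters `a`, `b`.
#' @param design treatment design, see [default_mixture_design()].
#' @param n_replicates replicate leaves per treatment.
#' @param n_exposed nymphs per replicate leaf.
#' @param deposition_cv lognormal coefficient of variation of realised
#'   fungal dose about its target (0 = exact).
#' @param horizon_days,census_interval_days time-course schedule.
#' @param lt50,slope_time true time-mortality parameters (shared across
#'   treatments unless named per treatment cell).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              ec50 = c(fungus = 100, chem = 1),
                              beta = c(fungus = 2, chem = 2),
                              m0 = c(0.027, 0.143, 0.033),
                              deviation = list(kind = "NONE", a = 0, b = 0),
                              design = default_mixture_design(),
                              n_replicates = 3,
                              n_exposed = 24,
                              deposition_cv = 0.15,
                              horizon_days = 14,
                              census_interval_days = 2,
                              lt50 = 10,
                              slope_time = 3) {
  deviation$a <- deviation$a %||% 0
  deviation$b <- deviation$b %||% 0
  kind <- match.arg(deviation$kind, c("NONE", "SA", "DR", "DL"))
  if (kind %in% c("SA", "DR", "DL") && is.null(deviation$a))
    stop_epfmix("deviation kind needs parameter a", "epfmix_config_error")
  if (kind %in% c("DR", "DL") && is.null(deviation$b))
    stop_epfmix("deviation kind needs parameter b", "epfmix_config_error")
  stopifnot(all(ec50 > 0), all(beta > 0), all(m0 >= 0 & m0 < 1),
            n_replicates >= 1, n_exposed >= 1, deposition_cv >= 0,
            horizon_days > 0, lt50 > 0, slope_time > 0)
  if (census_interval_days > horizon_days)
    stop_epfmix("census interval exceeds the horizon", "epfmix_config_error")
  if (anyDuplicated(design))
    stop_epfmix("design cells must be unique", "epfmix_config_error")
  structure(list(seed = seed, ec50 = ec50, beta = beta, m0 = m0,
                 deviation = list(kind = kind, a = deviation$a, b = deviation$b),
                 design = design, n_replicates = n_replicates,
                 n_exposed = n_exposed, deposition_cv = deposition_cv,
                 horizon_days = horizon_days,
                 census_interval_days = census_interval_days,
                 lt50 = lt50, slope_time = slope_time),
            class = "simulation_config")
}

# truth surface for bioassay b of a configuration
truth_surface <- function(config, bioassay = 1) {
  m0 <- config$m0[((bioassay - 1) %% length(config$m0)) + 1]
  surface_model(ec50_1 = config$ec50[1], ec50_2 = config$ec50[2],
                beta_1 = config$beta[1], beta_2 = config$beta[2],
                m0 = m0, kind = config$deviation$kind,
                a = config$deviation$a, b = config$deviation$b)
}

# target dose for an Abbott-scale LC level under the true curve
lc_target_dose <- function(level, ec50, beta) {
  ifelse(level <= 0, 0, ec50 * (level / (1 - level))^(1 / beta))
}

rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate terminal-mortality bioassay data from a known truth
#'
#' Emulates the replicated leaf-cohort design: per bioassay, treatment cell
#' and replicate leaf, the realised fungal dose is drawn lognormal around
#' the LC-target concentration (the chemical dose stays nominal, mirroring
#' the pipeline's dose semantics), and terminal deaths are binomial with
#' probability given by the true deviation surface. Coverslip deposition
#' triplicates are drawn around the same realised treatment means so the
#' calibration tables and the dose column tell one consistent story.
#'
#' @param config a [simulation_config()].
#' @param n_bioassays number of replicate bioassays (default 3).
#' @return list with `observations` (a `bioassay_data`-shaped data frame at
#'   the terminal assessment), `deposition` (coverslip samples), and
#'   `truth` (the generating `surface_fit` per bioassay).
#' @export
generate_bioassay <- function(config, n_bioassays = 3) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  des <- config$design
  obs <- list(); dep <- list()
  truths <- lapply(seq_len(n_bioassays), function(b) truth_surface(config, b))
  for (b in seq_len(n_bioassays)) {
    truth <- truths[[b]]
    for (i in seq_len(nrow(des))) {
      target_f <- lc_target_dose(des$lc_fungus[i], config$ec50[1], config$beta[1])
      dose_c <- lc_target_dose(des$lc_chem[i], config$ec50[2], config$beta[2])
      trt <- paste0("F", des$lc_fungus[i] * 100, "_C", des$lc_chem[i] * 100)
      dose_f <- rlnorm_cv(config$n_replicates, target_f, config$deposition_cv)
      p <- predict_surface(truth, dose_f, rep(dose_c, config$n_replicates))
      dead <- stats::rbinom(config$n_replicates, config$n_exposed, p)
      obs[[length(obs) + 1]] <- data.frame(
        bioassay = b, treatment = trt, replicate = seq_len(config$n_replicates),
        lc_fungus = des$lc_fungus[i], lc_chem = des$lc_chem[i],
        dose_fungus = dose_f, dose_chem = dose_c,
        day = config$horizon_days, n_exposed = config$n_exposed, n_dead = dead)
      if (target_f > 0) {
        # three coverslips per fungus treatment; back out integer CFU counts
        slip_dose <- rlnorm_cv(3, mean(dose_f), config$deposition_cv)
        cfu <- round(slip_dose * 484 * 0.04 / (1 * 100))
        dep[[length(dep) + 1]] <- data.frame(
          bioassay = b, treatment = trt, coverslip = 1:3,
          cfu_count = cfu, dilution_factor = 100, plated_volume = 0.04,
          wash_volume = 1, coverslip_area = 484)
      }
    }
  }
  list(observations = do.call(rbind, obs),
       deposition = do.call(rbind, dep),
       truth = truths)
}

#' Generate 48-h-census time-course data from a known truth
#'
#' Draws an individual death day for every exposed nymph from the
#' four-parameter time-mortality law whose asymptote per treatment is the
#' terminal mortality of the configuration's truth surface at the target
#' doses, bins deaths onto the census schedule, and returns cumulative
#' counts (monotone by construction).
#'
#' @param config a [simulation_config()]; `lt50` and `slope_time` may be a
#'   single value shared by all treatments or a vector named by treatment
#'   cell label.
#' @param n_bioassays number of replicate bioassays.
#' @return data frame with columns `bioassay`, `treatment`, `replicate`,
#'   `day`, `n_exposed`, `n_dead` (cumulative).
#' @export
generate_time_course <- function(config, n_bioassays = 3) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  des <- config$design
  days <- seq(config$census_interval_days, config$horizon_days,
              by = config$census_interval_days)
  out <- list()
  for (b in seq_len(n_bioassays)) {
    truth <- truth_surface(config, b)
    for (i in seq_len(nrow(des))) {
      target_f <- lc_target_dose(des$lc_fungus[i], config$ec50[1], config$beta[1])
      dose_c <- lc_target_dose(des$lc_chem[i], config$ec50[2], config$beta[2])
      trt <- paste0("F", des$lc_fungus[i] * 100, "_C", des$lc_chem[i] * 100)
      upper <- predict_surface(truth, target_f, dose_c)
      lt <- if (length(config$lt50) > 1) config$lt50[[trt]] else config$lt50
      sl <- if (length(config$slope_time) > 1) config$slope_time[[trt]]
            else config$slope_time
      for (r in seq_len(config$n_replicates)) {
        u <- stats::runif(config$n_exposed)
        Ft <- tm_cdf(days, 0, upper, sl, lt)
        cum <- vapply(Ft, function(f) sum(u < f), integer(1))
        out[[length(out) + 1]] <- data.frame(
          bioassay = b, treatment = trt, replicate = r, day = days,
          n_exposed = config$n_exposed, n_dead = cum)
      }
    }
  }
  do.call(rbind, out)
}

#' Filter candidate LC pairs by an expected-mortality ceiling
#'
#' Keeps only the mixture cells whose independent-action expected mortality
#' (via Bliss) does not exceed the ceiling — the design rule that makes
#' synergism detectable: cells expected to kill nearly everything under
#' additivity are redundant. With the default 0.9 ceiling an LC80 x LC80
#' cell (expected 96%) is excluded.
#'
#' @param pairs data frame with columns `lc1`, `lc2` of Abbott-scale
#'   single-agent mortality fractions.
#' @param ceiling maximum admissible expected mortality (default 0.9).
#' @return `pairs` restricted to admissible rows, with an
#'   `expected_mortality` column appended.
#' @export
design_ceiling_filter <- function(pairs, ceiling = 0.9) {
  stopifnot(all(c("lc1", "lc2") %in% names(pairs)))
  pairs$expected_mortality <- bliss_expected_mortality(pairs$lc1, pairs$lc2)
  pairs[pairs$expected_mortality <= ceiling, , drop = FALSE]
}
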