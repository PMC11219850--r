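# four-parameter time-mortality law: cumulative mortality at time t is
# F(t) = lower + (upper - lower) * link(slope * (log t - log lt50)),
# probit link by default. F(lt50) = (lower + upper)/2 by construction.
tm_cdf <- function(t, lower, upper, slope, lt50, link = "probit") {
  lp <- slope * (log(t) - log(lt50))
  h <- if (link == "probit") stats::pnorm(lp) else stats::plogis(lp)
  lower + (upper - lower) * h
}

# theta = (qlogis lower, qlogis upper-share, log slope, log lt50);
# upper = lower + (1 - lower) * plogis(theta2) guarantees lower <= upper <= 1
tm_theta_to_par <- function(theta) {
  lower <- stats::plogis(theta[1])
  list(lower = lower,
       upper = lower + (1 - lower) * stats::plogis(theta[2]),
       slope = exp(theta[3]),
       lt50 = exp(theta[4]))
}

# negative log-likelihood over replicate cohorts. Multinomial: each cohort's
# census increments are one multinomial draw over death intervals plus the
# survivors' cell (censuses of one cohort are not independent binomials).
# Binomial: independent binomial at each census, for comparability.
tm_nll <- function(theta, cohorts, link, likelihood) {
  if (any(!is.finite(theta))) return(1e10)
  p <- tm_theta_to_par(theta)
  if (any(!vapply(p, is.finite, logical(1)))) return(1e10)
  tot <- 0
  for (ch in cohorts) {
    Ft <- clamp01(tm_cdf(ch$day, p$lower, p$upper, p$slope, p$lt50, link))
    if (any(!is.finite(Ft))) return(1e10)
    if (likelihood == "multinomial") {
      pk <- diff(c(0, Ft))
      if (any(pk <= 0)) pk <- pmax(pk, 1e-12)
      inc <- diff(c(0, ch$n_dead))
      surv <- ch$n_exposed[1] - ch$n_dead[length(ch$n_dead)]
      tot <- tot - sum(inc * log(pk)) - surv * log(max(1 - Ft[length(Ft)], 1e-12))
    } else {
      tot <- tot - sum(stats::dbinom(ch$n_dead, ch$n_exposed, Ft, log = TRUE))
    }
  }
  if (!is.finite(tot)) 1e10 else tot
}

split_cohorts <- function(data) {
  key <- interaction(data$bioassay %||% 1,
                     if ("replicate" %in% names(data)) data$replicate else 1,
                     drop = TRUE)
  lapply(split(data, key), function(ch) ch[order(ch$day), , drop = FALSE])
}

#' Fit a four-parameter time-mortality curve and estimate LT50
#'
#' Fits `F(t) = lower + (upper - lower) * Phi(slope * (log t - log LT50))`
#' (probit on log time; a log-logistic link is available) to repeated-census
#' cumulative mortality counts for one treatment, by maximum likelihood.
#' Deaths between censuses are interval-censored onto the census day; the
#' default likelihood treats each replicate cohort's census increments as a
#' single multinomial draw (censuses of one cohort are not independent),
#' with a per-census binomial option. The LT50 standard error comes from
#' the observed information by the delta method. An LT50 beyond the study
#' horizon is reported with an `extrapolated` flag rather than censored.
#'
#' @param data data frame with columns `day`, `n_exposed`, `n_dead`
#'   (cumulative), and optionally `replicate`/`bioassay` identifying cohorts.
#' @param likelihood `"multinomial"` (default) or `"binomial"`.
#' @param link `"probit"` (default) or `"logit"`.
#' @param treatment optional treatment label carried into the fit.
#' @return object of class `time_mortality_fit` with `lower`, `upper`,
#'   `slope`, `lt50`, `lt50_se`, `loglik`, `n_params = 4`, `extrapolated`.
#' @export
fit_time_mortality <- function(data, likelihood = c("multinomial", "binomial"),
                               link = c("probit", "logit"), treatment = NULL) {
  likelihood <- match.arg(likelihood)
  link <- match.arg(link)
  stopifnot(all(c("day", "n_exposed", "n_dead") %in% names(data)))
  if (any(data$day <= 0))
    stop_epfmix("assessment days must be positive", "epfmix_validation_error")
  cohorts <- split_cohorts(data)
  if (length(unique(data$day)) < 3)
    stop_epfmix("need >= 3 assessment days", "epfmix_validation_error")
  for (ch in cohorts) {
    if (any(diff(ch$n_dead) < 0))
      stop_epfmix("cumulative deaths must be non-decreasing within a cohort",
                  "epfmix_validation_error")
  }
  total_final <- sum(vapply(cohorts, function(ch) ch$n_dead[nrow(ch)], 0))
  if (total_final == 0)
    stop_epfmix("no mortality signal: zero deaths throughout",
                "epfmix_identifiability_error")
  # constant non-zero mortality at every census carries no time signal
  if (all(vapply(cohorts, function(ch) all(diff(ch$n_dead) == 0), logical(1))))
    stop_epfmix("mortality constant across censuses: slope not identifiable",
                "epfmix_identifiability_error")

  # starts: lower near first-census rate, upper near final rate,
  # lt50 where pooled cumulative mortality crosses the midpoint
  days <- sort(unique(data$day))
  pooled <- vapply(days, function(dd) {
    sub <- data[data$day == dd, ]
    sum(sub$n_dead) / sum(sub$n_exposed)
  }, 0)
  lo0 <- min(max(pooled[1] / 2, 1e-3), 0.4)
  up0 <- min(max(pooled[length(pooled)], lo0 + 0.05), 0.995)
  mid <- (lo0 + up0) / 2
  lt0 <- if (any(pooled >= mid)) days[which(pooled >= mid)[1]] else max(days) * 1.5
  th_base <- c(stats::qlogis(lo0),
               stats::qlogis(min(max((up0 - lo0) / (1 - lo0), 1e-3), 1 - 1e-6)),
               0, log(lt0))
  starts <- lapply(c(1, 3, 0.5), function(s) {
    th <- th_base; th[3] <- log(s); th
  })

  best <- NULL
  for (th0 in starts) {
    opt <- try(stats::optim(th0, tm_nll, cohorts = cohorts, link = link,
                            likelihood = likelihood, method = "BFGS",
                            control = list(maxit = 1000)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop_epfmix("time-mortality optimisation failed", "epfmix_convergence_error")
  nm <- try(stats::optim(best$par, tm_nll, cohorts = cohorts, link = link,
                         likelihood = likelihood, method = "Nelder-Mead",
                         control = list(maxit = 2000)), silent = TRUE)
  if (!inherits(nm, "try-error") && nm$value < best$value) best <- nm
  opt <- stats::optim(best$par, tm_nll, cohorts = cohorts, link = link,
                      likelihood = likelihood, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000))
  if (opt$value > best$value) { opt$par <- best$par; opt$value <- best$value }
  par <- tm_theta_to_par(opt$par)
  cov_theta <- solve_cov(opt$hessian)
  lt50_se <- par$lt50 * sqrt(max(cov_theta[4, 4], 0))  # delta method on log scale

  extrapolated <- par$lt50 > max(data$day)
  if (extrapolated)
    warning("LT50 beyond the study horizon: extrapolated estimate")
  structure(list(
    treatment = treatment, lower = par$lower, upper = par$upper,
    slope = par$slope, lt50 = par$lt50, lt50_se = lt50_se,
    loglik = -opt$value, loglik_or_ss = -opt$value, n_params = 4L,
    extrapolated = extrapolated, link = link, likelihood = likelihood,
    theta = opt$par, cov_theta = cov_theta, data = data,
    convergence = opt$convergence
  ), class = "time_mortality_fit")
}

#' @export
coef.time_mortality_fit <- function(object, ...) {
  c(lower = object$lower, upper = object$upper, slope = object$slope,
    lt50 = object$lt50)
}

#' @export
predict.time_mortality_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$day else newdata$day
  tm_cdf(t, object$lower, object$upper, object$slope, object$lt50, object$link)
}

#' @export
residuals.time_mortality_fit <- function(object, ...) {
  object$data$n_dead / object$data$n_exposed - predict(object)
}

#' @export
print.time_mortality_fit <- function(x, ...) {
  cat("Time-mortality fit",
      if (!is.null(x$treatment)) paste0("(", x$treatment, ")"), "\n")
  cat(sprintf("  LT50 = %.3f +/- %.3f days%s\n", x$lt50, x$lt50_se,
              if (x$extrapolated) "  [extrapolated beyond horizon]" else ""))
  cat(sprintf("  lower = %.3f, upper = %.3f, slope = %.3f (%s on log time, %s likelihood)\n",
              x$lower, x$upper, x$slope, x$link, x$likelihood))
  invisible(x)
}

#' Confidence interval for the fitted LT50
#'
#' Default is a profile-likelihood interval on log time: the LT50 is fixed
#' on a candidate value, the remaining three parameters are re-optimised,
#' and the bounds solve `2 * (profile deviance) = qchisq(level, 1)`. The
#' profile respects the asymmetry that arises when the mortality plateau is
#' only weakly identified within the horizon, where the quadratic (Wald)
#' approximation is too narrow. A one-sided unbounded interval is returned
#' (with `Inf`) when the likelihood never drops below the cutoff on that
#' side. `method = "wald"` gives the log-scale Wald interval instead.
#'
#' @param object a `time_mortality_fit`.
#' @param parm ignored; only the LT50 is intervalled.
#' @param level confidence level.
#' @param method `"profile"` (default) or `"wald"`.
#' @param ... unused.
#' @export
confint.time_mortality_fit <- function(object, parm = "lt50", level = 0.95,
                                       method = c("profile", "wald"), ...) {
  method <- match.arg(method)
  se_log <- sqrt(max(object$cov_theta[4, 4], 0))
  lt <- object$lt50
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    return(matrix(c(lt * exp(-z * se_log), lt * exp(z * se_log)), nrow = 1,
                  dimnames = list("lt50", c("lower", "upper"))))
  }
  cohorts <- split_cohorts(object$data)
  nll_hat <- -object$loglik
  crit <- stats::qchisq(level, 1) / 2
  prof <- function(l4) {
    o <- stats::optim(object$theta[1:3],
                      function(th3) tm_nll(c(th3, l4), cohorts, object$link,
                                           object$likelihood),
                      method = "Nelder-Mead", control = list(maxit = 1500))
    o$value - nll_hat - crit
  }
  l4_hat <- object$theta[4]
  step <- max(se_log, 0.1)
  find_bound <- function(dir) {
    hi <- l4_hat
    for (k in 1:40) {
      hi <- hi + dir * step
      if (prof(hi) > 0)
        return(stats::uniroot(prof, sort(c(hi - dir * step, hi)),
                              tol = 1e-4)$root)
      if (abs(hi - l4_hat) > 6) break  # likelihood flat: unbounded side
    }
    dir * Inf
  }
  lo <- find_bound(-1)
  up <- find_bound(1)
  matrix(c(exp(lo), exp(up)), nrow = 1,
         dimnames = list("lt50", c("lower", "upper")))
}

#' Test whether one shared LT50 fits all treatments
#'
#' Fits the four-parameter model jointly across treatments twice — once with
#' a free LT50 per treatment, once constraining all treatments to a single
#' shared LT50 (lower, upper and slope remain treatment-specific) — and
#' compares by likelihood ratio against a chi-square with
#' `#treatments - 1` degrees of freedom.
#'
#' @param data data frame with a `treatment` column plus the columns of
#'   [fit_time_mortality()].
#' @param likelihood,link passed to the underlying likelihood.
#' @param alpha significance level for the report.
#' @return list of class `lt50_constraint_test` with `statistic`, `df`,
#'   `p_value`, `constraint_rejected`, and the per-treatment free fits.
#' @export
compare_lt50_constraint <- function(data, likelihood = c("multinomial", "binomial"),
                                    link = c("probit", "logit"), alpha = 0.05) {
  likelihood <- match.arg(likelihood)
  link <- match.arg(link)
  stopifnot("treatment" %in% names(data))
  trts <- unique(data$treatment)
  if (length(trts) < 2)
    stop_epfmix("need >= 2 treatments to test a shared LT50",
                "epfmix_validation_error")
  free_fits <- lapply(trts, function(tr)
    fit_time_mortality(data[data$treatment == tr, , drop = FALSE],
                       likelihood = likelihood, link = link, treatment = tr))
  names(free_fits) <- trts
  ll_free <- sum(vapply(free_fits, function(f) f$loglik, 0))

  # shared model: per-treatment (lower, upper-share, slope) + one log lt50
  cohorts_by <- lapply(trts, function(tr)
    split_cohorts(data[data$treatment == tr, , drop = FALSE]))
  K <- length(trts)
  shared_nll <- function(theta) {
    lt_log <- theta[3 * K + 1]
    tot <- 0
    for (i in seq_len(K)) {
      th_i <- c(theta[(3 * i - 2):(3 * i)], lt_log)
      tot <- tot + tm_nll(th_i, cohorts_by[[i]], link, likelihood)
    }
    tot
  }
  th0 <- c(unlist(lapply(free_fits, function(f) f$theta[1:3])),
           mean(vapply(free_fits, function(f) f$theta[4], 0)))
  opt <- stats::optim(th0, shared_nll, method = "BFGS",
                      control = list(maxit = 2000))
  opt2 <- stats::optim(opt$par, shared_nll, method = "Nelder-Mead",
                       control = list(maxit = 3000))
  ll_shared <- -min(opt$value, opt2$value)

  stat <- 2 * (ll_free - ll_shared)
  if (stat < 0) {
    warning("free fit worse than constrained (optimiser artefact); statistic clamped at 0")
    stat <- 0
  }
  df <- K - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 constraint_rejected = p < alpha, alpha = alpha,
                 shared_lt50 = exp(opt$par[3 * K + 1]),
                 fits = free_fits),
            class = "lt50_constraint_test")
}

#' @export
print.lt50_constraint_test <- function(x, ...) {
  cat("Shared-LT50 constraint test\n")
  cat(sprintf("  LR statistic = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(if (x$constraint_rejected)
    "  constraint rejected: LT50s differ between treatments\n"
    else "  constraint retained: one LT50 is tenable\n")
  invisible(x)
}

#' Reduction in LT50 of each mixture relative to its faster single agent
#'
#' For each mixture treatment, the reduction is
#' `min(LT50 of the two single agents) - LT50 of the mixture` in days, with
#' the standard error propagated as the root sum of squares. Negative
#' reductions (mixture slower than the faster single) are reported, not
#' suppressed.
#'
#' @param fits either a named list of `time_mortality_fit` objects or a data
#'   frame with columns `treatment`, `lt50`, `lt50_se` (e.g. a published
#'   LT50 table).
#' @param mapping data frame with columns `mixture`, `single1`, `single2`
#'   naming treatments in `fits`.
#' @return data frame with columns `mixture`, `lt50_mixture`,
#'   `faster_single`, `lt50_single`, `reduction_days`, `se`.
#' @export
lt50_reduction_table <- function(fits, mapping) {
  stopifnot(all(c("mixture", "single1", "single2") %in% names(mapping)))
  tab <- if (is.data.frame(fits)) {
    stopifnot(all(c("treatment", "lt50", "lt50_se") %in% names(fits)))
    fits
  } else {
    data.frame(treatment = names(fits),
               lt50 = vapply(fits, function(f) f$lt50, 0),
               lt50_se = vapply(fits, function(f) f$lt50_se, 0))
  }
  look <- function(tr) {
    i <- match(tr, tab$treatment)
    if (is.na(i))
      stop_epfmix(paste("no fit for treatment:", tr), "epfmix_validation_error")
    tab[i, ]
  }
  out <- lapply(seq_len(nrow(mapping)), function(i) {
    mx <- look(mapping$mixture[i])
    s1 <- look(mapping$single1[i])
    s2 <- look(mapping$single2[i])
    faster <- if (s1$lt50 <= s2$lt50) s1 else s2
    data.frame(mixture = mapping$mixture[i],
               lt50_mixture = mx$lt50,
               faster_single = faster$treatment,
               lt50_single = faster$lt50,
               reduction_days = faster$lt50 - mx$lt50,
               se = sqrt(mx$lt50_se^2 + faster$lt50_se^2))
  })
  do.call(rbind, out)
}
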