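#' Schneider-Orelli correction for control mortality
#'
#' Rescales treated-group percentage mortality for background (control)
#' mortality: `(a - b) / (100 - b) * 100`, where `a` is the treated and `b`
#' the control percentage. This is the percent-scale analogue of Abbott's
#' formula. Negative corrected values (treated mortality below control) are
#' returned as-is with a warning rather than truncated, since truncation
#' would bias downstream analyses of variance.
#'
#' @param raw_pct treated-group mortality, percent in \[0, 100].
#' @param control_pct control-group mortality, percent in \[0, 100).
#' @return corrected mortality in percent (may be negative).
#' @examples
#' schneider_orelli(87, 3.3)
#' @export
schneider_orelli <- function(raw_pct, control_pct) {
  if (any(!is.finite(raw_pct)) || any(!is.finite(control_pct)))
    stop_epfmix("mortality percentages must be finite", "epfmix_domain_error")
  if (any(raw_pct < 0 | raw_pct > 100))
    stop_epfmix("raw_pct must lie in [0, 100]", "epfmix_domain_error")
  if (any(control_pct < 0 | control_pct >= 100))
    stop_epfmix("control_pct must lie in [0, 100)", "epfmix_domain_error")
  out <- (raw_pct - control_pct) / (100 - control_pct) * 100
  if (any(out < 0))
    warning("corrected mortality below zero (treated < control); returned unchanged")
  out
}

#' Bliss independence: joint unaffected fraction and expected mixture mortality
#'
#' Under independent action, the probability of surviving a mixture of agents
#' A and B is the product of the single-agent survival probabilities:
#' `Pm = pA * pB`. `bliss_joint_survival()` returns that product;
#' `bliss_expected_mortality()` returns the complementary expected mixture
#' mortality `1 - Pm`.
#'
#' @param mort_a,mort_b single-agent mortality proportions in \[0, 1].
#' @return proportion in \[0, 1].
#' @examples
#' bliss_joint_survival(0.25, 0.25)     # 0.5625
#' bliss_expected_mortality(0.8, 0.8)   # 0.96
#' @export
bliss_joint_survival <- function(mort_a, mort_b) {
  if (any(mort_a < 0 | mort_a > 1 | mort_b < 0 | mort_b > 1, na.rm = FALSE) ||
      any(!is.finite(mort_a)) || any(!is.finite(mort_b)))
    stop_epfmix("mortality proportions must lie in [0, 1]", "epfmix_domain_error")
  (1 - mort_a) * (1 - mort_b)
}

#' @rdname bliss_joint_survival
#' @export
bliss_expected_mortality <- function(mort_a, mort_b) {
  1 - bliss_joint_survival(mort_a, mort_b)
}

# ---- single-agent concentration-response fitting ---------------------------

# mortality(c) = 1 - (1 - m0) * q(c) with q the log-logistic unaffected
# fraction; upper limit fixed at 1, background mortality m0 additive.
dr_mortality <- function(dose, ec50, beta, m0) {
  1 - (1 - m0) * loglogistic_unaffected(dose, ec50, beta)
}

# theta = (log ec50, log beta[, qlogis m0]); m0 may be fixed
dr_theta_to_par <- function(theta, fix_m0 = NULL) {
  list(
    ec50 = exp(theta[1]),
    beta = exp(theta[2]),
    m0 = if (is.null(fix_m0)) stats::plogis(theta[3]) else fix_m0
  )
}

dr_objective <- function(theta, dose, n, dead, objective, fix_m0) {
  if (any(!is.finite(theta))) return(1e10)
  p <- dr_theta_to_par(theta, fix_m0)
  mu <- clamp01(dr_mortality(dose, p$ec50, p$beta, p$m0))
  if (objective == "binomial-ML") {
    -sum(stats::dbinom(dead, n, mu, log = TRUE))
  } else {
    sum((dead / n - mu)^2)
  }
}

#' Fit a single-agent concentration-response curve
#'
#' Fits `mortality(c) = 1 - (1 - m0) * q(c)` with
#' `q(c) = 1 / (1 + (c/EC50)^beta)` to replicate-level binomial counts at the
#' terminal assessment, either by binomial maximum likelihood (default) or by
#' least squares on observed proportions. The background mortality `m0` is
#' estimated jointly by default or may be fixed (e.g. to the observed control
#' rate). Initialisation is a deterministic multi-start: EC50 at the dose
#' bracketing 50% observed mortality, slope in \{0.5, 1, 2, 4\}, `m0` at the
#' observed control rate.
#'
#' @param data data frame with columns `dose`, `n_exposed`, `n_dead`
#'   (one row per replicate and dose level).
#' @param objective `"binomial-ML"` or `"least-squares"`.
#' @param fix_m0 optional fixed background mortality in \[0, 1); `NULL`
#'   (default) estimates it.
#' @param agent optional agent label carried into the fit.
#' @return an object of class `dose_response_fit` with components `ec50`,
#'   `beta`, `m0`, `objective`, `loglik_or_ss`, `covariance` (over
#'   `(ec50, beta, m0)` by the delta method), `n_obs`, and the data.
#' @seealso [lc_x()], [predict.dose_response_fit()]
#' @export
fit_dose_response <- function(data,
                              objective = c("binomial-ML", "least-squares"),
                              fix_m0 = NULL, agent = NULL) {
  objective <- match.arg(objective)
  stopifnot(all(c("dose", "n_exposed", "n_dead") %in% names(data)))
  dose <- data$dose; n <- data$n_exposed; dead <- data$n_dead
  if (any(dose < 0) || any(n <= 0) || any(dead < 0 | dead > n))
    stop_epfmix("invalid dose/count data", "epfmix_validation_error")
  lev <- sort(unique(dose))
  if (length(lev) < 3 || lev[1] != 0)
    stop_epfmix("need >= 3 distinct dose levels including dose 0",
                "epfmix_validation_error")
  prop_by <- tapply(dead, dose, sum) / tapply(n, dose, sum)
  if (all(prop_by == 0) || all(prop_by == 1))
    stop_epfmix("all-dead or all-alive at every dose: parameters not identifiable",
                "epfmix_identifiability_error")
  if (!is.null(fix_m0) && (fix_m0 < 0 || fix_m0 >= 1))
    stop_epfmix("fix_m0 must lie in [0, 1)", "epfmix_domain_error")

  m0_obs <- min(max(prop_by[as.character(0)], 1e-3), 0.5)
  # dose bracketing 50% observed mortality: first positive level at/above 0.5,
  # falling back to the geometric mid-range
  pos <- lev[lev > 0]
  pb <- prop_by[as.character(pos)]
  ec_start <- if (any(pb >= 0.5)) pos[which(pb >= 0.5)[1]] else exp(mean(log(pos)))
  starts <- lapply(c(0.5, 1, 2, 4), function(b0) {
    th <- c(log(ec_start), log(b0))
    if (is.null(fix_m0)) th <- c(th, stats::qlogis(m0_obs))
    th
  })

  best <- NULL
  for (th0 in starts) {
    opt <- try(stats::optim(th0, dr_objective, dose = dose, n = n, dead = dead,
                            objective = objective, fix_m0 = fix_m0,
                            method = "BFGS", hessian = FALSE,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop_epfmix("optimisation failed from every start", "epfmix_convergence_error")
  nm <- try(stats::optim(best$par, dr_objective, dose = dose, n = n, dead = dead,
                         objective = objective, fix_m0 = fix_m0,
                         method = "Nelder-Mead", control = list(maxit = 500)),
            silent = TRUE)
  if (!inherits(nm, "try-error") && nm$value < best$value) best <- nm
  # polish + hessian at the optimum
  opt <- stats::optim(best$par, dr_objective, dose = dose, n = n, dead = dead,
                      objective = objective, fix_m0 = fix_m0,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500))
  if (opt$value > best$value + 1e-8) opt$par <- best$par
  par <- dr_theta_to_par(opt$par, fix_m0)

  k <- length(opt$par)
  cov_theta <- if (objective == "binomial-ML") {
    solve_cov(opt$hessian)
  } else {
    sigma2 <- opt$value / max(length(dose) - k, 1)
    2 * sigma2 * solve_cov(opt$hessian)
  }
  # delta method to the natural scale (ec50, beta, m0)
  D <- diag(c(par$ec50, par$beta,
              if (is.null(fix_m0)) par$m0 * (1 - par$m0)), nrow = k)
  cov_nat <- matrix(0, 3, 3,
                    dimnames = list(c("ec50", "beta", "m0"), c("ec50", "beta", "m0")))
  cov_nat[seq_len(k), seq_len(k)] <- D %*% cov_theta %*% t(D)

  fit <- structure(list(
    agent = agent, ec50 = par$ec50, beta = par$beta, m0 = par$m0,
    objective = objective,
    loglik_or_ss = if (objective == "binomial-ML") -opt$value else opt$value,
    covariance = cov_nat, n_obs = nrow(data),
    m0_fixed = !is.null(fix_m0), theta = opt$par, data = data,
    convergence = opt$convergence
  ), class = "dose_response_fit")
  fit
}

#' Invert a fitted curve to a lethal concentration
#'
#' Returns the concentration expected to kill a fraction `x` of the exposed
#' population over and above the background (Abbott scale):
#' `LCx = EC50 * (x / (1 - x))^(1/beta)`, with a delta-method standard error.
#'
#' @param fit a [fit_dose_response()] object.
#' @param x target mortality fraction(s) in (0, 1) on the Abbott scale.
#' @return data frame of class `lc_estimate` with columns `x`,
#'   `concentration`, `se`.
#' @export
lc_x <- function(fit, x) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (any(x <= 0 | x >= 1))
    stop_epfmix("x must lie strictly in (0, 1)", "epfmix_domain_error")
  r <- x / (1 - x)
  conc <- fit$ec50 * r^(1 / fit$beta)
  # gradient wrt (ec50, beta)
  d_ec <- r^(1 / fit$beta)
  d_be <- conc * log(r) * (-1 / fit$beta^2)
  V <- fit$covariance[c("ec50", "beta"), c("ec50", "beta")]
  se <- vapply(seq_along(x), function(i) {
    g <- c(d_ec[i], d_be[i])
    sqrt(max(drop(t(g) %*% V %*% g), 0))
  }, numeric(1))
  structure(data.frame(x = x, concentration = conc, se = se),
            class = c("lc_estimate", "data.frame"))
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(ec50 = object$ec50, beta = object$beta, m0 = object$m0)
}

#' @export
vcov.dose_response_fit <- function(object, ...) object$covariance

#' Predict mortality from a fitted concentration-response curve
#'
#' @param object a `dose_response_fit`.
#' @param newdata data frame with a `dose` column, or `NULL` for the fitted data.
#' @param scale `"raw"` (includes background mortality) or `"abbott"`
#'   (mortality over and above background, `1 - q(c)`).
#' @param ... unused.
#' @export
predict.dose_response_fit <- function(object, newdata = NULL,
                                      scale = c("raw", "abbott"), ...) {
  scale <- match.arg(scale)
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  if (scale == "raw") dr_mortality(dose, object$ec50, object$beta, object$m0)
  else 1 - loglogistic_unaffected(dose, object$ec50, object$beta)
}

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$data$n_dead / object$data$n_exposed - predict(object)
}

#' @export
simulate.dose_response_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  n <- object$data$n_exposed
  out <- replicate(nsim, stats::rbinom(length(n), n, mu))
  as.data.frame(out)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Single-agent concentration-response fit",
      if (!is.null(x$agent)) paste0("(", x$agent, ")"), "\n")
  cat(sprintf("  EC50 = %.4g   slope beta = %.4g   background m0 = %.4g%s\n",
              x$ec50, x$beta, x$m0, if (x$m0_fixed) " (fixed)" else ""))
  cat(sprintf("  objective: %s = %.4f on %d observations\n",
              x$objective, x$loglik_or_ss, x$n_obs))
  invisible(x)
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$covariance), 0))
  tab <- data.frame(estimate = coef(object), se = se)
  lcs <- lc_x(object, c(0.15, 0.5, 0.8))
  out <- list(fit = object, coefficients = tab, lc = lcs)
  class(out) <- "summary.dose_response_fit"
  out
}

#' @export
print.summary.dose_response_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 5))
  cat("\nLethal concentrations (Abbott scale):\n")
  print(transform(as.data.frame(x$lc),
                  concentration = signif(concentration, 5), se = signif(se, 4)))
  invisible(x)
}

#' @export
plot.dose_response_fit <- function(x, n_grid = 100, ...) {
  d <- x$data
  prop <- d$n_dead / d$n_exposed
  pos <- d$dose[d$dose > 0]
  grid <- c(0, exp(seq(log(min(pos)) - 1, log(max(pos)) + 1, length.out = n_grid)))
  graphics::plot(d$dose, prop, log = "x", xlab = "dose", ylab = "mortality",
                 ylim = c(0, 1), ...)
  graphics::lines(grid[-1], dr_mortality(grid[-1], x$ec50, x$beta, x$m0))
  invisible(x)
}
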