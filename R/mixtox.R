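#' Toxic units and mixture composition
#'
#' Expresses a dose pair on the toxic-unit scale: `tu_i = c_i / EC50_i`,
#' total `T = tu1 + tu2`, and the potency-weighted mixture composition
#' `z_i = tu_i / T` (so `z1 + z2 = 1`). `z` encodes the "proportion of
#' components in the mixture" on the potency scale, which is what the
#' dose-ratio deviation depends on. When both doses are zero `z` is
#' undefined and returned as `NA`; the deviation function treats that as
#' its neutral value (no deviation at the control point).
#'
#' @param c1,c2 non-negative doses (vectorised).
#' @param ec50_1,ec50_2 positive EC50s of the two agents.
#' @return list with components `tu1`, `tu2`, `z1`, `z2`, `T`.
#' @export
toxic_units <- function(c1, c2, ec50_1, ec50_2) {
  if (ec50_1 <= 0 || ec50_2 <= 0)
    stop_epfmix("EC50s must be positive", "epfmix_domain_error")
  if (any(c1 < 0) || any(c2 < 0))
    stop_epfmix("doses must be non-negative", "epfmix_domain_error")
  tu1 <- c1 / ec50_1
  tu2 <- c2 / ec50_2
  tot <- tu1 + tu2
  z1 <- ifelse(tot > 0, tu1 / tot, NA_real_)
  list(tu1 = tu1, tu2 = tu2, z1 = z1, z2 = ifelse(is.na(z1), NA_real_, 1 - z1),
       T = tot)
}

#' Deviation function G for the independent-action surface
#'
#' The deviation from the independent-action reference is a scalar `G`
#' added to the logit of the joint unaffected fraction (see
#' [predict_surface()]). The supported patterns are: `"NONE"` (no
#' deviation), `"SA"` absolute synergism/antagonism `G = a*z1*z2` (the same
#' deviation at every mixture composition), `"DR"` dose-ratio dependent
#' `G = (a + b*z1)*z1*z2` (deviation depends on the mixture composition),
#' and `"DL"` dose-level dependent `G = a*z1*z2*(1 - b*T)` (deviation
#' changes sign at total toxic units `T = 1/b`). `G` is zero whenever either
#' `z` is 0 or undefined: single agents and controls are never "deviated".
#'
#' Sign convention: `a > 0` means antagonism (less mortality than the
#' reference predicts); the synergy-signed quantity used for classification
#' is `-G`.
#'
#' @param kind one of `"NONE"`, `"SA"`, `"DR"`, `"DL"`.
#' @param a,b deviation parameters (`b` ignored for `"NONE"`/`"SA"`).
#' @param z1,z2 mixture composition from [toxic_units()] (may be `NA` at the
#'   control point).
#' @param T total toxic units.
#' @return numeric vector of deviations `G`.
#' @export
deviation_g <- function(kind, a = 0, b = 0, z1, z2, T = NULL) {
  kind <- match.arg(kind, c("NONE", "SA", "DR", "DL"))
  zz <- ifelse(is.na(z1) | is.na(z2), 0, z1 * z2)
  g <- switch(kind,
    NONE = rep(0, length(zz)),
    SA = a * zz,
    DR = (a + b * ifelse(is.na(z1), 0, z1)) * zz,
    DL = {
      if (is.null(T)) stop_epfmix("DL deviation needs total toxic units T",
                                  "epfmix_domain_error")
      a * zz * (1 - b * T)
    })
  g[zz == 0] <- 0
  g
}

surface_n_params <- function(kind) {
  switch(kind, NONE = 5L, SA = 6L, DR = 7L, DL = 7L)
}

#' Construct a mixture response-surface model
#'
#' Builds a `surface_fit` object from known parameter values (without
#' fitting); used for simulation truth records and testing. See
#' [fit_surface()] for the fitted counterpart.
#'
#' @param ec50_1,ec50_2,beta_1,beta_2 single-agent log-logistic parameters.
#' @param m0 background mortality in \[0, 1).
#' @param kind deviation kind, see [deviation_g()].
#' @param a,b deviation parameters.
#' @return object of class `surface_fit` (unfitted: no objective value).
#' @export
surface_model <- function(ec50_1, ec50_2, beta_1, beta_2, m0 = 0,
                          kind = "NONE", a = 0, b = 0) {
  kind <- match.arg(kind, c("NONE", "SA", "DR", "DL"))
  stopifnot(ec50_1 > 0, ec50_2 > 0, beta_1 > 0, beta_2 > 0, m0 >= 0, m0 < 1)
  structure(list(
    deviation_kind = kind, a = a, b = if (kind %in% c("DR", "DL")) b else NULL,
    ec50_1 = ec50_1, ec50_2 = ec50_2, beta_1 = beta_1, beta_2 = beta_2,
    m0 = m0, objective = NA_character_, loglik_or_ss = NA_real_,
    r_squared = NA_real_, n_params = surface_n_params(kind), data = NULL
  ), class = "surface_fit")
}

#' Predict mortality from an independent-action surface model
#'
#' The reference surface is the Bliss joint unaffected fraction
#' `P_ref = q1(c1) * q2(c2)` of the two single-agent log-logistic curves.
#' The deviation enters on the logit of the unaffected fraction,
#' `P = plogis(qlogis(P_ref) + G)`, which keeps predictions inside (0, 1)
#' for any parameter values and reduces exactly to the reference at
#' `G = 0`; positive `G` (antagonism, `a > 0`) raises survival. Observed
#' mortality then accounts for background mortality:
#' `mortality = 1 - (1 - m0) * P`, so the prediction at (0, 0) is `m0` and
#' output always lies in \[m0, 1]. `P_ref` is clamped at machine-safe
#' bounds before the logit.
#'
#' @param model a `surface_fit` (from [fit_surface()] or [surface_model()]).
#' @param c1,c2 non-negative dose vectors (recycled against each other).
#' @param component `"mortality"` (default), `"survival"` (deviated joint
#'   unaffected fraction), `"reference"` (IA mortality with G = 0), or
#'   `"g"` (the deviation itself).
#' @return numeric vector.
#' @export
predict_surface <- function(model, c1, c2,
                            component = c("mortality", "survival",
                                          "reference", "g")) {
  stopifnot(inherits(model, "surface_fit"))
  component <- match.arg(component)
  n <- max(length(c1), length(c2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  q1 <- loglogistic_unaffected(c1, model$ec50_1, model$beta_1)
  q2 <- loglogistic_unaffected(c2, model$ec50_2, model$beta_2)
  p_ref <- q1 * q2
  tu <- toxic_units(c1, c2, model$ec50_1, model$ec50_2)
  g <- deviation_g(model$deviation_kind, model$a %||% 0, model$b %||% 0,
                   tu$z1, tu$z2, tu$T)
  if (component == "g") return(g)
  if (component == "reference") return(1 - (1 - model$m0) * p_ref)
  # exact reference recovery when G vanishes; logit insertion otherwise
  p <- ifelse(g == 0, p_ref, stats::plogis(stats::qlogis(clamp01(p_ref)) + g))
  if (component == "survival") return(p)
  1 - (1 - model$m0) * p
}

# theta layout: (log e1, log e2, log b1, log b2, qlogis m0_1..m0_B, [a, [b]]);
# B > 1 when background mortality is fitted per bioassay
surface_theta_to_model <- function(theta, kind, B = 1L, m0_labels = NULL) {
  m0s <- stats::plogis(theta[4 + seq_len(B)])
  m <- surface_model(
    ec50_1 = exp(theta[1]), ec50_2 = exp(theta[2]),
    beta_1 = exp(theta[3]), beta_2 = exp(theta[4]),
    m0 = mean(m0s), kind = kind,
    a = if (kind != "NONE") theta[4 + B + 1] else 0,
    b = if (kind %in% c("DR", "DL")) theta[4 + B + 2] else 0
  )
  if (B > 1) m$m0_by <- stats::setNames(m0s, m0_labels)
  m
}

# per-row mortality for fitted data, honouring per-bioassay m0 when present
surface_mu <- function(model, d) {
  p <- predict_surface(model, d$dose1, d$dose2, component = "survival")
  m0 <- if (!is.null(model$m0_by) && !is.null(d$bioassay)) {
    unname(model$m0_by[as.character(d$bioassay)])
  } else model$m0
  1 - (1 - m0) * p
}

surface_objective <- function(theta, d, kind, objective, B = 1L,
                              m0_labels = NULL) {
  if (any(!is.finite(theta))) return(1e10)
  m <- try(surface_theta_to_model(theta, kind, B, m0_labels), silent = TRUE)
  if (inherits(m, "try-error")) return(1e10)
  mu <- clamp01(surface_mu(m, d))
  val <- if (objective == "binomial-ML") {
    -sum(stats::dbinom(d$n_dead, d$n_exposed, mu, log = TRUE))
  } else {
    sum((d$n_dead / d$n_exposed - mu)^2)
  }
  if (!is.finite(val)) 1e10 else val
}

# accept either generic (dose1/dose2) or bioassay (dose_fungus/dose_chem) names
as_surface_data <- function(data) {
  if (!all(c("dose1", "dose2") %in% names(data))) {
    if (all(c("dose_fungus", "dose_chem") %in% names(data))) {
      data$dose1 <- data$dose_fungus
      data$dose2 <- data$dose_chem
    } else {
      stop_epfmix("data needs dose1/dose2 (or dose_fungus/dose_chem) columns",
                  "epfmix_validation_error")
    }
  }
  stopifnot(all(c("n_exposed", "n_dead") %in% names(data)))
  data
}

#' Fit an independent-action mixture surface with optional deviation
#'
#' Jointly fits the two single-agent log-logistic curves, the shared
#' background mortality and (for deviated kinds) the deviation parameters to
#' all observations — single-agent, control and mixture cells together — by
#' binomial maximum likelihood or least squares on proportions. Uncorrected
#' mortality counts are used: the surface itself accounts for control
#' mortality through `m0`. Fungal doses should be the measured deposition.
#'
#' Initialisation is deterministic: single-agent edge fits via
#' [fit_dose_response()] anchor the EC50s and slopes, `m0` starts at the
#' observed control rate, deviation parameters start at zero; deviated fits
#' additionally restart from the fitted `NONE` solution so a deviated model
#' can never fit worse than its nested null.
#'
#' @param data data frame with columns `dose1`, `dose2` (or `dose_fungus`,
#'   `dose_chem`), `n_exposed`, `n_dead` at the terminal assessment.
#' @param kind deviation kind: `"NONE"`, `"SA"`, `"DR"`, `"DL"`.
#' @param objective `"binomial-ML"` or `"least-squares"`.
#' @param null_fit optional fitted `NONE` surface on the same data, reused
#'   as a starting point.
#' @param m0_by_bioassay when the data carry a `bioassay` column with two or
#'   more levels, fit one background mortality per bioassay (default):
#'   pooled bioassays each have their own control cohort, and forcing a
#'   single `m0` onto heterogeneous controls leaks lack-of-fit into the
#'   deviation terms. Set `FALSE` for a single shared `m0`.
#' @return object of class `surface_fit`; `r_squared` is
#'   `1 - SS_res/SS_tot` on observed vs predicted proportions regardless of
#'   the fitting objective.
#' @seealso [compare_surface_models()], [classify_interaction()]
#' @export
fit_surface <- function(data, kind = c("NONE", "SA", "DR", "DL"),
                        objective = c("binomial-ML", "least-squares"),
                        null_fit = NULL, m0_by_bioassay = TRUE) {
  kind <- match.arg(kind)
  objective <- match.arg(objective)
  d <- as_surface_data(data)
  m0_labels <- NULL
  B <- 1L
  if (m0_by_bioassay && "bioassay" %in% names(d)) {
    m0_labels <- as.character(sort(unique(d$bioassay)))
    B <- length(m0_labels)
    if (B < 2) { B <- 1L; m0_labels <- NULL }
  }
  has_ctrl <- any(d$dose1 == 0 & d$dose2 == 0)
  edge1 <- d$dose2 == 0
  edge2 <- d$dose1 == 0
  mix <- d$dose1 > 0 & d$dose2 > 0
  if (!has_ctrl || sum(edge1 & d$dose1 > 0) == 0 || sum(edge2 & d$dose2 > 0) == 0)
    stop_epfmix("data must include control and both single-agent edges",
                "epfmix_validation_error")
  if (kind != "NONE" && length(unique(paste(d$dose1[mix], d$dose2[mix]))) < 2)
    stop_epfmix("deviated surface needs >= 2 distinct mixture cells",
                "epfmix_identifiability_error")

  # single-agent anchors for initialisation (the null solution anchors
  # deviated fits instead, when one is supplied)
  sa_fit <- function(dose, sub) {
    if (!is.null(null_fit)) return(NULL)
    f <- try(fit_dose_response(
      data.frame(dose = dose[sub], n_exposed = d$n_exposed[sub],
                 n_dead = d$n_dead[sub]), objective = objective),
      silent = TRUE)
    if (inherits(f, "try-error")) NULL else f
  }
  f1 <- sa_fit(d$dose1, edge1)
  f2 <- sa_fit(d$dose2, edge2)
  ctrl <- d$dose1 == 0 & d$dose2 == 0
  ctrl_rate <- if (B > 1) {
    vapply(m0_labels, function(b) {
      sub <- ctrl & as.character(d$bioassay) == b
      if (!any(sub)) sum(d$n_dead[ctrl]) / sum(d$n_exposed[ctrl])
      else sum(d$n_dead[sub]) / sum(d$n_exposed[sub])
    }, 0)
  } else sum(d$n_dead[ctrl]) / sum(d$n_exposed[ctrl])
  m0_start <- pmin(pmax(ctrl_rate, 1e-3), 0.5)
  e1 <- if (!is.null(f1)) f1$ec50 else if (!is.null(null_fit)) null_fit$ec50_1
        else exp(mean(log(d$dose1[d$dose1 > 0])))
  e2 <- if (!is.null(f2)) f2$ec50 else if (!is.null(null_fit)) null_fit$ec50_2
        else exp(mean(log(d$dose2[d$dose2 > 0])))
  b1 <- if (!is.null(f1)) f1$beta else if (!is.null(null_fit)) null_fit$beta_1 else 2
  b2 <- if (!is.null(f2)) f2$beta else if (!is.null(null_fit)) null_fit$beta_2 else 2

  m0_block <- stats::qlogis(m0_start)
  base_theta <- c(log(e1), log(e2), log(b1), log(b2), m0_block)
  n_extra <- surface_n_params(kind) - 5L
  starts <- list(c(base_theta, rep(0, n_extra)))
  for (bb in c(0.5, 4)) {
    starts[[length(starts) + 1]] <-
      c(base_theta[1:2], log(bb), log(bb), m0_block, rep(0, n_extra))
  }
  if (kind != "NONE") {
    nf <- null_fit %||% fit_surface(d, "NONE", objective,
                                    m0_by_bioassay = m0_by_bioassay)
    nf_m0 <- if (!is.null(nf$m0_by)) nf$m0_by else rep(nf$m0, B)
    th_null <- c(log(nf$ec50_1), log(nf$ec50_2), log(nf$beta_1), log(nf$beta_2),
                 stats::qlogis(pmin(pmax(nf_m0, 1e-8), 1 - 1e-8)))
    starts <- c(list(c(th_null, rep(0, n_extra))), starts)
    # mild deviation starts to escape the a = 0 saddle when one exists
    for (a0 in c(-1, 1)) {
      starts[[length(starts) + 1]] <- c(th_null, a0, rep(0, n_extra - 1))
    }
  }

  best <- NULL
  for (th0 in starts) {
    opt <- try(stats::optim(th0, surface_objective, d = d, kind = kind,
                            objective = objective, B = B, m0_labels = m0_labels,
                            method = "BFGS",
                            control = list(maxit = 1000)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop_epfmix("surface optimisation failed from every start",
                "epfmix_convergence_error")
  nm <- try(stats::optim(best$par, surface_objective, d = d, kind = kind,
                         objective = objective, B = B, m0_labels = m0_labels,
                         method = "Nelder-Mead",
                         control = list(maxit = 2000)), silent = TRUE)
  if (!inherits(nm, "try-error") && nm$value < best$value) best <- nm
  opt <- stats::optim(best$par, surface_objective, d = d, kind = kind,
                      objective = objective, B = B, m0_labels = m0_labels,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000))
  if (opt$value > best$value) { opt$par <- best$par; opt$value <- best$value }

  model <- surface_theta_to_model(opt$par, kind, B, m0_labels)
  model$n_params <- surface_n_params(kind) + (B - 1L)
  prop <- d$n_dead / d$n_exposed
  mu <- surface_mu(model, d)
  ss_res <- sum((prop - mu)^2)
  ss_tot <- sum((prop - mean(prop))^2)
  model$objective <- objective
  model$loglik_or_ss <- if (objective == "binomial-ML") -opt$value else opt$value
  model$r_squared <- 1 - ss_res / ss_tot
  model$data <- d
  model$theta <- opt$par
  model$cov_theta <- if (opt$value < 1e9) solve_cov(opt$hessian) else NULL
  model$convergence <- opt$convergence
  model
}

#' @export
coef.surface_fit <- function(object, ...) {
  out <- c(ec50_1 = object$ec50_1, ec50_2 = object$ec50_2,
           beta_1 = object$beta_1, beta_2 = object$beta_2, m0 = object$m0)
  if (object$deviation_kind != "NONE") out <- c(out, a = object$a)
  if (object$deviation_kind %in% c("DR", "DL")) out <- c(out, b = object$b)
  out
}

#' @export
predict.surface_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else as_surface_data(newdata)
  args <- list(...)
  if (is.null(args$component) || identical(args$component, "mortality"))
    surface_mu(object, d)
  else predict_surface(object, d$dose1, d$dose2, ...)
}

#' @export
residuals.surface_fit <- function(object, ...) {
  d <- object$data
  d$n_dead / d$n_exposed - predict(object)
}

#' @export
simulate.surface_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  mu <- predict(object)
  as.data.frame(replicate(nsim, stats::rbinom(nrow(d), d$n_exposed, mu)))
}

#' @export
print.surface_fit <- function(x, ...) {
  cat("Independent-action mixture surface, deviation:", x$deviation_kind, "\n")
  cat(sprintf("  agent 1: EC50 = %.4g, beta = %.4g | agent 2: EC50 = %.4g, beta = %.4g\n",
              x$ec50_1, x$beta_1, x$ec50_2, x$beta_2))
  if (is.null(x$m0_by)) {
    cat(sprintf("  background m0 = %.4g\n", x$m0))
  } else {
    cat(sprintf("  background m0 per bioassay: %s\n",
                paste(sprintf("%s = %.4g", names(x$m0_by), x$m0_by),
                      collapse = ", ")))
  }
  if (x$deviation_kind != "NONE")
    cat(sprintf("  deviation: a = %.4g%s  (a > 0: antagonism; classification uses -G)\n",
                x$a,
                if (!is.null(x$b)) sprintf(", b = %.4g", x$b) else ""))
  if (!is.na(x$loglik_or_ss))
    cat(sprintf("  %s = %.4f, R^2 = %.3f, %d parameters\n",
                x$objective, x$loglik_or_ss, x$r_squared, x$n_params))
  invisible(x)
}

#' @export
summary.surface_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.surface_fit <- function(x, n_grid = 40, ...) {
  d <- x$data
  g1 <- exp(seq(log(min(d$dose1[d$dose1 > 0])), log(max(d$dose1)), length.out = n_grid))
  g2 <- exp(seq(log(min(d$dose2[d$dose2 > 0])), log(max(d$dose2)), length.out = n_grid))
  z <- outer(g1, g2, function(a, b) predict_surface(x, a, b))
  graphics::contour(log10(g1), log10(g2), z,
                    xlab = "log10 dose 1", ylab = "log10 dose 2", ...)
  graphics::points(log10(d$dose1[d$dose1 > 0 & d$dose2 > 0]),
                   log10(d$dose2[d$dose1 > 0 & d$dose2 > 0]), pch = 16)
  invisible(x)
}

#' Nested comparison and selection among surface models
#'
#' Compares a nested sequence of fitted surfaces (`NONE` into `SA` into
#' `DR` and/or `DL`) and selects the most parsimonious adequate model.
#' For binomial-ML fits the statistic is the likelihood ratio
#' `-2 (lnL_null - lnL_alt)` against a chi-square with df equal to the
#' parameter difference; for least-squares fits the analogous
#' `N * ln(SS_null / SS_alt)`. Selection walks the chain keeping the
#' simpler model unless `p < alpha`; when both `DR` and `DL` beat `SA`,
#' the better objective wins.
#'
#' @param fits list of `surface_fit` objects on identical data and
#'   objective; must contain a `NONE` fit.
#' @param alpha significance level for the nested tests (default 0.05).
#' @return object of class `surface_model_comparison`: a data frame of
#'   comparisons (`null`, `alt`, `statistic`, `df`, `p_value`) with the
#'   selected fit in attribute `selected` and accessible via `$selected`.
#' @export
compare_surface_models <- function(fits, alpha = 0.05) {
  stopifnot(is.list(fits), length(fits) >= 2)
  kinds <- vapply(fits, function(f) f$deviation_kind, character(1))
  names(fits) <- kinds
  if (!"NONE" %in% kinds)
    stop_epfmix("comparison chain needs the NONE reference fit",
                "epfmix_validation_error")
  obj <- unique(vapply(fits, function(f) f$objective, character(1)))
  if (length(obj) != 1)
    stop_epfmix("all fits must share one objective", "epfmix_validation_error")
  ns <- unique(vapply(fits, function(f) nrow(f$data), integer(1)))
  if (length(ns) != 1)
    stop_epfmix("all fits must be on identical data", "epfmix_validation_error")
  N <- ns

  stat_p <- function(null, alt) {
    df <- alt$n_params - null$n_params
    if (df <= 0)
      stop_epfmix("models are not nested in the stated order",
                  "epfmix_validation_error")
    stat <- if (obj == "binomial-ML") {
      2 * (alt$loglik_or_ss - null$loglik_or_ss)
    } else {
      N * log(null$loglik_or_ss / alt$loglik_or_ss)
    }
    if (stat < 0) {
      warning("alternative fit worse than its null (optimiser artefact); statistic clamped at 0")
      stat <- 0
    }
    c(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
  }

  rows <- list()
  add_row <- function(nk, ak) {
    sp <- stat_p(fits[[nk]], fits[[ak]])
    rows[[length(rows) + 1]] <<- data.frame(
      null = nk, alt = ak, statistic = sp["stat"], df = sp["df"],
      p_value = sp["p"], row.names = NULL)
    sp["p"]
  }

  # walk the chain: keep the simpler model unless the extension is significant
  sa_sig <- FALSE
  if ("SA" %in% kinds) sa_sig <- add_row("NONE", "SA") < alpha
  parent <- if ("SA" %in% kinds) "SA" else "NONE"
  cand <- character(0)
  for (k in intersect(c("DR", "DL"), kinds)) {
    if (add_row(parent, k) < alpha) cand <- c(cand, k)
  }
  selected <- if (length(cand) == 1) {
    cand
  } else if (length(cand) > 1) {
    ll <- vapply(cand, function(k) fits[[k]]$loglik_or_ss, 0)
    if (obj == "binomial-ML") cand[which.max(ll)] else cand[which.min(ll)]
  } else if (sa_sig) "SA" else "NONE"
  tab <- do.call(rbind, rows)
  structure(list(comparisons = tab, selected = fits[[selected]],
                 selected_kind = selected, alpha = alpha),
            class = "surface_model_comparison")
}

#' @export
print.surface_model_comparison <- function(x, ...) {
  cat("Nested surface model comparison (alpha =", x$alpha, ")\n")
  tab <- x$comparisons
  tab$statistic <- round(tab$statistic, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat("selected:", x$selected_kind, "\n")
  invisible(x)
}

#' Classify synergism/antagonism across the dose plane
#'
#' Evaluates the fitted deviation over a dose grid and labels each cell
#' `synergy`, `antagonism` or `additive` from the sign of the synergy-signed
#' deviation `-G`, with a dead-band `|G| < eps`. For a dose-ratio fit whose
#' `a` and `b` have opposite signs, the composition at which the deviation
#' changes sign is `z* = -a/b`, reported both on the toxic-unit scale and as
#' the raw dose ratio `dose_2/dose_1 = (EC50_2/EC50_1) * (1 - z*)/z*`.
#' The relative potency `EC50_1/EC50_2` is always reported.
#'
#' @param model fitted `surface_fit`.
#' @param grid optional list with numeric vectors `dose1`, `dose2`; default
#'   is a log-spaced grid over the fitted data's positive dose ranges.
#' @param n_grid grid resolution per axis when `grid` is `NULL`.
#' @param eps dead-band half-width on `G` (default 1e-8).
#' @return object of class `interaction_map`: data frame `grid` with
#'   columns `dose1`, `dose2`, `g`, `label`, plus fields `switch_z`,
#'   `switch_ratio` and `relative_potency`.
#' @export
classify_interaction <- function(model, grid = NULL, n_grid = 20, eps = 1e-8) {
  stopifnot(inherits(model, "surface_fit"))
  if (is.null(grid)) {
    d <- model$data
    if (is.null(d))
      stop_epfmix("unfitted model: supply an explicit grid", "epfmix_validation_error")
    mk <- function(x) exp(seq(log(min(x[x > 0])), log(max(x)), length.out = n_grid))
    grid <- list(dose1 = mk(d$dose1), dose2 = mk(d$dose2))
  }
  cells <- expand.grid(dose1 = grid$dose1, dose2 = grid$dose2)
  g <- predict_surface(model, cells$dose1, cells$dose2, component = "g")
  syn <- -g  # synergy-signed deviation
  label <- ifelse(abs(g) < eps, "additive",
                  ifelse(syn > 0, "synergy", "antagonism"))
  cells$g <- g
  cells$label <- label

  switch_z <- switch_ratio <- NULL
  if (model$deviation_kind == "DR" && !is.null(model$b) && model$b != 0) {
    z_star <- -model$a / model$b
    if (z_star > 0 && z_star < 1) {
      switch_z <- z_star
      switch_ratio <- (model$ec50_2 / model$ec50_1) * (1 - z_star) / z_star
    }
  }
  structure(list(grid = cells, switch_z = switch_z, switch_ratio = switch_ratio,
                 relative_potency = model$ec50_1 / model$ec50_2,
                 deviation_kind = model$deviation_kind, eps = eps),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  tab <- table(x$grid$label)
  cat("Interaction map (", x$deviation_kind, " deviation):\n", sep = "")
  print(tab)
  if (!is.null(x$switch_ratio))
    cat(sprintf("sign switch at z1* = %.4g (dose_2/dose_1 = %.4g)\n",
                x$switch_z, x$switch_ratio))
  cat(sprintf("relative potency EC50_1/EC50_2 = %.4g\n", x$relative_potency))
  invisible(x)
}

#' Export the fitted surface and reference isoboles as a table
#'
#' Produces a long table ready for contour plotting: a log-spaced dose grid
#' spanning the observed ranges with, per cell, the expected
#' independent-action mortality (the black-isobole reference), the fitted
#' (deviated) mortality, the deviation `G` and its interaction label; the
#' observed points are appended with their observed proportions.
#'
#' @param model fitted `surface_fit`.
#' @param data observations (defaults to the fitted data).
#' @param n_grid grid resolution per axis.
#' @param eps dead-band for labels, see [classify_interaction()].
#' @return data frame with columns `dose1`, `dose2`, `expected_ia`,
#'   `fitted`, `g`, `label`, `source` (`"grid"`/`"observed"`), `observed`.
#' @export
export_surface_grid <- function(model, data = NULL, n_grid = 20, eps = 1e-8) {
  stopifnot(inherits(model, "surface_fit"))
  d <- as_surface_data(data %||% model$data)
  if (is.null(d) || nrow(d) == 0)
    stop_epfmix("no observations to span the grid", "epfmix_validation_error")
  if (n_grid < 1) stop_epfmix("empty grid spec", "epfmix_validation_error")
  imap <- classify_interaction(
    model, grid = list(
      dose1 = exp(seq(log(min(d$dose1[d$dose1 > 0])), log(max(d$dose1)),
                      length.out = n_grid)),
      dose2 = exp(seq(log(min(d$dose2[d$dose2 > 0])), log(max(d$dose2)),
                      length.out = n_grid))), eps = eps)
  cells <- imap$grid
  cells$expected_ia <- predict_surface(model, cells$dose1, cells$dose2,
                                       component = "reference")
  cells$fitted <- predict_surface(model, cells$dose1, cells$dose2)
  cells$source <- "grid"
  cells$observed <- NA_real_

  obs <- data.frame(dose1 = d$dose1, dose2 = d$dose2)
  obs$g <- predict_surface(model, obs$dose1, obs$dose2, component = "g")
  obs$label <- ifelse(abs(obs$g) < eps, "additive",
                      ifelse(-obs$g > 0, "synergy", "antagonism"))
  obs$expected_ia <- predict_surface(model, obs$dose1, obs$dose2,
                                     component = "reference")
  obs$fitted <- predict_surface(model, obs$dose1, obs$dose2)
  obs$source <- "observed"
  obs$observed <- d$n_dead / d$n_exposed
  cols <- c("dose1", "dose2", "expected_ia", "fitted", "g", "label",
            "source", "observed")
  rbind(cells[cols], obs[cols])
}
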