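#' Run the full mixture-bioassay analysis
#'
#' Chains the analysis stages on one dataset: (1) Schneider-Orelli corrected
#' terminal mortality per replicate, (2) two-way ANOVA of corrected
#' mortality on treatment and bioassay with Bonferroni pairwise bioassay
#' contrasts and an advisory pooling partition, (3) per pooled set,
#' single-agent concentration-response fits along both edges, (4) the
#' independent-action surface with the requested deviation kinds, nested
#' model comparison, interaction classification and the exported contour
#' grid, and (5) optionally, per-treatment LT50 fits, the shared-LT50
#' constraint test and the mixture LT50-reduction table from time-course
#' data.
#'
#' @param observations terminal bioassay observations: a `bioassay_data`
#'   frame, a plain data frame in the same layout, or a CSV path (read via
#'   [read_bioassay_table()]).
#' @param manifest optional [bioassay_manifest()] used when `observations`
#'   is a path.
#' @param pooling_sets explicit list of bioassay-id vectors to analyse
#'   (reproducibility over automation); `NULL` uses the advisory partition
#'   from the QC stage.
#' @param kinds deviation kinds to fit beyond `NONE`.
#' @param objective `"binomial-ML"` or `"least-squares"`.
#' @param alpha significance level for all nested tests.
#' @param grid_n resolution of the exported surface grid.
#' @param time_course optional time-resolved observations for the LT50 stage.
#' @return object of class `epfmix_report` with components `qc`
#'   (`anova_table` + `bioassay_pooling`), `pooled` (per pooled set: fits,
#'   comparison, interaction map, surface grid), and `time_to_kill` when
#'   requested.
#' @export
run_pipeline <- function(observations, manifest = NULL, pooling_sets = NULL,
                         kinds = c("SA", "DR", "DL"),
                         objective = c("binomial-ML", "least-squares"),
                         alpha = 0.05, grid_n = 20, time_course = NULL) {
  objective <- match.arg(objective)
  kinds <- match.arg(kinds, c("SA", "DR", "DL"), several.ok = TRUE)
  if (is.character(observations) && !file.exists(observations))
    stop_epfmix(paste("input file not found:", observations), "epfmix_io_error")
  obs <- if (is.character(observations)) {
    read_bioassay_table(observations, manifest)
  } else if (!inherits(observations, "bioassay_data")) {
    read_bioassay_table(as.data.frame(observations), manifest)
  } else observations

  # terminal assessment per cohort
  cohort <- interaction(obs$bioassay, obs$treatment, obs$replicate, drop = TRUE)
  last <- unlist(lapply(split(seq_len(nrow(obs)), cohort), function(i)
    i[which.max(obs$day[i])]), use.names = FALSE)
  term <- obs[last, , drop = FALSE]

  is_ctrl <- term$dose_fungus == 0 & term$dose_chem == 0
  if (!any(is_ctrl))
    stop_epfmix("no control cell (both doses zero) found", "epfmix_validation_error")
  ctrl_pct <- vapply(split(term[is_ctrl, ], term$bioassay[is_ctrl]), function(s)
    100 * sum(s$n_dead) / sum(s$n_exposed), 0)
  term$corrected_mortality <- suppressWarnings(schneider_orelli(
    100 * term$n_dead / term$n_exposed,
    ctrl_pct[as.character(term$bioassay)]))

  qc_anova <- two_way_anova(term[!is_ctrl, ])
  qc_pairs <- pairwise_bonferroni(term[!is_ctrl, ], alpha = alpha)
  sets <- pooling_sets %||% qc_pairs$pooling_sets

  pooled <- lapply(sets, function(set) {
    sub <- term[term$bioassay %in% set, , drop = FALSE]
    res <- try({
      f1 <- fit_dose_response(
        data.frame(dose = sub$dose_fungus, n_exposed = sub$n_exposed,
                   n_dead = sub$n_dead)[sub$dose_chem == 0, ],
        objective = objective, agent = "fungus")
      f2 <- fit_dose_response(
        data.frame(dose = sub$dose_chem, n_exposed = sub$n_exposed,
                   n_dead = sub$n_dead)[sub$dose_fungus == 0, ],
        objective = objective, agent = "chem")
      none <- fit_surface(sub, "NONE", objective)
      fits <- c(list(none), lapply(kinds, function(k)
        fit_surface(sub, k, objective, null_fit = none)))
      comp <- compare_surface_models(fits, alpha = alpha)
      imap <- classify_interaction(comp$selected, n_grid = grid_n)
      grid <- export_surface_grid(comp$selected, n_grid = grid_n)
      list(bioassays = set, single_agent = list(fungus = f1, chem = f2),
           fits = fits, comparison = comp, selected = comp$selected,
           interaction = imap, surface_grid = grid)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      list(bioassays = set, error = attr(res, "condition")$message)
    else res
  })

  ttk <- NULL
  if (!is.null(time_course)) {
    tc <- if (is.character(time_course)) read_bioassay_table(time_course, manifest)
          else time_course
    trts <- unique(tc$treatment)
    lt_fits <- list()
    for (tr in trts) {
      f <- try(fit_time_mortality(tc[tc$treatment == tr, , drop = FALSE],
                                  treatment = tr), silent = TRUE)
      if (!inherits(f, "try-error")) lt_fits[[tr]] <- f
    }
    constraint <- if (length(lt_fits) >= 2) {
      try(compare_lt50_constraint(
        tc[tc$treatment %in% names(lt_fits), , drop = FALSE], alpha = alpha),
        silent = TRUE)
    } else NULL
    if (inherits(constraint, "try-error")) constraint <- NULL
    ttk <- list(fits = lt_fits, constraint = constraint)
  }

  structure(list(qc = list(anova = qc_anova, pairwise = qc_pairs),
                 pooling_sets = sets, pooled = pooled,
                 time_to_kill = ttk, objective = objective, alpha = alpha),
            class = "epfmix_report")
}

#' @export
print.epfmix_report <- function(x, ...) {
  cat("== Mixture bioassay analysis report ==\n\n")
  cat("Two-way ANOVA (corrected mortality ~ treatment + bioassay):\n")
  tab <- x$qc$anova
  tab[] <- lapply(tab, function(v) if (is.numeric(v)) signif(v, 4) else v)
  print(as.data.frame(tab), row.names = FALSE)
  cat("\n")
  print(x$qc$pairwise)
  for (p in x$pooled) {
    cat("\n-- pooled bioassays {", paste(p$bioassays, collapse = ", "), "} --\n")
    if (!is.null(p$error)) { cat("  stage failed:", p$error, "\n"); next }
    print(p$comparison)
    print(p$selected)
    print(p$interaction)
  }
  if (!is.null(x$time_to_kill)) {
    cat("\n-- time to kill --\n")
    lt <- x$time_to_kill$fits
    tab <- data.frame(treatment = names(lt),
                      lt50 = vapply(lt, function(f) f$lt50, 0),
                      se = vapply(lt, function(f) f$lt50_se, 0),
                      extrapolated = vapply(lt, function(f) f$extrapolated, NA))
    tab$lt50 <- round(tab$lt50, 2); tab$se <- round(tab$se, 2)
    print(tab, row.names = FALSE)
    if (!is.null(x$time_to_kill$constraint)) print(x$time_to_kill$constraint)
  }
  invisible(x)
}
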