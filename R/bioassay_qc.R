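#' Two-way ANOVA of corrected mortality on treatment and bioassay
#'
#' Fits `response ~ treatment + bioassay` (no interaction) and reports Type
#' II sums of squares — inert in the balanced case, pinned for the
#' unbalanced one — with F tests against the residual mean square.
#'
#' @param data data frame containing the response and the two factors.
#' @param response name of the response column (default
#'   `"corrected_mortality"`).
#' @param treatment,bioassay factor column names.
#' @return data frame of class `anova_table` with rows `treatment`,
#'   `bioassay`, `residual` and columns `sum_sq`, `df`, `mean_sq`,
#'   `f_value`, `p_value`.
#' @export
two_way_anova <- function(data, response = "corrected_mortality",
                          treatment = "treatment", bioassay = "bioassay") {
  stopifnot(all(c(response, treatment, bioassay) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  treatment = factor(data[[treatment]]),
                  bioassay = factor(data[[bioassay]]))
  for (f in c("treatment", "bioassay")) {
    if (nlevels(d[[f]]) < 2)
      stop_epfmix(paste("factor", f, "has fewer than 2 levels"),
                  "epfmix_validation_error")
  }
  fit <- stats::lm(y ~ treatment + bioassay, data = d)
  df_res <- stats::df.residual(fit)
  if (df_res == 0)
    stop_epfmix("zero residual degrees of freedom", "epfmix_validation_error")
  rss_full <- sum(stats::resid(fit)^2)
  # Type II: each factor adjusted for the other (no interaction term)
  rss_wo_t <- sum(stats::resid(stats::lm(y ~ bioassay, data = d))^2)
  rss_wo_b <- sum(stats::resid(stats::lm(y ~ treatment, data = d))^2)
  ss <- c(treatment = rss_wo_t - rss_full, bioassay = rss_wo_b - rss_full)
  dfs <- c(treatment = nlevels(d$treatment) - 1L,
           bioassay = nlevels(d$bioassay) - 1L)
  ms_res <- rss_full / df_res
  tol <- 1e-10 * (sum((d$y - mean(d$y))^2) + 1)
  # a factor explaining nothing has F = 0 even when the residual MS is 0 too
  fv <- if (ms_res < tol) rep(Inf, 2) else (ss / dfs) / ms_res
  fv[ss < tol] <- 0
  tab <- data.frame(
    term = c("treatment", "bioassay", "residual"),
    sum_sq = c(ss, rss_full),
    df = c(dfs, df_res),
    row.names = NULL)
  tab$mean_sq <- tab$sum_sq / tab$df
  tab$f_value <- c(fv, NA)
  tab$p_value <- c(stats::pf(fv, dfs, df_res, lower.tail = FALSE), NA)
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Pairwise Bonferroni contrasts between bioassays and a pooling partition
#'
#' Performs pairwise t-tests between replicate bioassays and adjusts the p
#' values by Bonferroni (`p_adj = min(1, p * m)` with `m` the number of
#' pairs). By default mortality is residualised on treatment means first, so
#' bioassay contrasts are not confounded by treatment composition; the raw
#' responses can be compared instead. When bioassays do not share all
#' treatments, each pair is compared on its shared treatments with a
#' warning. Bioassays with no significant pairwise difference are grouped
#' into maximal poolable sets — advisory output: mixture fitting consumes an
#' explicit user-chosen pooling set.
#'
#' @param data data frame with the response and factor columns.
#' @param response,treatment,bioassay column names as in [two_way_anova()].
#' @param adjust_for_treatment residualise on treatment before testing
#'   (default `TRUE`).
#' @param alpha significance level for the pooling partition.
#' @return list of class `bioassay_pooling` with `p_raw`, `p_adjusted`
#'   (matrices), `pooling_sets` (list of bioassay-id vectors), `alpha`.
#' @export
pairwise_bonferroni <- function(data, response = "corrected_mortality",
                                treatment = "treatment", bioassay = "bioassay",
                                adjust_for_treatment = TRUE, alpha = 0.05) {
  stopifnot(all(c(response, treatment, bioassay) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  treatment = factor(data[[treatment]]),
                  bioassay = factor(data[[bioassay]]))
  ids <- levels(d$bioassay)
  if (length(ids) < 2)
    stop_epfmix("need >= 2 bioassays", "epfmix_validation_error")
  cov_tab <- table(d$bioassay, d$treatment) > 0
  if (any(colSums(cov_tab) < nrow(cov_tab)))
    warning("unequal treatment coverage across bioassays; pairs compared on shared treatments")

  pairs <- utils::combn(ids, 2)
  m <- ncol(pairs)
  p_raw <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (j in seq_len(m)) {
    b1 <- pairs[1, j]; b2 <- pairs[2, j]
    shared <- colnames(cov_tab)[cov_tab[b1, ] & cov_tab[b2, ]]
    sub <- d[d$bioassay %in% c(b1, b2) & d$treatment %in% shared, , drop = FALSE]
    yy <- if (adjust_for_treatment) {
      stats::resid(stats::lm(y ~ treatment, data = sub))
    } else sub$y
    tt <- stats::t.test(yy[sub$bioassay == b1], yy[sub$bioassay == b2])
    p_raw[b1, b2] <- p_raw[b2, b1] <- tt$p.value
  }
  p_adj <- pmin(p_raw * m, 1)

  # maximal poolable sets: largest bioassay subsets with no significant pair
  compatible <- function(set) {
    if (length(set) < 2) return(TRUE)
    prs <- utils::combn(set, 2)
    all(p_adj[cbind(prs[1, ], prs[2, ])] >= alpha)
  }
  sets <- list()
  for (k in rev(seq_along(ids))) {
    for (cand in utils::combn(ids, k, simplify = FALSE)) {
      if (compatible(cand) &&
          !any(vapply(sets, function(s) all(cand %in% s), logical(1))))
        sets[[length(sets) + 1]] <- cand
    }
  }
  structure(list(p_raw = p_raw, p_adjusted = p_adj, pooling_sets = sets,
                 alpha = alpha, adjusted_for_treatment = adjust_for_treatment),
            class = "bioassay_pooling")
}

#' @export
print.bioassay_pooling <- function(x, ...) {
  cat("Pairwise bioassay contrasts (Bonferroni-adjusted p):\n")
  print(round(x$p_adjusted, 4))
  cat("poolable sets (no significant pairwise difference at alpha =",
      x$alpha, "):\n")
  for (s in x$pooling_sets) cat("  {", paste(s, collapse = ", "), "}\n")
  invisible(x)
}
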