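#' Describe a bioassay dataset: column mapping, death encoding, design
#'
#' A manifest tells [read_bioassay_table()] how a delimited file maps onto
#' the internal observation fields, whether the file stores cumulative or
#' incremental deaths, and the study horizon. Column mapping is
#' `internal_name = file_column_name`; internal names are `bioassay`,
#' `treatment`, `replicate`, `dose_fungus`, `dose_chem`, `lc_fungus`,
#' `lc_chem`, `day`, `n_exposed`, `n_dead`.
#'
#' @param columns named character vector mapping internal names to file
#'   column names; defaults to the identity mapping.
#' @param deaths `"cumulative"` (default; the repeated-census design records
#'   cumulative state) or `"incremental"` (converted on read).
#' @param horizon_days study horizon; assessment days beyond it fail
#'   validation.
#' @param treatments optional data frame of admissible `(lc_fungus, lc_chem)`
#'   cells.
#' @return object of class `bioassay_manifest`.
#' @export
bioassay_manifest <- function(columns = NULL, deaths = c("cumulative", "incremental"),
                              horizon_days = 14, treatments = NULL) {
  deaths <- match.arg(deaths)
  internal <- c("bioassay", "treatment", "replicate", "dose_fungus",
                "dose_chem", "lc_fungus", "lc_chem", "day",
                "n_exposed", "n_dead")
  map <- stats::setNames(internal, internal)
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), internal)
    if (length(bad))
      stop_epfmix(paste("unknown internal field(s):", paste(bad, collapse = ", ")),
                  "epfmix_schema_error")
    map[names(columns)] <- columns
  }
  stopifnot(horizon_days > 0)
  structure(list(columns = map, deaths = deaths, horizon_days = horizon_days,
                 treatments = treatments),
            class = "bioassay_manifest")
}

required_fields <- c("bioassay", "treatment", "replicate", "day",
                     "n_exposed", "n_dead")

#' Read and validate a bioassay table
#'
#' Reads a comma-separated, UTF-8 bioassay file (one row per replicate leaf
#' per assessment day), maps columns through the manifest, converts
#' incremental death counts to cumulative if so declared, and validates the
#' observation invariants: `n_dead <= n_exposed` per row, cumulative deaths
#' non-decreasing over assessment days within each replicate cohort,
#' assessment days within the horizon, and (when dose and LC-label columns
#' are both present) dose zero exactly when the label is the control level.
#' All violations are collected and reported together, with row numbers.
#'
#' @param path CSV file path, or a data frame (already-loaded table).
#' @param manifest a [bioassay_manifest()]; `NULL` uses defaults.
#' @return validated data frame of class `bioassay_data` (internal column
#'   names), ordered by bioassay, treatment, replicate, day.
#' @export
read_bioassay_table <- function(path, manifest = NULL) {
  manifest <- manifest %||% bioassay_manifest()
  raw <- if (is.data.frame(path)) path else {
    if (!file.exists(path))
      stop_epfmix(paste("file not found:", path), "epfmix_io_error")
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  map <- manifest$columns
  present <- map[map %in% names(raw)]
  missing_req <- setdiff(required_fields, names(present))
  if (length(missing_req))
    stop_epfmix(paste("missing required column(s):",
                      paste(map[missing_req], collapse = ", ")),
                "epfmix_schema_error")
  d <- raw[unname(present)]
  names(d) <- names(present)
  for (col in c("dose_fungus", "dose_chem"))
    if (!col %in% names(d)) d[[col]] <- NA_real_

  ord <- order(d$bioassay, d$treatment, d$replicate, d$day)
  d <- d[ord, , drop = FALSE]
  row_origin <- seq_len(nrow(raw))[ord]

  cohort <- interaction(d$bioassay, d$treatment, d$replicate, drop = TRUE)
  if (manifest$deaths == "incremental") {
    d$n_dead <- stats::ave(d$n_dead, cohort, FUN = cumsum)
  }

  problems <- character(0)
  bad <- which(d$n_dead > d$n_exposed | d$n_dead < 0)
  if (length(bad))
    problems <- c(problems, paste0("n_dead > n_exposed (or negative) in file row(s) ",
                                   paste(row_origin[bad], collapse = ", ")))
  for (cc in levels(cohort)) {
    idx <- which(cohort == cc)
    if (any(diff(d$n_dead[idx]) < 0))
      problems <- c(problems,
                    paste0("cumulative deaths decrease over time in replicate ", cc))
  }
  late <- which(d$day > manifest$horizon_days | d$day < 0)
  if (length(late))
    problems <- c(problems, paste0("assessment day outside [0, ",
                                   manifest$horizon_days, "] in file row(s) ",
                                   paste(row_origin[late], collapse = ", ")))
  for (ag in c("fungus", "chem")) {
    lc <- d[[paste0("lc_", ag)]]; dose <- d[[paste0("dose_", ag)]]
    if (!is.null(lc) && !all(is.na(dose))) {
      mismatch <- which((lc %in% c(0, "0") & dose > 0) |
                          (!lc %in% c(0, "0") & dose == 0))
      if (length(mismatch))
        problems <- c(problems, paste0("dose/LC-label mismatch (", ag,
                                       ") in file row(s) ",
                                       paste(row_origin[mismatch], collapse = ", ")))
    }
  }
  if (length(problems))
    stop_epfmix(paste0("bioassay table failed validation:\n  ",
                       paste(problems, collapse = "\n  ")),
                "epfmix_validation_error", data = problems)

  rownames(d) <- NULL
  class(d) <- c("bioassay_data", "data.frame")
  attr(d, "manifest") <- manifest
  d
}

#' Write a validated bioassay table to CSV
#'
#' @param data a `bioassay_data` data frame.
#' @param path output file path.
#' @export
write_bioassay_table <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Conidial deposition from colony-forming-unit calibration counts
#'
#' Converts CFU counts from washed, diluted and plated coverslip samples
#' into deposited dose per unit area:
#' `dose = cfu_count * dilution_factor * (wash_volume / plated_volume) /
#' (coverslip_area * viability)` in conidia per mm^2. The default coverslip
#' area is 484 mm^2 (22 x 22 mm). Viability defaults to 1 (no adjustment);
#' the argument exists for generality.
#'
#' @param cfu_count non-negative CFU count(s).
#' @param dilution_factor positive dilution factor of the plated aliquot.
#' @param plated_volume plated aliquot volume (mL).
#' @param wash_volume coverslip wash volume (mL).
#' @param coverslip_area coverslip area (mm^2), default 484.
#' @param viability conidial viability proportion in (0, 1], default 1.
#' @return deposited dose in conidia per mm^2.
#' @examples
#' deposition_from_cfu(100, 100, plated_volume = 0.04, wash_volume = 1)
#' @export
deposition_from_cfu <- function(cfu_count, dilution_factor, plated_volume,
                                wash_volume, coverslip_area = 484,
                                viability = 1) {
  if (any(plated_volume <= 0) || any(coverslip_area <= 0))
    stop_epfmix("plated_volume and coverslip_area must be positive",
                "epfmix_domain_error")
  if (any(dilution_factor <= 0) || any(wash_volume <= 0))
    stop_epfmix("dilution_factor and wash_volume must be positive",
                "epfmix_domain_error")
  if (any(viability <= 0 | viability > 1))
    stop_epfmix("viability must lie in (0, 1]", "epfmix_domain_error")
  if (any(cfu_count < 0))
    stop_epfmix("cfu_count must be non-negative", "epfmix_domain_error")
  cfu_count * dilution_factor * (wash_volume / plated_volume) /
    (coverslip_area * viability)
}

#' Summarise deposition samples per treatment (and bioassay)
#'
#' Computes the sample mean and sample standard deviation (n - 1
#' denominator) of derived deposition doses per treatment, and per bioassay
#' when a `bioassay` column is present — the layout of a deposition
#' calibration table. Treatments with a single coverslip get `NA` SD and a
#' flag rather than an error; declared treatment levels with no samples are
#' dropped with a warning.
#'
#' @param samples data frame with columns `treatment`, `cfu_count`,
#'   `dilution_factor`, `plated_volume`, `wash_volume` and optionally
#'   `coverslip_area`, `viability`, `bioassay`; or with a precomputed
#'   `dose` column.
#' @return data frame with columns (`bioassay`,) `treatment`, `n`,
#'   `mean_dose`, `sd_dose`, `single_sample`.
#' @export
summarize_deposition <- function(samples) {
  stopifnot(is.data.frame(samples), "treatment" %in% names(samples))
  if (is.factor(samples$treatment)) {
    empty <- setdiff(levels(samples$treatment), unique(as.character(samples$treatment)))
    if (length(empty))
      warning("treatment(s) with no deposition samples dropped: ",
              paste(empty, collapse = ", "))
  }
  if (!"dose" %in% names(samples)) {
    samples$dose <- deposition_from_cfu(
      samples$cfu_count, samples$dilution_factor, samples$plated_volume,
      samples$wash_volume,
      samples$coverslip_area %||% 484,
      if ("viability" %in% names(samples)) samples$viability else 1)
  }
  by_cols <- intersect(c("bioassay", "treatment"), names(samples))
  groups <- samples[by_cols]
  agg <- function(f) stats::aggregate(samples$dose, groups, f)$x
  out <- stats::aggregate(samples$dose, groups, length)
  names(out)[ncol(out)] <- "n"
  out$mean_dose <- agg(mean)
  out$sd_dose <- agg(function(x) if (length(x) > 1) stats::sd(x) else NA_real_)
  out$single_sample <- out$n < 2
  out[do.call(order, out[by_cols]), c(by_cols, "n", "mean_dose", "sd_dose",
                                      "single_sample")]
}
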