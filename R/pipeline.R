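#' @title End-to-end pipeline and reporting
#' @description
#' Orchestrates the full analysis from files on disk: read cohort and KB,
#' normalize names, apply the cleaning chain, screen for DDIs/MDIs,
#' summarize, extrapolate exposure, and write every artifact (filter
#' report, MDI JSON-lines and CSV, summary JSON, class and exposure CSVs,
#' text report). Deterministic given its inputs.
#' @name cli_reporting
NULL

#' Run the full analysis pipeline
#'
#' @param cohort_path cohort CSV (see [read_cohort()])
#' @param kb_path knowledge-base CSV or JSON (see [load_kb()])
#' @param out_dir output directory; created if needed
#' @param brand_map_path optional brand-to-generic CSV
#' @param class_map_path optional drug-class CSV
#' @param beneficiary_path optional beneficiary-count CSV for exposure
#'   extrapolation
#' @param min_age,inpatient_markers,exclude_routes,route_keywords cleaning
#'   parameters, see [filter_cohort()]
#' @param prevalence_mode numerator convention for computed per-drug
#'   prevalences, see [per_drug_prevalence()]
#' @param drug_ades optional per-drug ADE table for the pharmacodynamic
#'   classifier
#' @param verbose print progress and the effective configuration
#' @return invisibly, a list with `cohort`, `filter_report`, `findings`,
#'   `summary`, `exposure` (or NULL) and `artifacts` (named paths)
#' @export
run_pipeline <- function(cohort_path, kb_path, out_dir,
                         brand_map_path = NULL, class_map_path = NULL,
                         beneficiary_path = NULL,
                         min_age = 60,
                         inpatient_markers = INPATIENT_MARKERS,
                         exclude_routes = c("topical", "ophthalmic"),
                         route_keywords = NULL,
                         prevalence_mode = c("member", "on_list"),
                         drug_ades = NULL,
                         verbose = FALSE) {
  prevalence_mode <- match.arg(prevalence_mode)
  for (p in c(cohort_path, kb_path, brand_map_path, class_map_path,
              beneficiary_path)) {
    if (!is.null(p) && !file.exists(p))
      stop("input path does not exist: ", p)
  }
  cfg <- list(
    cohort_path = cohort_path, kb_path = kb_path, out_dir = out_dir,
    brand_map_path = brand_map_path, class_map_path = class_map_path,
    beneficiary_path = beneficiary_path, min_age = min_age,
    inpatient_markers = inpatient_markers, exclude_routes = exclude_routes,
    route_keywords = route_keywords, prevalence_mode = prevalence_mode
  )
  if (verbose) {
    message("pipeline configuration:")
    for (nm in names(cfg))
      message("  ", nm, " = ",
              paste(format(cfg[[nm]] %||% "NULL"), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  kb <- load_kb(kb_path)
  cohort <- read_cohort(cohort_path)
  brand_map <- if (!is.null(brand_map_path)) read_brand_map(brand_map_path)
  class_map <- if (!is.null(class_map_path)) read_class_map(class_map_path)
  cohort <- normalize_names(cohort, brand_map)
  filt <- filter_cohort(cohort, min_age = min_age,
                        inpatient_markers = inpatient_markers,
                        exclude_routes = exclude_routes,
                        route_keywords = route_keywords)
  if (nrow(filt$cohort) == 0)
    warning("no patients survive the cleaning chain; summary will be zeros")
  findings <- detect_interactions(filt$cohort, kb, drug_ades = drug_ades)
  summary <- summarize_cohort(filt$cohort, findings, class_map = class_map)

  exposure <- NULL
  if (!is.null(beneficiary_path)) {
    ben <- read_beneficiaries(beneficiary_path)
    if (!"prevalence_pct" %in% names(ben)) {
      present <- vapply(ben$drug, function(d)
        d %in% effective_name(filt$cohort), NA)
      ben <- ben[present, , drop = FALSE]
    }
    if (nrow(ben) > 0)
      exposure <- extrapolate_exposure(ben, filt$cohort, findings,
                                       mode = prevalence_mode)
  }

  artifacts <- c(
    config = file.path(out_dir, "config.json"),
    filter_report = file.path(out_dir, "filter_report.json"),
    mdis_jsonl = file.path(out_dir, "mdis.jsonl"),
    mdis_csv = file.path(out_dir, "mdis.csv"),
    summary = file.path(out_dir, "summary.json"),
    report = file.path(out_dir, "report.txt")
  )
  jsonlite::write_json(cfg, artifacts[["config"]], auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  jsonlite::write_json(filter_report_to_list(filt$report),
                       artifacts[["filter_report"]], auto_unbox = TRUE,
                       pretty = TRUE)
  write_mdi_jsonl(findings, artifacts[["mdis_jsonl"]])
  utils::write.csv(mdi_table(findings), artifacts[["mdis_csv"]],
                   row.names = FALSE)
  jsonlite::write_json(summary_to_list(summary), artifacts[["summary"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(summary$class_tally)) {
    artifacts[["class_csv"]] <- file.path(out_dir, "class_tally.csv")
    utils::write.csv(summary$class_tally, artifacts[["class_csv"]],
                     row.names = FALSE)
  }
  if (!is.null(exposure)) {
    artifacts[["exposure_csv"]] <- file.path(out_dir, "exposure.csv")
    utils::write.csv(exposure$estimates, artifacts[["exposure_csv"]],
                     row.names = FALSE)
  }
  writeLines(make_report(summary, exposure), artifacts[["report"]])
  if (verbose) message("wrote ", length(artifacts), " artifacts to ", out_dir)
  invisible(list(cohort = filt$cohort, filter_report = filt$report,
                 findings = findings, summary = summary,
                 exposure = exposure, artifacts = artifacts))
}

write_mdi_jsonl <- function(findings, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in findings$mdis) {
    amp <- m$amplification
    comp <- m$composite %||% compose_severity(m)
    rec <- list(
      patient_id = m$patient_id,
      drugs = as.list(m$drugs),
      size_class = m$size_class,
      pairs = lapply(seq_len(nrow(m$pairs)), function(k) list(
        drug_a = m$pairs$drug_a[k], drug_b = m$pairs$drug_b[k],
        severity = m$pairs$severity[k])),
      composite_severity = as.list(comp$tiers),
      max_severity = comp$max_tier,
      ades = as.list(mdi_ades(m)),
      amplifying = if (!is.null(amp)) amp$amplifying else NA,
      mechanisms = if (!is.null(amp)) as.list(amp$mechanisms) else list(),
      evidence = if (!is.null(amp)) as.list(amp$evidence) else list()
    )
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), con)
  }
  invisible(path)
}

summary_to_list <- function(s) {
  out <- unclass(s)
  out$ade_tally <- as.list(out$ade_tally)
  out
}

fmt1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)

#' Render a cohort summary as a plain-text report
#'
#' Section order mirrors a standard results write-up: cohort size and
#' medication totals, interaction prevalences, medication-count summaries
#' per group, MDI size distribution, severity mix, ADE tally, drug-class
#' shares, and the exposure-extrapolation table when present.
#'
#' @param summary a `cohort_summary`
#' @param exposure optional result of [extrapolate_exposure()]
#' @return character vector of report lines
#' @export
make_report <- function(summary, exposure = NULL) {
  s <- summary
  lines <- c(
    "=== Multidrug interaction screen ===",
    sprintf("Patients analyzed: %d", s$n_patients),
    sprintf("Medications: %d total, %d unique",
            s$n_medications_total, s$n_medications_unique),
    sprintf("Two-drug DDI patients: %d (%s%%)",
            s$n_two_drug_patients, fmt1(s$pct_two_drug)),
    sprintf("MDI patients: %d (%s%%); MDIs: %d",
            s$n_mdi_patients, fmt1(s$pct_mdi), s$n_mdis),
    "",
    "Medications per list (mean +/- sd):"
  )
  for (k in seq_len(nrow(s$med_count_stats))) {
    r <- s$med_count_stats[k, ]
    lines <- c(lines, sprintf(
      "  %-14s n=%-6d %s +/- %s", r$status, r$n,
      if (is.na(r$mean)) "-" else fmt1(r$mean),
      if (is.na(r$sd)) "-" else fmt1(r$sd)))
  }
  sd <- s$size_distribution
  lines <- c(lines, "", sprintf(
    "MDI size distribution: three %s%%, four %s%%, five_plus %s%%",
    fmt1(sd$percent[sd$size_class == "three"]),
    fmt1(sd$percent[sd$size_class == "four"]),
    fmt1(sd$percent[sd$size_class == "five_plus"])))
  sv <- s$severity_distribution
  lines <- c(lines, sprintf(
    "Pair severity mix: contraindicated %s%%, generally_avoid %s%%, monitor_closely %s%%",
    fmt1(sv$percent[sv$severity == "contraindicated"]),
    fmt1(sv$percent[sv$severity == "generally_avoid"]),
    fmt1(sv$percent[sv$severity == "monitor_closely"])))
  if (length(s$ade_tally) > 0) {
    lines <- c(lines, "", "Potential ADEs (per MDI):")
    for (nm in names(s$ade_tally))
      lines <- c(lines, sprintf("  %-28s %d", nm, s$ade_tally[[nm]]))
  }
  if (!is.null(s$class_tally) && nrow(s$class_tally) > 0) {
    lines <- c(lines, "", "Drug classes among MDI drug instances:")
    for (k in seq_len(nrow(s$class_tally)))
      lines <- c(lines, sprintf("  %-20s %s%%", s$class_tally$class[k],
                                fmt1(s$class_tally$percent[k])))
  }
  if (!is.null(exposure)) {
    lines <- c(lines, "", "Beneficiary exposure extrapolation:")
    est <- exposure$estimates
    for (k in seq_len(nrow(est)))
      lines <- c(lines, sprintf(
        "  %-16s %5.1f%% of %12s beneficiaries -> %10s exposed",
        est$drug[k], 100 * est$prevalence[k],
        format(est$n_beneficiaries[k], big.mark = ","),
        format(est$n_exposed[k], big.mark = ",")))
    lines <- c(lines, sprintf(
      "  %-16s        of %12s beneficiaries -> %10s exposed (round-after-sum)",
      "TOTAL", format(exposure$totals$total_beneficiaries, big.mark = ","),
      format(exposure$totals$total_exposed, big.mark = ",")))
  }
  lines
}
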