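#' @title Cohort-level interaction statistics
#' @description
#' Descriptive aggregates over a screened cohort: patient-status
#' prevalences, MDI size distribution, medication-count summaries per
#' status group, the severity-tier mix of MDI constituent pairs, ADE and
#' drug-class tallies, and per-drug MDI prevalence. All percentages are
#' reported half-up to one decimal.
#' @name cohort_stats
NULL

SIZE_CLASSES <- c("three", "four", "five_plus")
STATUS_LEVELS <- c("none", "two_drug_only", "mdi")

#' Summarize a screened cohort
#'
#' @param cohort the cleaned, normalized `mdi_cohort` the findings were
#'   computed from
#' @param findings an `mdi_findings` from [detect_interactions()]
#' @param class_map optional named character vector (drug -> class) for
#'   the drug-class tally
#' @param sd_type "sample" (n-1, default) or "population"
#' @return list of class `cohort_summary` with counts, prevalences, size
#'   and severity distributions, medication-count statistics per status
#'   group, and the ADE tally (plus `class_tally` when a map is given).
#'   An empty cohort summarizes to zeros.
#' @export
summarize_cohort <- function(cohort, findings, class_map = NULL,
                             sd_type = c("sample", "population")) {
  stopifnot(inherits(findings, "mdi_findings"))
  sd_type <- match.arg(sd_type)
  pat <- findings$patients
  n_patients <- nrow(pat)
  status <- factor(pat$status, levels = STATUS_LEVELS)
  status_counts <- as.integer(table(status))
  names(status_counts) <- STATUS_LEVELS

  sizes <- vapply(findings$mdis, function(m) m$size_class, "")
  size_counts <- as.integer(table(factor(sizes, levels = SIZE_CLASSES)))
  n_mdis <- length(findings$mdis)
  size_distribution <- data.frame(
    size_class = SIZE_CLASSES,
    count = size_counts,
    percent = if (n_mdis > 0) pct(size_counts, n_mdis) else rep(0, 3),
    stringsAsFactors = FALSE
  )

  med_count_stats <- do.call(rbind, lapply(STATUS_LEVELS, function(s) {
    x <- pat$n_medications[pat$status == s]
    data.frame(status = s, n = length(x),
               mean = if (length(x) > 0) mean(x) else NA_real_,
               sd = sd_by(x, sd_type), stringsAsFactors = FALSE)
  }))

  # severity mix over the constituent pairs of all MDIs
  tiers <- unlist(lapply(findings$mdis, function(m) m$pairs$severity))
  tier_counts <- as.integer(table(factor(tiers, levels = rev(SEVERITY_LEVELS))))
  severity_distribution <- data.frame(
    severity = rev(SEVERITY_LEVELS),
    count = tier_counts,
    percent = if (length(tiers) > 0) pct(tier_counts, length(tiers))
              else rep(0, 3),
    stringsAsFactors = FALSE
  )

  name <- if (n_patients > 0 && nrow(cohort) > 0) effective_name(cohort)
          else character()
  out <- list(
    n_patients = n_patients,
    n_medications_total = sum(pat$n_medications),
    n_medications_unique = length(unique(name)),
    n_none = status_counts[["none"]],
    n_two_drug_patients = status_counts[["two_drug_only"]],
    n_mdi_patients = status_counts[["mdi"]],
    pct_two_drug = pct(status_counts[["two_drug_only"]], max(n_patients, 1)),
    pct_mdi = pct(status_counts[["mdi"]], max(n_patients, 1)),
    n_mdis = n_mdis,
    size_distribution = size_distribution,
    med_count_stats = med_count_stats,
    severity_distribution = severity_distribution,
    ade_tally = ade_tally(findings)
  )
  if (n_patients == 0) { out$pct_two_drug <- 0; out$pct_mdi <- 0 }
  if (!is.null(class_map)) out$class_tally <- class_tally(findings, class_map)
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of ", x$n_patients, " patients, ", x$n_medications_total,
      " medications (", x$n_medications_unique, " unique)\n",
      "  two-drug DDI patients: ", x$n_two_drug_patients,
      " (", x$pct_two_drug, "%)\n",
      "  MDI patients: ", x$n_mdi_patients, " (", x$pct_mdi, "%), ",
      x$n_mdis, " MDIs\n", sep = "")
  invisible(x)
}

#' Per-drug MDI prevalence
#'
#' The share of medication lists containing a drug on which that drug is
#' itself a member of an MDI (`mode = "member"`, the default) or on which
#' any MDI is present (`mode = "on_list"`).
#'
#' @param cohort the screened `mdi_cohort`
#' @param findings an `mdi_findings`
#' @param drug drug name
#' @param mode numerator convention, see above
#' @return list of class `per_drug_prevalence`: `drug`,
#'   `n_lists_with_drug`, `n_lists_with_drug_in_mdi`, `prevalence`
#'   (percent, 1 decimal)
#' @export
per_drug_prevalence <- function(cohort, findings, drug,
                                mode = c("member", "on_list")) {
  mode <- match.arg(mode)
  drug <- normalize_drug_name(drug)
  name <- effective_name(cohort)
  with_drug <- unique(cohort$patient_id[name == drug])
  if (length(with_drug) == 0)
    stop("prevalence undefined: drug '", drug, "' appears on no list")
  num_ids <- if (mode == "member") {
    unique(unlist(lapply(findings$mdis, function(m)
      if (drug %in% m$drugs) m$patient_id)))
  } else {
    mdi_pat <- unique(vapply(findings$mdis, function(m) m$patient_id, ""))
    intersect(with_drug, mdi_pat)
  }
  num_ids <- intersect(num_ids %||% character(), with_drug)
  structure(
    list(drug = drug,
         n_lists_with_drug = length(with_drug),
         n_lists_with_drug_in_mdi = length(num_ids),
         prevalence = pct(length(num_ids), length(with_drug))),
    class = "per_drug_prevalence"
  )
}

#' @export
print.per_drug_prevalence <- function(x, ...) {
  cat(x$drug, ": in MDI on ", x$n_lists_with_drug_in_mdi, " of ",
      x$n_lists_with_drug, " lists (", x$prevalence, "%)\n", sep = "")
  invisible(x)
}

#' Tally ADE terms over MDIs
#'
#' Each MDI contributes each of its distinct ADE terms once; a patient
#' with one MDI carrying several terms therefore adds to several counts.
#' With `per = "patient"` the unit is the patient instead (a term counts
#' once per patient however many of their MDIs carry it).
#'
#' @param findings an `mdi_findings`
#' @param per counting unit, "mdi" (default) or "patient"
#' @return named integer vector, term -> count, decreasing
#' @export
ade_tally <- function(findings, per = c("mdi", "patient")) {
  per <- match.arg(per)
  units <- lapply(findings$mdis, function(m)
    list(id = m$patient_id, terms = mdi_ades(m)))
  if (per == "patient" && length(units) > 0) {
    ids <- vapply(units, `[[`, "", "id")
    units <- lapply(unique(ids), function(i)
      list(id = i, terms = unique(unlist(
        lapply(units[ids == i], `[[`, "terms")))))
  }
  terms <- unlist(lapply(units, `[[`, "terms"))
  if (length(terms) == 0) return(stats::setNames(integer(), character()))
  tab <- table(terms)
  out <- as.integer(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Drug-class shares among MDI drug instances
#'
#' Each drug counts once per MDI it appears in; the denominator is the
#' total number of such drug instances. Drugs absent from the map fall
#' into class "other".
#'
#' @param findings an `mdi_findings`
#' @param class_map named character vector, drug -> class
#' @return data frame `class`, `count`, `percent` (1 decimal), sorted by
#'   decreasing share
#' @export
class_tally <- function(findings, class_map) {
  instances <- unlist(lapply(findings$mdis, function(m) m$drugs))
  if (length(instances) == 0)
    return(data.frame(class = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  cls <- unname(class_map[instances])
  cls[is.na(cls)] <- "other"
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(class = names(tab), count = as.integer(tab),
             percent = pct(as.integer(tab), length(instances)),
             stringsAsFactors = FALSE)
}

#' Read a drug-class map CSV
#'
#' @param path CSV with columns `drug`, `class`
#' @return named character vector, drug -> class
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) stop("class map file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("drug", "class") %in% names(df)))
    stop("class map must have columns 'drug' and 'class'")
  stats::setNames(trimws(df$class), normalize_drug_name(df$drug))
}
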