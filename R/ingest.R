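#' @title Cohort ingest and cleaning
#' @description
#' Reads raw medication-list extracts (one row per medication entry) and
#' applies the cohort cleaning rules: minimum age, exclusion of patients
#' whose lists carry inpatient marker drugs, removal of topical/ophthalmic
#' entries, and restriction to lists whose entries were all recorded on one
#' calendar day (a proxy for a reconciled, current list).
#' @name cohort_ingest
NULL

#' Build a cohort object from a data frame
#'
#' @param df data frame with columns `patient_id`, `age`, `drug`,
#'   `entry_date` and optionally `route_class`
#' @return long-format data frame of class `mdi_cohort`, one row per
#'   medication entry, with `raw_name`/`generic_name` columns
#' @export
as_cohort <- function(df) {
  need <- c("patient_id", "age", "drug", "entry_date")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  date <- if (inherits(df$entry_date, "Date")) df$entry_date else {
    d <- as.Date(as.character(df$entry_date), format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(df$entry_date) & nzchar(df$entry_date))
    if (length(bad) > 0)
      stop("unparseable entry_date at row ", bad[1], ": '",
           df$entry_date[bad[1]], "' (expected ISO 8601, YYYY-MM-DD)")
    d
  }
  route <- if ("route_class" %in% names(df)) {
    r <- tolower(trimws(as.character(df$route_class)))
    r[is.na(r) | !nzchar(r)] <- "unknown"
    bad <- !r %in% c("systemic", "topical", "ophthalmic", "unknown")
    if (any(bad)) r[bad] <- "unknown"
    r
  } else rep("unknown", nrow(df))
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    age = as.integer(df$age),
    raw_name = as.character(df$drug),
    generic_name = if ("generic_name" %in% names(df))
      as.character(df$generic_name) else rep(NA_character_, nrow(df)),
    entry_date = date,
    route_class = route,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mdi_cohort", "data.frame")
  out
}

#' Read a cohort CSV
#'
#' Expected columns: `patient_id`, `age`, `drug`, `entry_date` (ISO 8601)
#' and optionally `route_class` (systemic / topical / ophthalmic /
#' unknown). One row per medication entry; rows sharing a `patient_id`
#' form that patient's medication list.
#'
#' @param path CSV file path
#' @return an `mdi_cohort`
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_cohort(df)
}

#' Read a brand-to-generic name map CSV
#'
#' @param path CSV with columns `brand`, `generic`
#' @return named character vector, normalized brand -> normalized generic
#' @export
read_brand_map <- function(path) {
  if (!file.exists(path)) stop("brand map file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("brand", "generic") %in% names(df)))
    stop("brand map must have columns 'brand' and 'generic'")
  stats::setNames(normalize_drug_name(df$generic), normalize_drug_name(df$brand))
}

#' Normalize medication names to lowercase generics
#'
#' Names are lowercased and trimmed, then mapped through the brand map;
#' names absent from the map pass through as their own generic. The
#' operation is idempotent, so it is safe to run on a cohort that was
#' already normalized.
#'
#' @param cohort an `mdi_cohort`
#' @param brand_map named character vector (brand -> generic) as returned
#'   by [read_brand_map()], or `NULL` for case-folding only
#' @return the cohort with `generic_name` filled in
#' @export
normalize_names <- function(cohort, brand_map = NULL) {
  stopifnot(inherits(cohort, "mdi_cohort"))
  base <- ifelse(is.na(cohort$generic_name),
                 cohort$raw_name, cohort$generic_name)
  name <- normalize_drug_name(base)
  if (!is.null(brand_map) && length(brand_map) > 0) {
    if (any(!nzchar(names(brand_map))) || any(!nzchar(brand_map)))
      stop("brand map keys and values must be non-empty")
    hit <- match(name, names(brand_map))
    name[!is.na(hit)] <- unname(brand_map[hit[!is.na(hit)]])
  }
  cohort$generic_name <- name
  cohort
}

effective_name <- function(cohort) {
  ifelse(is.na(cohort$generic_name),
         normalize_drug_name(cohort$raw_name), cohort$generic_name)
}

new_filter_report <- function(step, n_input, n_output, reasons = character(),
                              extra = list()) {
  structure(
    c(list(step = step, n_input = n_input, n_output = n_output,
           reasons = reasons), extra),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report [", x$step, "]: ", x$n_input, " -> ", x$n_output,
      " patients\n", sep = "")
  counts <- x[grepl("^n_", names(x)) & !names(x) %in% c("n_input", "n_output")]
  for (nm in names(counts)) cat("  ", nm, ": ", counts[[nm]], "\n", sep = "")
  invisible(x)
}

#' Apply age, inpatient-marker and route exclusions
#'
#' Rules are applied in a fixed order and each excluded patient is tagged
#' with the first rule that removed them:
#' 1. patients younger than `min_age` are excluded;
#' 2. patients whose list contains any inpatient marker drug are excluded
#'    entirely (the list is presumed stale after a recent hospitalization);
#' 3. topical and ophthalmic entries are removed from surviving lists
#'    (entry-level: the patient stays).
#'
#' `route_class` "unknown" is treated as systemic unless `route_keywords`
#' supplies a regex per route to reclassify unknown entries by name
#' (off by default).
#'
#' @param cohort an `mdi_cohort` (names should be normalized first)
#' @param min_age minimum age in years, default 60
#' @param inpatient_markers drugs that flag a recently hospitalized
#'   patient; defaults to [INPATIENT_MARKERS]
#' @param exclude_routes route classes removed at entry level
#' @param route_keywords optional named character vector
#'   (route -> regex on the raw name) used to reclassify `unknown` routes
#' @return list with elements `cohort` and `report` (a `filter_report`)
#' @export
apply_exclusions <- function(cohort, min_age = 60,
                             inpatient_markers = INPATIENT_MARKERS,
                             exclude_routes = c("topical", "ophthalmic"),
                             route_keywords = NULL) {
  stopifnot(inherits(cohort, "mdi_cohort"))
  inpatient_markers <- normalize_drug_name(inpatient_markers)
  name <- effective_name(cohort)
  ids <- unique(cohort$patient_id)
  n_input <- length(ids)
  reasons <- character()

  age_of <- cohort$age[match(ids, cohort$patient_id)]
  too_young <- ids[!is.na(age_of) & age_of < min_age]
  reasons[too_young] <- "age"

  survivors <- setdiff(ids, too_young)
  marked <- unique(cohort$patient_id[name %in% inpatient_markers])
  marked <- intersect(survivors, marked)
  reasons[marked] <- "inpatient_marker"
  survivors <- setdiff(survivors, marked)

  keep_pat <- cohort$patient_id %in% survivors
  route <- cohort$route_class
  if (!is.null(route_keywords)) {
    for (rt in names(route_keywords)) {
      unk <- route == "unknown" &
        grepl(route_keywords[[rt]], cohort$raw_name, ignore.case = TRUE)
      route[unk] <- rt
    }
  }
  keep_entry <- keep_pat & !(route %in% exclude_routes)
  n_route_removed <- sum(keep_pat & !keep_entry)

  out <- cohort[keep_entry, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mdi_cohort", "data.frame")
  report <- new_filter_report(
    "exclusions", n_input, length(survivors), reasons,
    extra = list(n_age_excluded = length(too_young),
                 n_inpatient_excluded = length(marked),
                 n_route_entries_removed = n_route_removed)
  )
  list(cohort = out, report = report)
}

#' Keep only single-day medication lists
#'
#' A patient survives if and only if all of their remaining entries share
#' one calendar date; lists spanning several entry dates are taken to be
#' unreconciled and are excluded, as are patients left with zero entries
#' by earlier filters.
#'
#' @param cohort an `mdi_cohort`
#' @return list with elements `cohort` and `report`
#' @export
same_day_filter <- function(cohort) {
  stopifnot(inherits(cohort, "mdi_cohort"))
  ids <- unique(cohort$patient_id)
  n_dates <- tapply(as.integer(cohort$entry_date), cohort$patient_id,
                    function(d) length(unique(d)))
  mixed <- names(n_dates)[n_dates > 1]
  reasons <- character()
  reasons[mixed] <- "mixed_dates"
  out <- cohort[!cohort$patient_id %in% mixed, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mdi_cohort", "data.frame")
  report <- new_filter_report(
    "same_day", length(ids), length(ids) - length(mixed), reasons,
    extra = list(n_mixed_date_excluded = length(mixed))
  )
  list(cohort = out, report = report)
}

#' Run the full cleaning chain
#'
#' Fixed order: age -> inpatient markers -> route exclusion -> same-day
#' restriction. Patients whose lists become empty after route exclusion
#' are dropped with reason `empty_list`. The combined report balances
#' exactly: `n_output = n_input - n_age_excluded - n_inpatient_excluded -
#' n_empty_excluded - n_mixed_date_excluded`.
#'
#' @inheritParams apply_exclusions
#' @return list with elements `cohort` and `report`
#' @export
filter_cohort <- function(cohort, min_age = 60,
                          inpatient_markers = INPATIENT_MARKERS,
                          exclude_routes = c("topical", "ophthalmic"),
                          route_keywords = NULL) {
  step1 <- apply_exclusions(cohort, min_age = min_age,
                            inpatient_markers = inpatient_markers,
                            exclude_routes = exclude_routes,
                            route_keywords = route_keywords)
  # route exclusion can empty a list; those patients are dropped here,
  # before the same-day rule, so reason codes stay unambiguous
  survivors_in <- setdiff(unique(cohort$patient_id),
                          names(step1$report$reasons))
  emptied <- setdiff(survivors_in, unique(step1$cohort$patient_id))
  reasons <- step1$report$reasons
  reasons[emptied] <- "empty_list"
  step2 <- same_day_filter(step1$cohort)
  reasons[names(step2$report$reasons)] <- step2$report$reasons

  n_input <- step1$report$n_input
  report <- new_filter_report(
    "full_chain", n_input, step2$report$n_output, reasons,
    extra = list(
      n_age_excluded = step1$report$n_age_excluded,
      n_inpatient_excluded = step1$report$n_inpatient_excluded,
      n_route_entries_removed = step1$report$n_route_entries_removed,
      n_empty_excluded = length(emptied),
      n_mixed_date_excluded = step2$report$n_mixed_date_excluded
    )
  )
  list(cohort = step2$cohort, report = report)
}

filter_report_to_list <- function(report) {
  out <- unclass(report)
  out$reasons <- as.list(out$reasons)
  out
}
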