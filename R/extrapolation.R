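#' @title Beneficiary-exposure extrapolation
#' @description
#' Projects per-drug MDI prevalences onto external prescription counts
#' (e.g. CMS Part D beneficiaries per drug) to estimate how many persons
#' filling prescriptions for a drug could be exposed to an MDI involving
#' it. Counts round half-up; the table total is computed by summing the
#' unrounded per-drug products and rounding once (round-after-sum), with
#' the sum of the per-row rounded counts also reported — the two can
#' differ by a unit or two.
#' @name extrapolation
NULL

#' Estimate beneficiaries exposed to MDIs for one or more drugs
#'
#' @param drug drug name(s)
#' @param n_beneficiaries count(s) of persons filling prescriptions
#' @param prevalence MDI prevalence as a fraction in `[0, 1]` (e.g. 0.273
#'   for 27.3 %), recycled against `drug`
#' @return data frame of class `exposure_estimates`: `drug`, `prevalence`,
#'   `n_beneficiaries`, `n_exposed_raw` (unrounded product) and
#'   `n_exposed` (half-up rounded)
#' @export
estimate_exposure <- function(drug, n_beneficiaries, prevalence) {
  if (any(is.na(prevalence)) || any(prevalence < 0) || any(prevalence > 1))
    stop("prevalence must be a fraction in [0, 1]")
  if (any(n_beneficiaries < 0)) stop("beneficiary counts must be non-negative")
  raw <- prevalence * n_beneficiaries
  out <- data.frame(
    drug = normalize_drug_name(drug),
    prevalence = prevalence,
    n_beneficiaries = as.numeric(n_beneficiaries),
    n_exposed_raw = raw,
    n_exposed = round_half_up(raw),
    stringsAsFactors = FALSE
  )
  class(out) <- c("exposure_estimates", "data.frame")
  out
}

#' Total a table of exposure estimates
#'
#' @param estimates an `exposure_estimates` data frame with at least one row
#' @return list with `total_beneficiaries`, `total_exposed` (round the sum
#'   of unrounded products — the default presentation) and
#'   `total_exposed_rowwise` (sum of the per-row rounded counts)
#' @export
total_exposure <- function(estimates) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0)
    stop("total_exposure needs at least one estimate")
  list(
    total_beneficiaries = sum(estimates$n_beneficiaries),
    total_exposed = round_half_up(sum(estimates$n_exposed_raw)),
    total_exposed_rowwise = sum(estimates$n_exposed)
  )
}

#' Read a beneficiary-count table CSV
#'
#' @param path CSV with columns `drug`, `n_beneficiaries` and optionally
#'   `prevalence_pct` (externally supplied prevalence in percent)
#' @return data frame with normalized drug names
#' @export
read_beneficiaries <- function(path) {
  if (!file.exists(path)) stop("beneficiary file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("drug", "n_beneficiaries") %in% names(df)))
    stop("beneficiary table must have columns 'drug' and 'n_beneficiaries'")
  df$drug <- normalize_drug_name(df$drug)
  df$n_beneficiaries <- as.numeric(df$n_beneficiaries)
  df
}

#' Build an exposure table from beneficiary counts
#'
#' Prevalences come from the table's `prevalence_pct` column when present,
#' otherwise from per-drug prevalence computed on the screened cohort.
#'
#' @param beneficiaries data frame from [read_beneficiaries()]
#' @param cohort,findings screened cohort, required when the table has no
#'   `prevalence_pct` column
#' @param mode numerator convention for computed prevalences,
#'   see [per_drug_prevalence()]
#' @return list with `estimates` (an `exposure_estimates`) and `totals`
#'   (from [total_exposure()])
#' @export
extrapolate_exposure <- function(beneficiaries, cohort = NULL,
                                 findings = NULL,
                                 mode = c("member", "on_list")) {
  mode <- match.arg(mode)
  if ("prevalence_pct" %in% names(beneficiaries)) {
    prev <- as.numeric(beneficiaries$prevalence_pct) / 100
  } else {
    if (is.null(cohort) || is.null(findings))
      stop("need a screened cohort to compute prevalences: the beneficiary ",
           "table has no prevalence_pct column")
    prev <- vapply(beneficiaries$drug, function(d)
      per_drug_prevalence(cohort, findings, d, mode = mode)$prevalence / 100,
      0)
  }
  est <- estimate_exposure(beneficiaries$drug, beneficiaries$n_beneficiaries,
                           prev)
  list(estimates = est, totals = total_exposure(est))
}
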