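#' @title Amplification mechanisms and composite severity
#' @description
#' An MDI amplifies ADE risk beyond its constituent two-drug interactions
#' through three mechanisms: pharmacodynamic (three or more of its drugs
#' share the same ADE), pharmacokinetic (inhibition of a drug's
#' metabolism compounds an interaction it is already part of, or two
#' drugs inhibit the same third drug), and conditional (one drug alters
#' the patient's physiology in a way that raises susceptibility to the
#' ADEs of two others). An MDI with no mechanism evidence is reported as
#' non-amplifying rather than an error — such MDIs exist.
#' @name amplification
NULL

# per-drug ADE attribution within an MDI: each pair record's terms are
# attributed to both pair members; an optional per-drug table adds terms
# for single-drug effects the pair records cannot carry
drug_ade_attribution <- function(mdi, drug_ades = NULL) {
  attrib <- stats::setNames(vector("list", length(mdi$drugs)), mdi$drugs)
  for (rec in mdi$records) {
    for (d in rec$pair) attrib[[d]] <- union(attrib[[d]], rec$ades)
  }
  if (!is.null(drug_ades)) {
    for (d in intersect(names(drug_ades), mdi$drugs))
      attrib[[d]] <- union(attrib[[d]], drug_ades[[d]])
  }
  attrib
}

#' Pharmacodynamic amplification: a shared ADE across three or more drugs
#'
#' ADE terms are attributed per drug from the MDI's pair records (a pair's
#' terms belong to both members), optionally supplemented by a per-drug
#' ADE table. Evidence is returned when some term is attributed to at
#' least three distinct drugs of the MDI.
#'
#' @param mdi an `mdi`
#' @param kb the `ddi_kb` (kept for interface symmetry; attribution uses
#'   the records already attached to the MDI)
#' @param drug_ades optional named list, drug -> character vector of terms
#' @return character vector of evidence strings, or `NULL`
#' @export
classify_pharmacodynamic <- function(mdi, kb = NULL, drug_ades = NULL) {
  attrib <- drug_ade_attribution(mdi, drug_ades)
  terms <- sort(unique(unlist(attrib)))
  ev <- character()
  for (tm in terms) {
    carriers <- sort(names(attrib)[vapply(attrib, function(a) tm %in% a, NA)])
    if (length(carriers) >= 3)
      ev <- c(ev, paste0("ADE '", tm, "' shared by ",
                         paste(carriers, collapse = ", ")))
  }
  if (length(ev) > 0) ev else NULL
}

# inhibitor -> substrate arcs among the MDI's drugs
pk_arcs <- function(mdi) {
  arcs <- list()
  for (rec in mdi$records) {
    for (m in rec$mechanisms) {
      if (m$kind == "pk_inhibition" &&
          all(c(m$inhibitor, m$substrate) %in% mdi$drugs))
        arcs[[length(arcs) + 1]] <-
          list(inhibitor = m$inhibitor, substrate = m$substrate,
               enzyme = m$enzyme)
    }
  }
  arcs
}

#' Pharmacokinetic amplification: compounded metabolic inhibition
#'
#' Evidence is returned when either
#' (a) two or more distinct drugs of the MDI are annotated inhibitors of
#' the same third MDI drug, or
#' (b) an inhibition arc X -> Y overlaps another interaction of Y: some
#' third MDI drug Z (Z != X) shares a KB pair with Y, so the inhibition
#' steepens an interaction Y is already part of. Case (b) covers both
#' inhibition chains (X inhibits Y while Y inhibits Z) and a single
#' inhibitor amplifying an existing pair (amiodarone inhibiting warfarin
#' while warfarin interacts with aspirin). A lone arc with no overlapping
#' pair is not amplification.
#'
#' @inheritParams classify_pharmacodynamic
#' @return character vector of evidence strings, or `NULL`
#' @export
classify_pharmacokinetic <- function(mdi, kb = NULL) {
  arcs <- pk_arcs(mdi)
  if (length(arcs) == 0) return(NULL)
  ev <- character()
  substrates <- vapply(arcs, `[[`, "", "substrate")
  inhibitors <- vapply(arcs, `[[`, "", "inhibitor")
  for (s in sort(unique(substrates))) {
    inh <- sort(unique(inhibitors[substrates == s]))
    if (length(inh) >= 2)
      ev <- c(ev, paste0("metabolism of ", s, " inhibited by ",
                         paste(inh, collapse = " and ")))
  }
  pair_partner <- function(d) {
    out <- character()
    for (rec in mdi$records)
      if (d %in% rec$pair) out <- c(out, setdiff(rec$pair, d))
    unique(out)
  }
  for (arc in arcs) {
    third <- setdiff(pair_partner(arc$substrate), arc$inhibitor)
    for (z in sort(third))
      ev <- c(ev, paste0(arc$inhibitor, " inhibits ", arc$substrate,
                         ", amplifying the ", arc$substrate, "-", z,
                         " interaction"))
  }
  ev <- unique(ev)
  if (length(ev) > 0) ev else NULL
}

#' Conditional amplification: physiology-mediated susceptibility
#'
#' Evidence is returned when a drug of the MDI carries a conditional
#' annotation whose scope covers at least two *other* drugs of the same
#' MDI; scope members outside the MDI do not count.
#'
#' @inheritParams classify_pharmacodynamic
#' @return character vector of evidence strings, or `NULL`
#' @export
classify_conditional <- function(mdi, kb = NULL) {
  ev <- character()
  for (rec in mdi$records) {
    for (m in rec$mechanisms) {
      if (m$kind != "conditional" || !(m$drug %in% mdi$drugs)) next
      covered <- sort(intersect(m$scope, setdiff(mdi$drugs, m$drug)))
      if (length(covered) >= 2)
        ev <- c(ev, paste0(m$drug, " raises susceptibility to ADEs of ",
                           paste(covered, collapse = ", ")))
    }
  }
  ev <- unique(ev)
  if (length(ev) > 0) ev else NULL
}

#' Classify an MDI's amplification mechanisms
#'
#' Runs all three mechanism classifiers; the MDI is amplifying when any
#' returns evidence.
#'
#' @inheritParams classify_pharmacodynamic
#' @return list of class `amplification_result`: `mechanisms` (subset of
#'   pharmacodynamic / pharmacokinetic / conditional), `amplifying`
#'   (logical) and `evidence` (character, deterministic order)
#' @export
classify_amplification <- function(mdi, kb = NULL, drug_ades = NULL) {
  found <- list(
    pharmacodynamic = classify_pharmacodynamic(mdi, kb, drug_ades),
    pharmacokinetic = classify_pharmacokinetic(mdi, kb),
    conditional = classify_conditional(mdi, kb)
  )
  mechanisms <- names(found)[!vapply(found, is.null, NA)]
  structure(
    list(mechanisms = mechanisms,
         amplifying = length(mechanisms) > 0,
         evidence = unlist(found, use.names = FALSE) %||% character()),
    class = "amplification_result"
  )
}

#' @export
print.amplification_result <- function(x, ...) {
  cat("Amplifying:", x$amplifying,
      if (x$amplifying) paste0("(", paste(x$mechanisms, collapse = ", "), ")"),
      "\n")
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Composite severity of an MDI
#'
#' An MDI is rated by the multiset of the severity tiers of its
#' constituent pairs, sorted from most to least severe, with the maximum
#' tier as headline rating.
#'
#' @param mdi an `mdi`, or a character vector of severity tiers
#' @return list of class `composite_severity` with `tiers` (descending)
#'   and `max_tier`
#' @export
compose_severity <- function(mdi) {
  tiers <- if (inherits(mdi, "mdi")) mdi$pairs$severity else
    normalize_severity(mdi)
  if (length(tiers) == 0 || anyNA(tiers))
    stop("every constituent pair must carry an admitted severity tier")
  tiers <- tiers[order(-severity_rank(tiers), tiers)]
  structure(list(tiers = tiers, max_tier = tiers[1]),
            class = "composite_severity")
}

#' @export
print.composite_severity <- function(x, ...) {
  cat("[", paste(gsub("_", " ", x$tiers), collapse = " - "), "]\n", sep = "")
  invisible(x)
}
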