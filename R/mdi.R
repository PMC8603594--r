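#' @title Multidrug-interaction detection by network analysis
#' @description
#' For each patient the deduplicated medication list becomes a graph:
#' nodes are drugs, and an edge joins every pair with a KB interaction
#' record. A two-node connected component is an ordinary two-drug DDI; a
#' connected component of three or more drugs is a multidrug interaction
#' (MDI) — by connectivity it necessarily contains a drug interacting with
#' at least two others. A patient may carry several disjoint MDIs; all are
#' returned.
#' @name mdi_engine
NULL

#' Build a patient's interaction graph
#'
#' Nodes are the deduplicated, normalized drugs of the list; for every
#' unordered node pair with a KB record exactly one edge is added. Pair
#' enumeration is quadratic in the list length, which is fine for
#' medication lists (tens of drugs at most).
#'
#' @param drugs character vector of drug names (a patient's list), or an
#'   `mdi_cohort` subset for one patient
#' @param kb a `ddi_kb`
#' @return object of class `interaction_graph`: `nodes` (sorted character
#'   vector), `edges` (data frame `drug_a`, `drug_b`, `severity`) and
#'   `records` (list of `ddi_record`, aligned with `edges` rows)
#' @export
build_graph <- function(drugs, kb) {
  stopifnot(inherits(kb, "ddi_kb"))
  if (inherits(drugs, "mdi_cohort")) drugs <- effective_name(drugs)
  nodes <- sort(unique(normalize_drug_name(drugs)))
  nodes <- nodes[nzchar(nodes)]
  ea <- character(); eb <- character(); sev <- character(); recs <- list()
  if (length(nodes) >= 2) {
    idx <- utils::combn(length(nodes), 2)
    for (k in seq_len(ncol(idx))) {
      a <- nodes[idx[1, k]]; b <- nodes[idx[2, k]]
      rec <- kb$records[[pair_key(a, b)]]
      if (!is.null(rec)) {
        ea <- c(ea, a); eb <- c(eb, b); sev <- c(sev, rec$severity)
        recs[[length(recs) + 1]] <- rec
      }
    }
  }
  structure(
    list(nodes = nodes,
         edges = data.frame(drug_a = ea, drug_b = eb, severity = sev,
                            stringsAsFactors = FALSE),
         records = recs),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Interaction graph: ", length(x$nodes), " drugs, ",
      nrow(x$edges), " interacting pairs\n", sep = "")
  invisible(x)
}

# connected components by breadth-first search over an adjacency list;
# returns a list of sorted node vectors, ordered by smallest member
graph_components <- function(g) {
  nodes <- g$nodes
  if (length(nodes) == 0) return(list())
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges$drug_a[k]; b <- g$edges$drug_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[[start]]) next
    queue <- start
    seen[[start]] <- TRUE
    members <- character()
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      for (w in adj[[v]]) {
        if (!seen[[w]]) { seen[[w]] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps[order(vapply(comps, `[`, "", 1))]
}

size_class_of <- function(n) {
  if (n <= 2) stop("an MDI needs at least 3 drugs")
  if (n == 3) "three" else if (n == 4) "four" else "five_plus"
}

mdi_object <- function(drugs, g, patient_id) {
  keep <- g$edges$drug_a %in% drugs & g$edges$drug_b %in% drugs
  structure(
    list(patient_id = patient_id,
         drugs = sort(drugs),
         pairs = g$edges[keep, , drop = FALSE],
         records = g$records[keep],
         size_class = size_class_of(length(drugs))),
    class = "mdi"
  )
}

#' @export
print.mdi <- function(x, ...) {
  cat("MDI (", x$size_class, "): ", paste(x$drugs, collapse = ", "),
      " [", nrow(x$pairs), " pairs]\n", sep = "")
  invisible(x)
}

#' Enumerate the MDIs of an interaction graph
#'
#' One MDI per connected component with three or more drugs, carrying the
#' component's induced edges. Components of exactly two drugs are plain
#' two-drug DDIs and are reported by [pair_findings()], not here. Output
#' order is deterministic: components sorted by their lexicographically
#' smallest drug.
#'
#' @param g an `interaction_graph`
#' @param patient_id identifier attached to each MDI
#' @return list of `mdi` objects (possibly several per patient)
#' @export
find_mdis <- function(g, patient_id = NA_character_) {
  comps <- graph_components(g)
  comps <- comps[vapply(comps, length, 0L) >= 3]
  lapply(comps, mdi_object, g = g, patient_id = patient_id)
}

#' Tabulate every interacting pair with its MDI membership
#'
#' @param g an `interaction_graph`
#' @param patient_id identifier attached to each row
#' @return data frame `patient_id`, `drug_a`, `drug_b`, `severity`,
#'   `in_mdi`; `in_mdi` is `TRUE` when the pair's connected component has
#'   three or more drugs
#' @export
pair_findings <- function(g, patient_id = NA_character_) {
  comps <- graph_components(g)
  comp_of <- stats::setNames(
    rep(seq_along(comps), vapply(comps, length, 0L)),
    unlist(comps)
  )
  comp_size <- vapply(comps, length, 0L)
  n <- nrow(g$edges)
  data.frame(
    patient_id = rep(patient_id, n),
    drug_a = g$edges$drug_a, drug_b = g$edges$drug_b,
    severity = g$edges$severity,
    in_mdi = if (n > 0) comp_size[comp_of[g$edges$drug_a]] >= 3 else logical(),
    stringsAsFactors = FALSE
  )
}

#' Classify a patient's interaction status
#'
#' Statuses are mutually exclusive: any MDI makes the patient `mdi`
#' (regardless of additional isolated pairs), otherwise any interacting
#' pair makes them `two_drug_only`, otherwise `none`.
#'
#' @param mdis list of `mdi` objects from [find_mdis()]
#' @param two_drug_pairs data frame of the patient's non-MDI pairs (rows
#'   of [pair_findings()] with `in_mdi = FALSE`)
#' @return one of "none", "two_drug_only", "mdi"
#' @export
classify_patient <- function(mdis, two_drug_pairs) {
  if (length(mdis) > 0) return("mdi")
  n_pairs <- if (is.data.frame(two_drug_pairs)) nrow(two_drug_pairs)
             else length(two_drug_pairs)
  if (n_pairs > 0) "two_drug_only" else "none"
}

#' Screen a whole cohort for DDIs and MDIs
#'
#' Runs [build_graph()], [find_mdis()] and [classify_patient()] for every
#' patient and classifies each MDI's amplification mechanisms and
#' composite severity.
#'
#' @param cohort a cleaned, normalized `mdi_cohort`
#' @param kb a `ddi_kb`
#' @param drug_ades optional per-drug ADE table (named list,
#'   drug -> character vector of terms) supplementing pair-derived
#'   attributions in the pharmacodynamic classifier
#' @return object of class `mdi_findings`: `patients` (data frame with
#'   `patient_id`, `age`, `n_medications`, `status`), `mdis` (list of
#'   `mdi` objects with `$amplification` and `$composite` filled in) and
#'   `pairs` (row-bound [pair_findings()])
#' @export
detect_interactions <- function(cohort, kb, drug_ades = NULL) {
  stopifnot(inherits(cohort, "mdi_cohort"), inherits(kb, "ddi_kb"))
  name <- effective_name(cohort)
  ids <- unique(cohort$patient_id)
  statuses <- character(length(ids))
  n_meds <- integer(length(ids))
  ages <- integer(length(ids))
  all_mdis <- list()
  pair_rows <- list()
  for (i in seq_along(ids)) {
    sel <- cohort$patient_id == ids[i]
    drugs <- unique(name[sel])     # brand+generic duplicates collapse here
    g <- build_graph(drugs, kb)
    mdis <- find_mdis(g, patient_id = ids[i])
    pf <- pair_findings(g, patient_id = ids[i])
    statuses[i] <- classify_patient(mdis, pf[!pf$in_mdi, , drop = FALSE])
    n_meds[i] <- length(drugs)
    ages[i] <- cohort$age[sel][1]
    for (m in mdis) {
      m$amplification <- classify_amplification(m, kb, drug_ades = drug_ades)
      m$composite <- compose_severity(m)
      all_mdis[[length(all_mdis) + 1]] <- m
    }
    if (nrow(pf) > 0) pair_rows[[length(pair_rows) + 1]] <- pf
  }
  pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else
    data.frame(patient_id = character(), drug_a = character(),
               drug_b = character(), severity = character(),
               in_mdi = logical(), stringsAsFactors = FALSE)
  structure(
    list(
      patients = data.frame(patient_id = ids, age = ages,
                            n_medications = n_meds, status = statuses,
                            stringsAsFactors = FALSE),
      mdis = all_mdis,
      pairs = pairs
    ),
    class = "mdi_findings"
  )
}

#' @export
print.mdi_findings <- function(x, ...) {
  tab <- table(factor(x$patients$status,
                      levels = c("none", "two_drug_only", "mdi")))
  cat("Interaction screen: ", nrow(x$patients), " patients (",
      tab[["none"]], " none / ", tab[["two_drug_only"]], " two-drug / ",
      tab[["mdi"]], " MDI), ", length(x$mdis), " MDIs\n", sep = "")
  invisible(x)
}

#' Flatten MDI findings to a data frame
#'
#' @param findings an `mdi_findings`
#' @return data frame with one row per MDI: `patient_id`, `drugs`
#'   (semicolon-joined), `n_drugs`, `size_class`, `n_pairs`, `max_severity`,
#'   `severities` (descending, semicolon-joined), `amplifying`,
#'   `mechanisms`, `ades`
#' @export
mdi_table <- function(findings) {
  stopifnot(inherits(findings, "mdi_findings"))
  rows <- lapply(findings$mdis, function(m) {
    comp <- m$composite %||% compose_severity(m)
    amp <- m$amplification
    data.frame(
      patient_id = m$patient_id,
      drugs = paste(m$drugs, collapse = ";"),
      n_drugs = length(m$drugs),
      size_class = m$size_class,
      n_pairs = nrow(m$pairs),
      max_severity = comp$max_tier,
      severities = paste(comp$tiers, collapse = ";"),
      amplifying = if (is.null(amp)) NA else amp$amplifying,
      mechanisms = if (is.null(amp)) "" else paste(amp$mechanisms,
                                                  collapse = ";"),
      ades = paste(mdi_ades(m), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0)
    return(data.frame(patient_id = character(), drugs = character(),
                      n_drugs = integer(), size_class = character(),
                      n_pairs = integer(), max_severity = character(),
                      severities = character(), amplifying = logical(),
                      mechanisms = character(), ades = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# union of ADE terms over an MDI's constituent pair records
mdi_ades <- function(mdi) {
  sort(unique(unlist(lapply(mdi$records, function(r) r$ades))))
}
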