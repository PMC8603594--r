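#' @title Drug-drug interaction knowledge base
#' @description
#' The knowledge base (KB) is the package's stand-in for an institutional
#' DDI alerting table: one record per unordered drug pair, carrying a
#' severity tier, the adverse-drug-event (ADE) terms associated with the
#' pair, and optional mechanism annotations used by the amplification
#' classifiers. Only the three alert-worthy severity tiers are admitted:
#' contraindicated > generally_avoid > monitor_closely.
#' @name kb
NULL

#' Severity tiers in ascending order of severity
#' @export
SEVERITY_LEVELS <- c("monitor_closely", "generally_avoid", "contraindicated")

#' Default inpatient marker drugs
#'
#' Drugs generally prescribed to hospitalized patients; a medication list
#' containing any of them is taken to be a stale post-discharge list and
#' the whole patient is excluded from the cohort.
#' @export
INPATIENT_MARKERS <- c(
  "enoxaparin", "vancomycin", "neomycin", "dalteparin", "lactulose", "heparin"
)

normalize_severity <- function(x) {
  y <- gsub("[ -]+", "_", trimws(tolower(as.character(x))))
  ifelse(y %in% SEVERITY_LEVELS, y, NA_character_)
}

#' Rank of a severity tier (1 = monitor_closely ... 3 = contraindicated)
#' @param x character vector of severity tiers
#' @return integer ranks
#' @export
severity_rank <- function(x) match(x, SEVERITY_LEVELS)

#' Construct a mechanism annotation
#'
#' Mechanism annotations ride on KB pair records and feed the three
#' amplification classifiers:
#' * `shared_ade` — the pair's ADE term is attributed to both members
#'   (pharmacodynamic additivity); requires `ade_term`.
#' * `pk_inhibition` — one member inhibits the metabolism of the other;
#'   requires `inhibitor` and `substrate`, both members of the owning pair.
#' * `conditional` — `drug` (a member of the pair) alters physiology in a
#'   way that raises susceptibility to ADEs of the drugs in `scope`.
#'
#' @param kind one of "shared_ade", "pk_inhibition", "conditional"
#' @param inhibitor,substrate drug names (pk_inhibition)
#' @param enzyme optional enzyme tag, e.g. "CYP2D6"
#' @param ade_term ADE term (shared_ade)
#' @param drug owning drug of a conditional annotation
#' @param scope drugs covered by a conditional annotation
#' @return a list of class `mechanism`
#' @export
mechanism <- function(kind, inhibitor = NULL, substrate = NULL, enzyme = NULL,
                      ade_term = NULL, drug = NULL, scope = NULL) {
  kind <- match.arg(kind, c("shared_ade", "pk_inhibition", "conditional"))
  if (kind == "pk_inhibition" && (is.null(inhibitor) || is.null(substrate)))
    stop("pk_inhibition annotation requires both inhibitor and substrate")
  if (kind == "shared_ade" && is.null(ade_term))
    stop("shared_ade annotation requires an ade_term")
  if (kind == "conditional" && (is.null(drug) || is.null(scope)))
    stop("conditional annotation requires a drug and a scope")
  structure(
    list(
      kind = kind,
      inhibitor = if (!is.null(inhibitor)) normalize_drug_name(inhibitor),
      substrate = if (!is.null(substrate)) normalize_drug_name(substrate),
      enzyme = enzyme,
      ade_term = ade_term,
      drug = if (!is.null(drug)) normalize_drug_name(drug),
      scope = if (!is.null(scope)) normalize_drug_name(scope)
    ),
    class = "mechanism"
  )
}

#' Construct an interaction record (the KB atom)
#'
#' @param drug_a,drug_b the two distinct drugs of the unordered pair
#' @param severity severity tier (aliases such as "generally avoid" accepted)
#' @param ades character vector of ADE terms associated with the pair
#' @param mechanisms list of [mechanism()] annotations
#' @return a list of class `ddi_record`; the pair is stored
#'   lexicographically sorted so serialization and deduplication are
#'   deterministic
#' @export
interaction_record <- function(drug_a, drug_b, severity, ades = character(),
                               mechanisms = list()) {
  a <- normalize_drug_name(drug_a)
  b <- normalize_drug_name(drug_b)
  if (!nzchar(a) || !nzchar(b)) stop("drug names must be non-empty")
  if (a == b) stop("an interaction record requires two distinct drugs: ", a)
  sev <- normalize_severity(severity)
  if (is.na(sev))
    stop("severity '", severity, "' is not one of: ",
         paste(SEVERITY_LEVELS, collapse = ", "))
  pair <- sort(c(a, b))
  for (m in mechanisms) {
    if (!inherits(m, "mechanism")) stop("mechanisms must be mechanism objects")
    if (m$kind == "pk_inhibition" &&
        !all(c(m$inhibitor, m$substrate) %in% pair))
      stop("pk_inhibition inhibitor and substrate must both belong to the pair ",
           paste(pair, collapse = "-"))
    if (m$kind == "conditional" && !(m$drug %in% pair))
      stop("conditional annotation drug must belong to the pair ",
           paste(pair, collapse = "-"))
  }
  structure(
    list(pair = pair, severity = sev,
         ades = sort(unique(as.character(ades))), mechanisms = mechanisms),
    class = "ddi_record"
  )
}

pair_key <- function(a, b) {
  p <- sort(c(a, b))
  paste(p[1], p[2], sep = "|")
}

#' Assemble a knowledge base from interaction records
#'
#' Duplicate unordered pairs collapse to a single record keeping the higher
#' severity tier, the union of ADE terms and the concatenated mechanism
#' annotations; a warning reports each collapse.
#'
#' @param records list of [interaction_record()] objects
#' @param version free-text version tag
#' @return object of class `ddi_kb`
#' @export
knowledge_base <- function(records = list(), version = "1") {
  store <- list()
  for (rec in records) {
    if (!inherits(rec, "ddi_record")) stop("records must be ddi_record objects")
    key <- pair_key(rec$pair[1], rec$pair[2])
    if (!is.null(store[[key]])) {
      old <- store[[key]]
      warning("duplicate pair ", gsub("\\|", "-", key),
              " collapsed to the higher severity", call. = FALSE)
      keep <- if (severity_rank(rec$severity) >= severity_rank(old$severity))
        rec$severity else old$severity
      rec <- interaction_record(
        rec$pair[1], rec$pair[2], keep,
        ades = union(old$ades, rec$ades),
        mechanisms = c(old$mechanisms, rec$mechanisms)
      )
    }
    store[[key]] <- rec
  }
  if (length(store) > 0) store <- store[order(names(store))]
  structure(list(records = store, version = version), class = "ddi_kb")
}

#' @export
length.ddi_kb <- function(x) length(x$records)

#' @export
print.ddi_kb <- function(x, ...) {
  cat("DDI knowledge base (version ", x$version, "): ",
      length(x$records), " pair records\n", sep = "")
  invisible(x)
}

#' Look up the interaction record for a drug pair
#'
#' Symmetric in its arguments: `kb_lookup(kb, a, b)` and
#' `kb_lookup(kb, b, a)` return the same record.
#'
#' @param kb a `ddi_kb`
#' @param a,b distinct drug names (normalized internally)
#' @return the `ddi_record` for the unordered pair, or `NULL` if the pair
#'   has no documented interaction
#' @export
kb_lookup <- function(kb, a, b) {
  stopifnot(inherits(kb, "ddi_kb"))
  a <- normalize_drug_name(a)
  b <- normalize_drug_name(b)
  if (a == b) stop("cannot look up a drug against itself: ", a)
  kb$records[[pair_key(a, b)]]
}

mechanism_to_list <- function(m) {
  Filter(Negate(is.null), unclass(m))
}

mechanism_from_list <- function(l) {
  mechanism(
    kind = l$kind,
    inhibitor = l$inhibitor, substrate = l$substrate, enzyme = l$enzyme,
    ade_term = l$ade_term, drug = l$drug,
    scope = if (!is.null(l$scope)) unlist(l$scope)
  )
}

#' Load a knowledge base from a CSV or JSON file
#'
#' CSV layout: columns `drug_a`, `drug_b`, `severity`, `ades`
#' (semicolon-joined terms) and `mechanisms` (a JSON array fragment, may be
#' empty). The JSON layout is an object with `version` and a `records`
#' array of the same fields with native lists. A row with a severity
#' outside the three admitted tiers is a load error: tiers below the
#' alerting threshold have no place in this KB.
#'
#' @param path file path
#' @param format "csv" or "json"; guessed from the file extension by default
#' @return a `ddi_kb`
#' @export
load_kb <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("KB file does not exist: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    doc <- jsonlite::read_json(path)
    recs <- lapply(seq_along(doc$records), function(i) {
      r <- doc$records[[i]]
      parse_kb_row(r$drug_a, r$drug_b, r$severity,
                   unlist(r$ades) %||% character(),
                   lapply(r$mechanisms %||% list(), mechanism_from_list),
                   where = paste0("record ", i))
    })
    return(knowledge_base(recs, version = doc$version %||% "1"))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("drug_a", "drug_b", "severity")
  if (!all(need %in% names(df)))
    stop("KB CSV is missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  recs <- lapply(seq_len(nrow(df)), function(i) {
    ades <- if ("ades" %in% names(df) && nzchar(df$ades[i]))
      strsplit(df$ades[i], ";", fixed = TRUE)[[1]] else character()
    mechs <- list()
    if ("mechanisms" %in% names(df) && nzchar(df$mechanisms[i])) {
      parsed <- tryCatch(
        jsonlite::fromJSON(df$mechanisms[i], simplifyVector = FALSE),
        error = function(e) stop("KB row ", i, ": malformed mechanisms JSON (",
                                 conditionMessage(e), ")", call. = FALSE))
      mechs <- lapply(parsed, mechanism_from_list)
    }
    parse_kb_row(df$drug_a[i], df$drug_b[i], df$severity[i], ades, mechs,
                 where = paste0("row ", i))
  })
  knowledge_base(recs)
}

parse_kb_row <- function(a, b, severity, ades, mechanisms, where) {
  if (is.null(a) || is.null(b) || !nzchar(trimws(a)) || !nzchar(trimws(b)))
    stop("KB ", where, ": missing drug name", call. = FALSE)
  if (is.na(normalize_severity(severity)))
    stop("KB ", where, ": severity '", severity,
         "' is not an admitted tier (", paste(SEVERITY_LEVELS, collapse = ", "),
         ")", call. = FALSE)
  tryCatch(interaction_record(a, b, severity, ades, mechanisms),
           error = function(e) stop("KB ", where, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write a knowledge base to CSV or JSON
#'
#' Round-trips with [load_kb()]: writing and re-loading yields an
#' identical KB.
#'
#' @param kb a `ddi_kb`
#' @param path output path
#' @param format "csv" or "json"; guessed from the extension by default
#' @return `path`, invisibly
#' @export
write_kb <- function(kb, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(kb, "ddi_kb"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  recs <- kb$records
  if (format == "json") {
    doc <- list(
      version = kb$version,
      records = lapply(unname(recs), function(r) list(
        drug_a = r$pair[1], drug_b = r$pair[2], severity = r$severity,
        ades = as.list(r$ades),
        mechanisms = lapply(r$mechanisms, mechanism_to_list)
      ))
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  df <- data.frame(
    drug_a = vapply(recs, function(r) r$pair[1], ""),
    drug_b = vapply(recs, function(r) r$pair[2], ""),
    severity = vapply(recs, function(r) r$severity, ""),
    ades = vapply(recs, function(r) paste(r$ades, collapse = ";"), ""),
    mechanisms = vapply(recs, function(r) {
      if (length(r$mechanisms) == 0) return("")
      as.character(jsonlite::toJSON(lapply(r$mechanisms, mechanism_to_list),
                                    auto_unbox = TRUE))
    }, ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
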