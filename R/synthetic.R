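#' @title Synthetic cohort and knowledge-base generator
#' @description
#' Emulates the statistical structure of an elderly outpatient cohort so
#' the whole pipeline can be exercised without protected health data:
#' interaction-status mix (91.3 / 7.4 / 1.3 %), per-status medication
#' counts (3.1 +/- 2.3, 6.6 +/- 2.9, 8.6 +/- 3.4), MDI size mix
#' (75.6 / 15.6 / 8.9 %) and severity-tier mix (2.1 / 27.4 / 70.5 %).
#' The generated KB is built from hub families — a hub drug interacting
#' with several partner drugs that interact with nothing else — so planted
#' MDIs are star components whose size is exactly controlled, and filler
#' drugs interact with nothing, so planting cannot create accidental
#' components and planted structure is exactly recoverable.
#' @name synthetic_data
NULL

#' Configuration for the synthetic generator
#'
#' Defaults encode the cohort conditions the package targets; probability
#' vectors must sum to 1 (the MDI size mix, whose printed shares total
#' 100.1 %, is renormalized). The seed fully determines every output.
#'
#' @param seed integer RNG seed
#' @param n_patients cohort size
#' @param status_probs P(none, two_drug, mdi) per patient
#' @param med_count_params per-status `c(mean, sd)` of medication-list
#'   length
#' @param mdi_size_probs P(three, four, five_plus) per planted MDI
#' @param five_plus_size_probs split of the five_plus class over sizes
#'   5, 6, 7 (the tail shape is unreported; a decreasing split is assumed)
#' @param severity_probs P(contraindicated, generally_avoid,
#'   monitor_closely) per KB record
#' @param second_mdi_prob probability an MDI patient carries a second,
#'   disjoint MDI (default 5/85)
#' @param n_hubs,partners_per_hub hub-family structure of the generated KB
#' @param n_filler_drugs pool of non-interacting drugs
#' @param p_shared_ade probability a hub family shares one ADE term across
#'   all its pair records (pharmacodynamic substrate)
#' @param p_pk_inhibition probability a pair record carries a
#'   partner-inhibits-hub annotation
#' @param p_conditional probability a hub family carries a conditional
#'   annotation over two of its partners
#' @param p_brand probability a filler entry is written under a brand
#'   alias (exercises name normalization)
#' @param date_discord_prob probability a list gets mixed entry dates
#'   (exercises the same-day filter)
#' @param inpatient_marker_prob probability a list gets an inpatient
#'   marker drug appended
#' @param underage_prob probability a patient is planted under `min_age`
#' @param min_age,age_mean,age_sd age model (truncated normal, years)
#' @param base_date center of the entry-date window
#' @return list of class `generator_config`
#' @export
generator_config <- function(
    seed = 1L,
    n_patients = 6545L,
    status_probs = c(none = 0.913, two_drug = 0.074, mdi = 0.013),
    med_count_params = list(none = c(3.1, 2.3), two_drug = c(6.6, 2.9),
                            mdi = c(8.6, 3.4)),
    mdi_size_probs = c(three = 0.756, four = 0.156, five_plus = 0.089),
    five_plus_size_probs = c("5" = 0.6, "6" = 0.3, "7" = 0.1),
    severity_probs = c(contraindicated = 0.021, generally_avoid = 0.274,
                       monitor_closely = 0.705),
    second_mdi_prob = 5 / 85,
    n_hubs = 10L, partners_per_hub = 6L,
    n_filler_drugs = 400L,
    p_shared_ade = 0.9, p_pk_inhibition = 0.35, p_conditional = 0.1,
    p_brand = 0.1,
    date_discord_prob = 0, inpatient_marker_prob = 0, underage_prob = 0,
    min_age = 60L, age_mean = 72.5, age_sd = 8.2,
    base_date = as.Date("2019-06-15")) {
  mdi_size_probs <- mdi_size_probs / sum(mdi_size_probs)
  five_plus_size_probs <- five_plus_size_probs / sum(five_plus_size_probs)
  cfg <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    status_probs = status_probs, med_count_params = med_count_params,
    mdi_size_probs = mdi_size_probs,
    five_plus_size_probs = five_plus_size_probs,
    severity_probs = severity_probs, second_mdi_prob = second_mdi_prob,
    n_hubs = as.integer(n_hubs),
    partners_per_hub = as.integer(partners_per_hub),
    n_filler_drugs = as.integer(n_filler_drugs),
    p_shared_ade = p_shared_ade, p_pk_inhibition = p_pk_inhibition,
    p_conditional = p_conditional, p_brand = p_brand,
    date_discord_prob = date_discord_prob,
    inpatient_marker_prob = inpatient_marker_prob,
    underage_prob = underage_prob,
    min_age = as.integer(min_age), age_mean = age_mean, age_sd = age_sd,
    base_date = as.Date(base_date)
  )
  for (p in list(cfg$status_probs, cfg$severity_probs, cfg$mdi_size_probs,
                 cfg$five_plus_size_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("probability vectors must be non-negative and sum to 1")
  }
  max_size <- cfg$partners_per_hub + 1L
  if (max_size < 7 && cfg$mdi_size_probs[["five_plus"]] > 0 &&
      any(as.integer(names(cfg$five_plus_size_probs)) > max_size &
          cfg$five_plus_size_probs > 0))
    stop("infeasible config: requested MDI sizes exceed hub family size (",
         max_size, " drugs)")
  structure(cfg, class = "generator_config")
}

# first two moments of max(min_count, floor(X + 0.5)) for X ~ N(mu, sd)
# conditioned on X >= min_count - 0.5 (the rejection sampler's output)
trunc_count_moments <- function(mu, sd, min_count) {
  kmax <- max(min_count + 10, ceiling(mu + 12 * sd))
  k <- seq.int(min_count, kmax)
  p <- stats::pnorm(k + 0.5, mu, sd) - stats::pnorm(k - 0.5, mu, sd)
  tot <- stats::pnorm(kmax + 0.5, mu, sd) -
    stats::pnorm(min_count - 0.5, mu, sd)
  m1 <- sum(k * p) / tot
  m2 <- sum(k^2 * p) / tot
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# latent normal (mu, sd) whose lower-truncated, integer-rounded law has
# exactly the target mean and sd; naive truncation of N(target_mean,
# target_sd) at the minimum inflates the mean well past sampling error at
# cohort scale and compresses the sd, so both latent parameters are
# solved for numerically (two-moment matching)
latent_params_for <- function(target_mean, target_sd, min_count) {
  mu_for <- function(s) {
    f <- function(mu) trunc_count_moments(mu, s, min_count)["mean"] -
      target_mean
    stats::uniroot(f, c(target_mean - 8 * s, target_mean + 2 * s),
                   tol = 1e-9)$root
  }
  g <- function(s) trunc_count_moments(mu_for(s), s, min_count)["sd"] -
    target_sd
  s <- stats::uniroot(g, c(target_sd * 0.8, target_sd * 6), tol = 1e-8)$root
  c(mu = mu_for(s), sd = s)
}

# one draw of max(min_count, round(N(mu, sd))) by rejection
draw_count <- function(mu, sd, min_count) {
  repeat {
    x <- stats::rnorm(1, mu, sd)
    if (x >= min_count - 0.5) return(as.integer(floor(x + 0.5)))
  }
}

# deterministic drug vocabulary: hub families and fillers depend only on
# the config, so the cohort generator can re-derive them without the KB
synth_families <- function(cfg) {
  lapply(seq_len(cfg$n_hubs), function(h) {
    hub <- sprintf("hubdrug%02d", h)
    partners <- sprintf("%s_ptn%02d", hub, seq_len(cfg$partners_per_hub))
    list(hub = hub, partners = partners,
         ade = sprintf("ade_family%02d", h))
  })
}

synth_fillers <- function(cfg) sprintf("filler%03d", seq_len(cfg$n_filler_drugs))

#' Generate a synthetic DDI knowledge base
#'
#' Hub families (a hub drug with `partners_per_hub` partner drugs, one
#' record per hub-partner pair) carry shared-ADE, metabolic-inhibition
#' and conditional annotations in configurable proportions; severity
#' tiers are drawn independently per record from `severity_probs`.
#' Partners never interact with each other or across families, and filler
#' drugs carry no records at all.
#'
#' @param cfg a [generator_config()]
#' @return a `ddi_kb`
#' @export
generate_kb <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  enzymes <- c("CYP1A2", "CYP2C9", "CYP2D6", "CYP3A4")
  recs <- list()
  for (fam in synth_families(cfg)) {
    fam_shared <- stats::runif(1) < cfg$p_shared_ade
    fam_cond <- stats::runif(1) < cfg$p_conditional
    for (j in seq_along(fam$partners)) {
      p <- fam$partners[j]
      sev <- sample(names(cfg$severity_probs), 1, prob = cfg$severity_probs)
      ades <- if (fam_shared) fam$ade else
        sprintf("ade_%s_%s", fam$hub, sub("^.*_", "", p))
      mechs <- list()
      if (fam_shared)
        mechs <- c(mechs, list(mechanism("shared_ade", ade_term = fam$ade)))
      if (stats::runif(1) < cfg$p_pk_inhibition)
        mechs <- c(mechs, list(mechanism(
          "pk_inhibition", inhibitor = p, substrate = fam$hub,
          enzyme = sample(enzymes, 1))))
      if (fam_cond && j == 1)
        mechs <- c(mechs, list(mechanism(
          "conditional", drug = fam$hub,
          scope = fam$partners[seq_len(min(2, length(fam$partners)))])))
      recs[[length(recs) + 1]] <-
        interaction_record(fam$hub, p, sev, ades = ades, mechanisms = mechs)
    }
  }
  knowledge_base(recs, version = sprintf("synthetic-seed%d", cfg$seed))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Each patient is assigned a status (none / two_drug / mdi) and a
#' medication-list length drawn from a lower-truncated, integer-rounded
#' normal whose latent mean and sd are solved so the realized length
#' distribution has exactly the per-status target mean and sd.
#' MDI patients receive a hub and `size - 1` partners from one family (a
#' star component of exactly the planted size), optionally a second
#' disjoint MDI from another family; two-drug patients receive one
#' hub-partner pair; the rest of every list is non-interacting filler.
#' All entries share one date unless date discord is planted.
#'
#' @param cfg a [generator_config()]
#' @param kb optional `ddi_kb` from [generate_kb()] (unused for structure,
#'   which is derived from `cfg`, but accepted for interface symmetry)
#' @return list with `cohort` (an `mdi_cohort`), `brand_map` (named
#'   vector) and `ground_truth` (data frame: `patient_id`, `status`,
#'   `age`, `n_drugs`, `n_mdis`, `mdi_drugs` — planted MDI drug sets,
#'   MDIs separated by "|", drugs by ";")
#' @export
generate_cohort <- function(cfg, kb = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 1L)
  fams <- synth_families(cfg)
  fillers <- synth_fillers(cfg)
  brand_map <- stats::setNames(fillers, paste0("br_", fillers))
  latent <- lapply(
    stats::setNames(names(cfg$med_count_params), names(cfg$med_count_params)),
    function(s) {
      mp <- cfg$med_count_params[[s]]
      minc <- c(none = 1L, two_drug = 2L, mdi = 3L)[[s]]
      lp <- latent_params_for(mp[1], mp[2], minc)
      c(mu = lp[["mu"]], sd = lp[["sd"]], min = minc)
    })

  rows <- vector("list", cfg$n_patients)
  gt <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    id <- sprintf("P%05d", i)
    status <- sample(names(cfg$status_probs), 1, prob = cfg$status_probs)
    age <- if (stats::runif(1) < cfg$underage_prob)
      sample(40:(cfg$min_age - 1), 1)
    else {
      repeat {
        a <- round(stats::rnorm(1, cfg$age_mean, cfg$age_sd))
        if (a >= cfg$min_age) break
      }
      a
    }
    lat <- latent[[status]]
    len <- draw_count(lat[["mu"]], lat[["sd"]], lat[["min"]])
    planted <- character()
    mdi_sets <- list()
    if (status == "mdi") {
      n_mdi_here <- 1L + (stats::runif(1) < cfg$second_mdi_prob)
      fam_idx <- sample(length(fams), n_mdi_here)
      for (f in fam_idx) {
        cls <- sample(names(cfg$mdi_size_probs), 1, prob = cfg$mdi_size_probs)
        size <- switch(cls, three = 3L, four = 4L,
                       five_plus = as.integer(sample(
                         names(cfg$five_plus_size_probs), 1,
                         prob = cfg$five_plus_size_probs)))
        fam <- fams[[f]]
        if (size - 1 > length(fam$partners))
          stop("infeasible config: MDI size ", size,
               " exceeds hub family size")
        drugs <- c(fam$hub, sample(fam$partners, size - 1))
        planted <- c(planted, drugs)
        mdi_sets[[length(mdi_sets) + 1]] <- sort(drugs)
      }
    } else if (status == "two_drug") {
      fam <- fams[[sample(length(fams), 1)]]
      planted <- c(fam$hub, sample(fam$partners, 1))
    }
    len <- max(len, length(planted) + 0L)
    n_fill <- len - length(planted)
    drugs <- c(planted, if (n_fill > 0) sample(fillers, n_fill))
    if (stats::runif(1) < cfg$inpatient_marker_prob)
      drugs <- c(drugs, sample(INPATIENT_MARKERS, 1))
    raw <- drugs
    is_fill <- raw %in% fillers
    use_brand <- is_fill & stats::runif(length(raw)) < cfg$p_brand
    raw[use_brand] <- paste0("br_", raw[use_brand])
    date <- cfg$base_date + sample(-180:180, 1)
    dates <- rep(date, length(raw))
    if (stats::runif(1) < cfg$date_discord_prob && length(raw) > 1)
      dates[1] <- date - sample(30:3650, 1)
    rows[[i]] <- data.frame(
      patient_id = id, age = age, drug = raw,
      entry_date = format(dates, "%Y-%m-%d"),
      route_class = "systemic", stringsAsFactors = FALSE
    )
    gt[[i]] <- data.frame(
      patient_id = id, status = status, age = age,
      n_drugs = length(drugs), n_mdis = length(mdi_sets),
      mdi_drugs = paste(vapply(mdi_sets, paste, "", collapse = ";"),
                        collapse = "|"),
      stringsAsFactors = FALSE
    )
  }
  list(cohort = as_cohort(do.call(rbind, rows)),
       brand_map = brand_map,
       ground_truth = do.call(rbind, gt))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `kb.csv`, `kb.json`, `cohort.csv`, `brand_map.csv` and
#' `ground_truth.json` under `dir`. Byte-identical across runs with the
#' same configuration.
#'
#' @param cfg a [generator_config()]
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kb <- generate_kb(cfg)
  gen <- generate_cohort(cfg, kb)
  paths <- c(
    kb_csv = file.path(dir, "kb.csv"),
    kb_json = file.path(dir, "kb.json"),
    cohort = file.path(dir, "cohort.csv"),
    brand_map = file.path(dir, "brand_map.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_kb(kb, paths[["kb_csv"]], format = "csv")
  write_kb(kb, paths[["kb_json"]], format = "json")
  cohort_out <- data.frame(
    patient_id = gen$cohort$patient_id, age = gen$cohort$age,
    drug = gen$cohort$raw_name,
    entry_date = format(gen$cohort$entry_date, "%Y-%m-%d"),
    route_class = gen$cohort$route_class, stringsAsFactors = FALSE
  )
  utils::write.csv(cohort_out, paths[["cohort"]], row.names = FALSE)
  utils::write.csv(
    data.frame(brand = names(gen$brand_map), generic = unname(gen$brand_map),
               stringsAsFactors = FALSE),
    paths[["brand_map"]], row.names = FALSE
  )
  jsonlite::write_json(gen$ground_truth, paths[["ground_truth"]],
                       dataframe = "rows", pretty = TRUE)
  invisible(paths)
}
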