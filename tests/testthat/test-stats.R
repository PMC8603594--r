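test_that("percent formatting rounds half-up to one decimal", {
  expect_equal(pct(487, 6545), 7.4)
  expect_equal(pct(85, 6545), 1.3)
  expect_equal(pct(c(68, 14, 8), 90), c(75.6, 15.6, 8.9))
  expect_equal(pct(107, 305), 35.1)
  expect_equal(round_half_up(0.15, 1), 0.2)  # ties go up, not to even
})

test_that("size distribution counts and percents follow the MDI sizes", {
  fam <- list(c("a", "b", "c"), c("d", "e", "f"), c("g", "h", "i"),
              c("j", "k", "l", "m"), c("n", "o", "p", "q", "r"))
  recs <- unlist(lapply(fam, function(dr)
    lapply(seq_len(length(dr) - 1), function(i)
      interaction_record(dr[1], dr[i + 1], "monitor_closely"))),
    recursive = FALSE)
  kb <- knowledge_base(recs)
  co <- cohort_from_lists(stats::setNames(fam, paste0("p", 1:5)))
  co <- normalize_names(co)
  fd <- detect_interactions(co, kb)
  s <- summarize_cohort(co, fd)
  expect_equal(s$n_mdis, 5L)
  expect_equal(s$size_distribution$count, c(3L, 1L, 1L))
  expect_equal(s$size_distribution$percent, c(60.0, 20.0, 20.0))
  expect_equal(sum(s$size_distribution$percent), 100, tolerance = 0.1)
})

test_that("status counts are disjoint and exhaustive", {
  cfg <- generator_config(seed = 31, n_patients = 500)
  gen <- generate_cohort(cfg)
  co <- normalize_names(gen$cohort, gen$brand_map)
  kb <- generate_kb(cfg)
  fd <- detect_interactions(co, kb)
  s <- summarize_cohort(co, fd)
  expect_equal(s$n_none + s$n_two_drug_patients + s$n_mdi_patients,
               s$n_patients)
  expect_gte(s$n_mdis, s$n_mdi_patients)
})

test_that("group medication-count means track the planted parameters", {
  cfg <- generator_config(seed = 1, n_patients = 3000)
  gen <- generate_cohort(cfg)
  co <- normalize_names(gen$cohort, gen$brand_map)
  fd <- detect_interactions(co, generate_kb(cfg))
  s <- summarize_cohort(co, fd)
  mcs <- s$med_count_stats
  for (grp in list(c("none", 3.1, 2.3), c("two_drug_only", 6.6, 2.9),
                   c("mdi", 8.6, 3.4))) {
    row <- mcs[mcs$status == grp[1], ]
    se <- as.numeric(grp[3]) / sqrt(row$n)
    expect_lt(abs(row$mean - as.numeric(grp[2])), 2 * se)
  }
})

test_that("degenerate cohorts summarize to zeros, not errors", {
  kb <- tiny_kb()
  co <- normalize_names(cohort_from_lists(list(solo = "metformin")))
  s <- summarize_cohort(co, detect_interactions(co, kb))
  expect_equal(s$n_two_drug_patients, 0L)
  expect_equal(s$n_mdis, 0L)
  expect_equal(s$pct_mdi, 0)

  empty <- co[0, , drop = FALSE]
  class(empty) <- c("mdi_cohort", "data.frame")
  s0 <- summarize_cohort(empty, detect_interactions(empty, kb))
  expect_equal(s0$n_patients, 0L)
  expect_equal(s0$n_mdis, 0L)
})

test_that("per-drug prevalence counts MDI membership over lists with the drug", {
  kb <- knowledge_base(list(
    interaction_record("hub", "p1", "monitor_closely"),
    interaction_record("hub", "p2", "monitor_closely")
  ))
  lists <- c(
    lapply(1:3, function(i) c("hub", "p1", "p2", "f1")),   # hub in MDI
    lapply(4:10, function(i) c("hub", "f1", "f2"))         # hub inert
  )
  co <- normalize_names(cohort_from_lists(stats::setNames(lists,
                                                          paste0("p", 1:10))))
  fd <- detect_interactions(co, kb)
  pp <- per_drug_prevalence(co, fd, "hub")
  expect_equal(pp$n_lists_with_drug, 10L)
  expect_equal(pp$n_lists_with_drug_in_mdi, 3L)
  expect_equal(pp$prevalence, 30.0)
  # a drug never in an MDI has prevalence zero; an absent drug errors
  expect_equal(per_drug_prevalence(co, fd, "f1")$prevalence, 0.0)
  expect_error(per_drug_prevalence(co, fd, "nosuchdrug"), "no list")
  expect_gte(pp$prevalence, 0)
  expect_lte(pp$prevalence, 100)
})

test_that("planted per-drug prevalence is recovered within binomial error", {
  kb <- knowledge_base(list(
    interaction_record("hub", "p1", "monitor_closely"),
    interaction_record("hub", "p2", "monitor_closely")
  ))
  set.seed(271)
  n <- 500
  in_mdi <- stats::runif(n) < 0.27
  lists <- lapply(seq_len(n), function(i)
    if (in_mdi[i]) c("hub", "p1", "p2") else c("hub", "f1"))
  co <- normalize_names(cohort_from_lists(stats::setNames(lists,
                                                          sprintf("q%03d", 1:n))))
  fd <- detect_interactions(co, kb)
  pp <- per_drug_prevalence(co, fd, "hub")
  ci <- 1.96 * sqrt(0.27 * 0.73 / n) * 100
  expect_lt(abs(pp$prevalence - 27), ci + 0.05)
})

test_that("ADE tally counts each term once per MDI", {
  kb <- knowledge_base(list(
    interaction_record("a", "b", "monitor_closely",
                       ades = c("seizures", "serotonin_syndrome")),
    interaction_record("b", "c", "monitor_closely",
                       ades = "serotonin_syndrome"),
    interaction_record("x", "y", "monitor_closely",
                       ades = "serotonin_syndrome"),
    interaction_record("y", "z", "monitor_closely",
                       ades = "serotonin_syndrome")
  ))
  co <- normalize_names(cohort_from_lists(list(
    p1 = c("a", "b", "c"), p2 = c("x", "y", "z"))))
  fd <- detect_interactions(co, kb)
  tal <- ade_tally(fd)
  expect_equal(tal[["serotonin_syndrome"]], 2L)  # once per MDI, two MDIs
  expect_equal(tal[["seizures"]], 1L)            # despite two terms on one pair
  expect_equal(length(ade_tally(detect_interactions(co[0, ], kb))), 0L)
})

test_that("class tally covers unmapped drugs as 'other'", {
  kb <- knowledge_base(list(
    interaction_record("a", "b", "monitor_closely"),
    interaction_record("b", "c", "monitor_closely")
  ))
  co <- normalize_names(cohort_from_lists(list(p1 = c("a", "b", "c"))))
  fd <- detect_interactions(co, kb)
  ct <- class_tally(fd, c(a = "psychotropic", b = "opiate", c = "hemostasis"))
  expect_equal(nrow(ct), 3L)
  expect_equal(ct$percent, rep(33.3, 3))
  ct2 <- class_tally(fd, c(a = "psychotropic"))
  expect_equal(ct2$count[ct2$class == "other"], 2L)
})
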