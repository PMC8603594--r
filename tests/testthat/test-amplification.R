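# build a one-component MDI directly from explicit records
mdi_from_records <- function(recs, id = "pt") {
  kb <- knowledge_base(recs)
  drugs <- unique(unlist(lapply(recs, function(r) r$pair)))
  mdis <- find_mdis(build_graph(drugs, kb), id)
  stopifnot(length(mdis) == 1)
  list(mdi = mdis[[1]], kb = kb)
}

test_that("a shared ADE across three drugs is pharmacodynamic amplification", {
  x <- mdi_from_records(list(
    interaction_record("drugx", "drugy", "monitor_closely",
                       ades = "serotonin_syndrome"),
    interaction_record("drugy", "drugz", "monitor_closely",
                       ades = "serotonin_syndrome")
  ))
  ev <- classify_pharmacodynamic(x$mdi, x$kb)
  expect_match(ev, "serotonin_syndrome")
  expect_match(ev, "drugx, drugy, drugz")

  # bleeding attributed to only two of the three drugs: no evidence
  y <- mdi_from_records(list(
    interaction_record("warfarin", "aspirin", "generally_avoid",
                       ades = "bleeding"),
    interaction_record("warfarin", "amiodarone", "monitor_closely",
                       ades = "arrhythmia")
  ))
  expect_null(classify_pharmacodynamic(y$mdi, y$kb))
  # ...unless a per-drug ADE table adds the third attribution
  expect_match(
    classify_pharmacodynamic(y$mdi, y$kb,
                             drug_ades = list(amiodarone = "bleeding")),
    "bleeding")
})

test_that("pharmacodynamic classification equals a term-counting oracle on all
          three-drug assignments", {
  terms <- c("t1", "t2", "t3")
  subsets <- lapply(0:7, function(m) terms[bitwAnd(m, c(1, 2, 4)) > 0])
  for (s1 in subsets) for (s2 in subsets) {
    x <- mdi_from_records(list(
      interaction_record("a", "b", "monitor_closely", ades = s1),
      interaction_record("b", "c", "monitor_closely", ades = s2)
    ))
    got <- classify_pharmacodynamic(x$mdi, x$kb)
    # oracle: direct predicate over per-drug term attribution
    attrib <- list(a = s1, b = union(s1, s2), c = s2)
    hit <- any(vapply(terms, function(tm)
      sum(vapply(attrib, function(a) tm %in% a, NA)) >= 3, NA))
    expect_equal(!is.null(got), hit)
  }
})

test_that("two inhibitors of one substrate are pharmacokinetic amplification", {
  kb <- tiny_kb()
  mdis <- find_mdis(build_graph(
    c("bupropion", "fluoxetine", "mirtazapine"), kb), "ptF")
  ev <- classify_pharmacokinetic(mdis[[1]], kb)
  expect_true(any(grepl("mirtazapine inhibited by bupropion and fluoxetine",
                        ev)))
  # the chain bupropion -> fluoxetine -> mirtazapine also surfaces
  expect_true(any(grepl("bupropion inhibits fluoxetine", ev)))
})

test_that("a single arc amplifies only an overlapping pair", {
  kb <- tiny_kb()
  # amiodarone -> warfarin arc overlapping the warfarin-aspirin pair
  mdis <- find_mdis(build_graph(c("warfarin", "amiodarone", "aspirin"), kb),
                    "ptD")
  ev <- classify_pharmacokinetic(mdis[[1]], kb)
  expect_true(any(grepl(
    "amiodarone inhibits warfarin, amplifying the warfarin-aspirin", ev)))

  # same arc with no overlapping interaction of the substrate: no evidence
  x <- mdi_from_records(list(
    interaction_record("a", "b", "monitor_closely", ades = "ade1",
                       mechanisms = list(mechanism(
                         "pk_inhibition", inhibitor = "a", substrate = "b"))),
    interaction_record("a", "c", "monitor_closely", ades = "ade2")
  ))
  expect_null(classify_pharmacokinetic(x$mdi, x$kb))

  # no pk annotations at all: no evidence
  y <- mdi_from_records(list(
    interaction_record("a", "b", "monitor_closely", ades = "ade1"),
    interaction_record("b", "c", "monitor_closely", ades = "ade2")
  ))
  expect_null(classify_pharmacokinetic(y$mdi, y$kb))
})

test_that("conditional evidence needs two covered drugs inside the MDI", {
  rec_cond <- function(scope) list(
    interaction_record("c", "a", "monitor_closely", ades = "ade1",
                       mechanisms = list(mechanism("conditional", drug = "c",
                                                   scope = scope))),
    interaction_record("c", "b", "monitor_closely", ades = "ade2")
  )
  x <- mdi_from_records(rec_cond(c("a", "b")))
  expect_match(classify_conditional(x$mdi, x$kb), "c raises susceptibility")
  # only one other MDI drug covered
  y <- mdi_from_records(rec_cond("a"))
  expect_null(classify_conditional(y$mdi, y$kb))
  # scope pointing outside the MDI does not count
  z <- mdi_from_records(rec_cond(c("a", "outsider")))
  expect_null(classify_conditional(z$mdi, z$kb))
})

test_that("non-amplifying MDIs report amplifying = FALSE, not an error", {
  x <- mdi_from_records(list(
    interaction_record("a", "b", "monitor_closely", ades = "ade1"),
    interaction_record("b", "c", "monitor_closely", ades = "ade2")
  ))
  res <- classify_amplification(x$mdi, x$kb)
  expect_false(res$amplifying)
  expect_equal(res$mechanisms, character(0))
  expect_equal(res$evidence, character(0))
})

test_that("adding annotations never flips an MDI to non-amplifying", {
  set.seed(23)
  for (rep in 1:20) {
    ades1 <- sample(c("t1", "t2"), sample(1:2, 1))
    ades2 <- sample(c("t1", "t3"), sample(1:2, 1))
    base <- list(
      interaction_record("a", "b", "monitor_closely", ades = ades1),
      interaction_record("b", "c", "monitor_closely", ades = ades2)
    )
    x <- mdi_from_records(base)
    before <- classify_amplification(x$mdi, x$kb)$amplifying
    richer <- list(
      interaction_record("a", "b", "monitor_closely", ades = ades1,
                         mechanisms = list(mechanism(
                           "pk_inhibition", inhibitor = "a",
                           substrate = "b"))),
      interaction_record("b", "c", "monitor_closely",
                         ades = union(ades2, "t1"))
    )
    y <- mdi_from_records(richer)
    after <- classify_amplification(y$mdi, y$kb)$amplifying
    expect_false(before && !after)
  }
})

test_that("classification is invariant to drug order", {
  kb <- tiny_kb()
  drugs <- c("bupropion", "fluoxetine", "mirtazapine")
  ref <- classify_amplification(
    find_mdis(build_graph(drugs, kb))[[1]], kb)
  for (perm in list(rev(drugs), drugs[c(2, 1, 3)], drugs[c(3, 1, 2)])) {
    got <- classify_amplification(
      find_mdis(build_graph(perm, kb))[[1]], kb)
    expect_identical(got, ref)
  }
})

test_that("composite severity sorts tiers descending with the max on top", {
  a <- compose_severity(c("contraindicated", "contraindicated"))
  expect_identical(a$tiers, c("contraindicated", "contraindicated"))
  expect_equal(a$max_tier, "contraindicated")

  f <- compose_severity(c("monitor_closely", "monitor_closely",
                          "generally_avoid", "monitor_closely"))
  expect_identical(f$tiers, c("generally_avoid", "monitor_closely",
                              "monitor_closely", "monitor_closely"))
  expect_equal(f$max_tier, "generally_avoid")

  expect_equal(compose_severity("monitor_closely")$max_tier,
               "monitor_closely")
  expect_error(compose_severity(character()), "severity")

  # from an MDI object: one tier per constituent pair
  kb <- tiny_kb()
  m <- find_mdis(build_graph(c("warfarin", "amiodarone", "aspirin"), kb))[[1]]
  comp <- compose_severity(m)
  expect_equal(length(comp$tiers), nrow(m$pairs))
  expect_identical(comp$tiers, c("generally_avoid", "monitor_closely"))
})
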