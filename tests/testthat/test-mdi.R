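test_that("the anticoagulant worked example forms one three-drug MDI", {
  kb <- tiny_kb()
  g <- build_graph(c("warfarin", "amiodarone", "aspirin"), kb)
  expect_equal(length(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)   # amiodarone-warfarin and aspirin-warfarin
  mdis <- find_mdis(g, "pt")
  expect_equal(length(mdis), 1L)
  expect_setequal(mdis[[1]]$drugs, c("warfarin", "amiodarone", "aspirin"))
  expect_equal(mdis[[1]]$size_class, "three")
})

test_that("degenerate lists build degenerate graphs", {
  kb <- tiny_kb()
  g1 <- build_graph("warfarin", kb)
  expect_equal(length(g1$nodes), 1L)
  expect_equal(nrow(g1$edges), 0L)
  expect_equal(find_mdis(g1), list())
  # duplicated names (brand + generic already normalized) collapse to one node
  g2 <- build_graph(c("warfarin", "Warfarin", " warfarin "), kb)
  expect_equal(length(g2$nodes), 1L)
})

test_that("edge sets equal brute-force all-pairs KB lookup", {
  kb <- demo_kb()
  all_drugs <- unique(unlist(lapply(kb$records, function(r) r$pair)))
  set.seed(42)
  for (rep in 1:10) {
    drugs <- sample(c(all_drugs, paste0("inert", 1:5)), 6)
    g <- build_graph(drugs, kb)
    expected <- 0L
    for (i in 1:5) for (j in (i + 1):6) {
      if (!is.null(kb_lookup(kb, drugs[i], drugs[j])))
        expected <- expected + 1L
    }
    expect_equal(nrow(g$edges), expected)
  }
})

test_that("components match a union-find oracle on every graph up to 5 nodes", {
  for (n in 1:5) {
    for (case in all_edge_subsets(n)) {
      kb <- kb_from_edges(case$edges)
      g <- build_graph(case$nodes, kb)
      got <- mdiscreen:::graph_components(g)
      expect_identical(got, uf_components(case$nodes, case$edges))
      # independent cross-check against igraph
      ig <- igraph::graph_from_data_frame(
        case$edges[, c("drug_a", "drug_b")], directed = FALSE,
        vertices = case$nodes)
      memb <- igraph::components(ig)$membership
      ref <- lapply(split(names(memb), memb), sort)
      names(ref) <- NULL
      ref <- ref[order(vapply(ref, `[`, "", 1))]
      expect_identical(got, ref)
    }
  }
})

test_that("components match the oracle on random graphs of 6 to 8 nodes", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(6:8, 1)
    nodes <- paste0("d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.25
    edges <- data.frame(drug_a = pairs[keep, 1], drug_b = pairs[keep, 2],
                        stringsAsFactors = FALSE)
    g <- build_graph(nodes, kb_from_edges(edges))
    expect_identical(mdiscreen:::graph_components(g),
                     uf_components(nodes, edges))
  }
})

test_that("every detected MDI contains a drug of degree at least two", {
  set.seed(19)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    nodes <- paste0("d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.3
    edges <- data.frame(drug_a = pairs[keep, 1], drug_b = pairs[keep, 2],
                        stringsAsFactors = FALSE)
    g <- build_graph(nodes, kb_from_edges(edges))
    for (m in find_mdis(g)) {
      deg <- table(c(m$pairs$drug_a, m$pairs$drug_b))
      expect_gte(max(deg), 2)
      expect_gte(length(m$drugs), 3)
    }
  }
})

test_that("disjoint pairs are two-drug DDIs and multiple MDIs are all returned", {
  edges <- data.frame(drug_a = c("a", "c"), drug_b = c("b", "d"))
  g <- build_graph(letters[1:4], kb_from_edges(edges))
  expect_equal(find_mdis(g), list())
  pf <- pair_findings(g, "p")
  expect_equal(nrow(pf), 2L)
  expect_false(any(pf$in_mdi))

  edges2 <- data.frame(drug_a = c("a", "b", "d", "e"),
                       drug_b = c("b", "c", "e", "f"))
  g2 <- build_graph(letters[1:6], kb_from_edges(edges2))
  mdis <- find_mdis(g2, "p")
  expect_equal(length(mdis), 2L)
  expect_identical(mdis[[1]]$drugs, c("a", "b", "c"))
  expect_identical(mdis[[2]]$drugs, c("d", "e", "f"))
  expect_true(all(pair_findings(g2, "p")$in_mdi))
})

test_that("shuffling the medication list never changes the MDI set", {
  kb <- demo_kb()
  drugs <- c("warfarin", "amiodarone", "aspirin", "bupropion", "fluoxetine",
             "mirtazapine", "metformin")
  ref <- find_mdis(build_graph(drugs, kb))
  set.seed(5)
  for (rep in 1:10) {
    got <- find_mdis(build_graph(sample(drugs), kb))
    expect_identical(lapply(got, `[[`, "drugs"), lapply(ref, `[[`, "drugs"))
  }
})

test_that("patient status is exclusive with MDI taking precedence", {
  kb <- tiny_kb()
  g0 <- build_graph(c("metformin", "lisinopril"), kb)
  expect_equal(classify_patient(find_mdis(g0), pair_findings(g0)), "none")
  g1 <- build_graph(c("aspirin", "warfarin"), kb)
  pf1 <- pair_findings(g1)
  expect_equal(classify_patient(find_mdis(g1), pf1[!pf1$in_mdi, ]),
               "two_drug_only")
  # a 3-drug component plus an isolated pair is still status mdi
  g2 <- build_graph(c("bupropion", "fluoxetine", "mirtazapine",
                      "aspirin", "warfarin"), kb)
  pf2 <- pair_findings(g2)
  expect_equal(classify_patient(find_mdis(g2), pf2[!pf2$in_mdi, ]), "mdi")
})
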