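# shared fixtures and independent oracles

extdata <- function(name) {
  system.file("extdata", name, package = "mdiscreen", mustWork = TRUE)
}

demo_kb <- function() load_kb(extdata("kb_demo.csv"))

# small KB built in code: one anticoagulation cluster, one psychotropic
# triangle (two inhibitors of one substrate plus an inhibitor chain)
tiny_kb <- function() {
  knowledge_base(list(
    interaction_record(
      "amiodarone", "warfarin", "monitor_closely", ades = "bleeding",
      mechanisms = list(mechanism("pk_inhibition", inhibitor = "amiodarone",
                                  substrate = "warfarin"))),
    interaction_record("aspirin", "warfarin", "generally_avoid",
                       ades = "bleeding"),
    interaction_record(
      "bupropion", "mirtazapine", "monitor_closely",
      ades = "serotonin_syndrome",
      mechanisms = list(mechanism("pk_inhibition", inhibitor = "bupropion",
                                  substrate = "mirtazapine"))),
    interaction_record(
      "fluoxetine", "mirtazapine", "monitor_closely",
      ades = "serotonin_syndrome",
      mechanisms = list(mechanism("pk_inhibition", inhibitor = "fluoxetine",
                                  substrate = "mirtazapine"))),
    interaction_record(
      "bupropion", "fluoxetine", "generally_avoid", ades = "seizures",
      mechanisms = list(mechanism("pk_inhibition", inhibitor = "bupropion",
                                  substrate = "fluoxetine")))
  ))
}

# union-find connected-components oracle, independent of the package's BFS
uf_components <- function(nodes, edges) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(which(nodes == edges$drug_a[k]))
      rb <- find(which(nodes == edges$drug_b[k]))
      if (ra != rb) parent[[rb]] <- ra
    }
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  comps <- lapply(split(nodes, roots), sort)
  names(comps) <- NULL
  comps[order(vapply(comps, `[`, "", 1))]
}

# a KB whose records are exactly the given edge list (monitor_closely)
kb_from_edges <- function(edges) {
  recs <- lapply(seq_len(nrow(edges)), function(k)
    interaction_record(edges$drug_a[k], edges$drug_b[k], "monitor_closely"))
  knowledge_base(recs)
}

# every possible edge subset on n labelled nodes
all_edge_subsets <- function(n) {
  nodes <- letters[seq_len(n)]
  pairs <- if (n >= 2) t(utils::combn(nodes, 2)) else
    matrix(character(), ncol = 2)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1, function(mask) {
    keep <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    list(nodes = nodes,
         edges = data.frame(drug_a = pairs[keep, 1],
                            drug_b = pairs[keep, 2],
                            stringsAsFactors = FALSE))
  })
}

# assemble a cohort data frame from per-patient drug lists (one date each)
cohort_from_lists <- function(lists, age = 75, date = "2019-03-01") {
  rows <- lapply(names(lists), function(id)
    data.frame(patient_id = id, age = age, drug = lists[[id]],
               entry_date = date, route_class = "systemic",
               stringsAsFactors = FALSE))
  as_cohort(do.call(rbind, rows))
}
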