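---
title: "Screening medication lists for multidrug interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening medication lists for multidrug interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdiscreen)
```

## The problem

Two-drug interaction (DDI) alerting is standard in electronic health
records: each pair of co-prescribed drugs is checked against a curated
interaction table and flagged with a severity tier. What pairwise alerts
cannot see is *overlap*: a patient on warfarin, aspirin and amiodarone
triggers two independent warnings (amiodarone–warfarin, aspirin–warfarin)
even though amiodarone inhibits warfarin's metabolism and thereby
steepens the bleeding risk of the warfarin–aspirin pair. Sets of three or
more mutually entangled drugs — multidrug interactions, MDIs — can
amplify adverse-drug-event (ADE) risk beyond what any constituent pair
suggests, and elderly ambulatory patients with long medication lists are
the population most exposed.

`mdiscreen` operationalizes MDI detection as network analysis. For each
patient, the deduplicated medication list becomes a graph whose nodes are
drugs and whose edges are knowledge-base (KB) interaction records. A
connected component of two nodes is an ordinary two-drug DDI; **a
connected component of three or more drugs is an MDI**. Connectivity
guarantees the defining property — some drug in the set interacts with at
least two others — and makes "a patient with two MDIs" precise: two
disjoint components of size three or more on one list. A single
five-drug component is *one* MDI (of size class `five_plus`), not a
bundle of overlapping triples; MDI counts and size distributions
therefore partition cleanly.

Patient status is exclusive: `mdi` if any MDI is present (isolated extra
pairs notwithstanding), otherwise `two_drug_only` if any pair is present,
otherwise `none`. Prevalences over the three statuses are disjoint and
sum to the cohort.

## The knowledge base

The KB emulates an institutional alerting table: one record per
*unordered* drug pair with

* a severity tier — `contraindicated` > `generally_avoid` >
  `monitor_closely`; only these three alert-worthy tiers are admitted,
  and a record carrying anything else is a load error, so the severity
  gate can never silently leak;
* a set of ADE terms associated with the pair;
* optional mechanism annotations: `shared_ade` (both members contribute
  to the same ADE), `pk_inhibition` (one member inhibits the other's
  metabolism, optionally naming the CYP enzyme), and `conditional` (one
  member alters physiology in a way that raises susceptibility to the
  ADEs of a set of other drugs).

Pairs are canonicalized by lexicographic sorting, so lookup is symmetric
and serialization deterministic; duplicate pairs collapse to the higher
severity and the union of ADE terms, with a warning. Drugs with no KB
record are perfectly legal — they are isolated nodes, which is the fate
of most drugs on most lists.

## Cohort cleaning

Raw extracts are long-format CSVs (one row per medication entry). The
cleaning chain applies, in fixed order:

1. **age**: patients under 60 years (configurable) are excluded —
   the screen targets elderly outpatients;
2. **inpatient markers**: a list containing enoxaparin, vancomycin,
   neomycin, dalteparin, lactulose or heparin is presumed to be a stale
   post-hospitalization list and the whole patient is excluded;
3. **route**: topical and ophthalmic entries are removed *entry-level*
   (the patient stays) — they do not expose the patient systemically.
   Route is an input column; a keyword heuristic for reclassifying
   `unknown` routes exists but is off by default, because there is no
   verifiable general rule for recognizing such preparations from names;
4. **same-day restriction**: only lists whose surviving entries were all
   recorded on one calendar day are analyzed. Entry dates spanning years
   usually signal absent medication reconciliation — old entries that no
   longer belong on the list would otherwise manufacture spurious
   interactions. Day precision is used; times are not modeled.

Each excluded patient carries exactly one reason code (the first failing
rule), and the filter report balances exactly:
`n_output = n_input - n_age - n_inpatient - n_empty - n_mixed_dates`.
Brand names are folded to lowercase generics through a user-supplied map
before any matching; names absent from the map pass through as their own
generic, and normalization is idempotent.

## Amplification classification

Each MDI is tested for three mechanisms; any evidence makes it
*amplifying*, and an MDI with no evidence is reported as non-amplifying
rather than an error (such MDIs occur).

* **Pharmacodynamic** — some ADE term is attributed to ≥ 3 distinct
  drugs of the MDI. Per-drug attributions are derived from the pair
  records (a pair's terms belong to both members), optionally
  supplemented by a per-drug ADE table; pair records alone cannot carry
  single-drug effects, which is why the supplement exists.
* **Pharmacokinetic** — either two distinct MDI drugs are annotated
  inhibitors of the same third MDI drug, or an inhibition arc X→Y
  overlaps another interaction of Y (some third MDI drug Z ≠ X shares a
  pair with Y). The overlap rule covers inhibition chains (X inhibits Y
  while Y inhibits Z) and the single-inhibitor case where the inhibition
  steepens an existing pair; a lone arc with nothing to amplify is not
  evidence.
* **Conditional** — an MDI drug carries a conditional annotation whose
  scope covers ≥ 2 *other* drugs of the same MDI; scope members outside
  the MDI do not count. Conditional links are explicit KB metadata, never
  inferred from physiology — inferring them would be invented clinical
  knowledge.

The composite severity of an MDI is the multiset of its constituent
pairs' tiers sorted descending, e.g. `[generally avoid - monitor
closely]` for the anticoagulant triple above, with the maximum tier as
headline.

## Statistics, rounding and extrapolation

All percentages round **half-up to one decimal** (`round_half_up()`);
base R's half-to-even rule changes published-style values, e.g. a size
mix of 68/14/8 over 90 MDIs must print as 75.6/15.6/8.9 and a raw
exposure of 425,681.25 must truncate to 425,681. Medication-count
summaries use the sample SD (n−1) by default; at cohort scale the
population/sample difference is negligible, and the choice is
configurable.

Per-drug MDI prevalence divides *lists where the drug is itself an MDI
member* by *lists containing the drug* — membership, not mere
co-presence, is the default numerator because the quantity is meant to
answer "if this drug is prescribed, how often is it entangled?". The
looser any-MDI-on-the-list reading is available via `mode = "on_list"`.

Exposure extrapolation multiplies a per-drug prevalence by an external
beneficiary count (e.g. CMS Part D prescription fillers) and rounds
half-up. The table **total** sums the *unrounded* products and rounds
once; summing the per-row rounded counts can differ by a few units
(3,568,271 vs 3,568,272 on the bundled table) and both are exposed.
ADE tallies count each distinct term once per MDI by default (an MDI
with seizures and serotonin syndrome increments both); a per-patient
variant is available, since reasonable readers may want either unit.

## The synthetic generator

No real EHR extract ships with the package, so the generator emulates
the statistical structure the analysis assumes and every stage is
testable offline:

* **statuses** are i.i.d. multinomial with defaults
  (none, two-drug, MDI) = (0.913, 0.074, 0.013);
* **list lengths** per status group target mean ± SD of 3.1 ± 2.3 /
  6.6 ± 2.9 / 8.6 ± 3.4 medications. Lengths are integers with a hard
  minimum (1 / 2 / 3 respectively), drawn from a lower-truncated,
  integer-rounded normal. Naive truncation of the target normal would
  inflate the no-interaction mean by ≈ 0.56 — far beyond sampling error
  at cohort scale — and compress its SD, so the generator solves
  numerically for the latent mean and SD whose truncated, rounded law
  has *exactly* the target moments (two-moment matching). For the
  no-interaction group this yields a heavily left-truncated latent
  normal, i.e. a mode at one or two drugs with a long right tail, which
  is also the realistic shape for outpatient lists;
* **MDI sizes** are drawn from (three, four, five_plus) =
  (0.756, 0.156, 0.089) renormalized; within `five_plus`, sizes 5/6/7
  with probabilities 0.6/0.3/0.1 — the tail shape is unreported anywhere,
  so a decreasing split was fixed once;
* **KB structure**: hub families — one hub drug interacting with several
  partners that interact with nothing else — plus a pool of completely
  inert filler drugs. A planted MDI of size *s* is a star (hub + *s*−1
  partners), a planted two-drug DDI is one hub–partner pair, and fillers
  pad every list. Because fillers and cross-family partners never
  interact, planting cannot create accidental components, which is what
  makes *exact* recovery assertable: with noise options off, the
  pipeline recovers every planted status and every planted MDI drug set
  identically. An MDI patient receives a second, disjoint MDI from a
  different family with probability 5/85;
* **severities** are i.i.d. (contraindicated, generally avoid, monitor
  closely) = (0.021, 0.274, 0.705) per record; family-level shared-ADE
  terms (probability 0.9), partner-inhibits-hub arcs (0.35) and
  conditional annotations (0.1) give the amplification classifiers
  realistic work. Ages are a truncated normal, 72.5 ± 8.2 years with a
  floor at 60;
* **noise options** (off by default) plant mixed entry dates, inpatient
  markers and under-age patients to exercise each exclusion rule, and a
  brand-alias probability (0.1) exercises name normalization.

One RNG stream per run, fully determined by the seed: identical
configurations write byte-identical files.

What the generator does *not* emulate: real drug-name vocabularies,
comorbidity-driven co-prescription structure, dose, prescription
temporality, and KB idiosyncrasies such as overlapping hub families or
interacting partners. Passing tests therefore demonstrate that the
machinery is correct and calibrated under the stated statistical
structure — not that any particular real cohort has these prevalences.

## Numerical and scale choices

Per-patient graphs are built by quadratic pair enumeration (lists are
tens of drugs at most) and components by breadth-first search; the test
suite checks equivalence against a union-find oracle exhaustively on all
graphs of up to 5 nodes and on random 6–8-node graphs, and against
igraph as an independent implementation. Calibration tests run at the
full cohort scale of 6,545 patients (a few tens of seconds on one core),
with recovery bands of 3 standard errors around planted parameters;
smaller property tests use 100–3,000 patients. Ties in severity sorting
are broken lexicographically; evidence strings are deterministic so
repeated runs write identical artifacts.

## A worked run

```{r demo}
kb <- load_kb(system.file("extdata", "kb_demo.csv", package = "mdiscreen"))
cohort <- read_cohort(system.file("extdata", "cohort_demo.csv",
                                  package = "mdiscreen"))
cohort <- normalize_names(cohort, read_brand_map(
  system.file("extdata", "brand_map_demo.csv", package = "mdiscreen")))
filt <- filter_cohort(cohort)
filt$report

findings <- detect_interactions(filt$cohort, kb)
findings

m <- findings$mdis[[1]]
m
m$amplification
m$composite
```

And the exposure table from the bundled beneficiary counts:

```{r exposure}
ben <- read_beneficiaries(system.file("extdata", "cms_partd_2019.csv",
                                      package = "mdiscreen"))
res <- extrapolate_exposure(ben)
head(res$estimates[, c("drug", "prevalence", "n_beneficiaries", "n_exposed")])
res$totals
```

## Limitations

Doses are ignored, so an interaction mitigated by deliberate
dose-reduction is still flagged. Daily-versus-as-needed use is unknown
from a medication list. MDI detection is only as good as the KB: pair
coverage and severity ratings vary substantially across institutions'
interaction tables, and a pair missing from the KB can split a true
component in two. The same-day restriction trades recall for precision —
it discards most patients to avoid analyzing stale lists.
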