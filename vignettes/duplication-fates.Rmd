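---
title: "Classifying the evolutionary fates of duplicated homomeric proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the evolutionary fates of duplicated homomeric proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

More than half of all proteins oligomerize, and because a homomer is encoded
by a single gene, parsimony says the ancestor of both homomeric and
heteromeric complexes of paralogous proteins was a homomer. When a gene
encoding a homomer duplicates, the first mutations produce a statistical
mixture of homo- and heteromeric complexes, which can then resolve into one
of four fates:

* **obligatory homomers** — the paralogs stop cross-interacting and each
  forms its own homomeric complex;
* **obligatory heteromers** — the paralogs lose self-interaction and form a
  heteromer together;
* **mixed homo/heteromers** — the paralogs cross-interact and at least one
  still self-interacts;
* **hetero-others** — one paralog keeps the homomeric interaction while the
  other binds a completely new, non-paralogous partner.

`duplofate` implements a pipeline that assigns these fates to every
paralogous pair of a proteome from two kinds of evidence — filtered
protein–protein interaction (PPI) networks and curated complex annotations —
and that systematically varies the stringency of each analysis step, because
the apparent dominance of one fate over another depends heavily on those
choices. A cross-species module then asks whether heteromeric pairs in a
eukaryote-like species descend from homomers in a prokaryote-like species,
and whether the oligomeric order (total subunit count) was retained.

Divergence into non-interacting monomers, or loss of all interactions in
both copies, cannot be attributed to a homomeric ancestor by parsimony;
pairs without interaction evidence are reported as `unassigned` and excluded
from every fate-fraction denominator.

## Pipeline stages and their parameters

### Step 1 — paralog detection

All-vs-all intra-species homology hits (BLAST tabular format) are collapsed
to one record per unordered pair — the hit with the smallest e-value, ties
broken by higher identity, then higher coverage, then lexicographic order —
and assigned to three *inclusive* confidence tiers:

| tier | min identity | min query coverage | extra requirement |
|------|--------------|--------------------|-------------------|
| LC   | 25%          | 40%                | — |
| MC   | 30%          | 50%                | — |
| HC   | 40%          | 60%                | identical domain content |

All thresholds are inclusive (`>=`). Domain content is compared as a
*multiset* of domain identifiers annotated with p < 1e-5: copy number
matters, so pairs differing by an internal domain duplication do not reach
HC. Two proteins with no significant domains at all have equal (empty)
multisets; when no domain table is supplied HC is simply unattainable.
Because the tabular format reports one alignment per row, a pair's tier is
judged from its single best hit; the generator emits symmetric hits in both
directions, so this choice is unambiguous on synthetic data. Pairs flagged
by a whole-genome-duplication (ohnolog) list are annotated but not treated
differently.

### Step 2 — PPI evidence filtering

Raw records from multiple source databases are aggregated into undirected
evidence edges (self-interactions are records with identical interactor
identifiers and become self-edges). Records whose evidence class is not
experimental — predicted or text-mining interactions — are dropped at
compile time. Three successive filters follow:

1. **Mobile elements** — every edge touching a flagged
   retrotransposon-like protein is removed. These near-identical,
   self-interacting families otherwise masquerade as large obligatory-homo
   paralog families.
2. **Evidence** — a non-self edge must be reported in at least two source
   databases *and* observed with both proteins as bait and as prey. Two
   databases need not mean two independent observations (curation overlaps),
   but it eliminates annotation mistakes; the count is therefore taken over
   database names, not publications. For a self-edge the bait/prey demand is
   unsatisfiable as modelled (one protein plays both roles), so only the
   two-database condition applies — homomer evidence must survive
   filtering, or no homomer could ever be called.
3. **Co-localization** — a non-self edge is removed only when *both*
   proteins have known compartment annotations and the sets are disjoint.
   Unknown localization is treated as compatible with everything: penalising
   missing annotation would silently bias against heteromers. Labels are
   matched exactly after lower-casing; a user-supplied synonym map can be
   applied upstream.

Each filter only shrinks the edge set and is idempotent. A companion
operation extracts the pairs detected *exclusively* by methods other than
two-hybrid and pulldown (applying the two-database and co-localization
filters but not the direction filter, which is meaningless for such
methods), to let users check how much the bait/prey demand costs.

### Step 3 — fate assignment

From one edge set, a pair's interaction status is a five-part record: self-edge on
each paralog, cross-edge between them, and an *outside partner* flag per
paralog — an edge to a protein that is neither itself nor any of its
detected paralogs (judged against the most inclusive, LC-level pair set, so
a hetero-others partner is genuinely new). Fates follow from the status:

* cross and no self → obligatory heteromer (both criteria);
* cross and any self → mixed (both criteria);
* no cross, both self → obligatory homomer (both criteria);
* no cross, exactly one self, outside partner on the **non**-self paralog →
  hetero-others under the *stringent* criterion;
* under the *flexible* criterion every no-cross case with at least one
  self-interactor becomes an obligatory homomer — hetero-others is never
  emitted, which is exactly how flexible assignment absorbs (and
  mis-assigns) hetero-others cases. The one-self/no-partner case, which is
  `unassigned` under stringent, is absorbed too.

In curated mode, evidence comes from complex records at three tiers. PDB
tier (composition, stoichiometry and contacts known): self requires copy
number ≥ 2 plus a self-contact; cross requires an inter-subunit contact
between the paralogs. CS tier (composition and stoichiometry): self requires
copy number ≥ 2 *and* a PPI self-edge; cross requires co-membership *and* a
PPI cross-edge. C tier (composition only): known copy numbers are honoured,
unknown ones fall back to membership plus the PPI self-edge rule. A curated
obligatory-homomer call is additionally vetoed (demoted to `unassigned`)
when the paralogs cross-interact in the same-level PPI data; the veto is
implemented as a separate flag rather than folding PPI cross-evidence into
the curated `cross` field, which would fabricate curated heteromer calls
with no complex evidence behind them. Cross- and self-evidence are always
read from the same filter level being evaluated, so grid cells stay
comparable.

### Complex counting

Because several pairs can sit in one complex, fates are also counted per
unique complex: for each (filter level, criterion, inclusive tier) cell, the
number of distinct complexes containing at least one pair of each fate. A
complex "contains" a hetero or mixed pair only when both paralogs are
subunits; for obligatory-homo and hetero-others — fates whose defining
complexes hold a single paralog — one member suffices, so the two homomeric
complexes of an obligatory-homo pair count as two. A complex with pairs of
k fates contributes to k cells; whether the original figure counted
multi-fate complexes once per fate or by a dominant fate is not stated, and
multi-counting is the choice that loses no information.

### Cross-species transitions

Orthology links are mutual sub-threshold BLAST hits (e-value < 1e-5 in both
directions). Strict reciprocal-*best*-hit filtering is available behind a
flag but is off by default: the weaker mutual-hit reading is chosen because
best-hit exclusivity is an additional assumption, and the downstream
shared-domain filter (≥ 1 common domain at p < 1e-5) already removes
spurious links. The manual same-function curation step of the original
analysis is not re-implementable; an optional user-supplied accept/reject
list takes its place, and by default every domain-sharing link passes.
A transition record is emitted per (A-side unit, B-side pair) where the
B pair is obligatory-hetero or mixed (stringent criterion, PPI dataset) and
at least one member links to a homomeric A protein — one-member linkage is
the default because divergent paralogs lose detectable similarity
asymmetrically; both-member linkage is available via a flag. The A side is
a singleton if the protein has no detected paralog, else the paralogous
pair. Oligomeric orders are compared only when both sides have
stoichiometry-bearing (CS/PDB) complexes; otherwise the relation is
`unknown`.

## The synthetic-data generator

Every stage is validated against seeded two-species scenarios with known
ground truth. The generator emulates:

* paralogous families with known fates, placed in an intended tier by
  sampling identity/coverage uniformly from closed per-tier bands (the
  boundary values are attainable because the thresholds are inclusive);
* multi-database PPI observations: each true edge is observed once per
  database per direction, then corrupted by the configured biases —
  homomer-blind method classes (pulldown-like observations of self-edges
  are lost with probability `p_homomer_blind_method` per record), missing
  bait/prey directions (`p_missing_direction` per edge), spurious
  single-database single-direction edges (`p_false_positive_edge`), and
  well-supported but cross-compartment edges (`p_mislocalized_edge`);
* hetero-others truths realised minimally: the non-self-interacting paralog
  receives exactly one non-paralogous partner protein created for that
  purpose;
* retrotransposon-like confounder families of 18 near-identical,
  self-interacting proteins, flagged for filter 1;
* curated complexes at all three tiers, consistent with the truth flags;
* a prokaryote-like species A: a configurable fraction of heteromeric
  B families receives a homomeric A ortholog (singleton or
  obligatory-homomeric pair), connected by reciprocal inter-species hits
  below the orthology threshold and sharing the family's domains.

Defaults encode the study conditions where the source analysis states them:
seven PPI source databases, five mobile-element families (90 flagged
proteins), transition fraction 0.34 with 65% singleton orthologs (the
observed split of heteromeric pairs with homomeric orthologs). Where no
value is stated the defaults are one-time realistic choices: uniform fate
mix over the four fates (the pre-filter fate frequencies of real proteomes
are unknown), 50 families per fate, 5 compartments, false-positive and
mislocalization rates of 5%, homomer-blind probability 0.3, missing
direction 0.2.

What the generator does **not** emulate: actual sequences (identity and
coverage are generated summary statistics, not alignments), binding
kinetics or affinities behind the statistical homo/hetero mixture,
correlated database curation (databases are sampled independently), and
multi-pair families sharing proteins (each family contributes one pair, and
partner proteins are unique to their family). Passing the recovery tests
therefore shows the pipeline's logic is faithful under the modelled biases,
not that real PPI noise is fully captured.

## Numerical and degenerate-input choices

* Pair identity is order-free everywhere: ids are sorted, self-edges have
  equal endpoints, and all outputs are sorted (pairs lexicographically,
  grid cells in axis-enumeration order) so reruns are byte-identical.
* Tie-breaks in hit collapse are total (e-value, identity, coverage,
  query/subject order), so collapse is deterministic for any input.
* Empty inputs are first-class: zero-family scenarios write headers-only
  files that round-trip; empty edge sets and complex tables flow through
  every filter and counter.
* An empty assignment set is a structural error for grid construction
  (there is nothing to tabulate); a missing axis combination is reported
  with the offending cell.
* When no localization table is configured the pipeline skips filter 3,
  logs an explicit warning, and the grid simply has no `f3` level.
* Scenario generation is fully determined by the single integer seed; the
  write/read cycle is lossless, with floating-point fields rounded at
  generation (not at I/O) so files are stable.

## Scale of the validation runs

The test-suite sizes are the package's own choices: end-to-end recovery
runs 20 seeds at 200 truth pairs per scenario (the scale of the filtered
yeast analysis set); filter-property and bias-direction sweeps use 100-pair
scenarios over 20 seeds per condition, with three databases so that
evidence loss is informative rather than saturated; brute-force oracle
comparisons run on scenarios of ≤ 50 proteins where exhaustive re-derivation
is cheap.

## Known limitations

* The pipeline consumes homology and contact evidence as tabular records;
  it does not run BLAST, parse structure files, or score interaction
  confidence.
* Manual curation steps of the original analysis (inspecting putative
  paralogs, checking orthologous function) are replaced by explicit,
  deterministic exclusion/accept lists supplied by the user.
* Fate assignment is hard (one label per pair per context); there is no
  probabilistic assignment or propagation of evidence uncertainty.
* Ring-like versus non-ring-like complex topology is not inferred; order
  comparison is limited to total subunit counts.
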