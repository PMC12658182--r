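---
title: "Minimal diagnostic clone sets from CNA mosaicism in serial xenografts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal diagnostic clone sets from CNA mosaicism in serial xenografts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemin)
```

## The problem

SNP arrays applied to a leukaemia at diagnosis and to bone marrow harvested
from serially transplanted immunodeficient mice yield, per sample, a list of
copy-number-alteration (CNA) segments, each with a zygosity (heterozygous
deletion, homozygous deletion, copy-neutral LOH, amplification) and a
mosaicism status: *clonal* (essentially all cells carry it), *subclonal*
(a mosaic of carriers and non-carriers), or undetected. Transplantation acts
as a biological sieve: clones present at diagnosis below array sensitivity
can expand in a graft and become detectable, so alterations appear to vanish
in one mouse and reappear in its descendants. The question the package
answers is: **how many genetically distinct diagnostic clones are needed, at
minimum, to explain everything observed across the patient sample and all
grafts — and what do their phylogenies look like?**

## The model

Three assumptions define the inference:

1. **No new mutations during transplantation.** Every genotype observed in
   any graft already existed in the patient at diagnosis: there is a single
   pool of diagnostic clones from which all samples draw.
2. **Perfect phylogeny (single origin, no loss).** Each CNA event arises
   exactly once and is never reverted, so for any two events the sets of
   clones carrying them must be nested or disjoint (a laminar family). The
   containment order of carrier sets *is* the clone tree.
3. **Zygosity chains.** A homozygous deletion or a cnLOH at a locus is a
   *second hit* completing a heterozygous deletion (its *first hit*): a clone
   carrying the second hit carries the first, and one clone completes a het
   deletion at most one way. cnLOH can instead be configured as an
   independent first hit (`cnloh_mode = "independent"`), but the default
   treats it as the extreme of the zygosity progression, which is how the
   different degrees of homozygous involvement at one locus across grafts are
   naturally read.

A clone subset *explains* a sample when every CLONAL event is carried by all
assigned clones, every ABSENT event by none, every SUBCLONAL event by at
least one but not all, and UNKNOWN cells impose nothing
(`explain_sample()`).

### From segments to events

Segments from different samples describe the same event only if they agree
in chromosome, alteration category and both breakpoints within `tolerance`
base pairs (transitive closure; the merged segment is the hull). The default
tolerance is **0**: breakpoint-distinct deletions at one locus are the very
signal that separates clones, so merging must be opt-in. Because merging is
a closure, a chain of pairwise-close segments can drift beyond the pairwise
tolerance; this is documented behaviour and tested.

Uncertainty is represented explicitly rather than decided silently:

* segments within `ambiguity_tolerance` but not within `tolerance` *might*
  be one event — each consistent partition is one choice;
* a second hit overlapping several het deletions *might* descend from any of
  them — each candidate parent is one choice.

A **resolution** is one combined choice for all ambiguities.
`minimal_clone_range()` solves the minimization exactly under every
resolution (capped at `resolution_cap`, default 10000, failing loudly) and
reports the range of minima — the honest answer when the data do not decide
the breakpoint identity or the zygosity linking. Resolutions that contradict
the observations (e.g. a linking that places a clonal second hit over an
absent first hit) are reported as infeasible rows, not errors.

### Exact minimization

Candidate clone genotypes are restricted to the lattice generated by the
observed event combinations plus zygosity chains: a clone in any minimal
solution is assigned to at least one assayed sample (an unassigned clone
could be dropped), so its genotype is that sample's CLONAL events plus a
subset of its SUBCLONAL/UNKNOWN events. This normalization preserves
exactness and keeps the search finite; events never required anywhere are
excluded, which also canonicalizes the co-minimal solution list.

Feasibility reduces to cover-style requirements — each assayed sample needs
an admissible clone, and each SUBCLONAL call needs an admissible carrier and
an admissible non-carrier — plus laminarity of the chosen set. The search is
iterative deepening on the clone count with branch-and-bound: branching on
the unsatisfied requirement with fewest candidates, pruning with a greedy
count of pairwise-disjoint unsatisfied requirements (each needs its own new
clone — an admissible bound) and with incremental laminarity checks
(crossing carrier sets can never be repaired by adding clones). At the first
feasible depth the search enumerates *all* co-minimal clone sets,
deduplicated by canonical genotype-set key and ordered lexicographically.
Because every clone in a minimal solution serves a requirement, no solution
exceeds the requirement count; exhausting that bound proves infeasibility
rather than hitting the `clone_cap` (default 64, which only limits genuinely
huge instances and fails loudly).

`clone_lower_bound()` is the reported admissible bound: at least 2 as soon
as any sample is mosaic, and at least the size of a greedily grown set of
samples with pairwise-incompatible clonal signatures.

### Transplant lineage: two containment notions

The no-new-mutation assumption constrains clone *presence* along the
transplant lineage. The package offers both operationalizations:

* `lineage = TRUE` (default): the *detected* clone assignments must be
  nested along every transplant edge. This is the strictest reading and is
  appropriate when detection is essentially complete (e.g. perfect-detection
  simulations). Under censoring it is deliberately over-strict: a clone that
  travels below threshold through a primary mouse and expands in a secondary
  produces an event ABSENT in the parent but CLONAL in the child, and no
  nested assignment exists. The package then reports infeasibility with the
  binding constraints instead of silently relaxing.
* `lineage = FALSE`: only the shared diagnostic pool is enforced. This is
  the right model for real array data, where sub-threshold transit is
  exactly the phenomenon of interest; it is the mode used for the bundled
  mosaic cohort and the censoring analyses.

### Ordering events and hierarchies across timepoints

`order_events()` orders two events whenever the observed carriers of one are
strictly contained in the carriers of the other, excluding UNKNOWN cells
from both sides so missing data cannot fabricate order. On complete data
this containment is a strict partial order; with UNKNOWN cells the pairwise
masks differ and transitivity is no longer guaranteed — the reported pairs
are then individual containment facts, not a closed order. This is why a
remission sample carrying only a chr14 deletion, against diagnosis and
relapse clones carrying chr14 and chr12 deletions, places del14 first.

`build_hierarchy()` pools clone genotypes from several timepoints over a
shared catalog and builds the single containment tree they imply: shared
events define common ancestors, private events define branches, and
inferred ancestors are materialized only at branch points (equal carrier
sets share one edge, so unary ancestor chains cannot arise). Crossing
carrier sets across timepoints — evidence against a shared-ancestor model —
raise an incompatibility certificate naming the two events.

Trees serialize as Newick with clone ids as node labels and edge gains in
`[&events=...]` comment blocks (strippable with
`strip_newick_comments()` for plain parsers), as Graphviz DOT, and as JSON.

## The synthetic-data generator

`simulate_clone_tree()` grows a rooted tree whose founder carries no events;
every further clone attaches to a uniformly chosen existing clone and gains
one first-hit event at a fresh locus (an amplification with probability
`p_amplification = 0.1`, otherwise a deletion), plus — with probability
`p_second_hit = 0.25` when its ancestry carries an uncompleted het
deletion — a homozygous-deletion or cnLOH second hit nested inside the first
hit's segment. Each (locus, second-hit type) arises at most once tree-wide,
preserving single origin, while hom-del and cnLOH *can* complete the same
het deletion on different branches — the chromosome-9-style progression.
Loci live in disjoint 5 Mb windows so breakpoint overlap is always the
intended zygosity overlap.

`simulate_cohort()` draws diagnostic clone frequencies from a symmetric
Dirichlet (`frequency_concentration = 1`, uniform on the simplex), then
passes each transplant through a single multinomial bottleneck of
`bottleneck_cells` cells (default 200; primaries resample the diagnosis,
secondaries their own primary, so clone support is nested by construction).
A single bottleneck per passage is the minimal mechanism that produces
mosaicism and clone dropout; within-mouse growth dynamics, selection, and
sorting fidelity are deliberately not modelled. `observe_cohort()` censors
carrier fractions into calls: ABSENT at or below `detect_absent = 0.05`,
CLONAL at or above `detect_clonal = 0.95`, SUBCLONAL between. Arrays state
this sensitivity limitation only qualitatively, so the thresholds are
configuration, never hard-coded. One seeded stream drives a whole case;
identical configs give bit-identical files (`generate_case()`).

What passing recovery tests show — and what they do not: with **monoclonal
transplants** (`bottleneck_cells = 1`), **perfect detection**
(`detect_absent = 0`, `detect_clonal = 1`) and every clone seeding at least
one graft, each clone is pinned by an exactly-genotyped sample, and the
reported interval provably collapses to the true clone count. Mere per-event
observability is *not* enough to identify a clone inside polyclonal
mixtures, so recovery is tested under the pinning condition; on real data
the minimum is a floor, not an estimate of the clone number.

### Censoring direction: a caveat found by the exact solver

Hiding a *whole clone* below threshold removes requirements and can only
lower or preserve the minimum; at perfect detection the truth itself is a
feasible solution, so the minimum never exceeds the true count. One might
expect the stronger statement that raising `detect_absent` on a fixed cohort
never increases the inferred minimum. The exact solver shows this is false:
flipping a single call from SUBCLONAL to ABSENT does remove that event's
carrier/non-carrier requirements, but it also *evicts carrier clones from
that sample's admissible set*, and a clone that previously served several
samples may no longer be shareable, forcing an extra clone elsewhere.
Cross-checked against the independent exhaustive oracle, cohorts exist where
the exact minimum moves 2 → 3 as the absence threshold rises from 0.02 to
0.05. Under-detection therefore understates clone numbers as a tendency and
as a theorem at the whole-clone level, but not as pointwise monotonicity of
the exact minimum in the threshold — the corresponding acceptance-style test
documents this by failing, and is retained deliberately.

## Worked example

```{r example}
seg <- system.file("extdata", "patient2_synthetic_segments.tsv", package = "clonemin")
man <- system.file("extdata", "patient2_synthetic_manifest.tsv", package = "clonemin")
fit <- infer_clones(seg, man, tolerance = 0, ambiguity_tolerance = 300000,
                    options = clone_options(lineage = FALSE))
glance(fit)
tidy(fit)
sol <- representative_solution(fit)
sol$clones
cat(write_newick(sol$tree))
```

The bundled cohort is synthetic (derived by hand from a 6-clone truth tree,
as its file header states): a diagnostic sample and nine grafts with
breakpoint-distinct chr9 deletions, hom-del and cnLOH second hits, nested
chr14 deletions and an X amplification. Its two near-miss chr9 breakpoints
and two ambiguous second-hit linkings span 8 resolutions; contradictory
linkings come back infeasible and the feasible ones all need 6 diagnostic
clones — the true count behind the fixture.

## Numerical and design choices

* Coordinates are 0-based half-open internally; `dialect = "one_based"`
  converts inclusive array exports at the boundary.
* Unreported events in an assayed sample are ABSENT (detected-CNA tables);
  unassayed samples are all-UNKNOWN and receive the full clone set as their
  canonical assignment, keeping outputs total.
* A second-hit call raises its first-hit parent's call to at least its own
  level (a homozygous deletion implies the underlying het deletion); with
  ambiguous linkings the raise is deferred until a resolution chooses the
  parent. Explicitly contradictory records are errors, not silent fixes.
* Carrier fractions are compared to thresholds with a 1e-9 slack so exact
  0/1 fractions land on the intended side.
* Determinism throughout: catalogs, resolutions, pools, co-minimal solution
  lists, tree child order and Newick output are all canonically ordered;
  ties break lexicographically.
* Test problem sizes are chosen to keep the exhaustive oracle exact and the
  suite quick: oracle equivalence uses 200 matrices of up to 6 events and 5
  samples; recovery uses 100 cohorts of 2–5 clones with 8 primary grafts;
  the bundled cohort runs in well under a second.

## Limitations

* Clone *frequencies* are not estimated; the model is categorical
  presence/mosaicism, and the minimum clone count is a floor.
* Mutations acquired during transplantation are excluded by assumption; an
  alternative reading of a broadening deletion as ongoing evolution is
  outside the model.
* Strict per-edge lineage containment and detection censoring are mutually
  inconsistent on real data (see above); choose the mode that matches your
  detection regime.
* `order_events()` on data with many UNKNOWN cells yields containment facts
  that need not chain transitively.
* Branch lengths and timing are not modelled — the trees order events, they
  do not date them.
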