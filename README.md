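# clonemin

Minimal diagnostic clone sets from copy-number mosaicism in serial
xenografts.

## What it does, and for whom

Childhood leukaemias are mosaics of genetically distinct subclones. SNP
arrays on a diagnostic bone-marrow sample and on grafts from serially
transplanted immunodeficient mice report, per sample, copy-number-alteration
(CNA) segments with a zygosity (het deletion, hom deletion, copy-neutral
LOH, amplification) and a mosaicism status — clonal, subclonal, or
undetected. Alterations can vanish in one graft and reappear in its
descendants because sub-threshold clones expand through transplantation.

`clonemin` is for groups doing this kind of clonal-tracking experiment. From
segment calls and a sample manifest it computes, under a perfect-phylogeny,
no-new-mutation model, the **exact minimum number of diagnostic clones**
needed to explain every observation, over **every resolution** of ambiguous
breakpoint merges and second-hit linkings, together with all co-minimal
clone sets, their clone trees, and diagnosis/remission/relapse hierarchies
ordered by event containment.

## The model in brief

For samples *s* and events *e* with calls in {ABSENT, SUBCLONAL, CLONAL,
UNKNOWN}, find a minimum-cardinality set *C* of clone genotypes
*g ⊆ E* and per-sample assignments *A(s) ⊆ C* such that

* CLONAL(s,e) ⟹ every clone in *A(s)* carries *e*; ABSENT(s,e) ⟹ none does;
  SUBCLONAL(s,e) ⟹ at least one carrier and one non-carrier (mosaicism);
* carrier sets are laminar — for any two events, nested or disjoint
  (perfect phylogeny, single origin); a second hit (hom del / cnLOH) is
  carried only with its underlying het deletion, and at most one way per
  clone;
* optionally, detected assignments are nested along transplant edges.

The search is exact (iterative-deepening branch-and-bound with an
admissible disjoint-requirement bound), candidate genotypes being
normalized to the lattice generated by observed event combinations plus
zygosity chains. Where observations do not decide whether two segments are
one event or which het deletion a second hit completes, each consistent
resolution is solved separately and the *range* of minima is reported.

## Worked example

A bundled synthetic cohort (one diagnostic sample, nine grafts; derived by
hand from a 6-clone truth tree) carries breakpoint-distinct chr9 deletions,
hom-del and cnLOH second hits, nested chr14 deletions and an X
amplification:

```r
library(clonemin)
seg <- system.file("extdata", "patient2_synthetic_segments.tsv", package = "clonemin")
man <- system.file("extdata", "patient2_synthetic_manifest.tsv", package = "clonemin")
fit <- infer_clones(seg, man, tolerance = 0, ambiguity_tolerance = 300000,
                    options = clone_options(lineage = FALSE))
fit
#> <clone_fit> 8 resolution(s); minimal diagnostic clones: 6 to 6
glance(fit)
#> # A tibble: 1 × 6
#>   min_clones max_clones n_resolutions n_feasible n_samples n_events
#>        <int>      <int>         <int>      <int>     <int>    <int>
#> 1          6          6             8          5        10        7
```

Two near-miss chr9 breakpoints and two ambiguous second-hit linkings span 8
resolutions; three contradict the observations and come back infeasible,
and every feasible one needs exactly 6 diagnostic clones — the true count
behind the fixture. The representative minimal tree:

```r
sol <- representative_solution(fit)
cat(write_newick(sol$tree))
#> (((C3[&events=amp_X_10000000_15000000],(C6[&events=homdel_9_21200000_22300000])
#>    C4[&events=del_14_50400000_51200000],C5[&events=cnloh_9_21100000_22400000])
#>    C2[&events=del_9_20800000_22600000])C1[&events=del_14_50000000_52000000])root;
```

read bottom-up: a founder deletion on chr14 (C1), a chr9 het deletion on
top of it (C2), then three branches — the X amplification (C3), a nested
second chr14 deletion whose lineage completes the chr9 deletion
homozygously (C4 → C6), and a cnLOH branch (C5). `autoplot(fit$obs)` draws
the call heatmap, `autoplot(sol$tree)` the tree; `tidy()`/`glance()` give
tabular views of every result object. `simulation_config()` +
`generate_case()` produce fully ground-truthed synthetic cohorts in the
same file formats, and `run_infer()`/`run_simulate()` (or the
`inst/scripts/clonemin` wrapper) drive everything from files to reports.

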