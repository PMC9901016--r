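---
title: "Tracing skeletal stem cell hierarchies with mitochondrial heteroplasmy, imaging and flow gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing skeletal stem cell hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Bone and marrow fat are produced by a branching system of progenitors:
a CD24+CD29+ skeletal stem cell (SSC, immunophenotype
Lin- THY- 6C3- CD200+ CD105-) sits at the apex and gives rise to
adipocyte-committed CD24+ SSCs, osteoblast-committed CD29+ SSCs, and —
through the CD29+ branch — more mature CD105+, THY+, 6C3+ and THY+6C3+
derivatives. Establishing such a hierarchy *in situ*, without
transplantation, can be done by reading somatic mitochondrial DNA (mtDNA)
variants as clonal barcodes: in a mitochondrial-mutator (error-prone
mtDNA polymerase) mouse, abundant somatic variants arise, drift in
heteroplasmy, and are inherited by a population's descendants, so the
pattern of variant sharing across sorted populations encodes the
differentiation tree.

`ssctrace` implements that analysis end to end, together with the two
companion assays used to corroborate the hierarchy: nearest-neighbour
statistics of gated cell types in multiplexed tissue images, and
hierarchical flow-cytometry gating of the CD24/CD29-defined SSC subsets.
Because the underlying mouse data are not published as reusable tables,
the package ships a first-class synthetic-data generator whose ground
truth makes every analysis step testable.

## The drift model

Heteroplasmy — the fraction `h` of a cell's `M` mtDNA copies carrying a
variant — evolves at each cell division by random partitioning and
re-replication of the copies. We model one division as Wright–Fisher
resampling:

    h' = Binomial(M, h) / M

This makes `h` a martingale with a closed-form variance after `t`
divisions:

    Var(h_t) = h0 (1 - h0) (1 - (1 - 1/M)^t)

which the test suite verifies against both the formula and an
independent per-copy resampling simulation (`drift_heteroplasmy()` is
the exposed kernel).

New somatic mutations arrive as `Poisson(mu)` events per cell per
division, each at a genome position not already used by another emitted
variant, entering at heteroplasmy `1/M`. Positions are assigned to the
variants that survive to observation, uniformly over the 16,299 bp mouse
mtDNA; extinct mutations never consume positions, so the mutation supply
is not artificially capped at mutator rates.

### Why an explicit pedigree

A naive implementation would drift every sampled cell independently down
the tree. That reproduces the per-lineage moments but destroys the one
thing the analysis needs: *clonal expansion*. A mutation can only mark a
subtree if the cell that acquired it leaves many descendants. Each tree
edge is therefore an explicit Wright–Fisher pedigree: a bottleneck of
`n_seeds_per_edge` progenitors is drawn from the parent population, the
compartment doubles each division until it reaches `n_cells_per_pop`,
and is then maintained at constant size by resampling. Founder clones
segregate through the bottlenecks (producing subtree-shaped presence
patterns), and somatic mutations acquired on an edge can expand
clonally and be transmitted to all downstream compartments.

### Default study conditions

The defaults of `sim_config()` define the simulated study and are fixed:

| parameter | default | rationale |
|---|---|---|
| `M` | 80 | mtDNA segregates as nucleoids; the *effective* number of segregating units per cell is tens, not the thousands of genome copies |
| `mu` | 0.5 / cell / division | mutator-polymerase mice accumulate somatic mtDNA variants orders of magnitude faster than wild type; ~1 mutation per two genome replications is in that regime |
| `divisions_per_edge` | 15 | enough divisions per differentiation step for measurable drift (variance factor ~0.17 at `M = 80`) |
| `n_founders` | 24 | few founder stem clones gives the "rich substrate" of mid-frequency clonal variants |
| `founder_variant_count` | 100 | pre-existing clonal barcodes, heteroplasmy ~ Beta(2, 2) |
| `n_seeds_per_edge` | 50 | progenitor bottleneck seeding each compartment; drives clone-frequency drift between populations |
| `n_cells_per_pop` | 300 | cells per sorted population |
| `depth_mean` | 2000 | per-position mitochondrial capture depth (Poisson); mito capture from ATAC libraries is deep because mtDNA is high copy |
| `sort_purity` | 0.98 | FACS impurity: a sorted cell is replaced by a draw from the other populations with probability 0.02 |
| `seq_error` | 5e-4 | per-base error, symmetric over the three alternate bases |

These were chosen once, as a realistic operating point for a mutator
mouse design, and the recovery surfaces in the acceptance tests are
measured *at* these conditions, not tuned per test.

What the generator does **not** emulate: selection on mtDNA variants
(all drift is neutral), mutational hotspots (positions are uniform),
ATAC fragment structure, index hopping, or shared germline variants.
Passing tests therefore show that the pipeline recovers hierarchies
under neutral drift with honest sequencing noise — not that it is robust
to selection or alignment artefacts.

## From counts to high-confidence variants

`compute_heteroplasmy()` uses the standard bulk allele fraction
`af = alt / (ref + alt)` pooled over strands, retaining per-strand
fractions for QC. `filter_high_confidence()` applies five rules (all
thresholds exposed in `filter_params()`; the defaults follow common
mito-capture QC practice since no single standard exists):

1. called somewhere: `af >= 0.005` at depth >= 100;
2. not homoplasmic everywhere (>= 0.95 in all callable populations is
   germline background, useless as a clonal mark);
3. strand balance in every called population
   (`|log2(af_fwd / af_rev)| <= 2`, both strands non-zero);
4. cross-population strand concordance (Pearson >= 0.65 over callable
   populations when at least 3; a variant whose population profile is
   not reproduced on both strands is an artefact);
5. no blacklist hit (default blacklist empty; supply intervals for
   hypervariable regions when analysing real captures).

A per-variant, per-rule audit trail (`filter_audit()`) records exactly
why each variant fell. One caveat worth knowing: rules 3–4 are evaluated
over the set of *called* / *callable* populations, which itself depends
on the call thresholds, so relaxing `min_depth` or `min_af_call` can
enlarge those sets and is not guaranteed to be monotone; relaxing the
homoplasmy cap, the strand-ratio bound, or the strand-correlation floor
is strictly monotone.

## The dendrogram and the consistency score

`cluster_populations()` performs unsupervised hierarchical clustering of
populations with distance `1 - Pearson` on `sqrt(af)` profiles (the
square root stabilises the variance of small fractions) and average
linkage. Both metric and linkage are arguments, since "unsupervised
clustering" admits many variants; a population with a constant profile
falls back to Euclidean distance for its pairs, with a warning.

`hierarchy_consistency()` formalises the overlay of allele frequencies
on a candidate differentiation model. A variant with presence set `S`
(populations with `af >= tau`, default `tau = 0.01`, chosen to sit above
FACS-contamination leakage at 2% impurity) is *transmission consistent*
when `S` has a unique topmost population and is contained in that
population's subtree — i.e. a single origin plus inheritance explains
it. The score is the consistent fraction of observed variants; its null
is the same score under `R = 999` random relabelings of the tree's
populations, reported with an empirical p-value
`(1 + #{null >= obs}) / (R + 1)`. Variants present everywhere (root
clones) or in exactly one population are consistent under any
relabeling, so discrimination comes entirely from partial sharing
patterns; the per-variant verdicts are returned so users can apply their
own rule.

```{r mito-pipeline}
library(ssctrace)
sim <- simulate_clonal_hierarchy(sim_config(seed = 1))
m   <- compute_heteroplasmy(sim$counts)
hi  <- filter_high_confidence(m, filter_params())
den <- cluster_populations(hi)
autoplot(den)
cons <- hierarchy_consistency(hi, default_ssc_hierarchy(), tau = 0.01,
                              R = 999, seed = 1)
glance(cons)
```

## The imaging component

`simulate_image()` renders 13-channel images (nuclear `DNA` channel plus
12 markers): nuclei are Gaussian blobs, each cell paints its type's
signature mean over a cytoplasmic disk, and i.i.d. Gaussian noise is
added per pixel. Only P1 (CD24+CD29+ SSC) has a panel-fixed definition;
the P2–P11 signatures in `default_cell_signatures()` are a labelled
synthetic fixture. One type can be attracted toward another (Gaussian
kernel around a random anchor, mixture weight `strength`), which plants
a known spatial association for power tests; `strength = 0` is uniform
placement and passes quadrat tests of complete spatial randomness at low
packing.

`segment_cells()` is nuclear-seeded watershed: Gaussian smoothing
(`sigma = 2` px), Otsu threshold, distance-transform watershed
(`tolerance = 0.1` — touching round nuclei differ from their saddle by
well under one distance unit, so a coarser tolerance merges them), and
fixed-radius (4 px) nearest-nucleus expansion. `annotate_types()` gates
per-cell mean intensities with per-channel thresholds; the default
`"bimodal"` mode is a deterministic two-class 1-D split accepted only
when the class gap exceeds the channel's internal spread (otherwise the
channel is unimodal and is called all-positive or all-negative against a
pooled background reference — the lower decile of all marker means).
Per-image `"quantile"` and fixed `"absolute"` modes are available for
instrument-calibrated data.

The neighbourhood statistic is the empirical distribution of the type of
the nearest other cell over focal (P1) cells, per ROI — probabilities
sum to 1 within an ROI — with ties broken by smallest cell id so results
are exactly reproducible. `pool_neighbors()` additionally reports the
composition pooled over ROIs, since either convention is defensible.
Enrichment is judged against a within-ROI label-permutation null
(positions fixed, labels shuffled, `K >= 99`): `z`-scores and empirical
p-values `(1 + #{perm >= obs}) / (K + 1)`. Discrete counts make these
p-values conservative (ties count against rejection); single-type ROIs
are degenerate and flagged rather than scored.

## The flow component

Events are consumed as raw per-event marker intensities, transformed
with `asinh(x / 150)` on load (the cofactor is an argument; 150 is a
common choice for fluorescence data), and a `Lin` dump channel is formed
as the per-event maximum of Ter119/CD45/CD31. `default_ssc_gate_tree()`
encodes the SSC backbone — Lin- → THY- 6C3- → CD200+ CD105- — followed
by the CD24 × CD29 quadrant gate, whose four children partition the SSC
gate exactly (side `+` is `>= t`, side `-` is `< t`), so the four
quadrant percentages of parent sum to exactly 100.
`compare_conditions()` summarises subset percentages by group with
seeded bootstrap CIs (B = 2000) and reports between-group differences as
effect sizes only — inferential testing is deliberately out of scope.

```{r flow}
fr <- c("CD24+CD29+" = 0.05, "CD24+" = 0.15, "CD29+" = 0.50,
        "CD24-CD29-" = 0.30)
ev  <- simulate_flow_events(fr, default_flow_model(), 50000, seed = 1)
rep <- apply_gating_tree(transform_flow(ev), default_ssc_gate_tree())
autoplot(rep)
```

## Numerical and reproducibility choices

* Every stochastic function takes a `seed` and is byte-reproducible;
  internal streams are derived so components stay decoupled.
* Ties: nearest-neighbour ties break to the smallest cell id; dendrogram
  ties follow `hclust`'s deterministic merge order on the input label
  order.
* Degenerate inputs return flagged results, not errors, wherever the
  quantity is merely undefined (single-type ROIs, zero-variance
  permutation distributions, single-sample groups); malformed inputs
  (cyclic trees, unknown markers, inconsistent counts) error with the
  offending row or name.
* Problem sizes in the test and acceptance suites — e.g. 20 simulated
  mice for hierarchy recovery, 1,000 random ROIs for the neighbour
  oracle, `K = 199` for null calibration, 50,000 flow events — are the
  package's chosen trade-off between statistical resolution and a test
  run that completes in minutes.
* The null-calibration fixture uses section-scale ROIs (1,000 cells,
  two types at 50/50). This is deliberate: the permutation p-value is
  computed on integer nearest-neighbour counts, and with few focal
  cells the tie mass at the rejection boundary makes it visibly
  conservative (a well-known property of discrete permutation tests,
  not an error). With ~500 focal cells the count support is wide and
  the realised false-positive rate sits near the nominal level.

## Known limitations

* The consistency statistic loses power when most variants are either
  ubiquitous or private; it is reported with its full null distribution
  so that borderline calls are visible.
* Bulk heteroplasmy cannot resolve single-cell clonal structure; a
  variant shared by two populations is evidence about their *pools*, not
  about any individual cell.
* The image model has no optics (no PSF beyond the nuclear Gaussian, no
  spillover between metal channels); segmentation performance on real
  IMC data will be worse than on these fixtures.
* Per-image bimodal thresholds assume each informative channel is
  either clearly bimodal or uniformly one class within an image; panels
  with continuous expression gradients need `"absolute"` thresholds.
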