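# ssctrace

Lineage analysis of skeletal stem cell (SSC) hierarchies from somatic
mitochondrial DNA variants, multiplexed tissue images, and flow
cytometry — with a ground-truthed synthetic-data generator that makes
the whole pipeline testable.

## The scientific problem

The CD24+CD29+ SSC (immunophenotype Lin− THY− 6C3− CD200+ CD105−) is
thought to sit at the apex of a differentiation hierarchy that splits
into adipocyte-committed CD24+ SSCs and osteoblast-committed CD29+
SSCs, the latter maturing into CD105+, THY+, 6C3+ and THY+6C3+
derivatives. Testing that model *without transplantation* is possible in
mitochondrial-mutator mice: somatic mtDNA variants act as clonal
barcodes whose heteroplasmy drifts as cells divide, so the pattern of
variant sharing across FACS-sorted populations encodes the hierarchy.

`ssctrace` covers the three computational arms of such a study:

1. **mitotrace** — per-population mitochondrial allele counts →
   heteroplasmy (`af = alt/(ref+alt)`), five-rule high-confidence
   variant filtering with a per-rule audit trail, unsupervised
   hierarchical clustering of populations (distance `1 − Pearson` on
   `sqrt(af)`, average linkage), variant-sharing tables, and a
   *transmission consistency* score: the fraction of variants whose
   presence set (`af ≥ τ`) is a single subtree of a candidate
   hierarchy, tested against random relabelings of the tree.
2. **spatial** — nuclear-seeded watershed segmentation of multi-channel
   images, per-cell marker quantification, P1–P11 gating, and the
   likelihood that each type is the nearest neighbour of a P1
   (CD24+CD29+ SSC) cell per ROI, with a within-ROI label-permutation
   null (z-scores, empirical p).
3. **flowgate** — hierarchical gating of flow-cytometry event tables
   (asinh transform, Lin dump channel, the SSC backbone gates, CD24 ×
   CD29 quadrants) and bootstrap comparison of subset percentages
   across conditions.

A fourth module, the simulator, is first-class: heteroplasmy drifts by
Wright–Fisher resampling of `M` mtDNA copies per division
(`Var(h_t) = h0(1−h0)(1−(1−1/M)^t)` in closed form), new mutations
arrive at `Poisson(mu)` per cell division, populations descend through
explicit pedigrees with progenitor bottlenecks, and bulk capture
sequencing, flow mixtures and 13-channel images are emulated with full
ground truth. See the vignette (`vignettes/ssc-lineage-tracing.Rmd`)
for the models and every default.

## Worked example

```r
library(ssctrace)

sim <- simulate_clonal_hierarchy(sim_config(seed = 1))  # one simulated mouse
m   <- compute_heteroplasmy(sim$counts)
hi  <- filter_high_confidence(m, filter_params())
# 3008 raw variants -> 107 high-confidence

cluster_populations(hi)
#> <pop_dendrogram> 8 populations, pearson_sqrt / average linkage
#> (CD24+:0.316,((CD24+CD29+:0.127,CD24-CD29-:0.127):0.077,((CD105+:0.110,
#>  (6C3+:0.084,CD29+:0.084):0.026):0.062,(THY+:0.126,THY+6C3+:0.126):0.046)
#>  :0.031):0.113);

hierarchy_consistency(hi, default_ssc_hierarchy(), tau = 0.01,
                      R = 999, seed = 1)
#> <consistency_result> score 0.923 over 78 observed variants; p = 0.032
#>   vs 999 random relabelings

head(sharing_counts(variant_sharing(hi, tau = 0.01)), 3)
#>   populations                                                 class   n_variants
#> 1 6C3+|CD105+|CD24+|CD24+CD29+|CD24-CD29-|CD29+|THY+|THY+6C3+ shared           6
#> 2 CD24+                                                       private          6
#> 3 CD24+|CD24+CD29+|CD24-CD29-                                 shared           5
```

Reading: of 107 surviving variants, 78 are present somewhere at
`τ = 0.01`; 92% of their presence patterns are explainable by a single
origin inherited down the transplantation-determined tree, which beats
all but ~3% of random relabelings (p = 0.032). The clustering places
the maturing CD29+ branch (CD105+/THY+/6C3+ derivatives) in one clade,
and variants shared exactly by {CD24+CD29+, CD24+, CD24−CD29−} — the
root and its direct daughters — are among the most common sharing
patterns, the signature of clonal transmission from the stem
population.

Each result has `tidy()`/`glance()` methods and an `autoplot()`; the
spatial and flow arms work the same way (see the vignette).

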