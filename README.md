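# coreacc

Core and accessory components of soil-metagenome functional gene
diversity: partitioning, component-aware β-diversity, a null model of
community assembly, and the inferential statistics of blocked 2×2 field
experiments.

## The problem

Shotgun metagenomes annotate reads into gene families (COG/KO terms).
In a set of soil samples those families split into a **core** component —
families detected in *every* sample, carrying ~99.8% of annotation mass —
and an **accessory** component — families detected in only some samples,
carrying ~0.2% of mass but most of the richness variation. Because of
this asymmetry, abundance-based composition (Bray-Curtis on relative
abundances) is governed by core genes, while richness and
presence/absence structure are governed by accessory genes. Different
environmental-change factors can therefore act on different components:
in a steppe-grassland N × W (nitrogen × water) addition experiment,
N addition shifts core-gene relative abundances (an ammonia-oxidizer
bloom that also lowers average genome size), while W addition prunes
accessory genes (ecological filtering that lowers richness and raises
within-treatment similarity above random assembly).

`coreacc` implements this analysis for people working with gene-family ×
sample count matrices and blocked two-factor designs:

* rare-gene presence filtering (present iff count > 0 and
  count/total ≥ θ, default θ = 5×10⁻⁷);
* the core/accessory/absent partition with per-sample component
  summaries;
* richness, Bray-Curtis d(i,j) = 1 − 2Σ min(pᵢ, pⱼ)/(Σpᵢ + Σpⱼ),
  Sørensen 1 − 2a/(2a + b + c) on presence/absence, classical PCoA,
  and abundance-weighted average genome size AGS(s) = Σₜ pₜₛ·Gₜ;
* a Raup–Crick-style null model: fixed per-sample richness, genes drawn
  ∝ occupancy (or uniformly), standardized effect size
  SES = (obs − null mean)/null sd with permutation p-values;
* split-plot ANOVA with whole-plot (Block×N) and subplot error strata,
  single-factor PERMANOVA with optional within-block permutation, and
  Mantel tests — all implemented directly and verified against
  brute-force oracles and vegan;
* pooled 2×2 treatment-effect arithmetic for printed field tables;
* a calibrated synthetic community-metagenome generator with planted
  ground truth (`generate_community()`), used by the test suite to make
  every statistical claim checkable.

## Worked example

Simulate the default study (16 samples, 4 blocks, 4,647 planted core
genes, ~2×10⁶ annotations per sample) and run the full pipeline:

```r
library(coreacc)
res <- run_core_accessory_analysis(
  simulate = synthetic_config(seed = 42),
  null_cfg = null_model_config(999, seed = 42),
  n_perm = 999, seed = 42)
summary(res)
```

```
== Partition ==
Core/accessory partition (threshold 5e-07)
  core genes:      4647  (99.86% +/- 0.01% of annotations)
  accessory genes: 7107 in pool; 1294 +/- 47 per sample (0.14% of annotations)
  absent genes:    893

== Richness ANOVA ==
Split-plot ANOVA (whole plot: N within blocks; subplot: W)
     term df       ss        ms        F         p
    Block  3   1728.5    576.17   0.9182 5.271e-01
        N  1   8649.0   8649.00  13.7800 3.398e-02
  Block:N  3   1882.5    627.50   0.6911 5.900e-01
        W  1 501260.0 501260.00 552.1000 3.900e-07
      N:W  1   1681.0   1681.00   1.8510 2.225e-01
 Residual  6   5448.0    908.00       NA        NA

== PERMANOVA ==
  all       ~ N: pseudo-F =  1.975, p = 0.002
  all       ~ W: pseudo-F =  0.953, p = 0.621
  core      ~ N: pseudo-F =  1.999, p = 0.001
  core      ~ W: pseudo-F =  0.943, p = 0.666
  accessory ~ N: pseudo-F =  0.977, p = 0.581
  accessory ~ W: pseudo-F =  1.616, p = 0.001

== Mantel (functional vs taxonomic) ==
Mantel test: r = 0.544, p = 0.001 (999 permutations, greater tail)
```

Reading the output: the partition recovers exactly the planted 4,647
core genes at 99.86% collective relative abundance and ~1,294 accessory
genes per sample. W addition dominates richness (p ≈ 4×10⁻⁷; the
planted 6.1% drop) and the accessory presence/absence structure
(PERMANOVA p = 0.001), while N addition moves the all-gene and core-gene
Bray-Curtis composition (p ≤ 0.002) — each factor acting on its own
component. The null-model table (see `summary(res)` in full) shows the
+W treatments with SES well above the −W treatments: the shared loss of
accessory genes is deterministic filtering, not drift. Functional and
taxonomic β-diversity correlate (Mantel r = 0.544) because gene content
rides on taxa.

With real data, replace `simulate =` with `table = "genes.tsv"`,
`design = "design.tsv"` (genes × samples TSV; design columns
`sample_id, block, N, W`). `write_results(res, "out/")` writes distance
matrices, ordinations, per-sample tables, scalar statistics and an
md5 manifest; reruns with the same seeds are byte-identical.

## Package layout

* `R/gene_table.R`, `R/design.R` — validated I/O for count matrices,
  designs, covariates (TSV/CSV in, TSV/JSON out)
* `R/partition.R` — presence filter and core/accessory partition
* `R/diversity.R` — richness, Bray-Curtis, Sørensen, PCoA, AGS
* `R/null_model.R` — fixed-richness randomization, SES, between-factor
  comparison
* `R/stats.R` — split-plot ANOVA, PERMANOVA, Mantel
* `R/effects.R` — pooled 2×2 treatment effects; bundled field table in
  `inst/extdata/grassland_field_means.tsv`
* `R/simulate.R` — the synthetic generator and its calibrations
* `R/pipeline.R` — orchestration and result bundles
* `vignettes/core-accessory-methods.Rmd` — the methods vignette: model
  assumptions, parameter meanings and defaults, calibration details,
  numerical choices, and what synthetic validation does and does not
  show.
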