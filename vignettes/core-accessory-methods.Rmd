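---
title: "Partitioning metagenome functional diversity into core and accessory components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning metagenome functional diversity into core and accessory components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreacc)
```

## The scientific question

Shotgun metagenomes of soil communities annotate millions of reads into
gene families (COG or KO identifiers). Those families split naturally into
two components with very different statistical behaviour:

* **core community genes** — families detected in *every* sample of a
  study after rare-gene filtering. They are few relative to the pool of
  observed families but carry almost all annotation mass (~99.8% here),
  so abundance-based compositional variation (Bray-Curtis on relative
  abundances) is essentially a statement about core genes.
* **accessory community genes** — families detected in some but not all
  samples. They carry a sliver of mass (~0.2%) but dominate richness
  variation, so presence/absence structure is essentially a statement
  about accessory genes.

The package asks, for a blocked 2x2 field experiment (nitrogen addition N
as the whole-plot factor, water addition W as the subplot factor, four
blocks, sixteen samples): which factor acts on which component, and is the
assembly of the accessory component deterministic (environmental
filtering) or stochastic?

## The analysis pipeline

`run_core_accessory_analysis()` chains the steps; each is exported on its
own.

**Presence filtering** (`call_presence`). A gene is present in a sample
when its count is positive and its relative abundance (count over the
sample's full annotation total) reaches a threshold, by default
5e-7 — about one read at the ~2 million annotations per sample typical of
soil COG profiles. The comparison is inclusive, so the boundary case "one
confident hit in the smallest library" counts as present. The same
operation serves OTU tables (e.g. threshold 1/892). Filtering is
per-sample by default: a family can be present in one sample and
filtered-absent in another, which is what per-sample richness requires.
The order filter-then-partition is fixed; the threshold is exposed.

**Partition** (`partition_core_accessory`). Core = present everywhere;
accessory = present somewhere but not everywhere; absent = filtered out
everywhere. Component relative abundances always use the full sample
total as denominator, so the filtered-out tail mass is excluded from both
components but still dilutes them — this matches the convention under
which core + accessory collective abundances sum to just under 100%.

**Component diversity** (`richness`, `bray_curtis`,
`presence_dissimilarity`, `pcoa`). Bray-Curtis runs on relative
abundances over full totals (no renormalization within the core subset by
default; `renormalize = TRUE` exists, and at 99.8% core mass the
difference is numerically negligible). Presence/absence dissimilarity is
Bray-Curtis on 0/1 vectors, i.e. Sørensen; a sample with no presences in
the chosen subset gets dissimilarity 1 to everything and is flagged
rather than dropped. PCoA is classical scaling: double-centre −D²/2,
eigendecompose, scale eigenvectors by the square root of their
eigenvalues. Negative eigenvalues (usual for Bray-Curtis) are dropped
from both the coordinates and the explained-variance denominator with a
warning stating their magnitude; a Cailliez correction is available but
off by default, matching common practice for ordination displays.

**Average genome size** (`average_genome_size`). The abundance-weighted
mean genome length, weighted by *cell* (taxon) relative abundance. A
bloom of a small-genome guild — ammonia-oxidizing bacteria under N
addition — drags AGS down. Read-level AGS estimation is out of scope; the
function works from a taxon table with genome sizes, which the synthetic
generator provides as ground truth.

**Null model and SES** (`ses_similarity`). To separate deterministic
filtering from stochastic assembly we compare observed within-group
similarity (1 − Sørensen) with its distribution over randomized
assemblages that conserve each sample's richness exactly and draw genes
from the pool either proportionally to occupancy (default, the standard
Raup-Crick construction) or uniformly. The standardized effect size is
(observed − null mean)/null sd; p-values are two-sided with the (r+1)/(B+1)
correction so p = 0 is impossible. SES > 0 means groups are more
coherent than random assembly — ecological filtering.

Two methodological points discovered while validating the null model are
worth stating plainly:

* *Pool choice matters.* Drawing the null from only the genes observed
  somewhere (the usual practice when the candidate pool is unknown)
  shrinks the pool and inflates null similarity, biasing SES downward.
  When the candidate universe is known — as for COG families — the
  presence matrix should retain undetected families as all-FALSE rows;
  the uniform null then coincides exactly with the conditional law of
  exchangeable assembly given richness, and its type-I error is nominal.
* *Occupancy weighting conditions on occupancy heterogeneity.* Under it,
  marginal differences in how widespread genes are become part of the
  null rather than part of the signal. Against a truly exchangeable
  community it is anti-conservative; against real data it asks a sharper
  question ("is there group structure beyond occupancy heterogeneity?").
  Both weightings are in `null_model_config` so the choice is auditable;
  calibration statements in the tests use the uniform null under the
  generator's exchangeable neutral mode, and power statements use the
  default occupancy weighting under the planted-effect mode.

Between-factor comparison of SES (`compare_ses_between_factors`) feeds
*per-sample* SES values (each sample's mean over the pair-level SES of
its within-group pairs) to the split-plot ANOVA. Pair-level values would
pseudo-replicate (pairs within a group share samples); group-level values
would leave no residual degrees of freedom in a 2x2 design.

**Inference** (`split_plot_anova`, `permanova`, `mantel`). The split-plot
ANOVA uses the balanced decomposition with the whole-plot error stratum
Block x N for Block and N, and the subplot residual for W and N x W;
degrees of freedom are (b−1, 1, b−1, 1, 1, 2b−2). Testing Block against
Block x N is a reporting convention (both terms appear in field-study
tables) and is labelled as such in the result's `error_terms` attribute.
F-distribution p-values are used, matching standard practice for such
tables. PERMANOVA is the direct distance partition (pseudo-F from
within/between squared distances) with free permutations by default and
within-block restriction via `strata`; the field-study-style analysis
runs one factor at a time. The Mantel test correlates upper triangles with
simultaneous row/column permutation of the second matrix, one-tailed
(positive association) by default.

## The synthetic community generator

`generate_community()` is first-class, tested code: it defines the study
conditions under which the package's statistical claims are made, and its
ground truth (`synthetic_truth`) is what recovery tests check against.

The model is taxon-mediated: all spatial and treatment structure lives at
the taxon level and propagates to gene families through carriage.

1. A community of 60 taxa: one small-genome AOB-like guild (2.8 Mb) and
   59 background taxa with lognormal baseline shares, per-block lognormal
   effects (sd 0.15), per-sample jitter (sd 0.05), and — when a W
   mechanism is planted — a shared lognormal W response (sd 0.10).
2. 4,647 core families carrying 99.83% of expected mass, lognormal across
   families (sd 0.7), each carried by every background taxon with
   lognormal carriage weights (sd 0.7). The AOB guild carries a subset of
   1,800 core families and no accessory families.
3. 8,000 candidate accessory families, each specific to one host taxon
   and planted independently per sample; abundances sit near the
   detection limit, as in real data, so presence is detection-thinned.
4. N effect: the AOB guild is multiplied 11.2-fold in +N samples, which
   shifts core relative abundances and lowers AGS.
5. W effect: one random subset of the accessory pool — shared by all +W
   samples — is zeroed (deterministic ecological filtering; the shared
   loss is what pushes within-group similarity above the null).
6. Counts are multinomial at exactly 2e6 annotations per sample, the
   depth at which the 5e-7 filter equals one read. At deeper simulated
   libraries the filter needs two reads and the 0.17% accessory mass
   budget cannot sustain ~1,300 detected accessory families — the
   generator refuses such configurations with an explanatory error
   rather than silently missing its targets.

Three calibrations run at generation time, with their inputs in the
config and their outputs in the emitted truth record:

* the W removal fraction and pre-pruning accessory richness solve, in
  closed form, for a grand mean of 1,317 detected accessory families and
  a 6.1% drop in total richness under W (removal fraction ~0.249 of the
  pool at the defaults — note 6.1% of *total* richness is ~28% of
  *accessory* richness);
* the accessory abundance lognormal location and the planting probability
  solve jointly, by quadrature and root finding, the detection-thinned
  richness target and the 0.17% mass budget;
* the AOB baseline share (~0.39%) solves the AGS pair 5.93 → 5.81 Mb for
  an 11.2-fold bloom.

The gene-level annotation noise (lognormal sd 0.08 per cell) is the one
free dispersion the sources do not pin down; it was set so that
functional and taxonomic Bray-Curtis matrices couple at the strength
observed in field data (Mantel r ≈ 0.6), and left alone thereafter.

What the generator does *not* emulate: read-level sequencing (no
sequences, no mapping errors), unequal library sizes, relic DNA,
phylogenetic structure among taxa, and covariance between accessory
carriage and genome size. Tests passing on synthetic data therefore
demonstrate the *statistical machinery* — recovery of planted partitions,
calibration and power of the null model, correctness of the inference —
not the biological fidelity of any particular field system.

`generate_covariates()` draws soil/plant covariates (SOM, pH, moisture,
respiration, ammonia-oxidation potential, ...) from the bundled
field-means table: cell mean plus Gaussian noise scaled from the printed
standard errors. At zero noise the pooled-effect arithmetic recovers the
configured contrasts identically.

## Pooled treatment effects

`pooled_effect()` reproduces the arithmetic used to summarise 2x2 field
tables in prose: the factor's effect is the unweighted mean of the two
cells with the factor minus the mean of the two cells without it
(balanced replication makes unweighted pooling exact), reported as
percent change, absolute difference and fold change. Rounding for
display is half-up, matching how such tables are printed. One published
prose value (available soil N, "+36.6%") is inconsistent with its own
table's pooled means (+57.7%) and is deliberately not asserted anywhere.

## Numerical choices and degenerate inputs

* Counts are integers; relative abundances are always derived on demand.
  Missing cells are errors, never zeros.
* Distance matrices are symmetrized to machine precision with exact zero
  diagonals; Sørensen on two empty gene sets is defined as dissimilarity 1
  and flagged.
* A constant ANOVA response reports SS = 0 and F = NaN with a degenerate
  flag instead of failing; an exact single-term contrast reports F = Inf,
  p = 0.
* Permutation p-values always use the +1 correction; every permutation
  and simulation stream derives from a named hash of the master seed, so
  any component can be reproduced in isolation and whole-pipeline reruns
  are byte-identical.
* Weighted sampling without replacement uses exponential keys
  (Efraimidis-Spirakis), which is exact and O(pool size) per draw.

## Problem sizes used in the tests

Oracle-equivalence tests run on more than a hundred random small
instances (4-10 samples); null-model calibration and power statements use
200 replicate communities at a reduced scale (300 core + 900 accessory
families, 1.2e5 annotations per sample, 25 taxa) chosen to preserve the
detection-limit regime of the full design; generator-recovery statements
run 20 replicates at the full default scale. These sizes are the
package's validation design; rerunning with larger replication only
tightens the Monte-Carlo bands.

## Known limitations

* The null model fills samples independently; it conserves per-sample
  richness exactly and occupancy only in expectation (no curveball/swap
  algorithms preserving both margins exactly).
* PERMANOVA is single-factor (with optional strata), run per factor, not
  a joint two-factor partition.
* The split-plot ANOVA requires a complete balanced design; there is no
  Type-III fallback for missing plots.
* Average genome size weighting is by cell abundance; base-pair-share
  weighting (closer to what read-sampling estimators measure) would give
  slightly different values.
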