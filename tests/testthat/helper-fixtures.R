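# Fixture builders used across test files.

toy_counts <- function() {
  matrix(c(1L, 0L, 4L, 2L, 3L, 0L), nrow = 3,
         dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
}

# complete 2x2 design over b blocks, sample ids B<i>_<trt>
make_design <- function(b = 4L) {
  trt <- c("C", "W", "N", "NW")
  experimental_design(
    sample_id = paste0(rep(paste0("B", seq_len(b)), each = 4L), "_",
                       rep(trt, b)),
    block = rep(paste0("B", seq_len(b)), each = 4L),
    n_treatment = rep(c(FALSE, FALSE, TRUE, TRUE), b),
    w_treatment = rep(c(FALSE, TRUE, FALSE, TRUE), b))
}

treatment_labels <- function(design) {
  ifelse(design$n_treatment & design$w_treatment, "NW",
         ifelse(design$n_treatment, "N",
                ifelse(design$w_treatment, "W", "control")))
}

# random gene table for property tests
random_table <- function(n_genes = 20L, n_samples = 5L, depth = 500L) {
  m <- matrix(rpois(n_genes * n_samples, 5), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  gene_table(m)
}

# small, fast synthetic configuration used by calibration-style tests;
# scaled-down analogue of the default study conditions
small_config <- function(seed, ...) {
  synthetic_config(n_core_genes = 300L, n_accessory_pool = 900L,
                   accessory_mean_target = 150, depth_per_sample = 1.2e5,
                   n_taxa = 25L, seed = seed, ...)
}

# neutral assembly: no treatment mechanisms and no planted heterogeneity,
# so gene sets are exchangeable and the uniform fixed-richness null is the
# exact conditional law of the data given richness
neutral_config <- function(seed) {
  small_config(seed, n_effect_strength = 1, w_richness_drop = 0,
               accessory_sigma = 0, block_sd = 0, taxon_jitter_sd = 0)
}

accessory_presence_of <- function(sim) {
  pres <- call_presence(sim$table, 5e-7)
  part <- partition_core_accessory(pres, sim$table)
  component_tables(sim$table, part)$accessory_presence
}

# presence over the full planted accessory pool, keeping genes detected in
# no sample as all-FALSE rows: with the candidate gene universe known (as
# for COG family annotations), the uniform fixed-richness null should draw
# from the whole pool, which makes it the exact conditional law of
# exchangeable assembly given per-sample richness
accessory_pool_presence_of <- function(sim) {
  pres <- call_presence(sim$table, 5e-7)
  m <- unclass(pres)[sim$truth$accessory_pool, , drop = FALSE]
  as_presence_matrix(m, attr(pres, "threshold"))
}
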