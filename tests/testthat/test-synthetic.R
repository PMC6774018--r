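test_that("emitted counts are multinomial at exact depth and reproducible", {
  cfg <- small_config(5)
  sim <- generate_community(cfg)
  expect_true(all(colSums(sim$table) == cfg$depth_per_sample))
  expect_identical(dim(sim$table),
                   c(cfg$n_core_genes + cfg$n_accessory_pool, 16L))
  sim2 <- generate_community(small_config(5))
  expect_identical(unclass(sim$table)[, ], unclass(sim2$table)[, ])
  expect_identical(sim$taxa$relabund, sim2$taxa$relabund)
  # a different seed changes the data
  sim3 <- generate_community(small_config(6))
  expect_false(identical(unclass(sim$table)[, ], unclass(sim3$table)[, ]))
})

test_that("emitted counts are consistent with the planted truth", {
  sim <- generate_community(small_config(7))
  counts <- unclass(sim$table)
  acc <- counts[sim$truth$accessory_pool, ]
  # no accessory counts where the gene was not planted
  expect_true(all(acc[!sim$truth$planted_presence] == 0L))
  # W-removed genes have zero counts in every +W sample
  wcols <- sim$design$w_treatment
  expect_true(all(acc[sim$truth$w_removed_genes, wcols] == 0L))
  # core genes are planted everywhere and deeply covered
  expect_true(all(counts[sim$truth$core_genes, ] >= 0L))
  expect_gt(min(colSums(counts[sim$truth$core_genes, ])),
            0.99 * small_config(7)$depth_per_sample)
})

test_that("partition of the emitted table recovers the planted core set", {
  sim <- generate_community(small_config(11))
  part <- partition_core_accessory(call_presence(sim$table, 5e-7), sim$table)
  expect_identical(part$core_genes, sort(sim$truth$core_genes))
})

test_that("calibration hits richness, mass and pruning targets", {
  cfg <- small_config(13)
  sim <- generate_community(cfg)
  pres <- call_presence(sim$table, cfg$presence_threshold)
  part <- partition_core_accessory(pres, sim$table)
  # grand-mean accessory richness near the configured target
  expect_lt(abs(mean(part$accessory_count) - cfg$accessory_mean_target),
            0.15 * cfg$accessory_mean_target)
  # core collective mass near the configured fraction
  expect_lt(abs(mean(part$core_relabund) - cfg$core_mass_fraction), 0.002)
  # +W vs -W richness contrast near the planted drop
  r <- richness(pres)
  w <- sim$design$w_treatment
  drop <- 1 - mean(r[w]) / mean(r[!w])
  expect_lt(abs(drop - cfg$w_richness_drop), 0.025)
  # the removal fraction solves the two calibration constraints
  cal <- sim$truth$calibration
  A <- cal$baseline_accessory_richness
  expect_equal((A + A * (1 - cal$removal_fraction)) / 2,
               cfg$accessory_mean_target, tolerance = 1e-9)
  expect_equal(A * cal$removal_fraction / (cfg$n_core_genes + A),
               cfg$w_richness_drop, tolerance = 1e-9)
})

test_that("average genome size contrast follows the planted AOB bloom", {
  cfg <- small_config(17)
  sim <- generate_community(cfg)
  ags <- average_genome_size(sim$taxa$relabund, sim$taxa$genome_sizes)
  nn <- sim$design$n_treatment
  # at this reduced community size (25 taxa) block/jitter fluctuations leave
  # more noise on the level than at the default 60-taxon scale
  expect_lt(abs(mean(ags[!nn]) - cfg$ags_minus_n), 0.15e6)
  expect_lt(abs(mean(ags[nn]) - cfg$ags_plus_n), 0.15e6)
  contrast <- mean(ags[!nn]) - mean(ags[nn])
  expect_gt(contrast, 0.04e6)
  expect_lt(contrast, 0.20e6)
  # a stronger bloom lowers +N AGS further (monotonicity in effect strength)
  strong <- generate_community(small_config(17, n_effect_strength = 30))
  ags_s <- average_genome_size(strong$taxa$relabund, strong$taxa$genome_sizes)
  expect_lt(mean(ags_s[nn]), mean(ags[nn]))
  # AOB-carried core genes gain relative abundance under +N
  p <- rel_abundance(sim$table, genes = sim$truth$aob_gene_ids)
  expect_gt(mean(colSums(p)[nn]), mean(colSums(p)[!nn]))
})

test_that("neutral mode makes the treatment groups exchangeable", {
  # with no planted mechanisms the richness ANOVA treatment p-values are
  # uniform across replicate communities
  pv <- t(sapply(1:60, function(sd) {
    sim <- generate_community(small_config(sd, n_effect_strength = 1,
                                           w_richness_drop = 0))
    r <- richness(call_presence(sim$table, 5e-7))
    fit <- split_plot_anova(r, sim$design)
    c(W = fit$p[fit$term == "W"], N = fit$p[fit$term == "N"],
      NW = fit$p[fit$term == "N:W"])
  }))
  for (cn in colnames(pv)) {
    expect_gt(suppressWarnings(ks.test(pv[, cn], "punif"))$p.value, 0.005)
  }
})

test_that("covariates mirror the field table and are exact at zero noise", {
  cfg <- small_config(19)
  design <- make_design(4L)
  cov0 <- generate_covariates(cfg, design, noise_scale = 0)
  tab <- grassland_field_means()
  som_row <- tab[tab$index_name == "SOM content", , drop = FALSE]
  class(som_row) <- c("treatment_means", "data.frame")
  target <- pooled_effect(som_row, "N")$percent_change
  plus <- mean(cov0$som[design$n_treatment])
  minus <- mean(cov0$som[!design$n_treatment])
  expect_equal(100 * (plus - minus) / minus, target, tolerance = 1e-9)
  # deterministic given the seed
  cov1 <- generate_covariates(cfg, design)
  cov2 <- generate_covariates(cfg, design)
  expect_identical(cov1, cov2)
  expect_false(identical(cov1, generate_covariates(small_config(20), design)))
})

test_that("infeasible accessory targets are rejected with guidance", {
  # at a depth needing >= 2 counts for presence, a 0.17% mass budget cannot
  # sustain this many detected accessory genes
  cfg <- synthetic_config(n_core_genes = 4647, n_accessory_pool = 2000,
                          accessory_mean_target = 1500,
                          depth_per_sample = 2.3e6, seed = 1)
  expect_error(generate_community(cfg), "pool too small|infeasible")
})
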