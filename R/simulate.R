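#' Configuration for the synthetic community-metagenome generator
#'
#' Defaults emulate the study conditions of a blocked 2x2 nitrogen x water
#' addition field experiment on steppe soil: 16 samples (4 blocks), 4,647
#' core genes carrying 99.83\% of annotation mass, a grand mean of 1,317
#' detected accessory genes per sample at ~0.17\% collective mass, ~2e6
#' COG annotations per sample, an 11.2-fold bloom of a small-genome
#' ammonia-oxidizer-like (AOB) guild under N, and a deterministic loss of
#' accessory genes under W sized to depress total gene richness by 6.1\%.
#'
#' Three quantities are calibrated at generation time rather than fixed:
#' (i) the accessory removal fraction under W and the pre-pruning baseline
#' accessory richness, in closed form from \code{accessory_mean_target} and
#' \code{w_richness_drop}; (ii) the accessory abundance lognormal location,
#' by root finding so that the detection-thinned richness and the mass
#' budget are met simultaneously at the configured depth and filter
#' threshold; (iii) the AOB guild's baseline share, by root finding from
#' the average-genome-size targets.
#'
#' @param n_blocks number of blocks (default 4).
#' @param n_core_genes planted core genes (default 4647).
#' @param n_accessory_pool accessory gene pool size (default 8000).
#' @param accessory_mean_target target grand mean of detected accessory
#'   genes per sample across all samples (default 1317).
#' @param core_mass_fraction expected share of annotation mass carried by
#'   core genes (default 0.9983).
#' @param depth_per_sample annotations per sample (default 2e6).
#' @param presence_threshold relative-abundance presence filter (5e-7).
#' @param n_effect_strength fold-increase of the AOB-like guild under N
#'   (default 11.2).
#' @param w_richness_drop planted fractional drop in total gene richness
#'   under W (default 0.061); the accessory genes removed are a single
#'   random pool subset shared by all +W samples (ecological filtering).
#' @param core_sigma,accessory_sigma lognormal sd (log scale) of gene
#'   abundances within each component.
#' @param block_sd lognormal sd of per-block multiplicative effects on
#'   taxon abundances (spatial heterogeneity; propagates to the genes each
#'   taxon carries).
#' @param noise_sd lognormal sd of per-cell gene-level noise (annotation
#'   and counting noise independent of community structure); the default is
#'   calibrated so that functional and taxonomic beta-diversity couple at
#'   the strength observed in field communities (Mantel r ~ 0.6).
#' @param carrier_sd lognormal sd of per-taxon carriage weights of core
#'   gene families (how unevenly a universal family is spread over taxa).
#' @param n_taxa community taxa in the taxon table (default 60).
#' @param genome_size_range range of background genome sizes in bases.
#' @param aob_genome_size AOB-like guild genome size (default 2.8e6 b).
#' @param aob_core_genes number of core genes carried by the AOB guild.
#' @param ags_minus_n,ags_plus_n average genome size targets (bases) under
#'   -N and +N (defaults 5.93e6, 5.81e6).
#' @param taxon_jitter_sd lognormal sd of per-sample taxon jitter.
#' @param w_taxon_sd sd of the shared log-effect of W on background taxa
#'   (applied only when \code{w_richness_drop > 0}: the neutral mode
#'   \code{w_richness_drop = 0, n_effect_strength = 1} disables every
#'   treatment mechanism so the four groups are exchangeable).
#' @param seed master seed; every component draws from a named substream.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_blocks = 4L,
                             n_core_genes = 4647L,
                             n_accessory_pool = 8000L,
                             accessory_mean_target = 1317,
                             core_mass_fraction = 0.9983,
                             depth_per_sample = 2e6,
                             presence_threshold = 5e-7,
                             n_effect_strength = 11.2,
                             w_richness_drop = 0.061,
                             core_sigma = 0.7,
                             accessory_sigma = 0.75,
                             block_sd = 0.15,
                             noise_sd = 0.08,
                             carrier_sd = 0.7,
                             n_taxa = 60L,
                             genome_size_range = c(2e6, 9e6),
                             aob_genome_size = 2.8e6,
                             aob_core_genes = 1800L,
                             ags_minus_n = 5.93e6,
                             ags_plus_n = 5.81e6,
                             taxon_jitter_sd = 0.05,
                             w_taxon_sd = 0.10,
                             seed = 1L) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              n_core_genes = as.integer(n_core_genes),
              n_accessory_pool = as.integer(n_accessory_pool),
              accessory_mean_target = accessory_mean_target,
              core_mass_fraction = core_mass_fraction,
              depth_per_sample = depth_per_sample,
              presence_threshold = presence_threshold,
              n_effect_strength = n_effect_strength,
              w_richness_drop = w_richness_drop,
              core_sigma = core_sigma, accessory_sigma = accessory_sigma,
              block_sd = block_sd, noise_sd = noise_sd,
              carrier_sd = carrier_sd,
              n_taxa = as.integer(n_taxa),
              genome_size_range = genome_size_range,
              aob_genome_size = aob_genome_size,
              aob_core_genes = as.integer(aob_core_genes),
              ags_minus_n = ags_minus_n, ags_plus_n = ags_plus_n,
              taxon_jitter_sd = taxon_jitter_sd, w_taxon_sd = w_taxon_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_blocks >= 1L, cfg$n_core_genes >= 1L,
            cfg$n_accessory_pool >= 1L,
            cfg$core_mass_fraction > 0, cfg$core_mass_fraction < 1,
            cfg$w_richness_drop >= 0, cfg$w_richness_drop < 1,
            cfg$n_effect_strength >= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

# Closed-form accessory pruning calibration.
# Let T = target grand mean of detected accessory richness, D = fractional
# total-richness drop under W, C = core count. With baseline (pre-pruning)
# richness A and removal fraction r applied to half the samples:
#   (A + A(1-r))/2 = T  and  A r = D (C + A)
# give r = 2 D (C + T) / (2 T + D C), A = 2 T / (2 - r).
accessory_pruning <- function(cfg) {
  T <- cfg$accessory_mean_target; D <- cfg$w_richness_drop
  C <- cfg$n_core_genes
  if (D == 0) return(list(removal_fraction = 0, baseline_richness = T))
  r <- 2 * D * (C + T) / (2 * T + D * C)
  if (r >= 1) stop_ca("w_richness_drop %.3g is too large for the accessory targets", D)
  list(removal_fraction = r, baseline_richness = 2 * T / (2 - r))
}

# Detection-aware accessory abundance calibration.
# Accessory relative abundances are lognormal(mu, sigma); a planted gene is
# detected when its count reaches the presence filter. Poisson-approximate
# detection, integrating over the lognormal and over the block/cell
# multiplier noise, gives E[p_det] and E[x]; mu solves
#   E[p_det] / E[x] = baseline_richness / accessory_mass
# and the per-sample planting probability follows from the mass budget.
accessory_abundance_calibration <- function(cfg, baseline_richness) {
  mass <- 1 - cfg$core_mass_fraction
  depth <- cfg$depth_per_sample
  c_thr <- ceiling(cfg$presence_threshold * depth - 1e-9)
  z <- seq(-4.5, 4.5, length.out = 181L)
  wz <- stats::dnorm(z); wz <- wz / sum(wz)
  # accessory genes are taxon-hosted: their counts fluctuate with the host
  # taxon (block + jitter) plus gene-level noise
  s_m <- sqrt(cfg$block_sd^2 + cfg$noise_sd^2 + cfg$taxon_jitter_sd^2)
  zm <- seq(-4, 4, length.out = 41L)
  wm <- stats::dnorm(zm); wm <- wm / sum(wm)
  mult <- exp(s_m * zm) / sum(wm * exp(s_m * zm))  # mean-one multiplier
  expectations <- function(mu) {
    lam0 <- exp(mu + cfg$accessory_sigma * z)      # expected counts, base
    pdet <- numeric(length(lam0))
    for (j in seq_along(zm)) {
      pdet <- pdet + wm[j] * stats::ppois(c_thr - 1L, lam0 * mult[j],
                                          lower.tail = FALSE)
    }
    c(p_det = sum(wz * pdet), lambda = sum(wz * lam0))
  }
  target <- baseline_richness / (mass * depth)
  f <- function(mu) { e <- expectations(mu); e[["p_det"]] / e[["lambda"]] - target }
  lo <- log(1e-3); hi <- log(50)
  if (f(lo) < 0) {
    stop_ca(paste0("accessory richness target %.0f is infeasible at depth %.3g ",
                   "with mass budget %.4f and threshold %g: lower the target ",
                   "or the depth"),
            baseline_richness, depth, mass, cfg$presence_threshold)
  }
  mu <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  e <- expectations(mu)
  planting_prob <- mass * depth / (cfg$n_accessory_pool * e[["lambda"]])
  if (planting_prob > 1) {
    stop_ca("accessory pool too small: planting probability %.3f > 1", planting_prob)
  }
  list(mu = mu, sigma = cfg$accessory_sigma,
       mean_lambda = e[["lambda"]], mean_p_det = e[["p_det"]],
       planting_prob = planting_prob, detection_count = c_thr)
}

# AOB share calibration from average-genome-size targets.
# With guild genome G_A, bloom factor k, baseline cell share a and
# background AGS B: a G_A + (1-a) B = AGS-; after the bloom the share is
# a' = k a / (1 + (k-1) a) and a' G_A + (1-a') B = AGS+.
aob_share_calibration <- function(cfg) {
  GA <- cfg$aob_genome_size; k <- cfg$n_effect_strength
  if (k == 1) {
    return(list(share = 0.004, background_ags = cfg$ags_minus_n))
  }
  g <- function(a) {
    B <- (cfg$ags_minus_n - a * GA) / (1 - a)
    ap <- k * a / (1 + (k - 1) * a)
    ap * GA + (1 - ap) * B - cfg$ags_plus_n
  }
  a <- uniroot(g, c(1e-6, 0.5), tol = 1e-12)$root
  list(share = a, background_ags = (cfg$ags_minus_n - a * GA) / (1 - a))
}

#' Generate a synthetic community metagenome with planted ground truth
#'
#' Emits a gene abundance table, the split-plot design, a per-sample taxon
#' relative-abundance table with genome sizes, and a \code{synthetic_truth}
#' record of everything that was planted. Mechanisms:
#' \enumerate{
#'   \item core genes share \code{core_mass_fraction} of expected mass
#'     (lognormal across genes) and are planted in every sample;
#'   \item accessory genes are planted independently per sample at a
#'     calibrated probability, with lognormal abundances near the
#'     detection limit (presence is detection-thinned, as in real shotgun
#'     data);
#'   \item gene content rides on taxa: core families are carried by every
#'     background taxon with lognormal carriage weights, accessory families
#'     are specific to a single host taxon, and per-block and per-sample
#'     taxon fluctuations propagate to the families each taxon carries --
#'     so functional and taxonomic beta-diversity are coupled, as in real
#'     communities;
#'   \item N effect: an AOB-like guild carrying only core genes is
#'     multiplied by \code{n_effect_strength} in +N samples, shifting core
#'     relative abundances and lowering average genome size;
#'   \item W effect: one shared random subset of the accessory pool is
#'     zeroed in every +W sample (deterministic ecological filtering; the
#'     shared loss raises within-group similarity above the null), and
#'     background taxa receive a shared lognormal W response;
#'   \item gene-level lognormal annotation noise; counts drawn
#'     multinomially at \code{depth_per_sample} (column sums exact).
#' }
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return A list of class \code{synthetic_community} with elements
#'   \code{table} (\code{gene_table}), \code{design}
#'   (\code{experimental_design}), \code{taxa} (list: \code{relabund}
#'   matrix, \code{genome_sizes}, \code{aob_taxon}), and \code{truth}
#'   (class \code{synthetic_truth}).
#' @export
generate_community <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  b <- cfg$n_blocks
  trt <- data.frame(code = c("C", "W", "N", "NW"),
                    n = c(FALSE, FALSE, TRUE, TRUE),
                    w = c(FALSE, TRUE, FALSE, TRUE))
  design <- experimental_design(
    sample_id = paste0(rep(paste0("B", seq_len(b)), each = 4L), "_",
                       rep(trt$code, times = b)),
    block = rep(paste0("B", seq_len(b)), each = 4L),
    n_treatment = rep(trt$n, times = b),
    w_treatment = rep(trt$w, times = b))
  n_samp <- nrow(design)
  ids_core <- sprintf("COG_C%05d", seq_len(cfg$n_core_genes))
  ids_acc <- sprintf("COG_A%05d", seq_len(cfg$n_accessory_pool))

  prune <- accessory_pruning(cfg)
  acal <- accessory_abundance_calibration(cfg, prune$baseline_richness)
  aob <- aob_share_calibration(cfg)

  # core expected mass profile, with the AOB guild layered on a subset
  core_base <- with_stream(cfg$seed, "core-abund",
                           rlnorm(cfg$n_core_genes, 0, cfg$core_sigma))
  core_base <- core_base / sum(core_base)
  aob_idx <- with_stream(cfg$seed, "aob-subset",
                         sort(sample.int(cfg$n_core_genes,
                                         min(cfg$aob_core_genes, cfg$n_core_genes))))
  aob_profile <- numeric(cfg$n_core_genes)
  aob_profile[aob_idx] <- core_base[aob_idx] / sum(core_base[aob_idx])
  a <- aob$share
  k <- cfg$n_effect_strength

  # taxa first: all block/treatment/sample structure lives at taxon level
  taxa <- generate_taxa(cfg, design, aob)
  # relative fluctuation of each background taxon around its baseline share
  R_bg <- sweep(taxa$bg_unnorm, 1L, taxa$bg_base, "/")
  R_aob <- taxa$aob_abundance / a

  # core families: carriage weights over background taxa (rows renormalized
  # so the baseline profile is exactly core_base)
  n_bg <- cfg$n_taxa - 1L
  carriers <- with_stream(cfg$seed, "core-carriers",
                          matrix(rlnorm(cfg$n_core_genes * n_bg, 0, cfg$carrier_sd),
                                 cfg$n_core_genes, n_bg))
  carriers <- carriers * rep(taxa$bg_base, each = cfg$n_core_genes)
  carriers <- carriers / rowSums(carriers) * core_base
  core_bg <- carriers %*% R_bg   # genes x samples, baseline rowMeans ~ core_base

  # accessory families: one host taxon each, planted per sample, with
  # abundances calibrated against the detection limit
  planted <- with_stream(cfg$seed, "accessory-occupancy",
                         matrix(runif(cfg$n_accessory_pool * n_samp) < acal$planting_prob,
                                cfg$n_accessory_pool, n_samp))
  acc_relab <- with_stream(cfg$seed, "accessory-abund",
                           exp(acal$mu + acal$sigma * rnorm(cfg$n_accessory_pool))) /
    cfg$depth_per_sample
  hosts <- with_stream(cfg$seed, "accessory-hosts",
                       sample.int(n_bg, cfg$n_accessory_pool, replace = TRUE,
                                  prob = taxa$bg_base))
  n_removed <- round(prune$removal_fraction * cfg$n_accessory_pool)
  w_subset <- with_stream(cfg$seed, "w-subset",
                          sort(sample.int(cfg$n_accessory_pool, n_removed)))
  planted[w_subset, design$w_treatment] <- FALSE

  n_genes <- cfg$n_core_genes + cfg$n_accessory_pool
  noise <- with_stream(cfg$seed, "noise",
                       matrix(exp(rnorm(n_genes * n_samp, 0, cfg$noise_sd)),
                              n_genes, n_samp))

  counts <- matrix(0L, n_genes, n_samp,
                   dimnames = list(c(ids_core, ids_acc), design$sample_id))
  expected <- matrix(0, n_genes, n_samp)
  for (s in seq_len(n_samp)) {
    core_mass <- cfg$core_mass_fraction *
      ((1 - a) * core_bg[, s] + a * R_aob[s] * aob_profile)
    acc_mass <- acc_relab * planted[, s] * R_bg[hosts, s]
    mass <- c(core_mass, acc_mass) * noise[, s]
    p <- mass / sum(mass)
    expected[, s] <- p
    counts[, s] <- with_stream(cfg$seed, paste0("counts-", design$sample_id[s]),
                               rmultinom(1L, cfg$depth_per_sample, p)[, 1L])
  }
  table <- gene_table(counts)

  truth <- structure(list(
    core_genes = ids_core,
    accessory_pool = ids_acc,
    planted_presence = structure(planted, dimnames = list(ids_acc, design$sample_id)),
    w_removed_genes = ids_acc[w_subset],
    accessory_hosts = structure(hosts, names = ids_acc),
    aob_gene_ids = ids_core[aob_idx],
    aob_baseline_share = a,
    aob_abundance = taxa$aob_abundance,
    expected_relabund = structure(expected,
                                  dimnames = list(c(ids_core, ids_acc),
                                                  design$sample_id)),
    calibration = list(removal_fraction = prune$removal_fraction,
                       baseline_accessory_richness = prune$baseline_richness,
                       accessory_mu = acal$mu,
                       accessory_planting_prob = acal$planting_prob,
                       mean_detection_prob = acal$mean_p_det,
                       detection_count = acal$detection_count,
                       background_ags = aob$background_ags),
    config = cfg), class = "synthetic_truth")

  structure(list(table = table, design = design,
                 taxa = taxa[c("relabund", "genome_sizes", "aob_taxon")],
                 truth = truth),
            class = "synthetic_community")
}

# Taxon table: AOB-like guild plus lognormal background taxa. All spatial
# and treatment structure is taxon-level: per-block lognormal effects,
# per-sample jitter, a shared W log-effect on background taxa (only when a
# W mechanism is planted), and the N bloom on the AOB guild. Genome sizes
# are shifted so the baseline abundance-weighted mean hits the calibrated
# background AGS.
generate_taxa <- function(cfg, design, aob) {
  n_bg <- cfg$n_taxa - 1L
  n_samp <- nrow(design)
  b <- nlevels(design$block)
  base <- with_stream(cfg$seed, "taxa-base", rlnorm(n_bg, 0, 1))
  base <- base / sum(base) * (1 - aob$share)
  sizes <- with_stream(cfg$seed, "taxa-genomes",
                       runif(n_bg, cfg$genome_size_range[1L], cfg$genome_size_range[2L]))
  sizes <- sizes + (aob$background_ags - sum(base * sizes) / (1 - aob$share))
  w_eff <- if (cfg$w_richness_drop > 0) {
    with_stream(cfg$seed, "taxa-w-effect", rnorm(n_bg, 0, cfg$w_taxon_sd))
  } else rep(0, n_bg)
  block_eff <- with_stream(cfg$seed, "taxa-block",
                           matrix(exp(rnorm((n_bg + 1L) * b, 0, cfg$block_sd)),
                                  n_bg + 1L, b))
  jitter <- with_stream(cfg$seed, "taxa-jitter",
                        matrix(exp(rnorm((n_bg + 1L) * n_samp, 0, cfg$taxon_jitter_sd)),
                               n_bg + 1L, n_samp))
  a <- aob$share
  k <- cfg$n_effect_strength
  blk_i <- as.integer(design$block)
  abund <- matrix(0, n_bg + 1L, n_samp)
  for (s in seq_len(n_samp)) {
    bg <- base * exp(if (design$w_treatment[s]) w_eff else rep(0, n_bg))
    ao <- a * (if (design$n_treatment[s]) k else 1)
    abund[, s] <- c(ao, bg) * block_eff[, blk_i[s]] * jitter[, s]
  }
  relab <- sweep(abund, 2L, colSums(abund), "/")
  taxon_ids <- c("AOB_guild", sprintf("taxon%03d", seq_len(n_bg)))
  dimnames(relab) <- list(taxon_ids, design$sample_id)
  dimnames(abund) <- list(taxon_ids, design$sample_id)
  gs <- c(cfg$aob_genome_size, sizes)
  names(gs) <- taxon_ids
  list(relabund = relab, genome_sizes = gs, aob_taxon = "AOB_guild",
       aob_abundance = structure(abund[1L, ], names = design$sample_id),
       bg_unnorm = abund[-1L, , drop = FALSE],
       bg_base = base)
}

#' @export
print.synthetic_community <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0(
    "Synthetic community metagenome: %d genes x %d samples\n",
    "  planted core: %d genes (%.2f%% mass); accessory pool: %d\n",
    "  N bloom x%.1f (AOB-like guild), W richness drop %.1f%%\n"),
    nrow(x$table), ncol(x$table), cfg$n_core_genes,
    100 * cfg$core_mass_fraction, cfg$n_accessory_pool,
    cfg$n_effect_strength, 100 * cfg$w_richness_drop))
  invisible(x)
}

#' Generate per-sample covariates consistent with the field experiment
#'
#' Draws each index from the bundled treatment-mean table: for a sample
#' under treatment cell \eqn{c}, value = printed mean of \eqn{c} plus
#' Gaussian noise with standard deviation \code{noise_scale} times the
#' printed SE times \eqn{\sqrt{4}} (the per-plot SD behind an SE of four
#' replicates). \code{noise_scale = 0} returns the cell means exactly, so
#' \code{\link{pooled_effect}} on the generated data reproduces the
#' configured effects by construction. Signs follow the field table
#' (N: +SOM, +available N, -pH, +ammonia-oxidation; W: +moisture,
#' +respiration, +plant richness).
#'
#' @param cfg a \code{\link{synthetic_config}} (supplies the seed).
#' @param design an \code{\link{experimental_design}}.
#' @param noise_scale non-negative noise multiplier (default 1).
#' @return A data.frame of covariates, rownames = sample ids.
#' @export
generate_covariates <- function(cfg, design, noise_scale = 1) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(design, "experimental_design"))
  means <- grassland_field_means()
  short <- c("som", "total_n", "avail_n", "moisture", "ph", "biomass",
             "plant_richness", "bact_qpcr", "bact_relab", "arch_relab",
             "fungal_relab", "respiration", "aop")
  cell <- ifelse(design$n_treatment & design$w_treatment, "NW",
                 ifelse(design$n_treatment, "N",
                        ifelse(design$w_treatment, "W", "control")))
  out <- with_stream(cfg$seed, "covariates", {
    vals <- lapply(seq_len(nrow(means)), function(i) {
      m <- c(control = means$mean_control[i], W = means$mean_W[i],
             N = means$mean_N[i], NW = means$mean_NW[i])
      s <- c(control = means$se_control[i], W = means$se_W[i],
             N = means$se_N[i], NW = means$se_NW[i])
      m[cell] + rnorm(nrow(design), 0, noise_scale * s[cell] * 2)
    })
    as.data.frame(vals, col.names = short)
  })
  rownames(out) <- design$sample_id
  out
}
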