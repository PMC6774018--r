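#' Null-model configuration
#'
#' Settings for the fixed-richness randomization used to separate
#' deterministic from stochastic community assembly. The default follows
#' the Raup-Crick construction common in community ecology: each null
#' sample receives exactly its observed number of genes, drawn without
#' replacement from the gene pool with probability proportional to
#' occupancy frequency (how many samples each gene occupies); uniform
#' weighting is available so the choice is auditable.
#'
#' @param n_randomizations number of null assemblages (>= 99; default 999).
#' @param seed integer seed.
#' @param similarity_basis \code{"presence"} (1 - Sorensen, default) or
#'   \code{"abundance"} (1 - Bray-Curtis on the 0/1 matrix; identical here,
#'   kept for interface symmetry).
#' @param occupancy_weighting draw genes proportional to occupancy?
#' @return A list of class \code{null_model_config}.
#' @export
null_model_config <- function(n_randomizations = 999L, seed = 1L,
                              similarity_basis = c("presence", "abundance"),
                              occupancy_weighting = TRUE) {
  similarity_basis <- match.arg(similarity_basis)
  if (n_randomizations < 99L) stop_ca("n_randomizations must be at least 99")
  structure(list(n_randomizations = as.integer(n_randomizations),
                 seed = as.integer(seed),
                 similarity_basis = similarity_basis,
                 occupancy_weighting = isTRUE(occupancy_weighting)),
            class = "null_model_config")
}

#' Draw one randomized assemblage
#'
#' Produces a null presence matrix over the same genes and samples:
#' per-sample richness is conserved exactly, and each sample's genes are
#' drawn without replacement from the full gene pool (all rows of the
#' matrix), with probability proportional to occupancy when
#' \code{occupancy_weighting} is \code{TRUE} (genes observed nowhere then
#' have weight zero and are never drawn), uniformly otherwise. Samples are
#' filled independently, so the expected occupancy structure -- but not any
#' shared deterministic filtering -- is preserved.
#'
#' @param presence a \code{presence_matrix}.
#' @param occupancy_weighting logical.
#' @return A \code{presence_matrix} of the same shape.
#' @export
randomize_assemblage <- function(presence, occupancy_weighting = TRUE) {
  stopifnot(inherits(presence, "presence_matrix"))
  occ <- rowSums(presence)
  rich <- colSums(presence)
  pool_size <- if (occupancy_weighting) sum(occ > 0L) else nrow(presence)
  if (any(rich > pool_size)) {
    stop_ca("a sample's richness exceeds the drawable gene pool size")
  }
  w <- if (occupancy_weighting) occ else NULL
  out <- matrix(FALSE, nrow(presence), ncol(presence),
                dimnames = dimnames(presence))
  for (s in seq_len(ncol(presence))) {
    if (rich[s] > 0L) {
      out[sample_weighted(nrow(presence), rich[s], w), s] <- TRUE
    }
  }
  as_presence_matrix(out, attr(presence, "threshold"))
}

# mean pairwise similarity (1 - Sorensen) within a set of columns of a
# logical matrix; also returns per-pair values when asked.
group_similarity <- function(m, idx, per_pair = FALSE) {
  k <- length(idx)
  sub <- m[, idx, drop = FALSE]
  storage.mode(sub) <- "double"
  shared <- crossprod(sub)            # a
  tot <- colSums(sub)                 # a + b (per sample)
  denom <- outer(tot, tot, "+")       # 2a + b + c
  sim <- ifelse(denom > 0, 2 * shared / denom, 0)
  ut <- upper.tri(sim)
  if (per_pair) list(mean = mean(sim[ut]), pairs = sim[ut]) else mean(sim[ut])
}

#' Standardized effect size of within-group similarity against the null
#'
#' For each sample group (e.g. treatment), compares the observed mean
#' within-group similarity (1 - Sorensen on presence/absence) with its
#' distribution over randomized assemblages. A positive SES -- observed
#' similarity exceeding the random expectation -- indicates deterministic
#' ecological filtering; SES near zero indicates stochastic assembly.
#'
#' The randomization spans the full matrix (all samples at once), so every
#' group is compared against a common species-pool null. P-values are
#' two-sided with the +1 correction: \eqn{p = (r + 1) / (B + 1)} where
#' \eqn{r} counts null values at least as far from the null mean as the
#' observation.
#'
#' Per-pair and per-sample SES values are also returned; the per-sample
#' values (mean over the pairs that involve the sample) are the unit fed to
#' \code{\link{compare_ses_between_factors}}, avoiding pair-level
#' pseudo-replication while retaining the design's degrees of freedom.
#'
#' @param presence a \code{presence_matrix}.
#' @param groups vector of group labels, one per sample; groups of size 1
#'   are skipped with a warning.
#' @param cfg a \code{\link{null_model_config}}.
#' @return Object of class \code{ses_result}: list with \code{groups}
#'   (data.frame: group, observed, null_mean, null_sd, ses, p_value),
#'   \code{per_sample} (data.frame: sample_id, group, ses),
#'   \code{per_pair} (list of per-group pair SES vectors), \code{config}.
#' @export
ses_similarity <- function(presence, groups, cfg = null_model_config()) {
  stopifnot(inherits(presence, "presence_matrix"),
            inherits(cfg, "null_model_config"))
  groups <- as.character(groups)
  if (length(groups) != ncol(presence)) {
    stop_ca("groups must have one label per sample")
  }
  sizes <- table(groups)
  skip <- names(sizes)[sizes < 2L]
  if (length(skip)) {
    warning(sprintf("skipping group(s) of size 1: %s",
                    paste(skip, collapse = ", ")), call. = FALSE)
  }
  keep <- setdiff(names(sizes), skip)
  idx_by_group <- lapply(keep, function(g) which(groups == g))
  names(idx_by_group) <- keep

  m <- unclass(presence)
  obs <- lapply(idx_by_group, function(ix) group_similarity(m, ix, per_pair = TRUE))

  B <- cfg$n_randomizations
  null_mean_mat <- matrix(NA_real_, B, length(keep), dimnames = list(NULL, keep))
  null_pairs <- lapply(idx_by_group, function(ix) {
    k <- length(ix); matrix(NA_real_, B, k * (k - 1L) / 2L)
  })
  with_stream(cfg$seed, "ses-similarity", {
    for (b in seq_len(B)) {
      nullm <- unclass(randomize_assemblage(presence, cfg$occupancy_weighting))
      for (g in keep) {
        gs <- group_similarity(nullm, idx_by_group[[g]], per_pair = TRUE)
        null_mean_mat[b, g] <- gs$mean
        null_pairs[[g]][b, ] <- gs$pairs
      }
    }
  })

  res <- lapply(keep, function(g) {
    nv <- null_mean_mat[, g]
    mu <- mean(nv); sdv <- sd(nv)
    o <- obs[[g]]$mean
    ses <- if (sdv > 0) (o - mu) / sdv else NaN
    r <- sum(abs(nv - mu) >= abs(o - mu))
    data.frame(group = g, observed = o, null_mean = mu, null_sd = sdv,
               ses = ses, p_value = (r + 1) / (B + 1),
               stringsAsFactors = FALSE)
  })
  group_df <- do.call(rbind, res)

  per_pair <- lapply(keep, function(g) {
    mu <- colMeans(null_pairs[[g]])
    sdv <- apply(null_pairs[[g]], 2L, sd)
    (obs[[g]]$pairs - mu) / ifelse(sdv > 0, sdv, NA)
  })
  names(per_pair) <- keep

  per_sample <- do.call(rbind, lapply(keep, function(g) {
    ix <- idx_by_group[[g]]
    k <- length(ix)
    pair_idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    ses_s <- vapply(seq_len(k), function(j) {
      mean(per_pair[[g]][pair_idx[, 1L] == j | pair_idx[, 2L] == j], na.rm = TRUE)
    }, numeric(1L))
    data.frame(sample_id = colnames(presence)[ix], group = g, ses = ses_s,
               stringsAsFactors = FALSE)
  }))

  structure(list(groups = group_df, per_sample = per_sample,
                 per_pair = per_pair, config = cfg),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("Null-model SES (%d randomizations, %s weighting)\n",
              x$config$n_randomizations,
              if (x$config$occupancy_weighting) "occupancy" else "uniform"))
  df <- x$groups
  df$observed <- round(df$observed, 4); df$null_mean <- round(df$null_mean, 4)
  df$null_sd <- signif(df$null_sd, 3); df$ses <- round(df$ses, 2)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare SES between experimental factors with the split-plot ANOVA
#'
#' Feeds the per-sample SES values from \code{\link{ses_similarity}} into
#' \code{\link{split_plot_anova}} under the 2x2 blocked design, testing
#' whether a factor (e.g. W addition) strengthened ecological filtering.
#'
#' @param ses a \code{ses_result} whose per-sample table covers the design.
#' @param design a complete \code{\link{experimental_design}}.
#' @return A \code{\link{split_plot_anova}} result.
#' @export
compare_ses_between_factors <- function(ses, design) {
  stopifnot(inherits(ses, "ses_result"))
  ps <- ses$per_sample
  y <- ps$ses
  names(y) <- ps$sample_id
  split_plot_anova(y, design)
}
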