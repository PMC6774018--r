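#' Run the full core/accessory analysis pipeline
#'
#' Orchestrates the analysis end-to-end: presence filter, core/accessory
#' partition, component-aware diversity (richness; Bray-Curtis on all
#' genes and on the core subset; Sorensen on the accessory presence
#' submatrix; PCoA of each), null-model SES per treatment on the accessory
#' presence matrix, split-plot ANOVA on richness and on per-sample SES,
#' PERMANOVA of each distance matrix against each factor, and a Mantel
#' test between functional and taxonomic dissimilarity when a taxon table
#' is supplied. Inputs are either file paths or in-memory objects, or a
#' \code{\link{synthetic_config}} to simulate them.
#'
#' @param table a \code{\link{gene_table}} or path to one (TSV).
#' @param design an \code{\link{experimental_design}} or path (TSV).
#' @param taxa optional list with \code{relabund} and \code{genome_sizes}
#'   (as from \code{\link{generate_community}}).
#' @param simulate optional \code{\link{synthetic_config}}; when given,
#'   \code{table}, \code{design} and \code{taxa} are generated and must not
#'   be supplied.
#' @param threshold presence filter threshold (default 5e-7).
#' @param null_cfg a \code{\link{null_model_config}}.
#' @param n_perm permutations for PERMANOVA and Mantel (default 999).
#' @param seed master seed for all permutation streams (default 1).
#' @param strata \code{"block"} to restrict PERMANOVA permutations within
#'   blocks, or \code{NULL} (default) for free permutation.
#' @param pcoa_axes axes to keep in each ordination (default 2).
#' @return An object of class \code{coreacc_analysis}: list with
#'   \code{partition}, \code{richness}, \code{distances}, \code{ordinations},
#'   \code{ses}, \code{anova} (richness and ses tables), \code{permanova}
#'   (per matrix x factor), \code{mantel_functional_taxonomic},
#'   \code{ags}, \code{design}, \code{parameters}.
#' @export
run_core_accessory_analysis <- function(table = NULL, design = NULL,
                                        taxa = NULL, simulate = NULL,
                                        threshold = 5e-7,
                                        null_cfg = null_model_config(seed = seed),
                                        n_perm = 999L, seed = 1L,
                                        strata = NULL, pcoa_axes = 2L) {
  truth <- NULL
  if (!is.null(simulate)) {
    if (!is.null(table) || !is.null(design)) {
      stop_ca("give either simulate= or table=/design=, not both")
    }
    sim <- generate_community(simulate)
    table <- sim$table; design <- sim$design; taxa <- sim$taxa
    truth <- sim$truth
  }
  if (is.null(table) || is.null(design)) {
    stop_ca("both a gene table and a design are required (or simulate=)")
  }
  if (is.character(table)) table <- read_gene_table(table)
  if (is.character(design)) design <- read_design(design)
  design <- align_design(design, colnames(table))
  if (!is_complete_design(design)) {
    stop_ca("the pipeline requires a complete balanced design")
  }

  presence <- call_presence(table, threshold)
  partition <- partition_core_accessory(presence, table)
  comp <- component_tables(table, partition)
  rich <- richness(presence)

  distances <- list(
    all = bray_curtis(table),
    core = bray_curtis(table, subset = partition$core_genes),
    accessory = presence_dissimilarity(comp$accessory_presence))
  ordinations <- lapply(distances, pcoa, n_axes = pcoa_axes)

  trt_group <- ifelse(design$n_treatment & design$w_treatment, "NW",
                      ifelse(design$n_treatment, "N",
                             ifelse(design$w_treatment, "W", "control")))
  ses <- ses_similarity(comp$accessory_presence, trt_group, null_cfg)

  anova <- list(richness = split_plot_anova(rich, design),
                ses = compare_ses_between_factors(ses, design))

  strata_labels <- if (identical(strata, "block")) as.character(design$block) else NULL
  factors <- list(N = design$n_treatment, W = design$w_treatment)
  perm <- lapply(names(distances), function(dn) {
    lapply(names(factors), function(fn) {
      permanova(distances[[dn]], factors[[fn]], n_perm = n_perm,
                seed = stream_seed(seed, paste0("permanova-", dn, "-", fn)),
                strata = strata_labels)
    })
  })
  names(perm) <- names(distances)
  for (i in seq_along(perm)) names(perm[[i]]) <- names(factors)

  mt <- NULL
  ags <- NULL
  if (!is.null(taxa)) {
    taxo_d <- new_dist_matrix(
      as.matrix(vegan::vegdist(t(taxa$relabund), method = "bray")),
      "bray-curtis (taxa)")
    mt <- mantel(distances$all, taxo_d, n_perm = n_perm,
                 seed = stream_seed(seed, "mantel-func-taxa"))
    ags <- average_genome_size(taxa$relabund, taxa$genome_sizes)
  }

  structure(list(partition = partition, richness = rich,
                 distances = distances, ordinations = ordinations,
                 ses = ses, anova = anova, permanova = perm,
                 mantel_functional_taxonomic = mt, ags = ags,
                 design = design, truth = truth,
                 parameters = list(threshold = threshold, n_perm = n_perm,
                                   seed = seed, strata = strata,
                                   null_model = unclass(null_cfg))),
            class = "coreacc_analysis")
}

#' @export
print.coreacc_analysis <- function(x, ...) {
  cat("Core/accessory community analysis\n\n")
  print(x$partition)
  cat("\nRichness: mean", round(mean(x$richness)), "genes/sample\n")
  cat("\nSplit-plot ANOVA p-values (richness): ")
  pr <- x$anova$richness
  cat(paste(sprintf("%s=%.3g", pr$term[1:5], pr$p[1:5]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.coreacc_analysis <- function(object, ...) {
  x <- object
  cat("== Partition ==\n"); print(x$partition)
  cat("\n== Richness ANOVA ==\n"); print(x$anova$richness)
  cat("\n== Null-model SES (accessory presence) ==\n"); print(x$ses)
  cat("\n== SES ANOVA ==\n"); print(x$anova$ses)
  cat("\n== PERMANOVA ==\n")
  for (dn in names(x$permanova)) {
    for (fn in names(x$permanova[[dn]])) {
      r <- x$permanova[[dn]][[fn]]
      cat(sprintf("  %-9s ~ %s: pseudo-F = %6.3f, p = %.4g\n", dn, fn,
                  r$pseudo_F, r$p_value))
    }
  }
  if (!is.null(x$mantel_functional_taxonomic)) {
    cat("\n== Mantel (functional vs taxonomic) ==\n")
    print(x$mantel_functional_taxonomic)
  }
  invisible(x)
}

flat_scalars <- function(x) {
  out <- list()
  pr <- x$anova$richness
  for (i in 1:5) out[[paste0("anova_richness_p_", gsub(":", "x", pr$term[i]))]] <- pr$p[i]
  ps <- x$anova$ses
  for (i in 1:5) out[[paste0("anova_ses_p_", gsub(":", "x", ps$term[i]))]] <- ps$p[i]
  for (dn in names(x$permanova)) {
    for (fn in names(x$permanova[[dn]])) {
      r <- x$permanova[[dn]][[fn]]
      out[[paste0("permanova_", dn, "_", fn, "_F")]] <- r$pseudo_F
      out[[paste0("permanova_", dn, "_", fn, "_p")]] <- r$p_value
    }
  }
  g <- x$ses$groups
  for (i in seq_len(nrow(g))) {
    out[[paste0("ses_", g$group[i])]] <- g$ses[i]
    out[[paste0("ses_p_", g$group[i])]] <- g$p_value[i]
  }
  out$n_core_genes <- length(x$partition$core_genes)
  out$mean_core_relabund <- mean(x$partition$core_relabund)
  out$mean_accessory_count <- mean(x$partition$accessory_count)
  out$mean_richness <- mean(x$richness)
  if (!is.null(x$mantel_functional_taxonomic) &&
      !isTRUE(x$mantel_functional_taxonomic$constant)) {
    out$mantel_functional_taxonomic_r <- x$mantel_functional_taxonomic$r
    out$mantel_functional_taxonomic_p <- x$mantel_functional_taxonomic$p_value
  }
  out
}

#' Write an analysis bundle to a directory
#'
#' Distance matrices become square labeled TSVs, scalar statistics a flat
#' key/value JSON document, per-sample tables TSVs. Every file is listed
#' in \code{manifest.tsv} with an md5 content checksum; a rerun with the
#' same seeds is byte-identical.
#'
#' @param bundle a \code{coreacc_analysis} (or a bare list of
#'   \code{dist_matrix} objects and scalars for ad-hoc use).
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame (file, md5).
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop_ca("cannot create output directory %s", dir)
  files <- character(0)
  put_tsv <- function(df, name, rn = FALSE) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = rn,
                col.names = if (rn) NA else TRUE)
    files <<- c(files, path)
  }
  if (inherits(bundle, "coreacc_analysis")) {
    for (dn in names(bundle$distances)) {
      put_tsv(format(unclass(bundle$distances[[dn]]), digits = 12),
              paste0("distance_", dn, ".tsv"), rn = TRUE)
    }
    for (dn in names(bundle$ordinations)) {
      ord <- bundle$ordinations[[dn]]
      put_tsv(data.frame(sample_id = ord$sample_ids,
                         format(ord$coordinates, digits = 12)),
              paste0("pcoa_", dn, ".tsv"))
    }
    put_tsv(data.frame(sample_id = names(bundle$richness),
                       richness = bundle$richness,
                       core_relabund = bundle$partition$core_relabund,
                       accessory_relabund = bundle$partition$accessory_relabund,
                       accessory_count = bundle$partition$accessory_count),
            "per_sample.tsv")
    put_tsv(bundle$ses$per_sample, "ses_per_sample.tsv")
    scal <- flat_scalars(bundle)
    path <- file.path(dir, "scalars.json")
    jsonlite::write_json(scal, path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
    part_path <- file.path(dir, "partition.json")
    jsonlite::write_json(list(threshold = bundle$partition$threshold,
                              core_genes = bundle$partition$core_genes,
                              accessory_genes = bundle$partition$accessory_genes,
                              absent_genes = bundle$partition$absent_genes),
                         part_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, part_path)
  } else if (is.list(bundle)) {
    scalars <- list()
    for (nm in names(bundle)) {
      x <- bundle[[nm]]
      if (inherits(x, "dist_matrix")) {
        put_tsv(format(unclass(x), digits = 12), paste0(nm, ".tsv"), rn = TRUE)
      } else if (is.numeric(x) && length(x) == 1L) {
        scalars[[nm]] <- x
      }
    }
    if (length(scalars)) {
      path <- file.path(dir, "scalars.json")
      jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA)
      files <- c(files, path)
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
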