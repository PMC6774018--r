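#' Call per-sample gene presence with a rare-gene filter
#'
#' A gene is called present in a sample when it has at least one count and
#' its relative abundance (count / full annotation total of that sample)
#' reaches \code{threshold}. The comparison is inclusive (\code{>=}), so at
#' a depth of 2e6 annotations the canonical shotgun-metagenome threshold of
#' 5e-7 means "at least one confident hit". The same operation serves
#' OTU tables with a threshold such as 1/892.
#'
#' The filter is applied per sample by default: a gene can be present in one
#' sample and filtered-absent in another, which is the reading under which
#' per-sample richness is defined. \code{scope = "global"} instead drops a
#' gene from every sample unless it passes the filter somewhere.
#'
#' @param table a \code{\link{gene_table}}.
#' @param threshold relative-abundance threshold in \code{[0, 1)}.
#' @param scope \code{"per-sample"} (default) or \code{"global"}.
#' @return A logical genes x samples matrix of class \code{presence_matrix}
#'   with attribute \code{threshold}.
#' @export
call_presence <- function(table, threshold = 5e-7, scope = c("per-sample", "global")) {
  stopifnot(inherits(table, "gene_table"))
  scope <- match.arg(scope)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop_ca("threshold must be a single value in [0, 1)")
  }
  p <- rel_abundance(table)
  pres <- (p >= threshold) & (unclass(table) > 0L)
  if (scope == "global") {
    keep <- rowSums(pres) > 0L
    pres <- (unclass(table) > 0L) & keep
  }
  structure(pres, threshold = threshold, scope = scope,
            class = c("presence_matrix", "matrix", "array"))
}

#' Coerce a logical matrix to a presence matrix
#'
#' For presence/absence data that did not come through
#' \code{\link{call_presence}} (e.g. externally filtered tables).
#'
#' @param m logical genes x samples matrix with dimnames.
#' @param threshold threshold to record (default 0).
#' @return A \code{presence_matrix}.
#' @export
as_presence_matrix <- function(m, threshold = 0) {
  stopifnot(is.matrix(m), is.logical(m))
  if (is.null(colnames(m)) || (nrow(m) > 0L && is.null(rownames(m)))) {
    stop_ca("presence matrix must carry gene and sample names")
  }
  if (nrow(m) == 0L && is.null(rownames(m))) {
    dimnames(m) <- list(character(0), colnames(m))
  }
  structure(m, threshold = threshold, scope = "per-sample",
            class = c("presence_matrix", "matrix", "array"))
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("Presence matrix: %d genes x %d samples (threshold %g)\n",
              nrow(x), ncol(x), attr(x, "threshold")))
  invisible(x)
}

#' Partition genes into core and accessory components
#'
#' Core genes are present in every sample after filtering; accessory genes
#' are present in at least one but not all samples; the remainder is absent
#' (filtered out everywhere). Component relative abundances are computed
#' against each sample's full annotation total, so the filtered-out tail
#' mass is excluded from both components but still sits in the denominator.
#'
#' @param presence a \code{presence_matrix} from \code{\link{call_presence}}.
#' @param table the \code{\link{gene_table}} the presence calls came from.
#' @return An object of class \code{gene_partition}: a list with
#'   \code{core_genes}, \code{accessory_genes}, \code{absent_genes} (sorted
#'   character vectors) and per-sample summaries
#'   \code{core_relabund}, \code{accessory_relabund},
#'   \code{accessory_count}, \code{richness}.
#' @export
partition_core_accessory <- function(presence, table) {
  stopifnot(inherits(presence, "presence_matrix"), inherits(table, "gene_table"))
  if (!identical(dim(presence), dim(table)) ||
      !identical(rownames(presence), rownames(table)) ||
      !identical(colnames(presence), colnames(table))) {
    stop_ca("presence matrix and gene table must share genes and samples")
  }
  if (ncol(presence) < 2L) {
    stop_ca("core/accessory partition requires at least 2 samples")
  }
  occ <- rowSums(presence)
  n <- ncol(presence)
  core <- sort(rownames(presence)[occ == n])
  accessory <- sort(rownames(presence)[occ > 0L & occ < n])
  absent <- sort(rownames(presence)[occ == 0L])

  p <- rel_abundance(table)
  # component mass: only counts at positions where the gene is called present
  masked <- p * presence
  core_mass <- colSums(masked[rownames(table) %in% core, , drop = FALSE])
  acc_rows <- rownames(table) %in% accessory
  acc_mass <- colSums(masked[acc_rows, , drop = FALSE])
  acc_count <- colSums(presence[acc_rows, , drop = FALSE])

  structure(list(core_genes = core,
                 accessory_genes = accessory,
                 absent_genes = absent,
                 core_relabund = core_mass,
                 accessory_relabund = acc_mass,
                 accessory_count = as.integer(acc_count),
                 richness = as.integer(colSums(presence)),
                 sample_ids = colnames(presence),
                 threshold = attr(presence, "threshold")),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf(paste0(
    "Core/accessory partition (threshold %g)\n",
    "  core genes:      %d  (%.2f%% +/- %.2f%% of annotations)\n",
    "  accessory genes: %d in pool; %.0f +/- %.0f per sample (%.2f%% of annotations)\n",
    "  absent genes:    %d\n"),
    x$threshold,
    length(x$core_genes), 100 * mean(x$core_relabund),
    100 * sd(x$core_relabund) / sqrt(length(x$core_relabund)),
    length(x$accessory_genes), mean(x$accessory_count),
    sd(x$accessory_count) / sqrt(length(x$accessory_count)),
    100 * mean(x$accessory_relabund),
    length(x$absent_genes)))
  invisible(x)
}

#' Extract component tables for downstream diversity analyses
#'
#' Returns the core-gene count subtable (relative abundances downstream are
#' still over full sample totals) and the accessory-gene presence submatrix,
#' the two inputs to the component-specific beta-diversity analyses.
#'
#' @param table a \code{\link{gene_table}}.
#' @param partition a \code{\link{partition_core_accessory}} result.
#' @return A list with \code{core_table} (a \code{gene_table} whose
#'   \code{sample_totals} attribute keeps the \emph{full} totals) and
#'   \code{accessory_presence} (a logical \code{presence_matrix}, possibly
#'   with zero rows).
#' @export
component_tables <- function(table, partition) {
  stopifnot(inherits(table, "gene_table"), inherits(partition, "gene_partition"))
  if (!identical(colnames(table), partition$sample_ids)) {
    stop_ca("partition and table must share samples in the same order")
  }
  if (length(partition$core_genes) == 0L) {
    stop_ca(paste0("empty core gene set: no gene passed the filter in every ",
                   "sample; review the presence threshold"))
  }
  core <- unclass(table)[partition$core_genes, , drop = FALSE]
  core_tab <- structure(core,
                        sample_totals = attr(table, "sample_totals"),
                        class = c("gene_table", "matrix", "array"))
  pres <- unclass(table)[partition$accessory_genes, , drop = FALSE] > 0L
  # re-apply the threshold so the submatrix agrees with the original calls
  pa <- rel_abundance(table)[partition$accessory_genes, , drop = FALSE]
  pres <- pres & (pa >= partition$threshold)
  list(core_table = core_tab,
       accessory_presence = as_presence_matrix(pres, partition$threshold))
}
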