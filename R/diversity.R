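#' Per-sample gene richness
#'
#' Number of genes called present in each sample (column sums of the
#' presence matrix, integer-exact).
#'
#' @param presence a \code{presence_matrix}.
#' @return Named integer vector, one value per sample.
#' @export
richness <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  r <- colSums(presence)
  storage.mode(r) <- "integer"
  r
}

new_dist_matrix <- function(m, label, flagged = character(0)) {
  stopifnot(is.matrix(m), isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  attr(m, "metric") <- label
  if (length(flagged)) attr(m, "flagged_samples") <- flagged
  class(m) <- c("dist_matrix", "matrix", "array")
  m
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("%d x %d distance matrix (%s)\n", nrow(x), ncol(x),
              attr(x, "metric")))
  print(unclass(round(x, 4)))
  invisible(x)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \deqn{d(i,j) = 1 - 2 \sum_g \min(p_{gi}, p_{gj}) /
#'   (\sum_g p_{gi} + \sum_g p_{gj})}
#' computed on per-sample relative abundances over \emph{full} annotation
#' totals. With \code{subset} (e.g. the core gene set) the abundances are
#' not renormalized within the subset unless \code{renormalize = TRUE};
#' core genes carry ~99.8\% of the mass so the default choice is numerically
#' minor but explicit.
#'
#' @param table a \code{\link{gene_table}}.
#' @param subset optional character vector of gene ids.
#' @param renormalize renormalize abundances within the subset?
#' @return A symmetric \code{dist_matrix} with values in \code{[0, 1]}.
#' @export
bray_curtis <- function(table, subset = NULL, renormalize = FALSE) {
  stopifnot(inherits(table, "gene_table"))
  if (!is.null(subset) && !any(subset %in% rownames(table))) {
    stop_ca("subset is disjoint from the table's genes")
  }
  p <- rel_abundance(table, genes = subset)
  if (renormalize) p <- sweep(p, 2L, colSums(p), "/")
  d <- as.matrix(vegan::vegdist(t(p), method = "bray"))
  new_dist_matrix(d, if (is.null(subset)) "bray-curtis (all genes)"
                  else "bray-curtis (subset)")
}

#' Presence/absence (Sorensen) dissimilarity between samples
#'
#' Bray-Curtis applied to 0/1 vectors, i.e. the Sorensen dissimilarity
#' \eqn{1 - 2a / (2a + b + c)} with \eqn{a} shared presences and
#' \eqn{b, c} presences unique to either sample. A sample with zero
#' presences in the subset has all its pairwise values defined as 1 and is
#' flagged in the output's \code{flagged_samples} attribute.
#'
#' @param presence a \code{presence_matrix}.
#' @param subset optional character vector of gene ids.
#' @return A symmetric \code{dist_matrix} with values in \code{[0, 1]}.
#' @export
presence_dissimilarity <- function(presence, subset = NULL) {
  stopifnot(inherits(presence, "presence_matrix"))
  m <- unclass(presence)
  if (!is.null(subset)) {
    if (!any(subset %in% rownames(m))) stop_ca("subset is disjoint from the matrix's genes")
    m <- m[intersect(subset, rownames(m)), , drop = FALSE]
  }
  counts <- colSums(m)
  empty <- colnames(m)[counts == 0L]
  storage.mode(m) <- "double"
  if (nrow(m) == 0L || length(empty) == ncol(m)) {
    d <- matrix(1, ncol(m), ncol(m), dimnames = list(colnames(m), colnames(m)))
    diag(d) <- 0
    return(new_dist_matrix(d, "sorensen (presence/absence)", flagged = empty))
  }
  # empty samples are handled explicitly below; silence vegdist's caution
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(m), method = "bray")))
  if (length(empty)) {
    d[empty, ] <- 1; d[, empty] <- 1
    diag(d) <- 0
  }
  new_dist_matrix(d, "sorensen (presence/absence)", flagged = empty)
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers \eqn{-\tfrac12 D^2}, eigendecomposes, and scales
#' eigenvectors by the square root of their eigenvalues. Negative
#' eigenvalues (common for Bray-Curtis matrices, which need not embed in
#' Euclidean space) are dropped from the coordinates and from the
#' explained-variance denominator, with a warning reporting their
#' magnitude; no Lingoes/Cailliez correction is applied unless
#' \code{correction = "cailliez"}.
#'
#' @param d a \code{dist_matrix} (or symmetric matrix / \code{dist}).
#' @param n_axes number of axes to return (default 2).
#' @param correction \code{"none"} (default) or \code{"cailliez"}.
#' @return An object of class \code{pcoa_result}: list with
#'   \code{coordinates} (samples x axes, centered),
#'   \code{explained_fraction} (non-increasing, over the sum of positive
#'   eigenvalues), \code{eigenvalues}, \code{negative_magnitude}.
#' @export
pcoa <- function(d, n_axes = 2L, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  m <- as.matrix(d)
  n <- nrow(m)
  if (n_axes < 1L) stop_ca("n_axes must be at least 1")
  if (n_axes > n - 1L) stop_ca("n_axes must be at most n_samples - 1")
  if (correction == "cailliez") {
    cc <- stats::cmdscale(stats::as.dist(m), k = 1L, add = TRUE)$ac
    m <- m + cc
    diag(m) <- 0
  }
  d2 <- m^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- ev > max(ev, 0) * 1e-12
  neg_mag <- sum(abs(ev[ev < 0]))
  if (neg_mag > sum(ev[pos]) * 1e-8) {
    warning(sprintf(
      "distance matrix is non-Euclidean: dropped negative eigenvalues (total magnitude %.4g, %.2f%% of positive total)",
      neg_mag, 100 * neg_mag / sum(ev[pos])), call. = FALSE)
  }
  k <- min(n_axes, sum(pos))
  lam <- ev[seq_len(k)]
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k, k)
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PCoA", seq_len(k))
  structure(list(sample_ids = rownames(m),
                 coordinates = coords,
                 explained_fraction = lam / sum(ev[pos]),
                 eigenvalues = ev,
                 negative_magnitude = neg_mag),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes kept\n", length(x$sample_ids),
              ncol(x$coordinates)))
  cat("Explained fraction:",
      paste0(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pcoa_result <- function(x, axes = c(1L, 2L), groups = NULL, ...) {
  co <- x$coordinates[, axes, drop = FALSE]
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  plot(co[, 1L], co[, 2L], col = col, pch = 19,
       xlab = sprintf("PCoA%d (%.1f%%)", axes[1L], 100 * x$explained_fraction[axes[1L]]),
       ylab = sprintf("PCoA%d (%.1f%%)", axes[2L], 100 * x$explained_fraction[axes[2L]]),
       ...)
  invisible(x)
}

#' Abundance-weighted average genome size
#'
#' \deqn{AGS_s = \sum_t p_{ts} \cdot G_t} with \eqn{p_{ts}} the cell
#' (taxon) relative abundance of taxon \eqn{t} in sample \eqn{s} and
#' \eqn{G_t} its genome size in bases. Weighting is by cell abundance, not
#' base-pair share. Blooms of small-genome taxa (e.g. ammonia-oxidizing
#' bacteria under N addition) decrease AGS.
#'
#' @param taxon_relabund taxa x samples matrix of relative abundances; each
#'   column must sum to 1 within 1e-9.
#' @param genome_sizes named numeric vector of genome sizes (bases) covering
#'   every taxon with non-zero abundance.
#' @return Named numeric vector of per-sample AGS in bases.
#' @export
average_genome_size <- function(taxon_relabund, genome_sizes) {
  stopifnot(is.matrix(taxon_relabund))
  cs <- colSums(taxon_relabund)
  if (any(abs(cs - 1) > 1e-9)) {
    stop_ca("taxon relative abundances must sum to 1 per sample (max dev %.3g)",
            max(abs(cs - 1)))
  }
  present <- rownames(taxon_relabund)[rowSums(taxon_relabund) > 0]
  missing <- setdiff(present, names(genome_sizes))
  if (length(missing)) {
    stop_ca("missing genome size for taxa: %s", paste(missing, collapse = ", "))
  }
  g <- genome_sizes[rownames(taxon_relabund)]
  g[is.na(g)] <- 0
  drop(t(taxon_relabund) %*% g)[colnames(taxon_relabund)]
}
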