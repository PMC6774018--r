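#' Construct a gene abundance table
#'
#' A gene abundance table holds non-negative integer annotation counts for
#' gene families (rows, e.g. COG or KO identifiers) across samples
#' (columns), together with per-sample annotation totals. Relative
#' abundances are never stored; they are derived on demand as
#' \code{count / sample_total} so there is a single source of truth.
#'
#' @param counts integer matrix, genes x samples, with unique non-empty
#'   dimnames. Values must be non-negative whole numbers.
#' @return An object of class \code{gene_table}: the integer count matrix
#'   with a \code{sample_totals} attribute (named per-sample column sums).
#' @examples
#' m <- matrix(c(1L, 0L, 4L, 2L, 3L, 0L), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' gt <- gene_table(m)
#' sample_totals(gt)
#' @export
gene_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) < 1L) stop_ca("no genes: the table must contain at least one gene row")
  if (ncol(counts) < 2L) stop_ca("at least 2 samples are required, got %d", ncol(counts))
  gi <- rownames(counts); si <- colnames(counts)
  if (is.null(gi) || is.null(si)) stop_ca("counts must carry gene and sample names")
  if (anyDuplicated(gi)) {
    stop_ca("duplicated gene id(s): %s",
            paste(unique(gi[duplicated(gi)]), collapse = ", "))
  }
  if (anyDuplicated(si)) {
    stop_ca("duplicated sample id(s): %s",
            paste(unique(si[duplicated(si)]), collapse = ", "))
  }
  if (any(!is.finite(counts))) {
    bad <- which(!is.finite(counts), arr.ind = TRUE)[1L, ]
    stop_ca("missing or non-numeric count at gene '%s', sample '%s'",
            gi[bad[1L]], si[bad[2L]])
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop_ca("negative count at gene '%s', sample '%s'", gi[bad[1L]], si[bad[2L]])
  }
  if (any(abs(counts - round(counts)) > 1e-9)) {
    bad <- which(abs(counts - round(counts)) > 1e-9, arr.ind = TRUE)[1L, ]
    stop_ca("non-integer count at gene '%s', sample '%s'", gi[bad[1L]], si[bad[2L]])
  }
  storage.mode(counts) <- "integer"
  structure(counts,
            sample_totals = colSums(counts),
            class = c("gene_table", "matrix", "array"))
}

#' @rdname gene_table
#' @param x a \code{gene_table}.
#' @export
sample_totals <- function(x) {
  stopifnot(inherits(x, "gene_table"))
  attr(x, "sample_totals")
}

#' Per-sample relative abundances
#'
#' Divides each column by its full annotation total. When \code{genes} is
#' given, rows are subset \emph{after} the division, so the denominator is
#' always the complete sample total (the convention used throughout:
#' component relative abundances are fractions of all annotations, not of
#' the component).
#'
#' @param x a \code{gene_table}.
#' @param genes optional character vector of gene ids to keep.
#' @return A numeric matrix of relative abundances.
#' @export
rel_abundance <- function(x, genes = NULL) {
  stopifnot(inherits(x, "gene_table"))
  p <- sweep(unclass(x), 2L, attr(x, "sample_totals"), "/")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(p))
    if (length(missing)) {
      stop_ca("gene id(s) not in table: %s", paste(head(missing, 5L), collapse = ", "))
    }
    p <- p[genes, , drop = FALSE]
  }
  p
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("Gene abundance table: %d genes x %d samples\n", nrow(x), ncol(x)))
  tot <- attr(x, "sample_totals")
  cat(sprintf("Annotation totals: %s .. %s per sample\n",
              format(min(tot), big.mark = ","), format(max(tot), big.mark = ",")))
  invisible(x)
}

#' Read a gene abundance table from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' the body must be non-negative integer counts. Missing cells are errors,
#' not zeros: silent zero-filling would corrupt presence calls downstream.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return A \code{\link{gene_table}}.
#' @export
read_gene_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_ca("file not found: %s", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                   check.names = FALSE, colClasses = "character",
                   comment.char = "", quote = "")
  if (nrow(df) == 0L) stop_ca("no genes: %s has an empty body", path)
  gi <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body), dimnames = list(NULL, names(body)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_ca("non-numeric or missing cell at gene '%s', sample '%s' in %s",
            gi[bad[1L]], colnames(num)[bad[2L]], path)
  }
  rownames(num) <- gi
  gene_table(num)
}

#' Write a gene abundance table
#'
#' Inverse of \code{\link{read_gene_table}}; the round trip is
#' integer-exact and preserves gene and sample ordering.
#'
#' @param x a \code{gene_table}.
#' @param path output file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_gene_table <- function(x, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(x, "gene_table"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
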