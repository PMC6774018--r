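#' Construct a treatment-means table
#'
#' Mean and standard error of an index under each cell of the 2x2 N x W
#' factorial (control, W, N, NW), as printed in field-experiment summary
#' tables.
#'
#' @param index_name name of the index (e.g. "SOM content").
#' @param units measurement units (free text; may be "").
#' @param means named numeric vector with entries \code{control}, \code{W},
#'   \code{N}, \code{NW}.
#' @param se named numeric vector of standard errors (same names, >= 0).
#' @return A one-row data.frame of class \code{treatment_means}.
#' @export
treatment_means <- function(index_name, units, means, se) {
  cells <- c("control", "W", "N", "NW")
  if (!all(cells %in% names(means)) || !all(cells %in% names(se))) {
    stop_ca("means and se must be named with control, W, N, NW")
  }
  if (any(!is.finite(means[cells]))) stop_ca("all four treatment means must be finite")
  if (any(se[cells] < 0)) stop_ca("standard errors must be non-negative")
  structure(data.frame(index_name = index_name, units = units,
                       mean_control = means[["control"]], se_control = se[["control"]],
                       mean_W = means[["W"]], se_W = se[["W"]],
                       mean_N = means[["N"]], se_N = se[["N"]],
                       mean_NW = means[["NW"]], se_NW = se[["NW"]],
                       stringsAsFactors = FALSE),
            class = c("treatment_means", "data.frame"))
}

#' Read a treatment-means table from TSV
#'
#' Columns: \code{index}, \code{units}, then \code{mean_control},
#' \code{se_control}, \code{mean_W}, \code{se_W}, \code{mean_N},
#' \code{se_N}, \code{mean_NW}, \code{se_NW}.
#'
#' @param path file path.
#' @return A data.frame of class \code{treatment_means} (one row per index).
#' @export
read_treatment_means <- function(path) {
  if (!file.exists(path)) stop_ca("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", quote = "")
  rows <- lapply(seq_len(nrow(df)), function(i) {
    treatment_means(df$index[i], df$units[i],
                    c(control = df$mean_control[i], W = df$mean_W[i],
                      N = df$mean_N[i], NW = df$mean_NW[i]),
                    c(control = df$se_control[i], W = df$se_W[i],
                      N = df$se_N[i], NW = df$se_NW[i]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("treatment_means", "data.frame")
  out
}

#' Bundled grassland field-experiment means
#'
#' Treatment-mean summary (13 biotic and abiotic indices) from a 5-year
#' N x W addition experiment on a semiarid temperate-steppe soil
#' (4 blocks, 16 samples), bundled as the canonical input for
#' \code{\link{pooled_effect}}.
#'
#' @return A \code{treatment_means} table with 13 rows.
#' @export
grassland_field_means <- function() {
  read_treatment_means(system.file("extdata", "grassland_field_means.tsv",
                                   package = "coreacc", mustWork = TRUE))
}

#' Pooled treatment effect of one factor
#'
#' Pools the two cells where the factor was applied against the two where
#' it was not, using unweighted means of the four printed treatment means
#' (replication is balanced). For factor N: plus = mean(N, NW), minus =
#' mean(control, W); for W: plus = mean(W, NW), minus = mean(control, N).
#' Reports percent change \eqn{100 (plus - minus) / minus}, absolute
#' difference and fold change \eqn{plus / minus}.
#'
#' @param row a one-row \code{treatment_means}.
#' @param factor \code{"N"} or \code{"W"}.
#' @return A one-row data.frame of class \code{effect_summary} with columns
#'   \code{index_name}, \code{factor}, \code{pooled_mean_plus},
#'   \code{pooled_mean_minus}, \code{percent_change},
#'   \code{absolute_difference}, \code{fold_change}.
#' @export
pooled_effect <- function(row, factor = c("N", "W")) {
  factor <- match.arg(factor)
  stopifnot(inherits(row, "treatment_means"))
  if (nrow(row) != 1L) stop_ca("pooled_effect expects a single index row")
  m <- c(control = row$mean_control, W = row$mean_W, N = row$mean_N,
         NW = row$mean_NW)
  plus <- if (factor == "N") mean(m[c("N", "NW")]) else mean(m[c("W", "NW")])
  minus <- if (factor == "N") mean(m[c("control", "W")]) else mean(m[c("control", "N")])
  if (minus == 0) {
    stop_ca("zero minus-pool for '%s': percent and fold change undefined",
            row$index_name)
  }
  structure(data.frame(index_name = row$index_name, factor = factor,
                       pooled_mean_plus = plus, pooled_mean_minus = minus,
                       percent_change = 100 * (plus - minus) / minus,
                       absolute_difference = plus - minus,
                       fold_change = plus / minus,
                       stringsAsFactors = FALSE),
            class = c("effect_summary", "data.frame"))
}

#' Pooled-effect report over a means table
#'
#' One \code{\link{pooled_effect}} summary per index per factor (N and W),
#' optionally rounded half-up to match printed tables.
#'
#' @param table a \code{treatment_means} table (any number of rows).
#' @param rounding decimals for half-up rounding, or \code{NULL} for none.
#' @return A data.frame of class \code{effect_summary} with
#'   \code{2 * nrow(table)} rows.
#' @export
effect_report <- function(table, rounding = NULL) {
  stopifnot(inherits(table, "treatment_means"))
  out <- do.call(rbind, unlist(lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, , drop = FALSE]
    class(row) <- c("treatment_means", "data.frame")
    list(pooled_effect(row, "N"), pooled_effect(row, "W"))
  }), recursive = FALSE))
  if (!is.null(rounding)) {
    for (col in c("pooled_mean_plus", "pooled_mean_minus", "percent_change",
                  "absolute_difference", "fold_change")) {
      out[[col]] <- half_up(out[[col]], rounding)
    }
  }
  class(out) <- c("effect_summary", "data.frame")
  out
}

#' Write an effect report to TSV
#' @param report an \code{effect_summary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_effect_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
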