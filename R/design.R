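#' Construct an experimental design table
#'
#' Describes the split-plot layout: each sample belongs to a block, received
#' or not the whole-plot treatment (N addition) and the subplot treatment
#' (W addition). A \emph{complete} design contains every block x N x W
#' combination exactly once.
#'
#' @param sample_id character vector of unique sample ids.
#' @param block block labels (coerced to factor).
#' @param n_treatment,w_treatment logical vectors (treatment applied?).
#' @return A \code{data.frame} of class \code{experimental_design} with a
#'   logical attribute \code{complete}.
#' @export
experimental_design <- function(sample_id, block, n_treatment, w_treatment) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop_ca("duplicated sample id(s): %s",
            paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (!is.logical(n_treatment) || !is.logical(w_treatment) ||
      anyNA(n_treatment) || anyNA(w_treatment)) {
    stop_ca("n_treatment and w_treatment must be logical without missing values")
  }
  d <- data.frame(sample_id = sample_id,
                  block = factor(block),
                  n_treatment = n_treatment,
                  w_treatment = w_treatment,
                  stringsAsFactors = FALSE)
  combos <- table(d$block, d$n_treatment, d$w_treatment)
  complete <- nlevels(d$block) >= 1L &&
    dim(combos)[2L] == 2L && dim(combos)[3L] == 2L && all(combos == 1L)
  structure(d, complete = complete,
            class = c("experimental_design", "data.frame"))
}

#' @rdname experimental_design
#' @param design an \code{experimental_design}.
#' @export
is_complete_design <- function(design) {
  stopifnot(inherits(design, "experimental_design"))
  isTRUE(attr(design, "complete"))
}

parse_bool <- function(x, column) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "yes", "t", "y")] <- TRUE
  out[v %in% c("0", "false", "no", "f", "n")] <- FALSE
  if (anyNA(out)) {
    stop_ca("unparseable boolean value '%s' in column %s",
            v[which(is.na(out))[1L]], column)
  }
  out
}

#' Read an experimental design table
#'
#' Expects columns \code{sample_id}, \code{block}, \code{N}, \code{W}
#' (case-insensitive header). Treatment values may be any of
#' 0/1, true/false, yes/no (case-insensitive) -- field metadata files vary.
#' An incomplete design is allowed (flagged, not an error).
#'
#' @param path file path (TSV).
#' @return An \code{\link{experimental_design}}.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_ca("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", comment.char = "", quote = "")
  names(df) <- tolower(names(df))
  need <- c("sample_id", "block", "n", "w")
  if (!all(need %in% names(df))) {
    stop_ca("design file must have columns sample_id, block, N, W; got: %s",
            paste(names(df), collapse = ", "))
  }
  experimental_design(df$sample_id, df$block,
                      parse_bool(df$n, "N"), parse_bool(df$w, "W"))
}

#' Write an experimental design table
#' @param design an \code{\link{experimental_design}}.
#' @param path output path (TSV).
#' @return \code{path}, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experimental_design"))
  df <- data.frame(sample_id = design$sample_id, block = design$block,
                   N = as.integer(design$n_treatment),
                   W = as.integer(design$w_treatment))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.experimental_design <- function(x, ...) {
  cat(sprintf("Experimental design: %d samples, %d blocks, %s\n",
              nrow(x), nlevels(x$block),
              if (is_complete_design(x)) "complete balanced split-plot"
              else "incomplete"))
  NextMethod()
}

# Match a design to the sample ids of a table, preserving table order.
align_design <- function(design, sample_ids) {
  stopifnot(inherits(design, "experimental_design"))
  missing <- setdiff(sample_ids, design$sample_id)
  if (length(missing)) {
    stop_ca("sample(s) missing from design: %s", paste(missing, collapse = ", "))
  }
  design[match(sample_ids, design$sample_id), , drop = FALSE]
}

#' Read a per-sample covariate table
#'
#' One row per sample, numeric covariates in columns (e.g. SOM g/kg, pH,
#' water content kg/kg). Missing sample ids or non-numeric cells are errors.
#'
#' @param path file path (TSV with a \code{sample_id} column).
#' @return A data.frame with rownames = sample ids.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_ca("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", quote = "")
  names(df)[1L] <- "sample_id"
  if (anyDuplicated(df$sample_id)) stop_ca("duplicated sample id in covariates")
  num <- df[, -1L, drop = FALSE]
  if (!all(vapply(num, is.numeric, logical(1L)))) {
    stop_ca("non-numeric covariate column in %s", path)
  }
  if (anyNA(num)) stop_ca("missing covariate value in %s", path)
  rownames(num) <- as.character(df$sample_id)
  num
}
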