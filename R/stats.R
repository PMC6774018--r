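#' Split-plot ANOVA for a blocked 2x2 N x W design
#'
#' Analysis of variance for the split-plot layout in which N addition is the
#' whole-plot factor (randomized to large plots within blocks) and W
#' addition is the subplot factor. Terms and error strata follow the
#' standard balanced decomposition: Block and N are tested against the
#' whole-plot error (Block x N), W and N x W against the subplot residual.
#' Degrees of freedom are \eqn{(b-1, 1, b-1, 1, 1, 2b-2)} for
#' (Block, N, Block x N, W, N x W, Residual). P-values come from the F
#' distribution, matching standard practice for field-experiment tables.
#'
#' @param response named numeric vector, one finite value per sample.
#' @param design a complete balanced \code{\link{experimental_design}};
#'   unbalanced or incomplete designs are an explicit error (no Type-III
#'   fallback).
#' @return A data.frame of class \code{split_plot_anova} with columns
#'   \code{df}, \code{ss}, \code{ms}, \code{F}, \code{p} and an
#'   \code{error_terms} attribute naming the denominator of each F. With a
#'   constant response all SS are 0 and F/p are \code{NaN}, flagged via the
#'   \code{degenerate} attribute.
#' @export
split_plot_anova <- function(response, design) {
  stopifnot(inherits(design, "experimental_design"))
  if (!is_complete_design(design)) {
    stop_ca("split-plot ANOVA requires a complete balanced design (every block x N x W combination exactly once)")
  }
  if (!is.null(names(response))) {
    design <- align_design(design, names(response))
  } else if (length(response) != nrow(design)) {
    stop_ca("response length %d does not match design rows %d",
            length(response), nrow(design))
  }
  y <- as.numeric(response)
  if (any(!is.finite(y))) stop_ca("response must be finite")
  b <- nlevels(design$block)
  n <- length(y)  # 4b
  blk <- design$block
  nf <- design$n_treatment
  wf <- design$w_treatment

  gm <- mean(y)
  mean_by <- function(...) tapply(y, list(...), mean)
  m_blk <- mean_by(blk)
  m_n <- mean_by(nf)
  m_w <- mean_by(wf)
  m_bn <- mean_by(blk, nf)
  m_nw <- mean_by(nf, wf)

  ss_blk <- 4 * sum((m_blk - gm)^2)
  ss_n <- 2 * b * sum((m_n - gm)^2)
  ss_w <- 2 * b * sum((m_w - gm)^2)
  ss_bn <- 2 * sum((m_bn - outer(m_blk, m_n, "+") + gm)^2)
  ss_nw <- b * sum((m_nw - outer(m_n, m_w, "+") + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_blk - ss_n - ss_bn - ss_w - ss_nw
  ss_res <- max(ss_res, 0)

  df <- c(Block = b - 1L, N = 1L, `Block:N` = b - 1L, W = 1L, `N:W` = 1L,
          Residual = 2L * (b - 1L))
  ss <- c(ss_blk, ss_n, ss_bn, ss_w, ss_nw, ss_res)
  ms <- ss / df
  degenerate <- ss_tot < 1e-300
  denom <- c(ms[["Block:N"]], ms[["Block:N"]], ms[["Residual"]],
             ms[["Residual"]], ms[["Residual"]], NA)
  f <- ms / denom
  f[6L] <- NA
  p <- pf(f, df, c(df[["Block:N"]], df[["Block:N"]], rep(df[["Residual"]], 3L), NA),
          lower.tail = FALSE)
  if (degenerate) { f[1:5] <- NaN; p[1:5] <- NaN }
  out <- data.frame(term = names(df), df = as.integer(df), ss = ss, ms = ms,
                    F = as.numeric(f), p = as.numeric(p),
                    row.names = NULL, check.names = FALSE)
  structure(out,
            error_terms = c(Block = "Block:N", N = "Block:N",
                            `Block:N` = "Residual", W = "Residual",
                            `N:W` = "Residual"),
            degenerate = degenerate,
            class = c("split_plot_anova", "data.frame"))
}

#' @export
print.split_plot_anova <- function(x, ...) {
  cat("Split-plot ANOVA (whole plot: N within blocks; subplot: W)\n")
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 5); df$ms <- signif(df$ms, 5)
  df$F <- signif(df$F, 4); df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  if (isTRUE(attr(x, "degenerate"))) {
    cat("note: constant response; F and p undefined\n")
  }
  invisible(x)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Single-factor PERMANOVA on a distance matrix (McArdle-Anderson direct
#' partition): \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n},
#' \eqn{SS_{within} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g}, pseudo-F =
#' \eqn{(SS_{between}/(a-1)) / (SS_{within}/(n-a))}. The p-value permutes
#' sample labels freely, or within \code{strata} (e.g. blocks) when given.
#'
#' @param d a \code{dist_matrix} (or symmetric matrix) of dissimilarities.
#' @param factor grouping with >= 2 levels, each with >= 2 samples.
#' @param n_perm number of permutations (default 999; < 99 warns).
#' @param seed integer seed for the permutation stream.
#' @param strata optional labels restricting permutations to within-stratum
#'   exchanges.
#' @return Object of class \code{permanova_result}: list with
#'   \code{pseudo_F}, \code{r_squared}, \code{p_value}, \code{n_permutations},
#'   \code{permutation_scheme}, \code{ss}.
#' @export
permanova <- function(d, factor, n_perm = 999L, seed = 1L, strata = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  g <- base::factor(factor)
  if (length(g) != n) stop_ca("factor length does not match distance matrix")
  if (nlevels(g) < 2L) stop_ca("factor needs at least 2 levels")
  if (any(table(g) < 2L)) stop_ca("every group needs at least 2 samples (singleton group found)")
  if (n_perm < 99L) warning("fewer than 99 permutations gives a coarse p-value", call. = FALSE)
  d2 <- m^2

  stat <- function(gg) {
    ss_tot <- sum(d2[upper.tri(d2)]) / n
    ss_w <- 0
    for (lev in levels(gg)) {
      idx <- which(gg == lev)
      sub <- d2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
    a <- nlevels(gg)
    ss_b <- ss_tot - ss_w
    list(F = (ss_b / (a - 1)) / (ss_w / (n - a)),
         r2 = ss_b / ss_tot, ss = c(between = ss_b, within = ss_w, total = ss_tot))
  }
  obs <- stat(g)

  perm_indices <- function() {
    if (is.null(strata)) return(sample.int(n))
    idx <- seq_len(n)
    for (s in unique(strata)) {
      w <- which(strata == s)
      idx[w] <- w[sample.int(length(w))]
    }
    idx
  }
  exceed <- with_stream(seed, "permanova", {
    sum(vapply(seq_len(n_perm), function(i) {
      stat(g[perm_indices()])$F >= obs$F
    }, logical(1L)))
  })
  structure(list(pseudo_F = obs$F,
                 r_squared = obs$r2,
                 p_value = (exceed + 1) / (n_perm + 1),
                 n_permutations = as.integer(n_perm),
                 permutation_scheme = if (is.null(strata)) "free" else "within-strata",
                 ss = obs$ss),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.3f, p = %.4g (%d %s permutations)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$n_permutations,
              x$permutation_scheme))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle vectors; significance by
#' simultaneous row/column permutation of the second matrix. Default tail
#' is \code{"greater"} (positive association, the usual ecological
#' question); \code{"two-sided"} is available.
#'
#' @param d1,d2 distance matrices over the same samples in the same order.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param tail \code{"greater"} or \code{"two-sided"}.
#' @return Object of class \code{mantel_result}: list with \code{r},
#'   \code{p_value}, \code{n_permutations}, \code{tail}; \code{r} is
#'   \code{NA} with \code{constant = TRUE} if either triangle is constant.
#' @export
mantel <- function(d1, d2, n_perm = 999L, seed = 1L,
                   tail = c("greater", "two-sided")) {
  tail <- match.arg(tail)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2))) stop_ca("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop_ca("distance matrices must cover the same samples in the same order")
  }
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (sd(v1) == 0 || sd(m2[ut]) == 0) {
    return(structure(list(r = NA_real_, p_value = NA_real_,
                          n_permutations = as.integer(n_perm), tail = tail,
                          constant = TRUE),
                     class = "mantel_result"))
  }
  r_obs <- cor(v1, m2[ut])
  n <- nrow(m1)
  exceed <- with_stream(seed, "mantel", {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      r <- cor(v1, m2[p, p][ut])
      if (tail == "greater") r >= r_obs else abs(r) >= abs(r_obs)
    }, logical(1L)))
  })
  structure(list(r = r_obs, p_value = (exceed + 1) / (n_perm + 1),
                 n_permutations = as.integer(n_perm), tail = tail,
                 constant = FALSE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (isTRUE(x$constant)) {
    cat("Mantel test: undefined (constant distance vector)\n")
  } else {
    cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d permutations, %s tail)\n",
                x$r, x$p_value, x$n_permutations, x$tail))
  }
  invisible(x)
}
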