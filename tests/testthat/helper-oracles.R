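# Brute-force oracles, kept deliberately independent of the package's
# implementation paths: direct formula evaluation, projection-matrix least
# squares, and exhaustive enumeration at tiny n.

brute_bray <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

brute_sorensen <- function(a, b) {
  # a, b: character vectors of present gene ids
  shared <- length(intersect(a, b))
  1 - 2 * shared / (length(a) + length(b))
}

brute_mantel_r <- function(m1, m2) {
  ut <- upper.tri(m1)
  cor(m1[ut], m2[ut])
}

brute_permanova_F <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  g <- factor(groups)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (lev in levels(g)) {
    i <- which(g == lev)
    ss_w <- ss_w + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  a <- nlevels(g)
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Split-plot F oracle via sequential least-squares sums of squares (the
# design is balanced and orthogonal, so sequential SS equal the direct
# decomposition) with the whole-plot / subplot error strata formed by hand.
oracle_split_plot_F <- function(y, design) {
  df <- data.frame(y = y, block = design$block,
                   n = factor(design$n_treatment),
                   w = factor(design$w_treatment))
  tab <- anova(lm(y ~ block + n + block:n + w + n:w, data = df))
  ss <- tab[, "Sum Sq"]; dfs <- tab[, "Df"]
  names(ss) <- names(dfs) <- rownames(tab)
  ms <- ss / dfs
  c(Block = ms[["block"]] / ms[["block:n"]],
    N = ms[["n"]] / ms[["block:n"]],
    `Block:N` = ms[["block:n"]] / ms[["Residuals"]],
    W = ms[["w"]] / ms[["Residuals"]],
    `N:W` = ms[["n:w"]] / ms[["Residuals"]])
}

# Optimal rigid alignment (translation + rotation/reflection) of Y onto X;
# returns the residual root-mean-square distance.
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  sqrt(mean((Xc - Yc %*% R)^2))
}

# All fixed-richness assemblages of a tiny universe: returns a list of
# logical matrices (genes x samples) with the given per-sample richness
# over a pool of n_genes.
enumerate_assemblages <- function(n_genes, richness) {
  per_sample <- lapply(richness, function(k) {
    combn(n_genes, k, simplify = FALSE)
  })
  grids <- expand.grid(lapply(per_sample, seq_along))
  lapply(seq_len(nrow(grids)), function(i) {
    m <- matrix(FALSE, n_genes, length(richness))
    for (s in seq_along(richness)) {
      m[per_sample[[s]][[grids[i, s]]], s] <- TRUE
    }
    m
  })
}

sorensen_similarity_cols <- function(m) {
  # mean pairwise 1 - Sorensen over columns of a logical matrix
  n <- ncol(m)
  sims <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sum(m[, i] & m[, j])
    tot <- sum(m[, i]) + sum(m[, j])
    sims <- c(sims, if (tot > 0) 2 * a / tot else 0)
  }
  mean(sims)
}
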