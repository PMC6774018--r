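test_that("split-plot ANOVA matches the least-squares oracle on simulated data", {
  set.seed(21)
  for (rep in 1:30) {
    b <- sample(c(3L, 4L, 5L), 1)
    design <- make_design(b)
    y <- rnorm(nrow(design), mean = 2 * design$n_treatment +
                 0.5 * design$w_treatment + as.integer(design$block) * 0.3)
    names(y) <- design$sample_id
    fit <- split_plot_anova(y, design)
    oracle <- oracle_split_plot_F(y, design)
    got <- fit$F[match(names(oracle), fit$term)]
    expect_equal(got, unname(oracle), tolerance = 1e-8)
    # df bookkeeping: (b-1, 1, b-1, 1, 1, 2b-2) summing to n-1
    expect_identical(fit$df, c(b - 1L, 1L, b - 1L, 1L, 1L, 2L * (b - 1L)))
    expect_equal(sum(fit$ss), sum((y - mean(y))^2), tolerance = 1e-9)
  }
})

test_that("a pure W contrast loads only the W term", {
  design <- make_design(4L)
  y <- ifelse(design$w_treatment, 1, 0)
  names(y) <- design$sample_id
  fit <- split_plot_anova(y, design)
  expect_equal(fit$ss[fit$term == "W"], 4)   # 16 * (0.5)^2
  expect_equal(sum(fit$ss[fit$term != "W"]), 0, tolerance = 1e-12)
  expect_identical(fit$F[fit$term == "W"], Inf)
  expect_equal(fit$p[fit$term == "W"], 0)
})

test_that("constant responses are flagged, incomplete designs rejected", {
  design <- make_design(4L)
  y <- rep(3.3, 16); names(y) <- design$sample_id
  fit <- split_plot_anova(y, design)
  expect_true(attr(fit, "degenerate"))
  expect_true(all(is.nan(fit$F[1:5])))
  incomplete <- experimental_design(design$sample_id[-1], design$block[-1],
                                    design$n_treatment[-1], design$w_treatment[-1])
  expect_error(split_plot_anova(y[-1], incomplete), "complete balanced")
})

test_that("split-plot p-values are uniform under the null", {
  set.seed(22)
  design <- make_design(4L)
  p_w <- replicate(400, {
    y <- rnorm(16); names(y) <- design$sample_id
    fit <- split_plot_anova(y, design)
    c(fit$p[fit$term == "W"], fit$p[fit$term == "N"])
  })
  expect_gt(ks.test(p_w[1, ], "punif")$p.value, 0.01)
  expect_gt(ks.test(p_w[2, ], "punif")$p.value, 0.01)
})

test_that("PERMANOVA pseudo-F matches brute force and vegan::adonis2", {
  set.seed(23)
  for (rep in 1:15) {
    n <- 10L
    X <- matrix(rnorm(n * 3), n, 3)
    dm <- as.matrix(dist(X))
    dimnames(dm) <- list(paste0("s", 1:n), paste0("s", 1:n))
    g <- rep(c("a", "b"), each = n / 2)
    res <- permanova(coreacc:::new_dist_matrix(dm, "euclid"), g,
                     n_perm = 99, seed = rep)
    expect_equal(res$pseudo_F, brute_permanova_F(dm, g), tolerance = 1e-8)
    ad <- suppressMessages(vegan::adonis2(as.dist(dm) ~ g, permutations = 49))
    expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-8)
    expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-8)
    # invariance to sample relabeling
    perm <- sample(n)
    res2 <- permanova(coreacc:::new_dist_matrix(dm[perm, perm], "euclid"),
                      g[perm], n_perm = 99, seed = rep)
    expect_equal(res2$pseudo_F, res$pseudo_F, tolerance = 1e-10)
  }
})

test_that("PERMANOVA permutation p is close to the exact enumeration", {
  # 8 samples, 2 groups of 4: the exact p enumerates all C(8,4)=70 splits
  set.seed(24)
  X <- matrix(rnorm(16), 8, 2)
  X[1:4, ] <- X[1:4, ] + 1.2
  dm <- as.matrix(dist(X))
  dimnames(dm) <- list(paste0("s", 1:8), paste0("s", 1:8))
  g <- rep(c("a", "b"), each = 4)
  f_obs <- brute_permanova_F(dm, g)
  splits <- combn(8, 4)
  f_all <- apply(splits, 2, function(i) {
    gg <- rep("b", 8); gg[i] <- "a"
    brute_permanova_F(dm, gg)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res <- permanova(coreacc:::new_dist_matrix(dm, "euclid"), g,
                   n_perm = 1999, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 1999)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1e-3)
})

test_that("PERMANOVA respects strata and rejects degenerate groupings", {
  dm <- as.matrix(dist(matrix(rnorm(24), 8, 3)))
  dimnames(dm) <- list(paste0("s", 1:8), paste0("s", 1:8))
  d <- coreacc:::new_dist_matrix(dm, "euclid")
  expect_error(permanova(d, c("a", rep("b", 7)), 99, 1), "singleton")
  expect_error(permanova(d, rep("a", 8), 99, 1), "2 levels")
  expect_warning(permanova(d, rep(c("a", "b"), 4), n_perm = 20, seed = 1),
                 "coarse")
})

test_that("Mantel r equals the direct formula and vegan, with affine invariance", {
  set.seed(25)
  for (rep in 1:10) {
    X <- matrix(rnorm(10), 5, 2); Y <- matrix(rnorm(10), 5, 2)
    m1 <- as.matrix(dist(X)); m2 <- as.matrix(dist(Y))
    dimnames(m1) <- dimnames(m2) <- list(paste0("s", 1:5), paste0("s", 1:5))
    res <- mantel(coreacc:::new_dist_matrix(m1, "a"),
                  coreacc:::new_dist_matrix(m2, "b"), n_perm = 99, seed = rep)
    expect_equal(res$r, brute_mantel_r(m1, m2), tolerance = 1e-10)
    vg <- suppressMessages(vegan::mantel(as.dist(m1), as.dist(m2), permutations = 9))
    expect_equal(res$r, unname(vg$statistic), tolerance = 1e-8)
    # affine transform of the same matrix: r = 1
    aff <- mantel(coreacc:::new_dist_matrix(m1, "a"),
                  coreacc:::new_dist_matrix(0.5 * m1 + 0.2, "b"),
                  n_perm = 99, seed = rep)
    expect_equal(aff$r, 1, tolerance = 1e-12)
  }
  # constant distance vector: flagged, not an error
  cm <- matrix(1, 4, 4); diag(cm) <- 0
  dimnames(cm) <- list(paste0("s", 1:4), paste0("s", 1:4))
  m1 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  dimnames(m1) <- dimnames(cm)
  res <- mantel(coreacc:::new_dist_matrix(m1, "a"),
                coreacc:::new_dist_matrix(cm, "b"), 99, 1)
  expect_true(res$constant)
  expect_true(is.na(res$r))
})

test_that("Mantel p is uniform when the matrices are independent", {
  set.seed(26)
  pv <- replicate(300, {
    m1 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
    m2 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
    dimnames(m1) <- dimnames(m2) <- list(paste0("s", 1:7), paste0("s", 1:7))
    mantel(coreacc:::new_dist_matrix(m1, "a"),
           coreacc:::new_dist_matrix(m2, "b"), n_perm = 99,
           seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.04)
})

test_that("permutation procedures are seed-deterministic", {
  dm <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  dimnames(dm) <- list(paste0("s", 1:10), paste0("s", 1:10))
  d <- coreacc:::new_dist_matrix(dm, "euclid")
  g <- rep(c("a", "b"), 5)
  r1 <- permanova(d, g, 199, seed = 42)
  r2 <- permanova(d, g, 199, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  m1 <- mantel(d, d, 199, seed = 42)
  m2 <- mantel(d, d, 199, seed = 42)
  expect_identical(m1$p_value, m2$p_value)
})
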