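test_that("richness equals presence column sums, including empty samples", {
  m <- matrix(TRUE, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_identical(unname(richness(as_presence_matrix(m))), rep(10L, 4))
  m[, 2] <- FALSE
  expect_identical(unname(richness(as_presence_matrix(m))), c(10L, 0L, 10L, 10L))
})

test_that("Bray-Curtis matches hand values and the brute-force formula", {
  # identical columns -> 0; disjoint supports -> 1
  m <- matrix(c(3L, 1L, 0L, 3L, 1L, 0L), 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(bray_curtis(gene_table(m))["s1", "s2"], 0)
  m2 <- matrix(c(3L, 0L, 0L, 4L), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(bray_curtis(gene_table(m2))["s1", "s2"], 1)

  # hand example: p_i = (1,0,3)/4, p_j = (0,2,1)/3 -> 2/3
  m3 <- matrix(c(1L, 0L, 3L, 0L, 2L, 1L), 3,
               dimnames = list(paste0("g", 1:3), c("i", "j")))
  expect_equal(bray_curtis(gene_table(m3))["i", "j"], 2 / 3, tolerance = 1e-12)

  # brute force on random tables, all pairs
  set.seed(11)
  for (rep in 1:25) {
    gt <- random_table(n_genes = 15, n_samples = 4)
    d <- bray_curtis(gt)
    p <- rel_abundance(gt)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(d[i, j], brute_bray(p[, i], p[, j]), tolerance = 1e-12)
    }
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unclass(d), t(unclass(d)), tolerance = 1e-14, ignore_attr = TRUE)
  }
})

test_that("presence dissimilarity is Sorensen and equals Bray-Curtis on 0/1 counts", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE), 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  pm <- as_presence_matrix(m)
  expect_equal(presence_dissimilarity(pm)["s1", "s2"], 0.5)  # {g1,g2} vs {g2,g3}
  ident <- as_presence_matrix(matrix(c(TRUE, FALSE, TRUE, FALSE), 2,
                                     dimnames = list(c("g1", "g2"), c("x", "y"))))
  expect_equal(presence_dissimilarity(ident)["x", "y"], 0)

  set.seed(12)
  for (rep in 1:20) {
    pres <- matrix(runif(60) < 0.5, 15, 4,
                   dimnames = list(sprintf("g%02d", 1:15), paste0("s", 1:4)))
    pres[, 1][1] <- TRUE  # avoid an all-empty matrix
    pm <- as_presence_matrix(pres)
    d <- presence_dissimilarity(pm)
    # brute-force set formula and the Bray-Curtis formula on the raw 0/1
    # vectors (the two coincide by construction)
    sets <- apply(pres, 2, function(col) rownames(pres)[col], simplify = FALSE)
    for (i in 1:3) for (j in (i + 1):4) {
      expected <- if (length(sets[[i]]) + length(sets[[j]]) == 0) 1
                  else brute_sorensen(sets[[i]], sets[[j]])
      expect_equal(d[i, j], expected, tolerance = 1e-12)
      if (length(sets[[i]]) + length(sets[[j]]) > 0) {
        expect_equal(d[i, j], brute_bray(as.numeric(pres[, i]),
                                         as.numeric(pres[, j])),
                     tolerance = 1e-12)
      }
    }
  }

  # with equal per-sample richness, casting 0/1 to counts and running the
  # abundance Bray-Curtis gives the same matrix
  eq <- matrix(FALSE, 8, 3, dimnames = list(sprintf("g%d", 1:8), paste0("s", 1:3)))
  eq[1:4, 1] <- eq[3:6, 2] <- eq[5:8, 3] <- TRUE
  cast <- gene_table(matrix(as.integer(eq), nrow(eq), dimnames = dimnames(eq)))
  expect_equal(unclass(presence_dissimilarity(as_presence_matrix(eq))),
               unclass(bray_curtis(cast)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("empty samples get dissimilarity 1 and are flagged", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  d <- presence_dissimilarity(as_presence_matrix(m))
  expect_equal(d["s1", "s2"], 1)
  expect_identical(attr(d, "flagged_samples"), "s2")
})

test_that("PCoA recovers known geometries", {
  # 3 equidistant points: two equal positive eigenvalues, explained ~ (.5, .5)
  d3 <- matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  diag(d3) <- 0
  ord <- pcoa(coreacc:::new_dist_matrix(d3, "toy"), n_axes = 2)
  expect_equal(ord$explained_fraction, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(max(abs(colMeans(ord$coordinates))), 0, tolerance = 1e-10)

  # collinear points: first axis explains everything
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x))
  dimnames(dl) <- list(paste0("s", 1:4), paste0("s", 1:4))
  ordl <- pcoa(coreacc:::new_dist_matrix(dl, "line"), n_axes = 2)
  expect_equal(ordl$explained_fraction[1], 1, tolerance = 1e-10)

  # random 2-D configurations are reproduced up to rigid motion
  set.seed(13)
  for (rep in 1:10) {
    X <- matrix(rnorm(16), 8, 2)
    dm <- as.matrix(dist(X))
    dimnames(dm) <- list(paste0("s", 1:8), paste0("s", 1:8))
    ord2 <- pcoa(coreacc:::new_dist_matrix(dm, "euclid"), n_axes = 2)
    expect_lt(procrustes_error(X, ord2$coordinates), 1e-8)
    expect_true(all(diff(ord2$explained_fraction) < 1e-12))
    # cross-check against classical scaling in stats::cmdscale
    cs <- stats::cmdscale(dm, k = 2, eig = TRUE)
    expect_lt(procrustes_error(cs$points, ord2$coordinates), 1e-8)
    # reconstructed inter-point distances are exact
    expect_equal(as.matrix(dist(ord2$coordinates)), dm,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("PCoA warns on non-Euclidean input and bounds n_axes", {
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  dm <- coreacc:::new_dist_matrix(d3, "toy")
  expect_error(pcoa(dm, n_axes = 0), "at least 1")
  expect_error(pcoa(dm, n_axes = 3), "at most")
  # a point at distance 1 from every vertex of an equilateral triangle of
  # side 2 cannot exist in Euclidean space (circumradius 2/sqrt(3) > 1)
  dn <- matrix(2, 4, 4); dn[4, ] <- dn[, 4] <- 1; diag(dn) <- 0
  dimnames(dn) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_warning(pcoa(coreacc:::new_dist_matrix(dn, "nonmetric"), 2), "non-Euclidean")
})

test_that("average genome size is the abundance-weighted mean", {
  one <- matrix(1, 1, 2, dimnames = list("t1", c("s1", "s2")))
  expect_equal(unname(average_genome_size(one, c(t1 = 5e6))), c(5e6, 5e6))
  two <- matrix(c(.5, .5, .9, .1), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  ags <- average_genome_size(two, c(a = 2e6, b = 6e6))
  expect_equal(unname(ags), c(4e6, 2.4e6))
  # shifting mass toward the smaller genome strictly decreases AGS
  expect_lt(ags[["s2"]], ags[["s1"]])
  # invariant to taxon order and to zero-abundance taxa
  three <- rbind(two, c = c(0, 0))
  expect_equal(average_genome_size(three[c(3, 2, 1), ], c(b = 6e6, a = 2e6, c = 1e9)),
               ags, tolerance = 1e-12)
  expect_error(average_genome_size(two, c(a = 2e6)), "missing genome size")
  expect_error(average_genome_size(two * 2, c(a = 2e6, b = 6e6)), "sum to 1")
})
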