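test_that("PERMANOVA equals classical ANOVA on 1-D Euclidean data", {
  set.seed(4)
  y <- c(rnorm(5), rnorm(7, 1.5))
  g <- factor(rep(c("a", "b"), c(5, 7)))
  dm <- dist_matrix(as.matrix(stats::dist(y)))
  pm <- permanova(dm, g, n_perm = 99, seed = 1)
  expect_equal(pm$statistic, anova(lm(y ~ g))[["F value"]][1],
               tolerance = 1e-10)
})

test_that("permutation tests reproduce exhaustive enumeration at n = 6", {
  set.seed(9)
  x <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(stats::dist(x))
  dm <- dist_matrix(D)
  g <- factor(rep(c("a", "b"), each = 3))

  # independent statistic implementations for the enumeration oracle
  f_oracle <- function(idx_a) {
    idx_b <- setdiff(1:6, idx_a)
    sst <- sum(D[upper.tri(D)]^2) / 6
    ssw <- (sum(D[idx_a, idx_a]^2) / 2 + sum(D[idx_b, idx_b]^2) / 2) / 3
    ((sst - ssw) / 1) / (ssw / 4)
  }
  delta_oracle <- function(idx_a) {
    idx_b <- setdiff(1:6, idx_a)
    0.5 * mean(D[idx_a, idx_a][upper.tri(diag(3))]) +
      0.5 * mean(D[idx_b, idx_b][upper.tri(diag(3))])
  }
  # dispersion statistic fully recomputed for each relabeling: distances
  # to own-group centroid in the plane (input is Euclidean 2-D)
  disp_oracle <- function(idx_a) {
    idx_b <- setdiff(1:6, idx_a)
    z <- numeric(6)
    for (ix in list(idx_a, idx_b)) {
      cen <- colMeans(x[ix, , drop = FALSE])
      z[ix] <- sqrt(rowSums(sweep(x[ix, , drop = FALSE], 2, cen)^2))
    }
    anova(lm(z ~ factor(1:6 %in% idx_a)))[["F value"]][1]
  }

  pm <- permanova(dm, g, exact = TRUE)
  expect_equal(pm$p_value, oracle_exact_p(f_oracle, 6, 3))
  mr <- mrpp(dm, g, exact = TRUE)
  expect_equal(mr$p_value, oracle_exact_p(delta_oracle, 6, 3, lower = TRUE))
  bd <- betadisper(dm, g, exact = TRUE)
  expect_equal(bd$p_value, oracle_exact_p(disp_oracle, 6, 3))
})

test_that("distance-based statistics agree with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(12)
  x <- matrix(rnorm(30), 15, 2)
  g <- factor(rep(c("a", "b", "c"), each = 5))
  D <- stats::dist(x)
  dm <- dist_matrix(as.matrix(D))
  expect_equal(permanova(dm, g, n_perm = 49, seed = 1)$statistic,
               vegan::adonis2(D ~ g, permutations = 2)$F[1],
               tolerance = 1e-10)
  expect_equal(mrpp(dm, g, n_perm = 49, seed = 1)$statistic,
               vegan::mrpp(D, g, permutations = 2)$delta, tolerance = 1e-10)
  vb <- vegan::betadisper(D, g, type = "centroid")
  bd <- betadisper(dm, g, n_perm = 49, seed = 1)
  expect_equal(unname(bd$distances), unname(vb$distances), tolerance = 1e-8)
})

test_that("permutation p-values are reproducible and never zero", {
  set.seed(5)
  x <- matrix(rnorm(20), 10, 2)
  dm <- dist_matrix(as.matrix(stats::dist(x)))
  g <- factor(rep(c("a", "b"), each = 5))
  p1 <- permanova(dm, g, n_perm = 199, seed = 7)$p_value
  p2 <- permanova(dm, g, n_perm = 199, seed = 7)$p_value
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_error(permanova(dm, factor(c(rep("a", 9), "b")), 99), "singleton")
})

test_that("MRPP separates clustered data and is null on merged groups", {
  # two tight, well-separated clusters
  set.seed(6)
  x <- c(rnorm(4, 0, 0.1), rnorm(4, 10, 0.1))
  dm <- dist_matrix(as.matrix(stats::dist(x)))
  g <- factor(rep(c("a", "b"), each = 4))
  mr <- mrpp(dm, g, exact = TRUE)
  expect_gt(mr$A, 0.5)
  expect_equal(mr$p_value, 1 / choose(8, 4) * 2, tolerance = 1e-12)

  # identical composition in both groups ({0,1,3} twice): no structure
  y <- c(0, 1, 3, 0, 1, 3)
  gy <- factor(rep(c("a", "b"), each = 3))
  mry <- mrpp(dist_matrix(as.matrix(stats::dist(y))), gy, n_perm = 199,
              seed = 2)
  expect_lt(abs(mry$A), 0.25)
  expect_gt(mry$p_value, 0.2)
})

test_that("PCoA reconstructs distances including negative eigenvalues", {
  # three equidistant points: two equal positive eigenvalues
  dm <- dist_matrix(matrix(1, 3, 3) - diag(3))
  pc <- pcoa(dm)
  expect_equal(length(pc$eig), 2)
  expect_equal(pc$eig[1], pc$eig[2], tolerance = 1e-12)
  expect_true(all(pc$eig > 0))

  # Euclidean input: recovered configuration matches up to rigid motion
  set.seed(8)
  x <- matrix(rnorm(20), 10, 2)
  pc <- pcoa(dist_matrix(as.matrix(stats::dist(x))))
  expect_false(any(pc$imaginary))
  xc <- scale(x, scale = FALSE)
  pts <- pc$points[, 1:2]
  # Procrustes: optimal rotation via SVD
  s <- svd(t(pts) %*% xc)
  rot <- pts %*% s$u %*% t(s$v)
  expect_lt(sqrt(mean((rot - xc)^2)), 1e-8)

  # non-Euclidean fixture: squared distances are real minus imaginary parts
  D <- as.matrix(stats::dist(x))
  D[1, 2] <- D[2, 1] <- D[1, 2] * 3
  pc <- pcoa(dist_matrix(D))
  expect_true(any(pc$imaginary))
  sgn <- ifelse(pc$imaginary, -1, 1)
  for (i in 1:9) for (j in (i + 1):10) {
    rec <- sum(sgn * (pc$points[i, ] - pc$points[j, ])^2)
    expect_equal(rec, D[i, j]^2, tolerance = 1e-8)
  }
})

test_that("dispersion test matches Levene form in 1-D and detects spread", {
  set.seed(11)
  y <- c(rnorm(6), rnorm(6, 0, 4))
  g <- factor(rep(c("a", "b"), each = 6))
  bd <- betadisper(dist_matrix(as.matrix(stats::dist(y))), g,
                   n_perm = 199, seed = 3)
  z <- abs(y - stats::ave(y, g))
  expect_equal(bd$statistic, anova(lm(z ~ g))[["F value"]][1],
               tolerance = 1e-10)

  # mirror groups have identical dispersion
  x <- c(0, 1, 4, 10, 11, 14)
  bd0 <- betadisper(dist_matrix(as.matrix(stats::dist(x))),
                    factor(rep(c("a", "b"), each = 3)), n_perm = 99, seed = 1)
  expect_lt(bd0$statistic, 1e-20)
  expect_gt(bd0$p_value, 0.9)

  # compact vs dispersed clusters are detected
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    y <- c(rnorm(8, 0, 0.2), rnorm(8, 0, 3))
    bds <- betadisper(dist_matrix(as.matrix(stats::dist(y))),
                      factor(rep(c("a", "b"), each = 8)),
                      n_perm = 199, seed = s)
    hits <- hits + (bds$p_value <= 0.05)
  }
  expect_gte(hits, 8)
})

test_that("rank tests match hand-computed forms", {
  # disjoint ranges attain the maximum Kruskal-Wallis H for n = 6, a = 3
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), factor(rep(1:3, each = 2)))
  H_direct <- 12 / (6 * 7) * 2 * ((1.5 - 3.5)^2 + 0 + (5.5 - 3.5)^2)
  expect_equal(kw$statistic, H_direct, tolerance = 1e-12)
  expect_equal(kruskal_wallis(rep(1, 6), factor(rep(1:2, 3)))$statistic, 0)
  expect_equal(kruskal_wallis(rep(1, 6), factor(rep(1:2, 3)))$p_value, 1)

  # exact two-sided Wilcoxon: all 6 rank splits of {1,2} vs {3,4}
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3, tolerance = 1e-12)
  expect_gte(wilcoxon_rank_sum(1:4, 1:4)$p_value, 0.99)
  # approximation accuracy at n = 8 vs 8
  set.seed(13)
  x <- rnorm(8); y <- rnorm(8)
  exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  approx_p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(wilcoxon_rank_sum(x, y)$p_value - exact_p), 1e-12)
  expect_lt(abs(approx_p - exact_p), 0.05)
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  f <- fisher_exact_2x2(rbind(c(0, 5), c(5, 0)))
  expect_equal(f$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  f2 <- fisher_exact_2x2(rbind(c(3, 4), c(3, 4)))
  expect_equal(f2$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(f2$p_value, 1)
  # direct enumeration for [[3,1],[1,3]]
  probs <- sapply(0:4, function(k) stats::dhyper(k, 4, 4, 4))
  obs <- stats::dhyper(3, 4, 4, 4)
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3)))$p_value,
               sum(probs[probs <= obs + 1e-12]), tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("differential abundance is calibrated and powered", {
  pool <- make_source_pool(60, seed = 3)
  ids <- function(n) paste0("s", seq_len(n))
  # null: two identical neutral groups
  minp <- sapply(1:5, function(s) {
    tab <- simulate_neutral_community(
      pool, sim_config(60, 16, m = 0.5, depth = 1000, seed = 600 + s))
    md <- small_metadata(rownames(tab),
                         treatment = rep(c("Ctrl", "CC"), each = 8))
    da <- differential_abundance(tab, md, "treatment", c("Ctrl", "CC"))
    min(da$p_adj, na.rm = TRUE)
  })
  expect_gte(sum(minp > 0.05), 4)

  # a strong induced shift is detected
  tab <- simulate_neutral_community(
    pool, sim_config(60, 48, m = 0.5, depth = 1000, seed = 99))
  m <- unclass(tab)
  m[25:48, 1] <- m[25:48, 1] + 120L   # ~10x abundance shift in group CC
  tab <- count_table(m)
  md <- small_metadata(rownames(tab),
                       treatment = rep(c("Ctrl", "CC"), each = 24))
  da <- differential_abundance(tab, md, "treatment", c("Ctrl", "CC"))
  expect_equal(nrow(da), 60)
  expect_lte(da$p_adj[1], 0.05)

  expect_error(differential_abundance(tab, md, "treatment", c("Ctrl", "CV")),
               "absent")
})
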