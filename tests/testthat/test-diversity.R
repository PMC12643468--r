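test_that("Shannon and Gini-Simpson match their closed forms", {
  expect_equal(shannon(rep(5, 4)), log(4))
  expect_equal(shannon(c(0, 7, 0)), 0)
  # hand entropy oracle for [1, 1, 2]
  p <- c(0.25, 0.25, 0.5)
  expect_equal(shannon(c(1, 1, 2)), -sum(p * log(p)))
  expect_equal(shannon(c(1, 1, 2)), 1.0397, tolerance = 1e-4)
  expect_equal(simpson(c(9, 0)), 0)
  expect_equal(simpson(c(3, 3)), 0.5)
  for (S in c(2, 5, 17)) expect_equal(simpson(rep(4, S)), 1 - 1 / S)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(simpson(numeric(0)), "all-zero")
})

test_that("diversity bounds hold with equality only at uniformity", {
  set.seed(13)
  for (i in 1:25) {
    x <- rpois(30, 10) + 1
    expect_lte(shannon(x), log(sum(x > 0)) + 1e-12)
    expect_lte(simpson(x), 1 - 1 / sum(x > 0) + 1e-12)
    # concentration: moving mass from the rarest to the most abundant
    # taxon never increases diversity
    y <- x
    i_max <- which.max(x); i_min <- which.min(x)
    y[i_max] <- y[i_max] + 1; y[i_min] <- y[i_min] - 1
    expect_lte(shannon(y), shannon(x) + 1e-12)
    expect_lte(simpson(y), simpson(x) + 1e-12)
  }
})

test_that("Bray-Curtis follows its definition and invariances", {
  m <- matrix(c(2, 2, 1, 1), 2, dimnames = list(NULL, c("u", "v")))
  expect_equal(as.numeric(bray_curtis(m)), 1 / 3)
  same <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disjoint <- cbind(a = c(4, 0), b = c(0, 9))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  set.seed(2)
  x <- matrix(rpois(40, 8), 10, 4)
  d <- as.matrix(bray_curtis(x))
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(as.matrix(bray_curtis(3.7 * x)), d)  # joint rescaling
  x[, 2] <- 0
  expect_error(bray_curtis(x), "all-zero")
})

test_that("PCoA reproduces Euclidean geometry exactly", {
  # points on a line: axis 1 recovers the line up to sign/translation
  pts <- c(0, 1, 4, 9)
  ord <- pcoa(dist(pts))
  ax1 <- ord$coordinates[, 1]
  expect_equal(abs(diff(ax1)), diff(pts), tolerance = 1e-8)
  # full reconstruction of Euclidean input distances
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3)
  ord <- pcoa(dist(X))
  expect_equal(as.matrix(dist(ord$coordinates)), as.matrix(dist(X)),
               tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
  # equilateral triangle: two equal positive eigenvalues
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  eig <- pcoa(tri)$eigenvalues
  expect_equal(eig[1], eig[2], tolerance = 1e-10)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA partitions distance sums of squares", {
  # perfect separation: zero within-group distances, R^2 = 1, and the
  # add-one p can only count permutations regenerating the same partition
  d <- matrix(1, 8, 8) - diag(8)
  d[1:4, 1:4] <- 0; d[5:8, 5:8] <- 0
  res <- permanova(as.dist(d), rep(c("a", "b"), each = 4), n_perm = 999,
                   seed = 1)
  expect_equal(res$r_squared, 1)
  expect_lt(res$p, 0.1)  # 2/choose(8,4) of labelings preserve the split
  expect_gte(res$p, 1 / (res$n_perm + 1))

  # observed F against an independently coded oracle at n = 6, plus vegan
  set.seed(6)
  X <- matrix(rnorm(12), 6, 2)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  d <- dist(X)
  res <- permanova(d, g, n_perm = 199, seed = 2)
  dm <- as.matrix(d)^2
  n <- 6; k <- 2
  sst <- sum(dm[lower.tri(dm)]) / n
  ssw <- sum(dm[1:3, 1:3][lower.tri(dm[1:3, 1:3])]) / 3 +
    sum(dm[4:6, 4:6][lower.tri(dm[4:6, 4:6])]) / 3
  f_oracle <- ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  expect_equal(res$pseudo_F, f_oracle, tolerance = 1e-12)
  expect_equal(res$r_squared + ssw / sst, 1, tolerance = 1e-9)
  ad <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-9)
  expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-9)

  expect_error(permanova(d, rep("a", 6)), "2 groups")
  expect_error(permanova(d, c("a", "a", "a", "a", "a", "b")), "2 members")
})

test_that("PERMANOVA p-values are uniform under the null", {
  set.seed(10)
  pvals <- replicate(150, {
    X <- matrix(rnorm(24), 12, 2)
    g <- rep(c("a", "b"), each = 6)
    permanova(dist(X), g, n_perm = 99)$p
  })
  # discrete permutation p-values tie; KS is used as an approximate check
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("beta dispersion flags diffuse groups and excludes singletons", {
  same <- matrix(0, 6, 6)
  res <- beta_dispersion(as.dist(same), rep(c("a", "b"), 3), n_perm = 99,
                         seed = 1)
  expect_equal(unname(res$distances), rep(0, 6), tolerance = 1e-12)

  set.seed(15)
  tight <- matrix(rnorm(20, sd = 0.05), 10, 2)
  diffuse <- matrix(rnorm(20, sd = 2), 10, 2)
  d <- dist(rbind(tight, diffuse))
  g <- rep(c("tight", "diffuse"), each = 10)
  res <- beta_dispersion(d, g, n_perm = 999, seed = 3)
  expect_lt(res$p, 0.05)
  expect_true(all(c("diff", "p adj") %in% colnames(res$pairwise)))

  expect_warning(
    beta_dispersion(dist(rbind(tight, diffuse[1, , drop = FALSE],
                               diffuse[1:10, ])),
                    c(rep("a", 10), "c", rep("b", 10)), n_perm = 99),
    "singleton")
})

test_that("Spearman correlation uses mid-ranks and asymptotic p", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_error(spearman_cor(1:4, rep(2, 4)), "constant")
  expect_error(spearman_cor(1:3, 1:3), ">= 4")
})

test_that("Dunn test matches Kruskal-Wallis for two groups and Holm is step-down", {
  set.seed(20)
  v <- rnorm(16); g <- rep(c("a", "b"), each = 8)
  dn <- dunn_test(v, g)
  kw <- kruskal.test(v, factor(g))
  expect_equal(dn$z^2, unname(kw$statistic), tolerance = 1e-12)
  # brute-force step-down oracle for Holm
  holm_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
    adj <- cummax(adj)
    out <- numeric(m); out[o] <- adj
    out
  }
  expect_equal(holm_oracle(c(0.01, 0.04)), c(0.02, 0.04))
  for (i in 1:10) {
    p <- runif(sample(2:10, 1))
    expect_equal(p.adjust(p, "holm"), holm_oracle(p))
  }
  v3 <- c(rnorm(6), rnorm(6, 10), rnorm(6, 20))
  g3 <- rep(c("a", "b", "c"), each = 6)
  dn3 <- dunn_test(v3, g3)
  expect_equal(dn3$p_adj, p.adjust(dn3$p, "holm"))
})

test_that("group comparisons choose designs and detect planted shifts", {
  set.seed(22)
  x <- c(rnorm(8), rnorm(8, 5))  # 5 SD shift
  g <- rep(c("a", "b"), each = 8)
  res <- compare_groups(x, g, design = "wilcoxon")
  expect_lt(res$omnibus$p, 0.01)

  gauss <- rnorm(24)
  g3 <- rep(c("a", "b", "c"), each = 8)
  res <- compare_groups(gauss, g3, design = "auto")
  expect_equal(res$design, "anova_tukey")
  skewed <- rlnorm(24, sdlog = 2.5)
  res2 <- compare_groups(skewed, g3, design = "auto")
  expect_equal(res2$design, "kw_dunn_holm")
  expect_true(all(c("z", "p_adj") %in% colnames(res2$pairwise)))
  expect_error(compare_groups(1:5, c("a", "a", "b", "b", "c")), ">= 2")
})

test_that("group-test p-values are uniform under permuted labels", {
  set.seed(30)
  pvals <- replicate(150, {
    compare_groups(rnorm(18), sample(rep(c("a", "b", "c"), 6)),
                   design = "kw_dunn_holm")$omnibus$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
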