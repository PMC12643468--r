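test_that("ASV filtering removes unassigned, organelle and blank taxa", {
  ids <- sprintf("t%02d", 1:10)
  counts <- matrix(5L, 10, 2, dimnames = list(ids, c("s1", "s2")))
  tax <- toy_taxonomy(ids)
  tax[c("t01", "t02"), "phylum"] <- ""          # phylum-unassigned
  tax["t03", "family"] <- "Chloroplast"         # organelle at any rank
  blanks <- "t04"
  out <- filter_asvs(counts, tax, blanks)
  # brute-force oracle: set subtraction
  expect_setequal(rownames(out), setdiff(ids, c("t01", "t02", "t03", "t04")))
  expect_equal(attr(out, "removal"),
               list(unassigned = 2L, organelle = 1L, blank = 1L))
  expect_equal(rownames(out), ids[5:10])  # order preserved

  expect_identical(rownames(filter_asvs(counts, toy_taxonomy(ids))), ids)
  expect_warning(filter_asvs(counts, toy_taxonomy(ids), blank_asvs = ids),
                 "all taxa removed")
  expect_error(filter_asvs(counts, tax[1:5, ], blanks), "does not cover")
})

test_that("rarefaction subsamples without replacement to exact depth", {
  set.seed(3)
  counts <- matrix(rpois(40, 50), 8, 5,
                   dimnames = list(paste0("t", 1:8), paste0("s", 1:5)))
  counts[, 5] <- 0L; counts[1, 5] <- 10L  # shallow sample
  storage.mode(counts) <- "integer"
  depth <- 100
  r <- rarefy_counts(counts, depth, seed = 9)
  expect_equal(attr(r, "dropped"), "s5")
  expect_true(all(colSums(r) == depth))
  expect_true(all(r <= counts[, colnames(r)]))  # without replacement
  # a sample whose total equals depth is returned unchanged
  cexact <- matrix(c(60L, 30L, 10L), 3, 1, dimnames = list(NULL, "s"))
  expect_equal(rarefy_counts(cexact, 100, seed = 1)[, 1], cexact[, 1])
  # reproducible under the same seed
  expect_identical(r, rarefy_counts(counts, depth, seed = 9))
  expect_error(rarefy_counts(counts, 0), "depth")
})

test_that("rarefied counts are unbiased: E[count] = depth * proportion", {
  counts <- matrix(c(600L, 300L, 100L), 3, 1,
                   dimnames = list(c("a", "b", "c"), "s"))
  draws <- vapply(1:300, function(i)
    rarefy_counts(counts, 100, seed = i)[, 1], numeric(3))
  m <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(m - c(60, 30, 10)) <= 3 * se + 1e-9))
})

test_that("relative abundances normalise each sample to 1", {
  m <- matrix(c(5, 5, 10, 1, 0, 0), 3, 2,
              dimnames = list(letters[1:3], c("s1", "s2")))
  rel <- relative_abundance(m)
  expect_equal(rel[, "s1"], c(a = 0.25, b = 0.25, c = 0.5))
  expect_equal(unname(colSums(rel)), c(1, 1))
  m[, 2] <- 0
  expect_error(relative_abundance(m), "zero-total")
})

test_that("standard curves recover slope, efficiency and R^2", {
  q <- 0.836 * 10^(0:-4)
  # perfect doubling: slope -1/log10(2)
  cq <- -3.321928 * log10(q) + 10
  curve <- fit_standard_curve(q, cq)
  expect_equal(curve$efficiency, 1, tolerance = 1e-6)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$slope, -3.321928, tolerance = 1e-9)

  curve3 <- fit_standard_curve(q, -3 * log10(q) + 12)
  expect_equal(curve3$efficiency, 10^(1 / 3) - 1, tolerance = 1e-9)

  expect_error(fit_standard_curve(q, 3 * log10(q) + 10), "slope")
  expect_error(fit_standard_curve(q[1:2], cq[1:2]), ">= 3")
  expect_error(fit_standard_curve(c(1, 2, 3), c(10, 9, 8)), "2 log10")
})

test_that("standard-curve fits are unbiased under Gaussian Cq noise", {
  q <- 0.836 * 10^(0:-4)
  true_slope <- -3.23
  set.seed(11)
  slopes <- replicate(300, {
    fit_standard_curve(rep(q, 3),
                       true_slope * log10(rep(q, 3)) + 9.75 +
                         rnorm(15, 0, 0.15))$slope
  })
  expect_lt(abs(mean(slopes) - true_slope),
            3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("copies_per_gram inverts the curve and scales by mass", {
  q <- 10^seq(0, -4)
  curve <- fit_standard_curve(q, -3.3 * log10(q) + 10)
  # Cq exactly at a standard point, unit scaling -> that quantity / mass
  cq0 <- -3.3 * log10(q[2]) + 10
  expect_equal(copies_per_gram(cq0, curve, elution_volume_ul = 1,
                               soil_mass_g = 1, copies_per_ng = 1),
               q[2], tolerance = 1e-9)
  base <- copies_per_gram(c(20, 20.1, 19.9), curve, 100, 0.25)
  expect_equal(copies_per_gram(c(20, 20.1, 19.9), curve, 100, 0.125),
               2 * base)  # halving soil mass doubles copies per gram
  expect_equal(copies_per_gram(20, curve, 100, 0.25), base,
               tolerance = 1e-12)  # triplicate averaged before inversion
  expect_warning(copies_per_gram(35, curve, 100, 0.25), "extrapolating")
})

test_that("absolute abundance scales columns to qPCR totals and back", {
  rel <- relative_abundance(matrix(c(1, 3, 2, 2), 2,
                                   dimnames = list(c("a", "b"),
                                                   c("s1", "s2"))))
  tot <- c(s1 = 4e7, s2 = 2e7)
  ab <- absolute_abundance(rel, tot)
  expect_equal(ab["a", "s1"], 1e7)
  expect_equal(unname(colSums(ab)), unname(tot))
  expect_equal(relative_abundance(ab), rel)  # renormalisation round trip
  expect_error(absolute_abundance(rel, tot["s1"]), "missing qPCR")
})

test_that("CLR transform centres log abundances per sample", {
  m <- matrix(c(2, 8, 1, 1), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  clr <- clr_transform(m)
  expect_equal(clr[, "s1"], c(a = -log(2), b = log(2)))
  expect_equal(clr[, "s2"], c(a = 0, b = 0))
  expect_equal(unname(colSums(clr)), c(0, 0))
  m[1, 1] <- 0
  expect_error(clr_transform(m), "pseudocount")
  expect_equal(unname(colSums(clr_transform(m, pseudocount = 0.5))), c(0, 0))
})
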