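test_that("pseudocount addition preserves ordering and removes zeros", {
  m <- matrix(c(0, 5, 2, 0), 2)
  out <- pseudocount_adjust(m)
  expect_equal(out[1, 1], 0.01)
  expect_equal(out[2, 1], 5.01)
  expect_equal(min(out), 0.01)
  expect_identical(order(m), order(out))
  expect_error(pseudocount_adjust(m, 0), "amount")
})

test_that("log response ratio matches the delta-method formula", {
  # vectors constructed to have exactly mean 2 sd 0.2 and mean 4 sd 0.4
  d <- 0.2 * sqrt(3) / 2
  pre <- c(2 - d, 2 - d, 2 + d, 2 + d)
  post <- 2 * pre
  expect_equal(sd(pre), 0.2)
  out <- log_response_ratio(pre, post)
  expect_equal(unname(out["rr"]), log(2), tolerance = 1e-12)
  # independent hand oracle: sqrt(sd_post^2/(n mean_post^2) +
  #                               sd_pre^2/(n mean_pre^2))
  expect_equal(unname(out["se"]),
               sqrt(0.4^2 / (4 * 16) + 0.2^2 / (4 * 4)), tolerance = 1e-12)
  expect_equal(unname(out["se"]), 0.07071068, tolerance = 1e-7)

  expect_equal(unname(log_response_ratio(c(1, 2, 3), c(3, 2, 1))["rr"]), 0)
  expect_error(log_response_ratio(1, c(1, 2)), "replicates")
  expect_error(log_response_ratio(c(0, 1), c(1, 2)), "pseudocount")
})

test_that("rr is antisymmetric and invariant to joint rescaling", {
  set.seed(21)
  for (i in 1:20) {
    pre <- rlnorm(4); post <- rlnorm(4)
    a <- log_response_ratio(pre, post)
    b <- log_response_ratio(post, pre)
    expect_equal(unname(a["rr"]), -unname(b["rr"]))
    k <- runif(1, 0.1, 100)
    expect_equal(unname(log_response_ratio(k * pre, k * post)["rr"]),
                 unname(a["rr"]))
  }
})

test_that("significance follows the two-tailed normal test", {
  out <- rr_significance(0, 1)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)
  expect_equal(rr_significance(1.959964, 1)$p, 0.05, tolerance = 1e-6)
  expect_equal(rr_significance(-0.7, 0.2)$p, rr_significance(0.7, 0.2)$p)
  # zero-variance policy: equal constant groups are uninformative...
  expect_equal(rr_significance(0, 0)$p, 1)
  # ...but differing means with zero estimated variance are flagged extreme
  expect_lt(rr_significance(0.5, 0)$p, 1e-10)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  # independent oracle: q_i = min over j with p_(j) >= p_(i) of m p_(j)/rank
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      cand <- vapply(which(p[o] >= p[o][i]), function(j)
        m * p[o][j] / j, 0)
      q[o[i]] <- min(1, cand)
    }
    q
  }
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    # rejection-set equivalence with the classic largest-k definition
    alpha <- runif(1, 0.01, 0.2)
    ps <- sort(p)
    k <- suppressWarnings(max(which(ps <= seq_along(ps) * alpha / length(p))))
    brute <- if (is.finite(k)) p <= ps[k] else rep(FALSE, length(p))
    expect_identical(bh_adjust(p) < alpha, brute)
  }
})

test_that("responder classification is inclusive at the two-fold boundary", {
  expect_true(classify_responders(log(2), 0.04))
  expect_false(classify_responders(0.5, 0.001))
  expect_false(classify_responders(2.0, 0.2))
  expect_false(classify_responders(-log(2) - 1, 0.001))
})

test_that("common responders intersect sites and map to genus", {
  expect_equal(common_responders(list(a = c("x", "y"), b = c("z"))),
               character(0))
  expect_setequal(common_responders(list(a = c("x", "y"), b = c("x", "y"))),
                  c("x", "y"))
  sets <- list(s1 = c("a", "b", "c"), s2 = c("b", "c", "d"), s3 = "c")
  expect_equal(common_responders(sets), "c")
  tax <- toy_taxonomy(c("a", "b", "c", "d"), genus = paste0("G", 1:4))
  expect_equal(common_responders(sets, "genus", taxonomy = tax), "G3")
  expect_error(common_responders(sets["s1"]), ">= 2 sites")
})

test_that("thaw_rr recovers planted responders and the common subset", {
  sim <- small_sim(seed = 31)
  cur <- curated_abundance(sim)
  fit <- thaw_rr(cur$abs, sim$metadata, taxonomy = sim$taxonomy,
                 counts = cur$filtered)
  expect_s3_class(fit, "thaw_rr")
  rec <- fit$records
  expect_true(all(rec$q >= rec$p))
  expect_equal(rec$z[rec$se > 0], (rec$rr / rec$se)[rec$se > 0])
  expect_true(all(rec$responder ==
                    (rec$q < 0.05 & rec$rr >= log(2))))
  sens <- vapply(names(fit$responders), function(s)
    mean(sim$truth$planted[[s]] %in% fit$responders[[s]]), 0)
  expect_true(all(sens >= 0.9))
  expect_true(all(sim$truth$common %in% fit$common$asv))
  expect_true(all(sort(unique(sim$taxonomy[sim$truth$common, "genus"])) %in%
                    fit$common$genus))
  # CLR robustness variant agrees on strong planted effects
  expect_gte(fit$clr$mean_jaccard, 0.8)

  cf <- coef(fit)
  expect_equal(sort(colnames(cf)), sort(names(fit$responders)))
  expect_equal(cf[rec$taxon_id[1], rec$site[1]], rec$rr[1])
  expect_output(print(fit), "common responders")
  expect_output(print(summary(fit)), "Per-site")
})

test_that("single-site fits warn and produce an empty common set", {
  sim <- null_sim(seed = 8)
  cur <- curated_abundance(sim)
  expect_warning(fit <- thaw_rr(cur$abs, sim$metadata), "fewer than 2")
  expect_length(fit$common$asv, 0)
  expect_named(fit$responders, "PT")
})

test_that("taxa absent at a site in both phases are excluded from testing", {
  sim <- small_sim(seed = 33)
  cur <- curated_abundance(sim)
  fit <- suppressWarnings(thaw_rr(cur$abs, sim$metadata))
  for (s in names(fit$responders)) {
    ids <- sim$metadata$sample_id[sim$metadata$site == s]
    ids <- intersect(ids, colnames(cur$abs))
    absent <- rownames(cur$abs)[rowSums(cur$abs[, ids, drop = FALSE]) == 0]
    expect_length(intersect(absent,
                            fit$records$taxon_id[fit$records$site == s]), 0)
  }
})
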