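# Alpha/beta diversity and the study-level inferential statistics: Shannon,
# Gini-Simpson, Bray-Curtis, PCoA, PERMANOVA, beta-dispersion, Spearman
# correlation and group comparisons.

#' Shannon diversity (nats)
#'
#' H = -sum p_i ln p_i over the non-zero proportions; natural log, the
#' community-ecology convention. Delegates to [vegan::diversity()].
#'
#' @param counts Non-negative vector with positive total.
#' @return Shannon index in nats; at most ln(richness), with equality for a
#'   perfectly even community.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop_domain("counts must be >= 0")
  if (sum(counts) <= 0) stop_domain("all-zero community")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Gini-Simpson diversity
#'
#' 1 - sum p_i^2: the probability that two randomly drawn reads belong to
#' different taxa. High values (near 1) indicate diverse communities, the
#' form consistent with published permafrost pre-thaw values of 0.83-0.99.
#'
#' @param counts Non-negative vector with positive total.
#' @return Index in \[0, 1); at most 1 - 1/richness.
#' @export
simpson <- function(counts) {
  if (any(counts < 0)) stop_domain("counts must be >= 0")
  if (sum(counts) <= 0) stop_domain("all-zero community")
  unname(vegan::diversity(counts, index = "simpson"))
}

#' Per-sample alpha diversity table
#'
#' @param counts Matrix, taxa x samples (by convention the rarefied table,
#'   so all samples share one sampling effort).
#' @return Data.frame with columns `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(counts) {
  stopifnot(is.matrix(counts))
  data.frame(sample_id = colnames(counts),
             shannon = apply(counts, 2, shannon),
             simpson = apply(counts, 2, simpson),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(u, v) = sum |u_i - v_i| / sum (u_i + v_i), bounded in \[0, 1\].
#' Delegates to [vegan::vegdist()].
#'
#' @param counts Non-negative matrix, taxa x samples; no sample may be
#'   all-zero (the dissimilarity of two empty samples is undefined).
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  if (any(counts < 0)) stop_domain("negative abundances")
  if (any(colSums(counts) == 0))
    stop_domain("all-zero sample(s); Bray-Curtis undefined")
  vegan::vegdist(t(counts), method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the double-centred Gower matrix. Coordinates are
#' built from the positive eigenvalues only; negative eigenvalues (possible
#' for non-Euclidean dissimilarities such as Bray-Curtis) are reported, not
#' corrected - no Lingoes/Cailliez adjustment is applied.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @return List of class `pcoa_result`: `coordinates` (samples x positive
#'   axes, ordered by non-increasing eigenvalue), `eigenvalues` (all, sorted
#'   decreasing), `prop_explained` (per positive axis, relative to the sum
#'   of positive eigenvalues).
#' @export
pcoa <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop_domain("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  # k = n - 1 is requested deliberately; cmdscale warns when some of those
  # axes have non-positive eigenvalues, which is expected for non-Euclidean
  # dissimilarities and handled below
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 prop_explained = eig[pos] / sum(eig[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3, length(x$prop_explained))
  cat(sprintf("PCoA: %d samples, %d positive axes (%d negative eigenvalues)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              sum(x$eigenvalues < 0)))
  cat(sprintf("  proportion explained, first %d axes: %s\n", k,
              paste(sprintf("%.1f%%", 100 * x$prop_explained[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix. The total sum of squares is sum of squared dissimilarities
#' divided by n; the within-group sum is the analogous quantity within each
#' group; pseudo-F = (SS_between/(k-1)) / (SS_within/(n-k)) and
#' R^2 = SS_between/SS_total. The p-value permutes group labels (never
#' distances) and uses the add-one estimator
#' p = (1 + #\{permuted F >= observed\}) / (1 + n_perm), so it is never zero
#' and never below 1/(n_perm + 1).
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @param groups Factor-like group labels, >= 2 groups with >= 2 members.
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Seed for the permutation stream.
#' @return List of class `permanova_result`: `pseudo_F`, `r_squared`, `p`,
#'   `n_perm`, `seed`, `ss` (between/within/total).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) stop_domain("groups must match the matrix size")
  if (nlevels(droplevels(groups)) < 2) stop_domain("need >= 2 groups")
  if (any(table(groups) < 2)) stop_domain("every group needs >= 2 members")
  if (n_perm < 99) stop_domain("n_perm must be >= 99")
  dm2 <- as.matrix(d)^2
  ss_total <- sum(dm2[lower.tri(dm2)]) / n
  k <- nlevels(droplevels(groups))
  f_stat <- function(g) {
    ss_within <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        sub <- dm2[idx, idx]
        ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
      }
    }
    ss_between <- ss_total - ss_within
    c(F = (ss_between / (k - 1)) / (ss_within / (n - k)),
      r2 = ss_between / ss_total, ssw = ss_within)
  }
  obs <- f_stat(groups)
  perm_f <- local_seed(seed, vapply(seq_len(n_perm), function(i)
    f_stat(groups[sample.int(n)])[1L], 0))
  structure(list(pseudo_F = unname(obs["F"]),
                 r_squared = unname(obs["r2"]),
                 p = (1 + sum(perm_f >= obs["F"])) / (1 + n_perm),
                 n_perm = n_perm, seed = seed,
                 ss = c(between = ss_total - unname(obs["ssw"]),
                        within = unname(obs["ssw"]), total = ss_total)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r_squared, x$p, x$n_perm))
  invisible(x)
}

#' Two-factor PERMANOVA report (site and thaw)
#'
#' Sequential (type-I) PERMANOVA of `d ~ site + phase` via
#' [vegan::adonis2()], computed in both term orders, since sequential sums
#' of squares depend on ordering in unbalanced designs. Both tables are
#' returned.
#'
#' @param d Dissimilarity `dist`.
#' @param site,phase Group labels aligned with `d`.
#' @param n_perm Permutations.
#' @param seed Seed.
#' @return List with elements `site_first` and `phase_first` (adonis2
#'   tables).
#' @export
permanova_site_thaw <- function(d, site, phase, n_perm = 999, seed = NULL) {
  df <- data.frame(site = factor(site), phase = factor(phase))
  local_seed(seed, list(
    site_first = vegan::adonis2(d ~ site + phase, data = df,
                                permutations = n_perm, by = "terms"),
    phase_first = vegan::adonis2(d ~ phase + site, data = df,
                                 permutations = n_perm, by = "terms")))
}

#' Homogeneity of multivariate dispersion
#'
#' Distances of samples to their group centroid in principal-coordinate
#' space (negative-eigenvalue axes handled by subtracting their squared
#' contributions), a permutation F-test on those distances, and Tukey-style
#' pairwise comparisons. Delegates to [vegan::betadisper()] and
#' [vegan::permutest()]. Groups of size 1 are flagged and excluded.
#'
#' @param d Dissimilarity `dist`.
#' @param groups Group labels.
#' @param n_perm Permutations for the F-test.
#' @param seed Seed for the permutation stream.
#' @return List: `distances` (per-sample distance to own centroid), `F`,
#'   `p`, `pairwise` (TukeyHSD table), `excluded` (singleton groups), and
#'   the underlying `betadisper` object.
#' @export
beta_dispersion <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2]
  if (length(excluded)) {
    warning("excluding singleton group(s): ", paste(excluded, collapse = ", "))
    keep <- !(groups %in% excluded)
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop_domain("need >= 2 groups of size >= 2")
  if (max(d) == 0) {
    # degenerate: all samples identical, every distance to centroid is 0
    return(list(distances = stats::setNames(rep(0, attr(d, "Size")),
                                            labels(d)),
                F = 0, p = 1, pairwise = NULL, excluded = excluded,
                betadisper = NULL))
  }
  bd <- vegan::betadisper(d, groups, type = "centroid")
  pt <- local_seed(seed, vegan::permutest(bd, permutations = n_perm))
  list(distances = bd$distances,
       F = pt$tab$F[1L], p = pt$tab$`Pr(>F)`[1L],
       pairwise = stats::TukeyHSD(bd)$group,
       excluded = excluded, betadisper = bd)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with the p-value from the standard
#' large-sample approximation (no exact enumeration), as used to relate
#' qPCR gene copy numbers to cumulative respiration.
#'
#' @param x,y Numeric vectors of equal length >= 4, neither constant.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  if (length(x) < 4) stop_domain("need >= 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_domain("rho undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Dunn's post-hoc test
#'
#' Pairwise z-tests on mean rank differences using the pooled
#' Kruskal-Wallis ranking with the usual tie correction, adjusted with
#' Holm's method by default. (For two groups the squared Dunn z equals the
#' Kruskal-Wallis statistic.)
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param p_adjust Adjustment method for [stats::p.adjust()].
#' @return Data.frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "holm") {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop_domain("need >= 2 groups")
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  z <- apply(pairs, 2, function(pr) {
    sigma <- sqrt((n * (n + 1) / 12 - tie_term) *
                    (1 / sizes[pr[1L]] + 1 / sizes[pr[2L]]))
    (mean_rank[pr[1L]] - mean_rank[pr[2L]]) / sigma
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = unname(z),
             p = unname(p), p_adj = stats::p.adjust(p, p_adjust),
             stringsAsFactors = FALSE)
}

#' Compare a variable across groups
#'
#' Runs the study's group-test designs: non-parametric Kruskal-Wallis with
#' Dunn/Holm post-hocs (`"kw_dunn_holm"`), one-way ANOVA with Tukey's HSD
#' (`"anova_tukey"`), or a two-group Wilcoxon rank-sum test (`"wilcoxon"`).
#' Normality (Shapiro-Wilk per group) and homogeneity of variance (Levene)
#' prechecks are always reported; with `design = "auto"` they pick ANOVA
#' when both hold (all p > 0.05) and Kruskal-Wallis otherwise.
#'
#' @param values Numeric vector.
#' @param groups Group labels (every group needs >= 2 observations).
#' @param design One of `"auto"`, `"kw_dunn_holm"`, `"anova_tukey"`,
#'   `"wilcoxon"`.
#' @return List: `design`, `prechecks` (shapiro p per group, levene p),
#'   `omnibus` (statistic, p), `pairwise` (post-hoc table or NULL).
#' @export
compare_groups <- function(values, groups,
                           design = c("auto", "kw_dunn_holm", "anova_tukey",
                                      "wilcoxon")) {
  design <- match.arg(design)
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) < 2))
    stop_domain("every group needs >= 2 observations")
  shapiro_p <- vapply(split(values, groups), function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, 0)
  levene_p <- tryCatch(
    car::leveneTest(values ~ groups)[["Pr(>F)"]][1L],
    error = function(e) NA_real_)
  if (design == "auto") {
    normal_ok <- all(is.na(shapiro_p) | shapiro_p > 0.05) &&
      (is.na(levene_p) || levene_p > 0.05)
    design <- if (normal_ok) "anova_tukey" else "kw_dunn_holm"
  }
  prechecks <- list(shapiro_p = shapiro_p, levene_p = levene_p)
  if (design == "wilcoxon") {
    if (nlevels(groups) != 2) stop_domain("wilcoxon needs exactly 2 groups")
    wt <- stats::wilcox.test(values ~ groups, exact = FALSE)
    return(list(design = design, prechecks = prechecks,
                omnibus = list(statistic = unname(wt$statistic),
                               p = wt$p.value),
                pairwise = NULL))
  }
  if (design == "anova_tukey") {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$groups
    return(list(design = design, prechecks = prechecks,
                omnibus = list(statistic = tab$`F value`[1L],
                               p = tab$`Pr(>F)`[1L]),
                pairwise = tk))
  }
  kw <- stats::kruskal.test(values, groups)
  list(design = design, prechecks = prechecks,
       omnibus = list(statistic = unname(kw$statistic), p = kw$p.value),
       pairwise = dunn_test(values, groups, "holm"))
}
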