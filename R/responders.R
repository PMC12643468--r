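# Thaw-responder identification: per-taxon log response ratios of post- vs
# pre-thaw absolute abundance with delta-method standard errors, Z-tests,
# Benjamini-Hochberg FDR control and a fold-change rule, plus the cross-site
# intersection of responders.

#' Add a pseudocount to an abundance table
#'
#' Adds a small constant to every cell so log ratios are defined for zero
#' cells while the ordering (presence/absence structure) of cells is
#' preserved. Addition, not multiplication: multiplying cannot eliminate
#' zeros.
#'
#' @param x Numeric matrix or vector.
#' @param amount Pseudocount (> 0), default 0.01.
#' @return `x + amount`.
#' @export
pseudocount_adjust <- function(x, amount = 0.01) {
  check_scalar(amount, "amount", positive = TRUE)
  x + amount
}

# Vectorised delta-method log response ratio over the rows of two matrices.
# Returns a data.frame of rr, se, means, sds and replicate counts. The
# variance of ln(mean_post/mean_pre) is approximated by
#   sd_post^2 / (n_post * mean_post^2) + sd_pre^2 / (n_pre * mean_pre^2),
# the first-order (delta-method) variance of a log ratio of independent
# group means.
rr_core <- function(pre, post) {
  n_pre <- ncol(pre); n_post <- ncol(post)
  m_pre <- rowMeans(pre); m_post <- rowMeans(post)
  if (any(m_pre <= 0) || any(m_post <= 0))
    stop_domain("group means must be > 0 (apply a pseudocount first)")
  s_pre <- row_sds(pre); s_post <- row_sds(post)
  data.frame(
    rr = log(m_post / m_pre),
    se = sqrt(s_post^2 / (n_post * m_post^2) + s_pre^2 / (n_pre * m_pre^2)),
    mean_pre = m_pre, mean_post = m_post,
    sd_pre = s_pre, sd_post = s_post,
    n_pre = n_pre, n_post = n_post
  )
}

#' Log response ratio of post- vs pre-thaw replicate abundances
#'
#' The effect size is rr = ln(mean(post) / mean(pre)), the natural log of
#' the ratio of group means, with a delta-method standard error
#' `sqrt(sd_post^2/(n_post mean_post^2) + sd_pre^2/(n_pre mean_pre^2))`.
#' Positive rr means the taxon increased after thaw; rr = ln 2 is a two-fold
#' increase.
#'
#' @param pre,post Numeric vectors of replicate abundances (length >= 2,
#'   all values > 0 - apply [pseudocount_adjust()] first if zeros occur).
#' @return Named vector `c(rr, se)`.
#' @examples
#' log_response_ratio(c(1.9, 2.1, 2.0, 2.0), c(3.8, 4.2, 4.0, 4.0))
#' @export
log_response_ratio <- function(pre, post) {
  if (length(pre) < 2 || length(post) < 2)
    stop_domain("need >= 2 replicates per group")
  if (any(pre <= 0) || any(post <= 0))
    stop_domain("abundances must be > 0 (apply a pseudocount first)")
  out <- rr_core(matrix(pre, nrow = 1), matrix(post, nrow = 1))
  c(rr = out$rr, se = out$se)
}

#' Z-score and two-tailed p-value for a log response ratio
#'
#' z = rr / se and p = 2 * (1 - Phi(|z|)) under the standard normal
#' reference. Degenerate zero-variance cases are resolved by the package's
#' zero-variance policy: if both groups are constant and equal (rr = 0,
#' se = 0) the taxon is uninformative and p = 1; if the means differ but the
#' estimated se is exactly 0, se is floored at a machine-epsilon-safe
#' minimum so the z-score is finite (and effectively always significant).
#'
#' @param rr Log response ratios.
#' @param se Their standard errors (>= 0).
#' @return A data.frame with columns `z` and `p`.
#' @export
rr_significance <- function(rr, se) {
  if (any(se < 0)) stop_domain("se must be >= 0")
  floor_se <- sqrt(.Machine$double.eps)
  se_eff <- ifelse(se == 0 & rr != 0, floor_se, se)
  z <- ifelse(se_eff > 0, rr / se_eff, 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[rr == 0 & se == 0] <- 1
  data.frame(z = z, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (q-values), delegated to [stats::p.adjust()].
#'
#' @param p P-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_domain("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify taxa as thaw responders
#'
#' A taxon is a responder when its FDR-adjusted p-value is below `alpha` and
#' its response ratio indicates at least a `fold_threshold`-fold increase,
#' i.e. `q < alpha` and `rr >= ln(fold_threshold)` (boundary inclusive:
#' "two-fold increase or more"). The rule is applied to the rr point
#' estimate.
#'
#' @param rr Log response ratios.
#' @param q BH-adjusted p-values.
#' @param fold_threshold Minimum post/pre fold increase (default 2).
#' @param alpha FDR level (default 0.05).
#' @return Logical vector.
#' @export
classify_responders <- function(rr, q, fold_threshold = 2, alpha = 0.05) {
  check_scalar(fold_threshold, "fold_threshold", positive = TRUE)
  check_scalar(alpha, "alpha", positive = TRUE)
  q < alpha & rr >= log(fold_threshold)
}

#' Responders common to all sites
#'
#' Set intersection of per-site responder sets at the ASV level; at
#' `level = "genus"` the surviving ASVs are mapped through the taxonomy and
#' reported by genus.
#'
#' @param sets Named list (site -> character vector of responder taxon IDs),
#'   length >= 2.
#' @param level `"asv"` or `"genus"`.
#' @param taxonomy Taxonomy data.frame (required for `level = "genus"`).
#' @return Character vector of common responder ASV IDs; for
#'   `level = "genus"`, their (unique, sorted) genus labels.
#' @export
common_responders <- function(sets, level = c("asv", "genus"),
                              taxonomy = NULL) {
  level <- match.arg(level)
  if (length(sets) < 2) stop_domain("need responder sets from >= 2 sites")
  common <- Reduce(intersect, sets)
  if (level == "asv") return(common)
  if (is.null(taxonomy)) stop_domain("taxonomy required for genus level")
  sort(unique(taxonomy[common, "genus"]))
}

#' Fit the thaw-responder response-ratio model
#'
#' The package's central analysis: for every site, each taxon's post-thaw
#' abundance replicates are compared against its pre-thaw replicates with a
#' log response ratio. The fitting steps per site are: (1) drop taxa absent
#' in both phases (they carry no information and inflate the number of
#' tests); (2) add the pseudocount; (3) compute rr and its delta-method se;
#' (4) Z-score and two-tailed p; (5) BH adjustment (within site by default,
#' the correction scope is configurable); (6) classify responders by
#' `q < alpha` and `rr >= ln(fold_threshold)`. Responder sets are then
#' intersected across sites at the ASV level and mapped to genus through the
#' taxonomy.
#'
#' If a non-rarefied count table is supplied via `counts`, a robustness
#' variant is also fitted on centred log-ratio (CLR) transformed counts: the
#' effect on the CLR scale is the difference of group means with a two-sample
#' delta-method se, tested and thresholded the same way, and per-site Jaccard
#' agreement between the two responder sets is reported.
#'
#' @param abundance Numeric matrix, taxa x samples - absolute abundances
#'   (copies g^-1 soil) from [absolute_abundance()], or rarefied counts.
#' @param metadata Metadata data.frame covering all columns of `abundance`
#'   (`sample_id`, `site`, `phase`).
#' @param taxonomy Optional taxonomy for genus-level reporting.
#' @param counts Optional non-rarefied count matrix for the CLR check.
#' @param pseudocount Constant added before taking ratios (default 0.01).
#' @param fold_threshold Fold-increase rule (default 2).
#' @param alpha FDR level (default 0.05).
#' @param bh_scope `"site"` (adjust within each site across its tested taxa)
#'   or `"global"` (adjust across all sites at once).
#' @param clr_pseudocount Pseudocount for the CLR variant (default 0.5, half
#'   a read, the usual choice for integer count tables).
#' @return An object of class `thaw_rr` with components `records` (one row
#'   per site x tested taxon: rr, se, z, p, q, means, n, responder),
#'   `responders` (site -> ASV IDs), `common` (ASV IDs and genus labels),
#'   `clr` (robustness report or NULL), `params`, and `sites`.
#' @seealso [print.thaw_rr()], [summary.thaw_rr()], [coef.thaw_rr()],
#'   [plot.thaw_rr()]
#' @export
thaw_rr <- function(abundance, metadata, taxonomy = NULL, counts = NULL,
                    pseudocount = 0.01, fold_threshold = 2, alpha = 0.05,
                    bh_scope = c("site", "global"), clr_pseudocount = 0.5) {
  bh_scope <- match.arg(bh_scope)
  stopifnot(is.matrix(abundance))
  meta <- metadata[match(colnames(abundance), metadata$sample_id), ]
  if (anyNA(meta$sample_id))
    stop_domain("metadata does not cover all abundance columns")

  fit_site <- function(x, site, effect_fun) {
    pre <- colnames(x)[meta$site == site & meta$phase == "pre"]
    post <- colnames(x)[meta$site == site & meta$phase == "post"]
    if (length(pre) < 2 || length(post) < 2) {
      warning("site ", site, " has < 2 replicates per phase; skipped")
      return(NULL)
    }
    tested <- rowSums(x[, c(pre, post), drop = FALSE]) > 0
    if (!any(tested)) return(NULL)
    eff <- effect_fun(x[tested, pre, drop = FALSE],
                      x[tested, post, drop = FALSE])
    sig <- rr_significance(eff$rr, eff$se)
    cbind(data.frame(taxon_id = rownames(x)[tested], site = site,
                     stringsAsFactors = FALSE),
          eff, sig)
  }

  sites <- unique(meta$site)
  rr_effect <- function(pre, post)
    rr_core(pseudocount_adjust(pre, pseudocount),
            pseudocount_adjust(post, pseudocount))
  records <- do.call(rbind, lapply(sites, function(s)
    fit_site(abundance, s, rr_effect)))
  if (is.null(records)) stop_domain("no site could be analysed")
  rownames(records) <- NULL
  records <- adjust_and_classify(records, bh_scope, fold_threshold, alpha)
  sets <- responder_sets(records)

  common <- list(asv = character(), genus = character())
  if (length(sets) >= 2) {
    common$asv <- common_responders(sets, "asv")
    if (!is.null(taxonomy))
      common$genus <- common_responders(sets, "genus", taxonomy = taxonomy)
  } else {
    warning("fewer than 2 analysed sites; common responder set is empty")
  }

  clr_report <- NULL
  if (!is.null(counts)) {
    clr_mat <- clr_transform(counts, pseudocount = clr_pseudocount)
    clr_effect <- function(pre, post) {
      n_pre <- ncol(pre); n_post <- ncol(post)
      data.frame(rr = rowMeans(post) - rowMeans(pre),
                 se = sqrt(row_sds(post)^2 / n_post + row_sds(pre)^2 / n_pre),
                 mean_pre = rowMeans(pre), mean_post = rowMeans(post),
                 sd_pre = row_sds(pre), sd_post = row_sds(post),
                 n_pre = n_pre, n_post = n_post)
    }
    # tested-taxon rule uses the raw counts, mirroring the main fit
    clr_records <- do.call(rbind, lapply(sites, function(s) {
      rec <- fit_site(clr_mat, s, clr_effect)
      if (is.null(rec)) return(NULL)
      keep_ids <- rownames(counts)[rowSums(
        counts[, meta$sample_id[meta$site == s], drop = FALSE]) > 0]
      rec[rec$taxon_id %in% keep_ids, , drop = FALSE]
    }))
    clr_records <- adjust_and_classify(clr_records, bh_scope, fold_threshold,
                                       alpha)
    clr_sets <- responder_sets(clr_records)
    jac <- vapply(intersect(names(sets), names(clr_sets)), function(s) {
      u <- union(sets[[s]], clr_sets[[s]])
      if (!length(u)) return(1)
      length(intersect(sets[[s]], clr_sets[[s]])) / length(u)
    }, 0)
    clr_report <- list(records = clr_records, responders = clr_sets,
                       jaccard = jac, mean_jaccard = mean(jac))
  }

  structure(list(records = records, responders = sets, common = common,
                 clr = clr_report,
                 params = list(pseudocount = pseudocount,
                               fold_threshold = fold_threshold,
                               alpha = alpha, bh_scope = bh_scope),
                 sites = vapply(split(records, records$site), nrow, 0L),
                 call = match.call()),
            class = "thaw_rr")
}

# BH adjustment at the configured scope plus responder classification.
adjust_and_classify <- function(records, bh_scope, fold_threshold, alpha) {
  if (bh_scope == "site") {
    records$q <- stats::ave(records$p, records$site, FUN = bh_adjust)
  } else {
    records$q <- bh_adjust(records$p)
  }
  records$responder <- classify_responders(records$rr, records$q,
                                           fold_threshold, alpha)
  records
}

responder_sets <- function(records) {
  lapply(split(records, records$site),
         function(d) d$taxon_id[d$responder])
}

#' @export
print.thaw_rr <- function(x, ...) {
  cat("Thaw-responder log response-ratio fit\n")
  cat(sprintf("  sites analysed: %s\n",
              paste(sprintf("%s (%d taxa)", names(x$sites), x$sites),
                    collapse = ", ")))
  n_resp <- vapply(x$responders, length, 0L)
  cat(sprintf("  responders (q < %g, >= %g-fold): %s\n",
              x$params$alpha, x$params$fold_threshold,
              paste(sprintf("%s: %d", names(n_resp), n_resp),
                    collapse = ", ")))
  cat(sprintf("  common responders across sites: %d ASV(s)\n",
              length(x$common$asv)))
  if (!is.null(x$clr))
    cat(sprintf("  CLR robustness check: mean Jaccard agreement %.2f\n",
                x$clr$mean_jaccard))
  invisible(x)
}

#' Summary of a thaw-responder fit
#'
#' @param object A `thaw_rr` fit.
#' @param n_top Number of top responders (by rr) to tabulate per site.
#' @param ... Unused.
#' @return A `summary.thaw_rr` list with per-site counts, the strongest
#'   responders and the common responder set.
#' @export
summary.thaw_rr <- function(object, n_top = 5, ...) {
  per_site <- do.call(rbind, lapply(split(object$records,
                                          object$records$site), function(d)
    data.frame(site = d$site[1L], n_tested = nrow(d),
               n_responders = sum(d$responder),
               median_rr = stats::median(d$rr),
               stringsAsFactors = FALSE)))
  rownames(per_site) <- NULL
  resp <- object$records[object$records$responder, , drop = FALSE]
  top <- do.call(rbind, lapply(split(resp, resp$site), function(d)
    utils::head(d[order(-d$rr),
                  c("taxon_id", "site", "rr", "se", "q")], n_top)))
  rownames(top) <- NULL
  structure(list(per_site = per_site, top = top, common = object$common,
                 params = object$params, clr = object$clr),
            class = "summary.thaw_rr")
}

#' @export
print.summary.thaw_rr <- function(x, ...) {
  cat("Per-site response-ratio tests:\n")
  print(x$per_site, row.names = FALSE)
  cat(sprintf("\nCommon responders across all sites: %d ASV(s)\n",
              length(x$common$asv)))
  if (length(x$common$genus))
    cat("  genera:", paste(x$common$genus, collapse = ", "), "\n")
  if (nrow(x$top)) {
    cat("\nStrongest responders (largest rr):\n")
    print(x$top, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$clr))
    cat(sprintf("\nCLR variant agreement (Jaccard): %s\n",
                paste(sprintf("%s %.2f", names(x$clr$jaccard),
                              x$clr$jaccard), collapse = ", ")))
  invisible(x)
}

#' Response-ratio estimates from a fit
#'
#' @param object A `thaw_rr` fit.
#' @param ... Unused.
#' @return A taxa x sites matrix of rr estimates (NA where a taxon was not
#'   tested at a site).
#' @export
coef.thaw_rr <- function(object, ...) {
  rec <- object$records
  taxa <- unique(rec$taxon_id)
  sites <- unique(rec$site)
  m <- matrix(NA_real_, length(taxa), length(sites),
              dimnames = list(taxa, sites))
  m[cbind(match(rec$taxon_id, taxa), match(rec$site, sites))] <- rec$rr
  m
}

#' Volcano plot of per-taxon response ratios
#'
#' One panel per site: rr against -log10(q), with the responder region
#' (q < alpha and rr >= ln(fold_threshold)) highlighted.
#'
#' @param x A `thaw_rr` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.thaw_rr <- function(x, ...) {
  rec <- x$records
  sites <- unique(rec$site)
  op <- graphics::par(mfrow = c(1, length(sites)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in sites) {
    d <- rec[rec$site == s, ]
    ql <- -log10(pmax(d$q, 1e-300))
    graphics::plot(d$rr, ql, pch = 16, cex = 0.5,
                   col = ifelse(d$responder, "firebrick", "grey50"),
                   xlab = "log response ratio",
                   ylab = expression(-log[10](q)), main = s, ...)
    graphics::abline(v = log(x$params$fold_threshold), lty = 2)
    graphics::abline(h = -log10(x$params$alpha), lty = 2)
  }
  invisible(x)
}
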