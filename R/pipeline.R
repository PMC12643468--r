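# End-to-end convenience: curation chain + responder fit + diversity for a
# complete experiment (read from files or produced by the simulator).

#' Run the full thaw-response analysis
#'
#' Chains the pipeline stages on in-memory inputs: ASV filtering
#' (unassigned/organelle/blank), rarefaction, relative abundance, qPCR
#' scaling to absolute abundance, the [thaw_rr()] responder fit (with the
#' CLR robustness variant on the non-rarefied filtered counts), per-sample
#' alpha diversity on the rarefied table, and - when a gas log is supplied -
#' the flux table and per-sample cumulative respiration.
#'
#' @param counts Count matrix (taxa x samples), e.g. [read_count_table()]
#'   or `simulate_experiment()$counts`.
#' @param taxonomy Taxonomy data.frame.
#' @param metadata Sample metadata data.frame.
#' @param qpcr qPCR records ([read_qpcr()] list or long data.frame).
#' @param blank_asvs Taxon IDs detected in blanks.
#' @param gas Optional gas log (list from [read_gas_log()] or long
#'   data.frame).
#' @param rarefaction_depth Rarefaction depth (default 5000).
#' @param seed Seed for the rarefaction draw.
#' @param ... Passed to [thaw_rr()] (e.g. `fold_threshold`, `alpha`).
#' @return A list of class `thaw_analysis`: `fit` (the `thaw_rr` object),
#'   `alpha` (alpha-diversity table joined with metadata), `flux`,
#'   `cumulative` (named vector, ug CO2-C g^-1), `qpcr` (curve + totals),
#'   `filtered`, `rarefied`, `abs` matrices.
#' @export
run_thaw_analysis <- function(counts, taxonomy, metadata, qpcr,
                              blank_asvs = character(), gas = NULL,
                              rarefaction_depth = 5000, seed = 1, ...) {
  filtered <- filter_asvs(counts, taxonomy, blank_asvs)
  rarefied <- rarefy_counts(filtered, rarefaction_depth, seed = seed)
  rel <- relative_abundance(rarefied)
  qt <- qpcr_totals(qpcr)
  abs_ab <- absolute_abundance(
    rel, stats::setNames(qt$totals$copies_per_g, qt$totals$sample_id))
  keep <- intersect(colnames(filtered), colnames(rarefied))
  fit <- thaw_rr(abs_ab, metadata, taxonomy = taxonomy,
                 counts = filtered[, keep, drop = FALSE], ...)
  alpha <- merge(alpha_diversity(rarefied), metadata, by = "sample_id")
  flux <- cumulative <- NULL
  if (!is.null(gas)) {
    if (is.data.frame(gas)) {
      tf <- tempfile(fileext = ".csv")
      on.exit(unlink(tf))
      utils::write.csv(gas, tf, row.names = FALSE)
      gas <- read_gas_log(tf)
    }
    flux <- flux_table(gas, metadata)
    agg <- stats::aggregate(cumulative ~ sample_id, flux, max)
    cumulative <- stats::setNames(agg$cumulative, agg$sample_id)
  }
  structure(list(fit = fit, alpha = alpha, flux = flux,
                 cumulative = cumulative, qpcr = qt, filtered = filtered,
                 rarefied = rarefied, abs = abs_ab),
            class = "thaw_analysis")
}

#' @export
print.thaw_analysis <- function(x, ...) {
  cat(sprintf("Thaw incubation analysis: %d taxa x %d samples after curation\n",
              nrow(x$rarefied), ncol(x$rarefied)))
  print(x$fit)
  if (!is.null(x$cumulative))
    cat(sprintf("  cumulative respiration: %.0f-%.0f ug CO2-C g^-1 dry soil\n",
                min(x$cumulative), max(x$cumulative)))
  invisible(x)
}
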