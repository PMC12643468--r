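# ASV table curation (filtering, rarefaction, normalisation) and qPCR-based
# scaling of relative abundances to absolute 16S copies per gram of soil.

#' Remove unassigned, organelle and blank-derived ASVs
#'
#' Applies the standard amplicon curation rules, in order: (1) drop taxa
#' unassigned at the phylum level; (2) drop taxa whose lineage contains
#' "Mitochondria" or "Chloroplast" at any rank; (3) drop taxa detected in
#' extraction/PCR blanks (supplied as an explicit ID list - no statistical
#' contamination guessing). Row order of the survivors is preserved and a
#' per-rule removal report is attached.
#'
#' @param counts Integer matrix, taxa x samples.
#' @param taxonomy Data.frame from [read_taxonomy()] covering all taxa.
#' @param blank_asvs Character vector of taxon IDs seen in blanks.
#' @return The filtered count matrix with a `"removal"` attribute:
#'   `list(unassigned =, organelle =, blank =)` counts.
#' @export
filter_asvs <- function(counts, taxonomy, blank_asvs = character()) {
  stopifnot(is.matrix(counts))
  taxa <- rownames(counts)
  missing_tax <- setdiff(taxa, rownames(taxonomy))
  if (length(missing_tax))
    stop_domain("taxonomy does not cover ", length(missing_tax), " taxa")
  tx <- taxonomy[taxa, , drop = FALSE]
  unassigned <- is.na(tx$phylum) | tx$phylum == ""
  lineage <- do.call(paste, c(tx, sep = ";"))
  organelle <- !unassigned &
    grepl("mitochondria|chloroplast", lineage, ignore.case = TRUE)
  blank <- !unassigned & !organelle & taxa %in% blank_asvs
  keep <- !(unassigned | organelle | blank)
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("all taxa removed by filtering rules")
  attr(out, "removal") <- list(unassigned = sum(unassigned),
                               organelle = sum(organelle),
                               blank = sum(blank))
  out
}

#' Rarefy a count table to a common depth
#'
#' Single random subsample without replacement (multivariate hypergeometric)
#' of each sample down to exactly `depth` reads; one draw, no averaging over
#' iterations, so all downstream statistics share one rarefied table.
#' Samples with fewer than `depth` total reads are dropped and listed in the
#' `"dropped"` attribute.
#'
#' @param counts Integer matrix, taxa x samples.
#' @param depth Target depth (> 0).
#' @param seed Integer seed for the subsampling draw.
#' @return Rarefied count matrix whose retained columns each sum to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  check_scalar(depth, "depth", positive = TRUE)
  stopifnot(is.matrix(counts))
  totals <- colSums(counts)
  keep <- totals >= depth
  dropped <- colnames(counts)[!keep]
  x <- counts[, keep, drop = FALSE]
  out <- local_seed(seed, {
    # inputs are validated as integer counts with totals >= depth, so
    # vegan's advisory "observed counts" warning is spurious here
    if (ncol(x)) suppressWarnings(t(vegan::rrarefy(t(x), sample = depth)))
    else x
  })
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- dropped
  out
}

#' Relative abundances (per-sample proportions)
#'
#' @param counts Non-negative matrix, taxa x samples, each column total > 0.
#' @return Matrix of the same shape whose columns sum to 1.
#' @export
relative_abundance <- function(counts) {
  stopifnot(is.matrix(counts))
  totals <- colSums(counts)
  if (any(totals <= 0)) stop_domain("zero-total sample(s): ",
                                    paste(colnames(counts)[totals <= 0],
                                          collapse = ", "))
  sweep(counts, 2, totals, "/")
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq = slope * log10(quantity) + intercept over a
#' dilution series, with the amplification efficiency derived from the
#' slope: efficiency = 10^(-1/slope) - 1 (1.0 means perfect doubling each
#' cycle).
#'
#' @param quantity Known template quantities (e.g. ng/uL), > 0, >= 3 points
#'   spanning at least 2 log10 units.
#' @param cq Measured quantification cycles.
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency` and the input `points`.
#' @export
fit_standard_curve <- function(quantity, cq) {
  stopifnot(length(quantity) == length(cq))
  if (any(quantity <= 0)) stop_domain("standard quantities must be > 0")
  if (length(unique(quantity)) < 3)
    stop_domain("need >= 3 distinct standard points")
  lq <- log10(quantity)
  if (diff(range(lq)) < 2)
    stop_domain("standards must span >= 2 log10 units")
  fit <- stats::lm(cq ~ lq)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop_domain("invalid standard curve: slope must be < 0 for a dilution series")
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 points = data.frame(quantity = quantity, cq = cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4f log10(q) + %.4f  (R^2 = %.4f, efficiency = %.1f%%)\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Invert a standard curve
#'
#' @param curve A `standard_curve`.
#' @param cq Quantification cycles.
#' @return Template quantities on the standards' scale.
#' @export
invert_standard_curve <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' 16S gene copies per nanogram of a genomic DNA standard
#'
#' Helper for converting a mass-based standard (ng of genomic DNA) to gene
#' copies, using the standard organism's genome size and rRNA operon count.
#' One double-stranded base pair weighs 660 g/mol / Avogadro.
#'
#' @param genome_size_bp Genome size in base pairs. Default is the
#'   Escherichia coli K-12 MG1655 chromosome (4,641,652 bp).
#' @param copies_per_genome rRNA operons per genome (7 for E. coli K-12).
#' @return Gene copies per nanogram of genomic DNA.
#' @export
copies_per_ng <- function(genome_size_bp = 4641652, copies_per_genome = 7) {
  ng_per_genome <- genome_size_bp * 660 / 6.02214076e23 * 1e9
  copies_per_genome / ng_per_genome
}

#' 16S gene copies per gram of soil from sample Cq values
#'
#' Averages the triplicate Cq values first, inverts the standard curve to a
#' template concentration, scales by the DNA elution volume, the copies-per-
#' nanogram factor of the standard, and the template fraction assayed, and
#' divides by the extracted soil mass (per g soil as extracted). Cq values
#' outside the range covered by the standards are flagged with an
#' extrapolation warning.
#'
#' @param cq Numeric vector of replicate Cq values (usually a triplicate).
#' @param curve A `standard_curve` fitted on quantities in ng/uL.
#' @param elution_volume_ul DNA elution volume in uL.
#' @param soil_mass_g Soil mass extracted, grams (> 0).
#' @param copies_per_ng Conversion factor from [copies_per_ng()].
#' @param template_fraction Fraction of the eluted DNA assayed per reaction
#'   relative to the standards' basis (1 when samples and standards are
#'   loaded identically).
#' @return Gene copies per gram of soil.
#' @export
copies_per_gram <- function(cq, curve, elution_volume_ul, soil_mass_g,
                            copies_per_ng = permathaw::copies_per_ng(),
                            template_fraction = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  check_scalar(soil_mass_g, "soil_mass_g", positive = TRUE)
  check_scalar(elution_volume_ul, "elution_volume_ul", positive = TRUE)
  check_scalar(template_fraction, "template_fraction", positive = TRUE)
  mcq <- mean(cq)
  rng <- range(curve$points$cq)
  if (mcq < rng[1L] || mcq > rng[2L])
    warning(sprintf("mean Cq %.2f outside standard range [%.2f, %.2f]; extrapolating",
                    mcq, rng[1L], rng[2L]))
  conc <- invert_standard_curve(curve, mcq)              # ng/uL
  conc * elution_volume_ul / template_fraction * copies_per_ng / soil_mass_g
}

#' qPCR totals for all samples in a parsed qPCR file
#'
#' Fits the standard curve from the file's dilution series and converts each
#' sample's replicate Cq values to 16S copies per gram of soil.
#'
#' @param qpcr List from [read_qpcr()], or an equivalent long data.frame
#'   with a `record_type` column (as produced by [simulate_experiment()]).
#' @param ... Passed to [copies_per_gram()] (e.g. `copies_per_ng`).
#' @return A list with the fitted `curve` and a data.frame `totals`
#'   (`sample_id`, `copies_per_g`, `n_wells`, `cq_mean`, `cq_sd`).
#' @export
qpcr_totals <- function(qpcr, ...) {
  if (is.data.frame(qpcr))
    qpcr <- list(
      standards = qpcr[qpcr$record_type == "standard",
                       c("sample_id", "quantity_ng_ul", "cq")],
      samples = qpcr[qpcr$record_type == "sample",
                     c("sample_id", "cq", "soil_mass_g", "elution_volume_ul")])
  curve <- fit_standard_curve(qpcr$standards$quantity_ng_ul,
                              qpcr$standards$cq)
  rows <- lapply(split(qpcr$samples, qpcr$samples$sample_id), function(s) {
    data.frame(sample_id = s$sample_id[1L],
               copies_per_g = copies_per_gram(
                 s$cq, curve, elution_volume_ul = s$elution_volume_ul[1L],
                 soil_mass_g = s$soil_mass_g[1L], ...),
               n_wells = nrow(s), cq_mean = mean(s$cq), cq_sd = stats::sd(s$cq),
               stringsAsFactors = FALSE)
  })
  totals <- do.call(rbind, rows)
  rownames(totals) <- NULL
  list(curve = curve, totals = totals)
}

#' Scale relative abundances to absolute abundances
#'
#' Multiplies each sample's relative abundances by its qPCR-measured 16S
#' total so that column sums equal the sample totals (copies per gram of
#' soil).
#'
#' @param rel Relative abundance matrix (columns sum to 1).
#' @param totals Named numeric vector of copies g^-1 per sample, covering
#'   every column of `rel`.
#' @return Absolute abundance matrix, taxa x samples.
#' @export
absolute_abundance <- function(rel, totals) {
  stopifnot(is.matrix(rel))
  if (is.data.frame(totals))
    totals <- stats::setNames(totals$copies_per_g, totals$sample_id)
  missing_tot <- setdiff(colnames(rel), names(totals))
  if (length(missing_tot))
    stop_domain("missing qPCR totals for: ", paste(missing_tot, collapse = ", "))
  sweep(rel, 2, totals[colnames(rel)], "*")
}

#' Centred log-ratio transform
#'
#' Per sample (column): ln(x_i / geometric mean(x)) after adding a
#' pseudocount, mapping compositional data to an unconstrained scale where
#' each column sums to zero.
#'
#' @param x Non-negative matrix, taxa x samples.
#' @param pseudocount Constant added to every cell; must be > 0 if `x`
#'   contains zeros.
#' @return The CLR-transformed matrix.
#' @export
clr_transform <- function(x, pseudocount = 0) {
  stopifnot(is.matrix(x))
  if (pseudocount < 0) stop_domain("pseudocount must be >= 0")
  x <- x + pseudocount
  if (any(x <= 0))
    stop_domain("non-positive values after pseudocount; use pseudocount > 0")
  lx <- log(x)
  sweep(lx, 2, colMeans(lx), "-")
}
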