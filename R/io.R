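TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

#' Read an ASV count table
#'
#' Reads a tab-separated count table with taxon identifiers in the first
#' column and sample identifiers in the header row. Cells must be
#' non-negative integers (sequence read counts).
#'
#' @param path Path to a TSV file.
#' @return An integer matrix (taxa x samples) with taxon IDs as row names and
#'   sample IDs as column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_count_table(matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2"))), tf)
#' read_count_table(tf)
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop_domain("count table not found: ", path)
  if (file.size(path) == 0) stop_domain("count table is empty: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2)
    stop_domain("count table must have a taxon ID column and >= 1 sample")
  taxa <- as.character(df[[1L]])
  if (anyDuplicated(taxa)) stop_domain("duplicate taxon IDs in count table")
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) stop_domain("duplicate sample IDs in count table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop_domain("count table cells must be numeric and non-missing")
  if (any(m < 0)) stop_domain("negative counts in count table")
  if (any(m != round(m))) stop_domain("non-integer counts in count table")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(taxa, samples)
  m
}

#' Write an ASV count table
#'
#' @param counts Integer matrix, taxa x samples.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Reads a TSV with taxon IDs in the first column and the seven Silva-style
#' ranks (domain, phylum, class, order, family, genus, species) as columns.
#' Unassigned ranks may be empty strings or NA.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with rownames = taxon IDs and one column per rank.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop_domain("taxonomy table needs taxon IDs plus ranks")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop_domain("duplicate taxon IDs in taxonomy")
  tx <- df[, -1L, drop = FALSE]
  colnames(tx) <- tolower(colnames(tx))
  missing_ranks <- setdiff(TAX_RANKS, colnames(tx))
  if (length(missing_ranks))
    stop_domain("taxonomy missing rank column(s): ",
                paste(missing_ranks, collapse = ", "))
  tx <- tx[, TAX_RANKS]
  tx[is.na(tx)] <- ""
  rownames(tx) <- ids
  tx
}

#' Read sample metadata
#'
#' Reads a CSV describing incubation samples: one row per sample with the
#' site, core, replicate, pre/post-thaw phase, soil masses and abiotic
#' measurements. Enforces that sample IDs are unique and that each
#' (site, core, replicate) triple has at most one pre-thaw and one post-thaw
#' record, so pre/post pairing is resolvable.
#'
#' @param path Path to a CSV file with columns `sample_id`, `site`, `core`,
#'   `replicate`, `phase` (`pre`/`post`), `wet_mass`, `gwc_percent`, `ph`,
#'   `ec`, `pct_c`, `pct_n`. Abiotic columns may contain NA (the study design
#'   measures some quantities on a subset of samples only).
#' @return A data.frame of validated metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample_id", "site", "core", "replicate", "phase", "wet_mass",
           "gwc_percent", "ph", "ec", "pct_c", "pct_n")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    stop_domain("metadata missing column(s): ",
                paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_domain("duplicate sample_id in metadata")
  if (!all(df$phase %in% c("pre", "post")))
    stop_domain("phase must be 'pre' or 'post'")
  if (any(!is.na(df$replicate) & df$replicate < 1))
    stop_domain("replicate must be >= 1")
  if (any(!is.na(df$wet_mass) & df$wet_mass <= 0))
    stop_domain("wet_mass must be > 0")
  if (any(!is.na(df$gwc_percent) & df$gwc_percent < 0))
    stop_domain("gwc_percent must be >= 0")
  key <- paste(df$site, df$core, df$replicate, df$phase)
  if (anyDuplicated(key))
    stop_domain("more than one record for a (site, core, replicate, phase)")
  df
}

#' Read a headspace gas measurement log
#'
#' Reads a long-format CSV (one row per sample per timepoint) of headspace
#' CO2 measurements with the jar's physical constants and flush markers, and
#' splits it into one time-sorted series per sample. A `flushed_flag` of
#' TRUE/1 means the headspace was flushed with CO2-free air immediately
#' after that measurement, resetting the accumulation baseline to zero.
#'
#' @param path Path to a CSV with columns `sample_id`, `elapsed_hours`,
#'   `co2_ppm`, `pressure_atm`, `volume_L`, `temp_K`, `flushed_flag`.
#' @return A named list of data.frames, one per sample, each sorted by
#'   `elapsed_hours`.
#' @export
read_gas_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample_id", "elapsed_hours", "co2_ppm", "pressure_atm",
           "volume_L", "temp_K", "flushed_flag")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    stop_domain("gas log missing column(s): ",
                paste(missing_cols, collapse = ", "))
  if (any(df$elapsed_hours < 0)) stop_domain("negative elapsed_hours in gas log")
  if (any(df$co2_ppm < 0)) stop_domain("negative co2_ppm in gas log")
  if (any(df$pressure_atm <= 0 | df$volume_L <= 0 | df$temp_K <= 0))
    stop_domain("pressure, volume and temperature must be > 0")
  df$flushed_flag <- as.logical(df$flushed_flag)
  out <- lapply(split(df, df$sample_id), function(s) {
    s <- s[order(s$elapsed_hours), , drop = FALSE]
    if (anyDuplicated(s$elapsed_hours))
      stop_domain("non-monotone measurement times for sample ", s$sample_id[1L])
    rownames(s) <- NULL
    s
  })
  out[unique(df$sample_id)]
}

#' Read qPCR results
#'
#' Reads a CSV holding both standard-curve points and sample quantification
#' cycles. Standards carry the known template quantity (ng/uL); samples carry
#' the extracted soil mass and DNA elution volume needed to express results
#' as 16S gene copies per gram of soil.
#'
#' @param path Path to a CSV with columns `record_type` (`standard` or
#'   `sample`), `sample_id`, `quantity_ng_ul`, `cq`, `soil_mass_g`,
#'   `elution_volume_ul`. Replicate wells are separate rows.
#' @return A list with elements `standards` and `samples` (data.frames).
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("record_type", "sample_id", "quantity_ng_ul", "cq", "soil_mass_g",
           "elution_volume_ul")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    stop_domain("qPCR file missing column(s): ",
                paste(missing_cols, collapse = ", "))
  if (!all(df$record_type %in% c("standard", "sample")))
    stop_domain("record_type must be 'standard' or 'sample'")
  std <- df[df$record_type == "standard", , drop = FALSE]
  smp <- df[df$record_type == "sample", , drop = FALSE]
  if (nrow(std) && any(is.na(std$quantity_ng_ul) | std$quantity_ng_ul <= 0))
    stop_domain("standards must have positive quantity_ng_ul")
  if (nrow(smp) && any(is.na(smp$soil_mass_g) | smp$soil_mass_g <= 0))
    stop_domain("samples must have positive soil_mass_g")
  list(standards = std[, c("sample_id", "quantity_ng_ul", "cq")],
       samples = smp[, c("sample_id", "cq", "soil_mass_g",
                         "elution_volume_ul")])
}

#' Write a result table with a provenance header
#'
#' All pipeline outputs are plain TSV files preceded by `#`-prefixed comment
#' lines recording how they were produced (tool version, seed, parameters).
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip is lossless for doubles.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param provenance Named list of key/value pairs for the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, provenance = list()) {
  stopifnot(is.data.frame(df))
  prov <- c(list(tool = paste0("permathaw ",
                               as.character(utils::packageVersion("permathaw")))),
            provenance)
  hdr <- vapply(names(prov), function(k)
    sprintf("# %s: %s", k, paste(format(prov[[k]]), collapse = " ")), "")
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' Comment lines are tolerated and skipped; the provenance header is returned
#' in the `"provenance"` attribute.
#'
#' @param path Path to a result TSV.
#' @return A data.frame.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "provenance") <- sub("^# *", "", hdr)
  df
}

#' Read a flat key-value configuration file
#'
#' Configuration files are flat YAML (one `key: value` per line). Every
#' pipeline stage reads defaults from the config; command-line flags
#' override it.
#'
#' @param path Path to a YAML file, or NULL for an empty config.
#' @return A named list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_domain("config must be a flat key: value mapping")
  cfg
}
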