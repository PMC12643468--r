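# Soil abiotic quantities: gravimetric water content, C:N and per-core
# summaries of the measured properties.

#' Gravimetric water content (dry-mass basis)
#'
#' @param wet_mass Soil mass before oven drying, grams.
#' @param dry_mass Soil mass after drying at 105 C, grams (> 0, <= wet_mass).
#' @return GWC in percent of dry mass; exceeds 100% for organic soils whose
#'   water mass is larger than their dry mass.
#' @examples
#' gwc(12, 10)  # 20
#' @export
gwc <- function(wet_mass, dry_mass) {
  if (any(dry_mass <= 0)) stop_domain("dry_mass must be > 0")
  if (any(wet_mass < dry_mass)) stop_domain("wet_mass must be >= dry_mass")
  (wet_mass - dry_mass) / dry_mass * 100
}

#' Carbon-to-nitrogen mass ratio
#'
#' Computed from combustion-derived total carbon and nitrogen percentages as
#' a mass ratio (not molar), reported to one decimal by default.
#'
#' @param pct_c Total carbon, percent of dry mass.
#' @param pct_n Total nitrogen, percent of dry mass (> 0).
#' @param digits Decimal places for reporting; `NULL` for the raw ratio.
#' @return C:N ratio (unitless).
#' @examples
#' cn_ratio(3.6, 0.18)  # 20
#' @export
cn_ratio <- function(pct_c, pct_n, digits = 1) {
  if (any(!is.finite(pct_n)) || any(pct_n <= 0))
    stop_domain("pct_n must be > 0")
  r <- pct_c / pct_n
  if (is.null(digits)) r else round(r, digits)
}

#' Change in gravimetric water content across thaw
#'
#' @param pre_gwc,post_gwc GWC in percent before and after incubation.
#' @return Signed change, `post_gwc - pre_gwc`, in percentage points.
#' @export
delta_gwc <- function(pre_gwc, post_gwc) post_gwc - pre_gwc

#' Summarise abiotic soil properties by site, core and phase
#'
#' Produces per-(site, core, phase) means and standard errors of pH, EC, GWC,
#' %C, %N and C:N over replicates, plus the pre-to-post change in GWC. The
#' "+/-" spread is the standard error of the mean (flagged in the output
#' provenance since published tables rarely say which was used); the n
#' entering each SE is recorded.
#'
#' @param metadata Metadata data.frame from [read_metadata()].
#' @return A data.frame with one row per (site, core, phase) and columns
#'   `<var>_mean`, `<var>_se` for each abiotic variable, `n`, and
#'   `delta_gwc` (post rows only).
#' @export
abiotic_summary <- function(metadata) {
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  metadata$cn <- ifelse(!is.na(metadata$pct_n) & metadata$pct_n > 0,
                        metadata$pct_c / metadata$pct_n, NA_real_)
  vars <- c("ph", "ec", "gwc_percent", "pct_c", "pct_n", "cn")
  grp <- interaction(metadata$site, metadata$core, metadata$phase, drop = TRUE)
  out <- do.call(rbind, lapply(split(metadata, grp), function(g) {
    row <- data.frame(site = g$site[1L], core = g$core[1L],
                      phase = g$phase[1L], n = nrow(g),
                      stringsAsFactors = FALSE)
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mn(g[[v]])
      row[[paste0(v, "_se")]] <- se(g[[v]])
    }
    row
  }))
  rownames(out) <- NULL
  out$delta_gwc <- NA_real_
  for (i in which(out$phase == "post")) {
    pre <- out$phase == "pre" & out$site == out$site[i] & out$core == out$core[i]
    if (any(pre))
      out$delta_gwc[i] <- delta_gwc(out$gwc_percent_mean[which(pre)[1L]],
                                    out$gwc_percent_mean[i])
  }
  out
}

#' Published abiotic soil properties of the three Alaskan permafrost sites
#'
#' Pre- and post-thaw soil properties of the six permafrost cores (two per
#' site) from the Permafrost Tunnel (PT), Farmers Loop (FL) and Barrow
#' Experimental Observatory (BEO) sites used in the worked examples:
#' pre-thaw pH, electrical conductivity (EC, carried verbatim in the units
#' of the source table), total carbon and nitrogen percent, printed C:N and
#' GWC, and post-thaw means with their printed spreads. Used to exercise
#' [cn_ratio()] and [delta_gwc()] against independently published arithmetic.
#'
#' @return A data.frame with one row per core.
#' @export
permafrost_abiotic <- function() {
  data.frame(
    site = c("PT", "PT", "FL", "FL", "BEO", "BEO"),
    core = c("AT 3", "AT 4", "FL 1", "FL 2", "BEO 1", "BEO 2"),
    ph_pre = c(4.84, 4.91, 4.71, 4.73, 4.41, 4.16),
    ec_pre = c(350.9, 245.3, 441.6, 388.1, 206.3, 328.6),
    pct_c = c(3.6, 1.8, 37.9, 39.6, 30.9, 21.8),
    pct_n = c(0.18, 0.11, 1.9, 2.15, 1.67, 1.07),
    cn_printed = c(20, 16.4, 19.9, 18.4, 18.5, 20.4),
    gwc_pre = c(61.6, 91.9, 313.8, 208.8, 176.5, 116.9),
    ph_post = c(4.83, 4.88, 4.71, 4.72, 4.06, 3.94),
    ec_post = c(264.2, 228.7, 345.6, 431.7, 440.4, 478.5),
    gwc_post = c(16.8, 6.6, 263.9, 146.6, 150.8, 129.3),
    gwc_post_se = c(7.4, 1.9, 23.1, 65.6, 41.5, 32.4),
    dgwc_printed = c(-44.8, -85.3, -49.9, -62.2, -27.5, 12.4),
    stringsAsFactors = FALSE
  )
}
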