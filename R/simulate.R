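# Seeded synthetic-data generator emulating a multi-site paired pre/post
# permafrost-thaw incubation: lognormal site-specific communities sampled
# multinomially, planted thaw responders, qPCR-measured biomass growth and a
# respiration series tied to biomass.

# Gas measurement schedule of the emulated incubation (days).
MEASUREMENT_DAYS <- c(0, 1, 2, 4, 6, 9, 12, 14, 19, 26, 30, 36, 44, 51, 58,
                      65, 74, 83, 92, 96)

#' Configuration for a synthetic thaw incubation experiment
#'
#' Builds and validates the parameter set of [simulate_experiment()]. The
#' defaults emulate the incubation design the package targets: 3 sites x 2
#' cores x 4 replicate jars (24 incubation samples), paired pre/post
#' communities of 500 taxa sequenced to ~20,000 reads, a planted set of
#' thaw responders with an 8-fold post-thaw increase (5% of taxa, of which
#' 8 are shared across all sites), post-thaw biomass growth measured by
#' qPCR, and a respiration series proportional to instantaneous biomass.
#'
#' @param n_sites,cores_per_site,replicates_per_core Design dimensions.
#' @param n_taxa Number of community taxa (before synthetic contaminants).
#' @param depth_mean,depth_cv Sequencing depth lognormal mean and CV.
#' @param rarefaction_depth Downstream rarefaction depth (used only to size
#'   deliberately shallow samples).
#' @param shallow_samples Number of samples forced below the rarefaction
#'   depth, to exercise sample dropping (default 0).
#' @param sigma_base,sigma_site SDs of the shared and site-specific
#'   components of the log taxon loadings; their combined spread (~1)
#'   yields rarefied Shannon near 5 and strong between-site separation.
#' @param responder_fraction Fraction of taxa planted as thaw responders per
#'   site (default 0.05).
#' @param fold Post-thaw fold increase applied to planted responders on the
#'   latent absolute scale before compositional renormalisation (>= 1;
#'   `fold = 1` gives a null dataset).
#' @param n_common Number of planted responders shared by all sites.
#' @param qpcr_pre_mean Mean pre-thaw biomass, 16S copies g^-1 soil.
#' @param core_biomass_sd_log,sample_biomass_sd_log Lognormal SDs of
#'   between-core biomass variation and of subsample heterogeneity within a
#'   homogenised core.
#' @param growth_sd_log Lognormal SD of per-jar biological growth
#'   variability around the site-level growth factor; replicate microcosms
#'   diverge substantially during a three-month incubation, and this jar
#'   term drives both the jar's respiration and its measured biomass
#'   change.
#' @param growth_link Coupling between the planted community growth and
#'   measured biomass: post biomass = pre x (1 + growth_link * (G - 1))
#'   where G is the latent community mass ratio.
#' @param resp_per_biomass Respiration per unit biomass, ug CO2-C g^-1 dry
#'   soil h^-1 per (copy g^-1).
#' @param gas_noise_sd_log Multiplicative (lognormal) noise SD on each
#'   measured respiration interval.
#' @param cq_sd Gaussian noise SD on every qPCR Cq well.
#' @param curve_slope,curve_intercept True standard-curve parameters
#'   (default slope -3.23, i.e. ~104% efficiency).
#' @param pressure_atm,volume_L,temp_K Jar headspace physical constants
#'   (incubation at 2 C).
#' @param soil_mass_g,elution_volume_ul DNA extraction mass and elution
#'   volume used in the qPCR scaling chain.
#' @param n_unassigned,n_organelle,n_blank Synthetic contaminant taxa
#'   (phylum-unassigned, mitochondria/chloroplast, blank-derived) appended
#'   to exercise the filtering rules.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 3, cores_per_site = 2,
                       replicates_per_core = 4, n_taxa = 500,
                       depth_mean = 20000, depth_cv = 0.1,
                       rarefaction_depth = 5000, shallow_samples = 0,
                       sigma_base = 0.7, sigma_site = 0.7,
                       responder_fraction = 0.05, fold = 8, n_common = 8,
                       qpcr_pre_mean = 5e7, core_biomass_sd_log = 0.3,
                       sample_biomass_sd_log = 0.1, growth_sd_log = 0.25,
                       growth_link = 1,
                       resp_per_biomass = 3e-9, gas_noise_sd_log = 0.15,
                       cq_sd = 0.15, curve_slope = -3.23,
                       curve_intercept = 9.75, pressure_atm = 1,
                       volume_L = 0.5, temp_K = 275.15, soil_mass_g = 0.25,
                       elution_volume_ul = 100, n_unassigned = 5,
                       n_organelle = 3, n_blank = 4, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$responder_fraction < 0 || cfg$responder_fraction > 1)
    stop_domain("responder_fraction must be in [0, 1]")
  if (cfg$fold < 1) stop_domain("fold must be >= 1")
  if (cfg$n_sites < 1 || cfg$cores_per_site < 1 ||
      cfg$replicates_per_core < 1)
    stop_domain("design dimensions must be >= 1")
  n_resp <- max(cfg$n_common * (cfg$responder_fraction > 0),
                round(cfg$responder_fraction * cfg$n_taxa))
  n_distinct <- cfg$n_common + cfg$n_sites * (n_resp - cfg$n_common)
  if (cfg$responder_fraction > 0 && n_distinct > 0.2 * cfg$n_taxa)
    stop_domain("too many planted responders for the eligible (dominant) pool")
  if (cfg$depth_mean * exp(-3 * cfg$depth_cv) <= cfg$rarefaction_depth &&
      cfg$shallow_samples == 0)
    stop_domain("depth_mean too close to rarefaction_depth")
  if (cfg$curve_slope >= 0) stop_domain("curve_slope must be < 0")
  structure(cfg, class = "sim_config")
}

site_names <- function(n) {
  base <- c("PT", "FL", "BEO")
  if (n <= 3) base[seq_len(n)] else c(base, paste0("S", seq_len(n - 3) + 3))
}

# Site-level abiotic centres used to fill the synthetic metadata (pH, EC,
# %C, %N and pre/post GWC); loosely shaped like mineral (PT), organic (FL)
# and mixed (BEO) permafrost.
site_abiotics <- function(sites) {
  pool <- data.frame(
    ph = c(4.85, 4.7, 4.3), ec = c(300, 415, 267),
    pct_c = c(2.7, 38.8, 26.4), pct_n = c(0.15, 2.0, 1.4),
    gwc_pre = c(75, 260, 147), gwc_post = c(12, 205, 140))
  pool[((seq_along(sites) - 1) %% 3) + 1, ]
}

#' Simulate a complete thaw incubation experiment
#'
#' Draws, deterministically under `config$seed`: (1) latent per-site taxon
#' loadings (shared lognormal baseline plus site-specific offsets); (2) a
#' planted responder set per site - `n_common` taxa shared by all sites plus
#' disjoint site-specific extras, all drawn from the prevalent (upper half)
#' of the baseline distribution; (3) pre- and post-thaw counts per sample as
#' multinomial reads at a lognormally drawn depth, with the fold effect
#' applied to responders' latent absolute abundances *before*
#' renormalisation (so the simulation exhibits the compositional distortion
#' the CLR robustness check targets); (4) per-sample biomass (16S copies
#' g^-1) whose post/pre growth follows the latent community mass ratio, and
#' noisy triplicate qPCR Cq values plus a 5-point 10-fold standard dilution
#' series; (5) a headspace gas series at the incubation's measurement days
#' with a flush after each measurement, whose CO2 mole fractions invert the
#' flux equation at a respiration rate proportional to instantaneous
#' biomass with multiplicative noise.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (matrix incl. synthetic contaminant taxa),
#'   `taxonomy`, `metadata`, `qpcr` (read_qpcr-shaped list), `gas` (long
#'   data.frame), and `truth` (planted/common responder IDs, blank ASV IDs,
#'   per-sample true biomass, true per-interval respiration rates, latent
#'   loadings).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  sites <- site_names(cfg$n_sites)
  n_taxa <- cfg$n_taxa
  taxa <- sprintf("ASV%04d", seq_len(n_taxa))

  base <- stats::rnorm(n_taxa, 0, cfg$sigma_base)
  load_pre <- sapply(sites, function(s)
    exp(base + stats::rnorm(n_taxa, 0, cfg$sigma_site)))
  rownames(load_pre) <- taxa

  # plant responders among the dominant taxa (top 20% of the baseline):
  # boosting already-abundant taxa concentrates the post-thaw community so
  # responders jointly dominate it and evenness (hence diversity) falls
  planted <- stats::setNames(vector("list", length(sites)), sites)
  common_ids <- character()
  if (cfg$responder_fraction > 0) {
    eligible <- taxa[base >= stats::quantile(base, 0.8)]
    n_resp <- max(cfg$n_common, round(cfg$responder_fraction * n_taxa))
    common_ids <- sample(eligible, min(cfg$n_common, n_resp))
    remaining <- setdiff(eligible, common_ids)
    for (s in sites) {
      extra <- sample(remaining, n_resp - length(common_ids))
      remaining <- setdiff(remaining, extra)  # site extras disjoint
      planted[[s]] <- sort(c(common_ids, extra))
    }
  } else {
    planted[] <- list(character())
  }

  load_post <- load_pre
  for (s in sites)
    load_post[planted[[s]], s] <- load_post[planted[[s]], s] * cfg$fold
  growth_latent <- colSums(load_post) / colSums(load_pre)

  # contaminant taxa shared across all samples
  n_extra <- cfg$n_unassigned + cfg$n_organelle + cfg$n_blank
  extra_ids <- if (n_extra) sprintf("CON%03d", seq_len(n_extra)) else character()
  extra_load <- exp(stats::rnorm(n_extra, -2, 0.5))

  abio <- site_abiotics(sites)

  meta_rows <- list(); count_cols <- list(); biomass <- c()
  design <- expand.grid(replicate = seq_len(cfg$replicates_per_core),
                        core = seq_len(cfg$cores_per_site),
                        site = sites, stringsAsFactors = FALSE)
  core_biomass <- stats::setNames(
    stats::rlnorm(nrow(unique(design[c("site", "core")])),
                  log(cfg$qpcr_pre_mean), cfg$core_biomass_sd_log),
    apply(unique(design[c("site", "core")]), 1, function(r)
      paste(r["site"], r["core"])))

  jar_initial <- c(); jar_growth <- c()
  for (i in seq_len(nrow(design))) {
    s <- design$site[i]; co <- design$core[i]; rep <- design$replicate[i]
    si <- match(s, sites)
    for (phase in c("pre", "post")) {
      id <- sprintf("%s_c%d_r%d_%s", s, co, rep, phase)
      lam <- if (phase == "pre") load_pre[, si] else load_post[, si]
      prob <- c(lam, extra_load)
      depth <- round(stats::rlnorm(1, log(cfg$depth_mean), cfg$depth_cv))
      count_cols[[id]] <- stats::rmultinom(1, depth, prob)[, 1L]
      if (phase == "pre") {
        # pre-thaw subsample of the homogenised core
        biomass[id] <- core_biomass[paste(s, co)] *
          stats::rlnorm(1, 0, cfg$sample_biomass_sd_log)
      } else {
        # the incubated jar starts from its own subsample of the same core
        # and grows by a site-level factor with per-jar biological noise;
        # the same trajectory drives this jar's respiration series
        b0 <- core_biomass[paste(s, co)] *
          stats::rlnorm(1, 0, cfg$sample_biomass_sd_log)
        g <- (1 + cfg$growth_link * (growth_latent[si] - 1)) *
          stats::rlnorm(1, 0, cfg$growth_sd_log)
        jar_initial[id] <- b0
        jar_growth[id] <- g
        biomass[id] <- b0 * g
      }
      gwc_val <- max(0, (if (phase == "pre") abio$gwc_pre[si] else
        abio$gwc_post[si]) * stats::rlnorm(1, 0, 0.05))
      meta_rows[[id]] <- data.frame(
        sample_id = id, site = s, core = paste0("c", co), replicate = rep,
        phase = phase, wet_mass = stats::runif(1, 20, 40),
        gwc_percent = gwc_val,
        ph = abio$ph[si] - (phase == "post") * 0.05 + stats::rnorm(1, 0, 0.03),
        ec = abio$ec[si] * stats::rlnorm(1, 0, 0.08),
        pct_c = abio$pct_c[si] * stats::rlnorm(1, 0, 0.05),
        pct_n = abio$pct_n[si] * stats::rlnorm(1, 0, 0.05),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, count_cols)
  rownames(counts) <- c(taxa, extra_ids)
  storage.mode(counts) <- "integer"
  metadata <- do.call(rbind, meta_rows); rownames(metadata) <- NULL

  if (cfg$shallow_samples > 0) {
    shallow <- sample(colnames(counts), cfg$shallow_samples)
    for (id in shallow) {
      tot <- sum(counts[, id])
      keep <- floor(cfg$rarefaction_depth / 2)
      counts[, id] <- as.integer(
        stats::rmultinom(1, keep, counts[, id] / tot)[, 1L])
    }
  }

  taxonomy <- make_taxonomy(taxa, extra_ids, cfg, common_ids)
  blank_ids <- if (cfg$n_blank)
    extra_ids[seq(cfg$n_unassigned + cfg$n_organelle + 1, n_extra)] else
      character()

  qpcr <- make_qpcr(cfg, biomass)
  gas <- make_gas(cfg, metadata, jar_initial, jar_growth)

  list(counts = counts, taxonomy = taxonomy, metadata = metadata,
       qpcr = qpcr$records, gas = gas$log,
       truth = list(planted = planted, common = sort(common_ids),
                    blank_asvs = blank_ids, biomass = biomass,
                    jar_initial = jar_initial, jar_growth = jar_growth,
                    growth_latent = growth_latent,
                    true_rates = gas$true_rates,
                    config = cfg))
}

make_taxonomy <- function(taxa, extra_ids, cfg, common_ids) {
  phyla <- c("Pseudomonadota", "Actinomycetota", "Bacillota",
             "Acidobacteriota", "Bacteroidota", "Verrucomicrobiota",
             "Planctomycetota", "Chloroflexota")
  n <- length(taxa)
  tx <- data.frame(
    domain = rep("Bacteria", n),
    phylum = sample(phyla, n, replace = TRUE),
    class = sprintf("Class%02d", sample(20, n, replace = TRUE)),
    order = sprintf("Order%02d", sample(40, n, replace = TRUE)),
    family = sprintf("Family%03d", sample(80, n, replace = TRUE)),
    genus = sprintf("Genus%03d", sample(150, n, replace = TRUE)),
    species = "", row.names = taxa, stringsAsFactors = FALSE)
  # recognisable genera for the shared responders, in the families the
  # thaw-responder literature reports
  resp_genera <- c("Methylorosula", "Burkholderia-Caballeronia-Paraburkholderia",
                   "Clostridium", "Actimicrobium", "Rugamonas", "Massilia",
                   "Pseudomonas", "Candidatus Planktophila")
  resp_families <- c("Beijerinckiaceae", "Burkholderiaceae", "Clostridiaceae",
                     "Oxalobacteraceae", "Oxalobacteraceae",
                     "Oxalobacteraceae", "Pseudomonadaceae", "Sporichthyaceae")
  if (length(common_ids)) {
    k <- seq_along(common_ids)
    tx[common_ids, "genus"] <- resp_genera[((k - 1) %% 8) + 1]
    tx[common_ids, "family"] <- resp_families[((k - 1) %% 8) + 1]
  }
  if (length(extra_ids)) {
    ne <- length(extra_ids)
    ex <- data.frame(domain = rep("Bacteria", ne), phylum = rep("", ne),
                     class = rep("", ne), order = rep("", ne),
                     family = rep("", ne), genus = rep("", ne),
                     species = rep("", ne), row.names = extra_ids,
                     stringsAsFactors = FALSE)
    iu <- seq_len(cfg$n_unassigned)
    io <- seq_len(cfg$n_organelle) + cfg$n_unassigned
    ib <- seq_len(cfg$n_blank) + cfg$n_unassigned + cfg$n_organelle
    if (cfg$n_organelle) {
      ex[io, "phylum"] <- "Cyanobacteria"
      ex[io, "family"] <- rep(c("Mitochondria", "Chloroplast"),
                              length.out = cfg$n_organelle)
    }
    if (cfg$n_blank) {
      ex[ib, "phylum"] <- "Pseudomonadota"
      ex[ib, "genus"] <- sprintf("BlankGenus%02d", seq_len(cfg$n_blank))
    }
    tx <- rbind(tx, ex)
  }
  tx
}

make_qpcr <- function(cfg, biomass) {
  std_q <- 0.836 * 10^(0:-5)  # five 10-fold serial dilutions, six points
  std <- do.call(rbind, lapply(seq_along(std_q), function(i)
    data.frame(record_type = "standard",
               sample_id = sprintf("STD%d", i),
               quantity_ng_ul = std_q[i],
               cq = cfg$curve_slope * log10(std_q[i]) + cfg$curve_intercept +
                 stats::rnorm(3, 0, cfg$cq_sd),
               soil_mass_g = NA_real_, elution_volume_ul = NA_real_,
               stringsAsFactors = FALSE)))
  cpn <- copies_per_ng()
  smp <- do.call(rbind, lapply(names(biomass), function(id) {
    conc <- biomass[[id]] * cfg$soil_mass_g / (cfg$elution_volume_ul * cpn)
    data.frame(record_type = "sample", sample_id = id,
               quantity_ng_ul = NA_real_,
               cq = cfg$curve_slope * log10(conc) + cfg$curve_intercept +
                 stats::rnorm(3, 0, cfg$cq_sd),
               soil_mass_g = cfg$soil_mass_g,
               elution_volume_ul = cfg$elution_volume_ul,
               stringsAsFactors = FALSE)
  }))
  list(records = rbind(std, smp))
}

make_gas <- function(cfg, metadata, jar_initial, jar_growth) {
  hours <- MEASUREMENT_DAYS * 24
  total_h <- max(hours)
  post_meta <- metadata[metadata$phase == "post", , drop = FALSE]
  logs <- list(); true_rates <- list()
  for (i in seq_len(nrow(post_meta))) {
    id <- post_meta$sample_id[i]
    b_pre <- jar_initial[[id]]
    g <- jar_growth[[id]]
    dry <- dry_mass(post_meta$wet_mass[i], post_meta$gwc_percent[i])
    # integral of k*B(t) with B(t) = B_pre * g^(t/T)
    mass_to <- function(t) {
      if (abs(g - 1) < 1e-12) cfg$resp_per_biomass * b_pre * t
      else cfg$resp_per_biomass * b_pre * total_h / log(g) *
        (g^(t / total_h) - 1)
    }
    dt <- diff(hours)
    true_rate <- (vapply(hours[-1L], mass_to, 0) -
                    vapply(hours[-length(hours)], mass_to, 0)) / dt
    noisy_rate <- true_rate *
      stats::rlnorm(length(true_rate), -cfg$gas_noise_sd_log^2 / 2,
                    cfg$gas_noise_sd_log)
    ppm <- noisy_rate * dt * (GAS_CONSTANT * cfg$temp_K) /
      (cfg$pressure_atm * cfg$volume_L) * dry / 12
    logs[[id]] <- data.frame(
      sample_id = id, elapsed_hours = hours,
      co2_ppm = c(0, ppm), pressure_atm = cfg$pressure_atm,
      volume_L = cfg$volume_L, temp_K = cfg$temp_K,
      flushed_flag = TRUE, stringsAsFactors = FALSE)
    true_rates[[id]] <- data.frame(interval_start_h = hours[-length(hours)],
                                   interval_end_h = hours[-1L],
                                   rate = true_rate)
  }
  list(log = do.call(rbind, c(logs, list(make.row.names = FALSE))),
       true_rates = true_rates)
}

#' Write a simulated experiment to a fixture directory
#'
#' Emits the file set every other pipeline stage consumes: `counts.tsv`,
#' `taxonomy.tsv`, `metadata.csv`, `qpcr.csv`, `gas.csv`, plus the ground
#' truth (`truth_responders.tsv`, `truth_blanks.tsv`, `truth_biomass.tsv`).
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_count_table(sim$counts, p("counts.tsv"))
  tx <- data.frame(taxon_id = rownames(sim$taxonomy), sim$taxonomy,
                   stringsAsFactors = FALSE)
  utils::write.table(tx, p("taxonomy.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(sim$metadata, p("metadata.csv"), row.names = FALSE)
  utils::write.csv(sim$qpcr, p("qpcr.csv"), row.names = FALSE)
  utils::write.csv(sim$gas, p("gas.csv"), row.names = FALSE)
  seed <- sim$truth$config$seed
  resp <- do.call(rbind, lapply(names(sim$truth$planted), function(s)
    if (length(sim$truth$planted[[s]]))
      data.frame(site = s, taxon_id = sim$truth$planted[[s]],
                 common = sim$truth$planted[[s]] %in% sim$truth$common)))
  if (is.null(resp))
    resp <- data.frame(site = character(), taxon_id = character(),
                       common = logical())
  write_result_table(resp, p("truth_responders.tsv"), list(seed = seed))
  write_result_table(data.frame(taxon_id = sim$truth$blank_asvs),
                     p("truth_blanks.tsv"), list(seed = seed))
  write_result_table(data.frame(sample_id = names(sim$truth$biomass),
                                copies_per_g = unname(sim$truth$biomass)),
                     p("truth_biomass.tsv"), list(seed = seed))
  invisible(dir)
}

#' Check planted effects against the simulation's ground truth
#'
#' Empirical validation that the generator does what it claims: for each
#' site, the mean post/pre ratio of realised absolute abundances (relative
#' abundances scaled by true biomass) over the planted responders should lie
#' within 3 Monte-Carlo standard errors of the configured fold, and the
#' ratio over non-planted taxa within 3 SEs of 1. Taxa with a zero pre-thaw
#' mean at a site are skipped (their ratio is undefined) and counted.
#'
#' @param sim Output of [simulate_experiment()].
#' @return Data.frame with one row per site and group
#'   (planted/non-planted): mean ratio, Monte-Carlo SE, target, `pass`.
#' @export
planted_effect_check <- function(sim) {
  cfg <- sim$truth$config
  if (is.null(cfg)) stop_domain("truth does not match this simulation")
  meta <- sim$metadata
  core_taxa <- setdiff(rownames(sim$counts),
                       grep("^CON", rownames(sim$counts), value = TRUE))
  rel <- relative_abundance(sim$counts)
  abs_ab <- sweep(rel, 2, sim$truth$biomass[colnames(rel)], "*")
  rows <- list()
  for (s in unique(meta$site)) {
    pre <- meta$sample_id[meta$site == s & meta$phase == "pre"]
    post <- meta$sample_id[meta$site == s & meta$phase == "post"]
    m_pre <- rowMeans(abs_ab[core_taxa, pre, drop = FALSE])
    m_post <- rowMeans(abs_ab[core_taxa, post, drop = FALSE])
    ok <- m_pre > 0
    ratio <- m_post[ok] / m_pre[ok]
    grp <- list(planted = intersect(names(ratio), sim$truth$planted[[s]]),
                non_planted = setdiff(names(ratio), sim$truth$planted[[s]]))
    target <- c(planted = cfg$fold, non_planted = 1)
    # subsample and jar-growth noise is shared by every taxon's ratio
    # within a site, so it does not average out across taxa; its
    # contribution to the SE of the mean ratio is added from the
    # configured noise levels
    sub_v <- exp(cfg$sample_biomass_sd_log^2) - 1
    shared_var <- sub_v / length(pre) +
      (sub_v + exp(cfg$growth_sd_log^2) - 1) / length(post)
    for (g in names(grp)) {
      r <- ratio[grp[[g]]]
      if (!length(r)) next
      v <- if (length(r) > 1) stats::var(r) else 0
      se <- sqrt(v / length(r) + target[[g]]^2 * shared_var)
      rows[[paste(s, g)]] <- data.frame(
        site = s, group = g, n = length(r),
        n_skipped = sum(!ok), mean_ratio = mean(r), mc_se = se,
        target = target[[g]],
        pass = abs(mean(r) - target[[g]]) <= 3 * se,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}
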