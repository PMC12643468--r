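# Shared fixtures, built in code.

# A small planted-effect experiment used by several test files.
small_sim <- function(seed = 101, ...) {
  simulate_experiment(sim_config(
    n_taxa = 120, depth_mean = 8000, rarefaction_depth = 2000,
    n_common = 4, seed = seed, ...))
}

# Single-site null dataset (no planted effect) at the analysis scale.
null_sim <- function(seed, ...) {
  simulate_experiment(sim_config(
    n_sites = 1, cores_per_site = 1, replicates_per_core = 4,
    fold = 1, seed = seed, ...))
}

# Curation chain up to absolute abundance, mirroring the documented
# workflow order: filter -> rarefy -> relative -> qPCR scaling.
curated_abundance <- function(sim, depth = sim$truth$config$rarefaction_depth,
                              seed = sim$truth$config$seed) {
  filtered <- filter_asvs(sim$counts, sim$taxonomy, sim$truth$blank_asvs)
  rarefied <- rarefy_counts(filtered, depth, seed = seed)
  rel <- relative_abundance(rarefied)
  qt <- qpcr_totals(sim$qpcr)
  list(filtered = filtered, rarefied = rarefied,
       abs = absolute_abundance(
         rel, stats::setNames(qt$totals$copies_per_g, qt$totals$sample_id)),
       qpcr = qt)
}

# Toy taxonomy builder for filtering tests.
toy_taxonomy <- function(ids, phylum = "Pseudomonadota", family = "Fam",
                         genus = "Gen") {
  n <- length(ids)
  data.frame(domain = rep("Bacteria", n), phylum = rep(phylum, length.out = n),
             class = rep("C", n), order = rep("O", n),
             family = rep(family, length.out = n),
             genus = rep(genus, length.out = n), species = rep("", n),
             row.names = ids, stringsAsFactors = FALSE)
}
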