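# permathaw

Analysis toolkit for laboratory permafrost-thaw microcosm experiments, for
soil microbial ecologists who incubate frozen cores, measure headspace CO2
and 16S rRNA gene abundance, and want to know **which taxa respond to thaw
and how microbial growth relates to carbon release**.

The package covers the full desk side of such an experiment:

* **Gas flux** — converts headspace CO2 mole fractions from a closed,
  periodically flushed jar into respiration rates and cumulative
  respiration per gram of dry soil.
* **Absolute abundance** — filters and rarefies ASV count tables, fits
  qPCR standard curves, and scales relative abundances to 16S gene copies
  per gram of soil.
* **Thaw responders** — the core statistic: a replicated log response-ratio
  test per taxon and site, with delta-method standard errors, Z-tests,
  Benjamini–Hochberg FDR control, a two-fold rule, and the cross-site
  intersection of responders.
* **Diversity and inference** — Shannon/Gini–Simpson, Bray–Curtis, PCoA,
  PERMANOVA, beta-dispersion, Spearman correlation, and the usual group
  tests (Kruskal–Wallis + Dunn/Holm, ANOVA + Tukey, Wilcoxon).
* **Synthetic data** — a seeded generator that emulates a 3-site x 2-core x
  4-replicate paired pre/post-thaw incubation, with planted responders and
  a biomass-linked respiration series, so the whole pipeline is testable
  without any sequencing data.

## The core model

For each taxon and site, let x̄_pre and x̄_post be the mean absolute
abundances (copies g⁻¹ soil, pseudocount-adjusted) over the pre- and
post-thaw replicates. The log response ratio and its delta-method standard
error are

    RR = ln(x̄_post / x̄_pre)
    SE = sqrt( s²_post / (n_post x̄²_post) + s²_pre / (n_pre x̄²_pre) )

with z = RR/SE tested two-tailed against the standard normal and p-values
adjusted within site by Benjamini–Hochberg. A taxon is a **thaw responder**
when q < 0.05 and RR ≥ ln 2 (a two-fold increase or more). Responder sets
are intersected across sites at the ASV level and reported at the genus
level. A robustness variant runs the same test on centred log-ratio (CLR)
transformed non-rarefied counts and reports the agreement.

Respiration rates come from the ideal-gas conversion

    µg CO2-C g⁻¹ h⁻¹ = CO2[µmol/mol] · (P·V)/(R·T) · 12 / (g dry soil · t)

with t the hours since the most recent headspace flush, and cumulative
respiration is the rectangle sum of rate × interval over flush-delimited
intervals.

## Worked example

```r
library(permathaw)
sim <- simulate_experiment(sim_config(seed = 7))
ana <- run_thaw_analysis(sim$counts, sim$taxonomy, sim$metadata, sim$qpcr,
                         blank_asvs = sim$truth$blank_asvs,
                         gas = split(sim$gas, sim$gas$sample_id), seed = 7)
ana
```

```
Thaw incubation analysis: 500 taxa x 48 samples after curation
Thaw-responder log response-ratio fit
  sites analysed: BEO (500 taxa), FL (500 taxa), PT (499 taxa)
  responders (q < 0.05, >= 2-fold): BEO: 27, FL: 28, PT: 25
  common responders across sites: 8 ASV(s)
  CLR robustness check: mean Jaccard agreement 0.94
  cumulative respiration: 366-693 ug CO2-C g^-1 dry soil
```

Each site yields 25–28 responders (the generator plants 25 per site at an
8-fold post-thaw increase), the 8 planted cross-site responders are all
recovered, and the rarefied and CLR analyses agree. `summary(ana$fit)`
lists the strongest responders with their RR, SE and q, and the shared set
mapped to genus:

```
Common responders across all sites: 8 ASV(s)
  genera: Actimicrobium, Burkholderia-Caballeronia-Paraburkholderia,
  Candidatus Planktophila, Clostridium, Massilia, Methylorosula,
  Pseudomonas, Rugamonas
```

The fitted qPCR standard curve prints its slope, R² and amplification
efficiency:

```
qPCR standard curve: Cq = -3.2507 log10(q) + 9.6854  (R^2 = 0.9992, efficiency = 103.1%)
```

There is also a thin command-line interface over the same functions
(`inst/scripts/permathaw`), with subcommands `simulate`, `flux`,
`abundance`, `responders`, `diversity` and `report`.

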