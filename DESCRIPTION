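Package: permathaw
Title: Microbial Response-Ratio Analysis of Permafrost Thaw Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for laboratory permafrost-thaw microcosm
    experiments. Converts closed-chamber headspace CO2 measurements into
    dry-soil-normalised respiration rates and cumulative respiration, scales
    16S rRNA amplicon (ASV) count tables to absolute abundances using qPCR
    standard curves, and identifies "thaw responders" - taxa whose absolute
    abundance increases at least two-fold after thaw - with a replicated log
    response-ratio test (delta-method standard errors, Z-scores, and
    Benjamini-Hochberg false-discovery control). Also provides soil abiotic
    summaries (gravimetric water content, C:N), alpha/beta diversity
    statistics (Shannon, Gini-Simpson, Bray-Curtis, PCoA, PERMANOVA,
    beta-dispersion, Spearman correlation, Kruskal-Wallis/Dunn and
    ANOVA/Tukey group tests), and a seeded synthetic-data generator that
    emulates a multi-site paired pre/post-thaw incubation design for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vegan,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
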