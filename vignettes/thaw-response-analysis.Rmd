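---
title: "Identifying thaw responders in permafrost incubation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying thaw responders in permafrost incubation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permathaw)
```

## The scientific problem

When permafrost thaws, previously frozen soil carbon becomes available to
microbial decomposition, and the community that wakes up determines how
much of that carbon leaves the soil as CO2. A thaw microcosm experiment
incubates replicate subsamples of frozen cores just above freezing,
follows headspace CO2 over weeks to months, and characterises the
community before and after thaw by 16S rRNA amplicon sequencing and qPCR.
`permathaw` implements the quantitative chain from those raw measurements
to the experiment's central question: *which taxa increase in absolute
abundance with thaw, consistently across sites, and how does microbial
growth relate to carbon release?*

## From headspace CO2 to cumulative respiration

Each jar is measured on a fixed schedule and flushed with CO2-free air
after every measurement, so a measured mole fraction is the accumulation
since the most recent flush against a zero baseline. With headspace
pressure $P$ (atm), volume $V$ (L), temperature $T$ (K), and the ideal gas
constant $R = 0.08206$ L atm K$^{-1}$ mol$^{-1}$, the respiration rate is

$$\mathrm{rate} \;=\; \mathrm{CO_2}\,[\mu\mathrm{mol\,mol^{-1}}] \cdot
\frac{PV}{RT} \cdot \frac{12\,\mu\mathrm{g\,C}}{\mu\mathrm{mol}} \cdot
\frac{1}{m_\mathrm{dry}\,t}$$

in µg CO2-C g$^{-1}$ dry soil h$^{-1}$, where $t$ is hours since the last
flush and $m_\mathrm{dry}$ the dry soil mass. Dry mass comes from the
gravimetric water content on a *dry-mass* basis,
$m_\mathrm{dry} = m_\mathrm{wet} / (1 + \mathrm{GWC}/100)$; the dry-mass
convention matters because organic permafrost routinely exceeds 100% GWC.
Cumulative respiration is the rectangle sum of rate × duration over the
flush-delimited intervals — each measured accumulation already integrates
its own interval, so no trapezoid correction is applied, and splitting an
interval at constant rate leaves the total unchanged (a property the test
suite asserts).

## From reads to absolute abundance

Curation follows the standard amplicon order: taxa unassigned at the
phylum level, lineages containing *Mitochondria* or *Chloroplast* at any
rank, and taxa observed in extraction/PCR blanks (an explicit ID list; the
package does not guess contamination statistically) are removed, then
samples are rarefied **once** to a common depth by a single multivariate
hypergeometric draw. A single rarefied table, rather than an average over
draws, keeps every downstream statistic consistent with one realisation of
the subsampling.

qPCR standard curves are fitted as $C_q = a \log_{10}(q) + b$ over a
dilution series, with amplification efficiency $10^{-1/a} - 1$. Triplicate
sample $C_q$ values are averaged *before* curve inversion (standard qPCR
practice; inversion is monotone, so the order matters only slightly at
triplicate spread). Converting a mass-based genomic standard to gene
copies requires the standard organism's genome size and rRNA operon count;
these are explicit arguments with an *E. coli* K-12 default
(`copies_per_ng()`), because a mass-to-copies conversion hidden inside a
function is a classic source of silent unit errors. Totals are expressed
per gram of soil *as extracted*. Relative abundances multiplied by these
totals give the absolute abundance table; renormalising it recovers the
relative table exactly.

## The response-ratio model

For each site and taxon, with pre- and post-thaw replicate abundances
(absolute scale), the effect is the log response ratio of group means with
a delta-method standard error:

$$RR = \ln\frac{\bar{x}_\mathrm{post}}{\bar{x}_\mathrm{pre}}, \qquad
SE^2 = \frac{s^2_\mathrm{post}}{n_\mathrm{post}\bar{x}^2_\mathrm{post}} +
       \frac{s^2_\mathrm{pre}}{n_\mathrm{pre}\bar{x}^2_\mathrm{pre}}$$

$z = RR/SE$ is tested two-tailed against the standard normal; p-values are
Benjamini–Hochberg adjusted; a taxon is a **responder** when $q < \alpha$
(default 0.05) *and* $RR \ge \ln(\mathrm{fold})$ (default 2, boundary
inclusive, applied to the point estimate). Design choices that the data do
not dictate, and how they were resolved:

* **Pseudocount.** Zeros are eliminated by *adding* 0.01 to every cell
  (multiplication cannot remove zeros; addition preserves the ordering and
  the presence/absence structure).
* **Degenerate taxa.** Taxa absent in both phases at a site are excluded
  from testing — they carry no information and only inflate the number of
  tests. If both groups are constant and equal, $p = 1$; if the means
  differ but the estimated SE is exactly zero, the SE is floored at a
  machine-epsilon-safe minimum (flagging the taxon as trivially
  significant rather than producing an infinite z).
* **Correction scope.** BH is applied within each site across its tested
  taxa (per-site responder counts are the quantity of interest); a global
  scope is available via `bh_scope = "global"`.
* **Cross-site responders.** Sets are intersected at the ASV level and
  then mapped to genus through the taxonomy — intersection first, naming
  second.
* **Robustness variant.** The same testing chain runs on CLR-transformed
  non-rarefied counts (effect = difference of CLR group means, with a
  two-sample delta-method SE; CLR pseudocount 0.5, the usual half-read for
  integer tables), and per-site Jaccard agreement between the two
  responder sets is reported. Under strong planted effects agreement
  exceeds 0.8 routinely.

## Diversity and inferential statistics

Shannon diversity uses natural logs; Simpson is the Gini–Simpson form
$1 - \sum p_i^2$ (high = diverse, the form consistent with values near 1
for diverse pre-thaw communities). Both are computed on the rarefied
table. Bray–Curtis dissimilarities feed classical-scaling PCoA; negative
eigenvalues are reported, not corrected (no Lingoes/Cailliez). The
one-factor PERMANOVA partitions sums of squared dissimilarities, permutes
group labels (never distances), and uses the add-one estimator
$p = (1 + \#\{F^* \ge F\})/(1 + n_\mathrm{perm})$, so p is never zero.
Because sequential sums of squares depend on term order in unbalanced
designs, the two-factor site + thaw report computes both orders
(`permanova_site_thaw()`). Beta-dispersion delegates to vegan's
`betadisper`/`permutest` with Tukey pairwise comparisons; singleton groups
are excluded with a warning. Group tests follow the usual decision rule:
ANOVA + Tukey when Shapiro–Wilk and Levene prechecks hold, otherwise
Kruskal–Wallis with a Dunn post-hoc (pooled-ranking z tests with tie
correction, Holm-adjusted); for two groups the squared Dunn z equals the
Kruskal–Wallis statistic, which the tests exploit as an oracle.

## What the synthetic generator emulates

`simulate_experiment()` produces a complete experiment — counts, taxonomy,
metadata, qPCR wells, gas log, and the generating truth — deterministically
from one seed. Its defaults encode the incubation design the package
targets:

| Parameter | Default | Why |
|---|---|---|
| design | 3 sites × 2 cores × 4 replicates | 24 incubation jars plus paired pre-thaw communities (48 samples) |
| `n_taxa` | 500 | desk-scale community; real ASV tables are ~30× richer |
| `depth_mean` | 20,000 | sequencing-depth QC floor of the emulated protocol |
| `rarefaction_depth` | 5,000 | retains nearly all samples |
| `sigma_base`, `sigma_site` | 0.7, 0.7 | combined lognormal spread ≈ 1: rarefied Shannon ≈ 5 with clear site separation |
| `responder_fraction`, `fold` | 0.05, 8 | 25 planted responders per site with a strong, recoverable effect |
| `n_common` | 8 | shared cross-site subset; site extras are disjoint across sites |
| responder pool | top 20% of baseline | planted responders jointly reach ~50% of the post-thaw community, so dominance rises and diversity falls — boosting mid-rank taxa would instead *even out* the community |
| `qpcr_pre_mean` | 5×10⁷ copies g⁻¹ | low-biomass frozen soil; keeps sample Cq inside the standard range |
| `growth_sd_log` | 0.25 | per-jar biological growth variability; replicate microcosms diverge substantially over three months, and the same jar trajectory drives both its respiration and its measured biomass change |
| `cq_sd`, curve slope | 0.15 cycles, −3.23 | realistic well noise; ~104% efficiency |
| gas model | rate ∝ instantaneous biomass | CO2 ppm per interval inverts the flux equation exactly up to multiplicative noise (sd 0.15) |

Fold effects are applied to *latent absolute* abundances before
compositional renormalisation, so the generator exhibits exactly the
compositional distortion the CLR check targets: non-responders keep an
absolute-abundance ratio of 1 while their relative abundances shrink.
Synthetic contaminant taxa (phylum-unassigned, organelle, blank-derived)
are appended to exercise the filtering rules, and `shallow_samples` can
force samples below the rarefaction depth to exercise sample dropping.

What it deliberately does **not** emulate: read-level sequencing error and
chimeras; the extreme sparsity and richness of real ASV tables (tens of
thousands of taxa, most of them rare); taxon-specific 16S operon copy
number; biological overdispersion of replicate communities beyond
multinomial sampling. Passing tests therefore demonstrate correctness of
the computational chain and the qualitative behaviour of the statistics,
not the operating characteristics of the test on real, sparser data —
see the limitation below.

## Problem sizes and numerical choices

Test and validation runs use 500-taxon communities, 200 single-site null
datasets and 50 replicate full experiments — sizes chosen so the whole
suite runs in about a minute on a laptop while Monte-Carlo checks retain
3-standard-error resolution. The gas constant is fixed at 0.08206 L atm
K⁻¹ mol⁻¹ (overridable only for testing); result tables are written with
17 significant digits so write/read round trips are lossless; permutation
tests never return p = 0 by construction; rarefaction, permutations and
simulations restore the caller's RNG state after use.

## Known limitations

The normal-reference Z-test on the log response ratio is **anti-conservative
at small replicate numbers**. With four replicates per phase, RR/SE is
closer to a t statistic with ~4–6 degrees of freedom than to a standard
normal, which inflates extreme tail probabilities by orders of magnitude —
exactly the region where BH rejections at q < 0.05 among hundreds of taxa
are decided. In addition, taxa absent before thaw but observed in a few
post-thaw reads acquire enormous z-scores once a pseudocount of 0.01 meets
absolute abundances of 10⁴–10⁵ copies g⁻¹. Both effects are visible in the
package's own null simulations (the `null_*` entries written by
`scripts/acceptance.R`): datasets with no planted effect still yield a
handful of (false) responder calls. Interpreting per-site responder counts
therefore warrants caution for low-prevalence taxa; the cross-site
intersection is far more robust, since independent false positives rarely
replicate across three sites. Users wanting stricter error control can
raise `fold_threshold`, lower `alpha`, or pre-filter low-prevalence taxa
before fitting — the test itself is kept exactly as specified so that its
behaviour is transparent.

Electrical conductivity values are carried verbatim in the units of the
source instrument table; the package performs no unit reinterpretation.
Where published tables print a mean ± spread, summaries here use the
standard error of the mean and record the n used, flagging the convention
in output provenance.
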