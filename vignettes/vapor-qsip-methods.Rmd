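---
title: "Estimating taxon-specific growth from vapor-equilibration qSIP gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating taxon-specific growth from vapor-equilibration qSIP gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaporqsip)
library(dplyr)
```

This vignette explains the models behind `vaporqsip`: what is assumed, which
parameters matter, what the synthetic-data generator does and does not
emulate, and where genuinely open design choices were made.

## 1. The measurement model

Quantitative stable isotope probing (qSIP) rests on a chain of three
physical relationships for bacterial/archaeal genomic DNA in a CsCl
gradient:

1. **Density–GC.** Unlabeled DNA equilibrates at a buoyant density linear in
   its GC content: $w_{light} = 1.646057 + 0.083506\,GC$ (g/mL). The package
   inverts this to infer GC from the *unlabeled* weighted average density
   (WAD) of each taxon.
2. **Molecular weight–GC.** The mean nucleotide weight of unlabeled DNA is
   $M_{light} = 307.691 + 0.496\,GC$ (g/mol), and full substitution of every
   backbone oxygen with ¹⁸O adds at most $12.07747$ g/mol
   ($M_{heavymax}$).
3. **Proportionality of density and molecular weight.** A taxon's labeled
   molecular weight follows from its relative density shift,
   $M_{lab} = M_{light} \, w_{lab}/w_{light}$.

The excess atom fraction of ¹⁸O is then
$$EAF \;=\; \frac{M_{lab} - M_{light}}{M_{heavymax} - M_{light}}
\,\bigl(1 - 0.002000429\bigr),$$
the last factor discounting the natural abundance of ¹⁸O. These constants
are the ones established for the qSIP method and used across its software
ecosystem; the package keeps them in `qsip_constants()`, overridable but not
silently configurable.

Assumptions worth keeping in mind: the linear density–GC relation holds for
genomic DNA fragments typical of soil extractions; a taxon's DNA in one tube
is summarized by a single WAD; and enrichment is homogeneous within a taxon
(one EAF per taxon per tube). The estimator is purely per-replicate — no
bootstrap pooling across tubes — so replicate scatter carries into the
downstream statistics, where it belongs.

### Abundance currency

Reads never leave their fraction: amplicon libraries are prepared per
fraction, so read counts measure *within-fraction composition* only. Every
quantity that needs mass is converted immediately to 16S copies,
$$y_{t,f} = \frac{\text{reads}_{t,f}}{\sum_t \text{reads}_{t,f}}
\times \text{ddPCR copies}_f,$$
and WADs are $\sum_f d_f\, y_{t,f} / \sum_f y_{t,f}$. Per-sample absolute
abundances agglomerate the same $y_{t,f}$ over the gradient. This makes all
estimates invariant to how sequencing depth happens to be distributed across
fractions — the property that a fixed-cycle PCR library prep would otherwise
destroy. (An alternative found in parts of the literature — tube-level read
proportions times summed copies — coincides with this exactly when depth is
proportional to DNA mass, and is biased otherwise; the per-fraction form is
the safer default and is what this package computes.)

### Filters

* **Density window** 1.614–1.753 g/mL (inclusive): lighter fractions are
  contaminated with displacement water, heavier ones with concentrated CsCl.
* **Read floor**: fractions need strictly more than 2000 read pairs.
* **Prevalence**: a taxon enters a treatment's analysis only if present in
  ≥ 4 fractions in each of ≥ 2 *labeled* replicate tubes of that treatment.
  (Whether unlabeled tubes should count toward the replicate rule is
  ambiguous in practice; this package counts labeled tubes, and the
  thresholds are arguments.)
* **WAD offset correction**: when low-density fractions of a tube are lost
  during collection, its community WAD is biased heavy. For explicitly
  flagged tubes — only flagged tubes, no auto-detection, since fraction loss
  is something the experimenter knows — the offset against the mean
  community WAD of unflagged same-treatment, same-isotope tubes is
  subtracted from all of the tube's densities.

### Unlabeled reference

Each taxon's $w_{light}$ is the mean of its WADs across the treatment's
natural-abundance tubes. If a taxon is missing from a treatment's unlabeled
tubes the global unlabeled mean substitutes (density–GC is a property of
the genome, not the treatment); taxa missing from all unlabeled tubes are
excluded and reported. Negative EAF values are kept in the table — they are
noise around zero and truncating them would bias replicate means — but are
clamped to zero when averaging growth rates over non-growing taxa, and never
count as "active".

### Thresholds

APE ¹⁸O $= 100 \times EAF$. Taxa with APE > 0 are *active*; APE > 5% marks
*growing*, a guard band against between-tube density jitter producing
spurious enrichment. Both thresholds are `qsip_config()` arguments; setting
the growing threshold to 0 collapses the two classes.

## 2. From enrichment to growth

Assuming linear growth over the incubation,
$$RGR = \frac{AFE_{taxon}}{AFE_{soil\,water} \times days} \quad
[\mathrm{day}^{-1}],$$
with both enrichments as decimal atom fraction excess. The soil-water term
is the *time-averaged* enrichment (Section 3), not the final value, because
DNA synthesized early in the incubation saw less label.

Community summaries are computed per labeled sample first — means of
taxon-level rates, growing richness, percent of 16S copies in growing taxa —
and only then compared across treatments, so each replicate contributes one
value and taxa are not pseudoreplicated. Mean RGRs are unweighted taxon
means, deliberately not abundance-weighted: the quantity of interest is the
typical taxon's growth, with community-weighted activity captured separately
by proportional assimilation,
$$p_i = \frac{a_i\,RGR_i}{\sum_j a_j\,RGR_j},$$
where $a_i$ re-normalizes abundances within the growing subset (so
$\sum p_i = 1$ per sample). Top-assimilator tables rank at the taxon (ASV)
level, require growth in ≥ 2 replicates of the treatment, and only then
agglomerate display labels at genus — falling back to family, then phylum,
where ranks are unassigned — so that ranking is never distorted by label
merging.

Treatment overlap works on "growing sets": taxa growing in ≥ 2 labeled
replicates of a treatment. `treatment_overlap()` returns all Venn region
cardinalities plus pairwise intersections; "drought-enduring" taxa are those
growing under a drought treatment that also grow in at least one
drought-unaffected treatment (`overlap_with_any()`).

## 3. Vapor equilibration

The dosing volume solves a two-pool mass balance between soil water (at
natural abundance, 0.2 atom%) and headspace water (75 or 95 atom% in
practice; 95 for moist soils, 75 for dry soils where less water remains for
isotopic analysis), for a target around 70 atom%:
$$V = V_{sw}\,\frac{at\%_{NA} - at\%_{target}}{at\%_{target} - at\%_{added}}.$$
`water_volume_for_target()` rejects degenerate specs (added = target) and
infeasible targets (above the added water's enrichment or below natural
abundance) rather than returning negative volumes.

Soil water approaches the equilibrium enrichment over 1–2 days. The package
fits $e(t) = a(1 - e^{-kt})$ by bounded Levenberg–Marquardt least squares
($a \in [0, 100]$ atom%, $k \ge 0$; start values $a_0 = \max e$,
$k_0 = 1/\mathrm{median}(t)$) and reports the time average from the closed
form
$$\bar e = a\Bigl(1 - \frac{1 - e^{-kT}}{kT}\Bigr),$$
switching to the series limit $a\,kT/2$ for $kT < 10^{-8}$ to avoid 0/0.
The curve is fitted as excess above zero: the natural-abundance baseline
(0.2 atom%) is three orders of magnitude below labeled values and modelling
it as an offset would add a parameter the 4-point calibration series cannot
support. One curve is fitted per grouping-column level, matching designs
with one calibration series per treatment. Degenerate series are resolved
analytically: all-zero values give a zero curve; flat positive values are
the $k \to \infty$ limit with $\bar e = a$.

## 4. What the synthetic generator emulates

`simulate_experiment()` produces the four input tables with known truth. Its
defaults are the study conditions of the grassland drought experiment this
package is built around:

| Parameter | Default | Meaning |
|---|---|---|
| treatments | 2×2 drought × climate factorial | scenario presets below |
| replicates | 4 | each contributes one ¹⁸O and one ¹⁶O tube |
| `n_fractions` | 24 | 250-µl fractions over 1.60–1.78 g/mL |
| `reads_per_tube` | 50 000 | total read pairs per tube |
| `incubation_days` | 5 | labeling period |
| `soil_water_ape` | drawn U(55, 64) atom% per treatment | time-averaged label |
| `sigma_d` | 0.006 g/mL | within-tube spread of a taxon's DNA |
| `pcr_saturation` | 0.005 | half-saturation DNA share of library yield |
| `wlight_sd` | 0.002 g/mL | taxon scatter around the density–GC line |
| `ddpcr_sdlog` | 0.1 | lognormal ddPCR measurement error |
| `density_sd` | 0.0005 g/mL | refractometer jitter |
| `tube_abund_sdlog` | 0.25 | between-replicate abundance variation |

Scenario presets set the abundance-weighted share of community 16S copies in
growing taxa: 35% (ambient), 4% (drought), 45% (future climate), 9% (future
climate + drought). The growing set is chosen by randomized greedy selection
with one refinement pass, so the realized share sits within a fraction of a
percentage point of the preset; growing taxa draw EAF from a Beta(2, 4)
rescaled onto (0.05, AFE of the soil water) — strictly above the growing
threshold, bounded by the label actually available — and non-growing taxa
have EAF exactly 0, since no DNA replication means no ¹⁸O incorporation.

Two modelling choices deserve emphasis:

* **Mass binning.** A taxon's DNA mass is a Gaussian in density, allocated
  onto the fraction grid with triangular (cloud-in-cell) weights. This
  allocation preserves the distribution's first moment exactly, so in the
  noiseless limit a taxon's binned WAD equals its generating center to
  machine precision — which is what makes exact recovery tests possible at
  all. `sigma_d = 0.006` g/mL spreads DNA over roughly 4–6 fractions,
  compatible with the ≥ 4-fraction prevalence rule; the generator warns if
  the grid is too coarse for the chosen spread (bin width > 2σ).
* **Library depth.** Sequencing depth per fraction follows a Michaelis-type
  saturation in the fraction's DNA share (half-saturation `pcr_saturation`
  = 0.5% of tube DNA): fixed-cycle PCR yields comparable libraries from any
  fraction with appreciable template, while nearly-empty fractions yield
  few reads and are later removed by the read floor. Depth proportional to
  DNA mass — the naive alternative — would starve the heavy, sparsely
  populated labeled tail of reads and make strongly labeled taxa invisible,
  which is not what per-fraction library preparation does.

Reads are one multinomial draw per tube over taxon × fraction cells (or
deterministic expected counts in the noiseless mode, `qsip_noise_off()`).
Seeds: one master seed, with per-tube seeds derived by a stable string hash
of the tube id, so a single tube can be re-simulated without replaying the
experiment.

**What it does not emulate.** No primer/PCR bias, chimeras or
nucleotide-level sequencing error (reads are taxon-labeled counts); no
treatment effect on taxon *abundances* (the same base community underlies
all treatments, with lognormal replicate jitter), so ordination/PERMANOVA
effect sizes on synthetic data are small even when growing-set differences
are large — the statistics layer is validated for calibration, not for
reproducing published effect sizes; no correlation between a taxon's growth
across treatments, so cross-treatment growth-rate contrasts of shared taxa
carry no designed signal; and no density-gradient artifacts beyond the
Gaussian spread. Passing recovery tests therefore demonstrates that the
estimator inverts the generative model it assumes, not that field data meet
those assumptions.

Recovery metrics (median EAF error, growing-flag precision and recall) are
scored over the taxon × treatment pairs that survive the prevalence filter:
taxa the pipeline never assesses cannot carry a flag in either direction.

## 5. Statistics layer

Absolute abundances are CLR-transformed per sample,
$x \mapsto \log(x + 1) - \overline{\log(x + 1)}$, with a pseudocount of one
gene copy — negligible against ddPCR-scale abundances, exposed in
`qsip_config()`. PCA is centered, unscaled SVD. PERMANOVA uses sequential
(type-I) sums of squares in the order drought, climate, interaction — the
factor order is the argument order and therefore explicit — with
permutation p-values $(1 + \#\{F^{perm} \ge F\})/(1 + n_{perm})$ and a
mandatory seed. Two-way ANOVA is the standard fixed-effects decomposition
(on the balanced designs used here, identical under any SS convention).
Welch's unequal-variance *t* with Satterthwaite df is the pairwise test;
Benjamini–Hochberg step-up corrects families of p-values.

Assumption gating mirrors field practice: Shapiro–Wilk on the one-way
residuals and median-centered Levene across groups, both at α = 0.05; if
either fails — or the gate cannot run (groups < 3, constant data) — analysis
routes to pairwise Wilcoxon rank-sum tests (exact for n ≤ 8 without ties,
normal approximation otherwise).

Degenerate-input conventions, chosen so pipelines fail loudly only where
silence would lie: identical multivariate points give PERMANOVA p = 1 on
every term; a constant ANOVA response reports F = 0, p = 1; two zero-
variance groups give Welch p = 1 when means agree and p = 0 otherwise;
all-zero CLR samples are an error.

## 6. Problem sizes in the test suite

The suite simulates at 60–200 taxa, 2–4 treatments, 2–3 replicates and
30–50 k reads per tube; the end-to-end recovery check uses the full
200-taxon, 4-treatment, 3 + 3-tube design at 50 k reads, and the PERMANOVA
type-I calibration runs 200 null datasets at 999 permutations. These sizes
make the whole suite run in well under a minute while leaving every
recovery margin (EAF error < 0.02, flag precision/recall > 0.9, share
within ±5 points) comfortably exercised rather than barely met.

## 7. Known limitations

* GC inference from $w_{light}$ inherits density noise; values outside
  [0, 1] are clamped (with a warning), which can compress EAF slightly for
  extreme-GC taxa.
* The 5% APE growing threshold is a convention, not an inference; taxa
  growing slowly but genuinely sit below it, and the active/growing split
  should be read accordingly.
* One EAF per taxon per tube cannot represent intra-taxon heterogeneity
  (e.g. only part of a population dividing).
* The window and read filters truncate extreme Gaussian tails of the most
  enriched taxa near the heavy window edge, a small negative bias inherent
  to any windowed gradient analysis.
* The mixed-model treatment of genus-level growth responses found in some
  analyses of such data is out of scope here; the package stops at the
  two-way ANOVA / rank-test layer.
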