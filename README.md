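# vaporqsip

Taxon-specific microbial growth rates in soil from **water-vapor
equilibration qSIP** (quantitative stable isotope probing with ¹⁸O water).

## The problem

Growth of soil bacteria and archaea can be measured by incubating soil with
¹⁸O-labeled water: organisms that replicate incorporate ¹⁸O into new DNA,
which makes that DNA heavier. After CsCl density-gradient ultracentrifugation
and fractionation, the buoyant-density shift of each taxon's DNA between
labeled and natural-abundance gradients quantifies its growth. Adding
*liquid* labeled water rewets dry soil and distorts the very activity being
measured; vapor equilibration instead lets ¹⁸O water placed in the headspace
of a sealed vial exchange with the soil water through the gas phase,
preserving soil moisture — which makes growth measurable in drought-affected
soils.

`vaporqsip` implements the full analysis for such experiments, for microbial
ecologists working from fraction-resolved 16S amplicon count tables, ddPCR
16S totals and refractometer densities:

* **Equilibration**: dosing volume from the two-pool mass balance
  V = V_sw·(at%_NA − at%_target)/(at%_target − at%_added), and the
  time-averaged soil-water enrichment from a saturating-exponential fit
  e(t) = a·(1 − e^(−kt)) integrated over the incubation.
* **qSIP core**: density-window and read-depth filtering of fractions,
  per-taxon weighted average densities (WAD), tube-level WAD offset
  correction for lost fractions, a prevalence filter, and the excess atom
  fraction of ¹⁸O per taxon and labeled replicate:
  EAF = (M_lab − M_light)/(M_heavymax − M_light) · (1 − 0.002000429), with
  GC content inferred from the unlabeled WAD. Taxa with APE ¹⁸O = 100·EAF
  above 5% are called growing.
* **Growth metrics**: relative growth rates
  RGR = AFE_taxon/(AFE_soil-water · days), per-sample growing richness and
  growing-community size (% of 16S copies), proportional ¹⁸O assimilation
  (each grower's share of community growth), top assimilators, growing-taxon
  overlap between treatments, per-phylum changes, and putative bacterial
  predators flagged by taxonomy.
* **Statistics**: centered log-ratio transform, PCA, seeded two-way
  permutation PERMANOVA, two-way ANOVA, Welch *t*-tests, Benjamini–Hochberg
  FDR, and a Shapiro–Wilk/Levene gate that routes to pairwise rank tests
  when ANOVA assumptions fail.
* **Synthetic data**: a gradient simulator with known per-taxon GC,
  abundance and true EAF, used to validate every stage against ground truth.

## Worked example

Simulate a two-treatment experiment (ambient vs drought; three labeled and
three natural-abundance tubes each; 24 fractions per tube) and run the whole
pipeline:

```r
library(vaporqsip)

des <- qsip_design(scenarios = c("ambient", "drought"), n_taxa = 100,
                   replicates = 3, seed = 42)
sim <- simulate_experiment(des)
res <- run_qsip_pipeline(sim$data, qsip_config(seed = 42))
res$sample_summary
#> # A tibble: 6 × 8
#>   tube_id        treatment replicate growing_richness growing_pct mean_rgr_growing mean_rgr_all total_copies
#>   <chr>          <chr>         <int>            <int>       <dbl>            <dbl>        <dbl>        <dbl>
#> 1 ambient_r1_18O ambient           1               29       37.9            0.0670       0.0211   309374228.
#> 2 ambient_r2_18O ambient           2               28       34.6            0.0688       0.0213   287767421.
#> 3 ambient_r3_18O ambient           3               30       33.5            0.0646       0.0210   315868134.
#> 4 drought_r1_18O drought           1               12        3.70           0.0814       0.0115   330154644.
#> 5 drought_r2_18O drought           2               11        3.68           0.0842       0.0116   324403542.
#> 6 drought_r3_18O drought           3               11        3.92           0.0853       0.0108   335335513.
```

Read across a row: in `ambient_r1_18O`, 29 taxa had APE ¹⁸O > 5% and these
growers held 37.9% of the sample's 16S copies; their mean relative growth
rate was 0.067 per day (0.021 per day when non-growing taxa are averaged
in). Under drought the growing community collapses to ~4% of the copies and
a third of the richness while the survivors keep growing at comparable
rates — the simulator's scenario presets encode exactly this contrast.

Per-taxon evidence sits in `res$enrichment`:

```r
dplyr::select(res$enrichment, taxon_id, tube_id, w_light, w_lab, ape, growing)
#> # A tibble: 4 × 6
#>   taxon_id tube_id        w_light w_lab    ape growing
#> 1 ASV_0001 ambient_r1_18O    1.69  1.70 18.1   TRUE
#> 2 ASV_0002 ambient_r1_18O    1.70  1.71 14.7   TRUE
#> 3 ASV_0003 ambient_r1_18O    1.69  1.69 -0.131 FALSE
#> 4 ASV_0004 ambient_r1_18O    1.67  1.67  0.483 FALSE
```

`w_light` is the taxon's unlabeled reference density (g/mL), `w_lab` its
density in this labeled tube; the 0.01 g/mL shift of ASV_0001 converts to
18.1 atom % excess ¹⁸O. Negative APE values (ASV_0003) are retained as
noise around zero.

The equilibration side:

```r
water_volume_for_target(100, 0.2, 70, 95)   # µl of 95 atom% water per 100 µl soil water
#> [1] 279.2

tt <- c(3, 6, 24, 48)
fit <- fit_enrichment_curve(
  data.frame(time_h = tt, atom_pct_18O = 70 * (1 - exp(-0.08 * tt))),
  duration_h = 120
)
tidy(fit)
#> # A tibble: 1 × 6
#>   group plateau  rate mean_enrichment      rss     n
#> 1 all        70  0.08            62.7 3.16e-28     4
```

A gradient reaching a 70 atom% plateau at 0.08 h⁻¹ averages 62.7 atom% over
a 5-day incubation — the value RGRs are referenced to.

Ordinations and summaries plot directly: `autoplot(res$pca_growing)`,
`plot_sample_summary(res$sample_summary, "growing_pct")`,
`plot_enrichment(res$enrichment)`.

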