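# premotormap

Quantitative comparison of labelled-neuron positions across monosynaptic
rabies tracing experiments in the mouse lumbar spinal cord.

Retrograde transsynaptic tracing from a hindlimb muscle labels the spinal
**premotor interneurons** of that muscle's motor pool. Whether the premotor
networks of antagonist muscles (e.g. the ankle flexor TA and extensor LG)
occupy segregated territories is a positional question that must be answered
across animals, laboratories and histological batches, each with its own
section shapes and deformations. `premotormap` implements the full analysis
chain for that question:

1. **Landmark normalization** — per-cell coordinates (central-canal origin)
   are rescaled quadrant-by-quadrant to white-matter landmarks of their own
   section and mapped into an idealized transverse frame of
   1700 μm × 900 μm; experiments are aligned rostro-caudally at the widest
   (L4/L5-border) section and binned in 800 μm segments.
2. **Density maps** — positions are convolved with a data-driven Gaussian
   kernel (SD · n^(−1/5) per axis) on a regular grid; maps and their
   marginals sum to 1.
3. **Median-centred correlation** between maps ρₙ, ρₘ:

   r(n,m) = Σᵢⱼ (ρₙ − med ρₙ)(ρₘ − med ρₘ) /
   √( Σᵢⱼ (ρₙ − med ρₙ)² · Σᵢⱼ (ρₘ − med ρₘ)² )

4. **Hedges' g effect sizes** with a two-level hierarchical bootstrap
   (animals resampled with replacement, then cells within each drawn animal;
   5000 replicas; median and IQR reported). No p-values, by design: with
   thousands of cells per experiment they are small for differences below
   the localisation accuracy, and pooled tests ignore the nested structure.
5. **Count analyses** — section-sampling scaling of counts, a log-log
   power-law fit of premotor-interneuron vs starter motor-neuron numbers,
   titre-grouped count ratios and starter-cell bookkeeping for double
   injections.
6. **Synthetic cohorts** — a generator for virtual experiments (quadrant
   Gaussian mixtures, per-animal jitter, raw-frame section geometry,
   section thinning) so the entire pipeline is testable without raw data.

## Worked example

Simulate a null cohort (no positional offset between muscles, 6 animals per
muscle) and run the full pipeline:

```r
library(premotormap)

spec <- cohort_spec(seed = 42)            # defaults: LG vs TA, delta_um = 0
cfg  <- run_config(synthetic = spec, output_dir = "run42", seed = 42)
rep  <- run_pipeline(cfg)

min(rep$correlation)      # 0.85  — lowest pairwise map correlation
rep$comparison$g_median   # -0.0043
rep$comparison$g_iqr      # -0.099  0.081
rep$comparison$band       # "none"
head(rep$medians, 3)
#>   experiment_id quadrant    axis  median_um n_cells
#> 1 LG_a01        ipsi_dorsal x          341.     360
#> 2 LG_a02        ipsi_dorsal x          322.     179
#> 3 LG_a03        ipsi_dorsal x          343.     260
```

Pairwise density correlations stay high, the bootstrap Hedges' g of the
dorsal-ipsilateral medio-lateral coordinate is in the "no effect" band, and
per-experiment medians scatter around the generator's 320 μm cluster centre
— the signature of spatially intermingled premotor populations. Rerunning
with `cohort_spec(delta_um = 100, seed = 42)` shifts one muscle's clusters
laterally by 100 μm and the same contrast lands in the "large" band.

Count analyses run off the shipped experiment table
(`inst/extdata/table1_metadata.csv`):

```r
fit_power_law(table1_counts())
#> <pm_powerlaw> y = 294.30 * x^0.533, R^2 = 0.488 (n = 51, 23 excluded)

starter_mn_summary(table1_counts())
#> $per_muscle: LG 200, TA 150;  $double: 13  (5 double-injection experiments)
```

A thin CLI with `simulate` / `analyze` / `compare` verbs is installed at
`system.file("cli", "premotormap", package = "premotormap")`.

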