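---
title: "Methods: spatial comparison of premotor interneuron maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial comparison of premotor interneuron maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premotormap)
```

## The problem

Monosynaptic rabies tracing from a hindlimb muscle labels the spinal
interneurons that synapse directly onto that muscle's motor pool. The
scientific question the pipeline addresses is positional: do the premotor
interneurons of different muscles (for instance the ankle flexor TA and
extensor LG) occupy different territories of the lumbar spinal cord, or are
they spatially intermingled? Answering it requires comparing point clouds of
labelled cells across animals, laboratories and histological batches, each
with its own section shapes and deformations. The package therefore
implements four stages — coordinate normalization, density estimation,
correlation, and effect sizes — plus the count analyses that characterise
the tracing itself, and a synthetic-cohort generator that lets every stage
be validated end to end.

## Coordinate frame and quadrant-wise normalization

Each cell is recorded in its transverse section with the central canal as
origin: x medio-lateral (positive toward the injected side), y
dorso-ventral (positive dorsal), z rostro-caudal (increasing caudally).
Because sections differ in shape and are individually deformed,
normalization is performed **independently for each section and each
quadrant**, using white-matter landmarks:

* x is scaled so the lateral white-matter edge at central-canal level on the
  cell's side maps to ±850 μm;
* y is scaled per quadrant so the outermost dorsal white-matter point of the
  cell's side maps to the dorsal frame extent and the outermost ventral
  point to the ventral extent.

The result lives in an idealized transverse frame of 1700 μm (medio-
lateral) × 900 μm (dorso-ventral). Only the 900 μm total height is fixed by
convention; the package splits it symmetrically (+450/−450 μm) by default
and exposes both extents in `idealized_frame()` so figures remain
comparable across configurations. The map is piecewise linear, keeps the
origin fixed, maps each landmark exactly to its frame boundary, and
preserves quadrant membership; cells on a boundary (x = 0 or y = 0) are
assigned ipsilateral/dorsal, a deterministic zero-measure rule.

Sections missing landmarks (damaged tissue is common in real exports) fall
back to the experiment-wise mean geometry with a warning rather than being
dropped, since discarding whole sections would bias rostro-caudal
occupancies.

Experiments are aligned along z at the widest section, which marks the
border between the L4 and L5 segments; ties go to the most rostral maximal
section so the alignment is deterministic. Rostro-caudal structure is then
summarised in half-open 800 μm bins `[k·w, (k+1)·w)`, a partition of the
cells by construction.

## Density maps and the median-centred correlation

Positions are projected along z onto the transverse plane and convolved
with a separable Gaussian kernel on a regular grid (default 25 μm spacing,
giving 68 × 36 cells over the frame — fine enough that the kernel, never
narrower than a cell diameter in practice, spans several grid cells). The
kernel SD per axis follows the data: `sd(coords) · n^(−1/5)` (a Scott-type
rule), with a configurable floor for degenerate samples. Kernels are
truncated at 4σ and renormalized per cell, so every density matrix sums to
exactly 1 and marginals (row/column sums) inherit unit mass. Truncation
bounds cost; renormalization keeps the mass invariant exact rather than
approximate.

Two experiments' maps ρₙ, ρₘ are compared with a median-centred
correlation:

$$r_{nm} = \frac{\sum_{ij}(\rho_n - \mathrm{med}\,\rho_n)(\rho_m - \mathrm{med}\,\rho_m)}
{\sqrt{\sum_{ij}(\rho_n - \mathrm{med}\,\rho_n)^2 \sum_{ij}(\rho_m - \mathrm{med}\,\rho_m)^2}}$$

Centring on the median rather than the mean is deliberate: anatomical maps
are mostly empty background, and the median tracks that background level,
making r sensitive to where the labelled mass sits rather than to the
overall sparsity. The sum runs over all (i, j) grid entries and the median
over all entries of each matrix. The coefficient is symmetric, equals 1 for
any positive affine transform of a map, and is left undefined (an error,
recorded as a missing entry in matrices) when a map has zero median-centred
variance. Group-level comparisons pool cells by concatenation before the
density computation — pooling densities instead would weight animals
equally regardless of cell count, which is not what pooled panels show.

```{r correlation-example}
a <- matrix(runif(25), 5, 5)
density_correlation(a, 3 * a + 0.1) # positive affine transform: exactly 1
```

## Effect sizes instead of p-values

With thousands of coordinates per experiment, p-values of location tests
become arbitrarily small for biologically meaningless differences of a few
μm — smaller than the localisation accuracy of cell detection — and pooling
cells ignores the nested animal/cell structure. The pipeline therefore
reports **standardized effect sizes** and never p-values.

The effect size is Hedges' g, the bias-corrected standardized mean
difference: `g = J (m_a − m_b)/s_pooled` with the pooled SD and
`J = 1 − 3/(4(n_a+n_b) − 9)`. Absolute values are banded as no effect
(< 0.2), small (0.2–0.49), medium (0.5–0.79), large (≥ 0.8).

Group contrasts use a two-level hierarchical bootstrap honouring the nested
structure: per replica, animals are resampled with replacement, then each
drawn animal's coordinate sample is resampled with replacement at its own
size (preserving per-animal weight). 5000 replicas are drawn per group;
replica i of group A is paired with an independently drawn replica of B
(pairing at random rather than index-by-index, so the pairing itself adds
no structure), g is computed per pair, and the distribution is summarised
by its median and (25th, 75th) percentiles. Everything is reproducible from
one root seed, with per-stage child seeds derived arithmetically. With a
single animal per group the procedure degrades, by construction, to a flat
bootstrap of that animal's cells.

Two readings of pairwise comparison coexist and both are exposed: plain
(non-bootstrap) g per pair of individual experiments
(`pairwise_effect_matrix()`, summarised by the median and IQR of the signed
pairwise values), and the bootstrap for group-level contrasts
(`hierarchical_bootstrap()` via `compare_groups()`).

## Count analyses

Experiments analyse different fractions of serial sections (all, 1/2, 1/8,
…), parsed from annotations like `"1/2 (30 μm)"`. Whole-cord totals are
estimated by dividing counts by the fraction. For the relation between
secondary (premotor) and primary (starter motor neuron) infected cells, a
power law `y = a·x^b` is fitted by ordinary least squares on (log x, log y)
— the conventional reading of a power-law fit with an R², matching the
log-axis presentation of such data. **Both** counts are scaled by the
sampling fraction before fitting (both are per-animal totals undercounted
by the same sampling); this is the default and a switch, and on the shipped
experiment table it is the choice that reproduces the published fit
quality. Rows with unknown or zero motor-neuron counts are excluded and
reported. Ratio summaries (premotor IN / starter MN) are grouped by an
explicit predicate on titre, defaulting to the study's definitions: high
≥ 5×10⁹ IU/ml, low < 10⁹ IU/ml, in-between unclassified.

```{r counts}
fit <- fit_power_law(table1_counts())
fit
starter_mn_summary(table1_counts())$per_muscle
```

## The synthetic cohort generator

`cohort_spec()` and `generate_experiment()` emulate the statistical
structure the analysis assumes, not the biology that produces it:

* interneurons drawn from a four-quadrant Gaussian mixture with the two
  main clusters dorsal-ipsilateral and ventral, a minority contralateral
  (mixture weights 0.55/0.30/0.10/0.05), the dorsal-ipsilateral
  medio-lateral centre at 320 μm — the anchor value around which real
  per-experiment medians cluster;
* starter motor neurons (Poisson, mean 35 — the scale of high-titre
  experiments) in the ventral ipsilateral horn, labelled `motor_neuron` so
  the pipeline's exclusion logic is exercised;
* per-animal positional jitter (SD 15 μm on both in-plane axes), matching
  the ~25 μm spread of per-experiment medians seen across real
  experiments;
* GlyT2-on probability differing by quadrant (enriched ventral-
  ipsilaterally), so the GlyT2-split stage has signal to find;
* an optional medio-lateral offset δ between the two muscles' clusters
  (applied laterally to the second muscle); δ = 0 is the default and
  represents the intermingled configuration, δ = 100 μm the segregation
  scale the pipeline must be able to detect;
* cells are generated in idealized coordinates, then **mapped back into
  each section's raw landmark frame by inverting the normalization**, with
  per-section landmark noise and a width profile peaking at a per-animal
  L4/L5 position — so reading, normalization and alignment are tested end
  to end rather than bypassed;
* section thinning at the spec's sampling fraction (default 1/2, a common
  real setting), implemented as keeping p of every q consecutive sections.

What the generator does **not** emulate: anisotropic section deformations
beyond linear scaling, rostro-caudally varying cluster positions, spatial
correlation between neighbouring cells, double-labelled cells, or any
dose–response between titre and infection. Passing the end-to-end tests
therefore shows the pipeline detects (or correctly fails to detect)
medio-lateral offsets under realistic sampling noise; it does not certify
performance on deformation patterns the generator cannot produce.

## Numerical choices and degenerate inputs

* Bandwidth floor 25 μm (one grid cell) for constant or single-point
  samples, with a warning.
* A cell farther than the truncation radius outside the grid keeps its mass
  at the nearest grid cell, so unit mass is conserved unconditionally.
* Zero-magnitude landmarks raise a geometry error naming the section;
  empty cell sets raise an empty-input error rather than returning a zero
  map, leaving the policy to the caller.
* Median of an even number of values is the midpoint, R's default.
* Widest-section ties break to the most rostral section; quadrant
  boundaries go ipsilateral/dorsal.
* All randomness flows from one root seed through arithmetic child seeds;
  bootstrap results are bit-reproducible given the seed, and the RNG state
  of the calling session is restored afterwards.

## Problem sizes

The shipped tests run the bootstrap at its default 5000 replicas with 6
animals × 200 cells per group (and 20 seeded repeats for the null), and the
end-to-end cohorts at 6 animals × ~1000 cells per muscle — the scale at
which the same-distribution correlation exceeds 0.9 and a 100 μm offset is
a large effect, chosen to mirror the cell counts of real high-titre
experiments while keeping a full test run in well under a minute on a
laptop.

## Known limitations

* The normalization is piecewise linear per quadrant; it cannot correct
  nonlinear tissue distortions, and positions exactly on the grey/white
  border may land slightly inside or outside the frame depending on the
  landmark set.
* The median-centred correlation depends on grid spacing and bandwidth;
  comparisons are only meaningful between maps computed on the same grid
  with the same bandwidth rule (the package enforces the shared grid).
* Real per-experiment medians quoted for the original data sets are not
  reproducible from this package alone, since the raw coordinate tables
  are not redistributed here; the synthetic cohorts act as property-based
  surrogates for those comparisons.
* The power-law fit is descriptive; no mechanistic claim about viral
  spread is implied, and the fitted exponent depends on which experiment
  subsets are included (exposed as the records you pass in).
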