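---
title: "Quantifying optical redox imaging and cell competition in epidermis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optical redox imaging and cell competition in epidermis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiredox)
```

## The measurement problem

Intravital two-photon imaging of mouse skin captures the autofluorescence of
NAD(P)H (collected at 425–475 nm) and FAD (500–550 nm). Only the reduced
nicotinamide cofactors and oxidized FAD fluoresce, so the intensity ratio
NAD(P)H/FAD reports the cellular redox state: a *drop* means a more oxidized
cell. The cells of interest — epidermal basal stem cells — form a single layer
draped over an undulating dermo-epidermal interface, sandwiched between
suprabasal layers above and collagen below. A fixed z-plane therefore cuts
through different layers at different lateral positions, and naive z-slab
projections mix basal signal with suprabasal contamination.

`epiredox` implements the quantification chain used to solve this:

1. threshold the second-harmonic (SHG) collagen channel and take, per lateral
   pixel, the shallowest collagen voxel → a dermis-interface height map;
2. compute for every voxel the full 3D Euclidean distance (in µm, anisotropic
   voxels) to the interface point cloud;
3. keep only voxels inside a physical distance band — 0–3 µm toward the
   epidermis for cytosolic NAD(P)H/FAD, 0–5 µm for nuclear reporters — and
   project them laterally;
4. measure per-cell channel means over ROI labels, form per-cell ratios,
   normalize, and aggregate into genotype differentials, coverage, thickness,
   density and proliferation metrics;
5. test group differences with per-animal statistics.

A companion module evaluates the ¹³C₆-glucose tracer panel (V_PDH/V_CS and
its seven companion ratios) from isotopologue enrichment tables, and a
statistics module provides the nested per-mouse tests.

Because the source imaging data are not publicly deposited, the package ships
a synthetic-tissue generator with exact ground truth; every stage is validated
by parameter recovery against it.

## Geometry: distance banding

`distance_to_surface()` computes the *exact* 3D Euclidean distance from every
voxel to the surface sampled at pixel centres, via a lower-envelope
(Felzenszwalb–Huttenlocher) transform implemented in C++ — two passes of 1D
parabola envelopes over the sampled squared vertical offsets. This is `O(N)`
in the voxel count, exact up to floating point (the test suite checks equality
against an exhaustive brute-force oracle on small grids), and respects
anisotropic voxel sizes. The sign convention is positive on the shallow (air)
side of a surface, negative below it.

Vertical-only distance is available as a documented fast mode; on undulating
surfaces it overestimates distance near slopes, which is why the Euclidean
form is the default.

Bands are closed intervals `[d_min, d_max]`: the interface voxel itself
(distance 0) belongs to the band, matching the convention of collecting
"0 to ~3 µm" of cytosolic signal starting at the surface.

### Numerical behaviour at surfaces

Surface detection quantizes depths to the z-step (`dz`, default 0.5 µm), so a
detected surface sits up to one z-step below the true interface and recovered
depths carry an RMSE of about `dz/√3`. Thickness (dermis depth − air depth)
benefits from partial cancellation of the two quantization errors; planted
outgrowth depths are recovered within one z-step. Columns with no detectable
surface stay `NA` (never silently zero), are nearest-neighbour interpolated
with a logged count before distance transforms, and abort the stage if they
exceed 50% of the field. Speckle is suppressed with an NA-aware median filter
(default 5×5) — written in-package because standard image median filters
neither tolerate missing pixels nor run on arbitrary intensity scales.

## Redox quantification conventions

* **Ratio of means, not mean of ratios.** Per cell, the NAD(P)H and FAD means
  are formed first and divided once. Pixel-level division is unstable at low
  FAD counts; the per-cell mean ratio of a dim cell would be dominated by its
  noisiest pixels.
* **FAD floor.** Pixels (or cells) with FAD below a floor are masked with a
  reason code rather than clipped. The default floor is 1% of the channel's
  99th-percentile intensity: no absolute intensity scale is trusted, and
  division by background must be excluded explicitly.
* **Genotype calls.** A cell is recombined (mutant) if its mean mCherry
  exceeds an Otsu threshold over cell means, with an absolute floor so a field
  with no recombined cells is not split on noise.
* **Normalization.** Per-cell ratios are divided by the mean ratio of baseline
  cells of the same mouse: day-0 cells for revisit timecourses, or WT
  neighbour cells of the same mouse and timepoint. Baselines therefore have
  unit mean by construction and the operation is idempotent.
* **Differential direction.** The WT/mutant differential is WT mean over
  mutant mean, so values above 1 mean the mutants are more oxidized than
  their neighbours.

## The synthetic tissue model

`generate_stack()` emulates the statistical structure the analysis assumes —
not the optics. The interface is a separable sinusoid (default mean depth
20 µm, amplitude 3 µm, wavelength 60 µm over a 300 × 300 µm field) with
optional Gaussian-random-field roughening and cosine-profile outgrowths.
Basal cells are placed by hard-sphere rejection sampling (minimum spacing
1.8 nuclear radii) and modelled as *columnar prisms* over the nearest-centre
(Voronoi) tessellation — telogen basal keratinocytes are confluent and
columnar — with a spherical nucleus one radius above the interface. Inside
the nucleus both channels are dimmed by the same factor, which preserves the
per-cell ratio while giving auto-segmentation its contrast. Two suprabasal
layers sit above a 1 µm dark seam; the seam guarantees that a Euclidean band
anchored on a sloped interface cannot reach suprabasal voxels.

Intensity noise is Poisson shot noise on scaled intensities (default 2
photons per intensity unit at FAD ≈ 100 a.u.) followed by additive Gaussian
read noise (SD 2), then clipping at zero — the standard two-photon detection
model. With noise disabled the construction makes `NADPH = ratio × FAD` hold
voxel-wise inside every cell column, so the *entire* pipeline (mask → surface
→ distance → band → projection → per-cell means) returns planted per-cell
ratios to machine precision; this is the backbone of the test suite. At the
default SNR, genotype group means land within a fraction of a percent of
truth with ≥100 cells per group.

Defaults chosen where no study condition fixes them, stated once here:

* lateral grid 1 µm/px (a down-sampled but fully resolved sampling of the
  300 µm field; nuclei of radius 2.5 µm span ~20 px);
* 800 basal cells per 300 × 300 µm field (≈10 µm cell spacing);
* G1 fraction 0.8 (the reported Fucci cell counts, 490 G1 vs 120 S/G2);
* G1 NAD(P)H boost 1.1 — the in vivo observation fixes the direction only;
* mCherry recombination fraction 0.8 of the basal layer.

Timecourse presets encode the competition trajectories as per-day true
ratios, linearly interpolated between anchor days 0/5/10:

| preset | day 5 | day 10 |
|---|---|---|
| `BCAT_GOF` ("loser" mutant) | both genotypes drop, mutant lower | WT recovers to 0.98, mutant stays 0.35 → differential 2.8 |
| `HRAS_G12V` ("winner" mutant) | both drop, mutant lower | both at 0.70 → differential 1.0 |
| `METFORMIN_FLAT` | no drop | no drop |
| `WT_CONTROL` | constant 1.0 | constant 1.0 |
| `CYANIDE` | — | post/pre shift drawn once per mouse from U(1.28, 1.37) |

A timecourse is one revisited region: geometry, cells, genotypes and phases
are generated from a region-level seed shared across days, while detection
noise is independent per day. Only the per-day ratios change — which is what
makes paired (pre/post) designs recover their planted shifts exactly in the
noise-free limit.

What the generator does *not* emulate — and what passing tests therefore do
not establish for real data: optical point-spread blur, depth-dependent
scattering and attenuation, channel bleed-through, motion artefacts,
hair-cycle geometry changes, or segmentation difficulty of genuinely
irregular nuclei. Parameter recovery here validates the *quantification
logic*, not robustness to acquisition physics.

## Flux ratios

`compute_ratios()` evaluates, per sample, the eight tracer ratios: the two
V_PDH/V_CS readouts (m+2 acetyl-CoA / m+3 alanine, and 4,5-¹³C₂-glutamate /
m+3 alanine — the fraction of TCA-cycle entry fuelled by glucose),
¹³CO₂/¹³C₆-glucose, the glycolytic ratios (pyruvate/glucose, lactate/glucose,
lactate/pyruvate), glutamate/acetyl-CoA (unity minus this is the glutamine
dilution) and malate/glutamate (anaplerotic dilution; m+2 malate is treated
as the integrated average of its 1,2- and 3,4-labelled forms, which MS cannot
separate). Inputs are assumed natural-abundance-corrected enrichment
fractions; correction is upstream and out of scope. Whether CO₂ enrichment is
per-carbon or per-molecule normalized is not specified by the convention this
follows; the ratio is computed as given (CO₂ enrichment over glucose m+6).

Ratios are computed per sample and then summarized — never as ratios of group
means — and a zero or missing denominator flags the ratio undefined rather
than zero. Noisy ratios may exceed 1 and are reported as such (with an
over-unity warning in the dilution check). The generator's lognormal noise is
median-preserving, so planted ratios round-trip exactly at zero CV and with
~1% expectation bias at CV 0.1 (below the sampling noise at the study's group
sizes).

## Statistics

Hundreds of cells from three mice are not hundreds of independent
observations. `nested_t_test()` collapses values to per-mouse means and runs
a two-sided equal-variance t-test on the means, reporting both unit-level and
value-level n. The test suite includes a calibration experiment: under a
hierarchical null with real between-mouse variance, the nested test holds its
5% level (±2 points at 2,000 replicates) while naive per-cell pooling
rejects in the majority of replicates — the pseudoreplication this design
guards against. The commercial nested-t implementations fit a mixed model,
which differs from mean-collapse when unit sizes are very unbalanced; the
per-unit n is reported so users can judge.

Comparisons of several groups against a control use one-way ANOVA on unit
means plus pairwise equal-variance t-tests with Holm adjustment — slightly
conservative relative to Dunnett but free of multivariate-t quantiles, and
exactly equal to the nested t-test when only two groups are present.
Degenerate (zero-variance) inputs are defined by continuity: identical groups
give t = 0, p = 1; a pure offset gives p = 0. Normality is assumed
throughout, mirroring standard practice for these designs.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` regenerate everything they measure.
Sizes used (the package's choices): full-field 300 × 300 × ~54 stacks for
surface and redox recovery; 200 × 200 µm stacks across 10 seeds per preset
for the differential trajectories; three mice × 110 cells for the cyanide
pairs (full pipeline, noise-free) plus 100 cell-level replicates at the
default SNR for detection power; four planted coverage fractions
(0.2/0.25/0.6/0.8) with two follicle exclusion discs; 200 replicates of the
flux power design (n = 8 control vs 6 mutant, CV 0.1); 2,000 replicates of
the type-I calibration. All randomness derives from the supplied seed; the
CLI writes a JSON run log with the config hash and seed of every stage.

## Known limitations

* Auto-segmentation is a stand-in for the reference workflow's manual ROIs;
  it assumes nuclei darker than cytoplasm and degrades above ~1.5× the
  default cell density. External label masks are the first-class path.
* Coverage treats the basal-band projection as the analysis plane; the
  3D-straightening used for late-timepoint mosaics is subsumed by distance
  banding (an equivalence assumption, not established here).
* Collagen thresholds and smoothing windows replace manual/commercial-tool
  steps whose exact parameters are unpublished; both are config parameters.
* No FLIM, no spectral unmixing of NADH vs NADPH, no bleed-through
  correction, no isotopomer network modelling (only the printed ratio
  definitions).
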