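# epiredox

Quantification pipeline for intravital two-photon **optical redox imaging**
of the epidermal basal stem-cell layer, and for the tissue-level readouts of
**cell competition** between oncogenic mutant and wild-type keratinocytes.

It is written for imaging labs that measure label-free NAD(P)H and FAD
autofluorescence in live skin and need to turn raw multi-channel z-stacks
into per-cell redox statistics, and for metabolism labs evaluating
¹³C₆-glucose tracer panels from the same tissues.

## What it computes

**The optical redox ratio.** Only reduced NAD(P)H and oxidized FAD
autofluoresce, so the per-pixel (or per-cell) intensity ratio

    R = I_NAD(P)H / I_FAD

reports cellular redox: a drop in R means a more oxidized cell. Basal cells
lie on an undulating dermo-epidermal interface, so the package first locates
that interface from the second-harmonic (SHG) collagen signal, computes an
exact anisotropic 3D Euclidean distance transform to it (C++ lower-envelope
algorithm), and isolates the basal layer as a physical distance band
(0–3 µm toward the epidermis for cytosolic signal, 0–5 µm for nuclear
reporters) before projecting and quantifying. Per-cell ratios are ratios of
channel means, normalized to per-mouse baselines (day-0 cells or WT
neighbours), and aggregated into the WT/mutant **redox differential**
`R_WT / R_mutant` per mouse and timepoint.

**Competition metrics.** Mutant (mCherry⁺) area coverage with hair-follicle
exclusions, epidermal thickness maps (air surface − dermis surface), basal
nuclear density, and deduplicated pH3⁺ proliferation counts.

**Tracer flux ratios.** From isotopologue enrichment tables:
`V_PDH/V_CS = [m+2 acetyl-CoA]/[m+3 alanine]` (the fraction of TCA-cycle
entry fuelled by glucose; also read as 4,5-¹³C₂-glutamate/m+3 alanine),
¹³CO₂/¹³C₆-glucose, pyruvate/glucose, lactate/glucose, lactate/pyruvate,
glutamate/acetyl-CoA (glutamine dilution) and malate/glutamate.

**Hierarchical statistics.** Nested t-tests on per-mouse averages (guarding
against per-cell pseudoreplication), paired t-tests for revisits, one-way
ANOVA with Holm-adjusted comparisons versus control, and violin-plot-ready
exports.

**Synthetic ground truth.** A generator builds multi-channel stacks
(NADPH/FAD/mCherry/SHG) of an undulating basal layer with known per-cell
ratios, mosaic recombination, outgrowths, follicles and two-photon detection
noise, plus timecourse presets for the competition trajectories (βcatGOF
"loser", HrasG12V "winner", cyanide, metformin, control) and isotopologue
tables with planted flux truths. Every pipeline stage is validated by
parameter recovery against it.

## Worked example

Generate a day-10 βcatGOF mosaic region (350 cells, 200 × 200 µm, default
noise), run the full pipeline with the generator's ROI labels, and measure
the redox differential:

```r
library(epiredox)

tc  <- generate_timecourse("BCAT_GOF", days = 10, seed = 42,
                           tissue = tissue_model(field_um = c(200, 200),
                                                 n_basal_cells = 350),
                           mutant_fraction = 0.5, output = "stack")
gen <- tc$timepoints$day10
res <- quantify_stack(gen$stack, labels = gen$truth$labels)
cells <- normalize_to_baseline(res$cells, "wt_cells_same_mouse")
head(cells[, c("cell_id", "genotype", "mean_nadph", "mean_fad",
               "ratio", "normalized_ratio")], 4)
#>   cell_id genotype mean_nadph mean_fad ratio normalized_ratio
#> 1       1 MUTANT         25.8     65.4 0.395            0.376
#> 2       2 MUTANT         25.7     66.7 0.385            0.366
#> 3       3 MUTANT         25.5     67.1 0.381            0.362
#> 4       4 WT             65.2     67.0 0.974            0.926

redox_differential(cells, min_cells = 50)$per_mouse
#>   mouse_id timepoint_days wt_mean mutant_mean n_wt n_mutant differential
#> 1 M1                   10       1       0.362  175      175         2.76
```

The planted day-10 differential of this preset is 2.8 (WT cells recover to
near-baseline ratios while mutants stay low); the pipeline recovers 2.76
from a noisy stack. Mutant cells read ≈0.38 — strongly oxidized relative to
their WT neighbours (≈0.97).

The flux panel on a synthetic infusion cohort (control n = 8 at
V_PDH/V_CS = 0.6, mutant n = 6 at 1.0, 10% CV):

```r
tab <- generate_isotopologues(
  list(CONTROL = c(v_pdh_vcs_acetylcoa = 0.6),
       BCAT_GOF = c(v_pdh_vcs_acetylcoa = 1.0)),
  n_per_group = c(CONTROL = 8, BCAT_GOF = 6), noise_cv = 0.1, seed = 42)
gs <- flux_group_summary(compute_ratios(tab), control = "CONTROL",
                         ratios = "v_pdh_vcs_acetylcoa")
gs$summary
#>   ratio               group     mean     sd     n
#> 1 v_pdh_vcs_acetylcoa BCAT_GOF 1.05  0.162      6
#> 2 v_pdh_vcs_acetylcoa CONTROL  0.620 0.0770     8
gs$tests$v_pdh_vcs_acetylcoa[, c("test", "statistic", "p_value")]
#>   test         statistic   p_value
#> 1 anova            44.3  0.0000235
#> 2 comparison_t     -6.65 0.0000235
```

A mutant group whose TCA cycle is fuelled entirely by glucose
(V_PDH/V_CS ≈ 1) separates cleanly from the control at these group sizes.

A thin CLI wraps the same functions
(`inst/cli/epiredox <simulate|surfaces|quantify|competition|flux|report>`);
every stage writes a JSON run log with its config hash and seed.

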