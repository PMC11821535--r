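TIMECOURSE_PRESETS <- c("BCAT_GOF", "HRAS_G12V", "CYANIDE",
                        "METFORMIN_FLAT", "WT_CONTROL")

# Per-day true NAD(P)H/FAD ratios (normalized units) for each preset,
# linearly interpolated between anchor days and held constant beyond them.
#
# BCAT_GOF: both genotypes drop by day 5; by day 10 WT recovers to near
#   baseline while mutants stay low, so the WT/mutant differential is
#   0.98 / 0.35 = 2.8. HRAS_G12V: both drop at day 5 with mutant below WT,
#   then equalize (differential 1.0) by day 10. METFORMIN_FLAT: no drop in
#   either genotype. WT_CONTROL: constant.
preset_anchors <- function(preset) {
  switch(preset,
    BCAT_GOF = list(days = c(0, 5, 10),
                    wt = c(1.0, 0.60, 0.98),
                    mutant = c(1.0, 0.40, 0.35)),
    HRAS_G12V = list(days = c(0, 5, 10),
                     wt = c(1.0, 0.75, 0.70),
                     mutant = c(1.0, 0.55, 0.70)),
    METFORMIN_FLAT = list(days = c(0, 5, 10),
                          wt = c(1.0, 1.0, 1.0),
                          mutant = c(1.0, 1.0, 1.0)),
    WT_CONTROL = list(days = c(0, 5, 10),
                      wt = c(1.0, 1.0, 1.0),
                      mutant = c(1.0, 1.0, 1.0)),
    stop(sprintf("unknown preset: %s", preset), call. = FALSE))
}

#' True ratio schedule of a timecourse preset
#'
#' @param preset One of `r paste(TIMECOURSE_PRESETS, collapse = ", ")`.
#' @param days Numeric vector of requested days (ascending).
#' @param seed Seed for presets with a random component (CYANIDE draws the
#'   per-mouse paired shift uniformly in \[1.28, 1.37\], the physiological
#'   envelope of the acute cyanide response).
#' @return Tibble with `day`, `wt_ratio`, `mutant_ratio` (and `shift` for
#'   CYANIDE, where day 0 is pre and later days post injection).
#' @export
preset_schedule <- function(preset = TIMECOURSE_PRESETS, days, seed = 1) {
  preset <- match.arg(preset)
  if (is.unsorted(days)) stop("preset_schedule: days must be ascending", call. = FALSE)
  if (preset == "CYANIDE") {
    set.seed(seed)
    shift <- runif(1, 1.28, 1.37)
    return(tibble::tibble(day = days,
                          wt_ratio = ifelse(days <= 0, 1.0, shift),
                          mutant_ratio = ifelse(days <= 0, 1.0, shift),
                          shift = shift))
  }
  a <- preset_anchors(preset)
  tibble::tibble(
    day = days,
    wt_ratio = approx(a$days, a$wt, xout = days, rule = 2)$y,
    mutant_ratio = approx(a$days, a$mutant, xout = days, rule = 2)$y)
}

#' Simulate per-cell measured intensities without painting voxels
#'
#' Cell-level counterpart of the voxel noise model: the per-cell mean of
#' `n_eff` voxel intensities under Poisson shot noise at `poisson_scale`
#' photons per unit plus Gaussian read noise. Used for Monte-Carlo studies
#' where repainting full stacks would add nothing but runtime; the full image
#' pipeline is exercised on the same presets separately.
#'
#' @param true_ratio Per-cell true NAD(P)H/FAD ratios.
#' @param redox A [redox_model()] (noise and intensity parameters).
#' @param n_eff Effective number of voxels averaged per cell.
#' @return Tibble with `mean_nadph`, `mean_fad`, `ratio`.
#' @export
simulate_cell_measurements <- function(true_ratio, redox = redox_model(),
                                       n_eff = 120) {
  n <- length(true_ratio)
  F0 <- redox$fad_intensity
  mean_counts <- function(mu) {
    v <- if (redox$poisson_scale > 0) {
      rpois(n, redox$poisson_scale * mu * n_eff) / (redox$poisson_scale * n_eff)
    } else mu
    if (redox$gaussian_sd > 0) {
      v <- v + rnorm(n, 0, redox$gaussian_sd / sqrt(n_eff))
    }
    pmax(v, .Machine$double.eps)
  }
  nad <- mean_counts(F0 * true_ratio)
  fad <- mean_counts(rep(F0, n))
  tibble::tibble(mean_nadph = nad, mean_fad = fad, ratio = nad / fad)
}

#' Simulate a measured cell table directly
#'
#' Cell-level shortcut around [generate_stack()] + quantification: draws
#' genotypes (exact seeded count), phases and true ratios as the stack
#' generator would, then applies the per-cell measurement noise model of
#' [simulate_cell_measurements()]. The `true_ratio` column carries the ground
#' truth.
#'
#' @param n_cells Number of cells.
#' @param mutant_fraction Recombined fraction.
#' @param wt_ratio,mutant_ratio True ratios by genotype.
#' @param redox A [redox_model()].
#' @param mouse_id,region_id,timepoint_days Metadata.
#' @param recombined_genotype Label for mCherry-positive cells.
#' @param n_eff Voxels averaged per cell.
#' @return A [cell_table()] with an extra `true_ratio` column.
#' @export
simulate_cell_table <- function(n_cells, mutant_fraction, wt_ratio, mutant_ratio,
                                redox, mouse_id, region_id, timepoint_days,
                                recombined_genotype = "MUTANT", n_eff = 120) {
  n_mut <- round(mutant_fraction * n_cells)
  recombined <- seq_len(n_cells) %in% sample.int(n_cells, n_mut)
  phase <- ifelse(runif(n_cells) < redox$phase_fraction_g1, "G1", "SG2")
  true_ratio <- ifelse(recombined, mutant_ratio, wt_ratio) *
    ifelse(phase == "G1", redox$g1_nadph_boost, 1)
  meas <- simulate_cell_measurements(true_ratio, redox, n_eff)
  cell_table(tibble::tibble(
    cell_id = seq_len(n_cells), mouse_id = mouse_id, region_id = region_id,
    timepoint_days = timepoint_days,
    genotype = ifelse(recombined, recombined_genotype, "WT"),
    phase = phase, mean_nadph = meas$mean_nadph, mean_fad = meas$mean_fad,
    ratio = meas$ratio, normalized_ratio = NA_real_,
    n_pixels = rep(20L, n_cells), qc_pass = TRUE,
    true_ratio = true_ratio))
}

#' Generate a synthetic revisit timecourse
#'
#' One mouse, one revisited region, imaged at the requested days under a named
#' biological preset. Output is either full voxel stacks with truth
#' ([generate_stack()] per day, shared `region_id`) or lightweight per-cell
#' measured tables (`output = "cells"`) built from the same ratio schedule and
#' noise model.
#'
#' @param preset One of `r paste(TIMECOURSE_PRESETS, collapse = ", ")`.
#' @param days Ascending days; for `CYANIDE`, day 0 is pre-injection and any
#'   later day is the 5--10 min post-injection revisit.
#' @param seed RNG seed.
#' @param tissue,redox Models passed through to the generator.
#' @param mutant_fraction Recombined fraction (default 0.8, the observed
#'   recombination extent of the stem-cell layer).
#' @param mouse_id,region_id Metadata (same region across days).
#' @param output `"stack"` or `"cells"`.
#' @return List with `schedule` (the true per-day ratios) and `timepoints`, a
#'   list per day of either `stack`+`truth` or a [cell_table()].
#' @export
generate_timecourse <- function(preset = TIMECOURSE_PRESETS,
                                days = c(0, 5, 10),
                                seed = 1,
                                tissue = tissue_model(),
                                redox = redox_model(),
                                mutant_fraction = 0.8,
                                mouse_id = "M1", region_id = "R1",
                                output = c("stack", "cells")) {
  preset <- match.arg(preset)
  output <- match.arg(output)
  sched <- preset_schedule(preset, days, seed = seed)
  recomb <- if (preset %in% c("WT_CONTROL", "CYANIDE")) "CONTROL_RECOMBINED" else "MUTANT"
  # one revisited region: geometry and cells are shared across days, while
  # per-day detection noise stays independent
  region_seed <- (seed * 1009L + 11L) %% .Machine$integer.max
  timepoints <- lapply(seq_along(days), function(i) {
    day_seed <- (seed * 1009L + i * 101L) %% .Machine$integer.max
    if (output == "stack") {
      generate_stack(tissue = tissue, redox = redox,
                     mutant_fraction = mutant_fraction,
                     seed = day_seed, timepoint_days = days[i],
                     mouse_id = mouse_id, region_id = region_id,
                     wt_ratio = sched$wt_ratio[i],
                     mutant_ratio = sched$mutant_ratio[i],
                     recombined_genotype = recomb,
                     placement_seed = region_seed)
    } else {
      set.seed(region_seed)
      tab <- simulate_cell_table(tissue$n_basal_cells, mutant_fraction,
                                 sched$wt_ratio[i], sched$mutant_ratio[i],
                                 noise_free(redox), mouse_id, region_id,
                                 days[i], recombined_genotype = recomb)
      set.seed(day_seed)
      meas <- simulate_cell_measurements(tab$true_ratio, redox)
      tab$mean_nadph <- meas$mean_nadph
      tab$mean_fad <- meas$mean_fad
      tab$ratio <- meas$ratio
      tab
    }
  })
  names(timepoints) <- paste0("day", days)
  list(preset = preset, schedule = sched, timepoints = timepoints)
}
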