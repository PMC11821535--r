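FLUX_METABOLITES <- c("GLUCOSE_M6", "ALANINE_M3", "PYRUVATE_M3", "LACTATE_M3",
                      "ACETYLCOA_M2", "GLUTAMATE_C4C5_M2", "MALATE_C2C3_M2",
                      "CO2_M1")

FLUX_RATIO_DEFS <- list(
  v_pdh_vcs_acetylcoa    = c("ACETYLCOA_M2", "ALANINE_M3"),
  v_pdh_vcs_glutamate    = c("GLUTAMATE_C4C5_M2", "ALANINE_M3"),
  co2_per_glucose        = c("CO2_M1", "GLUCOSE_M6"),
  pyruvate_per_glucose   = c("PYRUVATE_M3", "GLUCOSE_M6"),
  lactate_per_glucose    = c("LACTATE_M3", "GLUCOSE_M6"),
  lactate_per_pyruvate   = c("LACTATE_M3", "PYRUVATE_M3"),
  glutamate_per_acetylcoa = c("GLUTAMATE_C4C5_M2", "ACETYLCOA_M2"),
  malate_per_glutamate   = c("MALATE_C2C3_M2", "GLUTAMATE_C4C5_M2")
)

#' Generate synthetic isotopologue enrichment tables
#'
#' Builds per-sample enrichment fractions for the 13C6-glucose tracer panel
#' (glucose m+6, alanine/pyruvate/lactate m+3, acetyl-CoA m+2,
#' 4,5-13C2-glutamate, 2,3-13C2-malate, 13CO2) whose pairwise ratios match the
#' requested group truths, with multiplicative lognormal noise of a given CV
#' (median-preserving, so planted ratios are recovered exactly at
#' `noise_cv = 0`).
#'
#' Truth ratios are taken from each group's named vector (names from
#' `names(FLUX_RATIO_DEFS)`; unknown names are rejected). Unspecified ratios
#' fall back to homoeostatic defaults (V_PDH/V_CS 0.6 via both reporters, unit
#' glutamate/acetyl-CoA and malate/glutamate, i.e. no glutamine dilution or
#' anaplerotic dilution). Base enrichments anchor the scale: glucose m+6 0.45
#' (arterial enrichment under infusion), alanine m+3 0.25 (intracellular
#' pyruvate pool).
#'
#' @param group_truth Named list: group -> named numeric vector of ratios.
#' @param n_per_group Samples (mice) per group; scalar or named per group.
#' @param noise_cv Coefficient of variation of the lognormal noise.
#' @param seed RNG seed.
#' @return An `isotopologue_table` tibble (sample_id, mouse_id, group,
#'   metabolite, enrichment) with attribute `flux_truth`.
#' @export
generate_isotopologues <- function(group_truth, n_per_group = 8,
                                   noise_cv = 0.1, seed = 1) {
  stopifnot(noise_cv >= 0, length(group_truth) >= 1)
  set.seed(seed)
  rows <- list()
  for (g in names(group_truth)) {
    truth <- group_truth[[g]]
    bad <- setdiff(names(truth), names(FLUX_RATIO_DEFS))
    if (length(bad)) {
      stop(sprintf("generate_isotopologues: unknown ratio name(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (any(truth < 0)) {
      stop("generate_isotopologues: truth ratios must be nonnegative", call. = FALSE)
    }
    get <- function(nm, default) if (nm %in% names(truth)) truth[[nm]] else default
    glucose <- 0.45
    alanine <- 0.25
    acetyl  <- get("v_pdh_vcs_acetylcoa", 0.6) * alanine
    glut    <- if ("v_pdh_vcs_glutamate" %in% names(truth)) {
      truth[["v_pdh_vcs_glutamate"]] * alanine
    } else get("glutamate_per_acetylcoa", 1.0) * acetyl
    malate  <- get("malate_per_glutamate", 1.0) * glut
    pyruv   <- get("pyruvate_per_glucose", 0.35) * glucose
    lactate <- if ("lactate_per_pyruvate" %in% names(truth)) {
      truth[["lactate_per_pyruvate"]] * pyruv
    } else get("lactate_per_glucose", 0.3) * glucose
    co2     <- get("co2_per_glucose", 0.1) * glucose
    enr <- c(GLUCOSE_M6 = glucose, ALANINE_M3 = alanine, PYRUVATE_M3 = pyruv,
             LACTATE_M3 = lactate, ACETYLCOA_M2 = acetyl,
             GLUTAMATE_C4C5_M2 = glut, MALATE_C2C3_M2 = malate, CO2_M1 = co2)
    n_g <- if (length(n_per_group) > 1) n_per_group[[g]] else n_per_group
    slog <- sqrt(log(1 + noise_cv^2))
    for (i in seq_len(n_g)) {
      noisy <- enr * exp(rnorm(length(enr), 0, slog))
      if (any(noisy > 1)) {
        warning("generate_isotopologues: enrichment capped at 1", call. = FALSE)
        noisy <- pmin(noisy, 1)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("%s_%02d", g, i),
        mouse_id = sprintf("%s_%02d", g, i),
        group = g,
        metabolite = names(enr),
        enrichment = unname(noisy))
    }
  }
  out <- isotopologue_table(dplyr::bind_rows(rows))
  attr(out, "flux_truth") <- group_truth
  out
}
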