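#' Isotopologue enrichment table
#'
#' Long-format per-sample enrichment fractions for the 13C6-glucose tracer
#' panel. Enrichments are assumed already corrected for natural abundance
#' (correction is upstream of this pipeline); values must lie in \[0, 1\] with
#' one value per (sample, metabolite).
#'
#' @param df Data frame with `sample_id`, `mouse_id`, `group`, `metabolite`,
#'   `enrichment`.
#' @return A validated `isotopologue_table` tibble.
#' @export
isotopologue_table <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("sample_id", "mouse_id", "group", "metabolite", "enrichment")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("isotopologue_table: missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(df$metabolite), FLUX_METABOLITES)
  if (length(bad)) {
    stop(sprintf("isotopologue_table: unknown metabolite(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(df$enrichment < 0 | df$enrichment > 1, na.rm = TRUE)) {
    stop("isotopologue_table: enrichment must be in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(df[, c("sample_id", "metabolite")])) {
    stop("isotopologue_table: duplicate (sample, metabolite) entries", call. = FALSE)
  }
  class(df) <- c("isotopologue_table", class(df))
  df
}

#' Read an isotopologue table from CSV
#' @param path CSV with the `isotopologue_table` columns.
#' @return An [isotopologue_table()].
#' @export
read_isotopologue_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  isotopologue_table(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Per-sample flux-ratio panel
#'
#' Computes the eight tracer flux ratios per sample:
#' \describe{
#'   \item{v_pdh_vcs_acetylcoa}{m+2 acetyl-CoA / m+3 alanine — the ratio of
#'     pyruvate-dehydrogenase to citrate-synthase flux, i.e. the fraction of
#'     TCA-cycle entry fuelled by glucose.}
#'   \item{v_pdh_vcs_glutamate}{4,5-13C2-glutamate / m+3 alanine — the same
#'     flux ratio read one step later.}
#'   \item{co2_per_glucose}{13CO2 / m+6 glucose (glucose oxidation).}
#'   \item{pyruvate_per_glucose, lactate_per_glucose, lactate_per_pyruvate}{
#'     glycolytic label transfer and pyruvate-to-lactate exchange.}
#'   \item{glutamate_per_acetylcoa}{4,5-13C2-glutamate / m+2 acetyl-CoA —
#'     unity minus this is the glutamine dilution of TCA label.}
#'   \item{malate_per_glutamate}{2,3-13C2-malate / 4,5-13C2-glutamate —
#'     anaplerotic dilution downstream (m+2 malate taken as the integrated
#'     average of its 1,2- and 3,4-labelled forms, which are not separable by
#'     MS).}
#' }
#' Ratios are nonnegative and may exceed 1 under noise (not capped). A missing
#' or exactly-zero denominator flags the ratio undefined (`NA` plus a reason),
#' never zero.
#'
#' @param table An [isotopologue_table()].
#' @return Tibble, one row per sample, with the eight ratio columns and an
#'   `undefined` list-column naming flagged ratios.
#' @export
compute_ratios <- function(table) {
  stopifnot(inherits(table, "isotopologue_table") || is.data.frame(table))
  df <- tibble::as_tibble(table)
  wide <- tidyr::pivot_wider(
    df[, c("sample_id", "mouse_id", "group", "metabolite", "enrichment")],
    names_from = "metabolite", values_from = "enrichment")
  for (m in FLUX_METABOLITES) if (!m %in% names(wide)) wide[[m]] <- NA_real_
  out <- wide[, c("sample_id", "mouse_id", "group")]
  undefined <- vector("list", nrow(wide))
  for (rn in names(FLUX_RATIO_DEFS)) {
    num <- wide[[FLUX_RATIO_DEFS[[rn]][1]]]
    den <- wide[[FLUX_RATIO_DEFS[[rn]][2]]]
    val <- ifelse(!is.na(num) & !is.na(den) & den > 0, num / den, NA_real_)
    flag <- is.na(val)
    for (i in which(flag)) {
      why <- if (is.na(den[i]) || is.na(num[i])) "missing_metabolite" else "zero_denominator"
      undefined[[i]] <- c(undefined[[i]], setNames(why, rn))
    }
    out[[rn]] <- val
  }
  out$undefined <- undefined
  out
}

#' Glutamine dilution of TCA-cycle label
#'
#' `1 - glutamate_per_acetylcoa` per sample: the fraction of labelled
#' glutamate diluted by unlabelled glutamine entering through glutaminase.
#' Values near 0 indicate negligible net glutaminase carbon flow; noisy
#' over-unity input ratios give (flagged) negative dilutions.
#'
#' @param results Output of [compute_ratios()].
#' @return Tibble with `sample_id`, `group`, `dilution_fraction`,
#'   `over_unity` flag; undefined inputs propagate as NA.
#' @export
glutamine_dilution_check <- function(results) {
  dil <- 1 - results$glutamate_per_acetylcoa
  over <- !is.na(dil) & dil < 0
  if (any(over)) {
    warning(sprintf("glutamine_dilution_check: %d sample(s) with over-unity glutamate/acetyl-CoA",
                    sum(over)), call. = FALSE)
  }
  tibble::tibble(sample_id = results$sample_id, group = results$group,
                 dilution_fraction = dil, over_unity = over)
}

#' Group summary and control comparisons of flux ratios
#'
#' Per-group mean, SD and n for each ratio, plus a one-way ANOVA with
#' comparisons versus the control group (Holm-adjusted), treating each sample
#' (mouse) as the experimental unit. Groups with n < 2 are excluded with a
#' warning.
#'
#' @param results Output of [compute_ratios()].
#' @param control Control group label.
#' @param ratios Ratio columns to summarize (default: full panel).
#' @return List with `summary` (tidy per-group table) and `tests` (per-ratio
#'   [anova_vs_control()] results; `NULL` where fewer than two groups remain).
#' @export
flux_group_summary <- function(results, control = "CONTROL",
                               ratios = names(FLUX_RATIO_DEFS)) {
  df <- tibble::as_tibble(results)
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("flux_group_summary: excluding group(s) with n < 2: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    df <- df[!df$group %in% small, ]
  }
  long <- tidyr::pivot_longer(df[, c("sample_id", "group", ratios)],
                              dplyr::all_of(ratios),
                              names_to = "ratio", values_to = "value")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$ratio, .data$group),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)), .groups = "drop")
  tests <- NULL
  if (length(unique(df$group)) >= 2 && control %in% df$group) {
    tests <- lapply(setNames(ratios, ratios), function(rn) {
      sub <- df[!is.na(df[[rn]]), ]
      if (length(unique(sub$group)) < 2 || !control %in% sub$group) return(NULL)
      anova_vs_control(tibble::tibble(unit_id = sub$sample_id,
                                      group = sub$group,
                                      value = sub[[rn]]),
                       control = control)
    })
  }
  list(summary = summary, tests = tests)
}
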