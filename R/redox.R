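#' Per-pixel NAD(P)H/FAD ratio image
#'
#' Elementwise NADPH/FAD where FAD is at or above the floor; everything else is
#' masked with a reason code (`fad_below_floor`, or `no_voxels` where the input
#' projection itself was empty). Division by near-zero FAD is excluded
#' explicitly rather than clipped.
#'
#' @param nadph_map,fad_map Aligned y-x intensity matrices (NA = no voxels).
#' @param fad_floor Nonnegative intensity floor; `NULL` selects 1\% of the FAD
#'   map's 99th percentile.
#' @return A `ratio_image`: list with `ratio` (NA-masked matrix), `reason`
#'   (character matrix: `"ok"`, `"fad_below_floor"`, `"no_voxels"`) and
#'   `fad_floor`.
#' @export
ratio_image <- function(nadph_map, fad_map, fad_floor = NULL) {
  if (!all(dim(nadph_map) == dim(fad_map))) {
    stop("ratio_image: map shapes differ", call. = FALSE)
  }
  if (is.null(fad_floor)) fad_floor <- auto_fad_floor(fad_map)
  if (fad_floor < 0) stop("ratio_image: fad_floor must be nonnegative", call. = FALSE)
  reason <- matrix("ok", nrow(fad_map), ncol(fad_map))
  reason[is.na(nadph_map) | is.na(fad_map)] <- "no_voxels"
  low <- !is.na(fad_map) & fad_map < fad_floor & reason == "ok"
  # a zero floor still cannot divide by exactly zero FAD
  low <- low | (!is.na(fad_map) & fad_map == 0 & reason == "ok")
  reason[low] <- "fad_below_floor"
  ratio <- nadph_map / fad_map
  ratio[reason != "ok"] <- NA_real_
  structure(list(ratio = ratio, reason = reason, fad_floor = fad_floor),
            class = "ratio_image")
}

#' Automatic FAD floor
#'
#' 1\% of the 99th-percentile FAD intensity: low enough to keep all real
#' cytoplasmic signal, high enough to exclude division by background.
#'
#' @param fad_map FAD intensity matrix.
#' @return Floor intensity.
#' @export
auto_fad_floor <- function(fad_map) {
  v <- fad_map[!is.na(fad_map)]
  if (!length(v)) return(0)
  0.01 * quantile(v, 0.99, names = FALSE)
}

#' Segment cells in a layer projection
#'
#' `labels_provided` passes an external ROI label mask through after
#' validation (the reference workflow draws ROIs manually). `auto` segments
#' nuclei as the dim regions of the smoothed structural projection (nuclei
#' carry less cytoplasmic autofluorescence): Otsu split, Euclidean distance
#' map, watershed to separate touching nuclei, small regions discarded. FAD
#' is preferred as the structural channel because its intensity does not
#' depend on the redox state of the cell; NAD(P)H is the fallback.
#'
#' @param projection A [layer_projection()] from [extract_band()].
#' @param mode `"labels_provided"` or `"auto"`.
#' @param labels Integer label matrix (required for `labels_provided`).
#' @param channel Channel used in auto mode; `NULL` picks FAD, then NADPH.
#' @param min_cell_pixels Regions smaller than this are dropped in auto mode.
#' @return Integer label matrix (0 = background).
#' @export
segment_cells <- function(projection, mode = c("labels_provided", "auto"),
                          labels = NULL, channel = NULL,
                          min_cell_pixels = 8L) {
  mode <- match.arg(mode)
  if (mode == "labels_provided") {
    if (is.null(labels)) stop("segment_cells: labels_provided needs labels", call. = FALSE)
    if (!all(dim(labels) == dim(projection$n_voxels))) {
      stop("segment_cells: label mask shape mismatch", call. = FALSE)
    }
    return(labels)
  }
  if (is.null(channel)) {
    channel <- intersect(c("FAD", "NADPH"), names(projection$channels))[1]
  }
  if (is.na(channel) || !channel %in% names(projection$channels)) {
    stop("segment_cells: auto mode needs a structural (FAD or NADPH) channel",
         call. = FALSE)
  }
  img <- projection$channels[[channel]]
  img[is.na(img)] <- 0
  if (max(img) <= 0) {
    warning("segment_cells: blank image, zero labels", call. = FALSE)
    return(matrix(0L, nrow(img), ncol(img)))
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img / max(img)), sigma = 0.7))
  thr <- tryCatch(otsu_threshold(sm), error = function(e) NA_real_)
  if (is.na(thr)) {
    warning("segment_cells: degenerate intensity histogram, zero labels", call. = FALSE)
    return(matrix(0L, nrow(img), ncol(img)))
  }
  nuclei <- sm < thr & projection$n_voxels > 0 & img > 0
  if (!any(nuclei)) {
    warning("segment_cells: no nuclei found", call. = FALSE)
    return(matrix(0L, nrow(img), ncol(img)))
  }
  # split touching nuclei on a 2x-refined grid: the distance-map waist between
  # ~2.5 µm nuclei is below one pixel at typical lateral sampling
  up <- EBImage::resize(EBImage::Image(nuclei * 1),
                        w = nrow(nuclei) * 2, h = ncol(nuclei) * 2,
                        filter = "none")
  lab2 <- EBImage::watershed(EBImage::distmap(up), tolerance = 0.8, ext = 1)
  lab <- matrix(as.integer(EBImage::resize(lab2, w = nrow(nuclei),
                                           h = ncol(nuclei), filter = "none")),
                nrow(img), ncol(img))
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_cell_pixels)
  if (length(small)) lab[lab %in% small] <- 0L
  keep <- sort(unique(lab[lab > 0]))
  relabel <- integer(max(lab, 1L))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  lab
}

#' Per-cell mean intensities and redox ratios
#'
#' For every label, the arithmetic mean of each channel over unmasked pixels;
#' the per-cell redox ratio is the ratio of the two channel means (not the
#' mean of pixel ratios, which is unstable at low FAD counts). Genotype is
#' called from the mCherry cell mean: positive cells are the Otsu-separated
#' upper class (with an absolute floor so an all-negative field stays
#' all-negative), or a fixed threshold.
#'
#' Cells whose FAD mean falls below the floor or with fewer than
#' `min_cell_pixels` pixels are flagged `qc_pass = FALSE` and excluded from
#' downstream statistics.
#'
#' @param projection A [layer_projection()].
#' @param labels Integer label matrix aligned with the projection.
#' @param stack Optional [image_stack()] supplying mouse/region/timepoint
#'   metadata.
#' @param fad_floor As in [ratio_image()].
#' @param mcherry_threshold `"otsu"` or a fixed intensity.
#' @param mcherry_abs_floor Minimum mCherry mean that can ever count positive.
#' @param min_cell_pixels Minimum ROI size.
#' @param positive_genotype Genotype label of mCherry-positive cells.
#' @param phase Optional per-label phase assignment (named by label id).
#' @return A [cell_table()].
#' @export
per_cell_means <- function(projection, labels, stack = NULL,
                           fad_floor = NULL,
                           mcherry_threshold = "otsu",
                           mcherry_abs_floor = 5,
                           min_cell_pixels = 8L,
                           positive_genotype = "MUTANT",
                           phase = NULL) {
  if (!all(dim(labels) == dim(projection$n_voxels))) {
    stop("per_cell_means: labels not aligned with projection", call. = FALSE)
  }
  labv <- as.vector(labels)
  sel <- labv > 0
  ids <- sort(unique(labv[sel]))
  if (!length(ids)) return(cell_table())
  ch_mean <- function(name) {
    if (!name %in% names(projection$channels)) return(NULL)
    v <- as.vector(projection$channels[[name]])
    ok <- sel & !is.na(v)
    sums <- rowsum(v[ok], labv[ok])
    cnts <- rowsum(rep(1, sum(ok)), labv[ok])
    out <- setNames(rep(NA_real_, length(ids)), ids)
    out[rownames(sums)] <- sums / cnts
    out
  }
  npx <- {
    cnt <- rowsum(rep(1L, sum(sel)), labv[sel])
    setNames(as.integer(cnt), rownames(cnt))[as.character(ids)]
  }
  mean_nadph <- ch_mean("NADPH")
  mean_fad <- ch_mean("FAD")
  mean_mch <- ch_mean("MCHERRY")
  if (is.null(mean_nadph) || is.null(mean_fad)) {
    stop("per_cell_means: projection must carry NADPH and FAD channels", call. = FALSE)
  }
  if (is.null(fad_floor)) fad_floor <- auto_fad_floor(projection$channels$FAD)

  ratio <- ifelse(!is.na(mean_fad) & mean_fad >= fad_floor & mean_fad > 0,
                  mean_nadph / mean_fad, NA_real_)
  qc <- !is.na(ratio) & npx >= min_cell_pixels
  n_masked <- sum(is.na(ratio))
  if (n_masked > 0) pkg_log("per_cell_means: %d cells fully FAD-masked", n_masked)

  genotype <- rep("WT", length(ids))
  if (!is.null(mean_mch)) {
    m <- ifelse(is.na(mean_mch), 0, mean_mch)
    thr <- if (identical(mcherry_threshold, "otsu")) {
      ot <- tryCatch(otsu_threshold(m), error = function(e) Inf)
      max(ot, mcherry_abs_floor)
    } else as.numeric(mcherry_threshold)
    genotype[m > thr] <- positive_genotype
  }
  ph <- if (is.null(phase)) rep("UNKNOWN", length(ids)) else {
    out <- phase[as.character(ids)]
    ifelse(is.na(out), "UNKNOWN", out)
  }
  meta <- list(mouse_id = "M1", region_id = "R1", timepoint_days = 0)
  if (!is.null(stack)) {
    meta <- list(mouse_id = stack$mouse_id, region_id = stack$region_id,
                 timepoint_days = stack$timepoint_days)
  }
  cell_table(tibble::tibble(
    cell_id = as.integer(ids),
    mouse_id = meta$mouse_id, region_id = meta$region_id,
    timepoint_days = meta$timepoint_days,
    genotype = genotype, phase = unname(ph),
    mean_nadph = unname(mean_nadph), mean_fad = unname(mean_fad),
    ratio = unname(ratio), normalized_ratio = NA_real_,
    n_pixels = unname(npx), qc_pass = unname(qc)))
}

#' Normalize per-cell ratios to a baseline
#'
#' Divides each cell's ratio by the mean ratio of its mouse's baseline cells:
#' either the day-0 cells of the same mouse (revisit timecourses) or the WT
#' cells of the same mouse and timepoint (mutant-vs-neighbour comparisons).
#' Baseline cells then have unit mean normalized ratio by construction.
#'
#' @param cells A [cell_table()].
#' @param baseline `"day0_same_mouse"` or `"wt_cells_same_mouse"`.
#' @return The table with `normalized_ratio` filled in.
#' @export
normalize_to_baseline <- function(cells,
                                  baseline = c("day0_same_mouse",
                                               "wt_cells_same_mouse")) {
  baseline <- match.arg(baseline)
  df <- tibble::as_tibble(cells)
  use <- df$qc_pass & !is.na(df$ratio)
  if (baseline == "day0_same_mouse") {
    base <- dplyr::summarise(
      dplyr::group_by(df[use & df$timepoint_days == 0, ], .data$mouse_id),
      base_mean = mean(.data$ratio), .groups = "drop")
    missing <- setdiff(unique(df$mouse_id), base$mouse_id)
    if (length(missing)) {
      stop(sprintf("normalize_to_baseline: no day-0 baseline cells for mouse %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    df <- dplyr::left_join(df, base, by = "mouse_id")
  } else {
    base <- dplyr::summarise(
      dplyr::group_by(df[use & df$genotype == "WT", ],
                      .data$mouse_id, .data$timepoint_days),
      base_mean = mean(.data$ratio), .groups = "drop")
    key <- unique(df[, c("mouse_id", "timepoint_days")])
    missing <- dplyr::anti_join(key, base, by = c("mouse_id", "timepoint_days"))
    if (nrow(missing)) {
      stop(sprintf("normalize_to_baseline: no WT baseline cells for mouse %s",
                   paste(unique(missing$mouse_id), collapse = ", ")), call. = FALSE)
    }
    df <- dplyr::left_join(df, base, by = c("mouse_id", "timepoint_days"))
  }
  df$normalized_ratio <- df$ratio / df$base_mean
  df$base_mean <- NULL
  cell_table(df)
}

#' WT/mutant redox differential per mouse and timepoint
#'
#' The WT mean divided by the mutant mean of (normalized) per-cell ratios for
#' every mouse-timepoint with at least `min_cells` QC-passing cells of each
#' genotype (> 1 when WT ratios exceed mutant ratios). Entries with too few
#' cells are omitted with a log message.
#'
#' @param cells A [cell_table()] with both genotypes.
#' @param min_cells Minimum cells per genotype per mouse-timepoint.
#' @param value_col `"normalized_ratio"` (if filled) or `"ratio"`.
#' @return List with `per_mouse` (tibble: mouse, timepoint, means, counts,
#'   `differential`) and `by_timepoint` group means.
#' @export
redox_differential <- function(cells, min_cells = 10,
                               value_col = NULL) {
  df <- tibble::as_tibble(cells)
  if (is.null(value_col)) {
    value_col <- if (any(!is.na(df$normalized_ratio))) "normalized_ratio" else "ratio"
  }
  df <- df[df$qc_pass & !is.na(df[[value_col]]) &
             df$genotype %in% c("WT", "MUTANT"), ]
  g <- dplyr::summarise(
    dplyr::group_by(df, .data$mouse_id, .data$timepoint_days, .data$genotype),
    m = mean(.data[[value_col]]), n = dplyr::n(), .groups = "drop")
  w <- tidyr::pivot_wider(g, names_from = "genotype", values_from = c("m", "n"))
  for (nm in c("m_WT", "m_MUTANT", "n_WT", "n_MUTANT")) {
    if (!nm %in% names(w)) w[[nm]] <- NA_real_
  }
  ok <- !is.na(w$n_WT) & !is.na(w$n_MUTANT) &
    w$n_WT >= min_cells & w$n_MUTANT >= min_cells
  if (any(!ok)) {
    pkg_log("redox_differential: omitted %d mouse-timepoints with < %d cells per genotype",
            sum(!ok), min_cells)
  }
  per_mouse <- tibble::tibble(
    mouse_id = w$mouse_id[ok], timepoint_days = w$timepoint_days[ok],
    wt_mean = w$m_WT[ok], mutant_mean = w$m_MUTANT[ok],
    n_wt = w$n_WT[ok], n_mutant = w$n_MUTANT[ok],
    differential = w$m_WT[ok] / w$m_MUTANT[ok])
  by_tp <- dplyr::summarise(
    dplyr::group_by(per_mouse, .data$timepoint_days),
    mean_differential = mean(.data$differential),
    n_mice = dplyr::n(), .groups = "drop")
  list(per_mouse = per_mouse, by_timepoint = by_tp)
}

#' Paired pre/post redox shift per mouse
#'
#' Percentage change of the mean per-cell ratio from a pre- to a post-condition
#' revisit of the same mice, `100 * (post / pre - 1)`, with a paired t-test on
#' the per-mouse means.
#'
#' @param cells_pre,cells_post [cell_table()]s covering the same mice.
#' @param value_col Ratio column to compare.
#' @return List with `per_mouse` (pre/post means, `shift_pct`), `mean_shift_pct`
#'   and `test` (paired [TestResult][paired_t_test()]; `NULL` with < 2 mice).
#' @export
paired_shift <- function(cells_pre, cells_post, value_col = "ratio") {
  pre <- tibble::as_tibble(cells_pre); post <- tibble::as_tibble(cells_post)
  pre <- pre[pre$qc_pass & !is.na(pre[[value_col]]), ]
  post <- post[post$qc_pass & !is.na(post[[value_col]]), ]
  if (!setequal(unique(pre$mouse_id), unique(post$mouse_id))) {
    stop("paired_shift: pre and post tables cover different mice", call. = FALSE)
  }
  mpre <- tapply(pre[[value_col]], pre$mouse_id, mean)
  mpost <- tapply(post[[value_col]], post$mouse_id, mean)
  mice <- names(mpre)
  per_mouse <- tibble::tibble(
    mouse_id = mice,
    pre_mean = as.numeric(mpre[mice]),
    post_mean = as.numeric(mpost[mice]),
    shift_pct = 100 * (as.numeric(mpost[mice]) / as.numeric(mpre[mice]) - 1))
  test <- if (length(mice) >= 2) {
    paired_t_test(tibble::tibble(unit_id = mice, value = per_mouse$pre_mean),
                  tibble::tibble(unit_id = mice, value = per_mouse$post_mean))
  } else NULL
  list(per_mouse = per_mouse,
       mean_shift_pct = mean(per_mouse$shift_pct),
       test = test)
}

#' Cell-cycle effect on NAD(P)H intensity
#'
#' Per-mouse mean NAD(P)H intensity by Fucci phase, the G1/SG2 intensity ratio,
#' and a nested (per-mouse collapsed) t-test of the per-cell intensities.
#'
#' @param cells A [cell_table()] with `phase` in G1/SG2 for >= 2 mice each.
#' @return List with `per_mouse_phase`, `g1_over_sg2` and `test`.
#' @export
phase_effect <- function(cells) {
  df <- tibble::as_tibble(cells)
  df <- df[df$qc_pass & df$phase %in% c("G1", "SG2"), ]
  if (length(unique(df$phase)) < 2) {
    stop("phase_effect: both G1 and SG2 cells are required", call. = FALSE)
  }
  pm <- dplyr::summarise(
    dplyr::group_by(df, .data$mouse_id, .data$phase),
    mean_nadph = mean(.data$mean_nadph), n = dplyr::n(), .groups = "drop")
  n_mice <- tapply(pm$mouse_id, pm$phase, function(x) length(unique(x)))
  if (any(n_mice < 2)) {
    stop("phase_effect: each phase must be present in >= 2 mice", call. = FALSE)
  }
  g1 <- pm$mean_nadph[pm$phase == "G1"]
  sg2 <- pm$mean_nadph[pm$phase == "SG2"]
  test <- tryCatch(nested_t_test(
    tibble::tibble(unit_id = df$mouse_id[df$phase == "G1"],
                   value = df$mean_nadph[df$phase == "G1"]),
    tibble::tibble(unit_id = df$mouse_id[df$phase == "SG2"],
                   value = df$mean_nadph[df$phase == "SG2"])),
    error = function(e) NULL)  # degenerate (constant) unit means
  list(per_mouse_phase = pm,
       g1_over_sg2 = mean(g1) / mean(sg2),
       test = test)
}
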