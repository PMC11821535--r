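#' Mutant area coverage of the basal layer
#'
#' Fraction of the non-excluded field area occupied by mCherry-positive
#' (recombined) cells, after removing hair-follicle (or other) exclusion
#' regions: `|genotype & !exclusion| / |!exclusion|`, reported together with
#' the analyzed and excluded physical areas.
#'
#' @param genotype_mask Logical y-x matrix, TRUE on mutant-occupied pixels.
#' @param exclusion_mask Optional logical matrix of excluded pixels.
#' @param pixel_size_um `(dy, dx)` pixel size in µm.
#' @param region_id,timepoint_days Metadata carried into the result.
#' @return A `coverage_result` tibble row: `mutant_area_fraction`,
#'   `analyzed_area_um2`, `excluded_area_um2`.
#' @export
mutant_coverage <- function(genotype_mask, exclusion_mask = NULL,
                            pixel_size_um = c(1, 1),
                            region_id = "R1", timepoint_days = NA_real_) {
  stopifnot(is.logical(genotype_mask), is.matrix(genotype_mask))
  if (is.null(exclusion_mask)) {
    exclusion_mask <- matrix(FALSE, nrow(genotype_mask), ncol(genotype_mask))
  }
  if (!all(dim(exclusion_mask) == dim(genotype_mask))) {
    stop("mutant_coverage: mask shapes differ", call. = FALSE)
  }
  n_keep <- sum(!exclusion_mask)
  if (n_keep == 0) stop("mutant_coverage: exclusion mask covers everything", call. = FALSE)
  px_area <- prod(pixel_size_um)
  n_mut <- sum(genotype_mask & !exclusion_mask)
  tibble::tibble(
    region_id = region_id, timepoint_days = timepoint_days,
    mutant_area_fraction = n_mut / n_keep,
    analyzed_area_um2 = n_keep * px_area,
    excluded_area_um2 = sum(exclusion_mask) * px_area)
}

#' Genotype occupancy mask from a label map
#'
#' Marks the pixels of a cell territory (or ROI) label map belonging to a set
#' of positive cells — the mask form in which coverage is quantified from
#' basal-layer projections.
#'
#' @param labels Integer label matrix.
#' @param positive_ids Label ids of mCherry-positive cells.
#' @return Logical matrix.
#' @export
genotype_mask_from_labels <- function(labels, positive_ids) {
  matrix(labels %in% positive_ids, nrow(labels), ncol(labels))
}

#' Epidermal thickness map
#'
#' Pixelwise distance from the air/cornified surface down to the
#' dermo-epidermal interface, `dermis - air` in µm. Pixels where the surfaces
#' cross (negative thickness) are set missing with a logged count; fewer than
#' 50\% defined pixels aborts.
#'
#' @param air,dermis [height_map()]s on the same grid.
#' @return A `thickness_map`: list with `thickness_um` (matrix, NA = missing)
#'   and `mean_thickness_um`.
#' @export
thickness_map <- function(air, dermis) {
  stopifnot(inherits(air, "height_map"), inherits(dermis, "height_map"))
  if (!all(dim(air$depth_um) == dim(dermis$depth_um))) {
    stop("thickness_map: maps not aligned", call. = FALSE)
  }
  th <- dermis$depth_um - air$depth_um
  neg <- !is.na(th) & th < 0
  if (any(neg)) {
    warning(sprintf("thickness_map: %d pixels with crossing surfaces set missing",
                    sum(neg)), call. = FALSE)
    th[neg] <- NA_real_
  }
  defined <- mean(!is.na(th))
  if (defined < 0.5) {
    stop("thickness_map: fewer than 50% of pixels have defined thickness", call. = FALSE)
  }
  structure(list(thickness_um = th,
                 mean_thickness_um = mean(th, na.rm = TRUE),
                 lateral_size_um = air$lateral_size_um),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map %d x %d px, mean %.2f um, %d missing>\n",
              nrow(x$thickness_um), ncol(x$thickness_um),
              x$mean_thickness_um, sum(is.na(x$thickness_um))))
  invisible(x)
}

#' Count nuclei detections with 3D deduplication
#'
#' Counts positive nuclei (e.g. pH3) detected while scanning through a
#' z-stack: detections within `merge_radius_um` of each other in 3D are merged
#' (single-linkage) so the same nucleus seen on adjacent slices counts once.
#' The density is reported per mm².
#'
#' @param detections Data frame with `z_um`, `y_um`, `x_um` (one row per raw
#'   detection).
#' @param field_area_um2 Analyzed field area (µm²), positive.
#' @param merge_radius_um 3D merge radius.
#' @param kind `"PH3"` or `"BASAL_NUCLEI"`.
#' @return A `count_density` tibble row: `kind`, `count`, `area_um2`,
#'   `density_per_mm2`.
#' @export
count_positive_nuclei <- function(detections, field_area_um2,
                                  merge_radius_um = 3, kind = "PH3") {
  if (field_area_um2 <= 0) stop("count_positive_nuclei: zero field area", call. = FALSE)
  n_raw <- nrow(detections)
  count <- if (n_raw == 0) {
    0L
  } else if (n_raw == 1) {
    1L
  } else {
    d <- dist(cbind(detections$z_um, detections$y_um, detections$x_um))
    cl <- cutree(hclust(d, method = "single"), h = merge_radius_um)
    length(unique(cl))
  }
  tibble::tibble(kind = kind, count = as.integer(count),
                 area_um2 = field_area_um2,
                 density_per_mm2 = count / (field_area_um2 / 1e6))
}

#' Basal nuclear density
#'
#' Nuclei per mm² of basal layer, from either a QC-passing [cell_table()] or a
#' label matrix.
#'
#' @param cells_or_labels [cell_table()] or integer label matrix.
#' @param band_area_um2 Analyzed basal-band area (µm²).
#' @return A `count_density` row with `kind = "BASAL_NUCLEI"`.
#' @export
basal_density <- function(cells_or_labels, band_area_um2) {
  if (band_area_um2 <= 0) stop("basal_density: zero field area", call. = FALSE)
  count <- if (is.matrix(cells_or_labels)) {
    length(setdiff(unique(as.vector(cells_or_labels)), 0L))
  } else {
    df <- tibble::as_tibble(cells_or_labels)
    sum(df$qc_pass)
  }
  tibble::tibble(kind = "BASAL_NUCLEI", count = as.integer(count),
                 area_um2 = band_area_um2,
                 density_per_mm2 = count / (band_area_um2 / 1e6))
}
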