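#' Run the per-stack quantification pipeline
#'
#' Convenience wrapper chaining the standard stages on one stack: collagen
#' mask, dermis surface, signed distance volume, cytosolic and nuclear band
#' projections, segmentation (provided labels or auto) and per-cell means.
#'
#' @param stack An [image_stack()].
#' @param config A [default_config()] list.
#' @param labels Optional external ROI label matrix (e.g. generator truth
#'   labels); `NULL` segments automatically.
#' @param positive_genotype Genotype assigned to mCherry-positive cells.
#' @param distance_mode `"euclidean"` or `"vertical"`.
#' @return List with `dermis`, `distance`, `cytosolic` and `nuclear`
#'   projections, `labels` and `cells` (a [cell_table()]).
#' @export
quantify_stack <- function(stack, config = default_config(), labels = NULL,
                           positive_genotype = "MUTANT",
                           distance_mode = "euclidean") {
  mask <- collagen_mask(stack, method = config$threshold_method,
                        fixed_threshold = config$fixed_threshold,
                        min_object_voxels = config$min_object_voxels)
  dermis <- dermis_surface(mask, stack$voxel_size_um,
                           median_window = config$median_window)
  dvol <- distance_to_surface(dermis, dim(stack$voxels)[2],
                              stack$voxel_size_um, mode = distance_mode)
  cyto <- extract_band(stack, dvol,
                       layer_band(config$band_cytosolic_um[1],
                                  config$band_cytosolic_um[2]),
                       method = config$projection_method,
                       channels = intersect(c("NADPH", "FAD"),
                                            channel_names(stack)))
  nucl <- extract_band(stack, dvol,
                       layer_band(config$band_nuclear_um[1],
                                  config$band_nuclear_um[2]),
                       method = config$projection_method)
  seg <- if (is.null(labels)) {
    segment_cells(nucl, "auto", min_cell_pixels = config$min_cell_pixels)
  } else {
    segment_cells(nucl, "labels_provided", labels = labels)
  }
  cells <- per_cell_means(nucl, seg, stack = stack,
                          fad_floor = config$fad_floor,
                          mcherry_abs_floor = config$mcherry_abs_floor,
                          min_cell_pixels = config$min_cell_pixels,
                          positive_genotype = positive_genotype)
  list(dermis = dermis, distance = dvol, cytosolic = cyto, nuclear = nucl,
       labels = seg, cells = cells)
}
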