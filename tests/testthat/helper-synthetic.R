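# Shared fixtures: small fast tissue models and independent oracles.

small_tissue <- function(...) {
  args <- modifyList(
    list(field_um = c(60, 60), n_basal_cells = 35,
         interface_mean_depth_um = 18, interface_amplitude_um = 2,
         interface_wavelength_um = 30),
    list(...))
  do.call(tissue_model, args)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Exhaustive brute-force signed Euclidean distance to a surface point cloud;
# the independent oracle for the distance transform (grids <= 10^3 voxels).
brute_force_surface_distance <- function(h, nz, voxel_size_um) {
  dz <- voxel_size_um[1]; dy <- voxel_size_um[2]; dx <- voxel_size_um[3]
  ny <- nrow(h); nx <- ncol(h)
  out <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    best <- Inf
    for (sy in seq_len(ny)) for (sx in seq_len(nx)) {
      d2 <- ((z - 1) * dz - h[sy, sx])^2 +
        ((y - sy) * dy)^2 + ((x - sx) * dx)^2
      if (d2 < best) best <- d2
    }
    out[z, y, x] <- sign(h[y, x] - (z - 1) * dz) * sqrt(best)
  }
  out
}

# 1:1 matching fraction between a segmentation and truth nucleus labels
label_match_fraction <- function(seg, truth_labels, n_cells, min_iou = 0.5) {
  n_match <- 0
  for (i in seq_len(n_cells)) {
    tm <- truth_labels == i
    ids <- seg[tm]; ids <- ids[ids > 0]
    if (!length(ids)) next
    best <- as.integer(names(sort(table(ids), decreasing = TRUE))[1])
    sm <- seg == best
    if (sum(tm & sm) / sum(tm | sm) >= min_iou) n_match <- n_match + 1
  }
  n_match / n_cells
}

# truth-label quantification of a generated stack (shared by several tests)
quantify_with_truth <- function(gen, config = default_config(), ...) {
  quiet(quantify_stack(gen$stack, config = config,
                       labels = gen$truth$labels, ...))
}
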