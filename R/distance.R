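#' Signed 3D distance to a detected surface
#'
#' For every voxel, the Euclidean distance in µm to the surface point cloud
#' (the surface sampled at pixel centres, anisotropic voxel scaling), signed
#' positive on the epidermis side of the dermis interface (shallower than the
#' surface) and negative below it. Undulating surfaces make vertical distance
#' an overestimate, so full 3D Euclidean is the default; a vertical-only fast
#' mode is available.
#'
#' Missing surface columns are nearest-neighbour interpolated with a logged
#' count before the transform.
#'
#' @param surface A [height_map()].
#' @param nz Number of z planes of the target volume.
#' @param voxel_size_um `(dz, dy, dx)` µm.
#' @param mode `"euclidean"` (exact 3D, via a lower-envelope distance
#'   transform) or `"vertical"` (per-column depth difference).
#' @return Numeric `(nz, ny, nx)` array of signed distances (µm).
#' @export
distance_to_surface <- function(surface, nz, voxel_size_um,
                                mode = c("euclidean", "vertical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(surface, "height_map"))
  dz <- voxel_size_um[1]; dy <- voxel_size_um[2]; dx <- voxel_size_um[3]
  h <- surface$depth_um
  if (anyNA(h)) {
    filled <- fill_missing_nn(h, surface$lateral_size_um)
    pkg_log("distance_to_surface: interpolated %d missing surface columns",
            filled$n_filled)
    h <- filled$filled
  }
  ny <- nrow(h); nx <- ncol(h)
  depth_vox <- array(rep((seq_len(nz) - 1) * dz, ny * nx), dim = c(nz, ny, nx))
  h3 <- array(rep(as.vector(h), each = nz), dim = c(nz, ny, nx))
  sgn <- sign(h3 - depth_vox)  # + above surface (epidermis side), - below
  if (mode == "vertical") {
    return(sgn * abs(h3 - depth_vox))
  }
  sq <- surface_sqdist_cpp(h, as.integer(nz), dz, dy, dx)
  d <- array(sqrt(sq), dim = c(nz, ny, nx))
  sgn * d
}
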