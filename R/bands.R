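#' Distance band relative to a reference surface
#'
#' Closed interval `[d_min_um, d_max_um]` of distances from a reference surface
#' in a given direction; the surface voxel itself (distance 0) is included when
#' `d_min_um = 0`, matching the convention of taking "0 to ~3 µm" of cytosolic
#' signal starting at the interface.
#'
#' @param d_min_um,d_max_um Band limits, `0 <= d_min < d_max` (µm).
#' @param reference `"DERMIS_SURFACE"` or `"AIR_SURFACE"`.
#' @param direction `"TOWARD_EPIDERMIS"` or `"TOWARD_DERMIS"`.
#' @return A `layer_band` object.
#' @export
layer_band <- function(d_min_um, d_max_um,
                       reference = c("DERMIS_SURFACE", "AIR_SURFACE"),
                       direction = c("TOWARD_EPIDERMIS", "TOWARD_DERMIS")) {
  reference <- match.arg(reference)
  direction <- match.arg(direction)
  if (!is.numeric(d_min_um) || !is.numeric(d_max_um) ||
      d_min_um < 0 || d_min_um >= d_max_um) {
    stop("layer_band: need 0 <= d_min_um < d_max_um", call. = FALSE)
  }
  structure(list(d_min_um = d_min_um, d_max_um = d_max_um,
                 reference = reference, direction = direction),
            class = "layer_band")
}

#' @export
print.layer_band <- function(x, ...) {
  cat(sprintf("<layer_band [%g, %g] um from %s %s>\n",
              x$d_min_um, x$d_max_um, x$reference, tolower(x$direction)))
  invisible(x)
}

band_selection <- function(distance_volume, band) {
  # signed distance is positive on the shallow (air) side of the surface;
  # "toward the epidermis" is the shallow side of the dermis surface but the
  # deep side of the air surface.
  shallow_side <- (band$direction == "TOWARD_EPIDERMIS") ==
    (band$reference == "DERMIS_SURFACE")
  side <- if (shallow_side) 1 else -1
  s <- side * distance_volume
  s >= band$d_min_um & s <= band$d_max_um
}

#' Extract and project a distance band
#'
#' Selects voxels whose signed distance lies inside the band (closed interval
#' on the band's side) and projects each channel laterally with the configured
#' method, recording per-pixel contributing voxel counts. Pixels with no
#' contributing voxel are `NA` in every channel map.
#'
#' @param stack [image_stack()].
#' @param distance_volume Signed distance array from [distance_to_surface()],
#'   aligned with `stack`.
#' @param band A [layer_band()].
#' @param method `"mean"` or `"max"` intensity projection.
#' @param channels Channel names to project (default: all).
#' @return A `layer_projection`: list with named `channels` (y-x matrices),
#'   `n_voxels` count map, `method` and `band`.
#' @export
extract_band <- function(stack, distance_volume, band,
                         method = c("mean", "max"), channels = NULL) {
  method <- match.arg(method)
  d <- dim(stack$voxels)
  if (!all(dim(distance_volume) == d[2:4])) {
    stop("extract_band: distance volume not aligned with stack", call. = FALSE)
  }
  sel <- band_selection(distance_volume, band)
  if (!any(sel)) {
    stop("extract_band: band lies entirely outside the stack range", call. = FALSE)
  }
  if (is.null(channels)) channels <- channel_names(stack)
  nz <- d[2]; ny <- d[3]; nx <- d[4]
  n_voxels <- matrix(0L, ny, nx)
  for (z in seq_len(nz)) n_voxels <- n_voxels + sel[z, , ]
  maps <- lapply(channels, function(ch) {
    vol <- channel_volume(stack, ch)
    if (method == "mean") {
      acc <- matrix(0, ny, nx)
      for (z in seq_len(nz)) acc <- acc + vol[z, , ] * sel[z, , ]
      out <- acc / n_voxels
      out[n_voxels == 0L] <- NA_real_
    } else {
      out <- matrix(-Inf, ny, nx)
      for (z in seq_len(nz)) {
        sl <- vol[z, , ]
        sl[!sel[z, , ]] <- -Inf
        out <- pmax(out, sl)
      }
      out[n_voxels == 0L] <- NA_real_
    }
    out
  })
  names(maps) <- channels
  structure(list(channels = maps, n_voxels = n_voxels,
                 method = method, band = band,
                 lateral_size_um = stack$voxel_size_um[2:3]),
            class = "layer_projection")
}

#' @export
print.layer_projection <- function(x, ...) {
  cat(sprintf("<layer_projection (%s) [%g, %g] um: %s; %d x %d px, %d empty>\n",
              x$method, x$band$d_min_um, x$band$d_max_um,
              paste(names(x$channels), collapse = ","),
              nrow(x$n_voxels), ncol(x$n_voxels), sum(x$n_voxels == 0)))
  invisible(x)
}
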