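#' Multi-channel 3D image stack
#'
#' The raw container of the imaging pipeline: a channel-by-z-by-y-by-x voxel
#' array with physical voxel sizes and a channel registry. Plane `z = 1` is the
#' shallowest acquired plane (air side); depth increases with `z`, so the voxel
#' on plane `k` (1-based) sits at depth `(k - 1) * dz` µm.
#'
#' @param voxels Nonnegative numeric array, `dim = c(n_channels, nz, ny, nx)`.
#' @param voxel_size_um `(dz, dy, dx)` voxel size in µm, all positive.
#' @param channels Character vector of channel names or list of
#'   [channel_spec()] objects; length must equal `dim(voxels)[1]`.
#' @param region_id Revisit identity of the imaged region.
#' @param timepoint_days Nonnegative acquisition time in days.
#' @param mouse_id Animal identifier.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, voxel_size_um, channels,
                        region_id = "R1", timepoint_days = 0,
                        mouse_id = "M1") {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    stop("image_stack: voxels must be a 4D array (channel, z, y, x)", call. = FALSE)
  }
  channels <- as_channel_list(channels)
  if (dim(voxels)[1] != length(channels)) {
    stop("image_stack: channel count must equal first axis length", call. = FALSE)
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 3L ||
      any(voxel_size_um <= 0)) {
    stop("image_stack: voxel_size_um must be three positive numbers (dz, dy, dx)",
         call. = FALSE)
  }
  if (any(voxels < 0, na.rm = TRUE)) {
    stop("image_stack: intensities must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(timepoint_days) || timepoint_days < 0) {
    stop("image_stack: timepoint_days must be nonnegative", call. = FALSE)
  }
  structure(list(voxels = voxels,
                 voxel_size_um = as.numeric(voxel_size_um),
                 channels = channels,
                 region_id = as.character(region_id),
                 timepoint_days = as.numeric(timepoint_days),
                 mouse_id = as.character(mouse_id)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack %s/%s day %g: %d ch [%s], %d x %d x %d (z,y,x), voxel %g x %g x %g um>\n",
              x$mouse_id, x$region_id, x$timepoint_days, d[1],
              paste(channel_names(x), collapse = ","),
              d[2], d[3], d[4],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Extract one channel volume
#'
#' @param stack An [image_stack()].
#' @param name Channel name.
#' @return A `(nz, ny, nx)` numeric array.
#' @export
channel_volume <- function(stack, name) {
  idx <- find_channel(stack, name)
  d <- dim(stack$voxels)
  array(stack$voxels[idx, , , ], dim = d[2:4])
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack to TIFF with a JSON metadata sidecar
#'
#' Planes are written z-major with channels interleaved (channel fastest) as
#' 32-bit float TIFF. Because TIFF storage here is confined to \[0, 1\], voxels
#' are divided by a power-of-two scale recorded in the sidecar (exact in binary
#' floating point) and restored on read; round-trips are therefore exact to
#' 32-bit float precision.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  mx <- max(stack$voxels, na.rm = TRUE)
  scale <- 2^max(0, ceiling(log2(max(mx, 1))))
  planes <- vector("list", d[1] * d[2])
  k <- 1L
  for (z in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {
      planes[[k]] <- matrix(stack$voxels[ch, z, , ] / scale, d[3], d[4])
      k <- k + 1L
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  meta <- list(
    n_channels = d[1], nz = d[2], ny = d[3], nx = d[4],
    voxel_size_um = stack$voxel_size_um,
    channels = lapply(stack$channels, function(ch) {
      list(name = ch$name, excitation_nm = ch$excitation_nm,
           emission_band_nm = ch$emission_band_nm)
    }),
    region_id = stack$region_id,
    timepoint_days = stack$timepoint_days,
    mouse_id = stack$mouse_id,
    intensity_scale = scale
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack from TIFF
#'
#' With the sidecar written by [write_stack()] present, all metadata round-trip.
#' For a bare TIFF, `channel_map` declares the channel layout and voxel sizes
#' fall back to the configured defaults with a logged warning.
#'
#' @param path TIFF file path.
#' @param channel_map Named integer vector mapping channel names to 1-based
#'   within-z plane indices (e.g. `c(NADPH = 1, FAD = 2)`); required when no
#'   sidecar exists, optional (validated) otherwise.
#' @param config A [default_config()] list; supplies fallback voxel sizes.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = NULL, config = default_config()) {
  if (!file.exists(path)) stop(sprintf("read_stack: cannot read %s", path), call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) < 1L) stop("read_stack: file has no planes", call. = FALSE)
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    nc <- meta$n_channels; nz <- meta$nz
    chs <- lapply(seq_len(nc), function(i) {
      channel_spec(meta$channels$name[i],
                   meta$channels$excitation_nm[i],
                   unlist(meta$channels$emission_band_nm[i]))
    })
    voxel_size <- as.numeric(meta$voxel_size_um)
    scale <- meta$intensity_scale
    region_id <- meta$region_id
    timepoint_days <- meta$timepoint_days
    mouse_id <- meta$mouse_id
    if (!is.null(channel_map)) {
      if (any(channel_map < 1L) || any(channel_map > nc)) {
        stop("read_stack: channel_map index out of range", call. = FALSE)
      }
    }
  } else {
    if (is.null(channel_map)) {
      stop("read_stack: no metadata sidecar; a channel_map is required", call. = FALSE)
    }
    nc <- length(channel_map)
    if (length(planes) %% nc != 0L) {
      stop("read_stack: plane count is not a multiple of the channel count", call. = FALSE)
    }
    if (any(channel_map < 1L) || any(channel_map > nc)) {
      stop("read_stack: channel_map index out of range", call. = FALSE)
    }
    nz <- length(planes) %/% nc
    chs <- lapply(names(channel_map), channel_spec)[order(channel_map)]
    voxel_size <- config$voxel_size_um
    warning(sprintf(
      "read_stack: no voxel-size metadata in %s; falling back to config (%g, %g, %g) um",
      path, voxel_size[1], voxel_size[2], voxel_size[3]), call. = FALSE)
    scale <- 1
    region_id <- "R1"; timepoint_days <- 0; mouse_id <- "M1"
  }
  if (length(planes) != nc * nz) {
    stop("read_stack: plane count inconsistent with metadata", call. = FALSE)
  }
  voxels <- array(0, dim = c(nc, nz, ny, nx))
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in seq_len(nc)) {
      voxels[ch, z, , ] <- planes[[k]] * scale
      k <- k + 1L
    }
  }
  image_stack(voxels, voxel_size, chs,
              region_id = region_id, timepoint_days = timepoint_days,
              mouse_id = mouse_id)
}
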