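#' Per-pixel surface depth map
#'
#' Depth (µm from the shallowest acquired plane) of a detected tissue surface
#' at every lateral pixel. Undetermined columns are `NA`, never silently zero.
#'
#' @param depth_um `ny x nx` numeric matrix of nonnegative depths (µm), NA
#'   where missing.
#' @param lateral_size_um `(dy, dx)` lateral pixel size in µm.
#' @return A `height_map` object.
#' @export
height_map <- function(depth_um, lateral_size_um) {
  stopifnot(is.matrix(depth_um))
  if (any(depth_um < 0, na.rm = TRUE)) {
    stop("height_map: depths must be nonnegative", call. = FALSE)
  }
  if (length(lateral_size_um) != 2L || any(lateral_size_um <= 0)) {
    stop("height_map: lateral_size_um must be two positive numbers", call. = FALSE)
  }
  structure(list(depth_um = depth_um,
                 lateral_size_um = as.numeric(lateral_size_um)),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map %d x %d px (%g x %g um/px), depth %g-%g um, %d missing>\n",
              nrow(x$depth_um), ncol(x$depth_um),
              x$lateral_size_um[1], x$lateral_size_um[2],
              suppressWarnings(min(x$depth_um, na.rm = TRUE)),
              suppressWarnings(max(x$depth_um, na.rm = TRUE)),
              sum(is.na(x$depth_um))))
  invisible(x)
}

#' Threshold-based collagen (SHG) mask
#'
#' Marks dermis voxels: SHG intensity at or above threshold. The threshold is
#' Otsu on the pooled SHG histogram by default (the acquisition does not fix an
#' absolute collagen intensity), or a fixed value. Specks smaller than
#' `min_object_voxels` are removed slice-wise.
#'
#' @param stack [image_stack()] with an SHG channel.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold intensity when `method = "fixed"`.
#' @param min_object_voxels Connected 2D components (per z-slice) smaller than
#'   this are dropped; `0` disables.
#' @return Logical `(nz, ny, nx)` array with attribute `threshold`.
#' @export
collagen_mask <- function(stack, method = c("otsu", "fixed"),
                          fixed_threshold = NULL, min_object_voxels = 0L) {
  method <- match.arg(method)
  vol <- channel_volume(stack, "SHG")
  if (method == "otsu") {
    thr <- tryCatch(otsu_threshold(vol), error = function(e) {
      stop("collagen_mask: degenerate SHG histogram (constant channel); use a fixed threshold",
           call. = FALSE)
    })
  } else {
    if (is.null(fixed_threshold)) {
      stop("collagen_mask: fixed method needs fixed_threshold", call. = FALSE)
    }
    thr <- fixed_threshold
  }
  mask <- vol >= thr
  n_removed <- 0L
  if (min_object_voxels > 0L) {
    for (z in seq_len(dim(mask)[1])) {
      sl <- mask[z, , ]
      if (!any(sl)) next
      lab <- EBImage::bwlabel(sl * 1)
      sizes <- tabulate(lab[lab > 0])
      drop <- which(sizes < min_object_voxels)
      if (length(drop)) {
        rm_px <- lab %in% drop
        sl[rm_px] <- FALSE
        n_removed <- n_removed + sum(rm_px)
        mask[z, , ] <- sl
      }
    }
  }
  pkg_log("collagen_mask: threshold %.4g (%s), %d speckle voxels removed",
          thr, method, n_removed)
  attr(mask, "threshold") <- thr
  mask
}

first_true_depth <- function(mask3d, dz) {
  nz <- dim(mask3d)[1]
  firstz <- matrix(NA_real_, dim(mask3d)[2], dim(mask3d)[3])
  for (z in rev(seq_len(nz))) {
    sl <- mask3d[z, , ]
    firstz[sl] <- z
  }
  (firstz - 1) * dz
}

#' Dermo-epidermal interface from a collagen mask
#'
#' Per lateral pixel, the depth of the shallowest mask-true voxel (the first
#' appearance of collagen), median-filtered to suppress speckle. Columns with
#' no collagen stay missing; more than 50\% missing aborts (surface not
#' detectable).
#'
#' @param mask Logical `(nz, ny, nx)` array from [collagen_mask()].
#' @param voxel_size_um `(dz, dy, dx)` in µm.
#' @param median_window Odd side of the NA-aware median filter; `1` disables.
#' @return A [height_map()].
#' @export
dermis_surface <- function(mask, voxel_size_um, median_window = 5L) {
  if (!any(mask)) stop("dermis_surface: empty mask", call. = FALSE)
  depth <- first_true_depth(mask, voxel_size_um[1])
  miss <- mean(is.na(depth))
  if (miss > 0.5) {
    stop(sprintf("dermis_surface: %.0f%% of columns have no collagen; surface not detectable",
                 100 * miss), call. = FALSE)
  }
  if (miss > 0) pkg_log("dermis_surface: %d columns missing", sum(is.na(depth)))
  depth <- median_filter_na(depth, median_window)
  height_map(depth, voxel_size_um[2:3])
}

#' Air/cornified surface from tissue autofluorescence
#'
#' Per lateral pixel, the depth of the first voxel whose intensity exceeds
#' `fraction` of that column's maximum in the named background channel, then
#' smoothed as in [dermis_surface()]. Mirrors drawing an artificial air surface
#' just above the cornified layer from background tissue signal.
#'
#' @param stack [image_stack()].
#' @param background_channel Channel supplying tissue signal (default NADPH).
#' @param fraction Fraction of the column maximum that counts as tissue.
#' @param median_window As in [dermis_surface()].
#' @return A [height_map()].
#' @export
air_surface <- function(stack, background_channel = "NADPH",
                        fraction = 0.2, median_window = 5L) {
  vol <- channel_volume(stack, background_channel)
  if (all(vol == 0)) stop("air_surface: channel is all zero", call. = FALSE)
  colmax <- apply(vol, c(2, 3), max)
  nz <- dim(vol)[1]
  thrvol <- vol > rep(fraction * as.vector(colmax), each = nz)
  thrvol <- thrvol & array(rep(as.vector(colmax > 0), each = nz), dim(vol))
  depth <- first_true_depth(thrvol, stack$voxel_size_um[1])
  miss <- mean(is.na(depth))
  if (miss > 0.5) {
    stop(sprintf("air_surface: %.0f%% of columns carry no signal", 100 * miss),
         call. = FALSE)
  }
  if (miss > 0) pkg_log("air_surface: %d columns missing", sum(is.na(depth)))
  depth <- median_filter_na(depth, median_window)
  height_map(depth, stack$voxel_size_um[2:3])
}
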