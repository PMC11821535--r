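#' Default pipeline configuration
#'
#' All tunable stage parameters in one list, overridable from a YAML file via
#' [load_config()]. Distances are µm throughout.
#'
#' Key entries:
#' \describe{
#'   \item{band_cytosolic_um}{`(0, 3)` distance band from the dermis surface
#'     toward the epidermis holding cytosolic NAD(P)H/FAD signal.}
#'   \item{band_nuclear_um}{`(0, 5)` band holding nuclear reporter signal.}
#'   \item{fad_floor}{Intensity below which FAD pixels are masked before
#'     division; `NULL` selects 1\% of the channel's 99th-percentile.}
#'   \item{projection_method}{`"mean"` or `"max"` layer projection.}
#'   \item{threshold_method}{`"otsu"` or `"fixed"` collagen thresholding.}
#'   \item{median_window}{Side of the NA-aware median filter applied to
#'     detected surfaces (odd; 5 by default).}
#' }
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    band_cytosolic_um = c(0, 3),
    band_nuclear_um   = c(0, 5),
    fad_floor         = NULL,
    projection_method = "mean",
    seed              = 0L,
    threshold_method  = "otsu",
    fixed_threshold   = NULL,
    median_window     = 5L,
    min_object_voxels = 9L,
    air_fraction      = 0.2,
    min_cell_pixels   = 8L,
    min_cells_per_group = 10L,
    merge_radius_um   = 3,
    mcherry_abs_floor = 5,
    voxel_size_um     = c(0.5, 1, 1)
  )
}

validate_config <- function(config) {
  for (nm in c("band_cytosolic_um", "band_nuclear_um")) {
    b <- config[[nm]]
    if (!is.numeric(b) || length(b) != 2L || b[1] < 0 || b[1] >= b[2]) {
      stop(sprintf("config: %s must be (lo, hi) with 0 <= lo < hi", nm), call. = FALSE)
    }
  }
  if (!config$projection_method %in% c("mean", "max")) {
    stop("config: projection_method must be 'mean' or 'max'", call. = FALSE)
  }
  if (!config$threshold_method %in% c("otsu", "fixed")) {
    stop("config: threshold_method must be 'otsu' or 'fixed'", call. = FALSE)
  }
  if (identical(config$threshold_method, "fixed") &&
      is.null(config$fixed_threshold)) {
    stop("config: fixed threshold_method requires fixed_threshold", call. = FALSE)
  }
  if (!is.null(config$fad_floor) && config$fad_floor < 0) {
    stop("config: fad_floor must be nonnegative", call. = FALSE)
  }
  if (config$seed < 0) stop("config: seed must be nonnegative", call. = FALSE)
  if (!is.numeric(config$voxel_size_um) || length(config$voxel_size_um) != 3L ||
      any(config$voxel_size_um <= 0)) {
    stop("config: voxel_size_um must be three positive numbers", call. = FALSE)
  }
  invisible(config)
}

#' Load a YAML configuration file
#'
#' Entries in the file override [default_config()]; everything else keeps its
#' default. The merged configuration is validated.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) config <- modifyList(config, user)
  }
  validate_config(config)
  config
}
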