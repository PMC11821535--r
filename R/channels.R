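CHANNEL_NAMES <- c("NADPH", "FAD", "MCHERRY", "SHG",
                   "FUCCI_G1", "FUCCI_SG2", "PH3", "OTHER")

#' Imaging channel specification
#'
#' Describes one detection channel of a two-photon acquisition: which signal it
#' carries, the excitation wavelength and the emission collection band.
#' Defaults follow the intravital scheme used throughout the package: NAD(P)H
#' autofluorescence collected at 425--475 nm (750 nm excitation) and FAD at
#' 500--550 nm (890 nm excitation).
#'
#' @param name One of `r paste(CHANNEL_NAMES, collapse = ", ")`.
#' @param excitation_nm Positive excitation wavelength (nm).
#' @param emission_band_nm Length-2 `(low, high)` emission band in nm,
#'   `low < high`.
#' @return A `channel_spec` object.
#' @export
channel_spec <- function(name,
                         excitation_nm = NULL,
                         emission_band_nm = NULL) {
  name <- match.arg(name, CHANNEL_NAMES)
  defaults <- list(
    NADPH     = list(ex = 750,  em = c(425, 475)),
    FAD       = list(ex = 890,  em = c(500, 550)),
    MCHERRY   = list(ex = 1040, em = c(572, 647.5)),
    SHG       = list(ex = 890,  em = c(425, 475)),
    FUCCI_G1  = list(ex = 1040, em = c(572, 647.5)),
    FUCCI_SG2 = list(ex = 940,  em = c(500, 550)),
    PH3       = list(ex = 940,  em = c(500, 550)),
    OTHER     = list(ex = 900,  em = c(400, 700))
  )[[name]]
  if (is.null(excitation_nm)) excitation_nm <- defaults$ex
  if (is.null(emission_band_nm)) emission_band_nm <- defaults$em
  if (!is.numeric(excitation_nm) || length(excitation_nm) != 1L ||
      excitation_nm <= 0) {
    stop("channel_spec: excitation_nm must be a positive number", call. = FALSE)
  }
  if (!is.numeric(emission_band_nm) || length(emission_band_nm) != 2L ||
      any(emission_band_nm <= 0) ||
      emission_band_nm[1] >= emission_band_nm[2]) {
    stop("channel_spec: emission_band_nm must be positive (low, high) with low < high",
         call. = FALSE)
  }
  structure(list(name = name,
                 excitation_nm = excitation_nm,
                 emission_band_nm = emission_band_nm),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel %s: ex %g nm, em %g-%g nm>\n",
              x$name, x$excitation_nm,
              x$emission_band_nm[1], x$emission_band_nm[2]))
  invisible(x)
}

as_channel_list <- function(channels) {
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  lapply(channels, function(ch) {
    if (inherits(ch, "channel_spec")) ch else channel_spec(ch)
  })
}

channel_names <- function(stack) {
  vapply(stack$channels, function(ch) ch$name, character(1))
}

#' Locate a channel in a stack
#'
#' @param stack An [image_stack()].
#' @param name Channel name to look up.
#' @return The (1-based) channel index.
#' @export
find_channel <- function(stack, name) {
  idx <- which(channel_names(stack) == name)
  if (length(idx) == 0L) {
    stop(sprintf("channel %s not present in stack (has: %s)",
                 name, paste(channel_names(stack), collapse = ", ")),
         call. = FALSE)
  }
  idx[1]
}
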