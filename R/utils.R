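#' @keywords internal
#' @noRd
pkg_log <- function(fmt, ...) {
  message(sprintf(paste0("[epiredox] ", fmt), ...))
  invisible(NULL)
}

#' Otsu intensity threshold
#'
#' Global Otsu threshold on the pooled histogram of an intensity array, on the
#' array's own scale. A constant (degenerate) input has no between-class
#' variance to maximise and is rejected so callers can fall back to a fixed
#' threshold.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @param levels Number of histogram levels handed to the underlying optimiser.
#' @return A single threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("otsu_threshold: no finite values", call. = FALSE)
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    stop("otsu_threshold: constant input; use a fixed threshold instead",
         call. = FALSE)
  }
  scaled <- (v - rng[1]) / diff(rng)
  # EBImage::otsu computes per-frame thresholds; pool everything as one frame
  img <- EBImage::Image(matrix(scaled, nrow = length(scaled), ncol = 1L))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  rng[1] + thr * diff(rng)
}

#' NA-aware 2D median filter
#'
#' Square-window median filter that ignores NA entries instead of propagating
#' them (standard image median filters require complete data in \[0, 1\]).
#' Pixels whose whole window is NA stay NA.
#'
#' @param m Numeric matrix.
#' @param window Odd window side length; `1` disables filtering.
#' @return Filtered matrix of the same dimension.
#' @export
median_filter_na <- function(m, window = 5L) {
  stopifnot(is.matrix(m))
  window <- as.integer(window)
  if (window <= 1L) return(m)
  if (window %% 2L == 0L) stop("median_filter_na: window must be odd", call. = FALSE)
  r <- (window - 1L) %/% 2L
  ny <- nrow(m); nx <- ncol(m)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  stackarr <- array(NA_real_, dim = c(ny, nx, nrow(offs)))
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
    oky <- ys >= 1L & ys <= ny; okx <- xs >= 1L & xs <= nx
    sub <- matrix(NA_real_, ny, nx)
    sub[oky, okx] <- m[ys[oky], xs[okx]]
    stackarr[, , k] <- sub
  }
  out <- apply(stackarr, c(1, 2), median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Fill missing matrix entries by nearest neighbour
#'
#' Replaces NA entries with the value of the laterally nearest non-NA entry
#' (physical distances, anisotropic pixels allowed).
#'
#' @param m Numeric matrix with possible NAs.
#' @param lateral_size_um `(dy, dx)` pixel size in µm.
#' @return List with `filled` (matrix) and `n_filled` (count of replaced
#'   entries).
#' @export
fill_missing_nn <- function(m, lateral_size_um = c(1, 1)) {
  miss <- which(is.na(m))
  if (length(miss) == 0L) return(list(filled = m, n_filled = 0L))
  have <- which(!is.na(m))
  if (length(have) == 0L) stop("fill_missing_nn: all entries missing", call. = FALSE)
  ny <- nrow(m)
  coord <- function(idx) {
    cbind(((idx - 1L) %% ny) * lateral_size_um[1],
          ((idx - 1L) %/% ny) * lateral_size_um[2])
  }
  nn <- class::knn1(coord(have), coord(miss), factor(seq_along(have)))
  m[miss] <- m[have[as.integer(nn)]]
  list(filled = m, n_filled = length(miss))
}
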