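GENOTYPE_LEVELS <- c("MUTANT", "WT", "CONTROL_RECOMBINED")
PHASE_LEVELS <- c("G1", "SG2", "UNKNOWN")

CELL_TABLE_COLS <- c(cell_id = "integer", mouse_id = "character",
                     region_id = "character", timepoint_days = "double",
                     genotype = "character", phase = "character",
                     mean_nadph = "double", mean_fad = "double",
                     ratio = "double", normalized_ratio = "double",
                     n_pixels = "integer", qc_pass = "logical")

#' Per-cell redox record table
#'
#' The substrate of every violin plot and differential: one row per cell with
#' its provenance (mouse, region, timepoint), genotype call, cell-cycle phase,
#' mean channel intensities, the per-cell redox ratio
#' `mean_nadph / mean_fad`, its normalized version and QC fields. Rows failing
#' QC (`qc_pass = FALSE`, e.g. fully FAD-masked cells or undersized ROIs) are
#' retained for audit but excluded from statistics downstream.
#'
#' @param df Data frame carrying the canonical columns (missing ones are filled
#'   with NA defaults).
#' @return A validated `tbl_df` of class `cell_table`.
#' @export
cell_table <- function(df = NULL) {
  if (is.null(df)) df <- tibble::tibble()
  df <- tibble::as_tibble(df)
  template <- tibble::tibble(
    cell_id = integer(), mouse_id = character(), region_id = character(),
    timepoint_days = double(), genotype = character(), phase = character(),
    mean_nadph = double(), mean_fad = double(), ratio = double(),
    normalized_ratio = double(), n_pixels = integer(), qc_pass = logical())
  for (nm in names(template)) {
    if (!nm %in% names(df)) {
      df[[nm]] <- if (nrow(df) == 0) template[[nm]] else
        rep(template[[nm]][NA_integer_], nrow(df))
    }
  }
  df <- df[, c(names(template), setdiff(names(df), names(template)))]
  validate_cell_table(df)
  class(df) <- c("cell_table", class(df))
  df
}

validate_cell_table <- function(df) {
  bad_gt <- setdiff(unique(df$genotype[!is.na(df$genotype)]), GENOTYPE_LEVELS)
  if (length(bad_gt)) {
    stop(sprintf("cell_table: unknown genotype(s): %s", paste(bad_gt, collapse = ", ")),
         call. = FALSE)
  }
  bad_ph <- setdiff(unique(df$phase[!is.na(df$phase)]), PHASE_LEVELS)
  if (length(bad_ph)) {
    stop(sprintf("cell_table: unknown phase(s): %s", paste(bad_ph, collapse = ", ")),
         call. = FALSE)
  }
  bad_ratio <- !is.na(df$ratio) & df$qc_pass & df$ratio <= 0
  if (any(bad_ratio, na.rm = TRUE)) {
    stop("cell_table: QC-passing rows must have ratio > 0", call. = FALSE)
  }
  invisible(df)
}

#' Write a cell table to CSV
#'
#' Numeric fields keep full double precision (lossless to well beyond 9
#' significant digits on round-trip).
#'
#' @param table A [cell_table()].
#' @param path Output CSV path.
#' @export
write_cell_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' Malformed fields (e.g. a non-numeric ratio) raise a parse error naming the
#' offending row and column.
#'
#' @param path CSV path written by [write_cell_table()].
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_cell_table: no such file: %s", path), call. = FALSE)
  spec <- readr::cols(
    cell_id = readr::col_integer(), mouse_id = readr::col_character(),
    region_id = readr::col_character(), timepoint_days = readr::col_double(),
    genotype = readr::col_character(), phase = readr::col_character(),
    mean_nadph = readr::col_double(), mean_fad = readr::col_double(),
    ratio = readr::col_double(), normalized_ratio = readr::col_double(),
    n_pixels = readr::col_integer(), qc_pass = readr::col_logical(),
    .default = readr::col_guess())
  df <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                         progress = FALSE,
                                         show_col_types = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    stop(sprintf("read_cell_table: parse error at row %d, column %d (%s): expected %s",
                 p$row, p$col, path, p$expected), call. = FALSE)
  }
  cell_table(df)
}
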