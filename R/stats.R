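# two-sided equal-variance two-sample t that tolerates zero variance
# (identical unit means give t = 0, p = 1; a pure offset gives p = 0)
safe_t2 <- function(x, y) {
  df <- length(x) + length(y) - 2
  s2p <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (s2p <= .Machine$double.eps * max(1, mean(x)^2, mean(y)^2)) {
    delta <- mean(x) - mean(y)
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    return(list(statistic = stat, parameter = df,
                p.value = if (delta == 0) 1 else 0))
  }
  tt <- t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
       p.value = tt$p.value)
}

collapse_units <- function(df) {
  if (!all(c("unit_id", "value") %in% names(df))) {
    stop("hierarchical sample needs unit_id and value columns", call. = FALSE)
  }
  means <- tapply(df$value, df$unit_id, mean)
  tibble::tibble(unit_id = names(means), unit_mean = as.numeric(means))
}

test_result <- function(test, statistic, dof, p_value, group_means,
                        n_units, n_values, comparison = NA_character_,
                        p_adjusted = NA_real_) {
  tibble::tibble(test = test, comparison = comparison,
                 statistic = statistic, dof = dof,
                 p_value = p_value, p_adjusted = p_adjusted,
                 mean_a = group_means[1], mean_b = group_means[2],
                 n_units_a = n_units[1], n_units_b = n_units[2],
                 n_values_a = n_values[1], n_values_b = n_values[2])
}

#' Nested two-sample t-test via per-animal averages
#'
#' Guards against pseudoreplication when hundreds of cells come from a few
#' mice: per-cell values are first collapsed to one mean per experimental unit
#' (mouse), then a two-sided equal-variance two-sample t-test compares the
#' unit means. Both the unit-level and the value-level n are reported so
#' readers can judge the collapse. With exactly one value per unit this
#' reduces to the classical two-sample t-test.
#'
#' @param a,b Data frames with `unit_id` and `value` (one row per cell).
#' @return A one-row `TestResult` tibble (statistic, dof, p, means, n).
#' @export
nested_t_test <- function(a, b) {
  ma <- collapse_units(a); mb <- collapse_units(b)
  if (nrow(ma) < 2 || nrow(mb) < 2) {
    stop("nested_t_test: >= 2 units per group required", call. = FALSE)
  }
  tt <- safe_t2(ma$unit_mean, mb$unit_mean)
  test_result("nested_t", tt$statistic, tt$parameter,
              tt$p.value, c(mean(ma$unit_mean), mean(mb$unit_mean)),
              c(nrow(ma), nrow(mb)), c(nrow(a), nrow(b)))
}

#' Paired t-test on matched per-unit values
#'
#' For revisit designs (the same mice measured pre and post): per-unit values
#' are collapsed to unit means, matched by `unit_id`, and compared with a
#' two-sided paired t-test.
#'
#' @param pre,post Data frames with `unit_id` and `value`; same units.
#' @return A one-row `TestResult` tibble.
#' @export
paired_t_test <- function(pre, post) {
  mp <- collapse_units(pre); mq <- collapse_units(post)
  if (!setequal(mp$unit_id, mq$unit_id)) {
    stop("paired_t_test: unmatched unit ids", call. = FALSE)
  }
  if (nrow(mp) < 2) stop("paired_t_test: >= 2 pairs required", call. = FALSE)
  mq <- mq[match(mp$unit_id, mq$unit_id), ]
  d <- mp$unit_mean - mq$unit_mean
  tt <- if (sd(d) <= .Machine$double.eps * max(1, abs(mean(d)))) {
    # degenerate differences: identical pairs give t = 0, p = 1
    list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
         parameter = length(d) - 1,
         p.value = if (mean(d) == 0) 1 else 0)
  } else {
    raw <- t.test(mp$unit_mean, mq$unit_mean, paired = TRUE,
                  alternative = "two.sided")
    list(statistic = unname(raw$statistic), parameter = unname(raw$parameter),
         p.value = raw$p.value)
  }
  test_result("paired_t", tt$statistic, tt$parameter,
              tt$p.value, c(mean(mp$unit_mean), mean(mq$unit_mean)),
              c(nrow(mp), nrow(mq)), c(nrow(pre), nrow(post)))
}

#' One-way ANOVA on unit means with comparisons versus control
#'
#' Collapses to per-unit means, runs a one-way ANOVA across groups and then
#' pairwise two-sided equal-variance t-tests of each group against the control
#' with Holm adjustment (slightly conservative relative to Dunnett, but free
#' of multivariate-t quantiles).
#'
#' @param groups Data frame with `unit_id`, `group`, `value`.
#' @param control Control group label (must be present).
#' @return Tibble: one `anova` row (F statistic, dof, p) followed by one
#'   `comparison_t` row per non-control group with adjusted p.
#' @export
anova_vs_control <- function(groups, control) {
  df <- tibble::as_tibble(groups)
  if (!control %in% df$group) {
    stop(sprintf("anova_vs_control: control group '%s' absent", control), call. = FALSE)
  }
  gl <- unique(df$group)
  if (length(gl) < 2) stop("anova_vs_control: >= 2 groups required", call. = FALSE)
  units <- dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$unit_id),
    unit_mean = mean(.data$value), n_values = dplyr::n(), .groups = "drop")
  n_units <- table(units$group)
  if (any(n_units < 2)) {
    stop("anova_vs_control: >= 2 units per group required", call. = FALSE)
  }
  fit <- aov(unit_mean ~ group, data = units)
  # a perfect (noise-free) fit triggers a precision warning; the F and p
  # degenerate to Inf / 0 which is the intended reading
  an <- suppressWarnings(anova(fit))
  rows <- list(test_result(
    "anova", an$`F value`[1], an$Df[1], an$`Pr(>F)`[1],
    c(NA_real_, NA_real_), c(nrow(units), NA_real_),
    c(nrow(df), NA_real_)))
  others <- setdiff(gl, control)
  praw <- numeric(length(others))
  comp <- vector("list", length(others))
  for (i in seq_along(others)) {
    g <- others[i]
    x <- units$unit_mean[units$group == control]
    y <- units$unit_mean[units$group == g]
    tt <- safe_t2(x, y)
    praw[i] <- tt$p.value
    comp[[i]] <- test_result(
      "comparison_t", tt$statistic, tt$parameter, tt$p.value,
      c(mean(x), mean(y)), c(length(x), length(y)),
      c(sum(df$group == control), sum(df$group == g)),
      comparison = sprintf("%s vs %s", g, control))
  }
  padj <- p.adjust(praw, method = "holm")
  for (i in seq_along(comp)) comp[[i]]$p_adjusted <- padj[i]
  dplyr::bind_rows(c(rows, comp))
}

#' Export violin-plot-ready data
#'
#' Long-format per-cell values by group plus a separate per-mouse means table
#' (the coloured per-animal overlay dots): the layout in which pooled per-cell
#' redox ratios are plotted with per-mouse averages used for testing.
#'
#' @param cells A [cell_table()].
#' @param group_cols Columns defining the violin groups.
#' @param value_col Value column to export.
#' @param values_path,means_path Optional CSV output paths.
#' @return List with `values` (group, mouse_id, value) and `unit_means`.
#' @export
export_violin_data <- function(cells,
                               group_cols = c("genotype", "timepoint_days"),
                               value_col = "normalized_ratio",
                               values_path = NULL, means_path = NULL) {
  df <- tibble::as_tibble(cells)
  miss <- setdiff(c(group_cols, value_col, "mouse_id"), names(df))
  if (length(miss)) {
    stop(sprintf("export_violin_data: missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- df[df$qc_pass & !is.na(df[[value_col]]), , drop = FALSE]
  group <- if (nrow(df) == 0) character(0) else {
    do.call(paste, c(lapply(group_cols, function(g) df[[g]]), sep = "/"))
  }
  values <- tibble::tibble(group = group, mouse_id = df$mouse_id,
                           value = df[[value_col]])
  unit_means <- dplyr::summarise(
    dplyr::group_by(values, .data$group, .data$mouse_id),
    mean_value = mean(.data$value), n_cells = dplyr::n(), .groups = "drop")
  if (!is.null(values_path)) readr::write_csv(values, values_path)
  if (!is.null(means_path)) readr::write_csv(unit_means, means_path)
  list(values = values, unit_means = unit_means)
}
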