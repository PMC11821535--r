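test_that("ratio image matches elementwise hand computation with reason codes", {
  nad <- matrix(c(2, 0, 4, 6), 2, 2)
  fad <- matrix(c(1, 0, 2, 3), 2, 2)
  ri <- ratio_image(nad, fad, fad_floor = 0.5)
  expect_equal(ri$ratio, matrix(c(2, NA, 2, 2), 2, 2))
  expect_equal(ri$reason[2, 1], "fad_below_floor")
  expect_equal(sum(ri$reason == "ok"), 3)

  # brute-force elementwise oracle on random inputs
  set.seed(71)
  for (rep in 1:3) {
    n2 <- matrix(runif(30, 0, 5), 5, 6)
    f2 <- matrix(runif(30, 0, 2), 5, 6)
    floor2 <- runif(1, 0, 1)
    got <- ratio_image(n2, f2, floor2)
    for (i in 1:5) for (j in 1:6) {
      if (f2[i, j] >= floor2 && f2[i, j] > 0) {
        expect_identical(got$ratio[i, j], n2[i, j] / f2[i, j])
      } else {
        expect_true(is.na(got$ratio[i, j]))
      }
    }
  }

  expect_equal(ratio_image(matrix(5, 2, 2), matrix(5, 2, 2), 0)$ratio,
               matrix(1, 2, 2))
  allzero <- ratio_image(matrix(1, 2, 2), matrix(0, 2, 2), 0)
  expect_true(all(is.na(allzero$ratio)))
  expect_error(ratio_image(matrix(1, 2, 2), matrix(1, 3, 2)), "shapes differ")
})

test_that("per-cell means use ratio-of-means and the hand-summation oracle", {
  proj <- structure(list(
    channels = list(NADPH = matrix(c(2, 4, 10, 10), 2, 2),
                    FAD = matrix(c(1, 3, 10, 10), 2, 2),
                    MCHERRY = matrix(0, 2, 2)),
    n_voxels = matrix(1L, 2, 2), method = "mean",
    band = layer_band(0, 5), lateral_size_um = c(1, 1)),
    class = "layer_projection")
  labels <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  cells <- quiet(per_cell_means(proj, labels, fad_floor = 0, min_cell_pixels = 1))
  expect_equal(cells$mean_nadph, c(3, 10))
  expect_equal(cells$mean_fad, c(2, 10))
  expect_equal(cells$ratio, c(1.5, 1))
  expect_equal(cells$genotype, c("WT", "WT"))

  # gain invariance: rescaling both channels leaves ratios untouched
  proj2 <- proj
  proj2$channels$NADPH <- proj$channels$NADPH * 37.5
  proj2$channels$FAD <- proj$channels$FAD * 37.5
  cells2 <- quiet(per_cell_means(proj2, labels, fad_floor = 0, min_cell_pixels = 1))
  expect_equal(cells2$ratio, cells$ratio, tolerance = 1e-12)

  # a cell fully under the FAD floor is flagged, not dropped silently
  proj3 <- proj
  proj3$channels$FAD[, 1] <- 0.001
  cells3 <- quiet(per_cell_means(proj3, labels, fad_floor = 0.5, min_cell_pixels = 1))
  expect_false(cells3$qc_pass[cells3$cell_id == 1])
  expect_true(cells3$qc_pass[cells3$cell_id == 2])
})

test_that("label passthrough validates shape; auto mode matches planted nuclei", {
  gen <- generate_stack(tissue_model(field_um = c(100, 100),
                                     n_basal_cells = 90),
                        redox_model(), mutant_fraction = 0.5, seed = 12,
                        wt_ratio = 0.98, mutant_ratio = 0.35)
  res <- quantify_with_truth(gen)
  expect_identical(res$labels, gen$truth$labels)
  expect_error(segment_cells(res$nuclear, "labels_provided",
                             labels = matrix(0L, 3, 3)), "shape mismatch")

  seg <- segment_cells(res$nuclear, "auto")
  frac <- label_match_fraction(seg, gen$truth$labels, nrow(gen$truth$cells))
  expect_gte(frac, 0.9)

  blank <- res$nuclear
  for (ch in names(blank$channels)) blank$channels[[ch]][] <- 0
  expect_warning(z <- segment_cells(blank, "auto"), "blank image")
  expect_equal(max(z), 0L)
})

test_that("baseline normalization has unit-mean baseline, scale invariance and idempotence", {
  cells <- cell_table(tibble::tibble(
    cell_id = 1:8,
    mouse_id = rep(c("m1", "m2"), each = 4),
    region_id = "r", timepoint_days = rep(c(0, 0, 5, 5), 2),
    genotype = "WT", phase = "UNKNOWN",
    mean_nadph = 1, mean_fad = 1,
    ratio = c(1.0, 1.2, 0.8, 0.7, 2.0, 2.4, 1.5, 1.3),
    normalized_ratio = NA_real_, n_pixels = 20L, qc_pass = TRUE))
  norm <- normalize_to_baseline(cells, "day0_same_mouse")
  # per-mouse brute-force loop oracle
  for (m in c("m1", "m2")) {
    base <- mean(cells$ratio[cells$mouse_id == m & cells$timepoint_days == 0])
    expect_equal(norm$normalized_ratio[norm$mouse_id == m],
                 cells$ratio[cells$mouse_id == m] / base, tolerance = 1e-12)
  }
  day0 <- norm$timepoint_days == 0
  expect_equal(as.numeric(tapply(norm$normalized_ratio[day0],
                                 norm$mouse_id[day0], mean)),
               c(1, 1), tolerance = 1e-12)

  # global rescale of all ratios changes nothing after normalization
  scaled <- cells; scaled$ratio <- scaled$ratio * 3
  norm2 <- normalize_to_baseline(scaled, "day0_same_mouse")
  expect_equal(norm2$normalized_ratio, norm$normalized_ratio, tolerance = 1e-12)

  # idempotence: feeding normalized ratios back in leaves values unchanged
  again <- norm; again$ratio <- again$normalized_ratio
  norm3 <- normalize_to_baseline(again, "day0_same_mouse")
  expect_equal(norm3$normalized_ratio, norm$normalized_ratio, tolerance = 1e-12)

  # missing baseline errors and names the mouse
  nob <- cells[cells$timepoint_days == 5 | cells$mouse_id == "m1", ]
  expect_error(normalize_to_baseline(cell_table(nob), "day0_same_mouse"), "m2")
})

test_that("redox differential is 1 for identical genotypes and respects min cells", {
  set.seed(5)
  cells <- cell_table(tibble::tibble(
    cell_id = 1:40, mouse_id = rep(c("m1", "m2"), each = 20),
    region_id = "r", timepoint_days = 5,
    genotype = rep(c("WT", "MUTANT"), 20), phase = "UNKNOWN",
    mean_nadph = 1, mean_fad = 1, ratio = rep(0.9, 40),
    normalized_ratio = NA_real_, n_pixels = 20L, qc_pass = TRUE))
  d <- quiet(redox_differential(cells, min_cells = 5))
  expect_equal(d$per_mouse$differential, c(1, 1))
  # raising min_cells above availability omits entries with a log message
  expect_message(d2 <- redox_differential(cells, min_cells = 50), "omitted")
  expect_equal(nrow(d2$per_mouse), 0L)
})

test_that("paired shift recovers planted per-mouse increases and nulls", {
  set.seed(9)
  mk <- function(mouse, ratio, n = 120) cell_table(tibble::tibble(
    cell_id = seq_len(n), mouse_id = mouse, region_id = "r",
    timepoint_days = 0, genotype = "CONTROL_RECOMBINED", phase = "UNKNOWN",
    mean_nadph = ratio, mean_fad = 1, ratio = ratio,
    normalized_ratio = NA_real_, n_pixels = 20L, qc_pass = TRUE))
  pre <- dplyr::bind_rows(mk("m1", 1.0), mk("m2", 1.1), mk("m3", 0.95))
  post <- dplyr::bind_rows(mk("m1", 1.28), mk("m2", 1.1 * 1.33),
                           mk("m3", 0.95 * 1.37))
  ps <- paired_shift(cell_table(pre), cell_table(post))
  expect_equal(sort(ps$per_mouse$shift_pct), c(28, 33, 37), tolerance = 1e-9)
  expect_lt(ps$test$p_value, 0.05)

  same <- paired_shift(cell_table(pre), cell_table(pre))
  expect_equal(same$per_mouse$shift_pct, rep(0, 3))
  expect_error(paired_shift(cell_table(pre), cell_table(mk("m9", 1))),
               "different mice")
})

test_that("phase effect recovers the planted G1 NAD(P)H boost", {
  mk_mice <- function(redox, seed) {
    set.seed(seed)
    cell_table(dplyr::bind_rows(lapply(c("m1", "m2", "m3"), function(m) {
      simulate_cell_table(200, 0, 1.0, 1.0, redox, m, "r", 0)
    })))
  }
  # noise-free: the G1/SG2 intensity ratio is the boost exactly
  pe <- phase_effect(mk_mice(noise_free(redox_model(g1_nadph_boost = 1.1)), 1))
  expect_equal(pe$g1_over_sg2, 1.1, tolerance = 1e-9)

  # default SNR: direction G1 > SG2 detected in >= 95% of seeded replicates
  hits <- sum(vapply(1:100, function(s) {
    pe <- phase_effect(mk_mice(redox_model(g1_nadph_boost = 1.1), s))
    pe$g1_over_sg2 > 1
  }, logical(1)))
  expect_gte(hits, 95)

  only_g1 <- mk_mice(noise_free(), 2)
  only_g1$phase <- "G1"
  expect_error(phase_effect(cell_table(only_g1)), "both G1 and SG2")
})
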