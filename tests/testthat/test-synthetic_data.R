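test_that("noise-free flat tissue realizes the planted ratio in every basal voxel", {
  ts <- tissue_model(field_um = c(40, 40), n_basal_cells = 14,
                     interface_amplitude_um = 0)
  rx <- noise_free(redox_model(g1_nadph_boost = 1))
  gen <- generate_stack(ts, rx, mutant_fraction = 0, seed = 5)
  nad <- channel_volume(gen$stack, "NADPH")
  fad <- channel_volume(gen$stack, "FAD")
  nz <- dim(nad)[1]
  h3 <- array(rep(as.vector(gen$truth$interface_depth_um$depth_um), each = nz),
              dim = dim(nad))
  depth3 <- array(rep((seq_len(nz) - 1) * 0.5, 40 * 40), dim = dim(nad))
  basal <- depth3 >= h3 - 5 & depth3 < h3 & fad > 0
  expect_true(any(basal))
  expect_equal(max(abs(nad[basal] / fad[basal] - 1)), 0)
  # SHG strictly at/below the interface
  shg <- channel_volume(gen$stack, "SHG")
  dz <- gen$stack$voxel_size_um[1]
  h <- gen$truth$interface_depth_um$depth_um
  for (z in seq_len(dim(shg)[1])) {
    expect_true(all((shg[z, , ] > 0) == ((z - 1) * dz >= h)))
  }
})

test_that("recombination draw is exact and monotone in mutant fraction", {
  ts <- small_tissue(n_basal_cells = 50)
  gen <- generate_stack(ts, noise_free(), mutant_fraction = 0.8, seed = 9)
  expect_equal(sum(gen$truth$cells$recombined), 40L)  # round(0.8 * 50), exact
  counts <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(f) {
    g <- generate_stack(ts, noise_free(), mutant_fraction = f, seed = 9)
    sum(g$truth$cells$recombined)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[c(1, 5)], c(0, 50))
})

test_that("truth interface equals the analytic sinusoid at pixel centres", {
  ts <- tissue_model(field_um = c(50, 50), n_basal_cells = 16,
                     interface_mean_depth_um = 20, interface_amplitude_um = 5,
                     interface_wavelength_um = 25)
  gen <- generate_stack(ts, noise_free(), mutant_fraction = 0, seed = 2,
                        voxel_size_um = c(0.5, 1, 1))
  yy <- (0:49); xx <- (0:49)
  expected <- 20 + 5 * outer(sin(2 * pi * yy / 25), sin(2 * pi * xx / 25))
  expect_equal(gen$truth$interface_depth_um$depth_um, expected, tolerance = 1e-12)
})

test_that("generation is seed-reproducible and geometry-validated", {
  ts <- small_tissue()
  g1 <- generate_stack(ts, redox_model(), mutant_fraction = 0.5, seed = 21)
  g2 <- generate_stack(ts, redox_model(), mutant_fraction = 0.5, seed = 21)
  expect_identical(g1$stack$voxels, g2$stack$voxels)
  expect_identical(g1$truth$cells, g2$truth$cells)
  g3 <- generate_stack(ts, redox_model(), mutant_fraction = 0.5, seed = 22)
  expect_false(identical(g1$stack$voxels, g3$stack$voxels))
  # interface deeper than an explicitly requested stack depth
  expect_error(generate_stack(ts, noise_free(), seed = 1, nz = 10),
               "infeasible")
})

test_that("timecourse presets encode the published trajectory shapes", {
  wt <- preset_schedule("WT_CONTROL", c(0, 5, 15))
  expect_equal(wt$wt_ratio, rep(1, 3))
  expect_equal(wt$mutant_ratio, rep(1, 3))

  bc <- preset_schedule("BCAT_GOF", c(0, 5, 10))
  # both genotypes drop at day 5, mutants below WT
  expect_lt(bc$wt_ratio[2], bc$wt_ratio[1])
  expect_lt(bc$mutant_ratio[2], bc$wt_ratio[2])
  # day-10 WT/mutant differential of 2.8 through selective WT recovery
  expect_equal(bc$wt_ratio[3] / bc$mutant_ratio[3], 2.8, tolerance = 1e-12)

  hr <- preset_schedule("HRAS_G12V", c(0, 5, 10, 13))
  expect_lt(hr$mutant_ratio[2], hr$wt_ratio[2])
  expect_equal(hr$wt_ratio[3] / hr$mutant_ratio[3], 1.0, tolerance = 1e-12)
  expect_equal(hr$wt_ratio[4] / hr$mutant_ratio[4], 1.0, tolerance = 1e-12)

  mf <- preset_schedule("METFORMIN_FLAT", c(0, 5))
  expect_equal(mf$wt_ratio[2], 1)
  expect_equal(mf$mutant_ratio[2], 1)

  cy <- preset_schedule("CYANIDE", c(0, 0.01), seed = 4)
  expect_gte(cy$shift[1], 1.28)
  expect_lte(cy$shift[1], 1.37)
  expect_equal(cy$wt_ratio[2] / cy$wt_ratio[1], cy$shift[1])

  expect_error(preset_schedule("NOT_A_PRESET", 0), "arg")
})

test_that("timecourse stacks share region id and carry per-day truth ratios", {
  tc <- generate_timecourse("BCAT_GOF", days = c(0, 10), seed = 3,
                            tissue = small_tissue(), output = "stack")
  expect_equal(length(tc$timepoints), 2L)
  expect_equal(tc$timepoints$day0$stack$region_id,
               tc$timepoints$day10$stack$region_id)
  expect_equal(tc$timepoints$day10$truth$wt_ratio /
                 tc$timepoints$day10$truth$mutant_ratio, 2.8)
  expect_error(generate_timecourse("BCAT_GOF", days = c(10, 0)), "ascending")
})

test_that("isotopologue generation hits planted ratios and validates names", {
  tab <- generate_isotopologues(
    list(CONTROL = c(v_pdh_vcs_acetylcoa = 1.0)), n_per_group = 4,
    noise_cv = 0, seed = 1)
  wide <- tidyr::pivot_wider(tab, names_from = metabolite,
                             values_from = enrichment)
  # equal-enrichment identity: acetyl-CoA m+2 equals alanine m+3 per sample
  expect_equal(wide$ACETYLCOA_M2, wide$ALANINE_M3, tolerance = 1e-15)

  tab2 <- generate_isotopologues(
    list(CONTROL = c(v_pdh_vcs_acetylcoa = 0.6)), n_per_group = 3,
    noise_cv = 0, seed = 1)
  ratios <- compute_ratios(tab2)
  expect_equal(ratios$v_pdh_vcs_acetylcoa, rep(0.6, 3), tolerance = 1e-15)

  expect_error(generate_isotopologues(list(CONTROL = c(bogus_ratio = 1)),
                                      2, 0, 1), "unknown ratio")
})

test_that("noisy isotopologue group means land near truth at published n", {
  # n = 8 as in the control infusion arm; mean within 3 s.e. of planted truth
  tab <- generate_isotopologues(
    list(CONTROL = c(v_pdh_vcs_acetylcoa = 0.6)), n_per_group = 8,
    noise_cv = 0.1, seed = 42)
  r <- compute_ratios(tab)$v_pdh_vcs_acetylcoa
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 0.6), 3 * se + 0.02)
})

test_that("basal nuclei sit on the interface inside the nuclear band", {
  gen <- generate_stack(small_tissue(), noise_free(), mutant_fraction = 0.5,
                        seed = 13)
  cells <- gen$truth$cells
  h <- gen$truth$interface_depth_um$depth_um
  r <- 2.5
  # centres within one cell radius above the local interface
  idx <- cbind(pmin(nrow(h), pmax(1, round(cells$y_um) + 1)),
               pmin(ncol(h), pmax(1, round(cells$x_um) + 1)))
  expect_true(all(h[idx] - cells$depth_um <= r + 1e-9))
  expect_true(all(h[idx] - cells$depth_um >= 0))
})
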