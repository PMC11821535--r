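make_flat_stack <- function(depth_um = 10, dz = 0.5, n = 12, nz = 24,
                            shg = 100) {
  vox <- array(0, dim = c(2, nz, n, n))
  zdepth <- (seq_len(nz) - 1) * dz
  vox[2, zdepth >= depth_um, , ] <- shg
  vox[1, zdepth < depth_um, , ] <- 50  # tissue signal above the interface
  image_stack(vox, c(dz, 1, 1), c("NADPH", "SHG"))
}

test_that("fixed-threshold collagen mask reproduces the planted region exactly", {
  st <- make_flat_stack()
  mask <- quiet(collagen_mask(st, "fixed", fixed_threshold = 50))
  expected <- channel_volume(st, "SHG") >= 50
  expect_equal(unname(mask), unname(expected), ignore_attr = TRUE)
  expect_equal(attr(mask, "threshold"), 50)
})

test_that("otsu collagen mask rejects a degenerate constant channel", {
  st <- make_flat_stack()
  st$voxels[2, , , ] <- 7
  expect_error(quiet(collagen_mask(st, "otsu")), "fixed threshold")
})

test_that("dermis surface is exact for a flat interface and errors when empty", {
  st <- make_flat_stack(depth_um = 10, dz = 0.5)
  mask <- quiet(collagen_mask(st, "fixed", fixed_threshold = 50))
  hm <- dermis_surface(mask, st$voxel_size_um)
  expect_equal(unname(hm$depth_um), matrix(10, 12, 12))
  expect_error(dermis_surface(array(FALSE, c(4, 3, 3)), c(0.5, 1, 1)), "empty")
})

test_that("sinusoidal interface is recovered within one z-step", {
  ts <- tissue_model(field_um = c(60, 60), n_basal_cells = 35,
                     interface_mean_depth_um = 20, interface_amplitude_um = 5,
                     interface_wavelength_um = 30)
  for (rx in list(noise_free(), redox_model())) {
    gen <- generate_stack(ts, rx, mutant_fraction = 0.5, seed = 31)
    mask <- quiet(collagen_mask(gen$stack, "otsu", min_object_voxels = 9))
    hm <- quiet(dermis_surface(mask, gen$stack$voxel_size_um))
    rmse <- sqrt(mean((hm$depth_um - gen$truth$interface_depth_um$depth_um)^2))
    limit <- if (rx$poisson_scale == 0) 0.5 else 1.0  # dz, 2*dz
    expect_lt(rmse, limit)
  }
})

test_that("air surface finds the first tissue signal and smooths undulation", {
  st <- make_flat_stack(depth_um = 10)
  st$voxels[1, , , ] <- 0
  zdepth <- (seq_len(dim(st$voxels)[2]) - 1) * 0.5
  st$voxels[1, zdepth >= 2 & zdepth < 10, , ] <- 80
  hm <- air_surface(st, "NADPH", fraction = 0.2)
  expect_equal(unname(hm$depth_um), matrix(2, 12, 12))

  gen <- generate_stack(small_tissue(), noise_free(), mutant_fraction = 0.5,
                        seed = 17)
  hm2 <- quiet(air_surface(gen$stack, "FAD", fraction = 0.2))
  rmse <- sqrt(mean((hm2$depth_um - gen$truth$air_depth_um$depth_um)^2))
  expect_lt(rmse, 0.5)

  st$voxels[1, , , ] <- 0
  expect_error(air_surface(st, "NADPH"), "all zero")
})

test_that("surface detection is z-translation-equivariant", {
  gen <- generate_stack(small_tissue(), noise_free(), mutant_fraction = 0,
                        seed = 8)
  mask <- quiet(collagen_mask(gen$stack, "fixed", fixed_threshold = 50))
  hm <- quiet(dermis_surface(mask, gen$stack$voxel_size_um))
  # prepend one empty z-slice: every detected depth shifts by exactly dz
  d <- dim(mask)
  shifted <- array(FALSE, d + c(1, 0, 0))
  shifted[2:(d[1] + 1), , ] <- mask
  hm2 <- quiet(dermis_surface(shifted, gen$stack$voxel_size_um))
  expect_equal(hm2$depth_um, hm$depth_um + 0.5, tolerance = 1e-12)
})

test_that("euclidean distance equals the exhaustive brute-force oracle", {
  set.seed(404)
  for (rep in 1:4) {
    nz <- sample(4:8, 1); ny <- sample(4:8, 1); nx <- sample(4:8, 1)
    vs <- runif(3, 0.4, 1.6)
    h <- matrix(runif(ny * nx, 0, (nz - 1) * vs[1]), ny, nx)
    got <- distance_to_surface(height_map(h, vs[2:3]), nz, vs)
    want <- brute_force_surface_distance(h, nz, vs)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("distance is the vertical offset for flat surfaces and bounded by it otherwise", {
  h <- matrix(10, 8, 8)
  d <- distance_to_surface(height_map(h, c(1, 1)), 24, c(0.5, 1, 1))
  expect_equal(d[15, 4, 4], 3.0)   # depth 7 µm, +3 µm above the surface
  expect_equal(d[21, 2, 7], 0.0)   # the surface voxel itself
  expect_equal(d[23, 5, 5], -1.0)  # 1 µm into the dermis

  step <- matrix(5, 8, 8); step[, 5:8] <- 15  # steep step surface
  ds <- distance_to_surface(height_map(step, c(1, 1)), 32, c(0.5, 1, 1))
  dv <- distance_to_surface(height_map(step, c(1, 1)), 32, c(0.5, 1, 1),
                            mode = "vertical")
  expect_true(all(abs(ds) <= abs(dv) + 1e-12))
})

test_that("missing surface columns are interpolated with a logged count", {
  h <- matrix(10, 6, 6); h[3, 3] <- NA
  expect_message(d <- distance_to_surface(height_map(h, c(1, 1)), 12, c(0.5, 1, 1)),
                 "interpolated 1 missing")
  expect_equal(d[11, 3, 3], 5)  # depth 5 um; filled to the flat value
})

test_that("a [0,3] band over a flat 10 um surface selects exactly 7 slices", {
  st <- make_flat_stack(depth_um = 10, dz = 0.5, nz = 30)
  st$voxels[1, , , ] <- 0
  zdepth <- (seq_len(30) - 1) * 0.5
  for (z in seq_len(30)) st$voxels[1, z, , ] <- z  # z-coded intensity
  d <- distance_to_surface(height_map(matrix(10, 12, 12), c(1, 1)), 30,
                           c(0.5, 1, 1))
  proj <- extract_band(st, d, layer_band(0, 3), method = "mean",
                       channels = "NADPH")
  # depths 7.0..10.0 um inclusive = z indices 15..21 (7 slices)
  expect_equal(unique(as.vector(proj$n_voxels)), 7L)
  expect_equal(unique(as.vector(proj$channels$NADPH)), mean(15:21))
  # brute-force voxel check of the selected set
  sel_z <- which(zdepth >= 7 & zdepth <= 10)
  expect_equal(sel_z, 15:21)

  # max projection picks the deepest (largest z-code) selected slice
  pm <- extract_band(st, d, layer_band(0, 3), method = "max",
                     channels = "NADPH")
  expect_equal(unique(as.vector(pm$channels$NADPH)), 21)
})

test_that("bands are nested and a sub-dz band touches one slice", {
  st <- make_flat_stack(depth_um = 10, dz = 0.5, nz = 30)
  d <- distance_to_surface(height_map(matrix(10, 12, 12), c(1, 1)), 30,
                           c(0.5, 1, 1))
  for (pair in list(c(1, 2), c(2, 3), c(1, 5))) {
    a <- extract_band(st, d, layer_band(0, pair[1]), channels = "NADPH")
    b <- extract_band(st, d, layer_band(0, pair[2]), channels = "NADPH")
    expect_true(all(a$n_voxels <= b$n_voxels))
  }
  eps <- extract_band(st, d, layer_band(0, 0.25), channels = "NADPH")
  expect_equal(unique(as.vector(eps$n_voxels)), 1L)
  expect_error(extract_band(st, d, layer_band(200, 300)), "outside")
})

test_that("all basal nucleus centroids fall in the nuclear band, none suprabasal", {
  gen <- generate_stack(small_tissue(), noise_free(), mutant_fraction = 0.5,
                        seed = 23)
  st <- gen$stack
  mask <- quiet(collagen_mask(st, "fixed", fixed_threshold = 50))
  hm <- quiet(dermis_surface(mask, st$voxel_size_um))
  d <- distance_to_surface(hm, dim(st$voxels)[2], st$voxel_size_um)
  cells <- gen$truth$cells
  iz <- pmax(1, round(cells$depth_um / 0.5) + 1)
  iy <- pmin(60, pmax(1, round(cells$y_um) + 1))
  ix <- pmin(60, pmax(1, round(cells$x_um) + 1))
  centro_d <- d[cbind(iz, iy, ix)]
  expect_true(all(centro_d >= 0 & centro_d <= 5 + 1e-9))
  # suprabasal voxels (above seam) stay outside the nuclear band
  sel <- band_sel <- d >= 0 & d <= 5
  h3 <- array(rep(as.vector(gen$truth$interface_depth_um$depth_um),
                  each = dim(st$voxels)[2]), dim = dim(d))
  depth3 <- array(rep((seq_len(dim(st$voxels)[2]) - 1) * 0.5,
                      length(as.vector(gen$truth$interface_depth_um$depth_um))),
                  dim = dim(d))
  supra <- depth3 < h3 - 6  # above cell height + seam
  expect_equal(sum(band_sel & supra), 0L)
})
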