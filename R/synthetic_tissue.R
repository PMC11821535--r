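#' Synthetic tissue geometry model
#'
#' Geometry of the emulated telogen epidermis: an undulating dermo-epidermal
#' interface (separable 2D sinusoid, optionally roughened by a low-pass
#' Gaussian random field), a single confluent basal layer of columnar cells on
#' the interface, suprabasal layers above, optional hair-follicle exclusion
#' discs and optional epidermal outgrowths that locally deepen the interface.
#'
#' Basal cells are columnar prisms over a nearest-centre (Voronoi) lateral
#' tessellation with a spherical nucleus; a thin dark seam separates the basal
#' from the suprabasal compartment so that distance bands anchored on the
#' interface cannot capture suprabasal signal on sloped surfaces.
#'
#' @param field_um `(Ly, Lx)` lateral extent in µm (default 300 x 300).
#' @param interface_mean_depth_um Mean interface depth (µm).
#' @param interface_amplitude_um Sinusoid amplitude (µm).
#' @param interface_wavelength_um Sinusoid wavelength (µm).
#' @param interface_roughness_um SD of an optional smoothed Gaussian random
#'   field added to the interface; `0` keeps the surface analytic.
#' @param n_basal_cells Number of basal cells placed on the interface.
#' @param cell_radius_um Nuclear radius; basal cell height is `2 * radius`.
#' @param suprabasal_layers Number of suprabasal layers.
#' @param suprabasal_height_um Height of each suprabasal layer (µm).
#' @param seam_um Dark seam between basal and suprabasal compartments (µm).
#' @param follicle_regions List of `c(y, x, radius)` discs (µm) excluded from
#'   cell placement and flagged for downstream exclusion.
#' @param outgrowths List of `c(y, x, radius, extra_depth_um)` discs where the
#'   interface is pushed `extra_depth_um` deeper (cosine profile).
#' @return A `tissue_model` list.
#' @export
tissue_model <- function(field_um = c(300, 300),
                         interface_mean_depth_um = 20,
                         interface_amplitude_um = 3,
                         interface_wavelength_um = 60,
                         interface_roughness_um = 0,
                         n_basal_cells = 800,
                         cell_radius_um = 2.5,
                         suprabasal_layers = 2,
                         suprabasal_height_um = 4,
                         seam_um = 1,
                         follicle_regions = list(),
                         outgrowths = list()) {
  stopifnot(length(field_um) == 2L, all(field_um > 0),
            interface_mean_depth_um > 0, interface_amplitude_um >= 0,
            interface_wavelength_um > 0, n_basal_cells >= 1,
            cell_radius_um > 0, suprabasal_layers >= 0,
            suprabasal_height_um > 0, seam_um >= 0,
            interface_roughness_um >= 0)
  structure(list(field_um = as.numeric(field_um),
                 interface_mean_depth_um = interface_mean_depth_um,
                 interface_amplitude_um = interface_amplitude_um,
                 interface_wavelength_um = interface_wavelength_um,
                 interface_roughness_um = interface_roughness_um,
                 n_basal_cells = as.integer(n_basal_cells),
                 cell_radius_um = cell_radius_um,
                 suprabasal_layers = as.integer(suprabasal_layers),
                 suprabasal_height_um = suprabasal_height_um,
                 seam_um = seam_um,
                 follicle_regions = follicle_regions,
                 outgrowths = outgrowths),
            class = "tissue_model")
}

#' Synthetic redox and detection-noise model
#'
#' Per-cell NAD(P)H/FAD ratios by genotype, the multiplicative NAD(P)H boost
#' of G1 cells relative to S/G2 (direction reported in vivo; the default 1.1
#' magnitude is a free parameter), and the two-photon detection noise model:
#' Poisson photon noise on scaled intensities followed by additive Gaussian
#' read noise.
#'
#' @param wt_ratio Baseline WT NAD(P)H/FAD ratio (normalized units).
#' @param mutant_ratio_by_day,wt_ratio_by_day Optional named numeric vectors
#'   (names = days) of per-day ratios for timecourses.
#' @param g1_nadph_boost Multiplicative NAD(P)H factor for G1 cells (>= 1).
#' @param phase_fraction_g1 Fraction of basal cells in G1.
#' @param poisson_scale Photons per intensity unit; `0` disables shot noise.
#' @param gaussian_sd Additive read-noise SD (intensity units); `0` disables.
#' @param fad_intensity Mean FAD intensity of basal cytoplasm (a.u.).
#' @param supra_ratio NAD(P)H/FAD ratio of suprabasal cells.
#' @param nuclear_dim Factor applied to both channels inside nuclei (ratio
#'   preserving; nuclei are dimmer than cytoplasm in NAD(P)H images).
#' @param mcherry_intensity Nuclear H2BmCherry intensity of recombined cells.
#' @param shg_intensity Collagen SHG intensity below the interface.
#' @return A `redox_model` list.
#' @export
redox_model <- function(wt_ratio = 1.0,
                        mutant_ratio_by_day = NULL,
                        wt_ratio_by_day = NULL,
                        g1_nadph_boost = 1.1,
                        phase_fraction_g1 = 0.8,
                        poisson_scale = 2,
                        gaussian_sd = 2,
                        fad_intensity = 100,
                        supra_ratio = 0.9,
                        nuclear_dim = 0.6,
                        mcherry_intensity = 120,
                        shg_intensity = 100) {
  stopifnot(wt_ratio > 0, g1_nadph_boost >= 1,
            phase_fraction_g1 >= 0, phase_fraction_g1 <= 1,
            poisson_scale >= 0, gaussian_sd >= 0, fad_intensity > 0,
            supra_ratio > 0, nuclear_dim > 0, nuclear_dim <= 1)
  if (!is.null(mutant_ratio_by_day)) stopifnot(all(mutant_ratio_by_day > 0))
  if (!is.null(wt_ratio_by_day)) stopifnot(all(wt_ratio_by_day > 0))
  structure(list(wt_ratio = wt_ratio,
                 mutant_ratio_by_day = mutant_ratio_by_day,
                 wt_ratio_by_day = wt_ratio_by_day,
                 g1_nadph_boost = g1_nadph_boost,
                 phase_fraction_g1 = phase_fraction_g1,
                 poisson_scale = poisson_scale,
                 gaussian_sd = gaussian_sd,
                 fad_intensity = fad_intensity,
                 supra_ratio = supra_ratio,
                 nuclear_dim = nuclear_dim,
                 mcherry_intensity = mcherry_intensity,
                 shg_intensity = shg_intensity),
            class = "redox_model")
}

#' Noise-free variant of a redox model
#' @param redox A [redox_model()].
#' @return The same model with shot and read noise disabled.
#' @export
noise_free <- function(redox = redox_model()) {
  redox$poisson_scale <- 0
  redox$gaussian_sd <- 0
  redox
}

# interface depth (µm) at pixel centres; pixel i (1-based) sits at (i-1)*d
interface_height <- function(tissue, ny, nx, dy, dx) {
  yy <- (seq_len(ny) - 1) * dy
  xx <- (seq_len(nx) - 1) * dx
  lam <- tissue$interface_wavelength_um
  h <- tissue$interface_mean_depth_um +
    tissue$interface_amplitude_um *
    outer(sin(2 * pi * yy / lam), sin(2 * pi * xx / lam))
  if (tissue$interface_roughness_um > 0) {
    g <- matrix(rnorm(ny * nx), ny, nx)
    g <- as.matrix(EBImage::gblur(EBImage::Image(g), sigma = 8))
    g <- g / sd(g) * tissue$interface_roughness_um
    h <- h + g
  }
  base <- h
  for (og in tissue$outgrowths) {
    r2 <- outer((yy - og[1])^2, (xx - og[2])^2, "+")
    inside <- r2 < og[3]^2
    bump <- og[4] * (cos(pi * sqrt(pmax(r2, 0)) / og[3]) + 1) / 2
    h[inside] <- h[inside] + bump[inside]
  }
  list(h = h, base = base)
}

place_cells <- function(tissue, seed_offset = 0) {
  n <- tissue$n_basal_cells
  Ly <- tissue$field_um[1]; Lx <- tissue$field_um[2]
  spacing <- 1.8 * tissue$cell_radius_um
  sp2 <- spacing^2
  ys <- numeric(n); xs <- numeric(n)
  placed <- 0L
  # grid hashing for the hard-sphere (minimum spacing) rejection test
  cs <- spacing
  gy <- max(1L, ceiling(Ly / cs)); gx <- max(1L, ceiling(Lx / cs))
  grid <- vector("list", gy * gx)
  tries <- 0L; max_tries <- 2000L * n
  in_follicle <- function(y, x) {
    for (fr in tissue$follicle_regions) {
      if ((y - fr[1])^2 + (x - fr[2])^2 < fr[3]^2) return(TRUE)
    }
    FALSE
  }
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    y <- runif(1, 0, Ly); x <- runif(1, 0, Lx)
    if (length(tissue$follicle_regions) && in_follicle(y, x)) next
    cy <- min(gy, 1L + floor(y / cs)); cx <- min(gx, 1L + floor(x / cs))
    ok <- TRUE
    for (ny_ in max(1L, cy - 1L):min(gy, cy + 1L)) {
      for (nx_ in max(1L, cx - 1L):min(gx, cx + 1L)) {
        for (j in grid[[(nx_ - 1L) * gy + ny_]]) {
          if ((y - ys[j])^2 + (x - xs[j])^2 < sp2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    ys[placed] <- y; xs[placed] <- x
    key <- (cx - 1L) * gy + cy
    grid[[key]] <- c(grid[[key]], placed)
  }
  if (placed < n) {
    stop(sprintf("place_cells: could only place %d of %d cells at spacing %.2g um",
                 placed, n, spacing), call. = FALSE)
  }
  tibble::tibble(cell_id = seq_len(n), y_um = ys, x_um = xs)
}

#' Generate a synthetic epidermis stack with exact ground truth
#'
#' Builds a multi-channel stack (NADPH, FAD, MCHERRY, SHG) realizing a known
#' tissue geometry and per-cell redox state, plus a `synthetic_truth` object
#' holding the exact pre-noise values of everything the pipeline measures:
#' interface and air height maps sampled at pixel centres, thickness, per-cell
#' genotype/phase/ratio records, nuclear label and territory maps, and the
#' follicle exclusion mask.
#'
#' A seeded draw without replacement marks exactly
#' `round(mutant_fraction * n_basal_cells)` cells as recombined (mCherry
#' positive). In the noise-free limit every basal voxel of a cell satisfies
#' `NADPH = true_ratio * FAD` exactly, so the full pipeline recovers planted
#' ratios to machine precision.
#'
#' @param tissue A [tissue_model()].
#' @param redox A [redox_model()].
#' @param mutant_fraction Fraction of cells recombined, in \[0, 1\].
#' @param voxel_size_um `(dz, dy, dx)` µm.
#' @param seed RNG seed (all randomness is derived from it).
#' @param timepoint_days,mouse_id,region_id Stack metadata.
#' @param wt_ratio,mutant_ratio Override ratios for this stack; defaults come
#'   from the redox model (per-day maps if present, else `wt_ratio`).
#' @param recombined_genotype Genotype label of mCherry-positive cells:
#'   `"MUTANT"` or `"CONTROL_RECOMBINED"` (control arm).
#' @param nz Optional number of z planes; chosen automatically (interface plus
#'   margin) when `NULL`. An interface deeper than an explicit `nz` errors.
#' @param placement_seed Optional separate seed for geometry, cell placement,
#'   genotypes and phases; revisit timecourses fix it across days so the same
#'   region holds the same cells while detection noise stays independent.
#' @return List with elements `stack` ([image_stack()]) and `truth`.
#' @export
generate_stack <- function(tissue = tissue_model(),
                           redox = redox_model(),
                           mutant_fraction = 0.8,
                           voxel_size_um = c(0.5, 1, 1),
                           seed = 1,
                           timepoint_days = 0,
                           mouse_id = "M1", region_id = "R1",
                           wt_ratio = NULL, mutant_ratio = NULL,
                           recombined_genotype = c("MUTANT", "CONTROL_RECOMBINED"),
                           nz = NULL, placement_seed = NULL) {
  recombined_genotype <- match.arg(recombined_genotype)
  stopifnot(mutant_fraction >= 0, mutant_fraction <= 1)
  set.seed(if (is.null(placement_seed)) seed else placement_seed)
  dz <- voxel_size_um[1]; dy <- voxel_size_um[2]; dx <- voxel_size_um[3]
  ny <- round(tissue$field_um[1] / dy)
  nx <- round(tissue$field_um[2] / dx)

  day_key <- as.character(timepoint_days)
  if (is.null(wt_ratio)) {
    wt_ratio <- if (!is.null(redox$wt_ratio_by_day) &&
                    day_key %in% names(redox$wt_ratio_by_day)) {
      redox$wt_ratio_by_day[[day_key]]
    } else redox$wt_ratio
  }
  if (is.null(mutant_ratio)) {
    mutant_ratio <- if (!is.null(redox$mutant_ratio_by_day) &&
                        day_key %in% names(redox$mutant_ratio_by_day)) {
      redox$mutant_ratio_by_day[[day_key]]
    } else wt_ratio
  }

  hh <- interface_height(tissue, ny, nx, dy, dx)
  h <- hh$h; h_base <- hh$base
  cell_h <- 2 * tissue$cell_radius_um
  epi_total <- cell_h + tissue$seam_um +
    tissue$suprabasal_layers * tissue$suprabasal_height_um
  air <- h_base - epi_total
  if (min(air) < 0) {
    stop("generate_stack: infeasible geometry; epidermis would rise above the first plane",
         call. = FALSE)
  }
  if (is.null(nz)) {
    nz <- ceiling(max(h) / dz) + 4L
  } else if (max(h) > (nz - 1) * dz) {
    stop("generate_stack: infeasible geometry; interface deeper than stack", call. = FALSE)
  }

  cells <- place_cells(tissue)
  n <- nrow(cells)
  n_mut <- round(mutant_fraction * n)
  mut_idx <- if (n_mut > 0) sample.int(n, n_mut) else integer(0)
  cells$recombined <- seq_len(n) %in% mut_idx
  cells$genotype <- ifelse(cells$recombined, recombined_genotype, "WT")
  cells$phase <- ifelse(runif(n) < redox$phase_fraction_g1, "G1", "SG2")
  base_ratio <- ifelse(cells$recombined, mutant_ratio, wt_ratio)
  cells$true_ratio <- base_ratio *
    ifelse(cells$phase == "G1", redox$g1_nadph_boost, 1)

  # lateral pixel grid (µm) and nearest-centre territory tessellation
  py <- rep((seq_len(ny) - 1) * dy, times = nx)
  px <- rep((seq_len(nx) - 1) * dx, each = ny)
  owner <- as.integer(class::knn1(cbind(cells$y_um, cells$x_um),
                                  cbind(py, px),
                                  factor(seq_len(n))))
  territory <- matrix(owner, ny, nx)

  # nucleus discs (2D labels), nearest-centre on overlap
  labels <- matrix(0L, ny, nx)
  bestd2 <- matrix(Inf, ny, nx)
  r <- tissue$cell_radius_um
  for (i in seq_len(n)) {
    iy <- which(abs((seq_len(ny) - 1) * dy - cells$y_um[i]) <= r)
    ix <- which(abs((seq_len(nx) - 1) * dx - cells$x_um[i]) <= r)
    if (!length(iy) || !length(ix)) next
    d2 <- outer(((iy - 1) * dy - cells$y_um[i])^2,
                ((ix - 1) * dx - cells$x_um[i])^2, "+")
    sel <- d2 <= r^2 & d2 < bestd2[iy, ix]
    lab_sub <- labels[iy, ix]; best_sub <- bestd2[iy, ix]
    lab_sub[sel] <- i; best_sub[sel] <- d2[sel]
    labels[iy, ix] <- lab_sub; bestd2[iy, ix] <- best_sub
  }

  # cell centroids: nucleus centre sits one radius above the local interface
  ctr_pix <- cbind(pmin(ny, pmax(1L, round(cells$y_um / dy) + 1L)),
                   pmin(nx, pmax(1L, round(cells$x_um / dx) + 1L)))
  cells$depth_um <- h[ctr_pix] - r

  # volume scaffolding (z fastest)
  depth3 <- array(rep((seq_len(nz) - 1) * dz, ny * nx), dim = c(nz, ny, nx))
  expand <- function(m) array(rep(as.vector(m), each = nz), dim = c(nz, ny, nx))
  H3 <- expand(h)
  A3 <- expand(air)
  R3 <- expand(matrix(cells$true_ratio[owner], ny, nx))

  basal <- depth3 >= H3 - cell_h & depth3 < H3
  supra <- depth3 >= A3 & depth3 < H3 - cell_h - tissue$seam_um
  F0 <- redox$fad_intensity
  fad <- F0 * (basal + supra)
  nadph <- F0 * (R3 * basal + redox$supra_ratio * supra)
  shg <- redox$shg_intensity * (depth3 >= H3)
  rm(depth3, H3, A3, R3, basal, supra)

  # spherical nuclei: dim both channels (ratio preserved); mCherry in
  # recombined nuclei only
  mch <- array(0, dim = c(nz, ny, nx))
  zz_um <- (seq_len(nz) - 1) * dz
  for (i in seq_len(n)) {
    zc <- cells$depth_um[i]
    iz <- which(abs(zz_um - zc) <= r)
    iy <- which(abs((seq_len(ny) - 1) * dy - cells$y_um[i]) <= r)
    ix <- which(abs((seq_len(nx) - 1) * dx - cells$x_um[i]) <= r)
    if (!length(iz) || !length(iy) || !length(ix)) next
    d2 <- outer(outer((zz_um[iz] - zc)^2, ((iy - 1) * dy - cells$y_um[i])^2, "+"),
                ((ix - 1) * dx - cells$x_um[i])^2, "+")
    sphere <- d2 <= r^2
    sub_n <- nadph[iz, iy, ix, drop = FALSE]
    sub_f <- fad[iz, iy, ix, drop = FALSE]
    sub_n[sphere] <- sub_n[sphere] * redox$nuclear_dim
    sub_f[sphere] <- sub_f[sphere] * redox$nuclear_dim
    nadph[iz, iy, ix] <- sub_n
    fad[iz, iy, ix] <- sub_f
    if (cells$recombined[i]) {
      sub_m <- mch[iz, iy, ix, drop = FALSE]
      sub_m[sphere] <- redox$mcherry_intensity
      mch[iz, iy, ix] <- sub_m
    }
  }

  if (!is.null(placement_seed)) set.seed(seed)  # detection noise RNG
  add_noise <- function(v) {
    if (redox$poisson_scale > 0) {
      v <- rpois(length(v), redox$poisson_scale * v) / redox$poisson_scale
    }
    if (redox$gaussian_sd > 0) {
      v <- v + rnorm(length(v), 0, redox$gaussian_sd)
    }
    array(pmax(v, 0), dim = c(nz, ny, nx))
  }
  voxels <- array(0, dim = c(4L, nz, ny, nx))
  voxels[1, , , ] <- add_noise(nadph)
  voxels[2, , , ] <- add_noise(fad)
  voxels[3, , , ] <- add_noise(mch)
  voxels[4, , , ] <- add_noise(shg)
  rm(nadph, fad, mch, shg)

  stack <- image_stack(voxels, voxel_size_um,
                       c("NADPH", "FAD", "MCHERRY", "SHG"),
                       region_id = region_id,
                       timepoint_days = timepoint_days, mouse_id = mouse_id)

  follicle_mask <- matrix(FALSE, ny, nx)
  for (fr in tissue$follicle_regions) {
    r2 <- outer(((seq_len(ny) - 1) * dy - fr[1])^2,
                ((seq_len(nx) - 1) * dx - fr[2])^2, "+")
    follicle_mask <- follicle_mask | (r2 < fr[3]^2)
  }

  truth <- structure(list(
    interface_depth_um = height_map(h, c(dy, dx)),
    air_depth_um = height_map(air, c(dy, dx)),
    thickness_um = height_map(h - air, c(dy, dx)),
    cells = cells,
    labels = labels,
    territory = territory,
    follicle_mask = follicle_mask,
    mutant_fraction = n_mut / n,
    wt_ratio = wt_ratio,
    mutant_ratio = mutant_ratio,
    epidermis_total_um = epi_total,
    seed = seed,
    flux_truth = NULL
  ), class = "synthetic_truth")

  list(stack = stack, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth: %d cells (%.0f%% recombined), interface %g-%g um>\n",
              nrow(x$cells), 100 * x$mutant_fraction,
              min(x$interface_depth_um$depth_um),
              max(x$interface_depth_um$depth_um)))
  invisible(x)
}
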