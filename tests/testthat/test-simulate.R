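# Forward simulator: reproducibility, photoselection ring statistics,
# channel-split consistency, confocal volume helper.

test_that("simulation config validates its inputs", {
  expect_error(simulation_config(nu_deg = 38), "seed")
  expect_error(simulation_config(nu_deg = -5, seed = 1))
  cfg <- simulation_config(
    populations = list(
      list(nu_deg = 10, weight = 2, components = data.frame(tau_ns = 1,
                                                            amplitude = 1)),
      list(nu_deg = 80, weight = 2, components = data.frame(tau_ns = 6,
                                                            amplitude = 1))),
    seed = 1)
  w <- vapply(cfg$populations, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1)
})

test_that("the stack is bit-reproducible under its seed", {
  a <- simulate_guv_stack(small_config(seed = 5, n_bins = 32L))
  b <- simulate_guv_stack(small_config(seed = 5, n_bins = 32L))
  expect_identical(a$stack, b$stack)
  c <- simulate_guv_stack(small_config(seed = 6, n_bins = 32L))
  expect_false(identical(a$stack$raster_par, c$stack$raster_par))
})

test_that("magic-angle ring is azimuthally uniform within 2%", {
  out <- simulate_guv_stack(small_config(nu_deg = magic_angle_deg(),
                                         photons = 2e5, seed = 2,
                                         with_cube = FALSE))
  tot <- total_fluorescence(out$stack$raster_par, out$stack$raster_perp,
                            out$stack$G)
  n <- nrow(tot)
  center <- c((n + 1) / 2, (n + 1) / 2)
  yy <- matrix(rep(seq_len(n) - center[2], each = n), n, n)
  zz <- matrix(rep(center[1] - seq_len(n), times = n), n, n)
  rho <- sqrt(yy^2 + zz^2)
  psi <- atan2(zz, yy)
  ring <- abs(rho - out$truth$radius_px) <= 3
  # 30-degree bins: wide enough that pixel-count discretization of the
  # annulus averages out and the statistic reflects ring intensity itself
  sect <- cut((psi[ring] + pi) %% (2 * pi), breaks = seq(0, 2 * pi,
                                                         length.out = 13))
  per_sector <- tapply(tot[ring], sect, sum)
  expect_lt(stats::sd(per_sector) / mean(per_sector), 0.02)
})

test_that("in-plane dipoles light the pole sectors, not the sides", {
  out <- simulate_guv_stack(small_config(nu_deg = 90, seed = 3,
                                         with_cube = FALSE))
  n <- nrow(out$stack$raster_par)
  geom <- vesicle_geometry(c((n + 1) / 2, (n + 1) / 2), out$truth$radius_px,
                           3, dim_px = c(n, n))
  masks <- build_sector_masks(geom, 20, c(n, n))
  tot <- total_fluorescence(out$stack$raster_par, out$stack$raster_perp,
                            out$stack$G)
  expect_gt(sum(tot[masks$Z_plus | masks$Z_minus]),
            5 * sum(tot[masks$Y_plus | masks$Y_minus]))
})

test_that("simulated channel split reproduces the photoselection law", {
  # background-free so the sector sums are pure ring signal
  out <- simulate_guv_stack(small_config(nu_deg = 38, photons = 5e4, seed = 4,
                                         background_rate = 0,
                                         with_cube = FALSE))
  n <- nrow(out$stack$raster_par)
  geom <- vesicle_geometry(c((n + 1) / 2, (n + 1) / 2), out$truth$radius_px,
                           3, dim_px = c(n, n))
  masks <- build_sector_masks(geom, 20, c(n, n))
  G <- out$stack$G
  for (ax in c("Y", "Z")) {
    m <- masks[[paste0(ax, "_plus")]] | masks[[paste0(ax, "_minus")]]
    F_meas <- sum(out$stack$raster_par[m]) + 2 * G *
      sum(out$stack$raster_perp[m])
    # expected from the generator definition: the Y-sector pair pools
    # photons_per_sector, Z scales by the expected ratio
    F_exp <- 5e4 * if (ax == "Y") 1 else out$truth$expected_R
    sigma <- sqrt(sum(out$stack$raster_par[m]) + 4 * G^2 *
                    sum(out$stack$raster_perp[m]))
    expect_lt(abs(F_meas - F_exp), 3 * sigma)
  }
})

test_that("an isotropic immobile population gives image-wide r = 0.4", {
  out <- simulate_guv_stack(simulation_config(
    populations = list(list(isotropic = TRUE,
                            components = data.frame(tau_ns = 3,
                                                    amplitude = 1))),
    vesicle_diameter_um = 6, photons_per_sector = 2e5, background_rate = 0,
    with_cube = FALSE, seed = 5))
  rmap <- anisotropy_map(out$stack, min_total_counts = 30)
  expect_equal(mean(rmap, na.rm = TRUE), 0.4, tolerance = 0.01 / 0.4)
  expect_equal(out$truth$expected_nu_deg, magic_angle_deg(), tolerance = 1e-6)
})

test_that("effective confocal volume matches the Gaussian form", {
  expect_equal(effective_confocal_volume(140, 734), 0.080, tolerance = 0.002)
  expect_equal(effective_confocal_volume(100, 100), 0.00557,
               tolerance = 1e-5 / 0.00557)
  # quadratic in the lateral radius
  expect_equal(effective_confocal_volume(280, 734) /
                 effective_confocal_volume(140, 734), 4)
  # the naive ellipsoid underestimates the Gaussian volume
  expect_equal(effective_confocal_volume(140, 734, shape = "ellipsoid"),
               4 / 3 * pi * 140^2 * 734 / 1e9)
  expect_error(effective_confocal_volume(-1, 100), "positive")
})

test_that("zero photon budget yields an empty ring", {
  expect_warning(
    out <- simulate_guv_stack(small_config(photons = 0, seed = 1,
                                           background_rate = 0,
                                           with_cube = FALSE)),
    "photon budget")
  expect_equal(sum(out$stack$raster_par) + sum(out$stack$raster_perp), 0)
})
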