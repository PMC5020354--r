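# Closed-form photoselection model: sector absorption factors, ring weight,
# forward/inverse sector-ratio relation, emission channel fractions.

test_that("sector absorption factors match limits, magic angle and MC oracle", {
  expect_equal(absorption_sector_Z(orientation_angle(0)), 0)
  expect_equal(absorption_sector_Z(orientation_angle(90)), 0.5)
  expect_equal(absorption_sector_Y(orientation_angle(0)), 1)
  expect_equal(absorption_sector_Y(orientation_angle(90)), 0)
  expect_equal(absorption_sector_Z(orientation_angle(54.7356)), 1 / 3,
               tolerance = 1e-5)
  expect_equal(absorption_sector_Y(orientation_angle(54.7356)), 1 / 3,
               tolerance = 1e-5)

  # Monte-Carlo azimuth oracle at the magic angle, normal along Z (A_Z) and
  # along Y (A_Y); closed forms must agree within 3 standard errors
  for (psi in c(90, 0)) {
    mu_y <- mc_dipole_draws(54.7356, psi)
    mc <- mean(mu_y^2)
    se <- stats::sd(mu_y^2) / sqrt(length(mu_y))
    closed <- if (psi == 90) absorption_sector_Z(orientation_angle(54.7356))
              else absorption_sector_Y(orientation_angle(54.7356))
    expect_lt(abs(mc - closed), 3 * se + 1e-12)
  }
})

test_that("A_Y + 2 A_Z = 1 on a 0.1-degree grid", {
  nus <- seq(0, 90, by = 0.1)
  total <- vapply(nus, function(nu) {
    o <- orientation_angle(nu)
    absorption_sector_Y(o) + 2 * absorption_sector_Z(o)
  }, numeric(1))
  expect_equal(total, rep(1, length(nus)), tolerance = 1e-12)
})

test_that("ring excitation weight interpolates the sector factors", {
  o <- orientation_angle(38)
  expect_equal(ring_excitation_weight(o, 0), absorption_sector_Y(o))
  expect_equal(ring_excitation_weight(o, 90), absorption_sector_Z(o))
  expect_equal(ring_excitation_weight(orientation_angle(90), 45), 0.25)
  expect_equal(ring_excitation_weight(orientation_angle(0), 45), 0.5)
  # MC oracle with tilted normal
  mu_y <- mc_dipole_draws(38, 33)
  se <- stats::sd(mu_y^2) / sqrt(length(mu_y))
  expect_lt(abs(mean(mu_y^2) - ring_excitation_weight(o, 33)), 3 * se)
})

test_that("ring is uniform exactly at the magic angle", {
  psi <- seq(0, 359.9, by = 0.1)
  w_magic <- ring_excitation_weight(orientation_angle(magic_angle_deg()), psi)
  expect_lt(max(w_magic) - min(w_magic), 1e-12)
  for (nu in c(30, 54, 56, 80)) {
    w <- ring_excitation_weight(orientation_angle(nu), psi)
    expect_gt(max(w) - min(w), 1e-3)
  }
})

test_that("predicted sector ratio: checkpoints and error cases", {
  expect_equal(predicted_sector_ratio(orientation_angle(54.7356), 1, 1), 1,
               tolerance = 1e-4)
  expect_equal(predicted_sector_ratio(orientation_angle(45), 2, 2), 0.5)
  expect_equal(predicted_sector_ratio(orientation_angle(38), 1, 1),
               (1 - cos(38 * pi / 180)^2) / (2 * cos(38 * pi / 180)^2))
  expect_error(predicted_sector_ratio(orientation_angle(90), 1, 1),
               "unbounded")
  expect_error(predicted_sector_ratio(orientation_angle(45), -1, 1))
})

test_that("orientation inversion: checkpoints, round trip, monotonicity", {
  expect_equal(invert_orientation(1, 1, 1)$nu_deg, 54.7356, tolerance = 1e-4)
  expect_equal(invert_orientation(0.5, 1, 1)$nu_deg, 45)
  expect_lt(abs(invert_orientation(1e6, 1, 1)$nu_deg - 90), 0.1)
  expect_error(invert_orientation(-2), "non-physical")
  expect_error(invert_orientation(0), "non-physical")
  expect_error(invert_orientation(1, -1, 1))

  # forward/inverse round trip to 1e-9 relative
  for (T_ratio in c(0.5, 1, 2)) {
    for (nu in seq(1, 89, by = 1)) {
      R <- predicted_sector_ratio(orientation_angle(nu), T_ratio, 1)
      back <- invert_orientation(R, T_ratio, 1)
      expect_equal(back$nu_deg, nu, tolerance = 1e-9)
      expect_equal(predicted_sector_ratio(orientation_angle(back$nu_deg),
                                          T_ratio, 1), R, tolerance = 1e-9)
    }
  }

  # recovered nu strictly increases with R at fixed T
  R_grid <- exp(seq(log(0.01), log(100), length.out = 200))
  nus <- vapply(R_grid, function(R) invert_orientation(R, 1.3, 1)$nu_deg,
                numeric(1))
  expect_true(all(diff(nus) > 0))
})

test_that("Poisson uncertainty propagates through the inversion", {
  res <- invert_orientation(1, 1, 1, F_Z = 1e6, F_Y = 1e6)
  expect_true(is.finite(res$sigma_nu_deg))
  # more photons, less uncertainty
  res_hi <- invert_orientation(1, 1, 1, F_Z = 1e8, F_Y = 1e8)
  expect_lt(res_hi$sigma_nu_deg, res$sigma_nu_deg)
  # numeric check against a finite difference on the ratio
  eps <- 1e-6
  dnu <- (invert_orientation(1 + eps, 1, 1)$nu_deg -
          invert_orientation(1 - eps, 1, 1)$nu_deg) / (2 * eps)
  sigma_R <- 1 * sqrt(2 / 1e6)
  expect_equal(res$sigma_nu_deg, abs(dnu) * sigma_R, tolerance = 1e-4)
})

test_that("beta from fundamental anisotropy matches the r0 relation", {
  expect_equal(beta_from_fundamental_anisotropy(0.4)$beta_deg, 0)
  expect_equal(beta_from_fundamental_anisotropy(0.397)$beta_deg, 4.05,
               tolerance = 0.005)
  expect_equal(beta_from_fundamental_anisotropy(0.1)$beta_deg, 45)
  expect_error(beta_from_fundamental_anisotropy(0.5), "non-physical")
  expect_error(beta_from_fundamental_anisotropy(-0.3), "non-physical")
  # inverse relation: r0 = (3 cos^2 beta - 1)/5
  for (r0 in seq(-0.19, 0.39, by = 0.05)) {
    b <- beta_from_fundamental_anisotropy(r0)$beta_deg * pi / 180
    expect_equal((3 * cos(b)^2 - 1) / 5, r0, tolerance = 1e-12)
  }
})

test_that("polarized emission fractions: limits, isotropic ensemble, beta", {
  # single dipole along Y: fully polarized
  f <- polarized_emission_fractions(orientation_angle(0), 0, 0)
  r <- (f[1] - f[2]) / (f[1] + 2 * f[2])
  expect_equal(unname(r), 1)

  # isotropic immobile ensemble: classic photoselection r = 0.4,
  # cross-checked against a Monte-Carlo over uniformly random dipoles
  fi <- polarized_emission_fractions(isotropic = TRUE)
  ri <- unname((fi[1] - fi[2]) / (fi[1] + 2 * fi[2]))
  expect_equal(ri, 0.4, tolerance = 1e-12)
  mu_y <- mc_dipole_draws(NA, NA, isotropic = TRUE)
  f_par_mc <- mean(mu_y^4)
  f_perp_mc <- mean(mu_y^2 * (1 - mu_y^2)) / 2
  se <- stats::sd(mu_y^4) / sqrt(length(mu_y))
  expect_lt(abs(f_par_mc - fi[["f_parallel"]]), 3 * se)
  expect_lt(abs(f_perp_mc - fi[["f_perpendicular"]]), 3 * se)

  # a beta cone between absorption and emission reproduces the fundamental
  # anisotropy law on the isotropic ensemble
  for (beta in c(0, 4.05, 20, 45)) {
    fb <- polarized_emission_fractions(isotropic = TRUE, beta_deg = beta)
    rb <- unname((fb[1] - fb[2]) / (fb[1] + 2 * fb[2]))
    expect_equal(rb, (3 * cos(beta * pi / 180)^2 - 1) / 5, tolerance = 1e-12)
  }
})

test_that("channel fractions conserve the ring excitation law at beta = 0", {
  for (nu in c(10, 38, 54.7356, 75, 90)) {
    for (psi in c(0, 20, 45, 90, 135)) {
      f <- polarized_emission_fractions(orientation_angle(nu), psi)
      expect_equal(unname(f[1] + 2 * f[2]),
                   ring_excitation_weight(orientation_angle(nu), psi),
                   tolerance = 1e-9)
    }
  }
})

test_that("anisotropy contrast between side and pole sectors flips with nu", {
  r_at <- function(nu, psi) {
    f <- polarized_emission_fractions(orientation_angle(nu), psi)
    unname((f[1] - f[2]) / (f[1] + 2 * f[2]))
  }
  # below the magic angle (mostly vertical dipoles): side sectors brighter in r
  expect_gt(r_at(38, 0), r_at(38, 90))
  # above it (in-plane dipoles): pole sectors carry the higher anisotropy
  expect_lt(r_at(75, 0), r_at(75, 90))
})
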