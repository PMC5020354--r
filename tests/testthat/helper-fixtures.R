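# Small, fast fixture builders shared across test files. A 6-um vesicle at
# 0.1 um/px keeps the raster at 90x90 while preserving the ring/aperture
# geometry of the full-size (17 um) study conditions.

small_config <- function(nu_deg = 38, seed = 1, photons = 5e4, ...) {
  simulation_config(nu_deg = nu_deg, vesicle_diameter_um = 6,
                    photons_per_sector = photons, seed = seed, ...)
}

magic_angle_deg <- function() acos(sqrt(1 / 3)) * 180 / pi

# Monte-Carlo oracle: azimuth-averaged moments of the dipole projection on
# the polarization axis Y, for dipoles on a cone of angle nu about the
# membrane normal at ring position psi (both degrees). Returns draws of
# (mu_y^2, q_par, q_perp) so callers can form means and standard errors.
mc_dipole_draws <- function(nu_deg, psi_deg, n = 1e6, seed = 42,
                            isotropic = FALSE) {
  set.seed(seed)
  if (isotropic) {
    # uniform on the sphere
    u <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    mu_y <- s * cos(phi)
  } else {
    nu <- nu_deg * pi / 180
    psi <- psi_deg * pi / 180
    phi <- stats::runif(n, 0, 2 * pi)
    # normal n = (0, cos psi, sin psi); basis e1 = X, e2 = n x e1
    mu_y <- cos(nu) * cos(psi) + sin(nu) * sin(phi) * sin(psi)
  }
  mu_y
}

# deterministic temp dir for I/O tests
test_tempdir <- function(sub = "guvflim-tests") {
  d <- file.path(tempdir(), sub)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

pixel_dist <- function(n, center) {
  yy <- matrix(rep(seq_len(n) - center[2], each = n), n, n)
  zz <- matrix(rep(center[1] - seq_len(n), times = n), n, n)
  sqrt(yy^2 + zz^2)
}
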