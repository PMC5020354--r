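# Photoselection model for dipoles on a cone about the local membrane normal.
#
# Laboratory frame: X is the optical (detection) axis, the image plane is ZOY,
# the excitation field E is polarized along Y. The membrane normal at ring
# position psi (measured from the Y axis in the image plane) is
# n = (0, cos psi, sin psi). Transition dipoles sit at a fixed polar angle nu
# from n with uniform azimuth (in-plane rotational symmetry of the bilayer).

#' Dipole orientation angle
#'
#' Angle `nu` between the transition dipole and the local membrane normal,
#' stored in degrees together with its squared cosine. Cone symmetry makes
#' `nu` and `180 - nu` indistinguishable, so `nu` lives in \[0, 90\].
#'
#' @param nu_deg angle in degrees, in \[0, 90\].
#' @return An object of class `orientation_angle` with fields `nu_deg` and
#'   `cos2nu`.
#' @examples
#' orientation_angle(54.7356)$cos2nu  # 1/3, the magic angle
#' @export
orientation_angle <- function(nu_deg) {
  stopifnot(is.numeric(nu_deg), length(nu_deg) == 1L, is.finite(nu_deg))
  if (nu_deg < 0 || nu_deg > 90)
    stop("nu_deg must lie in [0, 90] (cone symmetry folds larger angles back)")
  structure(
    list(nu_deg = nu_deg, cos2nu = cospi(nu_deg / 180)^2),
    class = "orientation_angle"
  )
}

as_orientation_angle <- function(x) {
  if (inherits(x, "orientation_angle")) x else orientation_angle(x)
}

#' Absorption factor of the Z-spanned membrane sectors
#'
#' Relative light absorption of the membrane fragments perpendicular to the
#' image Z axis (top/bottom of the ring), for excitation polarized along Y.
#' There the membrane normal is along Z, so the dipole Y-component is
#' `sin(nu) sin(phi)`; averaging the squared projection over the uniform
#' azimuth replaces `sin^2(phi)` by 1/2, giving `A_Z = (1 - cos^2 nu)/2`.
#'
#' @param orient an [orientation_angle()] (or a bare angle in degrees).
#' @return Dimensionless absorption factor in \[0, 0.5\].
#' @export
absorption_sector_Z <- function(orient) {
  orient <- as_orientation_angle(orient)
  0.5 * (1 - orient$cos2nu)
}

#' Absorption factor of the Y-spanned membrane sectors
#'
#' Relative absorption of the fragments perpendicular to the Y axis
#' (left/right of the ring), where the membrane normal is parallel to the
#' excitation polarization: `A_Y = cos^2 nu`. For every `nu`,
#' `A_Y + 2 A_Z = 1`.
#'
#' @inheritParams absorption_sector_Z
#' @return Dimensionless absorption factor in \[0, 1\].
#' @export
absorption_sector_Y <- function(orient) {
  orient <- as_orientation_angle(orient)
  orient$cos2nu
}

#' Photoselection weight at an arbitrary ring position
#'
#' Continuous generalization of [absorption_sector_Y()] and
#' [absorption_sector_Z()] to any position on the equatorial ring:
#' `w(nu, psi) = cos^2(nu) cos^2(psi) + sin^2(nu) sin^2(psi) / 2`,
#' where `psi` is the angle between the local membrane normal and the Y axis.
#' At the magic angle (`cos^2 nu = 1/3`) the ring is uniform.
#'
#' @inheritParams absorption_sector_Z
#' @param psi_deg ring position angle(s) from the Y axis, degrees (vectorized).
#' @return Dimensionless excitation weight(s), same length as `psi_deg`.
#' @export
ring_excitation_weight <- function(orient, psi_deg) {
  orient <- as_orientation_angle(orient)
  stopifnot(is.numeric(psi_deg), all(is.finite(psi_deg)))
  psi <- psi_deg * pi / 180
  c2 <- orient$cos2nu
  c2 * cos(psi)^2 + 0.5 * (1 - c2) * sin(psi)^2
}

#' Predicted Z/Y sector fluorescence ratio
#'
#' Forward model of the measured ratio `R = F_Z / F_Y`. Sector fluorescence is
#' proportional to absorption times the amplitude-averaged lifetime of that
#' sector (quantum-yield weighting), so
#' `R = (tau_Z / tau_Y) * (1 - cos^2 nu) / (2 cos^2 nu)`.
#'
#' @inheritParams absorption_sector_Z
#' @param tau_Z_ns,tau_Y_ns amplitude-averaged lifetimes of the Z and Y sector
#'   pairs, ns.
#' @return Dimensionless ratio `R > 0`.
#' @export
predicted_sector_ratio <- function(orient, tau_Z_ns = 1, tau_Y_ns = 1) {
  orient <- as_orientation_angle(orient)
  stopifnot(tau_Z_ns > 0, tau_Y_ns > 0)
  if (orient$cos2nu <= 0)
    stop("nu = 90 deg: in-plane dipoles give an unbounded sector ratio")
  (tau_Z_ns / tau_Y_ns) * (1 - orient$cos2nu) / (2 * orient$cos2nu)
}

#' Invert a measured sector ratio to the dipole orientation angle
#'
#' Solves the forward model for `nu`: with `T = tau_Z / tau_Y`,
#' `cos^2 nu = T / (2 R + T)` and `nu = arccos(sqrt(cos^2 nu))`.
#' When the pooled sector counts `F_Z`, `F_Y` are supplied, a first-order
#' delta-method uncertainty from their Poisson variance is propagated to `nu`.
#'
#' @param ratio_R measured `F_Z / F_Y`, must be positive.
#' @param tau_Z_ns,tau_Y_ns amplitude-averaged sector lifetimes, ns.
#' @param F_Z,F_Y optional pooled sector counts used for the Poisson
#'   uncertainty; `NULL` leaves `sigma_nu_deg` as `NA`.
#' @return An object of class `orientation_result` with fields `nu_deg`,
#'   `cos2nu`, `ratio_R`, `lifetime_ratio_T`, `sigma_nu_deg`.
#' @examples
#' invert_orientation(1, 1, 1)$nu_deg  # magic angle, 54.74 deg
#' @export
invert_orientation <- function(ratio_R, tau_Z_ns = 1, tau_Y_ns = 1,
                               F_Z = NULL, F_Y = NULL) {
  if (!is.numeric(ratio_R) || length(ratio_R) != 1L || !is.finite(ratio_R) ||
      ratio_R <= 0)
    stop("non-physical sector ratio: ratio_R must be a positive number")
  if (!is.finite(tau_Z_ns) || !is.finite(tau_Y_ns) ||
      tau_Z_ns <= 0 || tau_Y_ns <= 0)
    stop("sector lifetimes must be positive")
  T_ratio <- tau_Z_ns / tau_Y_ns
  cos2 <- T_ratio / (2 * ratio_R + T_ratio)
  nu <- acos(sqrt(cos2)) * 180 / pi

  sigma <- NA_real_
  if (!is.null(F_Z) && !is.null(F_Y) && F_Z > 0 && F_Y > 0) {
    sigma_R <- ratio_R * sqrt(1 / F_Z + 1 / F_Y)
    dcos2_dR <- -2 * T_ratio / (2 * ratio_R + T_ratio)^2
    dnu_dcos2 <- if (cos2 > 0 && cos2 < 1)
      -1 / (2 * sqrt(cos2 * (1 - cos2))) else Inf
    sigma <- abs(dnu_dcos2 * dcos2_dR) * sigma_R * 180 / pi
  }

  structure(
    list(nu_deg = nu, cos2nu = cos2, ratio_R = ratio_R,
         lifetime_ratio_T = T_ratio, sigma_nu_deg = sigma),
    class = "orientation_result"
  )
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("orientation: nu = %.2f deg (cos^2 nu = %.4f)\n",
              x$nu_deg, x$cos2nu))
  cat(sprintf("  sector ratio R = %.4f, lifetime ratio T = %.4f", x$ratio_R,
              x$lifetime_ratio_T))
  if (is.finite(x$sigma_nu_deg))
    cat(sprintf(", sigma_nu = %.2f deg", x$sigma_nu_deg))
  cat("\n")
  invisible(x)
}

#' Absorption-emission dipole angle from the fundamental anisotropy
#'
#' The fundamental anisotropy of an immobile, randomly oriented ensemble is
#' `r0 = (3 cos^2 beta - 1)/5`, where `beta` is the angle between the
#' absorption and emission transition dipoles. This inverts that relation:
#' `beta = arccos(sqrt((5 r0 + 1)/3))`.
#'
#' @param r0 fundamental anisotropy, in \[-0.2, 0.4\].
#' @return An object of class `emission_dipole_offset` with `beta_deg`, `r0`.
#' @examples
#' beta_from_fundamental_anisotropy(0.397)$beta_deg  # 4.05 deg
#' @export
beta_from_fundamental_anisotropy <- function(r0) {
  stopifnot(is.numeric(r0), length(r0) == 1L, is.finite(r0))
  if (r0 < -0.2 || r0 > 0.4)
    stop("non-physical fundamental anisotropy: r0 must lie in [-0.2, 0.4]")
  cos2b <- min(1, max(0, (5 * r0 + 1) / 3))
  structure(
    list(beta_deg = acos(sqrt(cos2b)) * 180 / pi, r0 = r0),
    class = "emission_dipole_offset"
  )
}

# Azimuth-averaged second moments of the dipole projection at ring position
# psi. For dipoles at polar angle nu about n = (0, cos psi, sin psi) with
# uniform azimuth phi: mu_y = cos nu cos psi + sin nu sin phi sin psi. The
# integrands are trigonometric polynomials of degree <= 4 in phi, so an
# N-point periodic midpoint rule with N >= 8 integrates them exactly; N = 64
# leaves only rounding error (far below the 1e-6 contract).
azimuth_moments <- function(cos2nu, psi_rad, n_quad = 64L) {
  phi <- (seq_len(n_quad) - 0.5) * 2 * pi / n_quad
  cn <- sqrt(cos2nu)
  sn <- sqrt(1 - cos2nu)
  mu_y <- cn * cos(psi_rad) + sn * sin(phi) * sin(psi_rad)
  m2 <- mean(mu_y^2)
  m4 <- mean(mu_y^4)
  c(m2 = m2, m4 = m4)
}

#' Relative polarized emission channel intensities
#'
#' Azimuth-averaged photoselected emission split between the analyzer parallel
#' (Y) and perpendicular (Z) detection channels, for dipoles at cone angle
#' `nu` about the membrane normal at ring position `psi`. Excitation weight is
#' `(mu . Y)^2`; the emission dipole is averaged over a cone of half-angle
#' `beta` about the absorption dipole. Detection is modelled as
#' transverse-isotropic (the same assumption that makes
#' `F_par + 2 G F_perp` the total intensity): the perpendicular channel
#' carries the mean of the two emission components orthogonal to Y, so
#' `f_parallel + 2 f_perpendicular` equals [ring_excitation_weight()] exactly
#' when `beta = 0`.
#'
#' @inheritParams ring_excitation_weight
#' @param psi_deg ring position angle from the Y axis, degrees (scalar).
#' @param beta_deg absorption-emission dipole angle, degrees (default 0,
#'   collinear dipoles).
#' @param isotropic if `TRUE`, average the orientation uniformly over the
#'   sphere instead of a cone (`orient`/`psi_deg` are then ignored); this is
#'   the classic photoselection ensemble with anisotropy 0.4 at `beta = 0`.
#' @return Named numeric vector `c(f_parallel, f_perpendicular)`.
#' @export
polarized_emission_fractions <- function(orient = NULL, psi_deg = 0,
                                         beta_deg = 0, isotropic = FALSE) {
  stopifnot(beta_deg >= 0, beta_deg <= 90)
  cb2 <- cos(beta_deg * pi / 180)^2
  # cone average about mu: <(mu_em . u)^2> = cb2 (mu.u)^2 + (1-cb2)/2 (1-(mu.u)^2)
  if (isotropic) {
    # uniform mu on the sphere: <mu_y^2> = 1/3, <mu_y^4> = 1/5
    m2 <- 1 / 3
    m4 <- 1 / 5
  } else {
    orient <- as_orientation_angle(orient)
    stopifnot(is.numeric(psi_deg), length(psi_deg) == 1L,
              psi_deg >= 0, psi_deg < 360)
    m <- azimuth_moments(orient$cos2nu, psi_deg * pi / 180)
    m2 <- m[["m2"]]
    m4 <- m[["m4"]]
  }
  # f_par = <mu_y^2 * q>, q = cb2 mu_y^2 + (1-cb2)(1-mu_y^2)/2
  f_par <- cb2 * m4 + 0.5 * (1 - cb2) * (m2 - m4)
  # f_perp: mean transverse component, (excitation - parallel emission)/2
  f_perp <- 0.5 * (m2 - f_par)
  c(f_parallel = f_par, f_perpendicular = f_perp)
}
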