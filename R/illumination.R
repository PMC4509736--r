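# Excitation fields: TIRF evanescent decay behind a totally internally
# reflecting glass/water interface, and the focused Gaussian beam of a
# point-scanning confocal.

#' TIRF illumination configuration
#'
#' Objective-type TIRF: a beam of flux density `phi` strikes the
#' glass (refractive index `n1`) / sample (`n2`) interface at a supercritical
#' angle `theta`, generating an evanescent field that decays exponentially
#' with depth z. Defaults describe a typical 532 nm TIRF setup
#' (n1 = 1.52 glass, n2 = 1.33 water, theta = 70 deg, s-polarized).
#'
#' @param phi_W_per_cm2 Incident beam flux density in W/cm^2 (>= 0).
#' @param lambda_nm Excitation wavelength in nm.
#' @param theta_deg Incidence angle in degrees; must exceed the critical
#'   angle `asin(n2/n1)`.
#' @param n1,n2 Refractive indices, glass and sample side (`n1 > n2 > 0`).
#' @param polarization `"s"`, `"p"` or `"mixed"`.
#' @param fraction_s For `"mixed"`, the s-polarized intensity fraction.
#' @return A `tirf_illumination` object.
#' @export
tirf_illumination <- function(phi_W_per_cm2 = 20, lambda_nm = 532,
                              theta_deg = 70, n1 = 1.52, n2 = 1.33,
                              polarization = c("s", "p", "mixed"),
                              fraction_s = 0.5) {
  polarization <- match.arg(polarization)
  if (phi_W_per_cm2 < 0) stop_arg("'phi_W_per_cm2' must be >= 0")
  if (!(n1 > n2 && n2 > 0)) stop_arg("need n1 > n2 > 0")
  theta_c <- asin(n2 / n1) * 180 / pi
  if (theta_deg <= theta_c)
    stop_arg(sprintf(
      "incidence angle %.3f deg is not supercritical (critical angle %.3f deg)",
      theta_deg, theta_c))
  if (fraction_s < 0 || fraction_s > 1) stop_arg("'fraction_s' must be in [0,1]")
  structure(list(phi_W_per_cm2 = phi_W_per_cm2, lambda_nm = lambda_nm,
                 theta_deg = theta_deg, n1 = n1, n2 = n2,
                 polarization = polarization, fraction_s = fraction_s),
            class = "tirf_illumination")
}

#' @export
print.tirf_illumination <- function(x, ...) {
  cat(sprintf(
    "<tirf_illumination> %g W/cm2 @ %g nm, theta=%g deg (%s-pol), n1=%g n2=%g\n",
    x$phi_W_per_cm2, x$lambda_nm, x$theta_deg, x$polarization, x$n1, x$n2))
  cat(sprintf("  penetration depth d = %.4f um\n", penetration_depth(x)))
  invisible(x)
}

#' Evanescent-field penetration depth
#'
#' `d = lambda / (4 pi sqrt(n1^2 sin^2(theta) - n2^2))`: the depth over which
#' the evanescent intensity decays by 1/e.
#'
#' @param ill A [tirf_illumination()].
#' @return Penetration depth in micrometres.
#' @export
penetration_depth <- function(ill) {
  stopifnot(inherits(ill, "tirf_illumination"))
  th <- ill$theta_deg * pi / 180
  disc <- ill$n1^2 * sin(th)^2 - ill$n2^2
  if (disc <= 0)
    stop_arg(sprintf("subcritical angle (critical angle %.3f deg)",
                     asin(ill$n2 / ill$n1) * 180 / pi))
  (ill$lambda_nm * 1e-3) / (4 * pi * sqrt(disc))
}

# Interface intensity-enhancement factor of the evanescent field at z = 0
# relative to the incident intensity (Axelrod's TIR formulas), per
# polarization. n = n2/n1.
tir_enhancement <- function(theta_deg, n1, n2, polarization, fraction_s = 0.5) {
  th <- theta_deg * pi / 180
  n <- n2 / n1
  Ts <- 4 * cos(th)^2 / (1 - n^2)
  Tp <- 4 * cos(th)^2 * (2 * sin(th)^2 - n^2) /
    (n^4 * cos(th)^2 + sin(th)^2 - n^2)
  switch(polarization,
         s = Ts, p = Tp,
         mixed = fraction_s * Ts + (1 - fraction_s) * Tp)
}

#' Evanescent excitation flux density at depth z
#'
#' `|A_T(z)|^2 = T_pol(theta, n1, n2) * |A_I|^2 * exp(-z / d)` where
#' `|A_I|^2` is the incident photon flux density ([incident_flux_density()]),
#' `T_pol` the polarization-dependent interface intensity-enhancement factor
#' and `d` the penetration depth.
#'
#' @param ill A [tirf_illumination()].
#' @param z_um Depth(s) above the coverslip in micrometres (>= 0).
#' @return Photon flux density in photons s^-1 cm^-2.
#' @export
evanescent_flux_density <- function(ill, z_um) {
  stopifnot(inherits(ill, "tirf_illumination"))
  if (any(z_um < 0)) stop_arg("'z_um' must be >= 0")
  d <- penetration_depth(ill)
  Tpol <- tir_enhancement(ill$theta_deg, ill$n1, ill$n2,
                          ill$polarization, ill$fraction_s)
  Tpol * incident_flux_density(ill$phi_W_per_cm2, ill$lambda_nm) *
    exp(-z_um / d)
}

#' LSCM illumination configuration
#'
#' The scanning laser is modeled as an ideal Gaussian beam of power `Phi`
#' focused to waist radius `w0` at the focal plane (flat wavefront at focus;
#' intensity-only model, no Gouy phase). If `w0_um` is omitted, the
#' diffraction-limited waist `lambda / (pi NA)` is used.
#'
#' @param Phi_W Beam power in W (>= 0).
#' @param lambda_nm Excitation wavelength in nm.
#' @param w0_um Beam waist radius at the focal plane in micrometres.
#' @param n Sample refractive index.
#' @param na Numerical aperture, only used to default `w0_um`.
#' @return An `lscm_illumination` object.
#' @export
lscm_illumination <- function(Phi_W = 5e-6, lambda_nm = 488, w0_um = NULL,
                              n = 1.33, na = NULL) {
  if (Phi_W < 0) stop_arg("'Phi_W' must be >= 0")
  if (is.null(w0_um)) {
    if (is.null(na)) stop_arg("give 'w0_um' or 'na' to derive it")
    w0_um <- (lambda_nm * 1e-3) / (pi * na)
  }
  if (w0_um <= 0) stop_arg("'w0_um' must be positive")
  structure(list(Phi_W = Phi_W, lambda_nm = lambda_nm, w0_um = w0_um, n = n),
            class = "lscm_illumination")
}

#' @export
print.lscm_illumination <- function(x, ...) {
  cat(sprintf("<lscm_illumination> %.3g W @ %g nm, w0=%.3g um, n=%g\n",
              x$Phi_W, x$lambda_nm, x$w0_um, x$n))
  cat(sprintf("  Rayleigh range z_R = %.4f um\n", rayleigh_range(x)))
  invisible(x)
}

#' Gaussian beam geometry
#'
#' `rayleigh_range` returns `z_R = pi w0^2 n / lambda`;
#' `gaussian_beam_waist` returns `w(z) = w0 sqrt(1 + (z/z_R)^2)`.
#'
#' @param ill An [lscm_illumination()].
#' @param z_um Axial offset(s) from the focal plane in micrometres.
#' @return Micrometres.
#' @export
gaussian_beam_waist <- function(ill, z_um) {
  stopifnot(inherits(ill, "lscm_illumination"))
  ill$w0_um * sqrt(1 + (z_um / rayleigh_range(ill))^2)
}

#' @rdname gaussian_beam_waist
#' @export
rayleigh_range <- function(ill) {
  stopifnot(inherits(ill, "lscm_illumination"))
  pi * ill$w0_um^2 * ill$n / (ill$lambda_nm * 1e-3)
}

#' Gaussian-beam excitation flux density
#'
#' The transmitted beam flux density of the scanned confocal beam:
#' \deqn{I(r, z) = \frac{2 P'}{\pi w(z)^2} \exp(-2 r^2 / w(z)^2)}
#' with `P'` the photon flux ([incident_flux()]). The transverse integral of
#' `I` equals `P'` at every z (power conservation).
#'
#' @param ill An [lscm_illumination()].
#' @param r_um Radial offset(s) from the beam axis in micrometres.
#' @param z_um Axial offset(s) from the focal plane in micrometres.
#' @return Photon flux density in photons s^-1 cm^-2.
#' @export
gaussian_flux_density <- function(ill, r_um, z_um) {
  stopifnot(inherits(ill, "lscm_illumination"))
  Pp <- incident_flux(ill$Phi_W, ill$lambda_nm)
  w <- gaussian_beam_waist(ill, z_um)
  w_cm <- w * 1e-4
  2 * Pp / (pi * w_cm^2) * exp(-2 * r_um^2 / w^2)
}
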