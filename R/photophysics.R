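# Photon-budget arithmetic: energy per photon, flux conversions, expected
# per-fluorophore emission, spectral filter survival. All quantities are kept
# in photon-counting units so every later pixel value is traceable.

PLANCK_H <- 6.62607015e-34    # J s (CODATA)
SPEED_OF_LIGHT <- 2.99792458e8  # m/s

#' Energy of a single photon
#'
#' `E = h c / lambda` with CODATA constants.
#'
#' @param lambda_nm Wavelength in nm (> 0); vectorized.
#' @return Photon energy in joules.
#' @examples
#' photon_energy(532)  # ~3.73e-19 J
#' @export
photon_energy <- function(lambda_nm) {
  if (any(lambda_nm <= 0)) stop_arg("'lambda_nm' must be positive")
  PLANCK_H * SPEED_OF_LIGHT / (lambda_nm * 1e-9)
}

#' Convert beam power density to photon flux density
#'
#' A beam of flux density `phi` (W/cm^2) at wavelength `lambda` carries
#' `phi / (h c / lambda)` photons per second per cm^2 — the incident photon
#' flux density \eqn{|A_I|^2}.
#'
#' @param phi_W_per_cm2 Beam flux density in W/cm^2 (>= 0).
#' @param lambda_nm Wavelength in nm.
#' @return Photon flux density in photons s^-1 cm^-2.
#' @export
incident_flux_density <- function(phi_W_per_cm2, lambda_nm) {
  if (any(phi_W_per_cm2 < 0)) stop_arg("'phi_W_per_cm2' must be >= 0")
  phi_W_per_cm2 / photon_energy(lambda_nm)
}

#' Convert beam power to photon flux
#'
#' For a focused beam of total power `Phi` (W), the photon flux is
#' `Phi / (h c / lambda)` photons per second (the confocal quantity P').
#'
#' @param Phi_W Beam power in W (>= 0).
#' @param lambda_nm Wavelength in nm.
#' @return Photon flux in photons/s.
#' @export
incident_flux <- function(Phi_W, lambda_nm) {
  if (any(Phi_W < 0)) stop_arg("'Phi_W' must be >= 0")
  Phi_W / photon_energy(lambda_nm)
}

#' Expected photons emitted by one fluorophore
#'
#' The expected emission during a dwell/exposure `dT` under local excitation
#' photon flux density `F` is
#' \deqn{n_{emit} = \frac{\sigma \, \delta T}{4\pi} \, F \times c_{conv}}
#' where `sigma` is the absorption cross-section, `c_conv` the
#' photon-conversion factor (default 1e-6: one emitted photon per million
#' absorbed), and the division by the unit sphere surface `4 pi` accounts for
#' the detector sitting in one specific direction. The same arithmetic serves
#' TIRF (evanescent flux density at the molecule's depth) and LSCM (Gaussian
#' beam flux density at the molecule's position).
#'
#' @param flux_density Excitation photon flux density at the molecule, in
#'   photons s^-1 cm^-2 (vectorized).
#' @param species A [fluorophore()].
#' @param dT Detection time (exposure or per-pixel scan dwell) in seconds.
#' @param collection_efficiency Optional multiplicative factor (default 1)
#'   to fold in objective solid-angle collection without changing the model.
#' @return Expected photon count(s), real and >= 0.
#' @export
expected_emission <- function(flux_density, species, dT,
                              collection_efficiency = 1) {
  stopifnot(inherits(species, "fluorophore"))
  if (dT <= 0) stop_arg("'dT' must be positive")
  if (any(flux_density < 0)) stop_arg("'flux_density' must be >= 0")
  if (collection_efficiency <= 0) stop_arg("'collection_efficiency' must be > 0")
  species$cross_section_cm2 * dT / (4 * pi) * flux_density *
    species$conversion_factor * collection_efficiency
}

#' Spectral filter survival
#'
#' Applies the combined dichroic-mirror and emission-filter transmission:
#' with the default species settings, 55% of emitted photons survive.
#'
#' @param n_emit Expected emitted photons (>= 0, vectorized).
#' @param species A [fluorophore()].
#' @return Photons surviving the filter stage.
#' @export
apply_filter_transmission <- function(n_emit, species) {
  stopifnot(inherits(species, "fluorophore"))
  if (any(n_emit < 0)) stop_arg("'n_emit' must be >= 0")
  n_emit * species$filter_transmission
}
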