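#' Define a fluorophore species
#'
#' A fluorophore species bundles the photophysical constants the photon-budget
#' arithmetic needs: the excitation and emission wavelengths, the
#' photon-molecule interaction cross-section, the photon-conversion factor
#' (one emitted photon per million absorbed, by default) and the combined
#' dichroic-mirror/emission-filter transmission.
#'
#' @param name Species name used in trajectory tables, e.g. `"HaloTag-TMR"`.
#' @param excitation_nm Excitation wavelength in nm (> 0).
#' @param emission_nm Emission ("optimal") wavelength in nm (> 0); this is the
#'   wavelength at which the point spread function is evaluated.
#' @param cross_section_cm2 Absorption cross-section in cm^2; the default
#'   1e-14 cm^2 is a typical order of magnitude for small organic dyes.
#' @param conversion_factor Dimensionless photon-conversion factor: emitted
#'   photons per absorbed photon. Default 1e-6 (one emission per million
#'   absorptions).
#' @param filter_transmission Fraction of emitted photons surviving the
#'   dichroic mirror and emission filter, in \[0, 1\]. Default 0.55.
#' @return An object of class `fluorophore`.
#' @seealso [default_species_catalog()], [expected_emission()]
#' @examples
#' tmr <- fluorophore("HaloTag-TMR", 532, 578)
#' tmr
#' @export
fluorophore <- function(name, excitation_nm, emission_nm,
                        cross_section_cm2 = 1e-14,
                        conversion_factor = 1e-6,
                        filter_transmission = 0.55) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_arg("'name' must be a non-empty string")
  if (excitation_nm <= 0 || emission_nm <= 0)
    stop_arg("wavelengths must be positive")
  if (cross_section_cm2 <= 0)
    stop_arg("'cross_section_cm2' must be positive")
  if (conversion_factor <= 0)
    stop_arg("'conversion_factor' must be positive")
  if (filter_transmission < 0 || filter_transmission > 1)
    stop_arg("'filter_transmission' must be in [0, 1]")
  structure(
    list(name = name,
         excitation_nm = as.numeric(excitation_nm),
         emission_nm = as.numeric(emission_nm),
         cross_section_cm2 = as.numeric(cross_section_cm2),
         conversion_factor = as.numeric(conversion_factor),
         filter_transmission = as.numeric(filter_transmission)),
    class = "fluorophore")
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf("<fluorophore> %s\n", x$name))
  cat(sprintf("  excitation %g nm, emission %g nm\n",
              x$excitation_nm, x$emission_nm))
  cat(sprintf("  cross-section %.3g cm^2, conversion %.3g, filter %.0f%%\n",
              x$cross_section_cm2, x$conversion_factor,
              100 * x$filter_transmission))
  invisible(x)
}

#' Build a species catalog
#'
#' A species catalog is a named list of [fluorophore()] objects keyed by
#' species name; trajectory rows reference species through it.
#'
#' @param ... `fluorophore` objects.
#' @return A named list of class `species_catalog`.
#' @export
species_catalog <- function(...) {
  sp <- list(...)
  if (length(sp) == 1L && is.list(sp[[1L]]) && !inherits(sp[[1L]], "fluorophore"))
    sp <- sp[[1L]]
  ok <- vapply(sp, inherits, logical(1), "fluorophore")
  if (!all(ok)) stop_arg("all catalog entries must be 'fluorophore' objects")
  names(sp) <- vapply(sp, `[[`, character(1), "name")
  structure(sp, class = "species_catalog")
}

#' Default species catalog
#'
#' Contains the two labels used throughout the examples:
#' `HaloTag-TMR` (tetramethylrhodamine, excited at 532 nm, emitting at 578 nm)
#' and `mEGFP` (488 nm / 507 nm). Both carry the default cross-section
#' (1e-14 cm^2), conversion factor (1e-6) and 55% filter transmission.
#'
#' @return A `species_catalog`.
#' @export
default_species_catalog <- function() {
  species_catalog(
    fluorophore("HaloTag-TMR", 532, 578),
    fluorophore("mEGFP", 488, 507))
}

# Resolve `species` (a fluorophore, a catalog, or NULL) to a catalog.
as_species_catalog <- function(species) {
  if (is.null(species)) return(default_species_catalog())
  if (inherits(species, "fluorophore")) return(species_catalog(species))
  if (inherits(species, "species_catalog")) return(species)
  if (is.list(species)) return(species_catalog(species))
  stop_arg("'species' must be a fluorophore or a species_catalog")
}

#' Read or write a species catalog file
#'
#' The catalog file is a YAML list of entries with keys `name`,
#' `excitation_nm`, `emission_nm`, and optionally `cross_section_cm2`,
#' `conversion_factor`, `filter_transmission`.
#'
#' @param path File path.
#' @return For `read_species_catalog`, a `species_catalog`.
#' @export
read_species_catalog <- function(path) {
  if (!file.exists(path)) stop_arg("species catalog not found: ", path)
  raw <- yaml::read_yaml(path)
  species_catalog(lapply(raw, function(e) do.call(fluorophore, e)))
}

#' @rdname read_species_catalog
#' @param catalog A `species_catalog` to serialize.
#' @export
write_species_catalog <- function(catalog, path) {
  catalog <- as_species_catalog(catalog)
  yaml::write_yaml(lapply(unname(catalog), unclass), path)
  invisible(path)
}
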