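# Run configuration: one human-editable YAML file with the sections used
# throughout the package ([sample], [species], [psf], [detector], [tirf],
# [camera], [lscm], [pmt], [output]). Validation reports every failing key
# at once rather than stopping at the first.

#' Read a run configuration file
#'
#' @param path Path to a YAML run configuration.
#' @return The configuration as a nested list (class `run_config`).
#' @seealso [validate_run_config()], [run_simulation()]
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(fix_yaml_n_key(cfg), class = "run_config")
}

# YAML 1.1 reads a bare `n:` mapping key as the boolean FALSE ("n" = no).
# Our schema uses `n` for counts and refractive indices, so map such keys
# back recursively.
fix_yaml_n_key <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "n", nm)
  lapply(x, fix_yaml_n_key)
}

cfg_get <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

#' Validate a run configuration
#'
#' Checks modality, presence of the modality-required sections, sample-model
#' parameters, PSF-grid consistency (the normalization region must fit the
#' grid) and species references. Returns a character vector naming every
#' failing key (empty when valid).
#'
#' @param cfg A configuration list from [read_run_config()].
#' @return Character vector of problems, `section.key: message`.
#' @export
validate_run_config <- function(cfg) {
  bad <- character()
  note <- function(key, msg) bad <<- c(bad, paste0(key, ": ", msg))

  modality <- cfg$modality
  if (is.null(modality) || !modality %in% c("tirfm", "lscm"))
    note("modality", "must be 'tirfm' or 'lscm'")

  sm <- cfg$sample
  if (is.null(sm) || is.null(sm$model)) {
    note("sample.model", "missing")
  } else if (!sm$model %in% c("plate", "box", "hemisphere", "file")) {
    note("sample.model", "must be plate, box, hemisphere or file")
  } else {
    if (sm$model %in% c("plate", "box") &&
        (is.null(sm$n) || sm$n < 0))
      note("sample.n", "must be a count >= 0")
    if (sm$model == "file" && is.null(sm$path))
      note("sample.path", "missing trajectory CSV path")
    if (sm$model == "hemisphere" && is.null(sm$n_cytosol))
      note("sample.n_cytosol", "missing")
  }

  psf <- cfg$psf
  if (is.null(psf$na) || is.null(psf$n)) {
    note("psf.na", "need both psf.na and psf.n")
  } else if (psf$na >= psf$n) {
    note("psf.na", "numerical aperture must be < refractive index")
  }
  Lam <- cfg_get(cfg, "psf", "Lambda_um", 1.0)
  rmax <- cfg_get(cfg, "psf", "r_max_um", 1.5)
  zmax <- cfg_get(cfg, "psf", "z_max_um", 1.5)
  if (rmax < Lam || zmax < Lam)
    note("psf.Lambda_um", "normalization region exceeds the PSF grid extents")

  if (identical(modality, "tirfm")) {
    if (is.null(cfg$tirf)) note("tirf", "section required for modality tirfm")
    if (is.null(cfg$camera)) note("camera", "section required for modality tirfm")
    if (!is.null(cfg$tirf)) {
      th <- cfg_get(cfg, "tirf", "theta_deg", 70)
      n1 <- cfg_get(cfg, "tirf", "n1", 1.52)
      n2 <- cfg_get(cfg, "tirf", "n2", 1.33)
      if (n1 <= n2) note("tirf.n1", "need n1 > n2")
      else if (th <= asin(n2 / n1) * 180 / pi)
        note("tirf.theta_deg", "must exceed the critical angle")
    }
  }
  if (identical(modality, "lscm")) {
    if (is.null(cfg$lscm)) {
      note("lscm", "section required for modality lscm")
    } else {
      if (is.null(cfg$lscm$R_um) || cfg$lscm$R_um <= 0)
        note("lscm.R_um", "pinhole radius required (image-plane um)")
      if (is.null(cfg$lscm$dwell_s) || cfg$lscm$dwell_s <= 0)
        note("lscm.dwell_s", "per-pixel dwell time required (s)")
    }
    if (is.null(cfg$pmt)) note("pmt", "section required for modality lscm")
  }

  det <- cfg$detector
  if (!is.null(det)) {
    for (k in c("nx", "ny", "pixel_size_um", "magnification"))
      if (!is.null(det[[k]]) && det[[k]] <= 0)
        note(paste0("detector.", k), "must be positive")
  }

  if (!is.null(cfg$species)) {
    nm <- vapply(cfg$species, function(e)
      if (is.null(e$name)) NA_character_ else e$name, character(1))
    if (anyNA(nm)) note("species", "every catalog entry needs a name")
    sp <- cfg_get(cfg, "sample", "species", "HaloTag-TMR")
    if (!anyNA(nm) && !sp %in% nm && !is.null(cfg$sample))
      note("sample.species", paste0("'", sp, "' not in the species catalog"))
  }
  bad
}

config_catalog <- function(cfg) {
  if (is.null(cfg$species)) return(default_species_catalog())
  species_catalog(lapply(cfg$species, function(e) do.call(fluorophore, e)))
}

config_trajectory <- function(cfg, seed) {
  sm <- cfg$sample
  sp <- if (is.null(sm$species)) "HaloTag-TMR" else sm$species
  switch(sm$model,
    plate = generate_surface_plate(
      n = sm$n,
      fov_x = cfg_get(cfg, "sample", "fov_x_um", 39.9),
      fov_y = cfg_get(cfg, "sample", "fov_y_um", 41.0),
      n_frames = cfg_get(cfg, "sample", "n_frames", 1L),
      dt = cfg_get(cfg, "sample", "dt_s", 1),
      seed = seed, species = sp),
    box = generate_solution_box(
      n = sm$n,
      box = box_geometry(cfg_get(cfg, "sample", "Lx_um", 30),
                         cfg_get(cfg, "sample", "Ly_um", 30),
                         cfg_get(cfg, "sample", "Lz_um", 6)),
      D = cfg_get(cfg, "sample", "D_um2_per_s", 100),
      dt = cfg_get(cfg, "sample", "dt_s", 1e-3),
      n_frames = cfg_get(cfg, "sample", "n_frames", 1L),
      seed = seed, species = sp),
    hemisphere = generate_hemisphere_cell(
      n_cytosol = sm$n_cytosol,
      n_membrane = cfg_get(cfg, "sample", "n_membrane", 0L),
      geom = hemisphere_geometry(cfg_get(cfg, "sample", "diameter_um", 20),
                                 cfg_get(cfg, "sample", "height_um", 7)),
      D_cytosol = cfg_get(cfg, "sample", "D_cytosol_um2_per_s", 1),
      dt = cfg_get(cfg, "sample", "dt_s", 1e-3),
      n_frames = cfg_get(cfg, "sample", "n_frames", 1L),
      seed = seed, species_cytosol = sp, species_membrane = sp),
    file = read_trajectory(sm$path))
}
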