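#' Run a full imaging simulation from a configuration file
#'
#' End-to-end orchestration of one imaging run: generate (or load) the sample
#' trajectory, tabulate and normalize one PSF per imaged species, compute the
#' expected image for every frame, push each frame through the detector
#' Monte Carlo chain, and write all artifacts: the frame-averaged expected
#' image (32-bit float TIFF), one digital image per frame (16-bit TIFF), an
#' intensity-histogram CSV per digital frame, a photon-budget log, and a
#' manifest JSON echoing the configuration and hashing every output.
#' Deterministic given the configured seed.
#'
#' @param config Path to a YAML run configuration, or an equivalent list
#'   (see [read_run_config()]; sections `sample`, `psf`, `detector`,
#'   `tirf`/`camera` or `lscm`/`pmt`, `output`).
#' @param out_dir Output directory; defaults to `output$dir` from the config
#'   (or "." if unset). Created if missing.
#' @param seed Optional override of the config seed.
#' @return Invisibly, the manifest list (also written as JSON).
#' @export
run_simulation <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  problems <- validate_run_config(cfg)
  if (length(problems))
    stop_arg("invalid configuration:\n  ",
             paste(problems, collapse = "\n  "))
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  if (is.null(out_dir)) out_dir <- cfg_get(cfg, "output", "dir", ".")
  prefix <- cfg_get(cfg, "output", "prefix", "run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(prefix, ...))

  seeds <- derive_seeds(seed, 2L)
  traj <- config_trajectory(cfg, seeds[[1L]])
  catalog <- config_catalog(cfg)
  times <- traj_times(traj)
  nf <- length(times)

  geom <- detector_geometry(
    nx = cfg_get(cfg, "detector", "nx", 152L),
    ny = cfg_get(cfg, "detector", "ny", 156L),
    pixel_size_um = cfg_get(cfg, "detector", "pixel_size_um", 16),
    magnification = cfg_get(cfg, "detector", "magnification", 60),
    focal_plane_um = cfg_get(cfg, "detector", "focal_plane_um", 0))

  psf_cfg <- cfg$psf
  used_species <- unique(traj$species)
  tables <- lapply(used_species, function(sn) {
    sp <- catalog[[sn]]
    if (is.null(sp)) stop_arg("species '", sn, "' not in catalog")
    normalize_psf(tabulate_psf(
      lambda_nm = sp$emission_nm, na = psf_cfg$na, n = psf_cfg$n,
      r_max_um = cfg_get(cfg, "psf", "r_max_um", 1.5),
      z_max_um = cfg_get(cfg, "psf", "z_max_um", 1.5),
      dr_um = cfg_get(cfg, "psf", "dr_um", 0.01),
      dz_um = cfg_get(cfg, "psf", "dz_um", 0.01),
      Lambda_um = cfg_get(cfg, "psf", "Lambda_um", 1.0)))
  })
  names(tables) <- used_species

  modality <- cfg$modality
  log_lines <- character()
  frame_seeds <- derive_seeds(seeds[[2L]], nf)
  digital_paths <- character(nf)
  hist_paths <- character(nf)
  expected_imgs <- vector("list", nf)

  if (modality == "tirfm") {
    tirf <- tirf_illumination(
      phi_W_per_cm2 = cfg_get(cfg, "tirf", "phi_W_per_cm2", 20),
      lambda_nm = cfg_get(cfg, "tirf", "lambda_nm", 532),
      theta_deg = cfg_get(cfg, "tirf", "theta_deg", 70),
      n1 = cfg_get(cfg, "tirf", "n1", 1.52),
      n2 = cfg_get(cfg, "tirf", "n2", 1.33),
      polarization = cfg_get(cfg, "tirf", "polarization", "s"))
    cam <- camera_config(
      qe = cfg_get(cfg, "camera", "qe", 0.92),
      readout_noise = cfg_get(cfg, "camera", "readout_noise", 100),
      dark_current = cfg_get(cfg, "camera", "dark_current", 0.005),
      em_gain = cfg_get(cfg, "camera", "em_gain", 300),
      conversion_gain = cfg_get(cfg, "camera", "conversion_gain", 5.8),
      offset = cfg_get(cfg, "camera", "offset", 2000),
      bit_depth = cfg_get(cfg, "camera", "bit_depth", 16L),
      binning = cfg_get(cfg, "camera", "binning", 1L),
      exposure_s = cfg_get(cfg, "camera", "exposure_s", 0.030))
    for (f in seq_len(nf)) {
      frame <- traj_frame(traj, f)
      exp_img <- expected_image_tirf(frame, catalog, tirf, tables, geom,
                                     cam$exposure_s)
      dig <- emccd_chain(exp_img, cam, frame_seeds[[f]])
      expected_imgs[[f]] <- exp_img
      digital_paths[f] <- p(sprintf("_digital_%04d.tif", f))
      write_image(dig, digital_paths[f])
      hist_paths[f] <- p(sprintf("_hist_%04d.csv", f))
      write_histogram(intensity_histogram(dig), hist_paths[f])
      log_lines <- c(log_lines, sprintf(
        "frame %d: expected_photons=%.6g expected_photoelectrons=%.6g mean_adu=%.3f",
        f, sum(exp_img),
        cam$qe * sum(exp_img) + cam$dark_current * cam$exposure_s *
          length(exp_img), mean(dig)))
    }
  } else {
    lscm <- lscm_illumination(
      Phi_W = cfg_get(cfg, "lscm", "Phi_W", 5e-6),
      lambda_nm = cfg_get(cfg, "lscm", "lambda_nm", 488),
      w0_um = cfg_get(cfg, "lscm", "w0_um", NULL),
      n = cfg_get(cfg, "lscm", "n", 1.33),
      na = psf_cfg$na)
    scan <- scan_config(pinhole_radius_um = cfg$lscm$R_um,
                        dwell_s = cfg$lscm$dwell_s)
    pmt <- pmt_config(
      qe = cfg_get(cfg, "pmt", "qe", 0.30),
      dark_count_rate = cfg_get(cfg, "pmt", "dark_count_rate", 50),
      gain = cfg_get(cfg, "pmt", "gain", 1),
      conversion_gain = cfg_get(cfg, "pmt", "conversion_gain", 1),
      offset = cfg_get(cfg, "pmt", "offset", 0),
      bit_depth = cfg_get(cfg, "pmt", "bit_depth", 12L))
    R_obj <- scan$pinhole_radius_um / geom$magnification
    captures <- lapply(tables, pinhole_capture_table, R_um = R_obj)
    for (f in seq_len(nf)) {
      frame <- traj_frame(traj, f)
      exp_img <- expected_image_lscm(frame, catalog, lscm, tables, geom,
                                     scan, capture_tables = captures)
      dig <- pmt_chain(exp_img, pmt, scan, frame_seeds[[f]])
      expected_imgs[[f]] <- exp_img
      digital_paths[f] <- p(sprintf("_digital_%04d.tif", f))
      write_image(dig, digital_paths[f])
      hist_paths[f] <- p(sprintf("_hist_%04d.csv", f))
      write_histogram(intensity_histogram(dig), hist_paths[f])
      log_lines <- c(log_lines, sprintf(
        "frame %d: expected_photons=%.6g expected_pulses=%.6g mean_adu=%.3f",
        f, sum(exp_img),
        pmt$qe * sum(exp_img) + pmt$dark_count_rate * scan$dwell_s *
          length(exp_img), mean(dig)))
    }
  }

  avg <- average_expected_images(expected_imgs)
  expected_path <- p("_expected.tif")
  write_image(avg, expected_path)
  log_path <- p("_log.txt")
  writeLines(log_lines, log_path)

  outputs <- c(expected_path, digital_paths, hist_paths, log_path)
  manifest <- list(
    package = "photonsim",
    modality = modality,
    seed = seed,
    n_frames = nf,
    config = unclass(cfg),
    outputs = data.frame(path = outputs,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE))
  manifest_path <- p("_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$manifest_path <- manifest_path
  invisible(manifest)
}
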