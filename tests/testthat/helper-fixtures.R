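# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# Normalized Born-Wolf table on a coarser grid than the package default:
# accurate enough for image-formation tests, fast enough to build once.
coarse_psf <- function() {
  if (is.null(.fixture_env$psf))
    .fixture_env$psf <- normalize_psf(
      tabulate_psf(578, 1.49, 1.52, r_max_um = 1.5, z_max_um = 1.5,
                   dr_um = 0.02, dz_um = 0.02, nq = 256L))
  .fixture_env$psf
}

# Default-grid table (10 nm spacing) used where the tests probe numerical
# accuracy of the PSF itself.
fine_psf <- function() {
  if (is.null(.fixture_env$psf_fine))
    .fixture_env$psf_fine <- normalize_psf(tabulate_psf(578, 1.49, 1.52))
  .fixture_env$psf_fine
}

tmr <- function() default_species_catalog()[["HaloTag-TMR"]]

small_geom <- function(nx = 32L, ny = 32L, z0 = 0)
  detector_geometry(nx = nx, ny = ny, pixel_size_um = 16,
                    magnification = 60, focal_plane_um = z0)

# One molecule at given object-space position, single frame.
one_molecule_frame <- function(x, y, z = 0, species = "HaloTag-TMR") {
  sample_trajectory(data.frame(
    time_s = 0, molecule_id = 1L, species = species,
    x_um = x, y_um = y, z_um = z))
}
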