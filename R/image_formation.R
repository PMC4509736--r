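# Expected-image formation: wide-field PSF summation for TIRF and
# scanned-beam + pinhole integration for LSCM. All geometry is computed in
# object space: detector pixel centres are demagnified by M, the PSF is
# evaluated at object-space offsets, and the M^2 area factor is absorbed into
# the object-space pixel-area integration.

#' Detector geometry
#'
#' @param nx,ny Pixel counts along x and y.
#' @param pixel_size_um Physical pixel size at the detector, micrometres.
#' @param magnification Optical magnification M; object-space pixel pitch is
#'   `pixel_size_um / magnification`.
#' @param focal_plane_um Object-space z of the focal plane (z0), micrometres.
#' @return A `detector_geometry` object.
#' @export
detector_geometry <- function(nx = 152L, ny = 156L, pixel_size_um = 16,
                              magnification = 60, focal_plane_um = 0) {
  if (nx < 1 || ny < 1) stop_arg("pixel counts must be positive")
  if (pixel_size_um <= 0 || magnification <= 0)
    stop_arg("pixel size and magnification must be positive")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size_um = pixel_size_um,
                 magnification = magnification,
                 focal_plane_um = focal_plane_um),
            class = "detector_geometry")
}

#' @rdname detector_geometry
#' @param geom A `detector_geometry`.
#' @export
pixel_pitch <- function(geom) geom$pixel_size_um / geom$magnification

#' Confocal scan configuration
#'
#' @param pinhole_radius_um Pinhole radius R in image-plane micrometres
#'   (> 0); the object-space radius is `R / M`.
#' @param dwell_s Scan time per pixel in seconds (> 0).
#' @return A `scan_config` object.
#' @export
scan_config <- function(pinhole_radius_um = 28.8, dwell_s = 1e-4) {
  if (pinhole_radius_um <= 0) stop_arg("'pinhole_radius_um' must be positive")
  if (dwell_s <= 0) stop_arg("'dwell_s' must be positive")
  structure(list(pinhole_radius_um = pinhole_radius_um, dwell_s = dwell_s),
            class = "scan_config")
}

new_expected_image <- function(mat, pitch_um) {
  structure(mat, pixel_pitch_um = pitch_um, units = "#photons",
            class = c("expected_image", "matrix", "array"))
}

#' @export
print.expected_image <- function(x, ...) {
  cat(sprintf("<expected_image> %d x %d px, pitch %.4g um, units %s\n",
              nrow(x), ncol(x), attr(x, "pixel_pitch_um"), attr(x, "units")))
  cat(sprintf("  total %.4g photons, max pixel %.4g\n", sum(x), max(x)))
  invisible(x)
}

#' @export
plot.expected_image <- function(x, main = "expected image (#photons)", ...) {
  graphics::image(seq_len(nrow(x)), seq_len(ncol(x)), unclass(x),
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "pixel x", ylab = "pixel y", main = main,
                  useRaster = TRUE, ...)
  invisible(x)
}

check_frame <- function(frame) {
  if (!inherits(frame, "sample_trajectory"))
    frame <- sample_trajectory(frame)
  if (length(traj_times(frame)) > 1L)
    stop_arg("expected a single-frame trajectory; use traj_frame()")
  frame
}

resolve_psf_table <- function(psf_tables, sp_name) {
  if (inherits(psf_tables, "psf_table")) return(psf_tables)
  tab <- psf_tables[[sp_name]]
  if (is.null(tab))
    stop_arg("no PSF table supplied for species '", sp_name, "'")
  tab
}

# Accumulate per-molecule PSF windows into the image (TIRF wide field).
# supersample > 1 averages the PSF over an s x s midpoint grid inside each
# pixel instead of sampling the pixel centre — the escape hatch when the
# pixel pitch under-samples the PSF central lobe.
accumulate_psf <- function(img, xs, ys, xk, yk, dzk, amp, table, pix_area,
                           supersample = 1L, pitch = NULL) {
  rmax <- max(table$r_um)
  s <- as.integer(supersample)
  offs <- if (s > 1L) (seq_len(s) - (s + 1) / 2) / s * pitch else 0
  for (k in seq_along(xk)) {
    ix <- which(abs(xs - xk[k]) <= rmax)
    if (!length(ix)) next
    iy <- which(abs(ys - yk[k]) <= rmax)
    if (!length(iy)) next
    acc <- matrix(0, length(ix), length(iy))
    for (ox in offs) for (oy in offs) {
      rr <- sqrt(outer((xs[ix] + ox - xk[k])^2,
                       (ys[iy] + oy - yk[k])^2, "+"))
      vals <- psf_lookup(table, as.vector(rr), dzk[k])
      acc <- acc + matrix(vals, length(ix), length(iy))
    }
    img[ix, iy] <- img[ix, iy] + amp[k] * pix_area * acc / length(offs)^2
  }
  img
}

#' Expected TIRF image of one trajectory frame
#'
#' Implements wide-field image formation as the superposition of normalized
#' PSFs: each fluorophore contributes
#' `n'_emit * PSF(|pixel - r_k|, z0 - z_k) * pixel_area` to every pixel,
#' where `n'_emit` is its filtered expected emission under the evanescent
#' field at its depth. Pixel centres are demagnified to object space; the
#' image is deterministic (noise enters only in the detector chain).
#'
#' @param frame A single-frame [sample_trajectory()] (see [traj_frame()]).
#' @param species A [fluorophore()] or [species_catalog()]; every species in
#'   the frame must be resolvable.
#' @param tirf A [tirf_illumination()].
#' @param psf_tables A normalized `psf_table`, or a named list of tables per
#'   species.
#' @param geom A [detector_geometry()].
#' @param exposure_s Per-frame exposure time in seconds (> 0).
#' @param supersample Sub-pixel sampling factor `s`: the PSF is averaged
#'   over an `s x s` midpoint grid inside each pixel. The default 1 samples
#'   pixel centres, which under-samples the PSF central lobe when the
#'   object-space pitch is comparable to the Airy radius; use 3-4 for
#'   photometrically accurate single-molecule totals.
#' @return An `expected_image` (matrix `nx x ny` of expected photon counts).
#' @export
expected_image_tirf <- function(frame, species, tirf, psf_tables, geom,
                                exposure_s, supersample = 1L) {
  frame <- check_frame(frame)
  stopifnot(inherits(tirf, "tirf_illumination"),
            inherits(geom, "detector_geometry"))
  if (exposure_s <= 0) stop_arg("'exposure_s' must be positive")
  catalog <- as_species_catalog(species)
  pitch <- pixel_pitch(geom)
  img <- matrix(0, geom$nx, geom$ny)
  if (nrow(frame) == 0L) return(new_expected_image(img, pitch))
  xs <- (seq_len(geom$nx) - 0.5) * pitch
  ys <- (seq_len(geom$ny) - 0.5) * pitch
  for (sp_name in unique(frame$species)) {
    sp <- catalog[[sp_name]]
    if (is.null(sp)) stop_arg("species '", sp_name, "' not in catalog")
    tab <- resolve_psf_table(psf_tables, sp_name)
    rows <- frame$species == sp_name
    dzk <- geom$focal_plane_um - frame$z_um[rows]
    if (any(abs(dzk) > max(tab$z_um) + 1e-9))
      stop_arg("fluorophore defocus ", signif(max(abs(dzk)), 4),
               " um exceeds the PSF table z extent (", max(tab$z_um),
               " um); tabulate with a larger z_max_um")
    nprime <- apply_filter_transmission(
      expected_emission(evanescent_flux_density(tirf, frame$z_um[rows]),
                        sp, exposure_s), sp)
    img <- accumulate_psf(img, xs, ys, frame$x_um[rows], frame$y_um[rows],
                          dzk, nprime, tab, pitch^2, supersample, pitch)
  }
  new_expected_image(img, pitch)
}

#' Integrate a PSF slice over the confocal pinhole disk
#'
#' Polar quadrature of the PSF at defocus `dz_um` over a disk of radius
#' `R_um` (object-space units of the table) whose centre is laterally offset
#' by `offset_um` from the PSF axis — the inner integral of confocal image
#' formation. Gauss-Legendre in radius, trapezoid in angle (the integrand is
#' symmetric about the offset direction, so only half the circle is
#' evaluated).
#'
#' @param table A `psf_table`.
#' @param R_um Disk radius, object-space micrometres (> 0).
#' @param offset_um Lateral offset between disk centre and PSF axis.
#' @param dz_um Defocus of the PSF slice.
#' @param n_rho,n_theta Quadrature orders.
#' @return The disk integral (photons fraction per micrometre of depth).
#' @export
pinhole_integral <- function(table, R_um, offset_um = 0, dz_um = 0,
                             n_rho = 64L, n_theta = 64L) {
  stopifnot(inherits(table, "psf_table"))
  if (R_um <= 0) stop_arg("'R_um' must be positive")
  gl <- pracma::gaussLegendre(n_rho, 0, R_um)
  th <- seq(0, pi, length.out = n_theta)
  wth <- trap_weights(th)
  dist <- sqrt(outer(gl$x^2, rep(1, n_theta)) + offset_um^2 -
                 2 * offset_um * outer(gl$x, cos(th)))
  vals <- matrix(psf_lookup(table, as.vector(dist), dz_um), n_rho, n_theta)
  2 * sum((gl$w * gl$x) * (vals %*% wth))
}

# Tabulate the pinhole capture C(delta, |dz|): the pinhole-disk integral of
# the PSF as a function of the lateral offset delta between the beam/pinhole
# axis and the fluorophore, and of the defocus. Radially symmetric, so a 1-D
# delta grid suffices; the z grid reuses the PSF table's non-negative nodes.
pinhole_capture_table <- function(table, R_um, delta_step_um = NULL,
                                  n_rho = 16L, n_theta = 24L) {
  stopifnot(inherits(table, "psf_table"))
  if (is.null(delta_step_um))
    delta_step_um <- 2 * (table$r_um[2L] - table$r_um[1L])
  rmax <- max(table$r_um)
  deltas <- seq(0, rmax + R_um, by = delta_step_um)
  zpos <- table$z_um[table$z_um >= -1e-12]
  gl <- pracma::gaussLegendre(n_rho, 0, R_um)
  th <- seq(0, pi, length.out = n_theta)
  wth <- trap_weights(th)
  V <- matrix(0, length(deltas), length(zpos))
  base <- outer(gl$x, cos(th))  # n_rho x n_theta
  for (i in seq_along(deltas)) {
    d <- deltas[i]
    dist <- sqrt(outer(gl$x^2, rep(1, n_theta)) + d^2 - 2 * d * base)
    npt <- length(dist)
    vals <- psf_lookup(table, rep(as.vector(dist), length(zpos)),
                       rep(zpos, each = npt))
    dim(vals) <- c(n_rho, n_theta, length(zpos))
    for (j in seq_along(zpos))
      V[i, j] <- 2 * sum((gl$w * gl$x) * (vals[, , j] %*% wth))
  }
  structure(list(delta_um = deltas, z_um = zpos, values = V, R_um = R_um),
            class = "pinhole_capture_table")
}

capture_lookup <- function(cap, delta_um, dz_um) {
  bilinear(cap$delta_um, cap$z_um, cap$values, delta_um,
           pmin(abs(dz_um), max(cap$z_um)), outside = 0)
}

#' Expected LSCM image of one trajectory frame
#'
#' Point-scanning confocal image formation: the beam dwells once per output
#' pixel, centred on the pixel's object-space position in the focal plane
#' `z0`. For each fluorophore `k` at lateral offset `delta` from the beam
#' axis and depth `z_k`, the excitation is the Gaussian-beam flux density at
#' `(delta, z_k - z0)` ([gaussian_flux_density()]), converted to expected
#' emission and filtered; the pinhole then passes the integral of that
#' fluorophore's PSF over the pinhole disk of object-space radius `R / M`
#' centred on the beam axis. The pixel value sums over fluorophores;
#' everything is deterministic.
#'
#' @inheritParams expected_image_tirf
#' @param lscm An [lscm_illumination()].
#' @param scan A [scan_config()].
#' @param capture_tables Optional precomputed pinhole-capture tables (named
#'   per species) to reuse across frames; built internally when `NULL`.
#' @return An `expected_image`.
#' @export
expected_image_lscm <- function(frame, species, lscm, psf_tables, geom, scan,
                                capture_tables = NULL) {
  frame <- check_frame(frame)
  stopifnot(inherits(lscm, "lscm_illumination"),
            inherits(geom, "detector_geometry"),
            inherits(scan, "scan_config"))
  catalog <- as_species_catalog(species)
  pitch <- pixel_pitch(geom)
  R_obj <- scan$pinhole_radius_um / geom$magnification
  img <- matrix(0, geom$nx, geom$ny)
  if (nrow(frame) == 0L) return(new_expected_image(img, pitch))
  xs <- (seq_len(geom$nx) - 0.5) * pitch
  ys <- (seq_len(geom$ny) - 0.5) * pitch
  z0 <- geom$focal_plane_um
  for (sp_name in unique(frame$species)) {
    sp <- catalog[[sp_name]]
    if (is.null(sp)) stop_arg("species '", sp_name, "' not in catalog")
    tab <- resolve_psf_table(psf_tables, sp_name)
    rows <- which(frame$species == sp_name)
    dzk <- frame$z_um[rows] - z0
    if (any(abs(dzk) > max(tab$z_um) + 1e-9))
      stop_arg("fluorophore defocus ", signif(max(abs(dzk)), 4),
               " um exceeds the PSF table z extent (", max(tab$z_um),
               " um); tabulate with a larger z_max_um")
    cap <- if (!is.null(capture_tables))
      if (inherits(capture_tables, "pinhole_capture_table")) capture_tables
      else capture_tables[[sp_name]]
    else pinhole_capture_table(tab, R_obj)
    dmax <- max(cap$delta_um)
    xk <- frame$x_um[rows]; yk <- frame$y_um[rows]
    for (k in seq_along(rows)) {
      ix <- which(abs(xs - xk[k]) <= dmax)
      if (!length(ix)) next
      iy <- which(abs(ys - yk[k]) <= dmax)
      if (!length(iy)) next
      delta <- sqrt(outer((xs[ix] - xk[k])^2, (ys[iy] - yk[k])^2, "+"))
      keep <- delta <= dmax
      if (!any(keep)) next
      exc <- expected_emission(
        gaussian_flux_density(lscm, delta[keep], dzk[k]), sp, scan$dwell_s)
      pass <- apply_filter_transmission(exc, sp) *
        capture_lookup(cap, delta[keep], dzk[k])
      add <- matrix(0, length(ix), length(iy))
      add[keep] <- pass
      img[ix, iy] <- img[ix, iy] + add
    }
  }
  new_expected_image(img, pitch)
}

#' Average expected images
#'
#' Elementwise mean of expected images on identical rasters — e.g. the
#' 100-frame average used to display the expected optical distribution over
#' a 3 s exposure series.
#'
#' @param images A list of `expected_image`s with identical rasters.
#' @return An `expected_image`.
#' @export
average_expected_images <- function(images) {
  if (!length(images)) stop_arg("empty image list")
  d <- dim(images[[1L]]); p <- attr(images[[1L]], "pixel_pitch_um")
  for (im in images) {
    if (!identical(dim(im), d) ||
        !isTRUE(all.equal(attr(im, "pixel_pitch_um"), p)))
      stop_arg("images must share an identical raster")
  }
  acc <- Reduce(`+`, lapply(images, unclass))
  new_expected_image(acc / length(images), p)
}
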