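# Born-Wolf scalar 3-D point spread function: direct evaluation, dense
# tabulation on an (r, z) grid, finite-region normalization and bilinear
# lookup. The PSF is the contract between photon counting and image
# formation: after normalize_psf(), its volume integral over the cylinder
# {r <= Lambda, |z| <= Lambda} equals 1, so a fluorophore's photons are
# conserved when spread onto pixels.

bw_quad_nodes <- function(nq) {
  gl <- pracma::gaussLegendre(nq, 0, 1)
  list(rho = gl$x, w = gl$w)
}

# Complex pupil integral A(r, z) evaluated at paired (r, z) vectors.
bw_amplitude <- function(r_um, z_um, lambda_um, na, n, nodes) {
  k <- 2 * pi / lambda_um
  rho <- nodes$rho
  J <- besselJ(outer(r_um, rho) * (k * na), 0)          # npts x nq
  phase <- outer(z_um, rho^2) * (-0.5 * k * na^2 / n)   # npts x nq
  wr <- nodes$w * rho
  drop((J * exp(1i * phase)) %*% wr)
}

#' Born-Wolf PSF intensity
#'
#' Scalar paraxial Born-Wolf model: the intensity at radial offset `r` and
#' defocus `z` is the squared modulus of the pupil integral
#' \deqn{A(r,z) = \int_0^1 J_0(k\,NA\,r\,\rho)\,
#'   \exp\!\left(-\tfrac{i}{2} k \rho^2 z \, NA^2/n\right) \rho\, d\rho}
#' with `k = 2 pi / lambda`, evaluated by fixed-order Gauss-Legendre
#' quadrature (deterministic). The result is unnormalized; see
#' [normalize_psf()].
#'
#' @param r_um Radial offset(s) in micrometres (recycled against `z_um`).
#' @param z_um Axial offset(s) in micrometres.
#' @param lambda_nm Emission wavelength in nm.
#' @param na Numerical aperture (must be < `n`).
#' @param n Refractive index of the imaging medium.
#' @param nq Number of quadrature nodes on rho in \[0, 1\] (default 512).
#' @return Non-negative intensity value(s).
#' @export
born_wolf_intensity <- function(r_um, z_um, lambda_nm, na, n, nq = 512L) {
  if (na >= n)
    stop_arg("numerical aperture must be smaller than the refractive index")
  m <- max(length(r_um), length(z_um))
  r <- rep_len(abs(r_um), m); z <- rep_len(z_um, m)
  A <- bw_amplitude(r, z, lambda_nm * 1e-3, na, n, bw_quad_nodes(nq))
  Mod(A)^2
}

#' Tabulate the Born-Wolf PSF on an (r, z) grid
#'
#' Dense deterministic evaluation of [born_wolf_intensity()] on uniform
#' radial (`0..r_max`) and axial (`-z_max..z_max`) grids. The default
#' 10 nm spacing keeps the normalization drift under grid refinement below
#' 1e-3. The table must extend at least to the normalization region
#' `Lambda` so [normalize_psf()] can integrate over it.
#'
#' @inheritParams born_wolf_intensity
#' @param r_max_um,z_max_um Grid extents in micrometres (>= `Lambda_um`).
#' @param dr_um,dz_um Grid steps in micrometres (> 0).
#' @param Lambda_um Normalization region half-extent (default 1.0 um).
#' @return A `psf_table`: grids, value matrix (`length(r) x length(z)`),
#'   optical parameters, and a `normalized` flag.
#' @export
tabulate_psf <- function(lambda_nm, na, n, r_max_um = 1.5, z_max_um = 1.5,
                         dr_um = 0.01, dz_um = 0.01, Lambda_um = 1.0,
                         nq = 512L) {
  if (dr_um <= 0 || dz_um <= 0) stop_arg("grid steps must be positive")
  if (r_max_um < Lambda_um || z_max_um < Lambda_um)
    stop_arg("grid extents must cover the normalization region Lambda (",
             Lambda_um, " um); cannot normalize later otherwise")
  if (na >= n)
    stop_arg("numerical aperture must be smaller than the refractive index")
  r <- seq(0, r_max_um, by = dr_um)
  z <- seq(-z_max_um, z_max_um, by = dz_um)
  nodes <- bw_quad_nodes(nq)
  k <- 2 * pi / (lambda_nm * 1e-3)
  rho <- nodes$rho
  J <- besselJ(outer(r, rho) * (k * na), 0)                    # nr x nq
  ph <- exp(outer(rho^2, z) * complex(imaginary = -0.5 * k * na^2 / n))
  A <- J %*% (nodes$w * rho * ph)                              # nr x nz
  structure(list(r_um = r, z_um = z, values = Mod(A)^2,
                 lambda_nm = lambda_nm, na = na, n = n,
                 Lambda_um = Lambda_um, nq = nq, normalized = FALSE),
            class = "psf_table")
}

#' @export
print.psf_table <- function(x, ...) {
  cat(sprintf("<psf_table> lambda=%g nm, NA=%g, n=%g%s\n",
              x$lambda_nm, x$na, x$n,
              if (x$normalized) sprintf(", normalized (Lambda=%g um)",
                                        x$Lambda_um) else " (unnormalized)"))
  cat(sprintf("  r: 0..%g um (%d), z: %g..%g um (%d)\n",
              max(x$r_um), length(x$r_um), min(x$z_um), max(x$z_um),
              length(x$z_um)))
  invisible(x)
}

# Cylindrical volume integral over {r <= Lambda, |z| <= Lambda} by composite
# trapezoid, volume element 2 pi r dr dz.
psf_region_integral <- function(table, Lambda_um = table$Lambda_um) {
  ir <- table$r_um <= Lambda_um + 1e-12
  iz <- abs(table$z_um) <= Lambda_um + 1e-12
  if (max(table$r_um) < Lambda_um - 1e-12 ||
      max(table$z_um) < Lambda_um - 1e-12)
    stop_arg("table does not cover the Lambda region")
  wr <- trap_weights(table$r_um[ir]) * 2 * pi * table$r_um[ir]
  wz <- trap_weights(table$z_um[iz])
  sum(outer(wr, wz) * table$values[ir, iz])
}

#' Normalize a PSF table over a finite region
#'
#' Scales the table so the cylindrical volume integral
#' `int 2 pi r PSF(r, z) dr dz` over `{0 <= r <= Lambda, |z| <= Lambda}`
#' equals 1 (composite trapezoid rule). The finite region (default
#' +/- 1.0 um radially and axially) sidesteps the oscillatory tails of the
#' PSF, whose slow decay makes an infinite-volume normalization constant
#' impractical to pin down; miscounting it would corrupt every photon count
#' downstream. Idempotent, and invariant to input scaling.
#'
#' @param table A `psf_table` covering the Lambda region.
#' @param Lambda_um Normalization half-extent in micrometres.
#' @return The normalized `psf_table`.
#' @export
normalize_psf <- function(table, Lambda_um = table$Lambda_um) {
  stopifnot(inherits(table, "psf_table"))
  I <- psf_region_integral(table, Lambda_um)
  if (I <= 0) stop_arg("PSF integral over the Lambda region is zero")
  table$values <- table$values / I
  table$Lambda_um <- Lambda_um
  table$normalized <- TRUE
  table
}

#' Interpolate a PSF table
#'
#' Bilinear interpolation in (r, z). Radial positions beyond the table
#' extent return 0 (defined truncation); axial positions beyond the table
#' extent are a domain error — the caller must tabulate with a larger
#' `z_max_um` rather than silently truncate defocused light.
#'
#' @param table A `psf_table`.
#' @param r_um,z_um Query positions in micrometres (recycled).
#' @return Interpolated PSF value(s).
#' @export
psf_lookup <- function(table, r_um, z_um) {
  stopifnot(inherits(table, "psf_table"))
  m <- max(length(r_um), length(z_um))
  r <- rep_len(abs(r_um), m); z <- rep_len(z_um, m)
  zmax <- max(table$z_um)
  if (any(abs(z) > zmax + 1e-9))
    stop_arg("axial offset ", signif(max(abs(z)), 4),
             " um beyond table extent ", zmax,
             " um; tabulate the PSF with a larger z_max_um")
  bilinear(table$r_um, table$z_um, table$values, r, z, outside = 0)
}

#' Write / read a PSF table cache file
#'
#' Plain-text cache: `#key value` header lines (wavelength, NA, n, grids,
#' normalization state) followed by the value matrix in TSV, full double
#' precision.
#'
#' @param table A `psf_table`.
#' @param path File path.
#' @return `write_psf_table` returns `path` invisibly; `read_psf_table`
#'   returns the `psf_table`.
#' @export
write_psf_table <- function(table, path) {
  stopifnot(inherits(table, "psf_table"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(lambda_nm = table$lambda_nm, na = table$na, n = table$n,
           Lambda_um = table$Lambda_um, nq = table$nq,
           normalized = as.numeric(table$normalized),
           r0 = table$r_um[1L], dr = table$r_um[2L] - table$r_um[1L],
           nr = length(table$r_um),
           z0 = table$z_um[1L], dz = table$z_um[2L] - table$z_um[1L],
           nz = length(table$z_um))
  writeLines(sprintf("#%s %.17g", names(hdr), hdr), con)
  utils::write.table(format(table$values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_psf_table
#' @export
read_psf_table <- function(path) {
  if (!file.exists(path)) stop_arg("PSF table file not found: ", path)
  lines <- readLines(path, n = 20L)
  hl <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#", "", hl), " "))
  h <- stats::setNames(as.numeric(kv[, 2L]), kv[, 1L])
  vals <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(vals) <- NULL
  structure(list(
    r_um = h[["r0"]] + h[["dr"]] * (seq_len(h[["nr"]]) - 1),
    z_um = h[["z0"]] + h[["dz"]] * (seq_len(h[["nz"]]) - 1),
    values = vals, lambda_nm = h[["lambda_nm"]], na = h[["na"]], n = h[["n"]],
    Lambda_um = h[["Lambda_um"]], nq = as.integer(h[["nq"]]),
    normalized = h[["normalized"]] != 0), class = "psf_table")
}
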