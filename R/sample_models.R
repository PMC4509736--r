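#' Box and hemisphere sample geometries
#'
#' `box_geometry` describes a rectangular solution volume (dimensions in
#' micrometres, all positive). `hemisphere_geometry` describes a hemispherical
#' cell sitting on the coverslip: a sphere of the given diameter centred on
#' the glass surface, truncated at the given height (height <= diameter/2
#' gives a truncated cap, as for a 20 um diameter x 7 um high cell).
#'
#' @param Lx,Ly,Lz Box edge lengths in micrometres.
#' @return A `box_geometry` / `hemisphere_geometry` list.
#' @export
box_geometry <- function(Lx, Ly, Lz) {
  if (any(c(Lx, Ly, Lz) <= 0)) stop_arg("box dimensions must be positive")
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz), class = "box_geometry")
}

#' @rdname box_geometry
#' @param diameter Cell diameter in micrometres.
#' @param height Cell height in micrometres (may not exceed diameter/2).
#' @export
hemisphere_geometry <- function(diameter, height) {
  if (diameter <= 0 || height <= 0)
    stop_arg("diameter and height must be positive")
  if (height > diameter / 2 + 1e-12)
    stop_arg("height may not exceed the hemisphere radius (diameter/2)")
  structure(list(diameter = diameter, height = height),
            class = "hemisphere_geometry")
}

# Reflective boundary: fold coordinates back into [lo, hi] by mirroring.
# Exact for Gaussian increments small compared to the domain size.
fold_interval <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  y <- ifelse(y > L, 2 * L - y, y)
  y + lo
}

traj_from_frames <- function(times, ids, species, coords) {
  # coords: list of n_frames matrices (n x 3)
  n <- length(ids)
  species <- rep_len(species, n)
  df <- data.frame(
    time_s = rep(times, each = n),
    molecule_id = rep(ids, times = length(times)),
    species = rep(species, times = length(times)),
    x_um = unlist(lapply(coords, function(m) m[, 1L]), use.names = FALSE),
    y_um = unlist(lapply(coords, function(m) m[, 2L]), use.names = FALSE),
    z_um = unlist(lapply(coords, function(m) m[, 3L]), use.names = FALSE),
    stringsAsFactors = FALSE)
  sample_trajectory(df)
}

#' Stationary molecules on a glass surface
#'
#' Distributes `n` stationary molecules uniformly over the x-y field of view
#' at z = 0, replicated identically over `n_frames` frames — the classic
#' single-molecule TIRF test sample (e.g. 100 immobilized dye molecules on a
#' coverslip).
#'
#' @param n Number of molecules (>= 0).
#' @param fov_x,fov_y Field of view in micrometres (> 0).
#' @param n_frames Number of frames (>= 1).
#' @param dt Frame interval in seconds.
#' @param seed Integer seed; each generator call uses an independent stream.
#' @param species Species name written into the trajectory.
#' @return A [sample_trajectory()].
#' @export
generate_surface_plate <- function(n, fov_x = 39.9, fov_y = 41.0,
                                   n_frames = 1L, dt = 1, seed = NULL,
                                   species = "HaloTag-TMR") {
  if (n < 0) stop_arg("'n' must be >= 0")
  if (fov_x <= 0 || fov_y <= 0) stop_arg("field of view must be positive")
  if (n_frames < 1) stop_arg("'n_frames' must be >= 1")
  n <- as.integer(n)
  xy <- with_seed(seed, cbind(stats::runif(n, 0, fov_x),
                              stats::runif(n, 0, fov_y)))
  pos <- cbind(xy, rep(0, n))
  times <- (seq_len(n_frames) - 1L) * dt
  traj_from_frames(times, seq_len(n), species,
                   rep(list(pos), n_frames))
}

#' Diffusing molecules in a solution box
#'
#' Molecules start uniformly distributed in the box and perform free Brownian
#' motion: each frame adds independent Gaussian displacements with per-axis
#' variance `2 * D * dt`, with reflective (mirror-fold) boundaries keeping
#' every molecule inside. Defaults reproduce the solution benchmark of
#' rapidly diffusing dye in a 30 x 30 x 6 um^3 box at 100 um^2/s.
#'
#' @param n Number of molecules (>= 0).
#' @param box A [box_geometry()].
#' @param D Diffusion coefficient in um^2/s (>= 0).
#' @param dt Frame interval in seconds (> 0).
#' @param n_frames Number of frames.
#' @inheritParams generate_surface_plate
#' @return A [sample_trajectory()].
#' @export
generate_solution_box <- function(n, box = box_geometry(30, 30, 6),
                                  D = 100, dt = 1e-3, n_frames = 1L,
                                  seed = NULL, species = "HaloTag-TMR") {
  if (n < 0) stop_arg("'n' must be >= 0")
  if (D < 0) stop_arg("'D' must be >= 0")
  if (dt <= 0) stop_arg("'dt' must be positive")
  stopifnot(inherits(box, "box_geometry"))
  n <- as.integer(n)
  L <- c(box$Lx, box$Ly, box$Lz)
  sd_step <- sqrt(2 * D * dt)
  coords <- with_seed(seed, {
    pos <- cbind(stats::runif(n, 0, L[1L]),
                 stats::runif(n, 0, L[2L]),
                 stats::runif(n, 0, L[3L]))
    frames <- vector("list", n_frames)
    frames[[1L]] <- pos
    if (n_frames > 1L) for (f in 2L:n_frames) {
      step <- matrix(stats::rnorm(3L * n, 0, sd_step), n, 3L)
      pos <- pos + step
      for (j in 1:3) pos[, j] <- fold_interval(pos[, j], 0, L[j])
      frames[[f]] <- pos
    }
    frames
  })
  times <- (seq_len(n_frames) - 1L) * dt
  traj_from_frames(times, seq_len(n), species, coords)
}

# Keep a point inside the truncated hemisphere {x^2+y^2+z^2 <= R^2,
# 0 <= z <= h} by iterated mirror folds at the plane z=0, the cut plane z=h,
# and radially at the spherical surface.
fold_hemisphere <- function(pos, R, h) {
  for (it in 1:12) {
    pos[, 3L] <- fold_interval(pos[, 3L], 0, h)
    rad <- sqrt(rowSums(pos^2))
    out <- rad > R
    if (!any(out)) break
    scl <- (2 * R - rad[out]) / rad[out]
    scl[scl < 0] <- 0.999  # pathological large step: pull toward centre
    pos[out, ] <- pos[out, , drop = FALSE] * scl
  }
  # numerical safety clamp
  rad <- sqrt(rowSums(pos^2))
  bad <- rad > R
  if (any(bad)) pos[bad, ] <- pos[bad, , drop = FALSE] * (R / rad[bad]) * 0.999999
  pos[, 3L] <- pmin(pmax(pos[, 3L], 0), h)
  pos
}

#' Hemispherical cell with cytosolic and membrane molecules
#'
#' Places `n_cytosol` molecules uniformly inside a truncated hemispherical
#' cell (sphere of radius diameter/2 centred on the coverslip, cut at
#' `height`) diffusing with reflective boundaries at the cell surface, and
#' `n_membrane` molecules fixed on the curved membrane surface. Default
#' geometry is a 20 um diameter, 7 um high cell; the default cytosolic
#' diffusion coefficient of 1 um^2/s is typical of a cytosolic protein.
#'
#' @param n_cytosol,n_membrane Molecule counts (>= 0).
#' @param geom A [hemisphere_geometry()].
#' @param D_cytosol Cytosolic diffusion coefficient in um^2/s.
#' @param species_cytosol,species_membrane Species names for the two pools.
#' @inheritParams generate_solution_box
#' @return A [sample_trajectory()]; membrane molecule ids follow cytosolic.
#' @export
generate_hemisphere_cell <- function(n_cytosol, n_membrane = 0L,
                                     geom = hemisphere_geometry(20, 7),
                                     D_cytosol = 1, dt = 1e-3, n_frames = 1L,
                                     seed = NULL,
                                     species_cytosol = "HaloTag-TMR",
                                     species_membrane = "HaloTag-TMR") {
  if (n_cytosol < 0 || n_membrane < 0) stop_arg("counts must be >= 0")
  if (D_cytosol < 0) stop_arg("'D_cytosol' must be >= 0")
  stopifnot(inherits(geom, "hemisphere_geometry"))
  n_cytosol <- as.integer(n_cytosol); n_membrane <- as.integer(n_membrane)
  R <- geom$diameter / 2; h <- min(geom$height, R)
  sd_step <- sqrt(2 * D_cytosol * dt)
  res <- with_seed(seed, {
    # cytosol: rejection sampling from the bounding box
    cyt <- matrix(0, 0, 3L)
    while (nrow(cyt) < n_cytosol) {
      m <- max(2L * (n_cytosol - nrow(cyt)), 64L)
      cand <- cbind(stats::runif(m, -R, R), stats::runif(m, -R, R),
                    stats::runif(m, 0, h))
      keep <- rowSums(cand^2) <= R^2
      cyt <- rbind(cyt, cand[keep, , drop = FALSE])
    }
    cyt <- cyt[seq_len(n_cytosol), , drop = FALSE]
    # membrane: uniform on the spherical cap z in [0, h]
    # (area element on a sphere is uniform in z)
    zm <- stats::runif(n_membrane, 0, h)
    phim <- stats::runif(n_membrane, 0, 2 * pi)
    rxy <- sqrt(pmax(R^2 - zm^2, 0))
    mem <- cbind(rxy * cos(phim), rxy * sin(phim), zm)
    frames <- vector("list", n_frames)
    frames[[1L]] <- rbind(cyt, mem)
    if (n_frames > 1L) for (f in 2L:n_frames) {
      if (n_cytosol > 0L) {
        step <- matrix(stats::rnorm(3L * n_cytosol, 0, sd_step),
                       n_cytosol, 3L)
        cyt <- fold_hemisphere(cyt + step, R, h)
      }
      frames[[f]] <- rbind(cyt, mem)
    }
    frames
  })
  species <- c(rep(species_cytosol, n_cytosol),
               rep(species_membrane, n_membrane))
  times <- (seq_len(n_frames) - 1L) * dt
  # shift to positive coordinates so x,y >= 0 is not required; keep as-is:
  traj_from_frames(times, seq_len(n_cytosol + n_membrane), species, res)
}

#' Estimate a diffusion coefficient from ensemble MSD
#'
#' Computes the ensemble mean-squared displacement (averaged over molecules
#' and start frames) for the first `min(max_lags, n_frames - 1)` lag times,
#' fits a straight line by least squares, and returns `slope / 6` (the 3-D
#' Einstein relation MSD = 6 D t). Requires at least two frames on a uniform
#' time grid.
#'
#' @param traj A [sample_trajectory()].
#' @param max_lags Maximum number of lags entering the fit (default 10).
#' @return The estimated diffusion coefficient in um^2/s, with attributes
#'   `intercept`, `lags_s` and `msd_um2` exposing the fitted curve.
#' @export
estimate_diffusion_msd <- function(traj, max_lags = 10L) {
  times <- traj_times(traj)
  nf <- length(times)
  if (nf < 2L) stop_arg("need at least 2 frames to estimate diffusion")
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop_arg("frame times must be uniformly spaced")
  dt <- dts[1L]
  ord <- order(traj$time_s, traj$molecule_id)
  n <- nrow(traj) / nf
  X <- array(c(traj$x_um[ord], traj$y_um[ord], traj$z_um[ord]),
             dim = c(n, nf, 3L))
  nlag <- min(max_lags, nf - 1L)
  msd <- vapply(seq_len(nlag), function(L) {
    d <- X[, (1L + L):nf, , drop = FALSE] - X[, 1L:(nf - L), , drop = FALSE]
    d2 <- d[, , 1L]^2 + d[, , 2L]^2 + d[, , 3L]^2
    mean(d2)
  }, numeric(1))
  lag_t <- seq_len(nlag) * dt
  if (nlag == 1L) {
    slope <- msd / lag_t
    icpt <- 0
  } else {
    fit <- stats::lm.fit(cbind(1, lag_t), msd)
    icpt <- fit$coefficients[1L]
    slope <- fit$coefficients[2L]
  }
  structure(unname(slope) / 6, intercept = unname(icpt),
            lags_s = lag_t, msd_um2 = msd)
}
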