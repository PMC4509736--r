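# Expected-image formation for both modalities. Uses the coarse PSF fixture;
# tolerances reflect pixel-centre sampling, not physics.

tirf_std <- function() tirf_illumination(20, 532, 70, 1.52, 1.33)
lscm_std <- function() lscm_illumination(5e-6, 488, w0_um = 0.25, n = 1.33)

test_that("TIRF imaging: empty frame, superposition, linear flux scaling", {
  geom <- small_geom()
  tab <- coarse_psf()
  empty <- generate_surface_plate(0, 8, 8)
  img0 <- expected_image_tirf(empty, tmr(), tirf_std(), tab, geom, 0.03)
  expect_true(all(img0 == 0))
  expect_equal(dim(img0), c(32L, 32L))

  fA <- one_molecule_frame(3.1, 4.2)
  fB <- one_molecule_frame(5.0, 2.7)
  both <- sample_trajectory(rbind(as.data.frame(fA),
                                  within(as.data.frame(fB),
                                         molecule_id <- 2L)))
  iA <- expected_image_tirf(fA, tmr(), tirf_std(), tab, geom, 0.03)
  iB <- expected_image_tirf(fB, tmr(), tirf_std(), tab, geom, 0.03)
  iAB <- expected_image_tirf(both, tmr(), tirf_std(), tab, geom, 0.03)
  expect_equal(unclass(iAB), unclass(iA) + unclass(iB))

  # beam flux densities 20/30/40/50 W/cm2 give exact 2:3:4:5 multiples
  imgs <- lapply(c(20, 30, 40, 50), function(phi)
    expected_image_tirf(fA, tmr(),
                        tirf_illumination(phi, 532, 70, 1.52, 1.33),
                        tab, geom, 0.03))
  for (k in 2:4)
    expect_equal(unclass(imgs[[k]]), unclass(imgs[[1]]) * c(2, 3, 4, 5)[k] / 2)
  # exposure linearity
  i2 <- expected_image_tirf(fA, tmr(), tirf_std(), tab, geom, 0.06)
  expect_equal(unclass(i2), 2 * unclass(iA))
})

test_that("TIRF total photons match an independent slice quadrature", {
  geom <- small_geom()
  tab <- coarse_psf()
  pitch <- pixel_pitch(geom)
  ctr <- 16 * pitch  # pixel-grid-aligned centre
  frame <- one_molecule_frame(ctr, ctr)
  img <- expected_image_tirf(frame, tmr(), tirf_std(), tab, geom, 0.03,
                             supersample = 4L)
  nprime <- apply_filter_transmission(
    expected_emission(evanescent_flux_density(tirf_std(), 0), tmr(), 0.03),
    tmr())
  # oracle: dense midpoint quadrature of the normalized in-focus PSF slice
  # over the raster extent (independent of the pixel-centre accumulation)
  h <- 0.005
  gx <- seq(h / 2, 32 * pitch, by = h) - ctr
  slice <- outer(gx, gx, function(a, b) sqrt(a^2 + b^2))
  vals <- psf_lookup(tab, as.vector(slice), 0)
  oracle_frac <- sum(vals) * h^2
  expect_equal(sum(img) / nprime, oracle_frac, tolerance = 0.05)
  # captured fraction is below the full 3-D normalized volume
  expect_lt(sum(img), nprime)
})

test_that("TIRF image is translation-equivariant at grid-aligned shifts", {
  geom <- small_geom()
  tab <- coarse_psf()
  pitch <- pixel_pitch(geom)
  f1 <- one_molecule_frame(10 * pitch, 12 * pitch)
  f2 <- one_molecule_frame(11 * pitch, 12 * pitch)
  i1 <- expected_image_tirf(f1, tmr(), tirf_std(), tab, geom, 0.03)
  i2 <- expected_image_tirf(f2, tmr(), tirf_std(), tab, geom, 0.03)
  expect_equal(unclass(i2)[7:26, 7:18], unclass(i1)[6:25, 7:18],
               tolerance = 1e-9)
})

test_that("defocus beyond the PSF table is a loud error", {
  geom <- small_geom()
  frame <- one_molecule_frame(4, 4, z = 2.5)  # z_max is 1.5
  expect_error(
    expected_image_tirf(frame, tmr(), tirf_std(), coarse_psf(), geom, 0.03),
    "z_max")
})

test_that("pinhole integral has the right limits and Airy encircled energy", {
  tab <- coarse_psf()
  # R -> 0 collapses to zero; R beyond the PSF support captures the slice
  expect_lt(pinhole_integral(tab, 1e-4), 1e-6)
  big <- pinhole_integral(tab, max(tab$r_um), n_rho = 256L)
  # independent radial quadrature of the in-focus slice
  r <- seq(0, max(tab$r_um), by = 1e-3)
  slice_tot <- sum(2 * pi * r * psf_lookup(tab, r, 0)) * 1e-3
  expect_equal(big, slice_tot, tolerance = 1e-3)
  # encircled energy at the first Airy zero: oracle by brute-force
  # quadrature of the same slice
  r1 <- 3.8317 / (2 * pi / 0.578 * 1.49)
  ee_oracle <- sum(2 * pi * r[r <= r1] * psf_lookup(tab, r[r <= r1], 0)) * 1e-3
  expect_equal(pinhole_integral(tab, r1) / big, ee_oracle / slice_tot,
               tolerance = 0.02)
  # ~84% of the (truncated) slice energy lies inside the first dark ring
  expect_equal(pinhole_integral(tab, r1) / big, 0.86, tolerance = 0.03)
  # off-axis displacement only loses light
  expect_lt(pinhole_integral(tab, r1, offset_um = 0.3),
            pinhole_integral(tab, r1, offset_um = 0))
})

test_that("LSCM imaging: empty frame, peak location, exact power linearity", {
  geom <- small_geom(nx = 24L, ny = 24L, z0 = 0)
  tab <- coarse_psf()
  scan <- scan_config(pinhole_radius_um = 28.8, dwell_s = 1e-4)
  empty <- generate_surface_plate(0, 5, 5)
  expect_true(all(expected_image_lscm(empty, tmr(), lscm_std(), tab, geom,
                                      scan) == 0))
  # molecule on a pixel centre at focus: that pixel is the brightest
  pitch <- pixel_pitch(geom)
  frame <- one_molecule_frame((12 - 0.5) * pitch, (9 - 0.5) * pitch, z = 0)
  img <- expected_image_lscm(frame, tmr(), lscm_std(), tab, geom, scan)
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 12L, col = 9L))
  # the five beam powers produce images in exact ratio 5:10:30:50:100
  imgs <- lapply(c(5, 10, 30, 50, 100) * 1e-6, function(P)
    expected_image_lscm(frame, tmr(),
                        lscm_illumination(P, 488, w0_um = 0.25, n = 1.33),
                        tab, geom, scan))
  for (k in 2:5)
    expect_equal(unclass(imgs[[k]]),
                 unclass(imgs[[1]]) * c(5, 10, 30, 50, 100)[k] / 5)
})

test_that("frame averaging is exact and reduces variance for moving samples", {
  geom <- small_geom(nx = 16L, ny = 16L)
  tab <- coarse_psf()
  f <- one_molecule_frame(2, 2)
  img <- expected_image_tirf(f, tmr(), tirf_std(), tab, geom, 0.03)
  expect_equal(average_expected_images(list(img, img, img)), img)
  z <- expected_image_tirf(generate_surface_plate(0, 4, 4), tmr(),
                           tirf_std(), tab, geom, 0.03)
  expect_true(all(average_expected_images(list(z, z)) == 0))
  other <- expected_image_tirf(f, tmr(), tirf_std(), tab,
                               small_geom(nx = 8L, ny = 8L), 0.03)
  expect_error(average_expected_images(list(img, other)), "raster")
  # diffusing sample: averaging 20 frames lowers pixel variance
  traj <- generate_solution_box(60, box_geometry(4.3, 4.3, 1), D = 5,
                                dt = 1e-3, n_frames = 20L, seed = 8)
  frames <- lapply(seq_len(20), function(i)
    expected_image_tirf(traj_frame(traj, i), tmr(), tirf_std(), tab,
                        geom, 0.03))
  avg <- average_expected_images(frames)
  expect_lt(var(as.vector(avg)), var(as.vector(frames[[1]])))
})
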