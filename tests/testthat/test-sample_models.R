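# Ground-truth generators and the MSD diffusion estimator.

test_that("surface plate is uniform, stationary and validates", {
  traj <- generate_surface_plate(100, 39.9, 41.0, n_frames = 2L, seed = 1)
  expect_s3_class(traj, "sample_trajectory")
  expect_equal(nrow(traj), 200L)
  expect_true(all(traj$z_um == 0))
  expect_true(all(traj$x_um >= 0 & traj$x_um <= 39.9))
  expect_true(all(traj$y_um >= 0 & traj$y_um <= 41.0))
  f1 <- traj_frame(traj, 1); f2 <- traj_frame(traj, 2)
  expect_identical(f1$x_um, f2$x_um)
  expect_identical(f1$y_um, f2$y_um)
  # empty plate is a valid trajectory
  expect_equal(nrow(generate_surface_plate(0, 10, 10)), 0L)
  expect_error(generate_surface_plate(-1, 10, 10), ">= 0")
  expect_error(generate_surface_plate(5, -1, 10), "positive")
  # seeded reproducibility is bitwise
  expect_identical(generate_surface_plate(50, 20, 20, seed = 7),
                   generate_surface_plate(50, 20, 20, seed = 7))
})

test_that("solution box keeps molecules inside with reflective boundaries", {
  box <- box_geometry(30, 30, 6)
  traj <- generate_solution_box(2000, box, D = 100, dt = 1e-3,
                                n_frames = 5L, seed = 7)
  expect_true(all(traj$x_um >= 0 & traj$x_um <= 30))
  expect_true(all(traj$y_um >= 0 & traj$y_um <= 30))
  expect_true(all(traj$z_um >= 0 & traj$z_um <= 6))
  # molecule count conserved at every frame
  expect_true(all(table(traj$time_s) == 2000L))
  # no diffusion freezes the sample
  still <- generate_solution_box(100, box, D = 0, dt = 1e-3,
                                 n_frames = 3L, seed = 2)
  expect_identical(traj_frame(still, 1)$x_um, traj_frame(still, 3)$x_um)
  expect_error(generate_solution_box(10, box, D = -1), ">= 0")
})

test_that("per-axis displacement variance matches 2 D dt away from walls", {
  # weak-confinement regime: step sd 0.045 um in a 30 um box
  box <- box_geometry(30, 30, 30)
  traj <- generate_solution_box(4000, box, D = 1, dt = 1e-3,
                                n_frames = 2L, seed = 11)
  d <- traj_frame(traj, 2)$x_um - traj_frame(traj, 1)$x_um
  expect_equal(var(d), 2 * 1 * 1e-3, tolerance = 0.05)
  d <- traj_frame(traj, 2)$z_um - traj_frame(traj, 1)$z_um
  expect_equal(var(d), 2 * 1 * 1e-3, tolerance = 0.05)
})

test_that("MSD estimator recovers D and reports a small intercept", {
  # stationary sample: D exactly zero
  plate <- generate_surface_plate(50, 20, 20, n_frames = 3L, seed = 1)
  expect_equal(as.numeric(estimate_diffusion_msd(plate)), 0)
  # nearly unconfined diffusion: recovery within 5%
  box <- box_geometry(30, 30, 30)
  traj <- generate_solution_box(1000, box, D = 5, dt = 1e-3,
                                n_frames = 100L, seed = 42)
  D_hat <- estimate_diffusion_msd(traj)
  expect_equal(as.numeric(D_hat), 5, tolerance = 0.05)
  # fitted intercept is small relative to the first-lag MSD
  expect_lt(abs(attr(D_hat, "intercept")), 0.10 * attr(D_hat, "msd_um2")[1L])
  expect_error(estimate_diffusion_msd(generate_surface_plate(5, 10, 10)),
               "2 frames")
})

test_that("hemisphere cell respects the truncated-cap geometry", {
  geom <- hemisphere_geometry(20, 7)
  traj <- generate_hemisphere_cell(1000, 100, geom, D_cytosol = 1,
                                   dt = 1e-3, n_frames = 3L, seed = 5)
  R <- 10
  rad2 <- traj$x_um^2 + traj$y_um^2 + traj$z_um^2
  expect_true(all(rad2 <= R^2 + 1e-9))
  expect_true(all(traj$z_um >= 0 & traj$z_um <= 7))
  # membrane molecules (ids 1001..1100) sit on the sphere and never move
  mem <- traj[traj$molecule_id > 1000L, ]
  expect_equal(sqrt(mem$x_um^2 + mem$y_um^2 + mem$z_um^2),
               rep(R, nrow(mem)), tolerance = 1e-9)
  m1 <- mem[mem$time_s == 0, ]; m3 <- mem[mem$time_s == 2e-3, ]
  expect_identical(m1$x_um, m3$x_um)
  # exact hemisphere: samples reach the pole z -> R
  tiny <- generate_hemisphere_cell(5000, 0, hemisphere_geometry(2, 1),
                                   seed = 9)
  expect_gt(max(tiny$z_um), 0.95)
  expect_lte(max(tiny$z_um), 1)
  expect_error(hemisphere_geometry(20, 11), "radius")
  expect_error(hemisphere_geometry(-1, 1), "positive")
})

test_that("trajectory CSV round-trips exactly and flags bad files", {
  traj <- generate_solution_box(50, box_geometry(5, 5, 5), D = 2,
                                dt = 1e-3, n_frames = 3L, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_identical(as.data.frame(back), as.data.frame(traj))
  # decreasing time column names the offending line
  lines <- readLines(f)
  swapped <- c(lines[1], lines[102:151], lines[2:101])
  f2 <- tempfile(fileext = ".csv")
  writeLines(swapped, f2)
  expect_error(read_trajectory(f2), "line 52")
  # full-size solution fixture preserves its record count
  big <- generate_solution_box(19656, box_geometry(30, 30, 6), D = 100,
                               dt = 1e-3, n_frames = 1L, seed = 1)
  f3 <- tempfile(fileext = ".csv")
  write_trajectory(big, f3)
  expect_equal(nrow(read_trajectory(f3)), 19656L)
  unlink(c(f, f2, f3))
})

test_that("trajectory validation catches structural violations", {
  df <- data.frame(time_s = c(0, 0, 1), molecule_id = c(1L, 2L, 1L),
                   species = "s", x_um = 0, y_um = 0, z_um = 0)
  expect_error(sample_trajectory(df), "birth/death")
  df2 <- data.frame(time_s = 0, molecule_id = 1L, species = "s",
                    x_um = 0, y_um = 0, z_um = -0.5)
  expect_error(sample_trajectory(df2), "z")
})
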