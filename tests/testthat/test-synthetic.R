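# Imaging calibrations and the synthetic-microscopy phantom pipeline.

test_that("Beer-Lambert forward/inverse are exact inverses", {
  expect_equal(beer_lambert(0, 130, 1), 1)
  # half-attenuation at eps*c*path = ln 2
  expect_equal(beer_lambert(log(2) / 130, 130, 1), 0.5)
  cc <- seq(0, 0.2, length.out = 11)
  frac <- beer_lambert(cc, 130, 2.5)
  expect_equal(beer_lambert_inv(frac, 130, 2.5), cc, tolerance = 1e-12)
  expect_error(beer_lambert_inv(1.2, 130, 1), "\\(0, 1]")
  expect_error(beer_lambert_inv(0, 130, 1), "\\(0, 1]")
})

test_that("Ru(dpp) calibration matches its closed form and inverts", {
  expect_equal(rudpp_fluorescence(0), 7.5)
  expect_equal(rudpp_fluorescence(3), 1 + 6.5 / exp(1))  # ~3.391
  expect_lt(rudpp_fluorescence(1e4), 1 + 1e-10)
  p <- seq(0, 60, length.out = 25)
  expect_equal(rudpp_inverse(rudpp_fluorescence(p)), p, tolerance = 1e-10)
  expect_error(rudpp_inverse(1), "1, 7.5")
  expect_error(rudpp_inverse(8), "1, 7.5")
})

test_that("Henry conversion is linear and anchored at saturation", {
  expect_equal(henry_convert(0), 0)
  expect_equal(henry_convert(160, H = 250 / 160), 250)
  expect_equal(henry_convert(20), 2 * henry_convert(10))
  expect_equal(henry_inverse(henry_convert(37.5)), 37.5)
  expect_error(henry_convert(1, H = 0), "positive")
})

test_that("sector averaging recovers a radially symmetric field", {
  px <- 5
  x <- seq(-500, 500, by = px)
  r <- sqrt(outer(x^2, x^2, `+`))
  img <- 1 + r / 500  # smooth radial function
  img[r > 480] <- NA
  sa <- sector_average(img, x, x, theta0 = 0, half_angle = pi / 8,
                       n_bins = 40, r_max = 450)
  expect_lt(max(abs(sa$intensity - (1 + sa$r / 500)) / (1 + sa$r / 500)),
            0.01)
  # rotation invariance on a symmetric image
  sb <- sector_average(img, x, x, theta0 = pi / 3, half_angle = pi / 8,
                       n_bins = 40, r_max = 450)
  expect_equal(sb$intensity, sa$intensity, tolerance = 0.01)
})

test_that("phantom rendering is deterministic and round-trips noiselessly", {
  traj <- run_transient_256()
  cal <- phantom_calibration(ccell_0 = 0.04)
  cfg <- phantom_config(n_frames = 30, pixel_size = 10)
  ph <- phantom_droplet(traj, cfg, l_O2 = 1400 / 2.7, calib = cal)
  expect_s3_class(ph, "droplet_phantom")
  expect_equal(dim(ph$brightfield)[3], 30)
  # densest region transmits ~20% by the default attenuation calibration
  expect_equal(min(ph$brightfield, na.rm = TRUE), 0.2, tolerance = 1e-6)
  # noiseless sector average recovers the cell profile within 1%
  j <- 15
  prof <- sector_average(ph$brightfield[, , j], ph$x, ph$y,
                         half_angle = pi / 6, n_bins = 32,
                         r_max = ph$meta$R_um)
  cc_rec <- beer_lambert_inv(pmin(prof$intensity, 1), cal$path,
                             ph$meta$epsilon_att)
  cc_true <- approx(ph$truth$r_um, ph$truth$c_cell[, j], xout = prof$r)$y
  inner <- prof$r < 0.95 * ph$meta$R_um  # rim bins straddle the boundary
  expect_lt(max(abs(cc_rec[inner] - cc_true[inner])) / max(cc_true), 0.01)
  # determinism with a fixed seed
  cfgn <- phantom_config(noise = 0.05, n_frames = 5, pixel_size = 10,
                         seed = 42)
  ph1 <- phantom_droplet(traj, cfgn, l_O2 = 1400 / 2.7, calib = cal)
  ph2 <- phantom_droplet(traj, cfgn, l_O2 = 1400 / 2.7, calib = cal)
  expect_identical(ph1$brightfield, ph2$brightfield)
  expect_identical(ph1$fluorescence, ph2$fluorescence)
})

test_that("phantom generation does not disturb the session RNG", {
  set.seed(99)
  before <- .Random.seed
  invisible(phantom_droplet(run_transient_256(),
                            phantom_config(noise = 0.05, n_frames = 3),
                            l_O2 = 1400 / 2.7))
  expect_identical(.Random.seed, before)
})

test_that("observables recovered from noisy imperfect phantoms match truth", {
  traj <- run_transient_256()
  cal <- phantom_calibration(ccell_0 = 0.04)
  cfg <- phantom_config(boundary_eps = 0.03, boundary_mode = 3,
                        noise = 0.05, n_frames = 50, pixel_size = 7,
                        seed = 7)
  ph <- phantom_droplet(traj, cfg, l_O2 = 1400 / 2.7, calib = cal)
  rec <- recover_observables(ph, n_bins = 32)
  tru <- phantom_truth_observables(ph, c_crit = rec$meta$c_crit,
                                   c_ceiling = rec$meta$c_ceiling)
  # initial annulus width within 10%
  expect_lt(abs(attr(rec$core_trace, "ell_init") -
                  attr(tru$core_trace, "ell_init")) /
              attr(tru$core_trace, "ell_init"), 0.10)
  # vanishing time within 15%
  expect_lt(abs(attr(rec$core_trace, "t_vanish") -
                  attr(tru$core_trace, "t_vanish")) /
              attr(tru$core_trace, "t_vanish"), 0.15)
  # total-oxygen series within 5% of the (ceiling-censored) truth
  sel <- is.finite(rec$total_o2$o2_frac) & is.finite(tru$total_o2$o2_frac)
  expect_lt(max(abs(rec$total_o2$o2_frac[sel] -
                      tru$total_o2$o2_frac[sel])), 0.05)
})

test_that("recovered oxygen shows the expected radial structure", {
  traj <- run_transient_256()
  cal <- phantom_calibration(ccell_0 = 0.04)
  ph <- phantom_droplet(traj, phantom_config(n_frames = 40,
                                             pixel_size = 10),
                        l_O2 = 1400 / 2.7, calib = cal)
  rec <- recover_observables(ph, n_bins = 32)
  # early post-formation frame: ~0 at the core periphery, rising outward
  tf <- traj$diagnostics$t_formed
  j <- which(ph$times > tf + 2)[1]
  prof <- matrix(rec$kymo_oxy$value, nrow = 32)[, j]
  expect_lt(prof[16], 0.5)          # near-zero inside/near the core (uM)
  expect_gt(prof[32], 5 * prof[16]) # strong outward gradient to the rim
  # rim recovery is censored at the probe ceiling, which it reaches at t = 0
  expect_equal(max(matrix(rec$kymo_oxy$value, nrow = 32)[, 1]),
               rec$meta$c_ceiling, tolerance = 0.05)
})

test_that("two sectors on a perturbed phantom differ near the rim", {
  traj <- run_transient_256()
  ph <- phantom_droplet(traj, phantom_config(boundary_eps = 0.03,
                                             boundary_mode = 3,
                                             n_frames = 5,
                                             pixel_size = 7),
                        l_O2 = 1400 / 2.7,
                        calib = phantom_calibration(ccell_0 = 0.04))
  img <- ph$brightfield[, , 3]
  a <- sector_average(img, ph$x, ph$y, theta0 = 0, half_angle = pi / 12,
                      n_bins = 48, r_max = ph$meta$R_um * 1.02)
  b <- sector_average(img, ph$x, ph$y, theta0 = pi / 3,
                      half_angle = pi / 12, n_bins = 48,
                      r_max = ph$meta$R_um * 1.02)
  rim <- a$r > 0.93 * ph$meta$R_um
  bulk <- a$r < 0.7 * ph$meta$R_um & a$r > 0.2 * ph$meta$R_um
  expect_gt(max(abs(a$intensity[rim] - b$intensity[rim]), na.rm = TRUE),
            5 * max(abs(a$intensity[bulk] - b$intensity[bulk])))
})
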