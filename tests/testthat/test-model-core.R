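# Constitutive functions, unit conversions, penetration length, and the
# nondimensionalization round trip.

test_that("motility switch follows the tanh law and its limits", {
  expect_equal(motility_switch(0.3, 50, c_crit = 0.3, delta = 0.1), 25)
  expect_gte(motility_switch(0.3 + 5 * 0.1, 1, 0.3, 0.1), 0.9999)
  # frozen from (1 + tanh(-3))/2
  expect_equal(motility_switch(0, 1, c_crit = 0.3, delta = 0.1),
               0.00247262315663, tolerance = 1e-9)
  cgrid <- seq(0, 2, by = 0.01)
  y <- motility_switch(cgrid, 3, 0.3, 0.1)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y > 0 & y < 3))
  expect_error(motility_switch(1, 1, 0.3, delta = 0), "delta")
})

test_that("oxygen sensing is first-order receptor binding", {
  expect_equal(oxygen_sensing(7, 7), 0.5)
  expect_equal(oxygen_sensing(0), 0)
  expect_equal(oxygen_sensing(21, 7), 0.75)
  expect_true(all(diff(oxygen_sensing(seq(0, 100, 1))) > 0))
  expect_lt(oxygen_sensing(1e6), 1)
  expect_error(oxygen_sensing(-1), "non-negative")
})

test_that("uptake rate converts units and saturates correctly", {
  p <- physical_params()
  expect_equal(uptake_rate(0, 0.04, p), 0)
  # saturated limit kO2_0 * ccell / 602.214, frozen
  sat <- 4e4 * 0.04 / 602.214
  expect_equal(sat, 2.6568628, tolerance = 1e-7)
  # Michaelis-Menten at 1e4 K is within 1e-4 of saturation
  expect_equal(uptake_rate(1e4 * max(p$K, p$c_crit), 0.04, p), sat,
               tolerance = 2e-4)
  # Michaelis-Menten midpoint at cO2 = K (switch ~ 1 since c_crit << K)
  expect_equal(uptake_rate(p$K, 0.04, p), sat / 2, tolerance = 1e-3)
  expect_error(uptake_rate(-1, 0.04, p), "non-negative")
})

test_that("penetration length matches the square-root law", {
  p <- physical_params(ccell_0 = cells_per_ml(8e10))
  expect_equal(penetration_length(p), 306.7506, tolerance = 1e-6)
  # quadrupling the concentration halves it
  p4 <- physical_params(ccell_0 = cells_per_ml(3.2e11))
  expect_equal(penetration_length(p4), penetration_length(p) / 2)
  # rich-media uptake ratio sqrt(4/30)
  prich <- physical_params(kO2_0 = 3e5, ccell_0 = cells_per_ml(8e10))
  expect_equal(penetration_length(prich) / penetration_length(p),
               sqrt(4 / 30), tolerance = 1e-12)
})

test_that("penetration length agrees with the steady slab uptake oracle", {
  # dimensionless slab: depth at which O2 is essentially exhausted (below
  # 10% of the surface value), in units of l_O2
  x_p <- slab_decay_depth(K_tilde = 0.004)
  expect_lt(abs(x_p - 1) / 1, 0.2)
})

test_that("nondimensionalize/redimensionalize round-trips to 1e-12", {
  p <- physical_params(R = 1400, ccell_0 = cells_per_ml(4e10))
  dp <- nondimensionalize(p)
  expect_s3_class(dp, "dimensionless_params")
  expect_equal(dp$R_tilde, p$R / penetration_length(p))
  expect_equal(1 / dp$kt_tilde, p$DO2 / (p$kt * penetration_length(p)))
  back <- redimensionalize(dp, p$cO2_sat, p$ccell_0)
  for (nm in names(unclass(p)))
    expect_equal(back[[nm]], p[[nm]], tolerance = 1e-12, label = nm)
})

test_that("reference coordinates are honoured by the dimensionless constructor", {
  # R = 1.4 mm with l_O2 = R/2.7 gives R_tilde = 2.7
  dp <- dimensionless_params(R_tilde = 1400 / (1400 / 2.7), kt_inv = 1)
  expect_equal(dp$R_tilde, 2.7)
  expect_equal(dimensionless_params(1, kt_inv = 0)$kt_tilde, Inf)
  expect_error(dimensionless_params(-1, kt_inv = 1), "positive")
  expect_error(dimensionless_params(1, kt_inv = 1, c_crit_tilde = 0.02),
               "c_crit")
})

test_that("Peclet number is the convective/diffusive transport ratio", {
  expect_equal(peclet(0.05, 3500, 2000), 0.0875)
  expect_lte(peclet(0.05, 3500, 2000), 0.1)
  expect_equal(peclet(0, 3500, 2000), 0)
  expect_equal(peclet(0.05, 7000, 2000), 2 * peclet(0.05, 3500, 2000))
  expect_error(peclet(1, 1, 0), "DO2")
})

test_that("parameter files and presets round-trip", {
  p <- physical_params(R = 999, ccell_0 = 0.033)
  f <- tempfile(fileext = ".par")
  write_params(p, f)
  q <- read_params(f)
  for (nm in names(unclass(p))) expect_equal(q[[nm]], p[[nm]], label = nm)
  for (nm in c("bmb-minimal", "lb-rich", "peo-4x")) {
    pre <- load_preset(nm)
    expect_s3_class(pre, "physical_params")
  }
  expect_equal(load_preset("lb-rich")$kO2_0, 3e5)
  # fourfold-motility variant
  expect_equal(load_preset("peo-4x")$Dcell_0,
               4 * load_preset("bmb-minimal")$Dcell_0)
  expect_equal(load_preset("peo-4x")$chi_0,
               4 * load_preset("bmb-minimal")$chi_0)
  expect_error(read_params(textConnection("nope = 1")))
})

test_that("parameter validation enforces the physical invariants", {
  expect_error(physical_params(c_crit = 2), "K_chi")
  expect_error(physical_params(delta = 0.06, c_crit = 0.05), "delta")
  expect_error(physical_params(DO2 = -1), "positive")
  expect_silent(physical_params(Dcell_0 = 0, chi_0 = 0))
})
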