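# Observable extraction: core radius and trace, total oxygen, cell totals,
# kymographs, regime classification.

test_that("core radius thresholds contiguously from the centre", {
  g <- radial_grid(2, 64)
  expect_equal(core_radius(rep(1, 64), g, 0.5), 0)
  # step profile anoxic for r < 0.8
  prof <- ifelse(g$r < 0.8, 0, 1)
  expect_lt(abs(core_radius(prof, g, 0.5) - 0.8), g$h)
  # linear ramp: interpolated crossing
  expect_equal(core_radius(pmin(1, g$r), g, 0.5), 0.5, tolerance = 1e-12)
  # fully anoxic
  expect_equal(core_radius(rep(0, 64), g, 0.5), 2)
  # anoxic ring not touching the centre is not a core
  ring <- ifelse(g$r > 0.5 & g$r < 1, 0, 1)
  expect_equal(core_radius(ring, g, 0.5), 0)
})

test_that("core trace summarises formation, peak and vanishing", {
  traj <- run_transient_256()
  tr <- core_trace(traj)
  expect_true(all(tr$r_core >= 0 & tr$r_core <= 2.7))
  expect_equal(tr$ell, 2.7 - tr$r_core)
  expect_true(is.finite(attr(tr, "t_formed")))
  expect_true(is.finite(attr(tr, "t_vanish")))
  expect_gt(attr(tr, "t_vanish"), attr(tr, "t_formed"))
  expect_equal(attr(tr, "ell_init"),
               2.7 - traj$diagnostics$r_core_peak)
  # continuity during erosion: no jump larger than a few grid spacings
  # between frames (formation and the final collapse of the last core
  # remnant are near-instantaneous and excluded)
  mid <- tr$time > traj$diagnostics$t_peak &
    tr$time < traj$diagnostics$t_vanish - 2
  expect_lt(max(abs(diff(tr$r_core[mid]))), 10 * traj$grid$h)
})

test_that("aerobic runs yield an empty core trace", {
  traj <- cached_run("aerobic_small", simulate_droplet(
    dimensionless_params(0.8, kt_inv = 0.7), N = 128))
  tr <- core_trace(traj)
  expect_true(all(tr$r_core == 0))
  expect_true(is.na(attr(tr, "ell_init")))
  expect_true(is.na(attr(tr, "t_vanish")))
})

test_that("total oxygen is normalized, bounded, and rises during erosion", {
  traj <- run_transient_256()
  o2 <- total_oxygen(traj)
  expect_true(all(o2$o2_frac >= 0 & o2$o2_frac <= 1 + 1e-9))
  expect_equal(o2$o2_frac[1], 1)  # saturated initial state
  # monotone nondecreasing once the core has formed fully (erosion phase)
  post <- o2$o2_frac[o2$time >= traj$diagnostics$t_peak + 1]
  expect_true(all(diff(post) >= -1e-4))
})

test_that("total cells equals the disc content initially", {
  g <- radial_grid(2.7, 128)
  expect_equal(total_cells(initial_state(g), g), pi * 2.7^2,
               tolerance = 1e-12)
})

test_that("the three reference conditions classify into distinct regimes", {
  # coarse-grid versions of the reference conditions (the N = 512
  # classifications are exercised in the acceptance suite)
  lab <- function(R, kti, N = 128) {
    classify_regime(cached_run(
      paste0("cls_", R, "_", kti),
      simulate_droplet(dimensionless_params(R, kt_inv = kti), N = N,
                       stop_when = c("steady", "vanish", "plateau"))))$label
  }
  expect_equal(lab(0.96, 2.8), "aerobic")
  # erosion slows on coarser grids; N = 256 as in the reference runs
  expect_equal(classify_regime(run_transient_256())$label,
               "transient_anoxia")
  expect_equal(lab(9.3, 0.7), "permanent_anoxia")
})

test_that("classification is indeterminate when the horizon is too short", {
  traj <- simulate_droplet(dimensionless_params(9.3, kt_inv = 0.7),
                           N = 128, t_max = 20, stop_when = "none")
  expect_warning(lbl <- classify_regime(traj), "indeterminate")
  expect_equal(lbl$label, "indeterminate")
})

test_that("kymographs are tidy, normalized, and anchored at the start", {
  traj <- run_transient_256()
  ky <- kymograph(traj, "c_cell")
  expect_s3_class(ky, "droplet_kymograph")
  expect_equal(nrow(ky), length(traj$times) * traj$grid$N)
  first <- ky$value[ky$time == min(ky$time)]
  expect_equal(first, rep(1, traj$grid$N))  # uniform initial profile
  # the dense immotile interior region (c_cell > 1.5, away from the thin
  # rim accumulation band) shrinks radially and disappears
  interior <- traj$grid$r < 0.9 * traj$grid$R_tilde
  dense_extent <- vapply(seq_along(traj$times), function(j) {
    w <- which(traj$c_cell[interior, j] > 1.5)
    if (length(w)) traj$grid$r[max(w)] else 0
  }, 0)
  expect_gt(max(dense_extent), 0)
  late <- dense_extent[traj$times > traj$diagnostics$t_vanish + 5]
  expect_true(all(late < max(dense_extent) / 4))
  p <- autoplot(ky)
  expect_s3_class(p, "ggplot")
})

test_that("tidiers return one-row summaries", {
  traj <- run_transient_256()
  g <- glance(traj)
  expect_equal(nrow(g), 1)
  expect_true(g$vanished)
  td <- tidy(suppressWarnings(classify_regime(traj)))
  expect_equal(td$label, "transient_anoxia")
  tb <- tibble::as_tibble(traj)
  expect_named(tb, c("time", "r", "c_oxy", "c_cell"))
  expect_equal(nrow(tb), length(traj$times) * 256)
})
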