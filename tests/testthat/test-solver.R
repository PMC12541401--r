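# Finite-volume integrator: grid geometry, fixed points, analytic steady
# profiles, conservation, bounds, and equivalence with a brute-force
# explicit-Euler reference.

test_that("radial grid geometry is exact", {
  g <- radial_grid(1, 100)
  expect_equal(g$h, 0.01)
  expect_equal(tail(g$faces, 1), 1)
  expect_equal(sum(g$w), pi, tolerance = 1e-12)
  g2 <- radial_grid(9.3, 1024)
  expect_equal(g2$h, 9.3 / 1024)  # ~9.082e-3
  expect_equal(sum(g2$w), pi * 9.3^2, tolerance = 1e-12)
  expect_error(radial_grid(1, 8), "16")
})

test_that("uniform initial state carries the right totals", {
  g <- radial_grid(3, 64)
  st <- initial_state(g)
  expect_true(all(st$c_oxy == 1) && all(st$c_cell == 1))
  expect_equal(total_cells(st, g), pi * 9, tolerance = 1e-12)
})

test_that("uniform state with no uptake and no aerotaxis is a fixed point", {
  p <- dimensionless_params(2, kt_inv = 1, chi_tilde = 0)
  g <- radial_grid(2, 64)
  st <- advance(initial_state(g), p, dt = 2, g,
                test_opts = list(uptake_amp = 0))
  expect_equal(st$c_oxy, rep(1, 64), tolerance = 1e-12)
  expect_equal(st$c_cell, rep(1, 64), tolerance = 1e-12)
})

test_that("without a sink, oxygen relaxes monotonically to saturation", {
  p <- dimensionless_params(2, kt_inv = 1)
  g <- radial_grid(2, 64)
  st <- initial_state(g)
  st$c_oxy <- rep(0.5, 64)
  prev <- st
  for (i in 1:5) {
    nxt <- advance(prev, p, dt = 0.5, g, test_opts = list(uptake_amp = 0))
    expect_true(all(nxt$c_oxy >= prev$c_oxy - 1e-12))
    expect_true(all(nxt$c_oxy <= 1 + 1e-9))
    prev <- nxt
  }
  far <- advance(st, p, dt = 40, g, test_opts = list(uptake_amp = 0))
  expect_equal(far$c_oxy, rep(1, 64), tolerance = 1e-6)
})

test_that("constant-sink steady state matches the disc Poisson closed form", {
  # near-Dirichlet interface, frozen uniform cells, constant sink Q
  p <- dimensionless_params(1, kt_tilde = 1e6)
  traj <- simulate_droplet(p, N = 512, t_max = 10, cadence = 10,
                           stop_when = "none",
                           test_opts = list(sink_mode = 1, sink_q = 1,
                                            evolve_cells = FALSE))
  num <- traj$c_oxy[, length(traj$times)]
  exact <- steady_disc_oracle(1, 1, traj$grid)
  expect_lt(max(abs(num - exact) / abs(exact)), 1e-3)
})

test_that("steady disc oracle evaluates the closed form", {
  g <- radial_grid(2, 64)
  expect_equal(steady_disc_oracle(0, 0.7, g), rep(0.7, 64))
  expect_equal(min(steady_disc_oracle(1, 1, g)), 1 - (4 - g$r[1]^2) / 4)
  expect_lt(abs(steady_disc_oracle(1, 1, g)[1]), 1e-3)  # centre ~ 0
  expect_error(steady_disc_oracle(-1, 1, g), "non-negative")
})

test_that("production solver matches the explicit-Euler reference", {
  p <- dimensionless_params(2, kt_inv = 1)
  N <- 64
  ref <- euler_reference(p, N, t_end = 1, dt = 5e-5)
  traj <- simulate_droplet(p, N = N, t_max = 1, cadence = 1,
                           dt_max = 1e-4, stop_when = "none")
  n <- length(traj$times)
  l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
  expect_lt(l2(traj$c_oxy[, n], ref$oxy), 1e-3)
  expect_lt(l2(traj$c_cell[, n], ref$cel), 1e-3)
})

test_that("cells are conserved and oxygen stays within physical bounds", {
  traj <- run_transient_256()
  d <- traj$diagnostics
  expect_lt(d$mass_rel_error, 1e-8)
  tc <- total_cells(traj)
  expect_lt(max(abs(tc$cells - tc$cells[1])) / tc$cells[1], 1e-8)
  expect_gte(min(traj$c_oxy), 0)
  expect_lte(max(traj$c_oxy), 1 + 1e-9)
  expect_gte(min(traj$c_cell), -1e-12)
})

test_that("formation annulus width is grid-converged (N = 512 vs 1024)", {
  p <- dimensionless_params(9.3, kt_inv = 0.7)
  ell <- vapply(c(512, 1024), function(N) {
    tr <- simulate_droplet(p, N = N, t_max = 8, stop_when = "none")
    attr(core_trace(tr), "ell_init")
  }, 0)
  expect_lt(abs(ell[2] - ell[1]) / ell[1], 0.02)
})

test_that("fourfold-enhanced motility erodes the transient core faster", {
  base <- run_transient_256()
  fast <- cached_run("transient_4x_256", simulate_droplet(
    dimensionless_params(2.7, kt_inv = 1, Dcell_tilde = 4 * 0.05,
                         chi_tilde = 4 * 2),
    N = 256, stop_when = c("steady", "vanish")))
  expect_true(base$diagnostics$vanished && fast$diagnostics$vanished)
  expect_lt(fast$diagnostics$t_vanish, base$diagnostics$t_vanish)
})

test_that("trajectories persist to text files and back", {
  traj <- simulate_droplet(dimensionless_params(1.5, kt_inv = 1), N = 32,
                           t_max = 2, cadence = 1, stop_when = "none")
  pre <- file.path(tempdir(), "traj_test")
  write_trajectory(traj, pre)
  back <- read_trajectory(pre)
  expect_equal(back$times, traj$times)
  expect_equal(back$c_oxy, traj$c_oxy, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$params$R_tilde, 1.5)
  expect_equal(back$diagnostics$t_end, traj$diagnostics$t_end)
})
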