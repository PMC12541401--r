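# R-facing layer over the compiled finite-volume integrator.

#' Uniform face-centred radial grid on a disc
#'
#' Builds the cell-centred finite-volume grid on `[0, R_tilde]`: `N` control
#' volumes with faces at `i*h`, centres at `(i - 1/2)*h`, `h = R_tilde/N`.
#' Regularity at the origin is enforced by a zero-flux inner face; the
#' annular volume weights `2*pi*r_i*h` sum exactly to the disc area.
#'
#' @param R_tilde dimensionless droplet radius (> 0).
#' @param N number of control volumes (>= 16).
#' @return an object of class `radial_grid`: list with `N`, `R_tilde`, `h`,
#'   centres `r`, `faces`, and volume weights `w = 2*pi*r*h`.
#' @examples
#' g <- radial_grid(1, 100)
#' sum(g$w)  # pi
#' @export
radial_grid <- function(R_tilde, N = 512) {
  if (!is.numeric(N) || length(N) != 1L || N < 16 || N != round(N))
    stop("`N` must be an integer >= 16")
  if (R_tilde <= 0) stop("`R_tilde` must be strictly positive")
  N <- as.integer(N)
  h <- R_tilde / N
  r <- (seq_len(N) - 0.5) * h
  structure(list(N = N, R_tilde = R_tilde, h = h, r = r,
                 faces = (0:N) * h, w = 2 * pi * r * h),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("<radial_grid> N = %d on [0, %.4g], h = %.4g\n",
              x$N, x$R_tilde, x$h))
  invisible(x)
}

#' Initial field state: uniform saturated suspension
#'
#' Cells uniformly dispersed at the loading concentration and oxygen at its
#' air-equilibrated saturation value everywhere (suspensions are prepared
#' aerobically), i.e. both dimensionless fields equal to 1 at `t = 0`.
#'
#' @param grid a [radial_grid()].
#' @return an object of class `field_state`: list with `t`, `c_oxy`, `c_cell`.
#' @export
initial_state <- function(grid) {
  structure(list(t = 0, c_oxy = rep(1, grid$N), c_cell = rep(1, grid$N)),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> t = %.4g, N = %d, c_oxy in [%.3g, %.3g], ",
              x$t, length(x$c_oxy), min(x$c_oxy), max(x$c_oxy)))
  cat(sprintf("c_cell in [%.3g, %.3g]\n", min(x$c_cell), max(x$c_cell)))
  invisible(x)
}

solver_args <- function(params, grid, test_opts = list()) {
  stopifnot(inherits(params, "dimensionless_params"))
  opts <- list(uptake_amp = 1, sink_mode = 0L, sink_q = 0,
               evolve_cells = TRUE)
  opts[names(test_opts)] <- test_opts
  list(N = grid$N, R_tilde = grid$R_tilde, kt_tilde = params$kt_tilde,
       Dcell = params$Dcell_tilde, chi = params$chi_tilde,
       K = params$K_tilde, Kchi = params$K_chi_tilde,
       ccrit = params$c_crit_tilde, delta = params$delta_tilde,
       uptake_amp = opts$uptake_amp, sink_mode = as.integer(opts$sink_mode),
       sink_q = opts$sink_q, evolve_cells = isTRUE(opts$evolve_cells))
}

#' Advance a field state by a given time interval
#'
#' Integrates the dimensionless system from `state$t` to `state$t + dt`,
#' internally sub-stepping as required by the advective CFL condition and
#' halving the step on any positivity violation. One call with a small `dt`
#' is a single scheme step; larger `dt` is honoured exactly via sub-steps.
#'
#' @param state a [field_state][initial_state()].
#' @param params a [dimensionless_params()] object.
#' @param dt dimensionless time interval (> 0).
#' @param grid the [radial_grid()] the state lives on.
#' @param cfl advective CFL safety factor (default 0.4).
#' @param dt_max accuracy cap on the internal step (default `0.5*h`).
#' @param test_opts internal solver switches (see [simulate_droplet()]).
#' @return the advanced `field_state`.
#' @export
advance <- function(state, params, dt, grid, cfl = 0.4,
                    dt_max = 0.5 * grid$h, test_opts = list()) {
  if (dt <= 0) stop("`dt` must be strictly positive")
  a <- solver_args(params, grid, test_opts)
  res <- do.call(fv_integrate, c(a, list(
    c_oxy0 = state$c_oxy, c_cell0 = state$c_cell,
    t0 = state$t, t_max = state$t + dt, cadence = 0,
    cfl = cfl, dt_max = min(dt_max, dt),
    steady_tol = 0, steady_window = Inf,
    plateau_rate = 0, plateau_window = Inf,
    stop_on_steady = FALSE, stop_on_anoxia = FALSE, stop_on_vanish = FALSE,
    stop_on_plateau = FALSE)))
  n <- length(res$times)
  structure(list(t = res$t_end, c_oxy = res$c_oxy[, n],
                 c_cell = res$c_cell[, n]),
            class = "field_state")
}

#' Simulate the confined-droplet model
#'
#' Integrates the dimensionless oxygen-bacteria system from the uniform
#' saturated initial condition (or a supplied state) and returns the sampled
#' trajectory with solver diagnostics: anoxic-core formation/vanishing times
#' (tracked at full step resolution), the maximal core extent, steady-state
#' detection, the cell-mass ledger, and the global oxygen minimum.
#'
#' Physical parameters are nondimensionalized automatically. The default
#' horizon is the classification horizon `max(50, 10*R_tilde^2)` diffusive
#' time units, long enough for core erosion, which operates on the
#' droplet-scale diffusion time; by default the run stops early once the
#' steady-state criterion (max field rate < `steady_tol` sustained over one
#' diffusive time unit) is met.
#'
#' @param params a [dimensionless_params()] or [physical_params()] object.
#' @param N number of control volumes (default 512).
#' @param t_max horizon in diffusive time units; default
#'   `max(50, 10*R_tilde^2)`.
#' @param cadence output sampling interval; default `t_max/400`.
#' @param init optional initial [field_state][initial_state()]; default
#'   uniform saturated.
#' @param cfl advective CFL safety factor.
#' @param dt_max accuracy cap on the time step; default `0.5*h`.
#' @param steady_tol steady-state rate threshold (dimensionless per unit
#'   time).
#' @param steady_window time the rate must stay below `steady_tol`.
#' @param plateau_rate core-radius drift rate (penetration lengths per
#'   diffusive time) below which the core is considered plateaued.
#' @param plateau_window trailing window (time units) over which the drift
#'   must stay below `plateau_rate`.
#' @param stop_when early-stop policy, one or several of `"steady"`
#'   (default), `"anoxia"` (stop once any grid cell goes anoxic; used by
#'   onset bisection), `"vanish"` (stop when a formed core disappears),
#'   `"plateau"` (stop once the core radius has plateaued), and `"none"`;
#'   the run stops at the first triggered condition.
#' @param test_opts internal switches for verification runs: `uptake_amp`
#'   (scales the uptake term; 0 disables it), `sink_mode` (0 =
#'   Michaelis-Menten, 1 = constant volumetric sink `sink_q`), `sink_q`,
#'   and `evolve_cells` (FALSE freezes the cell field).
#' @return an object of class `droplet_trajectory`.
#' @examples
#' \donttest{
#' traj <- simulate_droplet(dimensionless_params(2.7, kt_inv = 1), N = 128)
#' classify_regime(traj)
#' }
#' @export
simulate_droplet <- function(params, N = 512, t_max = NULL, cadence = NULL,
                             init = NULL, cfl = 0.4, dt_max = NULL,
                             steady_tol = 1e-6, steady_window = 1,
                             plateau_rate = 1e-3, plateau_window = 50,
                             stop_when = c("steady", "anoxia", "vanish",
                                           "plateau", "none"),
                             test_opts = list()) {
  if (inherits(params, "physical_params")) params <- nondimensionalize(params)
  stopifnot(inherits(params, "dimensionless_params"))
  stop_when <- match.arg(stop_when, several.ok = TRUE)
  if ("none" %in% stop_when) stop_when <- "none"
  grid <- radial_grid(params$R_tilde, N)
  if (is.null(t_max)) t_max <- max(50, 10 * params$R_tilde^2)
  if (t_max <= 0) stop("`t_max` must be strictly positive")
  if (is.null(cadence)) cadence <- t_max / 400
  if (is.null(dt_max)) dt_max <- 0.5 * grid$h
  if (is.null(init)) init <- initial_state(grid)

  a <- solver_args(params, grid, test_opts)
  res <- do.call(fv_integrate, c(a, list(
    c_oxy0 = init$c_oxy, c_cell0 = init$c_cell,
    t0 = init$t, t_max = t_max, cadence = cadence,
    cfl = cfl, dt_max = dt_max,
    steady_tol = steady_tol, steady_window = steady_window,
    plateau_rate = plateau_rate, plateau_window = plateau_window,
    stop_on_steady = "steady" %in% stop_when,
    stop_on_anoxia = "anoxia" %in% stop_when,
    stop_on_vanish = "vanish" %in% stop_when,
    stop_on_plateau = "plateau" %in% stop_when)))

  diagnostics <- list(
    t_end = res$t_end, t_max_requested = t_max,
    formed = res$formed, t_formed = res$t_formed,
    vanished = res$vanished, t_vanish = res$t_vanish,
    steady = res$steady, t_steady = res$t_steady,
    plateau = res$plateau, t_plateau = res$t_plateau,
    r_core_plateau = res$r_core_plateau,
    r_core_peak = res$r_core_peak, t_peak = res$t_peak,
    max_r_core = res$max_r_core, t_max_r_core = res$t_max_r_core,
    min_oxy = res$min_oxy,
    n_steps = res$n_steps, n_reject = res$n_reject,
    cell_mass_initial = res$cell_mass_initial,
    cell_mass_final = res$cell_mass_final,
    mass_rel_error = abs(res$cell_mass_final - res$cell_mass_initial) /
      res$cell_mass_initial,
    stop_when = paste(stop_when, collapse = "+"))

  structure(list(times = res$times, grid = grid,
                 c_oxy = res$c_oxy, c_cell = res$c_cell,
                 r_core = res$r_core, params = params,
                 diagnostics = diagnostics),
            class = "droplet_trajectory")
}

#' Analytic steady profile of a uniformly absorbing disc
#'
#' Closed-form steady solution of `(1/r) d/dr(r dc/dr) = Q` on a disc with
#' edge value `c_edge`: `c(r) = c_edge - Q*(R_tilde^2 - r^2)/4`. Serves as an
#' independent oracle for the finite-volume diffusion operator when the sink
#' is frozen to a constant.
#'
#' @param Q constant volumetric sink (>= 0).
#' @param c_edge concentration at the rim r = R_tilde.
#' @param grid a [radial_grid()].
#' @return the profile evaluated at the grid centres.
#' @examples
#' g <- radial_grid(2, 64)
#' steady_disc_oracle(1, 1, g)[1]  # near 0 at the centre
#' @export
steady_disc_oracle <- function(Q, c_edge, grid) {
  if (Q < 0) stop("`Q` must be non-negative")
  c_edge - Q * (grid$R_tilde^2 - grid$r^2) / 4
}

#' @export
print.droplet_trajectory <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<droplet_trajectory> R_tilde = %.4g, kt_inv = %.4g, N = %d\n",
              x$params$R_tilde, 1 / x$params$kt_tilde, x$grid$N))
  cat(sprintf("  %d states over t = [%.4g, %.4g] (%g steps, %g rejected)\n",
              length(x$times), x$times[1], d$t_end, d$n_steps, d$n_reject))
  cat(sprintf("  core: formed = %s (t = %.4g), vanished = %s (t = %.4g), max r_core = %.4g\n",
              d$formed, d$t_formed, d$vanished, d$t_vanish, d$max_r_core))
  cat(sprintf("  steady = %s (t = %.4g); min c_oxy = %.3g; cell-mass rel. drift = %.2e\n",
              d$steady, d$t_steady, d$min_oxy, d$mass_rel_error))
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' @param x a `droplet_trajectory`.
#' @param ... unused.
#' @return a tibble with columns `time`, `r`, `c_oxy`, `c_cell`.
#' @exportS3Method tibble::as_tibble
as_tibble.droplet_trajectory <- function(x, ...) {
  nt <- length(x$times)
  tibble::tibble(
    time = rep(x$times, each = x$grid$N),
    r = rep(x$grid$r, nt),
    c_oxy = as.vector(x$c_oxy),
    c_cell = as.vector(x$c_cell))
}

#' Extract a single field state from a trajectory
#'
#' @param traj a `droplet_trajectory`.
#' @param i snapshot index (default: last).
#' @return a `field_state`.
#' @export
get_state <- function(traj, i = length(traj$times)) {
  structure(list(t = traj$times[i], c_oxy = traj$c_oxy[, i],
                 c_cell = traj$c_cell[, i]),
            class = "field_state")
}
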