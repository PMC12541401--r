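# Measured quantities extracted from trajectories: anoxic-core radius,
# annulus width, total oxygen content, cell totals, kymographs, and the
# three-way regime classification.

#' Anoxic-core radius of a radial oxygen profile
#'
#' The outer radius of the contiguous central region where oxygen lies below
#' the anoxia threshold (taken equal to the motility-switch threshold: the
#' core is identified with both anoxia and motility loss). The crossing
#' between adjacent cell centres is located by linear interpolation; 0 is
#' returned when no grid cell is anoxic.
#'
#' @param c_oxy dimensionless oxygen profile at the grid centres, or a
#'   [field_state][initial_state()].
#' @param grid the [radial_grid()] the profile lives on.
#' @param c_crit_tilde dimensionless anoxia threshold.
#' @return the core radius, dimensionless, in `[0, R_tilde]`.
#' @examples
#' g <- radial_grid(2, 64)
#' core_radius(pmin(1, g$r), g, c_crit_tilde = 0.5)  # ~0.5
#' @export
core_radius <- function(c_oxy, grid, c_crit_tilde = 2e-4) {
  if (inherits(c_oxy, "field_state")) c_oxy <- c_oxy$c_oxy
  stopifnot(length(c_oxy) == grid$N)
  core_radius_cpp(c_oxy, c_crit_tilde, grid$h, grid$R_tilde)
}

#' Core radius and annulus width over time
#'
#' Applies [core_radius()] to every stored state of a trajectory and derives
#' the annulus width `ell = R_tilde - r_core`. The summary attributes use
#' the solver's full-step-resolution event tracking (not just the sampled
#' frames): `ell_init` is the annulus width at the first local maximum of
#' the core radius (the maximal core extent of the rapid formation phase,
#' before the slight shrink-back and slow late-time drift), and `t_vanish`
#' the first time after formation at which the core radius returns to zero
#' (NA if it never forms or never vanishes).
#'
#' @param traj a `droplet_trajectory`, or any object with fields `times`,
#'   `c_oxy` (matrix), a `grid`, and optionally `diagnostics`.
#' @param c_crit_tilde anoxia threshold; defaults to the trajectory's own
#'   motility-switch threshold.
#' @return a tibble of class `core_trace` with columns `time`, `r_core`,
#'   `ell`, and attributes `ell_init`, `t_formed`, `t_vanish`,
#'   `r_core_max`, `R_tilde`.
#' @export
core_trace <- function(traj, c_crit_tilde = NULL) {
  if (is.null(c_crit_tilde)) c_crit_tilde <- traj$params$c_crit_tilde
  if (length(traj$times) < 2) stop("trajectory must hold at least 2 states")
  rc <- vapply(seq_along(traj$times), function(j) {
    prof <- traj$c_oxy[, j]
    if (anyNA(prof)) return(NA_real_)
    core_radius(prof, traj$grid, c_crit_tilde)
  }, 0)
  out <- tibble::tibble(time = traj$times, r_core = rc,
                        ell = traj$grid$R_tilde - rc)
  d <- traj$diagnostics
  if (is.null(d)) {
    # frame-resolution fallback (e.g. phantom-recovered fields)
    formed_idx <- which(!is.na(rc) & rc > 0)
    t_formed <- if (length(formed_idx)) traj$times[formed_idx[1]] else NA_real_
    r_core_max <- if (length(formed_idx)) max(rc, na.rm = TRUE) else 0
    t_vanish <- NA_real_
    if (length(formed_idx)) {
      after <- which(!is.na(rc) & rc == 0 & traj$times > t_formed)
      if (length(after)) t_vanish <- traj$times[after[1]]
    }
  } else {
    t_formed <- d$t_formed
    t_vanish <- d$t_vanish
    r_core_max <- if (is.finite(d$r_core_peak)) d$r_core_peak else
      d$max_r_core
  }
  ell_init <- if (is.finite(t_formed) && r_core_max > 0)
    traj$grid$R_tilde - r_core_max else NA_real_
  structure(out, class = c("core_trace", class(out)),
            ell_init = ell_init, t_formed = t_formed, t_vanish = t_vanish,
            r_core_max = r_core_max, R_tilde = traj$grid$R_tilde)
}

#' Total oxygen content of the motile annulus over time
#'
#' Integrates the dimensionless oxygen field over the annulus r > r_core(t)
#' and normalizes by the total oxygen content of the droplet at the
#' saturation condition (`c_oxy = 1` over the full disc), giving a value in
#' `[0, 1]`. During core erosion the content rises as influx outpaces
#' uptake. A fully anoxic state (empty annulus) yields 0 with
#' `fully_anoxic = TRUE`.
#'
#' @param traj a `droplet_trajectory`.
#' @param trace optionally a precomputed [core_trace()] for the annulus
#'   bounds.
#' @return a tibble with columns `time`, `o2_frac`, `fully_anoxic`.
#' @export
total_oxygen <- function(traj, trace = NULL) {
  if (is.null(trace)) trace <- core_trace(traj)
  g <- traj$grid
  sat_total <- sum(g$r)  # whole-disc saturation content (in units of h)
  o2 <- vapply(seq_along(traj$times), function(j) {
    if (is.na(trace$r_core[j])) return(NA_real_)
    sel <- g$r > trace$r_core[j]
    if (!any(sel)) return(0)
    sum(traj$c_oxy[sel, j] * g$r[sel]) / sat_total
  }, 0)
  tibble::tibble(time = traj$times, o2_frac = o2,
                 fully_anoxic = trace$ell <= 0)
}

#' Total cell content
#'
#' The annulus-weighted integral `2*pi*sum(c_cell * r * h)` per stored
#' state; conserved by the scheme up to solver round-off, and by the model's
#' assumption of no growth or lysis.
#'
#' @param x a `droplet_trajectory`, or a [field_state][initial_state()]
#'   (then `grid` is required).
#' @param grid the [radial_grid()] (only for a `field_state`).
#' @return for a trajectory, a tibble with columns `time`, `cells`; for a
#'   single state, a scalar.
#' @export
total_cells <- function(x, grid = NULL) {
  if (inherits(x, "field_state")) {
    if (is.null(grid)) stop("`grid` is required for a field_state")
    return(sum(x$c_cell * grid$w))
  }
  tibble::tibble(time = x$times,
                 cells = as.vector(crossprod(x$c_cell, x$grid$w)))
}

#' Classify the morphological regime of a run
#'
#' Three-way classification of a trajectory:
#' \describe{
#'   \item{aerobic}{no anoxic region ever formed;}
#'   \item{transient_anoxia}{a core formed and later vanished;}
#'   \item{permanent_anoxia}{a core formed and persists at steady state.}
#' }
#' "Persists at steady state" accepts either the field-wise steady-state
#' criterion or the operational core plateau (radius drift below
#' `plateau_rate` sustained over `plateau_window`; see
#' [simulate_droplet()]) - at core-forming conditions the discretized model
#' keeps exchanging a slow trickle of cells with the core, so the strict
#' field criterion may never fire even though the morphology is fixed on
#' any observational timescale. A run that reaches neither a vanishing nor
#' steadiness/plateau within its horizon is labelled `indeterminate` with a
#' warning (raise `t_max`). A core that vanishes at any time within the
#' horizon is transient regardless of later behaviour (the dynamics are
#' deterministic).
#'
#' @param traj a `droplet_trajectory`.
#' @return an object of class `regime_label`: list with `label` and
#'   diagnostics (`t_formed`, `t_vanish`, `r_core_steady`, `steady`,
#'   `t_end`).
#' @export
classify_regime <- function(traj) {
  d <- traj$diagnostics
  finished <- d$steady || d$t_end >= d$t_max_requested * (1 - 1e-9)
  r_core_end <- core_radius(traj$c_oxy[, length(traj$times)], traj$grid,
                            traj$params$c_crit_tilde)
  settled <- d$steady || isTRUE(d$plateau)
  label <- if (d$formed && d$vanished) {
    "transient_anoxia"
  } else if (d$formed && settled && r_core_end > 0) {
    "permanent_anoxia"
  } else if (!d$formed && finished) {
    "aerobic"
  } else {
    warning("run neither vanished nor reached steadiness within the ",
            "horizon; classification is indeterminate - raise `t_max`")
    "indeterminate"
  }
  structure(list(label = label, t_formed = d$t_formed,
                 t_vanish = d$t_vanish,
                 r_core_steady = if (settled) r_core_end else NA_real_,
                 steady = d$steady, t_end = d$t_end),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("<regime_label> %s\n", x$label))
  cat(sprintf("  t_formed = %.4g, t_vanish = %.4g, steady r_core = %.4g\n",
              x$t_formed, x$t_vanish, x$r_core_steady))
  invisible(x)
}

#' Kymograph of a trajectory field
#'
#' Space-time table of the azimuthally averaged radial profile. The cell
#' field is normalized by its initial spatially uniform value (identically 1
#' for dimensionless solver output, but meaningful for recovered phantom
#' fields).
#'
#' @param traj a `droplet_trajectory` (or compatible list).
#' @param field `"c_cell"` or `"c_oxy"`.
#' @param normalize normalize the cell field by its initial uniform value
#'   (default TRUE for `c_cell`, never for `c_oxy`).
#' @return a tibble of class `droplet_kymograph` with columns `time`, `r`,
#'   `value` and attribute `field`.
#' @export
kymograph <- function(traj, field = c("c_cell", "c_oxy"),
                      normalize = NULL) {
  field <- match.arg(field)
  m <- traj[[field]]
  if (is.null(normalize)) normalize <- field == "c_cell"
  if (normalize && field == "c_cell") {
    c0 <- mean(m[, 1])
    if (c0 > 0) m <- m / c0
  }
  nt <- length(traj$times)
  out <- tibble::tibble(time = rep(traj$times, each = traj$grid$N),
                        r = rep(traj$grid$r, nt),
                        value = as.vector(m))
  structure(out, class = c("droplet_kymograph", class(out)), field = field)
}
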