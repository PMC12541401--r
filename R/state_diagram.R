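# Parameter sweeps over (R_tilde, kt_inv), bisection of the phase
# boundaries, and the annulus-width scaling analysis.

regime_rank <- c(aerobic = 1L, transient_anoxia = 2L, permanent_anoxia = 3L)

#' Sweep the morphological state diagram
#'
#' Runs one classification per point of the `(R_tilde, kt_inv)` grid
#' (full factorial). Failures and indeterminate runs are recorded per point,
#' never silently dropped. After the sweep, label monotonicity along
#' `R_tilde` at each `kt_inv` (aerobic, then transient, then permanent) is
#' checked and any interleaving raises a warning.
#'
#' @param R_tilde numeric vector of dimensionless radii.
#' @param kt_inv numeric vector of inverse mass-transfer numbers.
#' @param N control volumes per run.
#' @param dimless_args extra arguments to [dimensionless_params()] (e.g. the
#'   fourfold-motility variant).
#' @param ... passed to [simulate_droplet()].
#' @return a tibble of class `droplet_sweep`: one row per grid point with
#'   `R_tilde`, `kt_inv`, `label`, `t_formed`, `t_vanish`, `r_core_steady`,
#'   `min_oxy`, `error`.
#' @export
sweep_state_diagram <- function(R_tilde, kt_inv, N = 256,
                                dimless_args = list(), ...) {
  if (!length(R_tilde) || !length(kt_inv))
    stop("`R_tilde` and `kt_inv` must be nonempty")
  pts <- tidyr::crossing(R_tilde = R_tilde, kt_inv = kt_inv)
  rows <- purrr::pmap(pts, function(R_tilde, kt_inv) {
    res <- tryCatch({
      p <- do.call(dimensionless_params,
                   c(list(R_tilde = R_tilde, kt_inv = kt_inv), dimless_args))
      traj <- simulate_droplet(p, N = N,
                               stop_when = c("steady", "vanish", "plateau"),
                               ...)
      lab <- suppressWarnings(classify_regime(traj))
      tibble::tibble(label = lab$label, t_formed = lab$t_formed,
                     t_vanish = lab$t_vanish,
                     r_core_steady = lab$r_core_steady,
                     min_oxy = traj$diagnostics$min_oxy, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(label = "error", t_formed = NA_real_,
                     t_vanish = NA_real_, r_core_steady = NA_real_,
                     min_oxy = NA_real_, error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_cols(pts, dplyr::bind_rows(rows))
  check_label_monotonicity(out)
  structure(out, class = c("droplet_sweep", class(out)))
}

check_label_monotonicity <- function(sweep) {
  ok <- sweep |>
    dplyr::filter(.data$label %in% names(regime_rank)) |>
    dplyr::mutate(rank = regime_rank[.data$label]) |>
    dplyr::arrange(.data$kt_inv, .data$R_tilde) |>
    dplyr::group_by(.data$kt_inv) |>
    dplyr::summarise(mono = !is.unsorted(.data$rank), .groups = "drop")
  if (any(!ok$mono))
    warning("regime labels interleave along R_tilde at kt_inv = ",
            paste(ok$kt_inv[!ok$mono], collapse = ", "))
  invisible(all(ok$mono))
}

bisect_on <- function(lo, hi, probe, tol, lab_lo, lab_hi) {
  evals <- list()
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    up <- probe(mid)
    evals[[length(evals) + 1L]] <- tibble::tibble(R_tilde = mid, upper = up)
    if (up) hi <- mid else lo <- mid
  }
  list(estimate = (lo + hi) / 2, lower = lo, upper = hi,
       evaluations = dplyr::bind_rows(evals))
}

#' Locate the aerobic / anoxia onset boundary
#'
#' Bisects in `R_tilde` at fixed `kt_inv` on the criterion "does the oxygen
#' concentration drop below the anoxia threshold anywhere, at any time".
#' Each probe integrates the model until either anoxia appears or the
#' steady-state criterion is met, so the space-time minimum is final.
#'
#' @param kt_inv inverse mass-transfer number(s); vectorised.
#' @param R_lo,R_hi initial bracket; the run at `R_lo` must stay aerobic and
#'   the run at `R_hi` must go anoxic, otherwise an error prompts a wider
#'   search.
#' @param tol bracket width at which bisection stops (default 0.1).
#' @param N control volumes per probe.
#' @param dimless_args extra arguments to [dimensionless_params()].
#' @param ... passed to [simulate_droplet()].
#' @return a tibble with one row per `kt_inv`: `kt_inv`, `R_star` (bracket
#'   midpoint), `lower`, `upper`, `n_probe`.
#' @export
onset_boundary <- function(kt_inv, R_lo = 0.5, R_hi = 2, tol = 0.1,
                           N = 256, dimless_args = list(), ...) {
  purrr::map_dfr(kt_inv, function(kti) {
    probe <- function(R) {
      p <- do.call(dimensionless_params,
                   c(list(R_tilde = R, kt_inv = kti), dimless_args))
      traj <- simulate_droplet(p, N = N,
                               stop_when = c("steady", "anoxia"), ...)
      traj$diagnostics$formed
    }
    if (probe(R_lo))
      stop("R_lo = ", R_lo, " already goes anoxic at kt_inv = ", kti,
           "; widen the bracket downward")
    if (!probe(R_hi))
      stop("R_hi = ", R_hi, " stays aerobic at kt_inv = ", kti,
           "; widen the bracket upward")
    b <- bisect_on(R_lo, R_hi, probe, tol)
    tibble::tibble(kt_inv = kti, R_star = b$estimate, lower = b$lower,
                   upper = b$upper, n_probe = nrow(b$evaluations) + 2L)
  })
}

#' Locate the transient / permanent anoxia boundary
#'
#' Bisects in `R_tilde` at fixed `kt_inv` on the regime classification:
#' permanent anoxia above the boundary, non-permanent (transient, or aerobic
#' where the transient window closes) below. Probes run until the core
#' vanishes or the steady-state criterion is met; an indeterminate
#' classification inside the bracket raises an error reporting the offending
#' horizon.
#'
#' @param kt_inv inverse mass-transfer number(s); vectorised.
#' @param R_lo,R_hi initial bracket: non-permanent at `R_lo`, permanent at
#'   `R_hi`.
#' @param tol bracket width (default 0.25; these runs are long).
#' @param N control volumes per probe (default 256, coarse by design).
#'   Probes run with horizon `max(200, 10*R_tilde^2)`: erosion slows near
#'   the boundary and the plateau certification needs its trailing window.
#' @param dimless_args extra arguments to [dimensionless_params()].
#' @param ... passed to [simulate_droplet()].
#' @return a tibble with one row per `kt_inv`: `kt_inv`, `R_dagger`,
#'   `lower`, `upper`, `n_probe`.
#' @export
permanence_boundary <- function(kt_inv, R_lo = 1, R_hi = 6, tol = 0.25,
                                N = 256, dimless_args = list(), ...) {
  purrr::map_dfr(kt_inv, function(kti) {
    probe <- function(R) {
      p <- do.call(dimensionless_params,
                   c(list(R_tilde = R, kt_inv = kti), dimless_args))
      traj <- simulate_droplet(p, N = N, t_max = max(200, 10 * R^2),
                               stop_when = c("steady", "vanish", "plateau"),
                               ...)
      lab <- withCallingHandlers(
        classify_regime(traj),
        warning = function(w) invokeRestart("muffleWarning"))
      if (lab$label == "indeterminate")
        stop("indeterminate classification at (R_tilde = ", R,
             ", kt_inv = ", kti, ") with t_max = ",
             traj$diagnostics$t_max_requested, "; raise `t_max`")
      lab$label == "permanent_anoxia"
    }
    if (probe(R_lo))
      stop("R_lo = ", R_lo, " is already permanent at kt_inv = ", kti,
           "; widen the bracket downward")
    if (!probe(R_hi))
      stop("R_hi = ", R_hi, " is not permanent at kt_inv = ", kti,
           "; widen the bracket upward")
    b <- bisect_on(R_lo, R_hi, probe, tol)
    tibble::tibble(kt_inv = kti, R_dagger = b$estimate, lower = b$lower,
                   upper = b$upper, n_probe = nrow(b$evaluations) + 2L)
  })
}

#' Fit the linear (unsaturated-influx) permanence boundary
#'
#' Origin-constrained least squares of the boundary `R_dagger = a * kt_tilde`
#' (i.e. `a / kt_inv`), the predicted form when oxygen does not saturate at
#' the interface (`kt_inv > 1`).
#'
#' @param points a data frame with columns `kt_inv` and `R_dagger` (or
#'   `R_star`); at least 2 rows with `kt_inv > 1`.
#' @return an object of class `boundary_fit_linear` with the prefactor `a`,
#'   its standard error, fitted values and residuals. Supports [tidy()] and
#'   [glance()].
#' @export
fit_boundary_linear <- function(points) {
  ycol <- if ("R_dagger" %in% names(points)) "R_dagger" else "R_star"
  pts <- points[points$kt_inv > 1, , drop = FALSE]
  if (nrow(pts) < 2)
    stop("need at least 2 boundary points with kt_inv > 1")
  x <- 1 / pts$kt_inv
  y <- pts[[ycol]]
  a <- sum(x * y) / sum(x * x)
  resid <- y - a * x
  se <- if (nrow(pts) > 2)
    sqrt(sum(resid^2) / (nrow(pts) - 1) / sum(x * x)) else NA_real_
  structure(list(a = a, se = se, points = tibble::as_tibble(pts),
                 fitted = a * x, residuals = resid),
            class = "boundary_fit_linear")
}

#' @export
print.boundary_fit_linear <- function(x, ...) {
  cat(sprintf("<boundary_fit_linear> R_dagger = a * kt_tilde, a = %.4g\n",
              x$a))
  invisible(x)
}

#' Fit the saturating permanence boundary
#'
#' Nonlinear least squares of `R_dagger = A/(B + C*kt_inv)`, the boundary
#' form interpolating between the saturation-limited plateau (`kt_inv << 1`)
#' and the linear regime (`kt_inv >> 1`). The form is degenerate under joint
#' rescaling of `(A, B, C)`; the scale is fixed by holding `B` at its
#' starting value, and the identifiable ratios `A/B` (plateau) and `A/C`
#' (linear prefactor) are reported alongside the raw coefficients.
#'
#' @param points a data frame with columns `kt_inv` and `R_dagger` (or
#'   `R_star`); at least 4 points spanning `kt_inv < 1` and `> 1`.
#' @param start named start values `c(A, B, C)`.
#' @return an object of class `boundary_fit_saturating` with coefficients,
#'   ratios, residuals and the underlying `nls` object. Supports [tidy()]
#'   and [glance()].
#' @export
fit_boundary_saturating <- function(points,
                                    start = c(A = 18.9, B = 4.1, C = 1.9)) {
  ycol <- if ("R_dagger" %in% names(points)) "R_dagger" else "R_star"
  if (nrow(points) < 4) stop("need at least 4 boundary points")
  if (all(points$kt_inv >= 1) || all(points$kt_inv <= 1))
    warning("boundary points do not span kt_inv < 1 and > 1; ",
            "the plateau and linear regimes are not both constrained")
  B0 <- unname(start["B"])
  df <- data.frame(x = points$kt_inv, y = points[[ycol]])
  fit <- minpack.lm::nlsLM(
    y ~ A / (B0 + C * x), data = df,
    start = list(A = unname(start["A"]), C = unname(start["C"])),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  resid <- stats::resid(fit)
  structure(list(A = unname(cf["A"]), B = B0, C = unname(cf["C"]),
                 A_over_B = unname(cf["A"]) / B0,
                 A_over_C = unname(cf["A"]) / unname(cf["C"]),
                 residuals = resid, points = tibble::as_tibble(points),
                 nls = fit),
            class = "boundary_fit_saturating")
}

#' @export
print.boundary_fit_saturating <- function(x, ...) {
  cat(sprintf("<boundary_fit_saturating> R_dagger = %.4g/(%.4g + %.4g*kt_inv)\n",
              x$A, x$B, x$C))
  cat(sprintf("  identifiable ratios: A/B = %.4g (plateau), A/C = %.4g\n",
              x$A_over_B, x$A_over_C))
  invisible(x)
}

#' Annulus-width scaling with cell concentration, and uptake-rate recovery
#'
#' Runs the full model at several loading concentrations, extracts the
#' initial motile-annulus width `ell_init` from each run (annulus width at
#' maximal core extent), and fits the penetration-length law
#' `ell_init = sqrt(DO2 * cO2_sat / (kO2 * ccell_0))` for the per-cell
#' uptake rate `kO2`. The fit is linear least squares of `ell_init` against
#' `1/sqrt(ccell_0)` through the origin; the log-log slope (expected -1/2)
#' is reported as a scaling diagnostic. Concentrations too low to form a
#' core are excluded with a warning.
#'
#' @param ccell_0 cell concentrations, cells/um^3 (>= 3 values that produce
#'   cores).
#' @param preset base condition, a preset name or `physical_params` object.
#' @param kt_inv if non-NULL, the interfacial coefficient is rescaled per
#'   concentration so the dimensionless `kt_inv` is held fixed (default
#'   0.7); set NULL to keep the preset's dimensional `kt`.
#' @param N control volumes per run.
#' @param ... passed to [simulate_droplet()].
#' @return an object of class `annulus_scaling`: the per-concentration
#'   table, the recovered `kO2_fit` (molecules s^-1 cell^-1), and the
#'   log-log slope. Supports [tidy()] and [glance()].
#' @export
annulus_scaling <- function(ccell_0, preset = "bmb-minimal", kt_inv = 0.7,
                            N = 512, ...) {
  base <- if (inherits(preset, "physical_params")) preset else
    load_preset(preset)
  if (length(ccell_0) < 3) stop("need at least 3 cell concentrations")
  rows <- purrr::map_dfr(ccell_0, function(cc) {
    p <- base
    p$ccell_0 <- cc
    l <- penetration_length(p)
    if (!is.null(kt_inv)) p$kt <- p$DO2 / (kt_inv * l)
    validate_physical_params(p)
    traj <- simulate_droplet(p, N = N,
                             stop_when = c("steady", "vanish", "plateau"),
                             ...)
    tr <- core_trace(traj)
    tibble::tibble(ccell_0 = cc, l_O2 = l, R_tilde = p$R / l,
                   ell_init_tilde = attr(tr, "ell_init"),
                   ell_init_um = attr(tr, "ell_init") * l,
                   formed = traj$diagnostics$formed)
  })
  if (any(!rows$formed)) {
    warning("no anoxic core at ccell_0 = ",
            paste(signif(rows$ccell_0[!rows$formed], 3), collapse = ", "),
            "; excluded from the fit")
    rows_fit <- rows[rows$formed, , drop = FALSE]
  } else rows_fit <- rows
  if (nrow(rows_fit) < 3)
    stop("fewer than 3 concentrations produced an anoxic core")
  x <- 1 / sqrt(rows_fit$ccell_0)
  y <- rows_fit$ell_init_um
  slope <- sum(x * y) / sum(x * x)     # = sqrt(DO2*cO2_sat/kO2)
  kO2_fit <- base$DO2 * base$cO2_sat * MOLEC_PER_UM3_PER_UM / slope^2
  loglog <- stats::coef(stats::lm(log(y) ~ log(rows_fit$ccell_0)))[[2]]
  structure(list(table = rows, kO2_fit = kO2_fit, loglog_slope = loglog,
                 kO2_preset = base$kO2_0),
            class = "annulus_scaling")
}

#' @export
print.annulus_scaling <- function(x, ...) {
  cat(sprintf("<annulus_scaling> %d concentrations\n", nrow(x$table)))
  cat(sprintf("  recovered kO2 = %.4g molecules/s/cell (preset %.4g)\n",
              x$kO2_fit, x$kO2_preset))
  cat(sprintf("  log-log slope = %.3f (sqrt law: -0.5)\n", x$loglog_slope))
  invisible(x)
}
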