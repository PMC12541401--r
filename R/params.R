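#' Molecules per cubic micrometre in a 1 micromolar solution
#'
#' Unit-conversion constant: 1 uM = 1e-6 mol/L = 602.214 molecules/um^3.
#' Used to convert per-cell uptake rates (molecules s^-1 cell^-1) into
#' volumetric rates (uM/s).
#' @export
MOLEC_PER_UM3_PER_UM <- 602.214

#' Convert a cell concentration from cells/mL to cells/um^3
#'
#' @param x cell concentration in cells per millilitre.
#' @return concentration in cells per cubic micrometre (1 mL = 1e12 um^3).
#' @examples
#' cells_per_ml(8e10)  # 0.08 cells/um^3
#' @export
cells_per_ml <- function(x) x / 1e12

#' Dimensional model parameters for a confined bacterial droplet
#'
#' Bundles the physical constants of the oxygen-bacteria model: oxygen
#' transport and saturation, Michaelis-Menten uptake, aerotactic sensing,
#' motility and its low-oxygen switching, interfacial mass transfer, and the
#' droplet geometry and loading. Defaults are the minimal-media reference
#' condition; named presets ship with the package (see [load_preset()]).
#'
#' @param DO2 oxygen diffusivity, um^2/s.
#' @param cO2_sat saturation (air-equilibrated) oxygen concentration, uM.
#' @param K Michaelis constant of oxygen uptake, uM.
#' @param K_chi dissociation constant of the aerotactic sensing function
#'   `f(c) = c/(K_chi + c)`, uM.
#' @param kO2_0 maximal per-cell oxygen uptake rate, molecules s^-1 cell^-1.
#' @param Dcell_0 active cell diffusivity at full motility, um^2/s.
#' @param chi_0 aerotactic coefficient at full motility, um^2/s.
#' @param c_crit oxygen concentration below which motility (and uptake) shut
#'   down, uM. Must satisfy `c_crit < K_chi/5`.
#' @param delta sharpness of the tanh motility switch, uM. Must be < `c_crit`.
#' @param kt interfacial mass-transfer coefficient of the Robin boundary
#'   condition, um/s.
#' @param R droplet radius, um.
#' @param ccell_0 initial (uniform) cell concentration, cells/um^3
#'   (see [cells_per_ml()]).
#' @param henry_H Henry's-law slope, uM per mmHg; the default maps
#'   atmospheric pO2 = 160 mmHg to `cO2_sat`.
#' @return an object of class `physical_params` (a named list).
#' @seealso [nondimensionalize()], [penetration_length()], [load_preset()]
#' @examples
#' p <- physical_params(ccell_0 = cells_per_ml(8e10))
#' penetration_length(p)
#' @export
physical_params <- function(DO2 = 2000, cO2_sat = 250, K = 1, K_chi = 7,
                            kO2_0 = 4e4, Dcell_0 = 100, chi_0 = 4000,
                            c_crit = 0.05, delta = c_crit / 3, kt = 9.3,
                            R = 3400, ccell_0 = 0.08,
                            henry_H = cO2_sat / 160) {
  p <- list(DO2 = DO2, cO2_sat = cO2_sat, K = K, K_chi = K_chi,
            kO2_0 = kO2_0, Dcell_0 = Dcell_0, chi_0 = chi_0,
            c_crit = c_crit, delta = delta, kt = kt, R = R,
            ccell_0 = ccell_0, henry_H = henry_H)
  validate_physical_params(p)
  structure(p, class = "physical_params")
}

validate_physical_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter `", nm, "` must be a finite scalar")
  }
  strict <- setdiff(names(p), c("Dcell_0", "chi_0"))
  for (nm in strict) {
    if (p[[nm]] <= 0) stop("parameter `", nm, "` must be strictly positive")
  }
  if (p$Dcell_0 < 0) stop("`Dcell_0` must be non-negative")
  if (p$chi_0 < 0) stop("`chi_0` must be non-negative")
  if (p$c_crit >= p$K_chi / 5)
    stop("`c_crit` must be well below the sensing constant: c_crit < K_chi/5")
  if (p$delta >= p$c_crit)
    stop("`delta` must be smaller than `c_crit` so the motility switch is ",
         "fully resolved above zero concentration")
  invisible(p)
}

#' @export
print.physical_params <- function(x, ...) {
  cat("<physical_params>\n")
  units <- c(DO2 = "um^2/s", cO2_sat = "uM", K = "uM", K_chi = "uM",
             kO2_0 = "molecules/s/cell", Dcell_0 = "um^2/s", chi_0 = "um^2/s",
             c_crit = "uM", delta = "uM", kt = "um/s", R = "um",
             ccell_0 = "cells/um^3", henry_H = "uM/mmHg")
  for (nm in names(units))
    cat(sprintf("  %-9s %12.6g  %s\n", nm, x[[nm]], units[[nm]]))
  cat(sprintf("  l_O2 = %.4g um;  R_tilde = %.4g;  kt_inv = %.4g\n",
              penetration_length(x),
              x$R / penetration_length(x),
              x$DO2 / (x$kt * penetration_length(x))))
  invisible(x)
}

#' Smooth motility/uptake switch
#'
#' Evaluates `X0/2 * (1 + tanh((cO2 - c_crit)/delta))`: the common
#' phenomenological law by which the active diffusivity, the aerotactic
#' coefficient, and the per-cell uptake rate all collapse to zero when oxygen
#' drops below the critical concentration `c_crit`, over a width `delta`.
#'
#' @param cO2 oxygen concentration (any consistent unit with `c_crit`,
#'   `delta`); vectorised.
#' @param X0 full-motility amplitude (sets the output units).
#' @param c_crit switching threshold.
#' @param delta switch sharpness; must be > 0.
#' @return the switched value, in the units of `X0`; monotone nondecreasing
#'   in `cO2` with range (0, X0).
#' @examples
#' motility_switch(0.3, 50, c_crit = 0.3, delta = 0.1)  # 25: half-amplitude
#' @export
motility_switch <- function(cO2, X0, c_crit, delta) {
  if (!is.numeric(delta) || any(delta <= 0))
    stop("`delta` must be strictly positive")
  X0 / 2 * (1 + tanh((cO2 - c_crit) / delta))
}

#' Aerotactic oxygen-sensing function
#'
#' First-order receptor-binding kinetics `f(cO2) = cO2/(K_chi + cO2)`. The
#' aerotactic drift velocity of the population is `chi * grad f(cO2)`.
#'
#' @param cO2 oxygen concentration, uM; must be non-negative; vectorised.
#' @param K_chi dissociation constant, uM (default 7).
#' @return dimensionless sensing level in `[0, 1)`.
#' @examples
#' oxygen_sensing(7)        # 0.5 at the dissociation constant
#' oxygen_sensing(21, 7)    # 0.75
#' @export
oxygen_sensing <- function(cO2, K_chi = 7) {
  if (any(cO2 < 0)) stop("`cO2` must be non-negative")
  if (any(K_chi <= 0)) stop("`K_chi` must be strictly positive")
  cO2 / (K_chi + cO2)
}

#' Volumetric oxygen uptake rate
#'
#' Michaelis-Menten uptake by the population, modulated by the low-oxygen
#' switch: `kO2(cO2) * ccell * cO2/(K + cO2)` with
#' `kO2(cO2) = motility_switch(cO2, kO2_0, c_crit, delta)`, converted from
#' molecules s^-1 um^-3 to uM/s.
#'
#' @param cO2 oxygen concentration, uM; non-negative; vectorised.
#' @param ccell cell concentration, cells/um^3; non-negative.
#' @param params a [physical_params()] object.
#' @return volumetric uptake rate, uM/s.
#' @examples
#' p <- physical_params()
#' uptake_rate(250, 0.04, p)  # near the saturated rate kO2_0*ccell/602.214
#' @export
uptake_rate <- function(cO2, ccell, params) {
  if (any(cO2 < 0) || any(ccell < 0))
    stop("`cO2` and `ccell` must be non-negative")
  k <- motility_switch(cO2, params$kO2_0, params$c_crit, params$delta)
  k * ccell * cO2 / (params$K + cO2) / MOLEC_PER_UM3_PER_UM
}

#' Oxygen penetration length
#'
#' The depth over which boundary-supplied oxygen diffuses into the suspension
#' before being consumed: `l_O2 = sqrt(DO2 * cO2_sat / (kO2_0 * ccell_0))`
#' with the saturation concentration expressed in molecules/um^3. This length
#' sets the width of the motile annulus when an anoxic core forms, and is the
#' length unit of the dimensionless model.
#'
#' @param params a [physical_params()] object.
#' @return penetration length, um. Scales as `ccell_0^-1/2` and `kO2_0^-1/2`.
#' @examples
#' penetration_length(physical_params(ccell_0 = cells_per_ml(8e10)))  # ~307 um
#' @export
penetration_length <- function(params) {
  if (params$kO2_0 <= 0 || params$ccell_0 <= 0)
    stop("`kO2_0` and `ccell_0` must be strictly positive")
  sqrt(params$DO2 * params$cO2_sat * MOLEC_PER_UM3_PER_UM /
         (params$kO2_0 * params$ccell_0))
}

#' Reduced (dimensionless) parameter set
#'
#' The dimensionless groups actually integrated by the solver. Lengths are
#' scaled by the penetration length `l_O2`, time by `tau = l_O2^2/DO2`,
#' oxygen by `cO2_sat`, and cells by `ccell_0`; with this scaling the uptake
#' prefactor is exactly 1. Two groups control the morphology: `R_tilde`
#' (droplet radius over penetration length) and `kt_tilde` (interfacial
#' influx rate over diffusive transport rate; the state diagram uses its
#' inverse `kt_inv = 1/kt_tilde`).
#'
#' Either `kt_inv` or `kt_tilde` may be given. `l_O2` and `tau` are optional
#' bookkeeping for unit restoration; when a run is specified directly in
#' dimensionless form they can be supplied later (e.g. `l_O2 = R/R_tilde`).
#'
#' @param R_tilde droplet radius over penetration length (> 0).
#' @param kt_inv `DO2/(kt * l_O2)`, the inverse dimensionless mass-transfer
#'   coefficient; `0` denotes a perfectly absorbing interface.
#' @param kt_tilde alternative to `kt_inv`; `Inf` allowed (Dirichlet limit).
#' @param Dcell_tilde `Dcell_0/DO2`.
#' @param chi_tilde `chi_0/DO2`.
#' @param K_tilde `K/cO2_sat`.
#' @param K_chi_tilde `K_chi/cO2_sat`.
#' @param c_crit_tilde `c_crit/cO2_sat`.
#' @param delta_tilde `delta/cO2_sat`.
#' @param l_O2 dimensional penetration length, um (optional, for unit
#'   restoration).
#' @param tau diffusive time unit `l_O2^2/DO2`, s (optional).
#' @return an object of class `dimensionless_params`.
#' @seealso [nondimensionalize()], [redimensionalize()]
#' @export
dimensionless_params <- function(R_tilde, kt_inv = NULL, kt_tilde = NULL,
                                 Dcell_tilde = 0.05, chi_tilde = 2,
                                 K_tilde = 0.004, K_chi_tilde = 0.028,
                                 c_crit_tilde = 2e-4,
                                 delta_tilde = c_crit_tilde / 3,
                                 l_O2 = NA_real_, tau = NA_real_) {
  if (is.null(kt_tilde)) {
    if (is.null(kt_inv)) stop("supply one of `kt_inv` or `kt_tilde`")
    kt_tilde <- if (kt_inv == 0) Inf else 1 / kt_inv
  }
  if (R_tilde <= 0) stop("`R_tilde` must be strictly positive")
  if (kt_tilde <= 0) stop("`kt_tilde` must be strictly positive")
  ratios <- c(K_tilde = K_tilde, K_chi_tilde = K_chi_tilde,
              c_crit_tilde = c_crit_tilde, delta_tilde = delta_tilde)
  if (any(ratios <= 0) || any(ratios >= 1))
    stop("concentration ratios must lie in (0, 1)")
  if (Dcell_tilde < 0 || chi_tilde < 0)
    stop("`Dcell_tilde` and `chi_tilde` must be non-negative")
  if (c_crit_tilde >= K_chi_tilde / 5)
    stop("`c_crit_tilde` must satisfy c_crit < K_chi/5")
  structure(list(R_tilde = R_tilde, kt_tilde = kt_tilde,
                 Dcell_tilde = Dcell_tilde, chi_tilde = chi_tilde,
                 K_tilde = K_tilde, K_chi_tilde = K_chi_tilde,
                 c_crit_tilde = c_crit_tilde, delta_tilde = delta_tilde,
                 l_O2 = l_O2, tau = tau),
            class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat("<dimensionless_params>\n")
  cat(sprintf("  R_tilde = %.4g, kt_tilde = %.4g (kt_inv = %.4g)\n",
              x$R_tilde, x$kt_tilde, 1 / x$kt_tilde))
  cat(sprintf("  Dcell = %.4g, chi = %.4g, K = %.4g, K_chi = %.4g\n",
              x$Dcell_tilde, x$chi_tilde, x$K_tilde, x$K_chi_tilde))
  cat(sprintf("  c_crit = %.4g, delta = %.4g\n", x$c_crit_tilde, x$delta_tilde))
  if (is.finite(x$l_O2))
    cat(sprintf("  units: l_O2 = %.4g um, tau = %.4g s\n", x$l_O2, x$tau))
  invisible(x)
}

#' Nondimensionalize the physical parameter set
#'
#' Scales lengths by the penetration length, time by the diffusive time
#' `tau = l_O2^2/DO2`, oxygen by `cO2_sat`, and cells by `ccell_0`, yielding
#' the reduced parameter set of the model (see [dimensionless_params()]).
#'
#' @param params a [physical_params()] object.
#' @return a `dimensionless_params` object carrying `l_O2` and `tau`.
#' @examples
#' nondimensionalize(physical_params(R = 1400, ccell_0 = cells_per_ml(4e10)))
#' @export
nondimensionalize <- function(params) {
  l <- penetration_length(params)
  dimensionless_params(
    R_tilde = params$R / l,
    kt_tilde = params$kt * l / params$DO2,
    Dcell_tilde = params$Dcell_0 / params$DO2,
    chi_tilde = params$chi_0 / params$DO2,
    K_tilde = params$K / params$cO2_sat,
    K_chi_tilde = params$K_chi / params$cO2_sat,
    c_crit_tilde = params$c_crit / params$cO2_sat,
    delta_tilde = params$delta / params$cO2_sat,
    l_O2 = l,
    tau = l^2 / params$DO2)
}

#' Restore dimensional parameters from the reduced set
#'
#' Inverse of [nondimensionalize()]: rebuilds a [physical_params()] object
#' from the dimensionless groups plus the scales (`l_O2`, `tau` carried in
#' the object; `cO2_sat` and `ccell_0` supplied).
#'
#' @param dp a [dimensionless_params()] object with finite `l_O2` and `tau`.
#' @param cO2_sat oxygen saturation concentration, uM.
#' @param ccell_0 initial cell concentration, cells/um^3.
#' @param henry_H Henry's-law slope, uM/mmHg (not part of the reduced set).
#' @return a `physical_params` object.
#' @export
redimensionalize <- function(dp, cO2_sat, ccell_0,
                             henry_H = cO2_sat / 160) {
  if (!is.finite(dp$l_O2) || !is.finite(dp$tau))
    stop("`dp` must carry finite `l_O2` and `tau` to restore units")
  DO2 <- dp$l_O2^2 / dp$tau
  kO2_0 <- DO2 * cO2_sat * MOLEC_PER_UM3_PER_UM / (dp$l_O2^2 * ccell_0)
  physical_params(
    DO2 = DO2,
    cO2_sat = cO2_sat,
    K = dp$K_tilde * cO2_sat,
    K_chi = dp$K_chi_tilde * cO2_sat,
    kO2_0 = kO2_0,
    Dcell_0 = dp$Dcell_tilde * DO2,
    chi_0 = dp$chi_tilde * DO2,
    c_crit = dp$c_crit_tilde * cO2_sat,
    delta = dp$delta_tilde * cO2_sat,
    kt = dp$kt_tilde * DO2 / dp$l_O2,
    R = dp$R_tilde * dp$l_O2,
    ccell_0 = ccell_0,
    henry_H = henry_H)
}

#' Peclet number for oxygen transport
#'
#' `Pe = vc * L / DO2`, the ratio of convective to diffusive oxygen
#' transport. In the confined-droplet experiments the residual convection
#' from evaporation gives Pe of order 1e-2 to 1e-1, justifying the purely
#' diffusive model.
#'
#' @param vc convective speed, um/s (non-negative).
#' @param L characteristic length, um (gap height to droplet radius).
#' @param DO2 oxygen diffusivity, um^2/s (> 0).
#' @return dimensionless Peclet number.
#' @examples
#' peclet(0.05, 3500, 2000)  # 0.0875
#' @export
peclet <- function(vc, L, DO2) {
  if (any(DO2 <= 0)) stop("`DO2` must be strictly positive")
  if (any(vc < 0) || any(L < 0)) stop("`vc` and `L` must be non-negative")
  vc * L / DO2
}
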