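# Synthetic experiment-like observables: bright-field and oxygen-fluorescence
# image stacks rendered from model trajectories, with droplet-shape
# imperfection and measurement noise, plus the sector-averaging
# quantification path that recovers kymographs and core traces from them.

#' Phantom imaging configuration
#'
#' @param boundary_eps amplitude of the droplet-shape imperfection
#'   `R(theta) = R * (1 + eps * cos(m * theta))`; must be < 0.1.
#' @param boundary_mode azimuthal mode `m` of the imperfection.
#' @param noise multiplicative Gaussian noise level (relative standard
#'   deviation per pixel).
#' @param pixel_size pixel size, um.
#' @param frame_interval nominal frame interval, s (metadata only).
#' @param n_frames number of frames rendered (evenly subsampled from the
#'   trajectory); NULL renders every stored state.
#' @param seed RNG seed; recorded in the output metadata so phantom
#'   generation is fully reproducible.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(boundary_eps = 0, boundary_mode = 0, noise = 0,
                           pixel_size = 10, frame_interval = NA_real_,
                           n_frames = NULL, seed = 1L) {
  if (boundary_eps < 0 || boundary_eps >= 0.1)
    stop("`boundary_eps` must lie in [0, 0.1)")
  if (noise < 0) stop("`noise` must be non-negative")
  if (pixel_size <= 0) stop("`pixel_size` must be strictly positive")
  structure(list(boundary_eps = boundary_eps,
                 boundary_mode = as.integer(boundary_mode),
                 noise = noise, pixel_size = pixel_size,
                 frame_interval = frame_interval, n_frames = n_frames,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Imaging calibration constants for phantom rendering
#'
#' @param epsilon_att Beer-Lambert attenuation per cell per unit path, um^2;
#'   NULL chooses it so the densest rendered region transmits about 20%
#'   (recorded in the phantom metadata).
#' @param path optical path length (chamber gap), um.
#' @param H Henry's-law slope, uM/mmHg.
#' @param cO2_sat saturation oxygen concentration, uM.
#' @param ccell_0 loading cell concentration, cells/um^3 (scales the
#'   dimensionless cell field).
#' @return an object of class `phantom_calibration`.
#' @export
phantom_calibration <- function(epsilon_att = NULL, path = 130,
                                H = 250 / 160, cO2_sat = 250,
                                ccell_0 = 0.04) {
  structure(list(epsilon_att = epsilon_att, path = path, H = H,
                 cO2_sat = cO2_sat, ccell_0 = ccell_0),
            class = "phantom_calibration")
}

with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Render synthetic image stacks from a model trajectory
#'
#' Maps the radial profiles of a trajectory onto a 2D pixel grid bounded by
#' the perturbed droplet outline `R(theta) = R*(1 + eps*cos(m*theta))` (the
#' radial coordinate is rescaled per azimuth so the profile follows the
#' outline, emulating shape imperfection). The bright-field channel is
#' rendered through the Beer-Lambert law, the oxygen channel through
#' Henry's law and the Ru(dpp) fluorescence calibration; multiplicative
#' Gaussian noise is applied with the configured seed. Ground truth is
#' emitted alongside.
#'
#' @param traj a `droplet_trajectory`.
#' @param cfg a [phantom_config()].
#' @param l_O2 penetration length, um, used to restore the dimensional
#'   radius (`R = R_tilde * l_O2`); defaults to the value carried by the
#'   trajectory's parameters.
#' @param calib a [phantom_calibration()].
#' @return an object of class `droplet_phantom`: arrays `brightfield` and
#'   `fluorescence` of dimension (nx, ny, n_frames) with NA outside the
#'   droplet, pixel coordinates `x`, `y` (um, origin at the droplet
#'   centre), frame `times` (trajectory time units), the ground-truth
#'   radial fields, and metadata (including the realised `epsilon_att` and
#'   the seed).
#' @export
phantom_droplet <- function(traj, cfg = phantom_config(), l_O2 = NULL,
                            calib = phantom_calibration()) {
  if (is.null(l_O2)) l_O2 <- traj$params$l_O2
  if (!is.finite(l_O2))
    stop("supply `l_O2` to restore dimensional lengths")
  nt_all <- length(traj$times)
  idx <- if (is.null(cfg$n_frames)) seq_len(nt_all) else
    unique(round(seq(1, nt_all, length.out = cfg$n_frames)))
  times <- traj$times[idx]
  R_um <- traj$grid$R_tilde * l_O2
  r_um <- traj$grid$r * l_O2
  cell_um <- traj$c_cell[, idx, drop = FALSE] * calib$ccell_0
  oxy_uM <- traj$c_oxy[, idx, drop = FALSE] * calib$cO2_sat
  if (is.null(calib$epsilon_att))
    calib$epsilon_att <- -log(0.2) / (max(cell_um) * calib$path)

  px <- cfg$pixel_size
  half <- ceiling((R_um * (1 + cfg$boundary_eps) + 2 * px) / px)
  x <- (-half:half) * px
  nx <- length(x)
  xy_r <- sqrt(outer(x^2, x^2, `+`))
  theta <- atan2(matrix(x, nx, nx, byrow = TRUE), matrix(x, nx, nx))
  R_theta <- R_um * (1 + cfg$boundary_eps * cos(cfg$boundary_mode * theta))
  inside <- xy_r <= R_theta
  r_eff <- xy_r * R_um / R_theta  # de-perturbed radial coordinate

  nf <- length(idx)
  bf <- array(NA_real_, c(nx, nx, nf))
  fl <- array(NA_real_, c(nx, nx, nf))
  for (j in seq_len(nf)) {
    cc <- stats::approx(r_um, cell_um[, j], xout = r_eff[inside],
                        rule = 2)$y
    co <- stats::approx(r_um, oxy_uM[, j], xout = r_eff[inside],
                        rule = 2)$y
    bfj <- matrix(NA_real_, nx, nx)
    flj <- matrix(NA_real_, nx, nx)
    bfj[inside] <- beer_lambert(cc, calib$path, calib$epsilon_att)
    flj[inside] <- rudpp_fluorescence(henry_inverse(co, calib$H))
    bf[, , j] <- bfj
    fl[, , j] <- flj
  }
  if (cfg$noise > 0) {
    with_preserved_seed(cfg$seed, {
      bf <- bf * (1 + cfg$noise * stats::rnorm(length(bf)))
      fl <- fl * (1 + cfg$noise * stats::rnorm(length(fl)))
    })
  }
  structure(list(brightfield = bf, fluorescence = fl, x = x, y = x,
                 times = times,
                 truth = list(r_um = r_um, c_cell = cell_um,
                              c_oxy = oxy_uM,
                              c_cell_tilde = traj$c_cell[, idx, drop = FALSE],
                              c_oxy_tilde = traj$c_oxy[, idx, drop = FALSE]),
                 cfg = cfg, calib = calib,
                 meta = list(R_um = R_um, l_O2 = l_O2, seed = cfg$seed,
                             epsilon_att = calib$epsilon_att)),
            class = "droplet_phantom")
}

#' @export
print.droplet_phantom <- function(x, ...) {
  cat(sprintf("<droplet_phantom> %d x %d px, %d frames, R = %.4g um\n",
              length(x$x), length(x$y), length(x$times), x$meta$R_um))
  cat(sprintf("  eps = %.3g (m = %d), noise = %.3g, seed = %d\n",
              x$cfg$boundary_eps, x$cfg$boundary_mode, x$cfg$noise,
              x$meta$seed))
  invisible(x)
}

#' Average intensity profile within an angular sector
#'
#' The quantification path used for noncircular droplets: pixels within a
#' narrow sector are binned by radius (half-open bins `[r, r + dr)`) and
#' averaged. The sector restriction only matters near the rim (where shape
#' imperfection distorts the azimuthal average); bins holding fewer than
#' `min_pix` in-sector pixels - the innermost bins - are widened to the
#' full circle for statistical strength. Empty bins are flagged and filled
#' by linear interpolation from their neighbours.
#'
#' @param img numeric matrix of pixel intensities (NA allowed).
#' @param x,y coordinate vectors, um, for the rows and columns of `img`,
#'   origin at the droplet centre.
#' @param theta0 sector axis, radians.
#' @param half_angle sector half-angle, radians.
#' @param n_bins number of radial bins.
#' @param r_max outer radius of the binning, um.
#' @param min_pix bins with fewer in-sector pixels use the full circle.
#' @return a tibble with columns `r` (bin centre), `intensity`, `n_pix`,
#'   `interpolated`, `widened`.
#' @export
sector_average <- function(img, x, y, theta0 = 0, half_angle = pi / 12,
                           n_bins = 64, r_max = max(abs(x)),
                           min_pix = 30L) {
  stopifnot(nrow(img) == length(x), ncol(img) == length(y))
  nx <- length(x); ny <- length(y)
  r_pix <- sqrt(outer(x^2, y^2, `+`))
  th <- atan2(matrix(y, nx, ny, byrow = TRUE), matrix(x, nx, ny))
  dth <- atan2(sin(th - theta0), cos(th - theta0))
  dr <- r_max / n_bins
  bin_stats <- function(mask) {
    bin <- pmin(floor(r_pix[mask] / dr) + 1L, n_bins)
    m <- rep(NA_real_, n_bins)
    mm <- tapply(img[mask], bin, mean)
    m[as.integer(names(mm))] <- mm
    np <- integer(n_bins)
    tb <- table(bin)
    np[as.integer(names(tb))] <- as.integer(tb)
    list(mean = m, n = np)
  }
  ok <- r_pix < r_max & is.finite(img)
  sect <- bin_stats(ok & abs(dth) <= half_angle)
  full <- bin_stats(ok)
  widened <- sect$n < min_pix
  out <- ifelse(widened, full$mean, sect$mean)
  npix <- ifelse(widened, full$n, sect$n)
  empty <- !is.finite(out)
  if (any(empty) && sum(!empty) >= 2)
    out[empty] <- stats::approx(which(!empty), out[!empty],
                                xout = which(empty), rule = 2)$y
  tibble::tibble(r = (seq_len(n_bins) - 0.5) * dr, intensity = out,
                 n_pix = npix, interpolated = empty, widened = widened)
}

#' Recover kymographs and core trace from phantom image stacks
#'
#' The quantification path of the imaging pipeline: each channel is
#' sector-averaged as a raw intensity image (averaging before calibration,
#' as for noncircular droplets in practice, which also suppresses pixel
#' noise before the nonlinear inversion), then the calibrations are
#' inverted on the averaged profiles - Beer-Lambert for the cell
#' concentration, Ru(dpp) fluorescence and Henry's law for oxygen - and the
#' core-trace and total-oxygen analyses run on the recovered fields.
#'
#' The oxygen probe has a finite dynamic range: its fluorescence is fully
#' quenched at high pO2, so intensities within `quench_floor` of the
#' quenched baseline carry no concentration information and are censored at
#' the corresponding ceiling concentration (reported in the metadata).
#' Recovered oxygen is therefore faithful at low concentrations (where the
#' core and annulus structure live) and right-censored at high ones.
#'
#' @param ph a [phantom_droplet()].
#' @param theta0,half_angle sector used for averaging (radians).
#' @param n_bins radial bins; NULL uses half the truth-profile resolution.
#' @param c_crit anoxia threshold for the recovered core trace, uM. The
#'   default (0.1) sits slightly above the motility threshold of the model
#'   (0.05): so close to full quenching the fluorescence excess over
#'   baseline is under 1% and the 0.05-uM contour is not resolvable at
#'   realistic noise, while the 0.1-uM contour is.
#' @param quench_floor relative fluorescence excess over the quenched
#'   baseline below which oxygen is censored at the ceiling (default 0.01).
#' @param smooth odd window of a radial running-median filter applied to
#'   the recovered oxygen profile before contouring (1 disables); guards
#'   the contiguous-core detection against single noisy bins.
#' @return a list of class `recovered_observables`: kymograph tibbles
#'   `kymo_cell` (cells/um^3) and `kymo_oxy` (uM, ceiling-censored), the
#'   recovered `core_trace`, the `total_o2` series (normalized by
#'   saturation), and the binning metadata including `c_ceiling`.
#' @export
recover_observables <- function(ph, theta0 = 0, half_angle = pi / 6,
                                n_bins = NULL, c_crit = 0.1,
                                quench_floor = 0.01, smooth = 3) {
  if (is.null(n_bins)) n_bins <- max(32L, length(ph$truth$r_um) %/% 2L)
  r_max <- ph$meta$R_um
  nf <- length(ph$times)
  cal <- ph$calib
  c_ceiling <- henry_convert(rudpp_inverse(1 + quench_floor), cal$H)
  prof_cell <- matrix(NA_real_, n_bins, nf)
  prof_oxy <- matrix(NA_real_, n_bins, nf)
  for (j in seq_len(nf)) {
    bf_prof <- sector_average(ph$brightfield[, , j], ph$x, ph$y, theta0,
                              half_angle, n_bins, r_max)$intensity
    bf_prof[!is.finite(bf_prof) | bf_prof <= 0] <- NA
    bf_prof <- pmin(bf_prof, 1)
    prof_cell[, j] <- beer_lambert_inv(bf_prof, cal$path, cal$epsilon_att)
    fl_prof <- sector_average(ph$fluorescence[, , j], ph$x, ph$y, theta0,
                              half_angle, n_bins, r_max)$intensity
    fl_prof[!is.finite(fl_prof)] <- NA
    # noise about the anoxic asymptote: censor to pO2 = 0
    fl_prof <- pmin(fl_prof, 7.5)
    low <- !is.na(fl_prof) & fl_prof <= 1 + quench_floor  # quenched: >= ceiling
    fl_prof[low] <- 1 + quench_floor
    oxy_j <- henry_convert(rudpp_inverse(fl_prof), cal$H)
    if (smooth > 1 && !anyNA(oxy_j))
      oxy_j <- stats::runmed(oxy_j, smooth, endrule = "median")
    prof_oxy[, j] <- oxy_j
  }
  grid <- radial_grid(r_max, max(16L, n_bins))
  pseudo <- list(times = ph$times, c_oxy = prof_oxy / cal$cO2_sat,
                 c_cell = prof_cell, grid = grid,
                 params = list(c_crit_tilde = c_crit / cal$cO2_sat),
                 diagnostics = NULL)
  trace <- core_trace(pseudo, c_crit_tilde = c_crit / cal$cO2_sat)
  o2 <- total_oxygen(pseudo, trace)
  structure(list(
    kymo_cell = kymograph(list(times = ph$times, c_cell = prof_cell,
                               grid = grid), "c_cell", normalize = FALSE),
    kymo_oxy = kymograph(list(times = ph$times, c_oxy = prof_oxy,
                              grid = grid), "c_oxy"),
    core_trace = trace, total_o2 = o2,
    meta = list(n_bins = n_bins, r_max = r_max, theta0 = theta0,
                half_angle = half_angle, c_crit = c_crit,
                c_ceiling = c_ceiling, quench_floor = quench_floor)),
    class = "recovered_observables")
}

#' Write phantom image stacks as multi-page TIFF files
#'
#' Optional export of the two channels as 32-bit float multi-page TIFFs
#' (requires the `tiff` package). NA pixels are written as 0.
#'
#' @param ph a [phantom_droplet()].
#' @param prefix output path prefix; writes `<prefix>_brightfield.tif` and
#'   `<prefix>_fluorescence.tif`.
#' @return the two paths, invisibly.
#' @export
write_phantom_tiff <- function(ph, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package `tiff` is required for TIFF export")
  paths <- paste0(prefix, c("_brightfield.tif", "_fluorescence.tif"))
  norm <- function(a, scale) {
    a[!is.finite(a)] <- 0
    lapply(seq_len(dim(a)[3]), function(j) a[, , j] / scale)
  }
  tiff::writeTIFF(norm(ph$brightfield, 1), paths[1], bits.per.sample = 32L)
  tiff::writeTIFF(norm(ph$fluorescence, 7.5), paths[2],
                  bits.per.sample = 32L)
  invisible(paths)
}

#' Ground-truth observables of a phantom at frame resolution
#'
#' Runs the same core-trace and total-oxygen analyses on the ground-truth
#' radial profiles stored in a phantom, sampled at the rendered frame
#' times. This is the reference against which [recover_observables()]
#' isolates the imaging-pipeline error (rendering, noise, sector
#' averaging, calibration inversion) from the temporal subsampling.
#'
#' @param ph a [phantom_droplet()].
#' @param c_crit anoxia threshold, uM.
#' @param c_ceiling optional censoring ceiling, uM, to mimic the probe
#'   dynamic range of the recovery (see [recover_observables()]); NA for
#'   no censoring.
#' @return a list with `core_trace` and `total_o2` at frame times.
#' @export
phantom_truth_observables <- function(ph, c_crit = 0.1,
                                      c_ceiling = NA_real_) {
  r_um <- ph$truth$r_um
  h <- r_um[2] - r_um[1]
  grid <- radial_grid(max(r_um) + h / 2, length(r_um))
  oxy <- ph$truth$c_oxy
  if (is.finite(c_ceiling)) oxy <- pmin(oxy, c_ceiling)
  pseudo <- list(times = ph$times, c_oxy = oxy / ph$calib$cO2_sat,
                 c_cell = ph$truth$c_cell, grid = grid,
                 params = list(c_crit_tilde = c_crit / ph$calib$cO2_sat),
                 diagnostics = NULL)
  trace <- core_trace(pseudo, c_crit_tilde = c_crit / ph$calib$cO2_sat)
  list(core_trace = trace, total_o2 = total_oxygen(pseudo, trace))
}
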