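# Imaging calibrations of the quantification pipeline: Beer-Lambert
# bright-field attenuation, Ru(dpp) oxygen-sensitive fluorescence, and
# Henry's law. All forward/inverse pairs are exact inverses on their valid
# domains.

#' Beer-Lambert bright-field attenuation
#'
#' Transmitted intensity fraction through a cell suspension:
#' `I/I0 = exp(-epsilon_att * c_cell * path)`. Used to calibrate cell
#' concentration in depth-averaged bright-field images.
#'
#' @param c_cell cell concentration, cells/um^3 (non-negative; vectorised).
#' @param path optical path length, um (the chamber gap).
#' @param epsilon_att attenuation cross-section per cell per unit path,
#'   um^2 (a free calibration constant of the imaging system).
#' @return transmitted fraction in (0, 1].
#' @seealso [beer_lambert_inv()]
#' @export
beer_lambert <- function(c_cell, path, epsilon_att) {
  if (any(c_cell < 0) || any(path < 0) || any(epsilon_att < 0))
    stop("`c_cell`, `path`, `epsilon_att` must be non-negative")
  exp(-epsilon_att * c_cell * path)
}

#' @rdname beer_lambert
#' @param frac transmitted intensity fraction `I/I0`, in (0, 1].
#' @export
beer_lambert_inv <- function(frac, path, epsilon_att) {
  if (any(frac <= 0 | frac > 1, na.rm = TRUE))
    stop("transmitted fraction must lie in (0, 1]")
  -log(frac) / (epsilon_att * path)
}

#' Ru(dpp) oxygen-sensitive fluorescence
#'
#' Calibration curve of the ruthenium-complex oxygen probe, whose
#' fluorescence is quenched by oxygen binding:
#' `Ifluo = 1 + 6.5 * exp(-pO2/3)` with `Ifluo` normalized by the signal at
#' saturation and `pO2` in mmHg. The anoxic asymptote is 7.5, the fully
#' quenched limit 1.
#'
#' @param pO2 oxygen partial pressure, mmHg (non-negative; vectorised).
#' @return normalized fluorescence intensity in (1, 7.5].
#' @seealso [rudpp_inverse()]
#' @examples
#' rudpp_fluorescence(0)   # 7.5
#' rudpp_fluorescence(3)   # 1 + 6.5/e
#' @export
rudpp_fluorescence <- function(pO2) {
  if (any(pO2 < 0, na.rm = TRUE)) stop("`pO2` must be non-negative")
  1 + 6.5 * exp(-pO2 / 3)
}

#' @rdname rudpp_fluorescence
#' @param Ifluo normalized fluorescence, in (1, 7.5]; values at or below 1
#'   (signal below the fully quenched asymptote) or above 7.5 are a domain
#'   error.
#' @export
rudpp_inverse <- function(Ifluo) {
  if (any(Ifluo <= 1 | Ifluo > 7.5, na.rm = TRUE))
    stop("`Ifluo` must lie in (1, 7.5]")
  -3 * log((Ifluo - 1) / 6.5)
}

#' Henry's-law conversion between partial pressure and concentration
#'
#' `cO2 = H * pO2`; the default calibration anchors atmospheric
#' `pO2 = 160 mmHg` to the air-saturated concentration.
#'
#' @param pO2 partial pressure, mmHg (non-negative; vectorised).
#' @param H Henry's-law slope, uM/mmHg (> 0).
#' @return dissolved concentration, uM.
#' @seealso [henry_inverse()]
#' @export
henry_convert <- function(pO2, H = 250 / 160) {
  if (any(H <= 0)) stop("`H` must be strictly positive")
  if (any(pO2 < 0, na.rm = TRUE)) stop("`pO2` must be non-negative")
  H * pO2
}

#' @rdname henry_convert
#' @param cO2 dissolved concentration, uM.
#' @export
henry_inverse <- function(cO2, H = 250 / 160) {
  if (any(H <= 0)) stop("`H` must be strictly positive")
  cO2 / H
}
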