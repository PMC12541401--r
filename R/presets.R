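# Flat key-value parameter files and named presets.

#' Read a parameter file
#'
#' Parses a flat key-value text file (one `key = value` pair per line,
#' `#` starts a comment) into a [physical_params()] object. Keys must match
#' the `physical_params` field names; missing keys take the defaults.
#'
#' @param path path to the parameter file.
#' @return a `physical_params` object.
#' @seealso [write_params()], [load_preset()]
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed parameter line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  if (anyNA(vals)) stop("non-numeric value for key(s): ",
                        paste(keys[is.na(vals)], collapse = ", "))
  known <- names(formals(physical_params))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown parameter key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(physical_params, as.list(stats::setNames(vals, keys)))
}

#' Write a parameter file
#'
#' Writes a [physical_params()] object as a flat key-value text file with
#' unit comments, readable by [read_params()].
#'
#' @param params a `physical_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  units <- c(DO2 = "um^2/s", cO2_sat = "uM", K = "uM", K_chi = "uM",
             kO2_0 = "molecules s^-1 cell^-1", Dcell_0 = "um^2/s",
             chi_0 = "um^2/s", c_crit = "uM", delta = "uM", kt = "um/s",
             R = "um", ccell_0 = "cells/um^3", henry_H = "uM/mmHg")
  lines <- vapply(names(units), function(nm)
    sprintf("%s = %.15g  # %s", nm, params[[nm]], units[[nm]]), "")
  writeLines(lines, path)
  invisible(path)
}

#' Load a named parameter preset
#'
#' Presets shipped with the package:
#' \describe{
#'   \item{`bmb-minimal`}{minimal-media reference: per-cell uptake
#'     `kO2_0 = 4e4` molecules/s, large concentrated droplet (R = 3.4 mm,
#'     8e10 cells/mL).}
#'   \item{`lb-rich`}{nutrient-rich media: uptake raised to `3e5`
#'     molecules/s, otherwise as `bmb-minimal`.}
#'   \item{`peo-4x`}{semidilute-polymer condition: motility enhanced
#'     fourfold (`Dcell_0` and `chi_0` both x4) in a small concentrated
#'     droplet (R = 1.4 mm, 4e10 cells/mL).}
#' }
#'
#' @param name preset name.
#' @return a `physical_params` object.
#' @examples
#' load_preset("bmb-minimal")
#' @export
load_preset <- function(name = c("bmb-minimal", "lb-rich", "peo-4x")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".par"),
                      package = "oxydrop", mustWork = TRUE)
  read_params(path)
}
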