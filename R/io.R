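# Plain-text persistence of trajectories and tabular exports.

#' Persist a trajectory to plain-text files
#'
#' Writes the field time series as a long CSV (`<prefix>_fields.csv`:
#' `time, r, c_oxy, c_cell`) and the parameters, grid and diagnostics as
#' JSON (`<prefix>_meta.json`).
#'
#' @param traj a `droplet_trajectory`.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @seealso [read_trajectory()]
#' @export
write_trajectory <- function(traj, prefix) {
  fields_path <- paste0(prefix, "_fields.csv")
  meta_path <- paste0(prefix, "_meta.json")
  utils::write.csv(as.data.frame(tibble::as_tibble(traj)), fields_path,
                   row.names = FALSE)
  meta <- list(params = unclass(traj$params),
               grid = list(N = traj$grid$N, R_tilde = traj$grid$R_tilde),
               diagnostics = traj$diagnostics)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(fields_path, meta_path))
}

#' Read a trajectory persisted by [write_trajectory()]
#'
#' @param prefix the path prefix used when writing.
#' @return a `droplet_trajectory`.
#' @export
read_trajectory <- function(prefix) {
  fields <- utils::read.csv(paste0(prefix, "_fields.csv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  grid <- radial_grid(meta$grid$R_tilde, meta$grid$N)
  times <- unique(fields$time)
  N <- grid$N
  stopifnot(nrow(fields) == N * length(times))
  params <- meta$params
  params$l_O2 <- params$l_O2 %||% NA_real_
  params$tau <- params$tau %||% NA_real_
  params <- structure(params, class = "dimensionless_params")
  diag <- meta$diagnostics
  num_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  for (nm in c("t_formed", "t_vanish", "t_steady", "t_max_r_core"))
    diag[[nm]] <- num_na(diag[[nm]])
  structure(list(times = times, grid = grid,
                 c_oxy = matrix(fields$c_oxy, N),
                 c_cell = matrix(fields$c_cell, N),
                 r_core = vapply(seq_along(times), function(j)
                   core_radius_cpp(matrix(fields$c_oxy, N)[, j],
                                   params$c_crit_tilde, grid$h,
                                   grid$R_tilde), 0),
                 params = params, diagnostics = diag),
            class = "droplet_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
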