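# broom-style tidiers for fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.boundary_fit_linear <- function(x, ...) {
  tibble::tibble(term = "a", estimate = x$a, std.error = x$se)
}

#' @export
glance.boundary_fit_linear <- function(x, ...) {
  tibble::tibble(a = x$a, n = nrow(x$points),
                 sigma = sqrt(mean(x$residuals^2)))
}

#' @export
tidy.boundary_fit_saturating <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C", "A_over_B", "A_over_C"),
                 estimate = c(x$A, x$B, x$C, x$A_over_B, x$A_over_C))
}

#' @export
glance.boundary_fit_saturating <- function(x, ...) {
  tibble::tibble(A_over_B = x$A_over_B, A_over_C = x$A_over_C,
                 n = nrow(x$points), sigma = sqrt(mean(x$residuals^2)))
}

#' @export
tidy.annulus_scaling <- function(x, ...) x$table

#' @export
glance.annulus_scaling <- function(x, ...) {
  tibble::tibble(kO2_fit = x$kO2_fit, kO2_preset = x$kO2_preset,
                 rel_error = abs(x$kO2_fit - x$kO2_preset) / x$kO2_preset,
                 loglog_slope = x$loglog_slope, n = nrow(x$table))
}

#' @export
tidy.regime_label <- function(x, ...) {
  tibble::tibble(label = x$label, t_formed = x$t_formed,
                 t_vanish = x$t_vanish, r_core_steady = x$r_core_steady,
                 steady = x$steady, t_end = x$t_end)
}

#' @export
glance.droplet_trajectory <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(R_tilde = x$params$R_tilde, kt_inv = 1 / x$params$kt_tilde,
                 N = x$grid$N, t_end = d$t_end, formed = d$formed,
                 t_formed = d$t_formed, vanished = d$vanished,
                 t_vanish = d$t_vanish, steady = d$steady,
                 max_r_core = d$max_r_core, min_oxy = d$min_oxy,
                 mass_rel_error = d$mass_rel_error, n_steps = d$n_steps)
}
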