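# Independent reference implementations and shared (memoised) fixture runs.

# Brute-force explicit-Euler integrator of the same finite-volume spatial
# discretization; written independently of the production time stepper.
euler_reference <- function(p, N, t_end, dt) {
  h <- p$R_tilde / N
  r <- (seq_len(N) - 0.5) * h
  rf <- (0:N) * h
  oxy <- rep(1, N)
  cel <- rep(1, N)
  beta <- if (is.finite(p$kt_tilde)) 1 / (1 / p$kt_tilde + h / 2) else 2 / h
  s_of <- function(c) 0.5 * (1 + tanh((c - p$c_crit_tilde) / p$delta_tilde))
  f_of <- function(c) c / (p$K_chi_tilde + c)
  nst <- ceiling(t_end / dt)
  dt <- t_end / nst
  for (i in seq_len(nst)) {
    s <- s_of(oxy)
    f <- f_of(oxy)
    Fo <- c(0, rf[2:N] * diff(oxy) / h, rf[N + 1] * beta * (1 - oxy[N]))
    upt <- s * cel * oxy / (p$K_tilde + oxy)
    oxy2 <- oxy + dt * (diff(Fo) / (r * h) - upt)
    sf <- s_of((oxy[1:(N - 1)] + oxy[2:N]) / 2)
    v <- p$chi_tilde * sf * diff(f) / h
    cup <- ifelse(v >= 0, cel[1:(N - 1)], cel[2:N])
    G <- c(0, rf[2:N] * (v * cup - p$Dcell_tilde * sf * diff(cel) / h), 0)
    cel2 <- cel - dt * diff(G) / (r * h)
    oxy <- oxy2
    cel <- cel2
  }
  list(oxy = oxy, cel = cel)
}

# Steady 1D slab uptake problem, marched to steady state with explicit
# Euler (dimensionless: c_t = c_xx - c/(K + c), c(0) = 1, no-flux far end).
# Returns the penetration depth: where c first falls below 10% of the
# surface value (the zeroth-order closed form is sqrt(2) - sqrt(0.2) ~
# 0.97 in units of l_O2).
slab_decay_depth <- function(K_tilde, L = 4, N = 200, dt = 2e-5,
                             t_end = 8) {
  h <- L / N
  x <- (seq_len(N) - 0.5) * h
  c <- rep(1, N)
  nst <- ceiling(t_end / dt)
  for (i in seq_len(nst)) {
    cb <- c(2 - c[1], c, c[N])  # c = 1 at x = 0 (ghost), no-flux at x = L
    lap <- (cb[1:N] - 2 * c + cb[3:(N + 2)]) / h^2
    c <- c + dt * (lap - c / (K_tilde + c))
    c[c < 0] <- 0
  }
  x[which(c < 0.1)[1]]
}

# Memoised fixture runs shared across test blocks.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

run_transient_256 <- function() {
  cached_run("transient_256", simulate_droplet(
    dimensionless_params(2.7, kt_inv = 1), N = 256, t_max = 100,
    stop_when = "none"))
}

run_transient_512 <- function() {
  cached_run("transient_512", simulate_droplet(
    dimensionless_params(2.7, kt_inv = 1), N = 512,
    stop_when = c("steady", "vanish")))
}

run_permanent_512 <- function() {
  cached_run("permanent_512", simulate_droplet(
    dimensionless_params(9.3, kt_inv = 0.7), N = 512,
    stop_when = c("steady", "plateau")))
}

run_aerobic_512 <- function() {
  cached_run("aerobic_512", simulate_droplet(
    dimensionless_params(0.96, kt_inv = 2.8), N = 512))
}
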