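// Finite-volume integrator for the dimensionless axisymmetric oxygen-bacteria
// system on r in [0, R_tilde]:
//
//   d(c_oxy)/dt  = (1/r) d/dr ( r d(c_oxy)/dr ) - s(c_oxy) c_cell c_oxy/(K + c_oxy)
//   d(c_cell)/dt = (1/r) d/dr [ r ( Dcell s d(c_cell)/dr - chi s c_cell d(f)/dr ) ]
//
// with s(c) = (1 + tanh((c - ccrit)/delta))/2, f(c) = c/(Kchi + c),
// Robin oxygen influx d(c_oxy)/dr = kt (1 - c_oxy) at r = R_tilde, zero oxygen
// flux at r = 0, and zero TOTAL cell flux through both boundary faces.
//
// Scheme: cell-centred finite volumes, two-point face fluxes, first-order
// upwinding of the aerotactic advection, backward-Euler diffusion for both
// fields, linearly-implicit (Patankar) uptake. Fluxes are assembled in
// conservative form, so cell mass is conserved to solver round-off; the
// implicit parts are M-matrices, so positivity and the oxygen maximum
// principle (c_oxy <= 1) hold for any dt. dt is limited by the advective
// CFL condition and a splitting-accuracy cap; steps producing a negative
// cell concentration are rejected and retried at dt/2.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline double switch_s(double c, double ccrit, double delta) {
  return 0.5 * (1.0 + std::tanh((c - ccrit) / delta));
}

// Thomas algorithm; overwrites inputs, solution returned in d.
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d) {
  const int n = (int) b.size();
  for (int i = 1; i < n; ++i) {
    const double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// Outer radius of the contiguous central region with c < ccrit, by linear
// interpolation of the crossing between adjacent cell centres.
static double core_radius_of(const std::vector<double>& c, double ccrit,
                             double h, double R_tilde) {
  const int N = (int) c.size();
  if (c[0] >= ccrit) return 0.0;
  int j = 1;
  while (j < N && c[j] < ccrit) ++j;
  if (j == N) return R_tilde;
  const double r_prev = (j - 0.5) * h;
  const double frac = (ccrit - c[j - 1]) / (c[j] - c[j - 1]);
  double rc = r_prev + frac * h;
  if (rc < 0.0) rc = 0.0;
  if (rc > R_tilde) rc = R_tilde;
  return rc;
}

// [[Rcpp::export]]
double core_radius_cpp(NumericVector c_oxy, double c_crit, double h,
                       double R_tilde) {
  std::vector<double> c(c_oxy.begin(), c_oxy.end());
  return core_radius_of(c, c_crit, h, R_tilde);
}

// [[Rcpp::export]]
List fv_integrate(int N, double R_tilde, double kt_tilde,
                  double Dcell, double chi, double K, double Kchi,
                  double ccrit, double delta, double uptake_amp,
                  int sink_mode, double sink_q, bool evolve_cells,
                  NumericVector c_oxy0, NumericVector c_cell0,
                  double t0, double t_max, double cadence,
                  double cfl, double dt_max,
                  double steady_tol, double steady_window,
                  double plateau_rate, double plateau_window,
                  bool stop_on_steady, bool stop_on_anoxia,
                  bool stop_on_vanish, bool stop_on_plateau) {
  if (N < 16) stop("grid must have at least 16 control volumes");
  if (c_oxy0.size() != N || c_cell0.size() != N)
    stop("initial fields must have length N");
  const double h = R_tilde / N;
  // Robin coefficient: eliminate the face value between the two-point
  // diffusive flux (c_face - c_N)*2/h and the interfacial flux kt*(1 - c_face);
  // kt -> Inf recovers the Dirichlet (perfectly absorbing interface) limit.
  const double beta = std::isfinite(kt_tilde)
    ? 1.0 / (1.0 / kt_tilde + 0.5 * h)
    : 2.0 / h;

  std::vector<double> oxy(c_oxy0.begin(), c_oxy0.end());
  std::vector<double> cel(c_cell0.begin(), c_cell0.end());
  std::vector<double> fval(N), sval(N);
  std::vector<double> aa(N), bb(N), cc(N), dd(N);
  std::vector<double> oxy_new(N), cel_new(N);
  std::vector<double> vface(N + 1, 0.0), sface(N + 1, 0.0), Gflux(N + 1, 0.0);

  std::vector<double> rc_vol(N), r_in(N), r_out(N);
  for (int i = 0; i < N; ++i) {
    r_in[i] = i * h;
    r_out[i] = (i + 1) * h;
    rc_vol[i] = (i + 0.5) * h * h;  // r_i * h
  }

  double mass0 = 0.0;
  for (int i = 0; i < N; ++i) mass0 += cel[i] * rc_vol[i];
  mass0 *= 2.0 * M_PI;

  // snapshot storage
  std::vector<double> out_t, out_rcore;
  std::vector<double> out_oxy, out_cel;
  auto record = [&](double t) {
    out_t.push_back(t);
    out_rcore.push_back(core_radius_of(oxy, ccrit, h, R_tilde));
    out_oxy.insert(out_oxy.end(), oxy.begin(), oxy.end());
    out_cel.insert(out_cel.end(), cel.begin(), cel.end());
  };

  double t = t0;
  record(t);
  double next_out = (cadence > 0) ? t0 + cadence : t_max;

  bool formed = false, vanished = false, steady = false;
  double t_formed = NA_REAL, t_vanish = NA_REAL, t_steady = NA_REAL;
  double max_rcore = 0.0, t_max_rcore = NA_REAL;
  // formation peak: running max of r_core, frozen at the first local
  // maximum (once r_core has dropped by 1% of R_tilde from the running max)
  double peak_rcore = 0.0, t_peak = NA_REAL;
  bool peak_locked = false;
  // plateau: |d r_core / dt| below plateau_rate sustained over a trailing
  // window of plateau_window time units (r_core sampled at unit-time marks)
  std::vector<double> rc_marks;
  double next_mark = t0;
  bool plateau = false;
  double t_plateau = NA_REAL, rc_plateau = NA_REAL;
  double min_oxy_glob = *std::min_element(oxy.begin(), oxy.end());
  double steady_acc = 0.0;
  long n_steps = 0, n_reject = 0;
  const double eps_t = 1e-12;

  {
    double rc0 = core_radius_of(oxy, ccrit, h, R_tilde);
    if (rc0 > 0.0) { formed = true; t_formed = t0; max_rcore = rc0; t_max_rcore = t0; }
  }

  while (t < t_max - eps_t) {
    // constitutive fields from current oxygen
    for (int i = 0; i < N; ++i) {
      sval[i] = switch_s(oxy[i], ccrit, delta);
      fval[i] = oxy[i] / (Kchi + oxy[i]);
    }
    double vmax = 0.0;
    for (int k = 1; k < N; ++k) {
      const double cf = 0.5 * (oxy[k - 1] + oxy[k]);
      sface[k] = switch_s(cf, ccrit, delta);
      vface[k] = chi * sface[k] * (fval[k] - fval[k - 1]) / h;
      const double av = std::fabs(vface[k]);
      if (av > vmax) vmax = av;
    }

    double dt = dt_max;
    if (t + dt > t_max) dt = t_max - t;
    if (cadence > 0 && t + dt > next_out - eps_t) dt = next_out - t;
    if (evolve_cells && vmax > 0.0) {
      const double dt_cfl = cfl * h / vmax;
      if (dt_cfl < dt) dt = dt_cfl;
    }
    if (dt <= 0) dt = eps_t;

    bool accepted = false;
    while (!accepted) {
      // --- oxygen: backward Euler diffusion + Robin + implicit uptake ---
      for (int i = 0; i < N; ++i) {
        const double wl = (i > 0) ? dt * r_in[i] / (rc_vol[i] * h) : 0.0;
        const double wr = (i < N - 1) ? dt * r_out[i] / (rc_vol[i] * h) : 0.0;
        aa[i] = -wl;
        cc[i] = -wr;
        bb[i] = 1.0 + wl + wr;
        dd[i] = oxy[i];
        if (sink_mode == 0) {
          bb[i] += dt * uptake_amp * sval[i] * cel[i] / (K + oxy[i]);
        } else {
          dd[i] -= dt * sink_q;
        }
      }
      {  // Robin influx at the outer face
        const double w = dt * r_out[N - 1] * beta / rc_vol[N - 1];
        bb[N - 1] += w;
        dd[N - 1] += w * 1.0;
      }
      {
        std::vector<double> a2(aa), b2(bb), c2(cc);
        std::vector<double> d2(dd);
        thomas(a2, b2, c2, d2);
        oxy_new = d2;
      }

      if (evolve_cells) {
        // constitutive fields from the updated oxygen
        for (int i = 0; i < N; ++i) {
          sval[i] = switch_s(oxy_new[i], ccrit, delta);
          fval[i] = oxy_new[i] / (Kchi + oxy_new[i]);
        }
        for (int k = 1; k < N; ++k) {
          const double cf = 0.5 * (oxy_new[k - 1] + oxy_new[k]);
          sface[k] = switch_s(cf, ccrit, delta);
          vface[k] = chi * sface[k] * (fval[k] - fval[k - 1]) / h;
        }
        // explicit upwind advective fluxes (zero at both boundary faces)
        Gflux[0] = 0.0; Gflux[N] = 0.0;
        for (int k = 1; k < N; ++k) {
          const double up = (vface[k] >= 0.0) ? cel[k - 1] : cel[k];
          Gflux[k] = (k * h) * vface[k] * up;
        }
        for (int i = 0; i < N; ++i) {
          const double Dl = (i > 0) ? Dcell * sface[i] : 0.0;
          const double Dr = (i < N - 1) ? Dcell * sface[i + 1] : 0.0;
          const double wl = (i > 0) ? dt * Dl * r_in[i] / (rc_vol[i] * h) : 0.0;
          const double wr = (i < N - 1) ? dt * Dr * r_out[i] / (rc_vol[i] * h) : 0.0;
          aa[i] = -wl;
          cc[i] = -wr;
          bb[i] = 1.0 + wl + wr;
          dd[i] = cel[i] - dt * (Gflux[i + 1] - Gflux[i]) / rc_vol[i];
        }
        thomas(aa, bb, cc, dd);
        cel_new = dd;
        double cmin = *std::min_element(cel_new.begin(), cel_new.end());
        if (cmin < -1e-12) {
          dt *= 0.5;
          ++n_reject;
          if (dt < 1e-13)
            stop("time step collapsed below 1e-13 while enforcing positivity");
          continue;
        }
      } else {
        cel_new = cel;
      }
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(oxy_new[i]) || !std::isfinite(cel_new[i]))
          stop("non-finite field encountered at t = %g (step %ld)", t, n_steps);
      }
      accepted = true;
    }

    // rate of change for the steady-state criterion
    double maxrate = 0.0;
    for (int i = 0; i < N; ++i) {
      double d1 = std::fabs(oxy_new[i] - oxy[i]);
      double d2 = std::fabs(cel_new[i] - cel[i]);
      if (d1 > maxrate) maxrate = d1;
      if (d2 > maxrate) maxrate = d2;
    }
    maxrate /= dt;

    oxy = oxy_new;
    cel = cel_new;
    t += dt;
    ++n_steps;

    const double rc = core_radius_of(oxy, ccrit, h, R_tilde);
    double omin = oxy[0];
    for (int i = 1; i < N; ++i) if (oxy[i] < omin) omin = oxy[i];
    if (omin < min_oxy_glob) min_oxy_glob = omin;
    if (rc > 0.0 && !formed) { formed = true; t_formed = t; }
    if (rc > max_rcore) { max_rcore = rc; t_max_rcore = t; }
    if (!peak_locked) {
      if (rc >= peak_rcore) { peak_rcore = rc; t_peak = t; }
      else if (peak_rcore - rc > 0.01 * R_tilde) peak_locked = true;
    }
    if (formed && !vanished && rc == 0.0) { vanished = true; t_vanish = t; }
    while (t >= next_mark - eps_t) {
      rc_marks.push_back(rc);
      next_mark += 1.0;
    }
    if (!plateau && formed && !vanished &&
        (double) rc_marks.size() > plateau_window) {
      const size_t lag = (size_t) plateau_window;
      double lo = rc_marks.back(), hi = lo;
      for (size_t k = rc_marks.size() - 1 - lag; k < rc_marks.size(); ++k) {
        if (rc_marks[k] < lo) lo = rc_marks[k];
        if (rc_marks[k] > hi) hi = rc_marks[k];
      }
      if (hi - lo < plateau_rate * plateau_window && lo > 0.0) {
        plateau = true; t_plateau = t; rc_plateau = rc;
      }
    }

    if (maxrate < steady_tol) {
      steady_acc += dt;
      if (!steady && steady_acc >= steady_window) { steady = true; t_steady = t; }
    } else {
      steady_acc = 0.0;
    }

    if (cadence > 0 && t >= next_out - eps_t) {
      record(t);
      while (next_out <= t + eps_t) next_out += cadence;
    }

    if ((stop_on_anoxia && formed) || (stop_on_vanish && vanished) ||
        (stop_on_steady && steady) || (stop_on_plateau && plateau)) break;
    if (n_steps % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  if (out_t.back() < t - eps_t) record(t);

  double mass1 = 0.0;
  for (int i = 0; i < N; ++i) mass1 += cel[i] * rc_vol[i];
  mass1 *= 2.0 * M_PI;

  const int n_out = (int) out_t.size();
  NumericMatrix m_oxy(N, n_out), m_cel(N, n_out);
  for (int j = 0; j < n_out; ++j)
    for (int i = 0; i < N; ++i) {
      m_oxy(i, j) = out_oxy[(size_t) j * N + i];
      m_cel(i, j) = out_cel[(size_t) j * N + i];
    }

  return List::create(
    _["times"] = wrap(out_t),
    _["c_oxy"] = m_oxy,
    _["c_cell"] = m_cel,
    _["r_core"] = wrap(out_rcore),
    _["t_end"] = t,
    _["formed"] = formed, _["t_formed"] = t_formed,
    _["vanished"] = vanished, _["t_vanish"] = t_vanish,
    _["steady"] = steady, _["t_steady"] = t_steady,
    _["plateau"] = plateau, _["t_plateau"] = t_plateau,
    _["r_core_plateau"] = rc_plateau,
    _["r_core_peak"] = peak_locked ? peak_rcore
                                   : (formed ? max_rcore : NA_REAL),
    _["t_peak"] = t_peak,
    _["max_r_core"] = max_rcore, _["t_max_r_core"] = t_max_rcore,
    _["min_oxy"] = min_oxy_glob,
    _["n_steps"] = (double) n_steps, _["n_reject"] = (double) n_reject,
    _["cell_mass_initial"] = mass0, _["cell_mass_final"] = mass1);
}
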