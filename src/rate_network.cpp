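#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the hierarchical excitatory-inhibitory rate
// network. Input currents are rectified at zero; local-excitatory and
// long-range drive are scaled by (1 + eta * h_i). White-noise drive enters
// the external current of both populations with a rate-equivalent SD
// (noise_sd, Hz) converted to current through the f-I slope and scaled by
// 1/sqrt(dt) so the integrated variance is dt-invariant. Uses R's RNG, so
// set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
List simulate_rates_cpp(NumericMatrix fln, NumericVector h,
                        double tau_e, double tau_i,
                        double beta_e, double beta_i,
                        NumericVector w_ee, NumericVector w_ie,
                        double w_ei, double w_ii,
                        double mu_ee, double mu_ie, double eta,
                        NumericVector iext_e, NumericVector iext_i,
                        NumericVector v_e0, NumericVector v_i0,
                        double dt, int n_steps, double noise_sd,
                        int record_every, int burn_steps) {
  const int n = fln.nrow();
  std::vector<double> ve(v_e0.begin(), v_e0.end());
  std::vector<double> vi(v_i0.begin(), v_i0.end());
  std::vector<double> hscale(n), ilr(n);
  for (int i = 0; i < n; ++i) hscale[i] = 1.0 + eta * h[i];

  const int n_rec = (n_steps - burn_steps) / record_every;
  NumericMatrix rec_e(n_rec, n), rec_i(n_rec, n);
  const double sig_e = (noise_sd / beta_e) / std::sqrt(dt);
  const double sig_i = (noise_sd / beta_i) / std::sqrt(dt);
  const bool noisy = noise_sd > 0.0;

  int out_row = 0;
  for (int s = 0; s < n_steps; ++s) {
    // long-range excitatory drive: FLN is target x source
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += fln(i, j) * ve[j];
      ilr[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      double ie = hscale[i] * (w_ee[i] * ve[i] + mu_ee * ilr[i])
                  - w_ei * vi[i] + iext_e[i];
      double ii = hscale[i] * (w_ie[i] * ve[i] + mu_ie * ilr[i])
                  - w_ii * vi[i] + iext_i[i];
      if (noisy) {
        ie += sig_e * R::norm_rand();
        ii += sig_i * R::norm_rand();
      }
      if (ie < 0.0) ie = 0.0;
      if (ii < 0.0) ii = 0.0;
      double ve_new = ve[i] + dt / tau_e * (-ve[i] + beta_e * ie);
      double vi_new = vi[i] + dt / tau_i * (-vi[i] + beta_i * ii);
      if (!std::isfinite(ve_new) || !std::isfinite(vi_new))
        stop("rate divergence at node %d, t = %f s", i + 1, s * dt);
      ve[i] = ve_new;
      vi[i] = vi_new;
    }
    if (s >= burn_steps && (s - burn_steps) % record_every == 0 &&
        out_row < n_rec) {
      for (int i = 0; i < n; ++i) {
        rec_e(out_row, i) = ve[i];
        rec_i(out_row, i) = vi[i];
      }
      ++out_row;
    }
  }
  return List::create(_["rates_e"] = rec_e, _["rates_i"] = rec_i);
}

// Balloon-Windkessel hemodynamic forward model, driven per node by the
// deviation of the excitatory rate from its steady-state baseline. States:
// vasodilatory signal s, blood inflow f, venous volume v, deoxyhemoglobin q.
// BOLD is the static nonlinearity of (q, v); output is decimated to the TR
// grid. Integration failure (v or q <= 0) aborts with a diagnostic.
// [[Rcpp::export]]
NumericMatrix bold_forward_cpp(NumericMatrix z, double dt,
                               double kappa, double gamma_f,
                               double tau_mtt, double alpha, double rho,
                               double v0, double k1, double k2, double k3,
                               int decim) {
  const int n_t = z.nrow(), n = z.ncol();
  const int n_out = n_t / decim;
  NumericMatrix bold(n_out, n);
  const double inv_alpha = 1.0 / alpha;

  for (int i = 0; i < n; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    int row = 0;
    for (int t = 0; t < n_t; ++t) {
      double fout = std::pow(v, inv_alpha);
      double ds = z(t, i) - kappa * s - gamma_f * (f - 1.0);
      double df = s;
      double dv = (f - fout) / tau_mtt;
      double dq = (f * (1.0 - std::pow(1.0 - rho, 1.0 / f)) / rho
                   - fout * q / v) / tau_mtt;
      s += dt * ds;
      f += dt * df;
      v += dt * dv;
      q += dt * dq;
      if (v <= 0.0 || q <= 0.0 || !std::isfinite(v) || !std::isfinite(q))
        stop("hemodynamic state collapse at node %d, t = %f s "
             "(try a smaller dt)", i + 1, t * dt);
      if ((t + 1) % decim == 0 && row < n_out) {
        bold(row, i) = v0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v)
                             + k3 * (1.0 - v));
        ++row;
      }
    }
  }
  return bold;
}
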