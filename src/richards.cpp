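// Inner loop of the mixed-form Richards solver: adaptive sub-daily stepping
// with modified Picard iteration (chord-slope capacity, geometric-mean
// interface conductivity with air-entry regularisation, implicit binding
// surface-flux limit, damped iterations).  Mirrors the reference R
// implementation in R/soil_water.R; the R richards_step() wrapper prepares
// inputs and interprets the outputs.

#include <Rcpp.h>
using namespace Rcpp;

static const double SS_SAT = 1e-5;   // specific storage above saturation, 1/cm

struct Hyd {
  const double *th_s, *th_r, *alpha, *n, *m, *l, *Ksat, *kscale;
  double hs;   // air-entry regularisation head (positive value, cm)
};

static inline double theta_of(double h, const Hyd &p, int i) {
  double hn = h < 0 ? -h : 0.0;
  double se = std::pow(1.0 + std::pow(p.alpha[i] * hn, p.n[i]), -p.m[i]);
  return p.th_r[i] + (p.th_s[i] - p.th_r[i]) * se;
}

static inline double w_of(double h, const Hyd &p, int i) {
  double w = theta_of(h, p, i);
  if (h > 0) w += SS_SAT * h;
  return w;
}

static inline double cap_of(double h, const Hyd &p, int i) {
  if (h >= 0) return SS_SAT;
  double ah = p.alpha[i] * std::fabs(h);
  return (p.th_s[i] - p.th_r[i]) * p.alpha[i] * p.n[i] * p.m[i] *
         std::pow(ah, p.n[i] - 1.0) *
         std::pow(1.0 + std::pow(ah, p.n[i]), -p.m[i] - 1.0);
}

static inline double k_raw(double h, const Hyd &p, int i) {
  double hn = h < 0 ? -h : 0.0;
  double se = std::pow(1.0 + std::pow(p.alpha[i] * hn, p.n[i]), -p.m[i]);
  if (se < 1e-12) se = 1e-12;
  double t = 1.0 - std::pow(1.0 - std::pow(se, 1.0 / p.m[i]), p.m[i]);
  return p.Ksat[i] * std::pow(se, p.l[i]) * t * t;
}

static inline double k_reg(double h, const Hyd &p, int i) {
  if (h >= -p.hs) return p.Ksat[i];
  double k = k_raw(h, p, i) * p.kscale[i];
  return k > p.Ksat[i] ? p.Ksat[i] : k;
}

static inline double head_from_w(double w, const Hyd &p, int i) {
  if (w >= p.th_s[i]) return (w - p.th_s[i]) / SS_SAT;
  double se = (w - p.th_r[i]) / (p.th_s[i] - p.th_r[i]);
  if (se < 1e-12) se = 1e-12;
  if (se >= 1.0) return 0.0;
  return -std::pow(std::pow(se, -1.0 / p.m[i]) - 1.0, 1.0 / p.n[i]) /
         p.alpha[i];
}

static inline double feddes(double h, double h_wilt, double h_lim) {
  double a = (h - h_wilt) / (h_lim - h_wilt);
  if (a < 0) a = 0;
  if (a > 1) a = 1;
  return a;
}

// [[Rcpp::export(name = ".richards_day_cpp")]]
List richards_day_cpp(NumericVector h0, NumericVector w0,
                      NumericVector th_s, NumericVector th_r,
                      NumericVector alpha, NumericVector nvg,
                      NumericVector mvg, NumericVector lvg,
                      NumericVector Ksat, NumericVector kscale,
                      NumericVector dz, NumericVector zc, NumericVector dzi,
                      double dt_h, double q_demand, int bc_type,
                      double bc_head, NumericVector sink_rate,
                      double tol_h, int max_iter, double dt_init,
                      double dt_min, double dt_max, double max_dtheta,
                      double h_dry, double h_wilt, double h_lim, double hs) {
  const int n = h0.size();
  Hyd p{th_s.begin(), th_r.begin(), alpha.begin(), nvg.begin(), mvg.begin(),
        lvg.begin(), Ksat.begin(), kscale.begin(), hs};

  std::vector<double> h_old(h0.begin(), h0.end());
  std::vector<double> th_old(w0.begin(), w0.end());
  std::vector<double> hk(n), thk(n), th_hold(n), th_prev(n), ck(n), kc(n),
      kint(n - 1), aa(n), bb(n), cc(n), rhs(n), cp(n), dp(n), q_int(n - 1),
      s_now(n), dth(n), th_prop(n);
  NumericVector edge_flux(n + 1), sink_acc(n);
  double runoff_cm = 0, t_done = 0;
  double dt_sub = std::min(dt_init, dt_h);
  int n_sub = 0;
  double err = 0;
  double q_top = 0, q_bot = 0;

  while (t_done < dt_h - 1e-12) {
    double dt_now = std::min(dt_sub, dt_h - t_done);
    int it = 0;
    for (;;) {   // retry loop (halving)
      for (int i = 0; i < n; ++i) {
        hk[i] = h_old[i];
        th_hold[i] = w_of(h_old[i], p, i);
        thk[i] = th_hold[i];
      }
      bool ok = false;
      err = 0;
      for (it = 1; it <= max_iter; ++it) {
        for (int i = 0; i < n; ++i) {
          double dh = hk[i] - h_old[i];
          double c = cap_of(hk[i], p, i);
          if (std::fabs(dh) > 1e-7) {
            c = (thk[i] - th_hold[i]) / dh;
            if (c < SS_SAT) c = SS_SAT;
          }
          ck[i] = c;
          kc[i] = k_reg(hk[i], p, i);
        }
        for (int i = 0; i < n - 1; ++i)
          kint[i] = std::sqrt(kc[i] * kc[i + 1]);
        // surface limit, implicit when binding
        double top_coef = 0, q_top_const;
        if (q_demand >= 0) {
          double q_cap = Ksat[0] * (1.0 - hk[0] / zc[0]);
          if (q_demand <= q_cap) q_top_const = q_demand;
          else { q_top_const = Ksat[0]; top_coef = Ksat[0] / zc[0]; }
        } else {
          double q_exf = kc[0] * (1.0 - (hk[0] - h_dry) / zc[0]);
          double lim = q_exf < 0 ? q_exf : 0;
          if (q_demand >= lim) q_top_const = q_demand;
          else { q_top_const = kc[0] * (1.0 + h_dry / zc[0]);
                 top_coef = kc[0] / zc[0]; }
        }
        // lower boundary
        double bot_coef = 0;
        if (bc_type == 0) q_bot = kc[n - 1];
        else if (bc_type == 1) q_bot = 0;
        else {
          double dzb = dz[n - 1] / 2.0;
          q_bot = kc[n - 1] * (1.0 - (bc_head - hk[n - 1]) / dzb);
          bot_coef = kc[n - 1] / dzb;
        }
        for (int i = 0; i < n; ++i) {
          double stor = ck[i] * dz[i] / dt_now;
          double s_act = sink_rate[i] * feddes(hk[i], h_wilt, h_lim);
          aa[i] = i == 0 ? 0 : -kint[i - 1] / dzi[i - 1];
          cc[i] = i == n - 1 ? 0 : -kint[i] / dzi[i];
          bb[i] = stor - aa[i] - cc[i];
          rhs[i] = stor * hk[i] - (thk[i] - th_old[i]) * dz[i] / dt_now -
                   s_act;
        }
        bb[0] += top_coef;
        bb[n - 1] += bot_coef;
        rhs[0] += q_top_const - kint[0];
        for (int i = 1; i < n - 1; ++i) rhs[i] += kint[i - 1] - kint[i];
        rhs[n - 1] += kint[n - 2] - q_bot + bot_coef * hk[n - 1];
        // Thomas
        cp[0] = cc[0] / bb[0];
        dp[0] = rhs[0] / bb[0];
        for (int i = 1; i < n; ++i) {
          double den = bb[i] - aa[i] * cp[i - 1];
          cp[i] = cc[i] / den;
          dp[i] = (rhs[i] - aa[i] * dp[i - 1]) / den;
        }
        double hn_new = dp[n - 1];
        err = 0;
        double relax = it > 25 ? 0.3 : (it > 4 ? 0.5 : 1.0);
        // back substitution with clamp, relax, error tracking
        double prev = hn_new;
        std::vector<double> hnew(n);
        hnew[n - 1] = prev;
        for (int i = n - 2; i >= 0; --i) {
          prev = dp[i] - cp[i] * prev;
          hnew[i] = prev;
        }
        double err_th = 0;
        for (int i = 0; i < n; ++i) {
          double v = hnew[i];
          if (v < -1e7) v = -1e7;
          if (v > 500) v = 500;
          double e = std::fabs(v - hk[i]);
          if (e > err) err = e;
          hk[i] += relax * (v - hk[i]);
          th_prev[i] = thk[i];
          thk[i] = w_of(hk[i], p, i);
          double et = std::fabs(thk[i] - th_prev[i]);
          if (et > err_th) err_th = et;
        }
        if (!std::isfinite(err) || err > 1e4) break;   // diverged
        if (err < tol_h || (it > 1 && err_th < 1e-8)) { ok = true; break; }
      }
      if (!ok && err < 0.05) ok = true;
      if (ok) {
        // diagnostic fluxes at the accepted iterate
        for (int i = 0; i < n; ++i) kc[i] = k_reg(hk[i], p, i);
        for (int i = 0; i < n - 1; ++i)
          kint[i] = std::sqrt(kc[i] * kc[i + 1]);
        if (q_demand >= 0) {
          double q_cap = Ksat[0] * (1.0 - hk[0] / zc[0]);
          q_top = q_demand <= q_cap ? q_demand : q_cap;
        } else {
          double q_exf = kc[0] * (1.0 - (hk[0] - h_dry) / zc[0]);
          double lim = q_exf < 0 ? q_exf : 0;
          q_top = q_demand >= lim ? q_demand : lim;
        }
        if (bc_type == 0) q_bot = kc[n - 1];
        else if (bc_type == 1) q_bot = 0;
        else q_bot = kc[n - 1] *
               (1.0 - (bc_head - hk[n - 1]) / (dz[n - 1] / 2.0));
        for (int i = 0; i < n - 1; ++i)
          q_int[i] = kint[i] * (1.0 - (hk[i + 1] - hk[i]) / dzi[i]);
        bool good = true;
        for (int i = 0; i < n; ++i) {
          s_now[i] = sink_rate[i] * feddes(hk[i], h_wilt, h_lim);
          double qin = i == 0 ? q_top : q_int[i - 1];
          double qout = i == n - 1 ? q_bot : q_int[i];
          dth[i] = (qin - qout - s_now[i]) / dz[i] * dt_now;
          th_prop[i] = th_old[i] + dth[i];
          if (std::fabs(dth[i]) > max_dtheta ||
              th_prop[i] <= th_r[i] + 1e-9) good = false;
        }
        if (good) break;
      }
      dt_sub = dt_now = dt_now / 2.0;
      if (dt_now < dt_min)
        return List::create(_["failed"] = true, _["t_done"] = t_done,
                            _["dt"] = dt_now, _["err"] = err);
    }
    // accept
    if (q_demand >= 0) runoff_cm += (q_demand - q_top) * dt_now;
    edge_flux[0] += q_top * dt_now;
    for (int i = 0; i < n - 1; ++i) edge_flux[i + 1] += q_int[i] * dt_now;
    edge_flux[n] += q_bot * dt_now;
    for (int i = 0; i < n; ++i) {
      sink_acc[i] += s_now[i] * dt_now;
      th_old[i] = th_prop[i];
      h_old[i] = th_old[i] < th_s[i] - 1e-9 ? head_from_w(th_old[i], p, i)
                                            : (hk[i] > 0 ? hk[i] : 0.0);
    }
    t_done += dt_now;
    ++n_sub;
    double grow = it <= 4 ? 2.0 : (it <= 12 ? 1.4 : 1.25);
    dt_sub = std::min(dt_sub * grow, dt_max);
  }

  return List::create(_["failed"] = false,
                      _["h"] = NumericVector(h_old.begin(), h_old.end()),
                      _["w"] = NumericVector(th_old.begin(), th_old.end()),
                      _["edge_flux"] = edge_flux,
                      _["sink_acc"] = sink_acc,
                      _["runoff_cm"] = runoff_cm,
                      _["n_substeps"] = n_sub);
}
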