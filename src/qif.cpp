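#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-step integrator for a network of quadratic integrate-and-fire units
//
//   dv_i/dt = b_i + v_i^2 + g * sum_{j ~ i} (v_j - v_i) + g0 * (u - v_i)
//   du/dt   = b0 + u^2                                   (autonomous drive)
//
// with hard resets: when a step carries a unit across v_peak, the crossing
// time is located by linear interpolation within the step and recorded as a
// spike; the unit restarts from v_reset at that instant and is advanced over
// the step remainder with a coupling-free Euler update (the remainder is
// O(dt), once per period).  The drive u always uses thresholds (0, 1), the
// range on which its transit time equals b0^{-1/2} atan(b0^{-1/2}).
//
// The dynamics are bounded above by v_peak through the reset, so no
// finite-time blow-up handling is needed.

struct NetDeriv {
  const std::vector<double>& b;
  const std::vector<int>& ei;   // edge endpoints, 0-based
  const std::vector<int>& ej;
  double g, g0, b0;

  NetDeriv(const std::vector<double>& b_, const std::vector<int>& ei_,
           const std::vector<int>& ej_, double g_, double g0_, double b0_)
      : b(b_), ei(ei_), ej(ej_), g(g_), g0(g0_), b0(b0_) {}

  void operator()(const std::vector<double>& v, double u,
                  std::vector<double>& dv, double& du) const {
    const int n = (int)v.size();
    du = b0 + u * u;
    for (int i = 0; i < n; ++i) dv[i] = b[i] + v[i] * v[i] + g0 * (u - v[i]);
    if (g != 0.0) {
      const int m = (int)ei.size();
      for (int k = 0; k < m; ++k) {
        const int a = ei[k], c = ej[k];
        const double d = g * (v[c] - v[a]);
        dv[a] += d;
        dv[c] -= d;
      }
    }
  }
};

// [[Rcpp::export(name = ".qif_integrate_cpp")]]
List qif_integrate_cpp(NumericVector b, IntegerVector edge_i,
                       IntegerVector edge_j, double g, double g0, double b0,
                       double v_reset, double v_peak, NumericVector v0,
                       double u0, double dt, int n_steps, int record_every,
                       bool rk4) {
  const int n = b.size();
  if (v0.size() != n) stop("length(v0) must equal length(b)");
  if (edge_i.size() != edge_j.size()) stop("edge endpoint vectors differ in length");
  if (dt <= 0) stop("dt must be positive");
  if (record_every < 1) record_every = 1;

  std::vector<double> bb(b.begin(), b.end());
  std::vector<int> ei(edge_i.begin(), edge_i.end());
  std::vector<int> ej(edge_j.begin(), edge_j.end());
  NetDeriv f(bb, ei, ej, g, g0, b0);

  std::vector<double> v(v0.begin(), v0.end());
  double u = u0;

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix V(n_rec, n);
  NumericVector U(n_rec), times(n_rec);
  std::vector<std::vector<double> > spikes(n);
  std::vector<double> u_spikes;

  // scratch for RK stages
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n), v_old(n);
  double l1, l2, l3, l4;

  int rec = 0;
  for (int i = 0; i < n; ++i) V(0, i) = v[i];
  U[0] = u;
  times[0] = 0.0;
  rec = 1;

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    v_old = v;
    const double u_old = u;

    if (rk4) {
      f(v, u, k1, l1);
      for (int i = 0; i < n; ++i) tmp[i] = v[i] + 0.5 * dt * k1[i];
      f(tmp, u + 0.5 * dt * l1, k2, l2);
      for (int i = 0; i < n; ++i) tmp[i] = v[i] + 0.5 * dt * k2[i];
      f(tmp, u + 0.5 * dt * l2, k3, l3);
      for (int i = 0; i < n; ++i) tmp[i] = v[i] + dt * k3[i];
      f(tmp, u + dt * l3, k4, l4);
      for (int i = 0; i < n; ++i)
        v[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      u += dt / 6.0 * (l1 + 2.0 * l2 + 2.0 * l3 + l4);
    } else {  // euler
      f(v, u, k1, l1);
      for (int i = 0; i < n; ++i) v[i] += dt * k1[i];
      u += dt * l1;
    }

    // reset of network units at v_peak
    for (int i = 0; i < n; ++i) {
      if (v[i] >= v_peak) {
        const double frac = (v_peak - v_old[i]) / (v[i] - v_old[i]);
        const double t_cross = t + frac * dt;
        spikes[i].push_back(t_cross);
        const double rem = dt - frac * dt;
        v[i] = v_reset + rem * (bb[i] + v_reset * v_reset);
      }
    }
    // drive resets on (0, 1)
    if (u >= 1.0) {
      const double frac = (1.0 - u_old) / (u - u_old);
      const double t_cross = t + frac * dt;
      u_spikes.push_back(t_cross);
      u = (dt - frac * dt) * b0;
    }

    if ((s + 1) % record_every == 0) {
      for (int i = 0; i < n; ++i) V(rec, i) = v[i];
      U[rec] = u;
      times[rec] = (s + 1) * dt;
      ++rec;
    }
  }

  List sp(n);
  for (int i = 0; i < n; ++i) sp[i] = NumericVector(spikes[i].begin(), spikes[i].end());

  return List::create(_["times"] = times, _["v"] = V, _["u"] = U,
                      _["spikes"] = sp,
                      _["u_spikes"] = NumericVector(u_spikes.begin(), u_spikes.end()));
}

// One evaluation of the diffusive-coupling field alone (no intrinsic terms,
// no drive), used to assert that gap-junction exchange conserves total
// "charge": the entries sum to zero for any symmetric edge set.
// [[Rcpp::export(name = ".qif_coupling_field_cpp")]]
NumericVector qif_coupling_field_cpp(NumericVector v, IntegerVector edge_i,
                                     IntegerVector edge_j, double g) {
  const int n = v.size();
  NumericVector dv(n);
  const int m = edge_i.size();
  for (int k = 0; k < m; ++k) {
    const int a = edge_i[k], c = edge_j[k];
    const double d = g * (v[c] - v[a]);
    dv[a] += d;
    dv[c] -= d;
  }
  return dv;
}
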