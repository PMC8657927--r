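#include <Rcpp.h>
using namespace Rcpp;

// Grid/probe interaction energies. For each evaluation point the three
// components are accumulated over atoms:
//   E_lj : eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6), Lorentz-Berthelot
//          mixing (geometric eps, arithmetic rmin)
//   E_el : 332.06 * q_probe * q_atom / (4 r^2)   (distance-dependent
//          dielectric eps(r) = 4r)
//   E_hb : 6-4 radial well eps_hb*(2 (r0/r)^6 - 3 (r0/r)^4) * cos^2(theta)
//          between complementary donor/acceptor partners; theta is the
//          angle between the atom's idealized interaction direction and
//          the atom->point vector (cos clamped to [0,1]).
// A pair closer than r_floor contributes exactly pair_cap (to the LJ
// component) and nothing else -- the documented core clamp. Elsewhere the
// raw r^-12 repulsion keeps van der Waals cores strongly positive, so
// filtered (negative-energy) nodes never sit inside an atom.
//
// hb_flag per atom: 0 = none, 1 = acceptor (hba), 2 = donor (hbd).
// probe_role:       0 = none, 1 = acceptor probe (pairs with hbd atoms),
//                   2 = donor probe (pairs with hba atoms).

// [[Rcpp::export]]
NumericMatrix mif_energies_cpp(NumericMatrix points, NumericMatrix atoms,
                               NumericVector charge, NumericVector eps,
                               NumericVector rmin, IntegerVector hb_flag,
                               NumericMatrix hb_dir,
                               double p_eps, double p_rmin, double p_charge,
                               int probe_role, double hb_eps, double hb_rmin,
                               double r_floor, double pair_cap) {
  const int np = points.nrow(), na = atoms.nrow();
  NumericMatrix out(np, 3);
  const double coulomb = 332.06;
  const int want_flag = (probe_role == 1) ? 2 : (probe_role == 2 ? 1 : 0);

  // per-atom mixed LJ parameters, hoisted out of the grid loop
  std::vector<double> mix_eps(na), mix_rm2(na);
  for (int a = 0; a < na; ++a) {
    const double rm = 0.5 * (rmin[a] + p_rmin);
    mix_eps[a] = std::sqrt(eps[a] * p_eps);
    mix_rm2[a] = rm * rm;
  }

  for (int p = 0; p < np; ++p) {
    const double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    double e_lj = 0.0, e_el = 0.0, e_hb = 0.0;
    for (int a = 0; a < na; ++a) {
      double dx = px - atoms(a, 0), dy = py - atoms(a, 1), dz = pz - atoms(a, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < r_floor * r_floor) { e_lj += pair_cap; continue; }
      // Lennard-Jones
      const double s2 = mix_rm2[a] / r2;
      const double s6 = s2 * s2 * s2;
      e_lj += mix_eps[a] * (s6 * s6 - 2.0 * s6);
      // electrostatics, eps(r) = 4r
      if (p_charge != 0.0 && charge[a] != 0.0)
        e_el += coulomb * p_charge * charge[a] / (4.0 * r2);
      // hydrogen bond
      if (want_flag != 0 && hb_flag[a] == want_flag) {
        const double t2 = (hb_rmin * hb_rmin) / r2;
        const double t4 = t2 * t2;
        const double t6 = t4 * t2;
        const double r = std::sqrt(r2);
        double c = (dx * hb_dir(a, 0) + dy * hb_dir(a, 1) + dz * hb_dir(a, 2)) / r;
        if (c < 0.0) c = 0.0;
        e_hb += hb_eps * (2.0 * t6 - 3.0 * t4) * c * c;
      }
    }
    out(p, 0) = e_lj;
    out(p, 1) = e_el;
    out(p, 2) = e_hb;
  }
  return out;
}

// Greedy energy/spread node selection over cutoff-passing candidates.
// First pick is the global energy minimum (ties: lowest index); then each
// step adds the candidate maximising
//   (1 - w) * |E| / |E|_max + w * d_min / d_max
// where d_min is the distance to the nearest already-selected node.
// Returns 1-based indices into the candidate set, in selection order.

// [[Rcpp::export]]
IntegerVector select_nodes_cpp(NumericMatrix coords, NumericVector energy,
                               int max_nodes, double spread_weight,
                               double d_max) {
  const int n = coords.nrow();
  IntegerVector sel;
  if (n == 0 || max_nodes <= 0) return sel;
  if (d_max <= 0.0) d_max = 1.0;

  double emax = 0.0;
  int first = 0;
  for (int i = 0; i < n; ++i)
    if (energy[i] < energy[first]) first = i;
  emax = std::fabs(energy[first]);
  if (emax <= 0.0) emax = 1.0;

  std::vector<bool> taken(n, false);
  std::vector<double> dmin(n);
  std::vector<int> order;
  order.reserve(std::min(n, max_nodes));
  order.push_back(first);
  taken[first] = true;
  for (int i = 0; i < n; ++i) {
    const double dx = coords(i, 0) - coords(first, 0);
    const double dy = coords(i, 1) - coords(first, 1);
    const double dz = coords(i, 2) - coords(first, 2);
    dmin[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  while ((int)order.size() < max_nodes && (int)order.size() < n) {
    int best = -1;
    double best_score = -1.0;
    for (int i = 0; i < n; ++i) {
      if (taken[i]) continue;
      const double score = (1.0 - spread_weight) * std::fabs(energy[i]) / emax +
                           spread_weight * dmin[i] / d_max;
      if (score > best_score + 1e-15) { best_score = score; best = i; }
    }
    if (best < 0) break;
    taken[best] = true;
    order.push_back(best);
    for (int i = 0; i < n; ++i) {
      if (taken[i]) continue;
      const double dx = coords(i, 0) - coords(best, 0);
      const double dy = coords(i, 1) - coords(best, 1);
      const double dz = coords(i, 2) - coords(best, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < dmin[i]) dmin[i] = d;
    }
  }
  IntegerVector res(order.size());
  for (size_t k = 0; k < order.size(); ++k) res[k] = order[k] + 1;
  return res;
}

// PLS1 (NIPALS, centred, optionally unit-variance scaled) PRESS under a
// fold assignment. For each fold the model is refit on the remaining
// samples and the held-out responses predicted. Returns the vector of
// out-of-fold predictions (same order as y).

static void pls1_coef(const std::vector<std::vector<double>> &X,
                      const std::vector<double> &y, int nlv,
                      std::vector<double> &beta, double &intercept,
                      bool scale_x) {
  const int n = (int)y.size();
  const int p = n > 0 ? (int)X[0].size() : 0;
  std::vector<double> xm(p, 0.0), xs(p, 1.0);
  double ym = 0.0;
  for (int i = 0; i < n; ++i) ym += y[i];
  ym /= n;
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += X[i][j];
    xm[j] = m / n;
  }
  if (scale_x) {
    for (int j = 0; j < p; ++j) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        const double d = X[i][j] - xm[j];
        ss += d * d;
      }
      xs[j] = ss > 0 ? std::sqrt(ss / (n - 1)) : 1.0;
    }
  }
  std::vector<std::vector<double>> E(n, std::vector<double>(p));
  std::vector<double> f(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) E[i][j] = (X[i][j] - xm[j]) / xs[j];
    f[i] = y[i] - ym;
  }
  // accumulate W, P, q per component; coefficients via B = W (P'W)^-1 q
  std::vector<std::vector<double>> W, P;
  std::vector<double> qv;
  std::vector<double> w(p), t(n), pl(p);
  for (int lv = 0; lv < nlv; ++lv) {
    double wn = 0.0;
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += E[i][j] * f[i];
      w[j] = s;
      wn += s * s;
    }
    wn = std::sqrt(wn);
    if (wn < 1e-12) break;
    for (int j = 0; j < p; ++j) w[j] /= wn;
    double tt = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += E[i][j] * w[j];
      t[i] = s;
      tt += s * s;
    }
    if (tt < 1e-12) break;
    double q = 0.0;
    for (int i = 0; i < n; ++i) q += t[i] * f[i];
    q /= tt;
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += E[i][j] * t[i];
      pl[j] = s / tt;
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) E[i][j] -= t[i] * pl[j];
      f[i] -= t[i] * q;
    }
    W.push_back(w);
    P.push_back(pl);
    qv.push_back(q);
  }
  const int k = (int)W.size();
  beta.assign(p, 0.0);
  intercept = ym;
  if (k == 0) return;
  // solve (P'W) r = q ; P'W is upper triangular with unit-ish structure
  std::vector<std::vector<double>> PW(k, std::vector<double>(k, 0.0));
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += P[a][j] * W[b][j];
      PW[a][b] = s;
    }
  // Gaussian elimination on the small k x k system
  std::vector<double> r(qv);
  for (int c = 0; c < k; ++c) {
    int piv = c;
    for (int a = c + 1; a < k; ++a)
      if (std::fabs(PW[a][c]) > std::fabs(PW[piv][c])) piv = a;
    std::swap(PW[c], PW[piv]);
    std::swap(r[c], r[piv]);
    if (std::fabs(PW[c][c]) < 1e-14) continue;
    for (int a = c + 1; a < k; ++a) {
      const double fct = PW[a][c] / PW[c][c];
      for (int b = c; b < k; ++b) PW[a][b] -= fct * PW[c][b];
      r[a] -= fct * r[c];
    }
  }
  for (int c = k - 1; c >= 0; --c) {
    double s = r[c];
    for (int b = c + 1; b < k; ++b) s -= PW[c][b] * r[b];
    r[c] = std::fabs(PW[c][c]) < 1e-14 ? 0.0 : s / PW[c][c];
  }
  std::vector<double> bscaled(p, 0.0);
  for (int a = 0; a < k; ++a)
    for (int j = 0; j < p; ++j) bscaled[j] += W[a][j] * r[a];
  for (int j = 0; j < p; ++j) {
    beta[j] = bscaled[j] / xs[j];
    intercept -= beta[j] * xm[j];
  }
}

// [[Rcpp::export]]
NumericVector pls_cv_predictions_cpp(NumericMatrix X, NumericVector y,
                                     int nlv, IntegerVector fold,
                                     bool scale_x) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector pred(n);
  IntegerVector ufold = sort_unique(fold);
  for (int fi = 0; fi < ufold.size(); ++fi) {
    const int f = ufold[fi];
    std::vector<std::vector<double>> Xtr;
    std::vector<double> ytr;
    std::vector<int> test_idx;
    for (int i = 0; i < n; ++i) {
      if (fold[i] == f) {
        test_idx.push_back(i);
      } else {
        std::vector<double> row(p);
        for (int j = 0; j < p; ++j) row[j] = X(i, j);
        Xtr.push_back(row);
        ytr.push_back(y[i]);
      }
    }
    std::vector<double> beta;
    double intercept;
    int k = std::min(nlv, (int)ytr.size() - 1);
    if (k < 1) k = 1;
    pls1_coef(Xtr, ytr, k, beta, intercept, scale_x);
    for (size_t t = 0; t < test_idx.size(); ++t) {
      const int i = test_idx[t];
      double s = intercept;
      for (int j = 0; j < p; ++j) s += beta[j] * X(i, j);
      pred[i] = s;
    }
  }
  return pred;
}
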