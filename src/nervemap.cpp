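#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---- 2D connected components (4-neighbourhood), union-find ----------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused (background)
  // first pass
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c)) continue;
      int up = (r > 0) ? lab(r - 1, c) : 0;
      int left = (c > 0) ? lab(r, c - 1) : 0;
      if (up == 0 && left == 0) {
        int id = (int)parent.size();
        parent.push_back(id);
        lab(r, c) = id;
      } else if (up != 0 && left == 0) {
        lab(r, c) = up;
      } else if (up == 0) {
        lab(r, c) = left;
      } else {
        int ru = uf_find(parent, up), rl = uf_find(parent, left);
        int m = ru < rl ? ru : rl;
        parent[ru] = m; parent[rl] = m;
        lab(r, c) = m;
      }
    }
  }
  // second pass: relabel compactly
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c)) {
        int root = uf_find(parent, lab(r, c));
        if (remap[root] == 0) remap[root] = ++next;
        lab(r, c) = remap[root];
      }
  return lab;
}

// ---- MRG double-cable backward-Euler integrator ---------------------------
//
// Units: mV, ms, uF, mS (=> currents in uA). Unknowns per compartment i:
// Vm_i (axolemma transmembrane) and p_i (periaxonal potential). Gates are
// advanced semi-implicitly from the previous voltage, then the linear
// system in (Vm, p) is solved with LAPACK's banded dgbsv (kl = 2, ku = 3).

static inline double vtrap(double a, double v, double v0, double k) {
  // a * (v - v0) / (1 - exp(-(v - v0)/k)); stable near v = v0
  double x = (v - v0) / k;
  if (std::fabs(x) < 1e-6) return a * k * (1.0 + x / 2.0);
  return a * (v - v0) / (1.0 - std::exp(-x));
}

struct Rates { double am, bm, ah, bh, ap, bp, as_, bs_; };

static Rates mrg_rates(double v, double q1, double q2, double q3) {
  Rates r;
  r.am = q1 * vtrap(6.57, v, -20.4, 10.3);
  r.bm = q1 * vtrap(0.304, -v, 25.7, 9.16);
  r.ah = q2 * vtrap(0.34, -v, 114.0, 11.0);
  r.bh = q2 * 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));
  r.ap = q1 * vtrap(0.0353, v, -27.0, 10.2);
  r.bp = q1 * vtrap(0.000883, -v, 34.0, 10.0);
  r.as_ = q3 * 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0));
  r.bs_ = q3 * 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0));
  return r;
}

// [[Rcpp::export]]
List mrg_backward_euler(NumericVector cm, NumericVector gpas,
                        NumericVector epas, NumericVector cmy,
                        NumericVector gmy, IntegerVector is_node,
                        NumericVector gnaf, NumericVector gnap,
                        NumericVector gks, NumericVector gax,
                        NumericVector gp, NumericVector ve_shape,
                        NumericVector weights, double dt, double v_init,
                        double ena, double ek, double q1, double q2,
                        double q3, IntegerVector record_idx) {
  int N = cm.size();
  int nsteps = weights.size() - 1;
  int n = 2 * N, kl = 2, ku = 3, nrhs = 1, ldab = 2 * kl + ku + 1; // 8
  std::vector<double> ab((size_t)ldab * n);
  std::vector<double> rhs(n);
  std::vector<int> ipiv(n);

  std::vector<double> vm(N, v_init), pp(N, 0.0);
  std::vector<double> m(N, 0), h(N, 0), pgate(N, 0), s(N, 0);
  for (int i = 0; i < N; ++i) {
    if (is_node[i]) {
      Rates r = mrg_rates(v_init, q1, q2, q3);
      m[i] = r.am / (r.am + r.bm);
      h[i] = r.ah / (r.ah + r.bh);
      pgate[i] = r.ap / (r.ap + r.bp);
      s[i] = r.as_ / (r.as_ + r.bs_);
    }
  }

  int nrec = record_idx.size();
  NumericMatrix traces(nrec, nsteps + 1);
  for (int k = 0; k < nrec; ++k) traces(k, 0) = vm[record_idx[k]];

  bool blowup = false;
  // band storage: element (r, c) of full matrix at ab[kl + ku + r - c, c]
  auto AB = [&](int r, int c) -> double& {
    return ab[(size_t)ldab * c + (kl + ku + r - c)];
  };

  for (int step = 1; step <= nsteps && !blowup; ++step) {
    double w_old = weights[step - 1], w_new = weights[step];

    std::fill(ab.begin(), ab.end(), 0.0);

    for (int i = 0; i < N; ++i) {
      double Gion = 0.0, SE = 0.0;
      if (is_node[i]) {
        Rates r = mrg_rates(vm[i], q1, q2, q3);
        m[i] = (m[i] + dt * r.am) / (1.0 + dt * (r.am + r.bm));
        h[i] = (h[i] + dt * r.ah) / (1.0 + dt * (r.ah + r.bh));
        pgate[i] = (pgate[i] + dt * r.ap) / (1.0 + dt * (r.ap + r.bp));
        s[i] = (s[i] + dt * r.as_) / (1.0 + dt * (r.as_ + r.bs_));
        double gna = gnaf[i] * m[i] * m[i] * m[i] * h[i];
        double gnp = gnap[i] * pgate[i] * pgate[i] * pgate[i];
        double gk = gks[i] * s[i];
        Gion = gna + gnp + gk;
        SE = (gna + gnp) * ena + gk * ek;
      }

      double gax_l = (i > 0) ? gax[i - 1] : 0.0;
      double gax_r = (i < N - 1) ? gax[i] : 0.0;
      double gp_l = (i > 0) ? gp[i - 1] : 0.0;
      double gp_r = (i < N - 1) ? gp[i] : 0.0;
      double gax_sum = gax_l + gax_r, gp_sum = gp_l + gp_r;
      double amemb = cm[i] / dt + Gion + gpas[i];

      int rv = 2 * i, rp = 2 * i + 1;
      // axolemma row
      AB(rv, rv) = amemb + gax_sum;
      AB(rv, rp) = gax_sum;
      if (i > 0) { AB(rv, rv - 2) = -gax_l; AB(rv, rv - 1) = -gax_l; }
      if (i < N - 1) { AB(rv, rv + 2) = -gax_r; AB(rv, rv + 3) = -gax_r; }
      rhs[rv] = cm[i] / dt * vm[i] + SE + gpas[i] * epas[i];

      // periaxonal row
      double ve_new = ve_shape[i] * w_new, ve_old = ve_shape[i] * w_old;
      AB(rp, rp) = cmy[i] / dt + gmy[i] + gp_sum;
      AB(rp, rv) = -amemb;
      if (i > 0) AB(rp, rp - 2) = -gp_l;
      if (i < N - 1) AB(rp, rp + 2) = -gp_r;
      rhs[rp] = cmy[i] / dt * (pp[i] + ve_new - ve_old) + gmy[i] * ve_new -
        (cm[i] / dt * vm[i] + SE + gpas[i] * epas[i]);
    }

    int info = 0;
    F77_CALL(dgbsv)(&n, &kl, &ku, &nrhs, ab.data(), &ldab, ipiv.data(),
                    rhs.data(), &n, &info);
    if (info != 0) { blowup = true; break; }

    for (int i = 0; i < N; ++i) {
      vm[i] = rhs[2 * i];
      pp[i] = rhs[2 * i + 1];
      if (!std::isfinite(vm[i])) blowup = true;
    }
    for (int k = 0; k < nrec; ++k) traces(k, step) = vm[record_idx[k]];
  }

  return List::create(_["traces"] = traces, _["blowup"] = blowup,
                      _["vm_final"] = NumericVector(vm.begin(), vm.end()));
}
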