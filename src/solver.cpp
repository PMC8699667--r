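// Exact grid minimization of the MAVB deviation objective.
//
// Every candidate is an integer grid point (delta_a, increments...) of one
// combinatorial "structure" (blocktype + ratio assignment + phase offsets).
// Simulated RR intervals are linear in the parameters with integer
// coefficients, so squared objectives are exact integers (representable in
// doubles far below 2^53) and ties are exact.
//
// Two search paths over the SAME candidate set:
//  * analytic ("enumerate"): per (structure, increments) the objective is a
//    convex quadratic in delta_a, whose integer minimizer over the feasible
//    interval is the clamped floor/ceil of the continuous argmin;
//  * brute force: full triple loop with optional monotone prefix-sum pruning
//    against the incumbent (sound: a prefix of a sum of squares never
//    shrinks, and only strict improvements replace the incumbent).
//
// Tie-break (total order): smaller F^2, then lower blocktype id, then lower
// delta_a, then lexicographically smaller free-parameter vector.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Structure {
  int bt;
  double rho;
  std::vector<long> a;          // n objective rows
  std::vector<long> B;          // n x nd, column-major
  std::vector<long> cons_a;     // monotonicity constraint rows
  std::vector<long> cons_B;     // ncons x nd, column-major
  std::vector<std::vector<int> > grids;  // increment grids
  std::vector<int> oc;          // free-parameter template
  std::vector<int> dpos;        // 0-based increment slots in oc
};

struct Incumbent {
  bool found = false;
  double F2 = R_PosInf;
  int bt = 0;
  long da = 0;
  std::vector<int> oc;
  int struct_idx = -1;
  std::vector<int> deltas;
};

bool better(double F2, int bt, long da, const std::vector<int> &oc,
            const Incumbent &inc) {
  if (!inc.found) return true;
  if (F2 != inc.F2) return F2 < inc.F2;
  if (bt != inc.bt) return bt < inc.bt;
  if (da != inc.da) return da < inc.da;
  const size_t m = std::min(oc.size(), inc.oc.size());
  for (size_t i = 0; i < m; ++i)
    if (oc[i] != inc.oc[i]) return oc[i] < inc.oc[i];
  return false;
}

// ceil(a / b), floor(a / b) for integer a and b > 0
inline long cdiv(long a, long b) { return (a >= 0) ? (a + b - 1) / b : -((-a) / b); }
inline long fdiv(long a, long b) { return (a >= 0) ? a / b : -(((-a) + b - 1) / b); }

}  // namespace

// [[Rcpp::export(name = ".solve_grid")]]
List solve_grid(IntegerVector y_, List structures, int lo, int hi, int step,
                int clip, bool brute, bool prune, bool restrict_da,
                double tau) {
  const int n = y_.size();
  std::vector<long> y(y_.begin(), y_.end());
  const long Kmax_global = (hi >= lo) ? (hi - lo) / step : -1;
  double mean_y = 0.0;
  for (int i = 0; i < n; ++i) mean_y += y[i];
  mean_y /= n;

  // pre-extract structures into POD form (keeps the hot loops free of SEXP)
  const int ns = structures.size();
  std::vector<Structure> S(ns);
  for (int si = 0; si < ns; ++si) {
    List st = structures[si];
    Structure &s = S[si];
    s.bt = as<int>(st["bt"]);
    s.rho = as<double>(st["rho"]);
    IntegerVector a = st["a"];
    s.a.assign(a.begin(), a.end());
    IntegerMatrix B = st["B"];
    s.B.assign(B.begin(), B.end());
    IntegerVector ca = st["cons_a"];
    s.cons_a.assign(ca.begin(), ca.end());
    IntegerMatrix cB = st["cons_B"];
    s.cons_B.assign(cB.begin(), cB.end());
    List grids = st["grids"];
    for (int j = 0; j < grids.size(); ++j) {
      IntegerVector g = grids[j];
      s.grids.push_back(std::vector<int>(g.begin(), g.end()));
    }
    IntegerVector oc = st["oc"];
    s.oc.assign(oc.begin(), oc.end());
    IntegerVector dp = st["dpos"];
    for (int j = 0; j < dp.size(); ++j) s.dpos.push_back(dp[j] - 1);
  }

  Incumbent inc;
  double n_eval = 0.0;
  std::vector<long> d(n);
  std::vector<int> oc, del;
  std::vector<size_t> gi;
  std::vector<long> dc;

  for (int si = 0; si < ns; ++si) {
    const Structure &s = S[si];
    const int nd = (int)s.grids.size();
    const int ncons = (int)s.cons_a.size();
    const long *a = s.a.data();
    const long *B = s.B.data();

    long kmin = 0, kmax = Kmax_global;
    if (restrict_da) {
      const double rlo = s.rho * mean_y * (1.0 - tau);
      const double rhi = s.rho * mean_y * (1.0 + tau);
      long k1 = (long)std::ceil((rlo - lo) / step - 1e-12);
      long k2 = (long)std::floor((rhi - lo) / step + 1e-12);
      if (k1 > kmin) kmin = k1;
      if (k2 < kmax) kmax = k2;
    }
    if (kmin > kmax) continue;

    long suma2 = 0;
    for (int i = 0; i < n; ++i) suma2 += a[i] * a[i];

    oc = s.oc;
    gi.assign(nd, 0);
    del.assign(nd, 0);
    dc.assign(ncons, 0);

    bool more = true;
    while (more) {
      for (int j = 0; j < nd; ++j) {
        del[j] = s.grids[j][gi[j]];
        oc[s.dpos[j]] = del[j];
      }
      for (int i = 0; i < n; ++i) {
        long sm = 0;
        for (int j = 0; j < nd; ++j) sm += B[i + (long)j * n] * del[j];
        d[i] = sm;
      }
      for (int i = 0; i < ncons; ++i) {
        long sm = 0;
        for (int j = 0; j < nd; ++j) sm += s.cons_B[i + (long)j * ncons] * del[j];
        dc[i] = sm;
      }

      // feasible delta_a index interval for this (structure, increments):
      //  data rows:       |a_i (lo + k step) + d_i - y_i| <= clip and >= 1
      //  constraint rows: ca_i (lo + k step) + dc_i >= 1
      long klo = kmin, khi = kmax;
      for (int i = 0; i < n && klo <= khi; ++i) {
        const long A = a[i] * step;
        const long C = a[i] * lo + d[i];
        long t1 = cdiv(y[i] - clip - C, A);
        long t2 = fdiv(y[i] + clip - C, A);
        long t3 = cdiv(1 - C, A);
        if (t1 > klo) klo = t1;
        if (t3 > klo) klo = t3;
        if (t2 < khi) khi = t2;
      }
      for (int i = 0; i < ncons && klo <= khi; ++i) {
        const long A = s.cons_a[i] * step;
        const long C = s.cons_a[i] * lo + dc[i];
        long t3 = cdiv(1 - C, A);
        if (t3 > klo) klo = t3;
      }

      if (klo <= khi) {
        if (!brute) {
          double num = 0.0;
          for (int i = 0; i < n; ++i)
            num += (double)a[i] * (double)(y[i] - d[i] - a[i] * lo);
          const double kstar = num / ((double)step * (double)suma2);
          long k1 = (long)std::floor(kstar);
          if (k1 < klo) k1 = klo;
          if (k1 > khi) k1 = khi;
          long k2 = (k1 + 1 > khi) ? k1 : k1 + 1;
          for (int c = 0; c < 2; ++c) {
            const long k = (c == 0) ? k1 : k2;
            if (c == 1 && k2 == k1) break;
            const long da = lo + k * step;
            double F2 = 0.0;
            for (int i = 0; i < n; ++i) {
              const double r = (double)(a[i] * da + d[i] - y[i]);
              F2 += r * r;
            }
            n_eval += 1.0;
            if (better(F2, s.bt, da, oc, inc)) {
              inc.found = true; inc.F2 = F2; inc.bt = s.bt; inc.da = da;
              inc.oc = oc; inc.struct_idx = si + 1; inc.deltas = del;
            }
          }
        } else {
          for (long k = klo; k <= khi; ++k) {
            const long da = lo + k * step;
            double F2 = 0.0;
            bool ok = true;
            for (int i = 0; i < n; ++i) {
              const long r = a[i] * da + d[i] - y[i];
              // row feasibility is guaranteed by [klo, khi]; keep the check
              // to mirror the definitional loop exactly
              if (r > clip || r < -clip) { ok = false; break; }
              F2 += (double)r * (double)r;
              if (prune && inc.found && F2 > inc.F2) { ok = false; break; }
            }
            n_eval += 1.0;
            if (ok && better(F2, s.bt, da, oc, inc)) {
              inc.found = true; inc.F2 = F2; inc.bt = s.bt; inc.da = da;
              inc.oc = oc; inc.struct_idx = si + 1; inc.deltas = del;
            }
          }
        }
      }

      // advance the increment odometer (last dimension fastest)
      more = false;
      for (int j = nd - 1; j >= 0; --j) {
        if (gi[j] + 1 < s.grids[j].size()) { gi[j]++; more = true; break; }
        gi[j] = 0;
      }
    }
  }

  if (!inc.found)
    return List::create(_["found"] = false, _["n_eval"] = n_eval);
  return List::create(
      _["found"] = true, _["F2"] = inc.F2, _["bt"] = inc.bt,
      _["delta_a"] = (double)inc.da, _["struct_idx"] = inc.struct_idx,
      _["oc"] = IntegerVector(inc.oc.begin(), inc.oc.end()),
      _["deltas"] = IntegerVector(inc.deltas.begin(), inc.deltas.end()),
      _["n_eval"] = n_eval);
}
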