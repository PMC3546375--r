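// Batch evaluation of (ESS, |bias|, MSE) criteria for two-stage design
// estimation classes, plus the simplex weight-grid argmin. These are the
// hot loops of the admissible search; the R implementations of the same
// quantities are the reference path and the two are tested against each
// other.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

// per-class workspace: all quantities for one (n1, l1, u1, n2)
struct TwoStage {
  int n1, l1, u1, n2, m;
  std::vector<double> lf;  // log factorials 0..n2
  // reusable work buffers: root-finding evaluates K and E_q[MLE] tens of
  // thousands of times per class, so per-call allocation would dominate
  mutable std::vector<double> wf1, wsf1, wf2, wsf2, wtp;

  TwoStage(int n1_, int l1_, int u1_, int n2_)
      : n1(n1_), l1(l1_), u1(u1_), n2(n2_), m(n2_ - n1_), lf(n2_ + 1) {
    lf[0] = 0.0;
    for (int i = 1; i <= n2; ++i) lf[i] = lf[i - 1] + std::log((double)i);
  }

  double lchoose_(int n, int k) const {
    if (k < 0 || k > n) return NEG_INF;
    return lf[n] - lf[k] - lf[n - k];
  }

  // binomial pmf vector 0..n (n is n1 or m), anchored at the mode and
  // filled by the ratio recurrence: one exp, no underflow (mode term is
  // the maximum)
  void pmf(int n, double p, std::vector<double>& out) const {
    out.assign(n + 1, 0.0);
    if (p <= 0.0) { out[0] = 1.0; return; }
    if (p >= 1.0) { out[n] = 1.0; return; }
    int mode = (int)std::floor((n + 1) * p);
    if (mode > n) mode = n;
    out[mode] = std::exp(lchoose_(n, mode) + mode * std::log(p) +
                         (n - mode) * std::log1p(-p));
    const double odds = p / (1.0 - p);
    for (int x = mode; x < n; ++x)
      out[x + 1] = out[x] * odds * (n - x) / (x + 1);
    for (int x = mode; x > 0; --x)
      out[x - 1] = out[x] / odds * x / (n - x + 1);
  }

  // safeguarded regula falsi (Illinois) for a monotone-bracketed root of
  // f on [lo, hi] with f(lo) <= 0 <= f(hi)
  template <class F>
  static double illinois(F f, double lo, double hi, double flo, double fhi,
                         double tol) {
    if (flo == 0.0) return lo;
    if (fhi == 0.0) return hi;
    int side = 0;
    for (int it = 0; it < 200 && hi - lo > tol; ++it) {
      double c = (lo * fhi - hi * flo) / (fhi - flo);
      if (!(c > lo && c < hi)) c = 0.5 * (lo + hi);
      const double fc = f(c);
      if (fc == 0.0) return c;
      if (fc < 0.0) {
        lo = c; flo = fc;
        if (side == -1) fhi *= 0.5;  // same side twice: unstick the other end
        side = -1;
      } else {
        hi = c; fhi = fc;
        if (side == 1) flo *= 0.5;
        side = 1;
      }
    }
    return 0.5 * (lo + hi);
  }

  // suffix sums: sf[s] = P(X >= s) for s = 0..n+1, from a pmf vector
  static void suffix(const std::vector<double>& f, std::vector<double>& sf) {
    const int n = (int)f.size() - 1;
    sf.assign(n + 2, 0.0);
    for (int s = n; s >= 0; --s) sf[s] = sf[s + 1] + f[s];
  }

  static double sf_at(const std::vector<double>& sf, int s) {
    const int n = (int)sf.size() - 2;
    if (s <= 0) return 1.0;
    if (s > n) return 0.0;
    return sf[s];
  }

  int cont_lo() const { return l1 + 1; }
  int cont_hi() const { return u1 - 1; }          // stage-1 continuation S1
  int tcont_hi() const { return m + u1 - 1; }     // continuation region of T

  // K(t, p) = P(T >= t | p); t may be n2 + 1 (identically 0)
  double K(int t, double p) const {
    if (t <= 0) return 1.0;
    if (t > n2) return 0.0;
    pmf(n1, p, wf1);
    if (t <= l1) { suffix(wf1, wsf1); return sf_at(wsf1, t); }
    if (t >= m + u1) { suffix(wf1, wsf1); return sf_at(wsf1, t - m); }
    pmf(m, p, wf2);
    suffix(wf2, wsf2);
    double v = 0.0;
    for (int x = u1; x <= n1; ++x) v += wf1[x];
    for (int x = cont_lo(); x <= cont_hi(); ++x)
      v += wf1[x] * sf_at(wsf2, t - x);
    return v;
  }

  // P(T = t | p) for t = 0..n2
  void tpmf(double p, std::vector<double>& out) const {
    pmf(n1, p, wf1);
    pmf(m, p, wf2);
    out.assign(n2 + 1, 0.0);
    for (int t = 0; t <= l1; ++t) out[t] = wf1[t];
    for (int t = m + u1; t <= n2; ++t) out[t] = wf1[t - m];
    for (int t = cont_lo(); t <= tcont_hi(); ++t) {
      const int lb = std::max(cont_lo(), t - m), ub = std::min(t, cont_hi());
      double s = 0.0;
      for (int x = lb; x <= ub; ++x) s += wf1[x] * wf2[t - x];
      out[t] = s;
    }
  }

  double cont_prob(double p) const {
    pmf(n1, p, wf1);
    double s = 0.0;
    for (int x = cont_lo(); x <= cont_hi(); ++x) s += wf1[x];
    return s;
  }

  double ess(double p) const { return n1 + m * cont_prob(p); }

  // ---- estimator value vectors over t = 0..n2 ----

  void mle_values(std::vector<double>& v) const {
    v.assign(n2 + 1, 0.0);
    for (int t = 0; t <= n2; ++t) {
      if (t <= l1) v[t] = (double)t / n1;
      else if (t >= m + u1) v[t] = (double)(t - m) / n1;
      else v[t] = (double)t / n2;
    }
  }

  double lse_window(const std::vector<double>& terms) const {
    double mx = NEG_INF;
    for (double t : terms) if (t > mx) mx = t;
    if (mx == NEG_INF) return NEG_INF;
    double s = 0.0;
    for (double t : terms) if (t > NEG_INF) s += std::exp(t - mx);
    return mx + std::log(s);
  }

  // ratio of binomial-coefficient window sums in log space
  double hyper_ratio(int t, bool umvcue) const {
    const int lb = std::max(cont_lo(), t - m), ub = std::min(t, cont_hi());
    std::vector<double> num, den;
    for (int x = lb; x <= ub; ++x) {
      den.push_back(lchoose_(n1, x) + lchoose_(m, t - x));
      if (umvcue)
        num.push_back(lchoose_(n1, x) + lchoose_(m - 1, t - x - 1));
      else
        num.push_back(lchoose_(n1 - 1, x - 1) + lchoose_(m, t - x));
    }
    return std::exp(lse_window(num) - lse_window(den));
  }

  void umvue_values(std::vector<double>& v) const {
    mle_values(v);
    for (int t = cont_lo(); t <= tcont_hi(); ++t) v[t] = hyper_ratio(t, false);
  }

  void c_umvcue_values(std::vector<double>& v) const {
    mle_values(v);
    for (int t = cont_lo(); t <= tcont_hi(); ++t) v[t] = hyper_ratio(t, true);
  }

  // UMVCUE proper: defined on the continuation region only; stop-region
  // slots are filled with NaN and must never be touched unconditionally
  void umvcue_values(std::vector<double>& v) const {
    v.assign(n2 + 1, std::numeric_limits<double>::quiet_NaN());
    for (int t = cont_lo(); t <= tcont_hi(); ++t) v[t] = hyper_ratio(t, true);
  }

  // E_q[MLE] via the tower property over the stage-1 count
  double expected_mle(double q) const {
    pmf(n1, q, wf1);
    double e = 0.0;
    for (int x = 0; x <= n1; ++x) {
      if (x >= cont_lo() && x <= cont_hi())
        e += wf1[x] * (x + m * q) / n2;
      else
        e += wf1[x] * (double)x / n1;
    }
    return e;
  }

  void bc_mle_values(std::vector<double>& v) const {
    // E_q[MLE] is scanned on a coarse grid for sign changes (multiplicity
    // guard), each bracket refined by safeguarded regula falsi; among
    // multiple roots the one closest to the observed MLE is kept
    const int G = 129;
    std::vector<double> qs(G), Eg(G);
    for (int i = 0; i < G; ++i) {
      qs[i] = (double)i / (G - 1);
      Eg[i] = expected_mle(qs[i]);
    }
    std::vector<double> mv;
    mle_values(mv);
    v.assign(n2 + 1, 0.0);
    for (int t = 0; t <= n2; ++t) {
      const double target = mv[t];
      auto f = [&](double q) { return expected_mle(q) - target; };
      double best = NA_REAL, bestdist = HUGE_VAL;
      bool found = false;
      for (int i = 0; i + 1 < G; ++i) {
        const double g0 = Eg[i] - target, g1 = Eg[i + 1] - target;
        if (g0 == 0.0) { best = qs[i]; found = true; break; }
        if (g0 * g1 < 0.0) {
          const double r = (g0 < 0.0)
            ? illinois(f, qs[i], qs[i + 1], g0, g1, 1e-10)
            : illinois([&](double q) { return -f(q); }, qs[i], qs[i + 1],
                       -g0, -g1, 1e-10);
          const double dist = std::fabs(r - target);
          if (!found || dist < bestdist) { best = r; bestdist = dist; }
          found = true;
        }
      }
      if (!found) {
        const double g0 = Eg[0] - target, g1 = Eg[G - 1] - target;
        best = (std::fabs(g0) < std::fabs(g1)) ? 0.0 : 1.0;
      }
      v[t] = best;
    }
  }

  void mue_values(std::vector<double>& v) const {
    // half-roots r[t] : K(t, r) = 0.5 are increasing in t (K decreases in
    // t and increases in p), so each root starts from the previous one
    std::vector<double> r(n2 + 2);
    r[0] = 0.0;
    r[n2 + 1] = 1.0;
    double lo = 0.0, flo = -0.5;  // K(t, 0) = 0 for t >= 1
    for (int t = 1; t <= n2; ++t) {
      auto f = [&](double p) { return K(t, p) - 0.5; };
      double flo_t = (lo == 0.0) ? -0.5 : f(lo);
      if (flo_t > 0.0) { flo_t = -0.5; lo = 0.0; }  // numeric safety
      r[t] = illinois(f, lo, 1.0, flo_t, 0.5, 1e-10);
      lo = r[t];
      (void)flo;
    }
    v.assign(n2 + 1, 0.0);
    for (int t = 0; t <= n2; ++t) v[t] = 0.5 * (r[t] + r[t + 1]);
  }

  void est_values(int code, std::vector<double>& v) const {
    switch (code) {
      case 0: mle_values(v); break;
      case 1: bc_mle_values(v); break;
      case 2: umvue_values(v); break;
      case 3: umvcue_values(v); break;
      case 4: c_umvcue_values(v); break;
      case 5: mue_values(v); break;
      default: stop("unknown estimator code");
    }
  }

  // bias (signed) and mse of a value vector at p
  void moments(const std::vector<double>& v, double p, bool conditional,
               double& bias, double& mse) const {
    std::vector<double>& w = wtp;
    tpmf(p, w);
    double eb = 0.0, em = 0.0, norm = 1.0;
    int lo = 0, hi = n2;
    if (conditional) {
      lo = cont_lo();
      hi = tcont_hi();
      norm = cont_prob(p);
    }
    for (int t = lo; t <= hi; ++t) {
      eb += v[t] * w[t];
      em += (v[t] - p) * (v[t] - p) * w[t];
    }
    bias = eb / norm - p;
    mse = em / norm;
  }
};

}  // namespace

// classes: K x 4 integer matrix (n1, l1, u1, n2); est_codes: estimator ids
// 0=mle 1=bc_mle 2=umvue 3=umvcue 4=c_umvcue 5=mue; ess_eval/perf_eval:
// length-1 (point) or length-2 (uniform interval); glx/glw: Gauss-Legendre
// reference nodes/weights on [0,1] with weights summing to 1.
// Returns K x (1 + 2E): ess, then (abs_bias, mse) per estimator.
// [[Rcpp::export]]
NumericMatrix criteria_classes_cpp(IntegerMatrix classes,
                                   IntegerVector est_codes,
                                   NumericVector ess_eval,
                                   NumericVector perf_eval,
                                   bool conditional,
                                   NumericVector glx, NumericVector glw) {
  const int K = classes.nrow(), E = est_codes.size(), Q = glx.size();
  NumericMatrix out(K, 1 + 2 * E);
  const bool ess_unif = ess_eval.size() == 2;
  const bool perf_unif = perf_eval.size() == 2;

  for (int k = 0; k < K; ++k) {
    TwoStage d(classes(k, 0), classes(k, 1), classes(k, 2), classes(k, 3));
    // ESS criterion
    if (ess_unif) {
      const double a = ess_eval[0], b = ess_eval[1];
      double s = 0.0;
      for (int i = 0; i < Q; ++i) s += glw[i] * d.ess(a + (b - a) * glx[i]);
      out(k, 0) = s;
    } else {
      out(k, 0) = d.ess(ess_eval[0]);
    }
    for (int e = 0; e < E; ++e) {
      std::vector<double> v;
      d.est_values(est_codes[e], v);
      double ab, ms;
      if (!perf_unif) {
        double b_, m_;
        d.moments(v, perf_eval[0], conditional, b_, m_);
        ab = std::fabs(b_);
        ms = m_;
      } else {
        const double a = perf_eval[0], b = perf_eval[1];
        // average MSE over U(a, b)
        ms = 0.0;
        for (int i = 0; i < Q; ++i) {
          double b_, m_;
          d.moments(v, a + (b - a) * glx[i], conditional, b_, m_);
          ms += glw[i] * m_;
        }
        // average |bias|: locate sign changes on a scan grid, then
        // integrate each signed piece with the reference rule
        const int S = 401;
        std::vector<double> gp(S), gb(S);
        for (int i = 0; i < S; ++i) {
          gp[i] = a + (b - a) * i / (S - 1);
          double b_, m_;
          d.moments(v, gp[i], conditional, b_, m_);
          gb[i] = b_;
        }
        double mx = 0.0;
        for (int i = 0; i < S; ++i) mx = std::max(mx, std::fabs(gb[i]));
        if (mx < 1e-13) {
          ab = 0.0;  // uniformly unbiased to rounding
        } else {
          std::vector<double> cuts;
          cuts.push_back(a);
          for (int i = 0; i + 1 < S; ++i) {
            if (gb[i] * gb[i + 1] < 0.0) {
              double lo = gp[i], hi = gp[i + 1];
              const double s0 = gb[i];
              for (int it = 0; it < 45; ++it) {
                const double mid = 0.5 * (lo + hi);
                double b_, m_;
                d.moments(v, mid, conditional, b_, m_);
                if (b_ * s0 <= 0.0) hi = mid;
                else lo = mid;
              }
              cuts.push_back(0.5 * (lo + hi));
            }
          }
          cuts.push_back(b);
          double total = 0.0;
          for (size_t c = 0; c + 1 < cuts.size(); ++c) {
            const double ca = cuts[c], cb = cuts[c + 1];
            double piece = 0.0;
            for (int i = 0; i < Q; ++i) {
              double b_, m_;
              d.moments(v, ca + (cb - ca) * glx[i], conditional, b_, m_);
              piece += glw[i] * b_ * (cb - ca);
            }
            total += std::fabs(piece);
          }
          ab = total / (b - a);
        }
      }
      out(k, 1 + 2 * e) = ab;
      out(k, 2 + 2 * e) = ms;
    }
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// For each weight row (w_bias, w_mse, w_ess), the indices (1-based) of the
// criteria rows minimising w . (abs_bias*, mse*, ess*). Score ties within
// tol are broken lexicographically on (mse*, ess*, abs_bias*): at boundary
// weights a zero component makes whole criteria irrelevant to the score
// (every unbiased pairing scores 0 at (1,0,0)), and the tie-break keeps
// the selection meaningful there. Rows tied on the full key (identical
// criteria, e.g. designs differing only in u2) are all returned.
// M: K x 3 rescaled criteria; W: G x 3 weights.
// [[Rcpp::export]]
List weight_argmin_cpp(NumericMatrix M, NumericMatrix W, double tol) {
  const int K = M.nrow(), G = W.nrow();
  List out(G);
  std::vector<double> s(K);
  const double* c1 = &M(0, 0);  // abs_bias*
  const double* c2 = &M(0, 1);  // mse*
  const double* c3 = &M(0, 2);  // ess*
  std::vector<int> cand, keep;
  for (int g = 0; g < G; ++g) {
    const double w1 = W(g, 0), w2 = W(g, 1), w3 = W(g, 2);
    double mn = HUGE_VAL;
    for (int k = 0; k < K; ++k) {
      s[k] = w1 * c1[k] + w2 * c2[k] + w3 * c3[k];
      if (s[k] < mn) mn = s[k];
    }
    cand.clear();
    for (int k = 0; k < K; ++k)
      if (s[k] <= mn + tol) cand.push_back(k);
    const double* keys[3] = {c2, c3, c1};
    for (int j = 0; j < 3 && cand.size() > 1; ++j) {
      double km = HUGE_VAL;
      for (int k : cand) km = std::min(km, keys[j][k]);
      keep.clear();
      for (int k : cand)
        if (keys[j][k] <= km + tol) keep.push_back(k);
      cand.swap(keep);
    }
    IntegerVector idx(cand.size());
    for (size_t i = 0; i < cand.size(); ++i) idx[i] = cand[i] + 1;
    out[g] = idx;
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
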