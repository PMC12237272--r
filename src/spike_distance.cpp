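#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Rate-independent SPIKE-distance, piecewise-exact.
//
// Each train is augmented with auxiliary spikes at the window edges (the
// standard edge correction), so preceding/following spikes and the current
// interspike interval are defined everywhere in the window. Between spikes
// of one train its contribution
//   S_n(t) = (dtP * xF + dtF * xP) / xISI
// is linear in t (dtP, dtF, xISI constant; xP, xF linear), and the
// rate-independent profile
//   S'(t) = (S1(t) + S2(t)) / (2 * meanISI(t))
// is linear between consecutive spikes of either train, so the time
// integral is exact by the trapezoid rule over the union breakpoints.

static std::vector<double> augment(const NumericVector& t, double t0,
                                   double t1) {
  std::vector<double> a;
  a.reserve(t.size() + 2);
  a.push_back(t0);
  for (double v : t)
    if (v > t0 && v < t1) a.push_back(v);
  a.push_back(t1);
  std::sort(a.begin(), a.end());
  return a;
}

// nearest-spike distance from each element of a to any element of b
static std::vector<double> nearest_dist(const std::vector<double>& a,
                                        const std::vector<double>& b) {
  std::vector<double> d(a.size());
  size_t j = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    while (j + 1 < b.size() && b[j + 1] <= a[i]) ++j;
    double best = std::abs(a[i] - b[j]);
    if (j + 1 < b.size()) best = std::min(best, std::abs(b[j + 1] - a[i]));
    d[i] = best;
  }
  return d;
}

struct TrainCtx {
  const std::vector<double>* sp;
  const std::vector<double>* dn; // nearest distance per aug spike
  size_t idx;                    // current interval [sp[idx], sp[idx+1]]

  void seek(double t) {
    while (idx + 2 < sp->size() && (*sp)[idx + 1] <= t) ++idx;
  }
  double isi() const { return (*sp)[idx + 1] - (*sp)[idx]; }
  // S_n evaluated at time t inside the current interval
  double S(double t) const {
    double tP = (*sp)[idx], tF = (*sp)[idx + 1];
    double dtP = (*dn)[idx], dtF = (*dn)[idx + 1];
    double xP = t - tP, xF = tF - t;
    double x = tF - tP;
    if (x <= 0.0) return 0.0;
    return (dtP * xF + dtF * xP) / x;
  }
};

static double pair_D(const NumericVector& t1, const NumericVector& t2,
                     double w0, double w1) {
  std::vector<double> a = augment(t1, w0, w1);
  std::vector<double> b = augment(t2, w0, w1);
  std::vector<double> da = nearest_dist(a, b);
  std::vector<double> db = nearest_dist(b, a);

  std::vector<double> brk;
  brk.reserve(a.size() + b.size());
  std::merge(a.begin(), a.end(), b.begin(), b.end(), std::back_inserter(brk));
  brk.erase(std::unique(brk.begin(), brk.end()), brk.end());

  TrainCtx c1{&a, &da, 0}, c2{&b, &db, 0};
  double integral = 0.0;
  for (size_t s = 0; s + 1 < brk.size(); ++s) {
    double u = brk[s], v = brk[s + 1];
    if (v <= u) continue;
    double mid = 0.5 * (u + v);
    c1.seek(mid);
    c2.seek(mid);
    double meanISI = 0.5 * (c1.isi() + c2.isi());
    if (meanISI <= 0.0) continue;
    double su = (c1.S(u) + c2.S(u)) / (2.0 * meanISI);
    double sv = (c1.S(v) + c2.S(v)) / (2.0 * meanISI);
    integral += 0.5 * (su + sv) * (v - u);
  }
  return integral / (w1 - w0);
}

// [[Rcpp::export]]
double cpp_pair_spike_distance(NumericVector t1, NumericVector t2,
                               double w0, double w1) {
  if (w1 <= w0) stop("empty window");
  return pair_D(t1, t2, w0, w1);
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_spike_distance(List trains, double w0, double w1) {
  if (w1 <= w0) stop("empty window");
  int n = trains.size();
  NumericMatrix D(n, n);
  std::vector<NumericVector> tv(n);
  for (int i = 0; i < n; ++i) tv[i] = as<NumericVector>(trains[i]);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = pair_D(tv[i], tv[j], w0, w1);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}

// [[Rcpp::export]]
double cpp_multitrain_spike_distance(List trains, double w0, double w1) {
  if (w1 <= w0) stop("empty window");
  int n = trains.size();
  if (n < 2) stop("need at least 2 trains");
  std::vector<NumericVector> tv(n);
  for (int i = 0; i < n; ++i) tv[i] = as<NumericVector>(trains[i]);
  double acc = 0.0;
  long npair = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      acc += pair_D(tv[i], tv[j], w0, w1);
      ++npair;
    }
  return acc / (double)npair;
}
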