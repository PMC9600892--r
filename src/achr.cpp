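// Artificial-centering hit-and-run over a full-dimensional polytope
// { z : G z <= h }. Directions are drawn from a warmup point set relative to
// a running center (updated with every visited state), chords are computed
// by ratio tests on the inequality rows, and every `thinning`-th state is
// retained. Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix achr_sample_cpp(const NumericMatrix& G, const NumericVector& h,
                              const NumericMatrix& warmup,
                              int n_samples, int thinning, double tol) {
  const int m = G.nrow(), d = G.ncol(), w = warmup.nrow();
  if (w < 1) stop("empty warmup set");

  std::vector<double> center(d, 0.0);
  for (int i = 0; i < w; ++i)
    for (int j = 0; j < d; ++j) center[j] += warmup(i, j);
  for (int j = 0; j < d; ++j) center[j] /= w;

  std::vector<double> x(center), Gx(m, 0.0), dir(d), Gd(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += G(i, j) * x[j];
    Gx[i] = s;
  }

  NumericMatrix out(n_samples, d);
  RNGScope scope;
  long long visited = w;
  int collected = 0, step = 0, stuck = 0;
  long long moves = 0;

  while (collected < n_samples) {
    int pick = (int)std::floor(unif_rand() * w);
    if (pick >= w) pick = w - 1;
    double norm = 0.0;
    for (int j = 0; j < d; ++j) {
      dir[j] = warmup(pick, j) - center[j];
      norm += dir[j] * dir[j];
    }
    norm = std::sqrt(norm);
    if (norm < tol) {
      if (++stuck > 10000)
        stop("hit-and-run chain stuck: polytope width below tolerance in all "
             "sampled directions; reduce dimensions or loosen tolerance");
      continue;
    }
    for (int j = 0; j < d; ++j) dir[j] /= norm;

    double tmin = -1e30, tmax = 1e30;
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) s += G(i, j) * dir[j];
      Gd[i] = s;
      double slack = h[i] - Gx[i];
      if (slack < 0.0) slack = 0.0;  // clamp tiny round-off excursions
      if (s > tol) {
        double t = slack / s;
        if (t < tmax) tmax = t;
      } else if (s < -tol) {
        double t = slack / s;
        if (t > tmin) tmin = t;
      }
    }
    if (!(tmax - tmin > tol)) {
      if (++stuck > 10000)
        stop("hit-and-run chain stuck: polytope width below tolerance in all "
             "sampled directions; reduce dimensions or loosen tolerance");
      continue;
    }
    stuck = 0;

    double t = tmin + (tmax - tmin) * unif_rand();
    for (int j = 0; j < d; ++j) x[j] += t * dir[j];
    for (int i = 0; i < m; ++i) Gx[i] += t * Gd[i];
    if (++moves % 8192 == 0) {  // refresh against incremental drift
      for (int i = 0; i < m; ++i) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) s += G(i, j) * x[j];
        Gx[i] = s;
      }
    }
    ++visited;
    for (int j = 0; j < d; ++j)
      center[j] += (x[j] - center[j]) / (double)visited;

    if (++step == thinning) {
      step = 0;
      for (int j = 0; j < d; ++j) out(collected, j) = x[j];
      ++collected;
    }
  }
  return out;
}
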