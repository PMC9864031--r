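#include <Rcpp.h>
using namespace Rcpp;

// Artificially-centered hit-and-run chain.
//
// The walk lives in an affine slice {S v = b} of the flux space (the
// caller removes fixed coordinates and rescales): stored points (warmup
// and accepted samples) lie in it, directions are differences of stored
// points and the running center, and the iterate is re-projected onto the
// slice (v <- v0 + N N'(v - v0), N orthonormal) at every record,
// so mass balance cannot drift along the chain. Only the box bounds enter
// the per-step chord computation, which keeps a step at O(n). A step cap
// and a small ratio-test tolerance keep quasi-degenerate chords from
// pushing coordinates outside the box.
//
// [[Rcpp::export(name = ".achr_chain")]]
NumericMatrix achr_chain(NumericMatrix nullbasis, NumericMatrix warmup,
                         NumericVector v0, NumericVector lb,
                         NumericVector ub, int n_samples, int thinning) {
  const int n = nullbasis.nrow();     // reactions
  const int k = nullbasis.ncol();     // null-space dimension
  const int nw = warmup.ncol();
  NumericMatrix samples(n, n_samples);

  std::vector< std::vector<double> > pts;
  pts.reserve(nw + n_samples);
  std::vector<double> center(n, 0.0), v(n), dir(n), y(k);
  for (int j = 0; j < nw; ++j) {
    std::vector<double> p(n);
    for (int i = 0; i < n; ++i) p[i] = warmup(i, j);
    pts.push_back(p);
    for (int i = 0; i < n; ++i) center[i] += p[i] / nw;
  }
  v = center;
  double npts = nw;

  const double tol = 1e-13, t_cap = 1e6;
  const int project_every = 25;
  int since_proj = 0;

  auto project = [&]() {            // v <- v0 + N N' (v - v0)
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int r = 0; r < n; ++r) s += nullbasis(r, i) * (v[r] - v0[r]);
      y[i] = s;
    }
    for (int r = 0; r < n; ++r) {
      double s = 0.0;
      for (int i = 0; i < k; ++i) s += nullbasis(r, i) * y[i];
      v[r] = v0[r] + s;
    }
    since_proj = 0;
  };
  project();

  for (int s = 0; s < n_samples; ++s) {
    for (int step = 0; step < thinning; ++step) {
      int idx = (int)std::floor(R::runif(0.0, 1.0) * pts.size());
      if (idx >= (int)pts.size()) idx = pts.size() - 1;
      double norm = 0.0;
      for (int i = 0; i < n; ++i) {
        dir[i] = pts[idx][i] - center[i];
        norm += dir[i] * dir[i];
      }
      norm = std::sqrt(norm);
      if (norm < 1e-10) continue;
      double tmin = -t_cap, tmax = t_cap;
      for (int r = 0; r < n; ++r) {
        double d = dir[r] / norm;
        if (std::fabs(d) < tol) continue;
        double t1 = (lb[r] - v[r]) / d;
        double t2 = (ub[r] - v[r]) / d;
        if (d > 0) {
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
        } else {
          if (t2 > tmin) tmin = t2;
          if (t1 < tmax) tmax = t1;
        }
      }
      if (tmax < tmin) continue;
      double t = R::runif(tmin, tmax) / norm;
      for (int i = 0; i < n; ++i) v[i] += t * dir[i];
      if (++since_proj >= project_every) project();
    }
    project();
    std::vector<double> p(n);
    for (int r = 0; r < n; ++r) {
      double sv = v[r];
      if (sv < lb[r]) sv = lb[r];
      if (sv > ub[r]) sv = ub[r];
      samples(r, s) = sv;
      p[r] = sv;
      center[r] = (center[r] * npts + sv) / (npts + 1.0);
    }
    pts.push_back(p);
    npts += 1.0;
  }
  return samples;
}
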