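#include <Rcpp.h>
using namespace Rcpp;

// Weighted pair-distance histogram: bin b accumulates sum over unordered
// pairs (i<j) of 2*w_i*w_j with floor(d_ij/bin_width) == b. This is the
// O(N^2) kernel behind both the histogram-accelerated Debye sum and the
// model pair-distance distribution.
// [[Rcpp::export(name = ".pair_hist_weighted")]]
List pair_hist_weighted(NumericMatrix xyz, NumericVector w, double bin_width) {
  const int n = xyz.nrow();
  if (w.size() != n) stop("weight length mismatch");
  if (bin_width <= 0) stop("bin_width must be positive");
  // first pass: max distance determines histogram size
  double dmax2 = 0.0;
  const double *x = &xyz(0, 0), *y = &xyz(0, 1), *z = &xyz(0, 2);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > dmax2) dmax2 = d2;
    }
  }
  double dmax = std::sqrt(dmax2);
  int nbins = (int)(dmax / bin_width) + 1;
  if (n < 2) nbins = 1;
  NumericVector hist(nbins), rbar(nbins), rvar(nbins);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(d / bin_width);
      if (b >= nbins) b = nbins - 1;
      double ww = 2.0 * w[i] * w[j];
      hist[b] += ww;
      rbar[b] += ww * d;
      rvar[b] += ww * d * d;
    }
  }
  // per-bin weighted mean and variance of the pair distance (fall back to
  // the bin center when a bin's net weight cancels): evaluating the kernel
  // at the mean removes the first-order binning error, and the variance
  // feeds a second-order curvature correction
  for (int b = 0; b < nbins; ++b) {
    if (hist[b] != 0.0) {
      rbar[b] /= hist[b];
      rvar[b] = rvar[b] / hist[b] - rbar[b] * rbar[b];
      if (rvar[b] < 0) rvar[b] = 0;
    } else {
      rbar[b] = (b + 0.5) * bin_width;
      rvar[b] = 0.0;
    }
  }
  return List::create(_["hist"] = hist, _["rbar"] = rbar, _["rvar"] = rvar,
                      _["dmax"] = dmax, _["bin_width"] = bin_width);
}

// Largest clearance (min over atoms of |c - atom| - vdW) for a set of probe
// centers; used by the pore profiler's multi-start search.
// [[Rcpp::export(name = ".min_clearance")]]
NumericVector min_clearance(NumericMatrix centers, NumericMatrix atoms,
                            NumericVector vdw) {
  const int nc = centers.nrow(), na = atoms.nrow();
  NumericVector out(nc);
  for (int k = 0; k < nc; ++k) {
    double best = R_PosInf;
    for (int i = 0; i < na; ++i) {
      double dx = centers(k, 0) - atoms(i, 0);
      double dy = centers(k, 1) - atoms(i, 1);
      double dz = centers(k, 2) - atoms(i, 2);
      double c = std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[i];
      if (c < best) best = c;
    }
    out[k] = best;
  }
  return out;
}
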