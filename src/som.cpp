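#include <Rcpp.h>
using namespace Rcpp;

// Online self-organizing map training.
//
// X:      cells x d data matrix
// codes:  nodes x d initial codebook (modified copy returned)
// xdim,ydim: grid geometry (nodes laid out row-major on a rectangular grid)
// order:  0-based presentation order, length n_epochs * n_cells
// alpha0 -> alpha1: learning rate, linear decay over all presentations
// radius0 -> radius1: Gaussian neighborhood radius (grid units), linear decay
//
// Returns the trained codebook, per-cell best-matching units (1-based) and
// the mean quantization error after each epoch.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix X, NumericMatrix codes, int xdim, int ydim,
                   IntegerVector order, int n_epochs,
                   double alpha0, double alpha1,
                   double radius0, double radius1) {
  const int n = X.nrow(), d = X.ncol(), nnodes = xdim * ydim;
  NumericMatrix cb(clone(codes));
  std::vector<double> gx(nnodes), gy(nnodes);
  for (int j = 0; j < nnodes; ++j) {
    gx[j] = j % xdim;
    gy[j] = j / xdim;
  }
  const R_xlen_t total = (R_xlen_t)order.size();
  NumericVector qe(n_epochs);
  IntegerVector bmu(n);

  for (R_xlen_t t = 0; t < total; ++t) {
    const int i = order[t];
    const double frac = (total > 1) ? (double)t / (double)(total - 1) : 0.0;
    const double alpha = alpha0 + (alpha1 - alpha0) * frac;
    const double radius = radius0 + (radius1 - radius0) * frac;
    // Gaussian kernel scaled so the neighborhood effectively ends at
    // `radius` grid units (three standard deviations)
    const double sigma = radius / 3.0;
    const double denom = 2.0 * sigma * sigma;

    // best-matching unit
    int best = 0;
    double bestd = R_PosInf;
    for (int j = 0; j < nnodes; ++j) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        const double diff = X(i, m) - cb(j, m);
        s += diff * diff;
      }
      if (s < bestd) { bestd = s; best = j; }
    }
    // Gaussian neighborhood update
    const double bx = gx[best], by = gy[best];
    for (int j = 0; j < nnodes; ++j) {
      const double dx = gx[j] - bx, dy = gy[j] - by;
      const double g2 = dx * dx + dy * dy;
      const double h = alpha * std::exp(-g2 / denom);
      if (h < 1e-12) continue;
      for (int m = 0; m < d; ++m)
        cb(j, m) += h * (X(i, m) - cb(j, m));
    }

    // end of an epoch: record mean quantization error
    if ((t + 1) % n == 0) {
      const int epoch = (int)((t + 1) / n) - 1;
      double tot = 0.0;
      for (int ii = 0; ii < n; ++ii) {
        int b2 = 0;
        double d2 = R_PosInf;
        for (int j = 0; j < nnodes; ++j) {
          double s = 0.0;
          for (int m = 0; m < d; ++m) {
            const double diff = X(ii, m) - cb(j, m);
            s += diff * diff;
          }
          if (s < d2) { d2 = s; b2 = j; }
        }
        tot += std::sqrt(d2);
        if (epoch == n_epochs - 1) bmu[ii] = b2 + 1;
      }
      qe[epoch] = tot / n;
    }
  }
  return List::create(_["codebook"] = cb, _["bmu"] = bmu, _["qe"] = qe);
}

// Best-matching unit lookup for new data (1-based node indices).
// [[Rcpp::export]]
IntegerVector som_map_cpp(NumericMatrix X, NumericMatrix codes) {
  const int n = X.nrow(), d = X.ncol(), nnodes = codes.nrow();
  IntegerVector bmu(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bestd = R_PosInf;
    for (int j = 0; j < nnodes; ++j) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        const double diff = X(i, m) - codes(j, m);
        s += diff * diff;
      }
      if (s < bestd) { bestd = s; best = j; }
    }
    bmu[i] = best + 1;
  }
  return bmu;
}
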