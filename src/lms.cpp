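#include <Rcpp.h>
using namespace Rcpp;

static inline double logistic(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Sequential Widrow-Hoff (least-mean-squares) training of a single-layer
// unit on a fixed feature matrix with targets in {0,1}.  With
// `logistic_update = true` (the default used by the package) the prediction
// error is taken on the logistic-activated output, so the trained output is
// a calibrated probability; with `false` the update is the literal LMS rule
// on the pre-activation.  `order` holds one column of 1-based sample
// indices per epoch, so the per-epoch presentation order is controlled by
// R's RNG.  The returned per-epoch loss is the mean squared error of the
// (activated) output.
// [[Rcpp::export]]
List lms_train(const NumericMatrix& F, const NumericVector& y,
               double eta, const IntegerMatrix& order, bool logistic_update) {
  const int n = F.nrow(), m = F.ncol(), epochs = order.ncol();
  if (order.nrow() != n) stop("order must have one row per sample");
  // transpose once so each sample's features are contiguous
  std::vector<double> Ft(static_cast<size_t>(n) * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) Ft[static_cast<size_t>(i) * m + j] = F(i, j);
  std::vector<double> w(m, 0.0);
  double b = 0.0;
  NumericVector loss(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int t = 0; t < n; ++t) {
      const int i = order(t, ep) - 1;
      const double* f = &Ft[static_cast<size_t>(i) * m];
      double z = b;
      for (int j = 0; j < m; ++j) z += w[j] * f[j];
      const double pred = logistic_update ? logistic(z) : z;
      const double e = y[i] - pred;
      const double step = eta * e;
      for (int j = 0; j < m; ++j) w[j] += step * f[j];
      b += step;
    }
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* f = &Ft[static_cast<size_t>(i) * m];
      double z = b;
      for (int j = 0; j < m; ++j) z += w[j] * f[j];
      const double pred = logistic_update ? logistic(z) : z;
      const double e = y[i] - pred;
      sse += e * e;
    }
    loss[ep] = sse / n;
  }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["bias"] = b, _["loss"] = loss);
}
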