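#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous threshold dynamics. States are {0,1}; a node switches to 1
// only on strictly positive feedforward input (ties -> 0). The running
// field h = W x is maintained incrementally so a full pass is O(n + n*flips)
// after the O(n^2) initialisation.

static void init_field(const NumericMatrix& W, const IntegerVector& x,
                       std::vector<double>& h) {
  int n = W.nrow();
  std::fill(h.begin(), h.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    if (x[j] == 1) {
      for (int i = 0; i < n; ++i) h[i] += W(i, j);
    }
  }
}

// One asynchronous pass through the nodes in `order` (0-based), updating the
// state in place. Returns the number of bits changed.
static int one_pass(const NumericMatrix& W, const NumericVector& theta,
                    IntegerVector& x, const IntegerVector& order,
                    std::vector<double>& h) {
  int n = W.nrow();
  int changed = 0;
  for (int k = 0; k < n; ++k) {
    int i = order[k];
    int newv = (h[i] - theta[i] > 0.0) ? 1 : 0;
    if (newv != x[i]) {
      double delta = newv - x[i];
      x[i] = newv;
      for (int j = 0; j < n; ++j) h[j] += delta * W(j, i);
      ++changed;
    }
  }
  return changed;
}

// [[Rcpp::export]]
IntegerVector cpp_async_pass(NumericMatrix W, NumericVector theta,
                             IntegerVector x, IntegerVector order) {
  int n = W.nrow();
  IntegerVector out = clone(x);
  std::vector<double> h(n);
  init_field(W, out, h);
  one_pass(W, theta, out, order, h);
  return out;
}

// [[Rcpp::export]]
List cpp_converge(NumericMatrix W, NumericVector theta, IntegerVector x,
                  IntegerVector order, int max_passes) {
  int n = W.nrow();
  IntegerVector out = clone(x);
  std::vector<double> h(n);
  init_field(W, out, h);
  int passes = 0;
  while (passes < max_passes) {
    ++passes;
    if (one_pass(W, theta, out, order, h) == 0)
      return List::create(_["state"] = out, _["passes"] = passes,
                          _["converged"] = true);
  }
  return List::create(_["state"] = out, _["passes"] = passes,
                      _["converged"] = false);
}

// Converge every row of X; rows are independent patterns.
// [[Rcpp::export]]
List cpp_converge_batch(NumericMatrix W, NumericVector theta, IntegerMatrix X,
                        IntegerVector order, int max_passes) {
  int m = X.nrow(), n = X.ncol();
  IntegerMatrix out(m, n);
  LogicalVector ok(m);
  IntegerVector np(m);
  std::vector<double> h(n);
  IntegerVector x(n);
  for (int r = 0; r < m; ++r) {
    for (int i = 0; i < n; ++i) x[i] = X(r, i);
    init_field(W, x, h);
    int passes = 0;
    bool conv = false;
    while (passes < max_passes) {
      ++passes;
      if (one_pass(W, theta, x, order, h) == 0) { conv = true; break; }
    }
    for (int i = 0; i < n; ++i) out(r, i) = x[i];
    ok[r] = conv;
    np[r] = passes;
  }
  return List::create(_["states"] = out, _["passes"] = np,
                      _["converged"] = ok);
}
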