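#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fully connected n -> h -> 1 network. Weight layout:
//   W1: (n + 1) x h, last row is the hidden biases (constant-1 input)
//   W2: length h + 1, last entry is the output bias
// Hidden units are logistic; the output unit is logistic unless
// linear_out is set. Training is per-pattern gradient descent on
// E = 0.5 * (output - target)^2 with a momentum term. The hot loops work
// on raw column-major pointers: column j of W1 is W1 + j * (n + 1).

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static double forward_raw(const double *W1, const double *W2,
                          const double *x, int n, int h, bool linear_out,
                          double *hidden) {
  for (int j = 0; j < h; ++j) {
    const double *col = W1 + (size_t)j * (n + 1);
    double z = col[n];
    for (int i = 0; i < n; ++i) z += col[i] * x[i];
    hidden[j] = sigmoid(z);
  }
  double z = W2[h];
  for (int j = 0; j < h; ++j) z += W2[j] * hidden[j];
  return linear_out ? z : sigmoid(z);
}

// One backprop step, in place; v_old is a caller-provided length-h scratch
// buffer. Returns the pre-update output.
static double step_raw(double *W1, double *W2, double *P1, double *P2,
                       const double *x, double target,
                       double eta, double mu, bool linear_out,
                       int n, int h, double *hidden, double *v_old) {
  const double out = forward_raw(W1, W2, x, n, h, linear_out, hidden);
  const double delta_o = (out - target) * (linear_out ? 1.0 : out * (1.0 - out));
  // output layer (pre-update W2 feeds the hidden deltas)
  for (int j = 0; j < h; ++j) {
    v_old[j] = W2[j];
    const double dw = -eta * delta_o * hidden[j] + mu * P2[j];
    W2[j] += dw;
    P2[j] = dw;
  }
  {
    const double dw = -eta * delta_o + mu * P2[h];
    W2[h] += dw;
    P2[h] = dw;
  }
  // hidden layer
  for (int j = 0; j < h; ++j) {
    const double delta_h = delta_o * v_old[j] * hidden[j] * (1.0 - hidden[j]);
    const double f = -eta * delta_h;
    double *col = W1 + (size_t)j * (n + 1);
    double *pcol = P1 + (size_t)j * (n + 1);
    for (int i = 0; i < n; ++i) {
      const double dw = f * x[i] + mu * pcol[i];
      col[i] += dw;
      pcol[i] = dw;
    }
    const double dw = f + mu * pcol[n];
    col[n] += dw;
    pcol[n] = dw;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bpe_forward(NumericMatrix W1, NumericVector W2, NumericVector x,
                     bool linear_out) {
  const int n = W1.nrow() - 1, h = W1.ncol();
  if (x.size() != n)
    stop("input length (%d) does not match network input size (%d)",
         (int)x.size(), n);
  NumericVector hidden(h);
  const double out = forward_raw(REAL(W1), REAL(W2), REAL(x), n, h,
                                 linear_out, REAL(hidden));
  return List::create(_["output"] = out, _["hidden"] = hidden);
}

// [[Rcpp::export]]
NumericVector cpp_bpe_predict(NumericMatrix W1, NumericVector W2,
                              NumericMatrix X, bool linear_out) {
  const int n = W1.nrow() - 1, h = W1.ncol();
  if (X.ncol() != n)
    stop("input matrix has %d columns, network expects %d", X.ncol(), n);
  const int m = X.nrow();
  NumericVector out(m);
  std::vector<double> hidden(h), x(n);
  for (int s = 0; s < m; ++s) {
    for (int i = 0; i < n; ++i) x[i] = X(s, i);
    out[s] = forward_raw(REAL(W1), REAL(W2), x.data(), n, h, linear_out,
                         hidden.data());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bpe_step(NumericMatrix W1, NumericVector W2,
                  NumericMatrix P1, NumericVector P2,
                  NumericVector x, double target,
                  double eta, double mu, bool linear_out) {
  const int n = W1.nrow() - 1, h = W1.ncol();
  if (x.size() != n) stop("input length does not match network input size");
  NumericMatrix W1c = clone(W1), P1c = clone(P1);
  NumericVector W2c = clone(W2), P2c = clone(P2);
  std::vector<double> hidden(h), v_old(h);
  const double out = step_raw(REAL(W1c), REAL(W2c), REAL(P1c), REAL(P2c),
                              REAL(x), target, eta, mu, linear_out,
                              n, h, hidden.data(), v_old.data());
  return List::create(_["W1"] = W1c, _["W2"] = W2c, _["P1"] = P1c,
                      _["P2"] = P2c, _["output"] = out);
}

// [[Rcpp::export]]
List cpp_train_bpe(NumericMatrix X, NumericVector targets,
                   NumericMatrix W1, NumericVector W2,
                   int epochs, double eta, double mu, bool linear_out) {
  const int m = X.nrow(), n = X.ncol(), h = W1.ncol();
  if (W1.nrow() != n + 1) stop("W1 must have n + 1 rows");
  if (W2.size() != h + 1) stop("W2 must have h + 1 entries");
  NumericMatrix W1c = clone(W1);
  NumericVector W2c = clone(W2);
  NumericMatrix P1(n + 1, h);
  NumericVector P2(h + 1);
  NumericVector trace(epochs);
  double *w1 = REAL(W1c), *w2 = REAL(W2c), *p1 = REAL(P1), *p2 = REAL(P2);
  std::vector<int> ord(m);
  for (int s = 0; s < m; ++s) ord[s] = s;
  std::vector<double> hidden(h), v_old(h), x(n);
  // row-major copy of X so each pattern is a contiguous slice
  std::vector<double> Xr((size_t)m * n);
  for (int s = 0; s < m; ++s)
    for (int i = 0; i < n; ++i) Xr[(size_t)s * n + i] = X(s, i);

  for (int t = 0; t < epochs; ++t) {
    for (int s = m - 1; s > 0; --s) {
      int jdx = (int)(unif_rand() * (s + 1));
      if (jdx > s) jdx = s;
      std::swap(ord[s], ord[jdx]);
    }
    double sse = 0.0;
    for (int si = 0; si < m; ++si) {
      const int s = ord[si];
      const double out = step_raw(w1, w2, p1, p2, &Xr[(size_t)s * n],
                                  targets[s], eta, mu, linear_out,
                                  n, h, hidden.data(), v_old.data());
      if (!R_finite(out))
        stop("training diverged (non-finite output at epoch %d); "
             "try a lower learning rate", t + 1);
      const double e = out - targets[s];
      sse += e * e;
    }
    trace[t] = std::sqrt(sse / m);
  }
  return List::create(_["W1"] = W1c, _["W2"] = W2c, _["P1"] = P1,
                      _["P2"] = P2, _["trace"] = trace);
}
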