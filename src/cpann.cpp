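#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Neurons are indexed row-major: j = (row - 1) * map_cols + col (1-based on
// the R side, 0-based here). All distances are Euclidean in scaled
// descriptor space; the neighbourhood metric is Chebyshev on the grid.

static inline int cheb(int r1, int c1, int r2, int c2,
                       int rows, int cols, bool toroidal) {
  int dr = std::abs(r1 - r2), dc = std::abs(c1 - c2);
  if (toroidal) {
    dr = std::min(dr, rows - dr);
    dc = std::min(dc, cols - dc);
  }
  return std::max(dr, dc);
}

static inline int winner_index(const NumericMatrix &W, const double *x,
                               double *dist_out) {
  const int k = W.nrow(), n = W.ncol();
  double best = R_PosInf;
  int bi = 0;
  for (int j = 0; j < k; ++j) {
    double d = 0.0;
    for (int i = 0; i < n; ++i) {
      const double t = W(j, i) - x[i];
      d += t * t;
    }
    if (d < best) {  // strict '<' keeps the smallest row-major index on ties
      best = d;
      bi = j;
    }
  }
  *dist_out = std::sqrt(best);
  return bi;
}

// [[Rcpp::export]]
List cpp_find_winner(NumericMatrix W, NumericVector x) {
  if (x.size() != W.ncol())
    stop("descriptor vector length (%d) does not match weight columns (%d)",
         (int)x.size(), W.ncol());
  std::vector<double> xv(x.begin(), x.end());
  double d;
  int j = winner_index(W, xv.data(), &d);
  return List::create(_["index"] = j + 1, _["distance"] = d);
}

// Batch winner search: one row of X per object.
// [[Rcpp::export]]
List cpp_map_objects(NumericMatrix W, NumericMatrix X) {
  if (X.ncol() != W.ncol())
    stop("descriptor matrix has %d columns, weights have %d",
         X.ncol(), W.ncol());
  const int m = X.nrow(), n = X.ncol();
  IntegerVector win(m);
  NumericVector dist(m);
  std::vector<double> x(n);
  for (int s = 0; s < m; ++s) {
    for (int i = 0; i < n; ++i) x[i] = X(s, i);
    double d;
    win[s] = winner_index(W, x.data(), &d) + 1;
    dist[s] = d;
  }
  return List::create(_["winner"] = win, _["distance"] = dist);
}

// Online counter-propagation training. The Kohonen layer is pulled toward
// the descriptor vector and the Grossberg layer toward the target with the
// same eta * neighbourhood correction; passing supervised = false gives a
// plain self-organizing map (used for splitting and descriptor grouping).
// Uses R's RNG stream for the per-epoch shuffles, so set.seed() on the R
// side makes training fully reproducible.
// [[Rcpp::export]]
List cpp_train_cpann(NumericMatrix X, NumericVector targets,
                     int map_rows, int map_cols, int epochs,
                     double eta_max, double eta_min,
                     bool toroidal, bool rectangular,
                     NumericMatrix kohonen_init, NumericVector grossberg_init,
                     bool supervised, double radius_override = -1.0) {
  const int m = X.nrow(), n = X.ncol();
  const int k = map_rows * map_cols;
  if (m < 1 || n < 1) stop("training data must have at least one row and one column");
  if (kohonen_init.nrow() != k || kohonen_init.ncol() != n)
    stop("kohonen_init has the wrong shape");

  NumericMatrix koh = clone(kohonen_init);
  NumericVector gro = clone(grossberg_init);
  std::vector<int> ord(m);
  for (int s = 0; s < m; ++s) ord[s] = s;
  std::vector<double> x(n);
  const double rmax = std::max(map_rows, map_cols) / 2.0;

  for (int t = 0; t < epochs; ++t) {
    const double frac = epochs > 1 ? (double)t / (epochs - 1) : 0.0;
    const double eta = eta_max + (eta_min - eta_max) * frac;
    const double radius = radius_override >= 0.0 ? radius_override
                                                 : rmax * (1.0 - frac);
    // Fisher-Yates shuffle from R's RNG
    for (int s = m - 1; s > 0; --s) {
      int jdx = (int)(unif_rand() * (s + 1));
      if (jdx > s) jdx = s;
      std::swap(ord[s], ord[jdx]);
    }
    for (int si = 0; si < m; ++si) {
      const int s = ord[si];
      for (int i = 0; i < n; ++i) x[i] = X(s, i);
      double dwin;
      const int w = winner_index(koh, x.data(), &dwin);
      const int wr = w / map_cols, wc = w % map_cols;
      for (int j = 0; j < k; ++j) {
        const int jr = j / map_cols, jc = j % map_cols;
        const int d = cheb(wr, wc, jr, jc, map_rows, map_cols, toroidal);
        double a;
        if (rectangular) {
          a = (d <= radius) ? 1.0 : 0.0;
        } else {
          // linear decay inside the radius, zero beyond it
          a = (d <= radius) ? 1.0 - d / (radius + 1.0) : 0.0;
        }
        if (a <= 0.0) continue;
        const double f = eta * a;
        for (int i = 0; i < n; ++i) koh(j, i) += f * (x[i] - koh(j, i));
        if (supervised) gro[j] += f * (targets[s] - gro[j]);
      }
    }
  }

  // Map the training objects onto the final weights.
  IntegerVector winner(m);
  NumericVector distance(m);
  IntegerVector occupancy(k);
  for (int s = 0; s < m; ++s) {
    for (int i = 0; i < n; ++i) x[i] = X(s, i);
    double d;
    const int w = winner_index(koh, x.data(), &d);
    winner[s] = w + 1;
    distance[s] = d;
    occupancy[w] += 1;
  }
  return List::create(_["kohonen"] = koh, _["grossberg"] = gro,
                      _["winner"] = winner, _["distance"] = distance,
                      _["occupancy"] = occupancy);
}
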