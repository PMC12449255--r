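#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// numerically stable log(sigmoid(x))
static inline double log_sigmoid(double x) {
  if (x >= 0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// uniform integer in [0, n) from R's RNG
static inline int r_unif_int(int n) {
  int k;
  do {
    k = (int)(unif_rand() * n);
  } while (k >= n); // guard the unif_rand() == 1.0 edge
  return k;
}

// draw one negative uniformly over [0, vocab) excluding a and b
static inline int draw_negative(int vocab, int a, int b) {
  int c;
  do {
    c = r_unif_int(vocab);
  } while (c == a || c == b);
  return c;
}

// [[Rcpp::export]]
double objective_cpp(const NumericMatrix& F, const IntegerVector& u,
                     const IntegerVector& v, const NumericVector& w,
                     const IntegerMatrix& neg) {
  const int d = F.ncol();
  const int R = u.size();
  const int M = neg.ncol();
  double total = 0.0;
  for (int r = 0; r < R; ++r) {
    const int ur = u[r], vr = v[r];
    double dot = 0.0;
    for (int k = 0; k < d; ++k) dot += F(vr, k) * F(ur, k);
    double contrib = log_sigmoid(dot);
    for (int m = 0; m < M; ++m) {
      const int c = neg(r, m);
      double dc = 0.0;
      for (int k = 0; k < d; ++k) dc += F(c, k) * F(ur, k);
      contrib += log_sigmoid(-dc);
    }
    total += w[r] * contrib;
  }
  return total;
}

// Skip-gram with negative sampling, minibatch SGD (gradient ascent on the
// weighted objective). Uses R's RNG throughout so results are reproducible
// under set.seed(). Node indices are 0-based.
// [[Rcpp::export]]
List sgd_train_cpp(NumericMatrix F, const IntegerVector& u,
                   const IntegerVector& v, const NumericVector& w,
                   int vocab, int M, int batch_size, double lr,
                   int max_epochs, bool early_stop, double tol,
                   int patience, const IntegerMatrix& eval_neg) {
  RNGScope scope;
  const int d = F.ncol();
  const int R = u.size();
  std::vector<int> order(R);
  for (int i = 0; i < R; ++i) order[i] = i;

  std::vector<double> log_obj;
  log_obj.reserve(max_epochs);
  double best = R_NegInf;
  int stall = 0;
  int epochs_run = 0;

  // per-batch sparse gradient accumulator
  std::unordered_map<int, std::vector<double> > grad;
  grad.reserve(batch_size * (M + 2));

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = R - 1; i > 0; --i) {
      int j = r_unif_int(i + 1);
      std::swap(order[i], order[j]);
    }
    int in_batch = 0;
    grad.clear();
    for (int t = 0; t < R; ++t) {
      const int r = order[t];
      const int ur = u[r], vr = v[r];
      const double wr = w[r];

      std::vector<double>& gu = grad[ur];
      if (gu.empty()) gu.assign(d, 0.0);
      std::vector<double>& gv = grad[vr];
      if (gv.empty()) gv.assign(d, 0.0);

      double dot = 0.0;
      for (int k = 0; k < d; ++k) dot += F(vr, k) * F(ur, k);
      const double s = 1.0 - sigmoid(dot); // d log_sigmoid / d dot
      for (int k = 0; k < d; ++k) {
        gu[k] += wr * s * F(vr, k);
        gv[k] += wr * s * F(ur, k);
      }
      for (int m = 0; m < M; ++m) {
        const int c = draw_negative(vocab, ur, vr);
        std::vector<double>& gc = grad[c];
        if (gc.empty()) gc.assign(d, 0.0);
        double dc = 0.0;
        for (int k = 0; k < d; ++k) dc += F(c, k) * F(ur, k);
        const double sc = sigmoid(dc);
        for (int k = 0; k < d; ++k) {
          gu[k] -= wr * sc * F(c, k);
          gc[k] -= wr * sc * F(ur, k);
        }
      }
      ++in_batch;
      if (in_batch == batch_size || t == R - 1) {
        // summed (not averaged) batch gradient: one pass moves the
        // embeddings as far as per-pair updates would, word2vec-style
        const double step = lr;
        for (std::unordered_map<int, std::vector<double> >::iterator it =
               grad.begin(); it != grad.end(); ++it) {
          const int row = it->first;
          const std::vector<double>& g = it->second;
          for (int k = 0; k < d; ++k) F(row, k) += step * g[k];
        }
        grad.clear();
        in_batch = 0;
      }
    }
    const double obj = objective_cpp(F, u, v, w, eval_neg);
    if (!std::isfinite(obj))
      stop("embedding training diverged (non-finite objective) at epoch %d",
           epoch + 1);
    log_obj.push_back(obj);
    epochs_run = epoch + 1;
    if (early_stop) {
      if (obj > best + tol) {
        best = obj;
        stall = 0;
      } else {
        if (++stall >= patience) break;
      }
    } else if (obj > best) {
      best = obj;
    }
  }
  for (int i = 0; i < F.nrow(); ++i)
    for (int k = 0; k < d; ++k)
      if (!std::isfinite(F(i, k)))
        stop("embedding training diverged: non-finite embedding entries");
  return List::create(_["F"] = F, _["objective"] = wrap(log_obj),
                      _["epochs"] = epochs_run);
}
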