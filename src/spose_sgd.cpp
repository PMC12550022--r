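#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Triplet choice model: for a trial (i, j, k) the score of "item m is the odd
// one out" is the dot product of the OTHER two rows; the three scores go
// through a softmax. All computations subtract the max score before
// exponentiating so large dot products cannot overflow.

namespace {

inline double dot_row(const std::vector<double> &W, int K, int a, int b) {
  const double *ra = &W[(size_t)a * K];
  const double *rb = &W[(size_t)b * K];
  double s = 0.0;
  for (int d = 0; d < K; ++d) s += ra[d] * rb[d];
  return s;
}

// -log p(observed odd) for one trial; fills q with the softmax probabilities.
inline double trial_nll(const std::vector<double> &W, int K,
                        int i, int j, int k, int odd, double q[3]) {
  double s[3];
  s[0] = dot_row(W, K, j, k);
  s[1] = dot_row(W, K, i, k);
  s[2] = dot_row(W, K, i, j);
  double m = std::max(s[0], std::max(s[1], s[2]));
  double z = 0.0;
  for (int t = 0; t < 3; ++t) { q[t] = std::exp(s[t] - m); z += q[t]; }
  for (int t = 0; t < 3; ++t) q[t] /= z;
  return std::log(z) + m - s[odd];
}

inline double weight_sum(const std::vector<double> &W) {
  double s = 0.0;
  for (double w : W) s += w;
  return s;
}

double mean_nll(const std::vector<double> &W, int K,
                const IntegerMatrix &trips, const IntegerVector &odd) {
  int nt = trips.nrow();
  if (nt == 0) return NA_REAL;
  double q[3];
  double tot = 0.0;
  for (int t = 0; t < nt; ++t)
    tot += trial_nll(W, K, trips(t, 0), trips(t, 1), trips(t, 2), odd[t], q);
  return tot / nt;
}

}  // namespace

// Mean cross-entropy plus L1 penalty lambda * sum(W) / n_items.
// [[Rcpp::export(name = ".spose_loss_cpp")]]
double spose_loss_cpp(NumericMatrix W, IntegerMatrix trips, IntegerVector odd,
                      double lambda) {
  int n = W.nrow(), K = W.ncol();
  std::vector<double> Wv((size_t)n * K);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < K; ++d) Wv[(size_t)i * K + d] = W(i, d);
  return mean_nll(Wv, K, trips, odd) + lambda * weight_sum(Wv) / n;
}

// Projected Adam on the SPoSE objective. Trials are row indices (0-based)
// into W; odd is the within-triplet column (0, 1, 2) of the observed
// odd-one-out. Batches are contiguous slices of a per-epoch Fisher-Yates
// shuffle driven by a Mersenne Twister, so runs are reproducible given seed.
// [[Rcpp::export(name = ".spose_sgd_cpp")]]
List spose_sgd_cpp(NumericMatrix W0,
                   IntegerMatrix trips_tr, IntegerVector odd_tr,
                   IntegerMatrix trips_va, IntegerVector odd_va,
                   double lambda, double lr, int batch_size,
                   int max_epochs, int window, int seed) {
  const int n = W0.nrow(), K = W0.ncol();
  const int nt = trips_tr.nrow();
  const size_t nw = (size_t)n * K;

  std::vector<double> W(nw), mom(nw, 0.0), vel(nw, 0.0), grad(nw);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < K; ++d) W[(size_t)i * K + d] = W0(i, d);

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  const double pen_grad = lambda / n;
  long step = 0;

  std::mt19937 gen((unsigned)seed);
  std::vector<int> order(nt);
  for (int t = 0; t < nt; ++t) order[t] = t;

  std::vector<double> train_hist, val_hist;
  double best_val = R_PosInf;
  int best_epoch = 0, since_improve = 0, stopped_epoch = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates with the raw generator: standardized mt19937 output keeps
    // the permutation identical across standard-library implementations.
    for (int t = nt - 1; t > 0; --t) {
      int jj = (int)(gen() % (unsigned)(t + 1));
      std::swap(order[t], order[jj]);
    }

    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < nt; start += batch_size) {
      int end = std::min(start + batch_size, nt);
      int bn = end - start;

      std::fill(grad.begin(), grad.end(), pen_grad);
      double batch_nll = 0.0, q[3];
      for (int t = start; t < end; ++t) {
        int tr = order[t];
        int i = trips_tr(tr, 0), j = trips_tr(tr, 1), k = trips_tr(tr, 2);
        int o = odd_tr[tr];
        batch_nll += trial_nll(W, K, i, j, k, o, q);
        double c0 = (q[0] - (o == 0)) / bn;
        double c1 = (q[1] - (o == 1)) / bn;
        double c2 = (q[2] - (o == 2)) / bn;
        double *gi = &grad[(size_t)i * K], *gj = &grad[(size_t)j * K],
               *gk = &grad[(size_t)k * K];
        const double *wi = &W[(size_t)i * K], *wj = &W[(size_t)j * K],
                     *wk = &W[(size_t)k * K];
        for (int d = 0; d < K; ++d) {
          gi[d] += c1 * wk[d] + c2 * wj[d];
          gj[d] += c0 * wk[d] + c2 * wi[d];
          gk[d] += c0 * wj[d] + c1 * wi[d];
        }
      }
      epoch_loss += batch_nll / bn + lambda * weight_sum(W) / n;
      ++n_batches;

      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t w = 0; w < nw; ++w) {
        mom[w] = beta1 * mom[w] + (1.0 - beta1) * grad[w];
        vel[w] = beta2 * vel[w] + (1.0 - beta2) * grad[w] * grad[w];
        double upd = lr * (mom[w] / bc1) / (std::sqrt(vel[w] / bc2) + eps);
        W[w] -= upd;
        if (W[w] < 0.0) W[w] = 0.0;  // projection onto the non-negative orthant
      }
    }

    train_hist.push_back(epoch_loss / n_batches);
    double vl = mean_nll(W, K, trips_va, odd_va) + lambda * weight_sum(W) / n;
    val_hist.push_back(vl);
    stopped_epoch = epoch;

    if (vl < best_val - 1e-12) {
      best_val = vl;
      best_epoch = epoch;
      since_improve = 0;
    } else if (++since_improve >= window) {
      break;
    }
    if (epoch % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Wout(n, K);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < K; ++d) Wout(i, d) = W[(size_t)i * K + d];

  return List::create(_["weights"] = Wout,
                      _["train_loss"] = train_hist,
                      _["validation_loss"] = val_hist,
                      _["stopped_epoch"] = stopped_epoch,
                      _["best_epoch"] = best_epoch,
                      _["best_validation_loss"] = best_val);
}
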