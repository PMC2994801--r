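// Feed-forward network with one logistic hidden layer and two logistic
// output neurons, trained by online (per-example) gradient descent on
// squared error. The per-residue score is the normalized positive share
// out_pos / (out_pos + out_neg). Epoch selection keeps the weights of the
// epoch with the best test-set MCC at threshold 0.5.
//
// All randomness (weight init, per-epoch shuffling) comes from a local
// std::mt19937 so results are fully determined by the seed argument.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat logistic(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// scores for a weight set; X is n x d
static vec nn_scores_impl(const mat& X, const mat& W1, const vec& b1,
                          const mat& W2, const vec& b2) {
  mat H = logistic(X * W1.t() + repmat(b1.t(), X.n_rows, 1)); // n x h
  mat O = logistic(H * W2.t() + repmat(b2.t(), X.n_rows, 1)); // n x 2
  return O.col(0) / (O.col(0) + O.col(1));
}

static double mcc_at_half(const vec& scores, const ivec& y) {
  double tp = 0, fp = 0, tn = 0, fn = 0;
  for (uword i = 0; i < scores.n_elem; ++i) {
    bool call = scores[i] >= 0.5;
    if (call && y[i] == 1) tp++;
    else if (call && y[i] == 0) fp++;
    else if (!call && y[i] == 0) tn++;
    else fn++;
  }
  double den = (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn);
  if (den <= 0) return 0.0;  // undefined MCC ranks as 0 for epoch selection
  return (tp * tn - fp * fn) / std::sqrt(den);
}

// [[Rcpp::export(name = ".nn_init_cpp")]]
Rcpp::List nn_init_cpp(int d, int hidden, double init_range, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(-init_range, init_range);
  mat W1(hidden, d), W2(2, hidden);
  vec b1(hidden), b2(2);
  // fixed fill order: W1 row-major, b1, W2 row-major, b2
  for (int i = 0; i < hidden; ++i)
    for (int j = 0; j < d; ++j) W1(i, j) = unif(rng);
  for (int i = 0; i < hidden; ++i) b1[i] = unif(rng);
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < hidden; ++j) W2(i, j) = unif(rng);
  for (int i = 0; i < 2; ++i) b2[i] = unif(rng);
  return Rcpp::List::create(Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
                            Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2);
}

// [[Rcpp::export(name = ".nn_scores_cpp")]]
arma::vec nn_scores_cpp(const arma::mat& X, const arma::mat& W1,
                        const arma::vec& b1, const arma::mat& W2,
                        const arma::vec& b2) {
  return nn_scores_impl(X, W1, b1, W2, b2);
}

// Analytic gradient of the squared error 0.5*sum((o - t)^2) for one
// example (target one-hot over the two outputs). Used by training and by
// the finite-difference gradient check.
// [[Rcpp::export(name = ".nn_gradient_cpp")]]
Rcpp::List nn_gradient_cpp(const arma::vec& x, int y, const arma::mat& W1,
                           const arma::vec& b1, const arma::mat& W2,
                           const arma::vec& b2) {
  vec h = 1.0 / (1.0 + exp(-(W1 * x + b1)));
  vec o = 1.0 / (1.0 + exp(-(W2 * h + b2)));
  vec t(2);
  t[0] = (y == 1) ? 1.0 : 0.0;
  t[1] = 1.0 - t[0];
  vec delta_o = (o - t) % o % (1.0 - o);          // 2
  vec delta_h = (W2.t() * delta_o) % h % (1.0 - h); // h
  return Rcpp::List::create(
    Rcpp::Named("gW1") = mat(delta_h * x.t()),
    Rcpp::Named("gb1") = delta_h,
    Rcpp::Named("gW2") = mat(delta_o * h.t()),
    Rcpp::Named("gb2") = delta_o,
    Rcpp::Named("loss") = 0.5 * accu(square(o - t)));
}

// [[Rcpp::export(name = ".nn_train_cpp")]]
Rcpp::List nn_train_cpp(const arma::mat& X, const arma::ivec& y,
                        const arma::mat& Xtest, const arma::ivec& ytest,
                        int hidden, double lr, int max_epochs,
                        double momentum, double weight_decay,
                        double init_range, int seed) {
  const uword n = X.n_rows, d = X.n_cols;
  const uword H = static_cast<uword>(hidden);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(-init_range, init_range);
  // W1 kept transposed (d x H) so each hidden unit's weights are a
  // contiguous column; fill order matches the documented row-major
  // (unit, input) sequence of the init draw
  mat W1t(d, H), W2(2, H);
  vec b1(H), b2(2);
  for (uword i = 0; i < H; ++i)
    for (uword j = 0; j < d; ++j) W1t(j, i) = unif(rng);
  for (uword i = 0; i < H; ++i) b1[i] = unif(rng);
  for (uword i = 0; i < 2; ++i)
    for (uword j = 0; j < H; ++j) W2(i, j) = unif(rng);
  for (uword i = 0; i < 2; ++i) b2[i] = unif(rng);

  mat vW1t, vW2;
  vec vb1, vb2;
  const bool plain = (momentum == 0.0 && weight_decay == 0.0);
  if (!plain) {
    vW1t = zeros<mat>(d, H); vW2 = zeros<mat>(2, H);
    vb1 = zeros<vec>(H); vb2 = zeros<vec>(2);
  }

  const mat Xt = X.t();  // column per example, contiguous
  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  mat bW1t = W1t, bW2 = W2;
  vec bb1 = b1, bb2 = b2;
  double best_mcc = -datum::inf;
  double best_err = datum::inf;
  int best_epoch = 0;
  std::vector<double> train_err, test_mcc;
  vec h(H), delta_h(H);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double err = 0.0;
    for (uword k = 0; k < n; ++k) {
      const uword i = order[k];
      const double* x = Xt.colptr(i);
      for (uword j = 0; j < H; ++j) {
        const double* w = W1t.colptr(j);
        double a = b1[j];
        for (uword q = 0; q < d; ++q) a += w[q] * x[q];
        h[j] = 1.0 / (1.0 + std::exp(-a));
      }
      double o0 = b2[0], o1 = b2[1];
      for (uword j = 0; j < H; ++j) {
        o0 += W2(0, j) * h[j];
        o1 += W2(1, j) * h[j];
      }
      o0 = 1.0 / (1.0 + std::exp(-o0));
      o1 = 1.0 / (1.0 + std::exp(-o1));
      const double t0 = (y[i] == 1) ? 1.0 : 0.0;
      err += 0.5 * ((o0 - t0) * (o0 - t0) + (o1 - (1.0 - t0)) * (o1 - (1.0 - t0)));
      const double d0 = (o0 - t0) * o0 * (1.0 - o0);
      const double d1 = (o1 - (1.0 - t0)) * o1 * (1.0 - o1);
      for (uword j = 0; j < H; ++j) {
        delta_h[j] = (W2(0, j) * d0 + W2(1, j) * d1) * h[j] * (1.0 - h[j]);
      }
      if (plain) {
        for (uword j = 0; j < H; ++j) {
          W2(0, j) -= lr * d0 * h[j];
          W2(1, j) -= lr * d1 * h[j];
        }
        b2[0] -= lr * d0; b2[1] -= lr * d1;
        for (uword j = 0; j < H; ++j) {
          const double step = lr * delta_h[j];
          if (step == 0.0) continue;
          double* w = W1t.colptr(j);
          for (uword q = 0; q < d; ++q) w[q] -= step * x[q];
          b1[j] -= step;
        }
      } else {
        for (uword j = 0; j < H; ++j) {
          vW2(0, j) = momentum * vW2(0, j) -
            lr * (d0 * h[j] + weight_decay * W2(0, j));
          vW2(1, j) = momentum * vW2(1, j) -
            lr * (d1 * h[j] + weight_decay * W2(1, j));
          W2(0, j) += vW2(0, j);
          W2(1, j) += vW2(1, j);
        }
        vb2[0] = momentum * vb2[0] - lr * d0; b2[0] += vb2[0];
        vb2[1] = momentum * vb2[1] - lr * d1; b2[1] += vb2[1];
        for (uword j = 0; j < H; ++j) {
          double* w = W1t.colptr(j);
          double* v = vW1t.colptr(j);
          const double dh = delta_h[j];
          for (uword q = 0; q < d; ++q) {
            v[q] = momentum * v[q] - lr * (dh * x[q] + weight_decay * w[q]);
            w[q] += v[q];
          }
          vb1[j] = momentum * vb1[j] - lr * dh;
          b1[j] += vb1[j];
        }
      }
    }
    double m = mcc_at_half(nn_scores_impl(Xtest, W1t.t(), b1, W2, b2),
                           ytest);
    train_err.push_back(err / n);
    test_mcc.push_back(m);
    // best test MCC wins; equal MCC (e.g. a long all-negative plateau on
    // imbalanced data) falls back to the lower training error
    if (m > best_mcc || (m == best_mcc && err / n < best_err)) {
      best_mcc = m;
      best_err = err / n;
      best_epoch = epoch;
      bW1t = W1t; bb1 = b1; bW2 = W2; bb2 = b2;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("W1") = mat(bW1t.t()), Rcpp::Named("b1") = bb1,
    Rcpp::Named("W2") = bW2, Rcpp::Named("b2") = bb2,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("leaveout_mcc") = best_mcc,
    Rcpp::Named("train_error") = train_err,
    Rcpp::Named("test_mcc") = test_mcc);
}
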