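// Feed-forward network core: forward pass, backprop gradients and
// full-batch Adam training on mean-squared-error loss.  Kept in C++ so
// that leave-one-out cross-validation and the randomization battery
// (hundreds of retrainings of a 2 x 15-node net) stay fast; all
// randomness (weight initialization, fold seeds) lives on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// activation codes shared with R/nn.R:
// 0 linear, 1 relu, 2 leaky_relu, 3 softplus, 4 sigmoid, 5 tanh
static arma::mat act_apply(const arma::mat& z, int kind, double slope) {
  switch (kind) {
  case 0: return z;
  case 1: return arma::clamp(z, 0.0, arma::datum::inf);
  case 2: {
    arma::mat out = z;
    out.transform([slope](double v) { return v > 0.0 ? v : slope * v; });
    return out;
  }
  case 3: {
    // softplus, overflow-safe: log(1+e^z) = max(z,0) + log1p(e^{-|z|})
    arma::mat out = z;
    out.transform([](double v) {
      return (v > 0.0 ? v : 0.0) + std::log1p(std::exp(-std::abs(v)));
    });
    return out;
  }
  case 4: {
    arma::mat out = z;
    out.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
    return out;
  }
  case 5: return arma::tanh(z);
  default: stop("unknown activation code");
  }
}

static arma::mat act_deriv(const arma::mat& z, int kind, double slope) {
  switch (kind) {
  case 0: return arma::ones<arma::mat>(z.n_rows, z.n_cols);
  case 1: return arma::conv_to<arma::mat>::from(z > 0.0);
  case 2: {
    arma::mat out = z;
    out.transform([slope](double v) { return v > 0.0 ? 1.0 : slope; });
    return out;
  }
  case 3: {
    arma::mat out = z;
    out.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
    return out;
  }
  case 4: {
    arma::mat s = act_apply(z, 4, slope);
    return s % (1.0 - s);
  }
  case 5: {
    arma::mat t = arma::tanh(z);
    return 1.0 - t % t;
  }
  default: stop("unknown activation code");
  }
}

static std::vector<arma::mat> as_mat_list(const List& x) {
  std::vector<arma::mat> out;
  for (int i = 0; i < x.size(); ++i)
    out.push_back(as<arma::mat>(x[i]));
  return out;
}

static std::vector<arma::vec> as_vec_list(const List& x) {
  std::vector<arma::vec> out;
  for (int i = 0; i < x.size(); ++i)
    out.push_back(as<arma::vec>(x[i]));
  return out;
}

// forward pass; if keep != nullptr stores layer inputs A[0..L] and
// pre-activations Z[1..L] for backprop (A[l] is the input to layer l).
static arma::vec forward_impl(const arma::mat& X,
                              const std::vector<arma::mat>& W,
                              const std::vector<arma::vec>& b,
                              int kind, double slope,
                              std::vector<arma::mat>* A,
                              std::vector<arma::mat>* Z) {
  const size_t L = W.size();            // L-1 hidden layers + linear output
  arma::mat cur = X;                    // n x d
  if (A) A->push_back(cur);
  for (size_t l = 0; l < L; ++l) {
    arma::mat z = cur * W[l].t();       // n x width
    z.each_row() += b[l].t();
    if (Z) Z->push_back(z);
    cur = (l + 1 == L) ? z : act_apply(z, kind, slope);  // linear output
    if (A && l + 1 < L) A->push_back(cur);
  }
  return cur.col(0);
}

// backprop of d(MSE)/d(params); also returns loss. gW/gb are filled.
static double loss_grad_impl(const arma::mat& X, const arma::vec& y,
                             const std::vector<arma::mat>& W,
                             const std::vector<arma::vec>& b,
                             int kind, double slope, double l2,
                             std::vector<arma::mat>& gW,
                             std::vector<arma::vec>& gb) {
  const size_t L = W.size();
  const double n = (double)X.n_rows;
  std::vector<arma::mat> A, Z;
  arma::vec pred = forward_impl(X, W, b, kind, slope, &A, &Z);
  arma::vec resid = pred - y;
  double loss = arma::dot(resid, resid) / n;

  gW.assign(L, arma::mat());
  gb.assign(L, arma::vec());
  arma::mat delta = resid * (2.0 / n);  // n x 1, dLoss/dZ[last]
  for (size_t l = L; l-- > 0;) {
    gW[l] = delta.t() * A[l];           // width x fan_in
    gb[l] = arma::sum(delta, 0).t();
    if (l2 > 0.0) {
      gW[l] += 2.0 * l2 * W[l];
      loss += l2 * arma::accu(W[l] % W[l]);
    }
    if (l > 0)
      delta = (delta * W[l]) % act_deriv(Z[l - 1], kind, slope);
  }
  return loss;
}

// [[Rcpp::export]]
NumericVector nn_forward_cpp(const arma::mat& X, List W, List b,
                             int activation, double leaky_slope) {
  std::vector<arma::mat> Wm = as_mat_list(W);
  std::vector<arma::vec> bv = as_vec_list(b);
  arma::vec out = forward_impl(X, Wm, bv, activation, leaky_slope,
                               nullptr, nullptr);
  return wrap(out);
}

// [[Rcpp::export]]
List nn_loss_grad_cpp(const arma::mat& X, const arma::vec& y,
                      List W, List b, int activation, double leaky_slope,
                      double l2) {
  std::vector<arma::mat> Wm = as_mat_list(W);
  std::vector<arma::vec> bv = as_vec_list(b);
  std::vector<arma::mat> gW;
  std::vector<arma::vec> gb;
  double loss = loss_grad_impl(X, y, Wm, bv, activation, leaky_slope, l2,
                               gW, gb);
  List gWl(gW.size()), gbl(gb.size());
  for (size_t i = 0; i < gW.size(); ++i) {
    gWl[i] = wrap(gW[i]);
    gbl[i] = wrap(gb[i]);
  }
  return List::create(_["loss"] = loss, _["gW"] = gWl, _["gb"] = gbl);
}

// Full-batch Adam on MSE.  Stops at max_epochs or when the relative
// loss change drops below tol.
// [[Rcpp::export]]
List nn_train_cpp(const arma::mat& X, const arma::vec& y,
                  List W0, List b0, int activation, double leaky_slope,
                  double lr, int max_epochs, double tol, double l2) {
  std::vector<arma::mat> W = as_mat_list(W0);
  std::vector<arma::vec> b = as_vec_list(b0);
  const size_t L = W.size();
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  std::vector<arma::mat> mW(L), vW(L), gW;
  std::vector<arma::vec> mb(L), vb(L), gb;
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }

  std::vector<double> trace;
  trace.reserve(max_epochs);
  double prev = R_PosInf;
  int epoch = 0;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    double loss = loss_grad_impl(X, y, W, b, activation, leaky_slope, l2,
                                 gW, gb);
    if (!std::isfinite(loss))
      stop("non-finite training loss at epoch %d", epoch);
    trace.push_back(loss);
    if (std::isfinite(prev) &&
        std::abs(prev - loss) <= tol * std::max(prev, 1e-12)) break;
    prev = loss;
    double c1 = 1.0 - std::pow(beta1, (double)epoch);
    double c2 = 1.0 - std::pow(beta2, (double)epoch);
    for (size_t l = 0; l < L; ++l) {
      mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW[l];
      vW[l] = beta2 * vW[l] + (1.0 - beta2) * (gW[l] % gW[l]);
      W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
      mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb[l];
      vb[l] = beta2 * vb[l] + (1.0 - beta2) * (gb[l] % gb[l]);
      b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
    }
  }

  List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) {
    Wl[l] = wrap(W[l]);
    bl[l] = wrap(b[l]);
  }
  return List::create(_["W"] = Wl, _["b"] = bl,
                      _["loss_trace"] = wrap(trace),
                      _["epochs"] = std::min(epoch, max_epochs));
}
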