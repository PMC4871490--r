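// Training engines for the pooled machine-learning regressors:
//  - a 6-25-10-1 multilayer perceptron (logistic hidden layers, linear
//    output) trained full-batch by resilient backpropagation with weight
//    backtracking (Rprop+), stopping when max |dSSE/dw| < grad_stop;
//  - a randomized regression forest (bootstrap + mtry feature sampling,
//    SSE split criterion, mean-of-leaf prediction).
// All randomness goes through R's RNG so set.seed() controls both engines.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat logistic(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

struct NNShape {
  int p, h1, h2, nw;
  NNShape(int p_, int h1_, int h2_)
    : p(p_), h1(h1_), h2(h2_),
      nw(h1_ * p_ + h1_ + h2_ * h1_ + h2_ + h2_ + 1) {}
};

// forward pass + gradient of SSE wrt flattened weights
static double nn_sse_grad(const arma::vec& w, const NNShape& s,
                          const arma::mat& Xt, const arma::rowvec& y,
                          arma::vec& grad) {
  int o = 0;
  arma::mat W1(w.memptr() + o, s.h1, s.p); o += s.h1 * s.p;
  arma::vec b1(w.memptr() + o, s.h1); o += s.h1;
  arma::mat W2(w.memptr() + o, s.h2, s.h1); o += s.h2 * s.h1;
  arma::vec b2(w.memptr() + o, s.h2); o += s.h2;
  arma::vec w3(w.memptr() + o, s.h2); o += s.h2;
  double b3 = w(o);

  arma::mat A1 = logistic(W1 * Xt + arma::repmat(b1, 1, Xt.n_cols));
  arma::mat A2 = logistic(W2 * A1 + arma::repmat(b2, 1, Xt.n_cols));
  arma::rowvec pred = w3.t() * A2 + b3;
  arma::rowvec r = pred - y;
  double sse = arma::dot(r, r);

  arma::rowvec r2 = 2.0 * r;
  arma::vec gw3 = A2 * r2.t();
  double gb3 = arma::accu(r2);
  arma::mat d2 = (w3 * r2) % A2 % (1.0 - A2);
  arma::mat gW2 = d2 * A1.t();
  arma::vec gb2 = arma::sum(d2, 1);
  arma::mat d1 = (W2.t() * d2) % A1 % (1.0 - A1);
  arma::mat gW1 = d1 * Xt.t();
  arma::vec gb1 = arma::sum(d1, 1);

  o = 0;
  grad.subvec(o, o + s.h1 * s.p - 1) = arma::vectorise(gW1); o += s.h1 * s.p;
  grad.subvec(o, o + s.h1 - 1) = gb1; o += s.h1;
  grad.subvec(o, o + s.h2 * s.h1 - 1) = arma::vectorise(gW2); o += s.h2 * s.h1;
  grad.subvec(o, o + s.h2 - 1) = gb2; o += s.h2;
  grad.subvec(o, o + s.h2 - 1) = gw3; o += s.h2;
  grad(o) = gb3;
  return sse;
}

// Rprop+ (resilient backpropagation with weight backtracking)
static double nn_train_once(arma::vec& w, const NNShape& s,
                            const arma::mat& Xt, const arma::rowvec& y,
                            double grad_stop, int max_epochs,
                            bool& converged, int& epochs) {
  const double eta_plus = 1.2, eta_minus = 0.5;
  const double step_min = 1e-6, step_max = 50.0, step0 = 0.1;
  arma::vec step(s.nw, arma::fill::value(step0));
  arma::vec gprev(s.nw, arma::fill::zeros);
  arma::vec dwprev(s.nw, arma::fill::zeros);
  arma::vec g(s.nw);
  double sse = nn_sse_grad(w, s, Xt, y, g);
  double sse_prev = sse;
  converged = false;
  epochs = 0;
  for (int ep = 0; ep < max_epochs; ++ep) {
    epochs = ep + 1;
    if (arma::abs(g).max() < grad_stop) { converged = true; break; }
    for (int i = 0; i < s.nw; ++i) {
      double sgn = g(i) * gprev(i);
      if (sgn > 0) {
        step(i) = std::min(step(i) * eta_plus, step_max);
        double dw = (g(i) > 0 ? -step(i) : step(i));
        w(i) += dw; dwprev(i) = dw; gprev(i) = g(i);
      } else if (sgn < 0) {
        step(i) = std::max(step(i) * eta_minus, step_min);
        if (sse > sse_prev) w(i) -= dwprev(i);  // backtracking
        dwprev(i) = 0.0; gprev(i) = 0.0;
      } else {
        double dw = (g(i) > 0 ? -step(i) : (g(i) < 0 ? step(i) : 0.0));
        w(i) += dw; dwprev(i) = dw; gprev(i) = g(i);
      }
    }
    sse_prev = sse;
    sse = nn_sse_grad(w, s, Xt, y, g);
  }
  return sse;
}

// [[Rcpp::export]]
List cpp_train_nn(const arma::mat& X, const arma::vec& y,
                  int h1, int h2, int n_restarts,
                  double grad_stop, int max_epochs) {
  NNShape s(X.n_cols, h1, h2);
  arma::mat Xt = X.t();
  arma::rowvec yr = y.t();
  arma::vec best_w(s.nw);
  double best_sse = R_PosInf;
  bool best_conv = false;
  int best_epochs = 0;
  RNGScope scope;
  for (int r = 0; r < n_restarts; ++r) {
    arma::vec w(s.nw);
    for (int i = 0; i < s.nw; ++i) w(i) = R::rnorm(0.0, 0.5);
    bool conv; int ep;
    double sse = nn_train_once(w, s, Xt, yr, grad_stop, max_epochs, conv, ep);
    if (sse < best_sse) {
      best_sse = sse; best_w = w; best_conv = conv; best_epochs = ep;
    }
  }
  return List::create(_["weights"] = best_w, _["sse"] = best_sse,
                      _["converged"] = best_conv, _["epochs"] = best_epochs,
                      _["h1"] = h1, _["h2"] = h2, _["p"] = (int)X.n_cols);
}

// [[Rcpp::export]]
arma::vec cpp_predict_nn(const arma::vec& w, int p, int h1, int h2,
                         const arma::mat& X) {
  NNShape s(p, h1, h2);
  int o = 0;
  arma::mat W1(w.memptr() + o, h1, p); o += h1 * p;
  arma::vec b1(w.memptr() + o, h1); o += h1;
  arma::mat W2(w.memptr() + o, h2, h1); o += h2 * h1;
  arma::vec b2(w.memptr() + o, h2); o += h2;
  arma::vec w3(w.memptr() + o, h2); o += h2;
  double b3 = w(o);
  arma::mat Xt = X.t();
  arma::mat A1 = logistic(W1 * Xt + arma::repmat(b1, 1, Xt.n_cols));
  arma::mat A2 = logistic(W2 * A1 + arma::repmat(b2, 1, Xt.n_cols));
  return (w3.t() * A2 + b3).t();
}

// ---------------- random forest ----------------

struct RFNode { int feat; double thr; int left; int right; double value; };

struct TreeBuilder {
  const arma::mat& X;
  const arma::vec& y;
  int mtry, min_node;
  std::vector<RFNode> nodes;
  TreeBuilder(const arma::mat& X_, const arma::vec& y_, int mtry_, int mn)
    : X(X_), y(y_), mtry(mtry_), min_node(mn) {}

  int build(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    double sum = 0.0, sum2 = 0.0;
    for (int i = lo; i < hi; ++i) { sum += y(idx[i]); sum2 += y(idx[i]) * y(idx[i]); }
    double mean = sum / n;
    double sse_node = sum2 - sum * sum / n;
    RFNode node; node.feat = -1; node.thr = 0.0;
    node.left = -1; node.right = -1; node.value = mean;
    // nodes with fewer than min_node rows (or constant response) are leaves
    if (n < min_node || sse_node <= 1e-12) {
      nodes.push_back(node); return (int)nodes.size() - 1;
    }
    // sample mtry candidate features without replacement
    int p = X.n_cols;
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry; ++j) {
      int k = j + (int)std::floor(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }
    double best_gain = 0.0; int best_feat = -1; double best_thr = 0.0;
    std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
    for (int j = 0; j < mtry; ++j) {
      int f = feats[j];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += y(ord[i]);
        if (X(ord[i + 1], f) <= X(ord[i], f)) continue;  // tied values
        int nl = i + 1, nr = n - nl;
        double rsum = sum - lsum;
        double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain; best_feat = f;
          best_thr = (X(ord[i], f) + X(ord[i + 1], f)) / 2.0;
        }
      }
    }
    if (best_feat < 0) { nodes.push_back(node); return (int)nodes.size() - 1; }
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) { nodes.push_back(node); return (int)nodes.size() - 1; }
    node.feat = best_feat; node.thr = best_thr;
    nodes.push_back(node);
    int self = (int)nodes.size() - 1;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    nodes[self].left = l; nodes[self].right = r;
    return self;
  }
};

// [[Rcpp::export]]
List cpp_train_rf(const arma::mat& X, const arma::vec& y,
                  int n_trees, int mtry, int min_node) {
  RNGScope scope;
  int n = X.n_rows;
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)std::floor(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;  // bootstrap sample
    }
    TreeBuilder tb(X, y, mtry, min_node);
    tb.build(idx, 0, n);
    int m = (int)tb.nodes.size();
    NumericMatrix nm(m, 5);
    for (int i = 0; i < m; ++i) {
      nm(i, 0) = tb.nodes[i].feat; nm(i, 1) = tb.nodes[i].thr;
      nm(i, 2) = tb.nodes[i].left; nm(i, 3) = tb.nodes[i].right;
      nm(i, 4) = tb.nodes[i].value;
    }
    forest[t] = nm;
  }
  return forest;
}

// [[Rcpp::export]]
arma::vec cpp_predict_rf(const List& forest, const arma::mat& X) {
  int n = X.n_rows, T = forest.size();
  arma::vec out(n, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    NumericMatrix nm = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)nm(node, 0) >= 0) {
        int f = (int)nm(node, 0);
        node = (X(i, f) <= nm(node, 1)) ? (int)nm(node, 2) : (int)nm(node, 3);
      }
      out(i) += nm(node, 4);
    }
  }
  return out / T;
}
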