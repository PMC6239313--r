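// Numerical core of the data-driven background model: patch flattening,
// minibatch Adam training of the single-hidden-layer softplus autoencoder,
// and its convolutional application to whole images.  All randomness
// (weight init, patch sampling, epoch shuffles) is generated on the R side
// so results are reproducible from a single seed.
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double softplus1(double x) {
  // log(1 + e^x), stable for large |x|
  if (x > 0.0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

static inline void softplus_inplace(arma::mat &m) {
  for (arma::uword i = 0; i < m.n_elem; ++i) m[i] = softplus1(m[i]);
}

static inline void sigmoid_inplace(arma::mat &m) {
  for (arma::uword i = 0; i < m.n_elem; ++i) m[i] = 1.0 / (1.0 + std::exp(-m[i]));
}

// Flatten square patches centred at 0-based (cx, cy) into columns of an
// r x n matrix.  Component order within a column: pixels row-major within
// the patch, channels interleaved per pixel (R, G, B), i.e. index
// 3*(py*edge + px) + channel.
// [[Rcpp::export]]
arma::mat cpp_extract_patches(const arma::mat &R, const arma::mat &G,
                              const arma::mat &B, const arma::ivec &cx,
                              const arma::ivec &cy, const int edge) {
  const int n = cx.n_elem;
  const int h = (edge - 1) / 2;
  const int r = 3 * edge * edge;
  arma::mat out(r, n);
  for (int j = 0; j < n; ++j) {
    const int x0 = cx[j] - h, y0 = cy[j] - h;
    double *col = out.colptr(j);
    for (int py = 0; py < edge; ++py) {
      for (int px = 0; px < edge; ++px) {
        const int k = 3 * (py * edge + px);
        col[k]     = R(y0 + py, x0 + px);
        col[k + 1] = G(y0 + py, x0 + px);
        col[k + 2] = B(y0 + py, x0 + px);
      }
    }
  }
  return out;
}

struct AdamState {
  arma::mat m, v;
  AdamState(arma::uword nr, arma::uword nc)
      : m(nr, nc, arma::fill::zeros), v(nr, nc, arma::fill::zeros) {}
  void step(arma::mat &w, const arma::mat &g, double lr, double b1, double b2,
            double eps, int t) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * arma::square(g);
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

// Train the autoencoder on the r x n patch matrix X.  `order` holds, per
// epoch (column), a 0-based permutation of 0..n-1 drawn in R.  Minimises
// the minibatch mean of the summed squared reconstruction error.
// Returns trained weights plus the per-epoch mean training error.
// [[Rcpp::export]]
List cpp_train_aen(const arma::mat &X, arma::mat W1, arma::vec b1,
                   arma::mat W2, arma::vec b2, const int epochs,
                   const int batch, const double lr,
                   const arma::imat &order, const double beta1 = 0.9,
                   const double beta2 = 0.999, const double eps = 1e-8) {
  const int n = X.n_cols;
  AdamState aW1(W1.n_rows, W1.n_cols), aW2(W2.n_rows, W2.n_cols);
  AdamState ab1(b1.n_elem, 1), ab2(b2.n_elem, 1);
  arma::vec epoch_loss(epochs, arma::fill::zeros);
  int t = 0;
  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0.0;
    for (int start = 0; start < n; start += batch) {
      const int m = std::min(batch, n - start);
      arma::uvec idx(m);
      for (int j = 0; j < m; ++j) idx[j] = (arma::uword)order(start + j, e);
      arma::mat Xb = X.cols(idx);
      // forward
      arma::mat Z1 = W1 * Xb;
      Z1.each_col() += b1;
      arma::mat S1 = Z1;
      sigmoid_inplace(S1);          // softplus' = sigmoid
      softplus_inplace(Z1);         // Z1 now holds L
      arma::mat Z2 = W2 * Z1;
      Z2.each_col() += b2;
      arma::mat S2 = Z2;
      sigmoid_inplace(S2);
      softplus_inplace(Z2);         // Z2 now holds X'
      arma::mat D = Z2 - Xb;
      loss_sum += arma::accu(arma::square(D));
      if (!std::isfinite(loss_sum))
        stop("autoencoder training diverged (non-finite loss) at epoch %d", e + 1);
      // backward: loss = (1/m) * sum_j ||x_j - x'_j||^2
      arma::mat dZ2 = (2.0 / m) * (D % S2);
      arma::mat gW2 = dZ2 * Z1.t();
      arma::vec gb2 = arma::sum(dZ2, 1);
      arma::mat dZ1 = (W2.t() * dZ2) % S1;
      arma::mat gW1 = dZ1 * Xb.t();
      arma::vec gb1 = arma::sum(dZ1, 1);
      ++t;
      aW1.step(W1, gW1, lr, beta1, beta2, eps, t);
      aW2.step(W2, gW2, lr, beta1, beta2, eps, t);
      arma::mat b1m(b1.memptr(), b1.n_elem, 1, false, true);
      arma::mat b2m(b2.memptr(), b2.n_elem, 1, false, true);
      ab1.step(b1m, arma::mat(gb1), lr, beta1, beta2, eps, t);
      ab2.step(b2m, arma::mat(gb2), lr, beta1, beta2, eps, t);
    }
    epoch_loss[e] = loss_sum / n;
  }
  return List::create(_["W"] = W1, _["b"] = b1, _["W_dec"] = W2,
                      _["b_dec"] = b2, _["epoch_loss"] = epoch_loss);
}

// Apply a trained autoencoder convolutionally: every patch whose
// edge x edge support fits inside the image, stepping by `stride` in x and
// y, is encoded and decoded, and the summed squared reconstruction error is
// stored at its grid position.  Returns a gh x gw matrix (rows index y).
// Grid rows are processed in slices of `slice_rows` to bound memory; the
// result is independent of the slicing.
// [[Rcpp::export]]
arma::mat cpp_apply_aen(const arma::mat &R, const arma::mat &G,
                        const arma::mat &B, const arma::mat &W1,
                        const arma::vec &b1, const arma::mat &W2,
                        const arma::vec &b2, const int edge, const int stride,
                        const int slice_rows) {
  const int H = R.n_rows, W = R.n_cols;
  const int gw = (W - edge) / stride + 1;
  const int gh = (H - edge) / stride + 1;
  const int h = (edge - 1) / 2;
  arma::mat out(gh, gw);
  for (int gy0 = 0; gy0 < gh; gy0 += slice_rows) {
    const int rows = std::min(slice_rows, gh - gy0);
    const int n = rows * gw;
    arma::ivec cx(n), cy(n);
    int j = 0;
    for (int gy = gy0; gy < gy0 + rows; ++gy) {
      for (int gx = 0; gx < gw; ++gx, ++j) {
        cx[j] = gx * stride + h;
        cy[j] = gy * stride + h;
      }
    }
    arma::mat P = cpp_extract_patches(R, G, B, cx, cy, edge);
    arma::mat L = W1 * P;
    L.each_col() += b1;
    softplus_inplace(L);
    arma::mat Xp = W2 * L;
    Xp.each_col() += b2;
    softplus_inplace(Xp);
    Xp -= P;
    arma::rowvec f = arma::sum(arma::square(Xp), 0);
    j = 0;
    for (int gy = gy0; gy < gy0 + rows; ++gy)
      for (int gx = 0; gx < gw; ++gx, ++j) out(gy, gx) = f[j];
  }
  return out;
}

// 8-connected component labelling of a logical mask (two-pass union-find).
// Labels are 1..n_regions in row-major discovery order of each region's
// first pixel (scanning y by y, x within y); background stays 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix &mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x)) continue;
      int best = 0;
      const int nx[4] = {x - 1, x - 1, x, x + 1};
      const int ny[4] = {y, y - 1, y - 1, y - 1};
      for (int k = 0; k < 4; ++k) {
        if (nx[k] < 0 || nx[k] >= W || ny[k] < 0) continue;
        const int l = lab(ny[k], nx[k]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(y, x) = best;
    }
  }
  // relabel roots in row-major discovery order
  std::vector<int> newlab(next + 1, 0);
  int out_next = 0;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int l = lab(y, x);
      if (l == 0) continue;
      l = find(l);
      if (newlab[l] == 0) newlab[l] = ++out_next;
      lab(y, x) = newlab[l];
    }
  }
  return lab;
}
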