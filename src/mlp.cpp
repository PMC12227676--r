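// Minimal feed-forward network for the modeling grid: two hidden ReLU
// layers, sigmoid output, binary cross-entropy, Adam, mini-batch training.
// Self-contained RNG (mt19937) so results are reproducible from the seed
// independently of R's RNG state.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::rowvec;
using arma::vec;

static mat he_init(int in, int out, std::mt19937 &rng) {
  std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / in));
  mat w(in, out);
  for (arma::uword j = 0; j < w.n_cols; ++j)
    for (arma::uword i = 0; i < w.n_rows; ++i) w(i, j) = nd(rng);
  return w;
}

struct Adam {
  mat m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  explicit Adam(const mat &shape) : m(arma::size(shape), arma::fill::zeros),
                                    v(arma::size(shape), arma::fill::zeros) {}
  void step(mat &w, const mat &g, double lr, int t) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    mat mh = m / (1 - std::pow(b1, t));
    mat vh = v / (1 - std::pow(b2, t));
    w -= lr * mh / (arma::sqrt(vh) + eps);
  }
};

// [[Rcpp::export(name = ".mlp_train_predict")]]
arma::vec mlp_train_predict(const arma::mat &Xtr, const arma::vec &ytr,
                            const arma::mat &Xte, int h1, int h2, double lr,
                            int epochs, int batch, int seed) {
  const int n = Xtr.n_rows, p = Xtr.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  mat W1 = he_init(p, h1, rng);  rowvec b1(h1, arma::fill::zeros);
  mat W2 = he_init(h1, h2, rng); rowvec b2(h2, arma::fill::zeros);
  mat W3 = he_init(h2, 1, rng);  rowvec b3(1, arma::fill::zeros);
  Adam aW1(W1), aW2(W2), aW3(W3);
  Adam ab1{mat(b1)}, ab2{mat(b2)}, ab3{mat(b3)};

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int s = 0; s < n; s += batch) {
      int e = std::min(s + batch, n);
      arma::uvec rows(e - s);
      for (int i = s; i < e; ++i) rows(i - s) = idx[i];
      mat X = Xtr.rows(rows);
      vec y = ytr.elem(rows);
      const double B = static_cast<double>(e - s);

      mat Z1 = X * W1; Z1.each_row() += b1;
      mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);
      mat Z2 = A1 * W2; Z2.each_row() += b2;
      mat A2 = arma::clamp(Z2, 0.0, arma::datum::inf);
      vec z3 = A2 * W3 + b3(0);
      vec prob = 1.0 / (1.0 + arma::exp(-z3));

      vec d3 = (prob - y) / B;                       // dL/dz3
      mat gW3 = A2.t() * d3;
      double gb3 = arma::accu(d3);
      mat mask2 = arma::conv_to<mat>::from(Z2 > 0);
      mat mask1 = arma::conv_to<mat>::from(Z1 > 0);
      mat d2 = (d3 * W3.t()) % mask2;                // dL/dZ2
      mat gW2 = A1.t() * d2;
      rowvec gb2 = arma::sum(d2, 0);
      mat d1 = (d2 * W2.t()) % mask1;
      mat gW1 = X.t() * d1;
      rowvec gb1 = arma::sum(d1, 0);

      ++t;
      aW1.step(W1, gW1, lr, t);
      aW2.step(W2, gW2, lr, t);
      aW3.step(W3, gW3, lr, t);
      mat b1m(b1), b2m(b2), b3m(b3);
      ab1.step(b1m, mat(gb1), lr, t); b1 = b1m.row(0);
      ab2.step(b2m, mat(gb2), lr, t); b2 = b2m.row(0);
      ab3.step(b3m, mat(1, 1, arma::fill::value(gb3)), lr, t); b3 = b3m.row(0);
    }
  }

  mat Z1 = Xte * W1; Z1.each_row() += b1;
  mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);
  mat Z2 = A1 * W2; Z2.each_row() += b2;
  mat A2 = arma::clamp(Z2, 0.0, arma::datum::inf);
  vec z3 = A2 * W3 + b3(0);
  return 1.0 / (1.0 + arma::exp(-z3));
}
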