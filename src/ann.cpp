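// Feed-forward network used as the movement classifier: ReLU hidden layers,
// softmax output, cross-entropy loss, Adam updates.  Written in Armadillo so
// that single-feature ranking and exhaustive subset search (thousands of
// trainings) stay within desk-scale budgets.  Deterministic for a fixed seed:
// all randomness comes from one std::mt19937 (He-scaled init, epoch shuffles).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat relu(const mat& z) { return clamp(z, 0.0, datum::inf); }

static mat softmax_rows(const mat& z) {
  mat s = z.each_col() - max(z, 1);
  s = exp(s);
  return s.each_col() / sum(s, 1);
}

// [[Rcpp::export]]
Rcpp::List ann_train_cpp(const arma::mat& X, const arma::ivec& y, int n_classes,
                         const arma::ivec& hidden, int epochs, double lr,
                         int batch_size, int seed) {
  const int n = X.n_rows, p = X.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> norm(0.0, 1.0);

  std::vector<int> sizes;
  sizes.push_back(p);
  for (uword l = 0; l < hidden.n_elem; ++l) sizes.push_back(hidden[l]);
  sizes.push_back(n_classes);
  const int L = sizes.size() - 1;  // number of weight layers

  std::vector<mat> W(L), mW(L), vW(L);
  std::vector<rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l].set_size(sizes[l], sizes[l + 1]);
    double sd = std::sqrt(2.0 / sizes[l]);  // He init for ReLU
    for (uword j = 0; j < W[l].n_cols; ++j)
      for (uword i = 0; i < W[l].n_rows; ++i) W[l](i, j) = sd * norm(rng);
    b[l] = rowvec(sizes[l + 1], fill::zeros);
    mW[l] = mat(size(W[l]), fill::zeros);
    vW[l] = mat(size(W[l]), fill::zeros);
    mb[l] = rowvec(sizes[l + 1], fill::zeros);
    vb[l] = rowvec(sizes[l + 1], fill::zeros);
  }

  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  const int bs = std::min(n, batch_size);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  long step = 0;
  std::vector<mat> A(L + 1), Z(L);
  for (int epoch = 0; epoch < epochs; ++epoch) {
    if (bs < n) std::shuffle(idx.begin(), idx.end(), rng);
    for (int start = 0; start < n; start += bs) {
      int stop = std::min(start + bs, n);
      uvec rows(stop - start);
      for (int i = start; i < stop; ++i) rows[i - start] = idx[i];
      const int m = rows.n_elem;

      A[0] = X.rows(rows);
      for (int l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = (l == L - 1) ? softmax_rows(Z[l]) : relu(Z[l]);
      }

      mat delta = A[L];  // softmax - one-hot, averaged over the batch
      for (int i = 0; i < m; ++i) delta(i, y[rows[i]]) -= 1.0;
      delta /= m;

      ++step;
      double c1 = 1.0 - std::pow(beta1, (double)step);
      double c2 = 1.0 - std::pow(beta2, (double)step);
      for (int l = L - 1; l >= 0; --l) {
        mat gW = A[l].t() * delta;
        rowvec gb = sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta.elem(find(Z[l - 1] <= 0.0)).zeros();  // ReLU gate
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * square(gW);
        W[l] -= lr * (mW[l] / c1) / (sqrt(vW[l] / c2) + adam_eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * square(gb);
        b[l] -= lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + adam_eps);
      }
    }
  }

  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = mat(b[l]);
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wout, Rcpp::Named("b") = bout);
}

// [[Rcpp::export]]
arma::mat ann_forward_cpp(const Rcpp::List& W, const Rcpp::List& b,
                          const arma::mat& X) {
  const int L = W.size();
  mat A = X;
  for (int l = 0; l < L; ++l) {
    mat Wl = W[l];
    mat bl = b[l];
    mat Z = A * Wl;
    Z.each_row() += bl.row(0);
    A = (l == L - 1) ? softmax_rows(Z) : relu(Z);
  }
  return A;  // class probabilities
}
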