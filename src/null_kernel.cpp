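// Monte-Carlo null for the projection score: informativeness of
// row-wise permuted copies of a selected submatrix.
//
// Determinism contract: the permutation applied to a given variable (row)
// depends only on (seed, copy index, original variable index), never on the
// position of the row inside the submatrix or on evaluation order. The RNG
// is an explicitly coded mt19937_64 + Fisher-Yates so streams do not depend
// on the standard library's distribution implementations.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t mix3(uint64_t seed, uint64_t copy, uint64_t row_id) {
  uint64_t z = splitmix64(seed);
  z = splitmix64(z ^ (copy * 0xBF58476D1CE4E5B9ULL));
  z = splitmix64(z ^ (row_id * 0x94D049BB133111EBULL));
  return z;
}

// Fisher-Yates permutation of idx[0..n-1], bounded draws by modulo (bias is
// irrelevant for a shuffling null; determinism is what matters).
static void fy_perm(std::mt19937_64& rng, arma::uword* idx, arma::uword n) {
  for (arma::uword i = n - 1; i > 0; --i) {
    arma::uword j = static_cast<arma::uword>(rng() % (uint64_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// tau_d for d = 1..dmax from a Gram-matrix eigendecomposition;
// total = ||M||_F^2 is passed in (permutation invariant).
static arma::vec tau_from_gram(const arma::mat& M, double total, int dmax) {
  arma::mat G;
  if (M.n_rows <= M.n_cols) G = M * M.t(); else G = M.t() * M;
  arma::vec ev;
  arma::eig_sym(ev, G);             // ascending
  arma::vec tau(dmax);
  double acc = 0.0;
  const arma::uword n = ev.n_elem;
  for (int d = 1; d <= dmax; ++d) {
    double lam = ev(n - d);
    acc += (lam > 0.0) ? lam : 0.0;
    tau(d - 1) = std::sqrt(acc / total);
  }
  return tau;
}

// [[Rcpp::export]]
NumericMatrix cpp_null_tau(const arma::mat& X, IntegerVector row_ids,
                           int dmax, int n_rand, double seed) {
  const arma::uword L = X.n_rows, N = X.n_cols;
  if ((int)row_ids.size() != (int)L) stop("row_ids length must match nrow(X)");
  if (dmax < 1 || (arma::uword)dmax > std::min(L, N))
    stop("dmax out of range");
  const double total = arma::accu(arma::square(X));
  if (total <= 0.0) stop("all-zero submatrix");
  const uint64_t s = (uint64_t)seed;

  NumericMatrix out(n_rand, dmax);
  arma::mat M(L, N);
  std::vector<arma::uword> idx(N);
  for (int j = 0; j < n_rand; ++j) {
    for (arma::uword r = 0; r < L; ++r) {
      std::mt19937_64 rng(mix3(s, (uint64_t)(j + 1), (uint64_t)row_ids[r]));
      for (arma::uword c = 0; c < N; ++c) idx[c] = c;
      fy_perm(rng, idx.data(), N);
      for (arma::uword c = 0; c < N; ++c) M(r, c) = X(r, idx[c]);
    }
    arma::vec tau = tau_from_gram(M, total, dmax);
    for (int d = 0; d < dmax; ++d) out(j, d) = tau(d);
  }
  return out;
}

// The exact permutation streams used by cpp_null_tau, exposed so that an
// independent re-implementation (e.g. base R svd) can reproduce the null.
// Returns a list of n_rand L x N integer matrices of 1-based column indices:
// permuted_row = original_row[perm[r, ]].
// [[Rcpp::export]]
List cpp_row_permutations(IntegerVector row_ids, int ncol, int n_rand,
                          double seed) {
  const int L = row_ids.size();
  const uint64_t s = (uint64_t)seed;
  List out(n_rand);
  std::vector<arma::uword> idx(ncol);
  for (int j = 0; j < n_rand; ++j) {
    IntegerMatrix P(L, ncol);
    for (int r = 0; r < L; ++r) {
      std::mt19937_64 rng(mix3(s, (uint64_t)(j + 1), (uint64_t)row_ids[r]));
      for (int c = 0; c < ncol; ++c) idx[c] = (arma::uword)c;
      fy_perm(rng, idx.data(), (arma::uword)ncol);
      for (int c = 0; c < ncol; ++c) P(r, c) = (int)idx[c] + 1;
    }
    out[j] = P;
  }
  return out;
}
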