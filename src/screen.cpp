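// Least-squares screening of candidate fusion carrier sets.
//
// For every subset S of samples with 1 <= |S| <= k (size-then-lexicographic
// order), solve the least-squares problem
//     [lambda * A[, S] | 1] x ~= y
// and record the l2 residual.  The all-ones column absorbs a shared
// per-pool error term.  Only the `top` candidates with smallest residual
// are returned (ties resolved by enumeration order, i.e. smaller set then
// lexicographic); with per_size = true the top `top` of every set size
// are kept, so larger sets (which always fit at least as well) cannot
// crowd smaller ones out of the refinement stage.  Solved via normal
// equations on a precomputed Gram matrix, so the cost per candidate is
// one (|S|+1)-dimensional solve.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List screen_carrier_sets_cpp(const arma::mat& A, const arma::vec& y,
                             double lambda, int k, int top,
                             bool per_size = true) {
  const int T = A.n_rows, N = A.n_cols;
  if (k < 0 || k > N) stop("k must lie in 0..N");

  arma::mat B(T, N + 1);
  B.cols(0, N - 1) = lambda * A;
  B.col(N).ones();
  const arma::mat G = B.t() * B;
  const arma::vec c = B.t() * y;
  const double yty = arma::dot(y, y);

  std::vector<int> set_store;      // flattened carrier sets
  std::vector<int> set_size;
  std::vector<double> res2_store;  // squared residuals (inf if degenerate)

  std::vector<arma::uword> idx(k + 1);
  for (int s = 1; s <= k; ++s) {
    // lexicographic enumeration of s-subsets of 0..N-1
    std::vector<int> comb(s);
    for (int i = 0; i < s; ++i) comb[i] = i;
    bool more = (s <= N);
    while (more) {
      for (int i = 0; i < s; ++i) idx[i] = comb[i];
      idx[s] = N;  // error column
      arma::uvec ui(&idx[0], s + 1, false);
      arma::mat Gs = G.submat(ui, ui);
      arma::vec cs = c.elem(ui);
      arma::vec x;
      double res2;
      if (arma::solve(x, Gs, cs, arma::solve_opts::no_approx)) {
        res2 = yty - arma::dot(cs, x);
        if (res2 < 0) res2 = 0;
      } else {
        res2 = R_PosInf;
      }
      for (int i = 0; i < s; ++i) set_store.push_back(comb[i] + 1);
      set_size.push_back(s);
      res2_store.push_back(res2);
      // next combination
      int i = s - 1;
      while (i >= 0 && comb[i] == N - s + i) --i;
      if (i < 0) { more = false; }
      else { ++comb[i]; for (int j = i + 1; j < s; ++j) comb[j] = comb[j - 1] + 1; }
    }
  }

  const int total = (int) res2_store.size();
  auto by_residual = [&](int a, int b) {
    if (res2_store[a] != res2_store[b]) return res2_store[a] < res2_store[b];
    return a < b;  // enumeration order: size then lex
  };
  std::vector<int> ord;
  if (per_size) {
    for (int s = 1; s <= k; ++s) {
      std::vector<int> idx_s;
      for (int i = 0; i < total; ++i)
        if (set_size[i] == s) idx_s.push_back(i);
      int keep_s = std::min<int>(top, idx_s.size());
      std::partial_sort(idx_s.begin(), idx_s.begin() + keep_s, idx_s.end(),
                        by_residual);
      ord.insert(ord.end(), idx_s.begin(), idx_s.begin() + keep_s);
    }
    std::sort(ord.begin(), ord.end(), by_residual);
  } else {
    ord.resize(total);
    for (int i = 0; i < total; ++i) ord[i] = i;
    int keep_all = std::min(top, total);
    std::partial_sort(ord.begin(), ord.begin() + keep_all, ord.end(),
                      by_residual);
    ord.resize(keep_all);
  }
  int keep = (int) ord.size();

  // offsets of each candidate in the flattened store
  std::vector<int> offset(total);
  int off = 0;
  for (int i = 0; i < total; ++i) { offset[i] = off; off += set_size[i]; }

  List sets(keep);
  NumericVector residual(keep);
  NumericVector per_pool_error(keep);
  List coefs(keep);
  for (int r = 0; r < keep; ++r) {
    int i = ord[r];
    int s = set_size[i];
    IntegerVector S(s);
    for (int j = 0; j < s; ++j) S[j] = set_store[offset[i] + j];
    sets[r] = S;
    if (std::isfinite(res2_store[i])) {
      // recompute coefficients for the survivors only
      for (int j = 0; j < s; ++j) idx[j] = S[j] - 1;
      idx[s] = N;
      arma::uvec ui(&idx[0], s + 1, false);
      arma::vec x = arma::solve(G.submat(ui, ui), c.elem(ui));
      NumericVector xc(s);
      for (int j = 0; j < s; ++j) xc[j] = x[j];
      coefs[r] = xc;
      per_pool_error[r] = x[s];
      residual[r] = std::sqrt(res2_store[i]);
    } else {
      coefs[r] = NumericVector(s, NA_REAL);
      per_pool_error[r] = NA_REAL;
      residual[r] = R_PosInf;
    }
  }
  return List::create(_["sets"] = sets, _["residual"] = residual,
                      _["coefs"] = coefs, _["per_pool_error"] = per_pool_error,
                      _["n_evaluated"] = total);
}
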