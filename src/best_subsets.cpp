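#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Exhaustive best-subsets scorer. Enumerates every predictor subset of size
// 1..kmax in lexicographic order, fits OLS (with intercept) on the training
// Gram system, scores it by average squared error on the held-out partition,
// and returns the subset with the smallest ASE (first hit wins ties, giving
// a deterministic lexicographic tie-break). Singular subsets are skipped.
// [[Rcpp::export]]
Rcpp::List bs_search_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                         const arma::mat& Xte, const arma::vec& yte,
                         const int kmax) {
  const int p = Xtr.n_cols;
  const arma::mat Atr = arma::join_rows(arma::ones(Xtr.n_rows), Xtr);
  const arma::mat Ate = arma::join_rows(arma::ones(Xte.n_rows), Xte);
  const arma::mat G = Atr.t() * Atr;
  const arma::vec b = Atr.t() * ytr;
  const arma::mat H = Ate.t() * Ate;
  const arma::vec d = Ate.t() * yte;
  const double yTy = arma::dot(yte, yte);
  const double nte = static_cast<double>(Xte.n_rows);

  double best_ase = arma::datum::inf;
  arma::uvec best_S;
  long n_eval = 0;

  const int kcap = std::min(kmax, p);
  std::vector<int> comb;
  for (int k = 1; k <= kcap; ++k) {
    comb.assign(k, 0);
    for (int i = 0; i < k; ++i) comb[i] = i;
    for (;;) {
      arma::uvec idx(k + 1);
      idx(0) = 0;
      for (int i = 0; i < k; ++i) idx(i + 1) = comb[i] + 1;
      arma::vec beta;
      const bool ok = arma::solve(beta, G.submat(idx, idx), b.elem(idx),
                                  arma::solve_opts::no_approx +
                                  arma::solve_opts::likely_sympd);
      if (ok && beta.is_finite()) {
        ++n_eval;
        const double ase =
          (yTy - 2.0 * arma::dot(beta, d.elem(idx)) +
           arma::as_scalar(beta.t() * H.submat(idx, idx) * beta)) / nte;
        if (ase < best_ase) {
          best_ase = ase;
          best_S = idx.subvec(1, k) - 1;
        }
      }
      int i = k - 1;
      while (i >= 0 && comb[i] == p - k + i) --i;
      if (i < 0) break;
      ++comb[i];
      for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
    }
  }
  Rcpp::IntegerVector subset(best_S.n_elem);
  for (arma::uword i = 0; i < best_S.n_elem; ++i)
    subset[i] = static_cast<int>(best_S(i)) + 1;  // 1-based predictor index
  return Rcpp::List::create(Rcpp::Named("subset") = subset,
                            Rcpp::Named("ase") = best_ase,
                            Rcpp::Named("n_evaluated") = n_eval);
}
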