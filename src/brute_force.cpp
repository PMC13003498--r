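// Exhaustive correspondence enumeration for the brute-force matching
// oracle: every injective assignment of every peak subset onto every atom
// subset is superposed (Kabsch, proper rotations only) and scored.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double kabsch_rmsd(const arma::mat& P, const arma::mat& Q) {
  arma::rowvec cp = arma::mean(P, 0), cq = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - cp;
  arma::mat Qc = Q.each_row() - cq;
  arma::mat H = Qc.t() * Pc;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) return arma::datum::inf;
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  if (d < 0) D(2, 2) = -1.0;
  arma::mat R = V * D * U.t();
  arma::mat diff = Qc * R.t() - Pc;
  return std::sqrt(arma::accu(diff % diff) / P.n_rows);
}

static void combinations(int n, int k, std::vector<std::vector<int>>& out) {
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  while (true) {
    out.push_back(idx);
    int i = k - 1;
    while (i >= 0 && idx[i] == n - k + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
}

// [[Rcpp::export]]
List cpp_brute_force(const arma::mat& P, const arma::mat& Q, int min_size,
                     double lambda) {
  const int np = P.n_rows, na = Q.n_rows;
  const int kmax = std::min(np, na);
  double best_score = arma::datum::inf;
  double best_rmsd = arma::datum::inf;
  int best_k = -1;
  std::vector<int> best_peaks, best_atoms;
  const int denom = std::max(np, na);
  for (int k = std::max(min_size, 1); k <= kmax; ++k) {
    std::vector<std::vector<int>> psub, asub;
    combinations(np, k, psub);
    combinations(na, k, asub);
    const double pen = lambda * (1.0 - (double)k / denom);
    for (const auto& ps : psub) {
      arma::mat Pk(k, 3);
      for (int i = 0; i < k; ++i) Pk.row(i) = P.row(ps[i]);
      for (const auto& as0 : asub) {
        std::vector<int> perm = as0;
        std::sort(perm.begin(), perm.end());
        do {
          arma::mat Qk(k, 3);
          for (int i = 0; i < k; ++i) Qk.row(i) = Q.row(perm[i]);
          const double rmsd = kabsch_rmsd(Pk, Qk);
          const double score = rmsd + pen;
          const bool better =
            score < best_score - 1e-12 ||
            (std::abs(score - best_score) <= 1e-12 && k > best_k);
          if (better) {
            best_score = score;
            best_rmsd = rmsd;
            best_k = k;
            best_peaks = ps;
            best_atoms = perm;
          }
        } while (std::next_permutation(perm.begin(), perm.end()));
      }
    }
  }
  if (best_k < 0) return List::create(Named("found") = false);
  IntegerVector pk(best_k), at(best_k);
  for (int i = 0; i < best_k; ++i) { pk[i] = best_peaks[i] + 1; at[i] = best_atoms[i] + 1; }
  return List::create(Named("found") = true, Named("score") = best_score,
                      Named("rmsd") = best_rmsd, Named("k") = best_k,
                      Named("peaks") = pk, Named("atoms") = at);
}
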