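#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-node locality statistics for a stack of symmetric zero-diagonal
// adjacency matrices.
//
// For each slice t and node i:
//   O0 = weighted degree: sum of row i,
//   Ok = sum of entries over unordered pairs whose endpoints both lie in the
//        k-th neighborhood of i (k = 1, 2), where neighborhood membership is
//        taken on the support graph (entry >= 1) and includes i itself.
//
// With m_k the 0/1 membership indicator of N_k(i), the pair sum is the
// quadratic form m_k' A m_k / 2, evaluated for all nodes at once as
// rowSums((M_k A) % M_k) / 2 with M_k the V x V membership matrix.
// [[Rcpp::export]]
Rcpp::List scan_node_stats_cpp(const arma::cube& counts) {
  const uword V = counts.n_rows;
  const uword T = counts.n_slices;

  mat O0(T, V), O1(T, V), O2(T, V);

  for (uword t = 0; t < T; ++t) {
    const mat& A = counts.slice(t);

    mat M1 = conv_to<mat>::from(A > 0);
    M1.diag().ones();                       // a node is in its own neighborhood
    mat M2 = conv_to<mat>::from((M1 * M1) > 0);  // reachable within 2 steps

    O0.row(t) = sum(A, 0);                  // symmetric: col sums == row sums
    O1.row(t) = 0.5 * sum((M1 * A) % M1, 1).t();
    O2.row(t) = 0.5 * sum((M2 * A) % M2, 1).t();
  }

  return Rcpp::List::create(Rcpp::Named("O0") = O0,
                            Rcpp::Named("O1") = O1,
                            Rcpp::Named("O2") = O2);
}
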