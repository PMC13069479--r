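// Grouped (per-target-node) primitives for graph attention: segment
// softmax over in-neighbourhoods, grouped row sums, and per-row expansion
// of group sums. Groups are 1-based node indices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".segment_softmax_cpp")]]
arma::mat segment_softmax_cpp(const arma::mat& logits,
                              const arma::ivec& groups, int n) {
  const uword E = logits.n_rows, H = logits.n_cols;
  mat alpha(E, H);
  for (uword h = 0; h < H; ++h) {
    vec mx(n); mx.fill(-datum::inf);
    for (uword t = 0; t < E; ++t) {
      int g = groups(t) - 1;
      if (logits(t, h) > mx(g)) mx(g) = logits(t, h);
    }
    vec denom(n, fill::zeros);
    for (uword t = 0; t < E; ++t) {
      int g = groups(t) - 1;
      alpha(t, h) = std::exp(logits(t, h) - mx(g));
      denom(g) += alpha(t, h);
    }
    for (uword t = 0; t < E; ++t) alpha(t, h) /= denom(groups(t) - 1);
  }
  return alpha;
}

// sums rows of `values` into their group's row of an n-row output
// [[Rcpp::export(name = ".segment_sum_rows_cpp")]]
arma::mat segment_sum_rows_cpp(const arma::mat& values,
                               const arma::ivec& groups, int n) {
  mat out(n, values.n_cols, fill::zeros);
  for (uword t = 0; t < values.n_rows; ++t)
    out.row(groups(t) - 1) += values.row(t);
  return out;
}

// per-row expansion of column-wise group sums (same shape as `values`)
// [[Rcpp::export(name = ".segment_expand_sum_cpp")]]
arma::mat segment_expand_sum_cpp(const arma::mat& values,
                                 const arma::ivec& groups, int n) {
  mat gs(n, values.n_cols, fill::zeros);
  for (uword t = 0; t < values.n_rows; ++t)
    gs.row(groups(t) - 1) += values.row(t);
  mat out(values.n_rows, values.n_cols);
  for (uword t = 0; t < values.n_rows; ++t)
    out.row(t) = gs.row(groups(t) - 1);
  return out;
}
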