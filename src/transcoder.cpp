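// Per-gene transformer encoder over cell positions ("expression transcoder").
//
// Each gene's feature row (z-scored expression across cells plus a TF-flag
// position) is lifted pointwise to d channels by a kernel-1 convolution,
// passed through one multi-head self-attention encoder layer (no positional
// encoding: cells are exchangeable), and mean-pooled over positions into a
// fixed d-dimensional embedding. Forward and backward are hand-derived.
// The cached-forward variant keeps per-gene activations alive between the
// forward and backward calls of one training step so nothing is recomputed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline mat lrelu(const mat& x, double slope) {
  mat y = x;
  for (uword i = 0; i < y.n_elem; ++i) if (y(i) < 0) y(i) *= slope;
  return y;
}

inline mat lrelu_grad(const mat& x, double slope) {
  mat g(size(x));
  for (uword i = 0; i < x.n_elem; ++i) g(i) = x(i) > 0 ? 1.0 : slope;
  return g;
}

void layernorm_fwd(const mat& x, const rowvec& g, const rowvec& b,
                   mat& y, mat& xhat, vec& sd) {
  const double eps = 1e-5;
  vec mu = mean(x, 1);
  vec var = mean(square(x.each_col() - mu), 1);
  sd = sqrt(var + eps);
  xhat = (x.each_col() - mu).each_col() / sd;
  y = (xhat.each_row() % g).each_row() + b;
}

void layernorm_bwd(const mat& dy, const mat& xhat, const vec& sd,
                   const rowvec& g, mat& dx, rowvec& dg, rowvec& db) {
  dg += sum(dy % xhat, 0);
  db += sum(dy, 0);
  mat dxh = dy.each_row() % g;
  vec m1 = mean(dxh, 1);
  vec m2 = mean(dxh % xhat, 1);
  mat tmp = dxh;
  tmp.each_col() -= m1;
  tmp -= xhat.each_col() % m2;
  tmp.each_col() /= sd;
  dx = tmp;
}

struct Params {
  vec conv_w, conv_b, bq, bk, bv, bo, ff_b1, ff_b2;
  mat Wq, Wk, Wv, Wo, ff_W1, ff_W2, Wqkv;
  rowvec ln1_g, ln1_b, ln2_g, ln2_b, bqkv;
  int heads;
  double slope;
};

Params unpack(const Rcpp::List& p) {
  Params s;
  s.conv_w = Rcpp::as<vec>(p["conv_w"]);
  s.conv_b = Rcpp::as<vec>(p["conv_b"]);
  s.Wq = Rcpp::as<mat>(p["Wq"]); s.bq = Rcpp::as<vec>(p["bq"]);
  s.Wk = Rcpp::as<mat>(p["Wk"]); s.bk = Rcpp::as<vec>(p["bk"]);
  s.Wv = Rcpp::as<mat>(p["Wv"]); s.bv = Rcpp::as<vec>(p["bv"]);
  s.Wo = Rcpp::as<mat>(p["Wo"]); s.bo = Rcpp::as<vec>(p["bo"]);
  s.ln1_g = Rcpp::as<rowvec>(p["ln1_g"]); s.ln1_b = Rcpp::as<rowvec>(p["ln1_b"]);
  s.ff_W1 = Rcpp::as<mat>(p["ff_W1"]); s.ff_b1 = Rcpp::as<vec>(p["ff_b1"]);
  s.ff_W2 = Rcpp::as<mat>(p["ff_W2"]); s.ff_b2 = Rcpp::as<vec>(p["ff_b2"]);
  s.ln2_g = Rcpp::as<rowvec>(p["ln2_g"]); s.ln2_b = Rcpp::as<rowvec>(p["ln2_b"]);
  s.heads = Rcpp::as<int>(p["heads"]);
  s.slope = Rcpp::as<double>(p["slope"]);
  s.Wqkv = join_rows(s.Wq, join_rows(s.Wk, s.Wv));
  s.bqkv = join_rows(s.bq.t(), join_rows(s.bk.t(), s.bv.t()));
  return s;
}

struct GeneCache {
  mat H1, QKV, Ocat, U, xhat1, F1, F1a, xhat2;
  vec sd1, sd2;
  std::vector<mat> A;
};

// forward for one gene; fills cache, returns pooled embedding
rowvec gene_forward(const vec& s, const Params& p, GeneCache& c) {
  const uword d = p.conv_w.n_elem;
  const int H = p.heads;
  const uword dh = d / H;
  const double scale = std::sqrt((double)dh);
  mat H0 = s * p.conv_w.t();
  H0.each_row() += p.conv_b.t();
  c.H1 = lrelu(H0, p.slope);
  c.QKV = c.H1 * p.Wqkv;
  c.QKV.each_row() += p.bqkv;
  const uword P = s.n_elem;
  c.Ocat.set_size(P, d);
  c.A.assign(H, mat());
  for (int h = 0; h < H; ++h) {
    uword c0 = h * dh, c1 = (h + 1) * dh - 1;
    mat S = c.QKV.cols(c0, c1) * c.QKV.cols(d + c0, d + c1).t();
    S /= scale;
    S.each_col() -= max(S, 1);
    S = exp(S);
    S.each_col() /= sum(S, 1);
    c.A[h] = std::move(S);
    c.Ocat.cols(c0, c1) = c.A[h] * c.QKV.cols(2 * d + c0, 2 * d + c1);
  }
  c.U = c.Ocat * p.Wo;
  c.U.each_row() += p.bo.t();
  c.U += c.H1;
  mat X1;
  layernorm_fwd(c.U, p.ln1_g, p.ln1_b, X1, c.xhat1, c.sd1);
  c.F1 = X1 * p.ff_W1;
  c.F1.each_row() += p.ff_b1.t();
  c.F1a = lrelu(c.F1, p.slope);
  mat U2 = c.F1a * p.ff_W2;
  U2.each_row() += p.ff_b2.t();
  U2 += X1;
  mat X2;
  layernorm_fwd(U2, p.ln2_g, p.ln2_b, X2, c.xhat2, c.sd2);
  return mean(X2, 0);
}

struct Grads {
  vec conv_w, conv_b, bo, ff_b1, ff_b2;
  rowvec bqkv;
  mat Wqkv, Wo, ff_W1, ff_W2;
  rowvec ln1_g, ln1_b, ln2_g, ln2_b;
  void init(const Params& p) {
    uword d = p.conv_w.n_elem;
    conv_w = zeros(d); conv_b = zeros(d);
    bqkv = zeros<rowvec>(3 * d); bo = zeros(d);
    ff_b1 = zeros(d); ff_b2 = zeros(d);
    Wqkv = zeros(d, 3 * d); Wo = zeros(d, d);
    ff_W1 = zeros(size(p.ff_W1)); ff_W2 = zeros(size(p.ff_W2));
    ln1_g = zeros<rowvec>(d); ln1_b = ln1_g; ln2_g = ln1_g; ln2_b = ln1_g;
  }
};

void gene_backward(const vec& s, const rowvec& demb, const Params& p,
                   const GeneCache& c, Grads& g) {
  const uword P = s.n_elem, d = p.conv_w.n_elem;
  const int H = p.heads;
  const uword dh = d / H;
  const double scale = std::sqrt((double)dh);
  // reconstruct X1 from cached xhat1 (cheaper than storing it)
  mat X1 = (c.xhat1.each_row() % p.ln1_g).each_row() + p.ln1_b;
  mat dX2 = repmat(demb / (double)P, P, 1);
  mat dU2;
  layernorm_bwd(dX2, c.xhat2, c.sd2, p.ln2_g, dU2, g.ln2_g, g.ln2_b);
  mat dX1 = dU2;
  g.ff_W2 += c.F1a.t() * dU2;
  g.ff_b2 += sum(dU2, 0).t();
  mat dF1 = (dU2 * p.ff_W2.t()) % lrelu_grad(c.F1, p.slope);
  g.ff_W1 += X1.t() * dF1;
  g.ff_b1 += sum(dF1, 0).t();
  dX1 += dF1 * p.ff_W1.t();
  mat dU;
  layernorm_bwd(dX1, c.xhat1, c.sd1, p.ln1_g, dU, g.ln1_g, g.ln1_b);
  mat dH1 = dU;
  g.Wo += c.Ocat.t() * dU;
  g.bo += sum(dU, 0).t();
  mat dOcat = dU * p.Wo.t();
  mat dQKV(P, 3 * d, fill::zeros);
  for (int h = 0; h < H; ++h) {
    uword c0 = h * dh, c1 = (h + 1) * dh - 1;
    const mat& A = c.A[h];
    mat dOh = dOcat.cols(c0, c1);
    mat dA = dOh * c.QKV.cols(2 * d + c0, 2 * d + c1).t();
    dQKV.cols(2 * d + c0, 2 * d + c1) = A.t() * dOh;
    vec rs = sum(dA % A, 1);
    mat dS = (dA.each_col() - rs) % A / scale;
    dQKV.cols(c0, c1) = dS * c.QKV.cols(d + c0, d + c1);
    dQKV.cols(d + c0, d + c1) = dS.t() * c.QKV.cols(c0, c1);
  }
  g.Wqkv += c.H1.t() * dQKV;
  g.bqkv += sum(dQKV, 0);
  dH1 += dQKV * p.Wqkv.t();
  // H0 = s conv_w^T + conv_b; dH0 = dH1 * lrelu'(H0); H0 sign == H1 sign
  mat dH0 = dH1 % lrelu_grad(c.H1, p.slope);
  g.conv_w += dH0.t() * s;
  g.conv_b += sum(dH0, 0).t();
}

Rcpp::List grads_to_list(const Grads& g, uword d) {
  return Rcpp::List::create(
    Rcpp::Named("conv_w") = g.conv_w, Rcpp::Named("conv_b") = g.conv_b,
    Rcpp::Named("Wq") = mat(g.Wqkv.cols(0, d - 1)),
    Rcpp::Named("bq") = vec(g.bqkv.cols(0, d - 1).t()),
    Rcpp::Named("Wk") = mat(g.Wqkv.cols(d, 2 * d - 1)),
    Rcpp::Named("bk") = vec(g.bqkv.cols(d, 2 * d - 1).t()),
    Rcpp::Named("Wv") = mat(g.Wqkv.cols(2 * d, 3 * d - 1)),
    Rcpp::Named("bv") = vec(g.bqkv.cols(2 * d, 3 * d - 1).t()),
    Rcpp::Named("Wo") = g.Wo, Rcpp::Named("bo") = g.bo,
    Rcpp::Named("ln1_g") = g.ln1_g, Rcpp::Named("ln1_b") = g.ln1_b,
    Rcpp::Named("ff_W1") = g.ff_W1, Rcpp::Named("ff_b1") = g.ff_b1,
    Rcpp::Named("ff_W2") = g.ff_W2, Rcpp::Named("ff_b2") = g.ff_b2,
    Rcpp::Named("ln2_g") = g.ln2_g, Rcpp::Named("ln2_b") = g.ln2_b);
}

} // namespace

// [[Rcpp::export(name = ".transcoder_forward_cpp")]]
arma::mat transcoder_forward_cpp(const arma::mat& features,
                                 const Rcpp::List& params) {
  Params p = unpack(params);
  const uword N = features.n_rows, d = p.conv_w.n_elem;
  mat emb(N, d);
  GeneCache c;
  for (uword gidx = 0; gidx < N; ++gidx)
    emb.row(gidx) = gene_forward(features.row(gidx).t(), p, c);
  return emb;
}

// forward keeping all per-gene activations alive for the matching backward
// [[Rcpp::export(name = ".transcoder_forward_cached_cpp")]]
Rcpp::List transcoder_forward_cached_cpp(const arma::mat& features,
                                         const Rcpp::List& params) {
  Params p = unpack(params);
  const uword N = features.n_rows, d = p.conv_w.n_elem;
  mat emb(N, d);
  Rcpp::XPtr<std::vector<GeneCache>> caches(new std::vector<GeneCache>(N),
                                            true);
  for (uword gidx = 0; gidx < N; ++gidx)
    emb.row(gidx) = gene_forward(features.row(gidx).t(), p, (*caches)[gidx]);
  return Rcpp::List::create(Rcpp::Named("emb") = emb,
                            Rcpp::Named("handle") = caches);
}

// [[Rcpp::export(name = ".transcoder_backward_cached_cpp")]]
Rcpp::List transcoder_backward_cached_cpp(SEXP handle,
                                          const arma::mat& features,
                                          const arma::mat& demb,
                                          const Rcpp::List& params) {
  Rcpp::XPtr<std::vector<GeneCache>> caches(handle);
  Params p = unpack(params);
  const uword N = features.n_rows, d = p.conv_w.n_elem;
  if (caches->size() != N) Rcpp::stop("stale transcoder cache");
  Grads g;
  g.init(p);
  for (uword gidx = 0; gidx < N; ++gidx)
    gene_backward(features.row(gidx).t(), demb.row(gidx), p,
                  (*caches)[gidx], g);
  caches->clear();
  return grads_to_list(g, d);
}

// standalone backward (recomputes the forward gene by gene)
// [[Rcpp::export(name = ".transcoder_backward_cpp")]]
Rcpp::List transcoder_backward_cpp(const arma::mat& features,
                                   const arma::mat& demb,
                                   const Rcpp::List& params) {
  Params p = unpack(params);
  const uword N = features.n_rows, d = p.conv_w.n_elem;
  Grads g;
  g.init(p);
  GeneCache c;
  for (uword gidx = 0; gidx < N; ++gidx) {
    vec s = features.row(gidx).t();
    gene_forward(s, p, c);
    gene_backward(s, demb.row(gidx), p, c, g);
  }
  return grads_to_list(g, d);
}
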