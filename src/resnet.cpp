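// Residual 1-D convolutional ECG encoder: forward pass and explicit
// backpropagation. All randomness (weight init, crop positions, shuffling)
// lives on the R side; these routines are deterministic.
//
// Architecture (channel widths implied by the weight shapes):
//   stem : conv k=7 stride 2 + ReLU
//   block: conv k=5 stride 2 + ReLU + conv k=5 stride 1,
//          1x1 stride-2 skip, ReLU after the sum
//   head : global average pool -> linear embedding -> linear logit
//
// Weight list layout (R list of matrices, vectors as 1-column matrices):
//   [ W_stem, b_stem,
//     per block: W1, b1, W2, b2, Wskip, bskip,
//     W_emb, b_emb, W_out, b_out ]

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int K_STEM = 7;
static const int K_BLOCK = 5;

static mat im2col(const mat& x, int k, int s, int pad) {
  const int C = x.n_rows, T = x.n_cols;
  const int To = (T + 2 * pad - k) / s + 1;
  mat M(C * k, To, fill::zeros);
  for (int t = 0; t < To; ++t) {
    const int start = t * s - pad;
    for (int j = 0; j < k; ++j) {
      const int src = start + j;
      if (src >= 0 && src < T)
        M.submat(j * C, t, (j + 1) * C - 1, t) = x.col(src);
    }
  }
  return M;
}

static mat col2im(const mat& dM, int C, int T, int k, int s, int pad) {
  const int To = dM.n_cols;
  mat dX(C, T, fill::zeros);
  for (int t = 0; t < To; ++t) {
    const int start = t * s - pad;
    for (int j = 0; j < k; ++j) {
      const int src = start + j;
      if (src >= 0 && src < T)
        dX.col(src) += dM.submat(j * C, t, (j + 1) * C - 1, t);
    }
  }
  return dX;
}

struct ConvCache { mat M; int C, T, k, s, pad; };

static mat conv_fwd(const mat& W, const vec& b, const mat& x,
                    int k, int s, ConvCache& cache) {
  const int pad = (k - 1) / 2;
  cache.M = im2col(x, k, s, pad);
  cache.C = x.n_rows; cache.T = x.n_cols;
  cache.k = k; cache.s = s; cache.pad = pad;
  mat y = W * cache.M;
  y.each_col() += b;
  return y;
}

static mat conv_bwd(const mat& W, const ConvCache& cache, const mat& dY,
                    mat& dW, vec& db) {
  dW += dY * cache.M.t();
  db += sum(dY, 1);
  mat dM = W.t() * dY;
  return col2im(dM, cache.C, cache.T, cache.k, cache.s, cache.pad);
}

struct Net {
  mat W_stem; vec b_stem;
  std::vector<mat> W1, W2, Ws;
  std::vector<vec> b1, b2, bs;
  mat W_emb; vec b_emb;
  mat W_out; vec b_out;
  int n_blocks;
};

static Net unpack(const Rcpp::List& weights) {
  Net net;
  const int len = weights.size();
  net.n_blocks = (len - 6) / 6;
  int i = 0;
  net.W_stem = Rcpp::as<mat>(weights[i++]);
  net.b_stem = vectorise(Rcpp::as<mat>(weights[i++]));
  for (int b = 0; b < net.n_blocks; ++b) {
    net.W1.push_back(Rcpp::as<mat>(weights[i++]));
    net.b1.push_back(vectorise(Rcpp::as<mat>(weights[i++])));
    net.W2.push_back(Rcpp::as<mat>(weights[i++]));
    net.b2.push_back(vectorise(Rcpp::as<mat>(weights[i++])));
    net.Ws.push_back(Rcpp::as<mat>(weights[i++]));
    net.bs.push_back(vectorise(Rcpp::as<mat>(weights[i++])));
  }
  net.W_emb = Rcpp::as<mat>(weights[i++]);
  net.b_emb = vectorise(Rcpp::as<mat>(weights[i++]));
  net.W_out = Rcpp::as<mat>(weights[i++]);
  net.b_out = vectorise(Rcpp::as<mat>(weights[i++]));
  return net;
}

struct FwdCache {
  ConvCache c_stem;
  mat a_stem;                       // pre-ReLU stem
  std::vector<ConvCache> c1, c2, cs;
  std::vector<mat> a1, pre, r, in;  // per-block intermediates
  mat z_last;
  vec g, e;
  double logit;
};

static void forward_one(const Net& net, const mat& x, FwdCache& fc) {
  fc.c1.resize(net.n_blocks); fc.c2.resize(net.n_blocks);
  fc.cs.resize(net.n_blocks);
  fc.a1.resize(net.n_blocks); fc.pre.resize(net.n_blocks);
  fc.r.resize(net.n_blocks); fc.in.resize(net.n_blocks);

  fc.a_stem = conv_fwd(net.W_stem, net.b_stem, x, K_STEM, 2, fc.c_stem);
  mat z = clamp(fc.a_stem, 0.0, datum::inf);
  for (int b = 0; b < net.n_blocks; ++b) {
    fc.in[b] = z;
    fc.a1[b] = conv_fwd(net.W1[b], net.b1[b], z, K_BLOCK, 2, fc.c1[b]);
    fc.r[b] = clamp(fc.a1[b], 0.0, datum::inf);
    mat main = conv_fwd(net.W2[b], net.b2[b], fc.r[b], K_BLOCK, 1, fc.c2[b]);
    mat skip = conv_fwd(net.Ws[b], net.bs[b], z, 1, 2, fc.cs[b]);
    fc.pre[b] = main + skip;
    z = clamp(fc.pre[b], 0.0, datum::inf);
  }
  fc.z_last = z;
  fc.g = mean(z, 1);
  fc.e = net.W_emb * fc.g + net.b_emb;
  fc.logit = as_scalar(net.W_out * fc.e + net.b_out);
}

// [[Rcpp::export]]
Rcpp::List resnet_forward_cpp(Rcpp::List weights, arma::cube X) {
  Net net = unpack(weights);
  const int n = X.n_slices;
  vec logits(n);
  mat emb(net.W_emb.n_rows, n);
  FwdCache fc;
  for (int i = 0; i < n; ++i) {
    forward_one(net, X.slice(i), fc);
    logits(i) = fc.logit;
    emb.col(i) = fc.e;
  }
  return Rcpp::List::create(Rcpp::Named("logits") = logits,
                            Rcpp::Named("embedding") = emb);
}

// [[Rcpp::export]]
Rcpp::List resnet_grad_cpp(Rcpp::List weights, arma::cube X, arma::vec y,
                           double pos_weight) {
  Net net = unpack(weights);
  const int n = X.n_slices;

  mat dW_stem(size(net.W_stem), fill::zeros);
  vec db_stem(net.b_stem.n_elem, fill::zeros);
  std::vector<mat> dW1, dW2, dWs;
  std::vector<vec> db1, db2, dbs;
  for (int b = 0; b < net.n_blocks; ++b) {
    dW1.push_back(mat(size(net.W1[b]), fill::zeros));
    db1.push_back(vec(net.b1[b].n_elem, fill::zeros));
    dW2.push_back(mat(size(net.W2[b]), fill::zeros));
    db2.push_back(vec(net.b2[b].n_elem, fill::zeros));
    dWs.push_back(mat(size(net.Ws[b]), fill::zeros));
    dbs.push_back(vec(net.bs[b].n_elem, fill::zeros));
  }
  mat dW_emb(size(net.W_emb), fill::zeros);
  vec db_emb(net.b_emb.n_elem, fill::zeros);
  mat dW_out(size(net.W_out), fill::zeros);
  vec db_out(net.b_out.n_elem, fill::zeros);

  double loss = 0.0;
  FwdCache fc;
  for (int i = 0; i < n; ++i) {
    forward_one(net, X.slice(i), fc);
    const double w = (y(i) > 0.5) ? pos_weight : 1.0;
    const double z = fc.logit;
    // numerically stable softplus(z) - y*z
    const double sp = (z > 0) ? z + std::log1p(std::exp(-z))
                              : std::log1p(std::exp(z));
    loss += w * (sp - y(i) * z);
    const double sig = 1.0 / (1.0 + std::exp(-z));
    const double dlogit = w * (sig - y(i));

    dW_out += dlogit * fc.e.t();
    db_out += dlogit;
    vec de = net.W_out.t() * dlogit;
    dW_emb += de * fc.g.t();
    db_emb += de;
    vec dg = net.W_emb.t() * de;

    const int T_last = fc.z_last.n_cols;
    mat dz = repmat(dg / T_last, 1, T_last);
    for (int b = net.n_blocks - 1; b >= 0; --b) {
      mat dpre = dz % conv_to<mat>::from(fc.pre[b] > 0);
      mat dr = conv_bwd(net.W2[b], fc.c2[b], dpre, dW2[b], db2[b]);
      dr = dr % conv_to<mat>::from(fc.a1[b] > 0);
      mat din1 = conv_bwd(net.W1[b], fc.c1[b], dr, dW1[b], db1[b]);
      mat din2 = conv_bwd(net.Ws[b], fc.cs[b], dpre, dWs[b], dbs[b]);
      dz = din1 + din2;
    }
    mat da = dz % conv_to<mat>::from(fc.a_stem > 0);
    conv_bwd(net.W_stem, fc.c_stem, da, dW_stem, db_stem);
  }

  const double inv_n = 1.0 / n;
  loss *= inv_n;
  Rcpp::List grads(weights.size());
  int i = 0;
  grads[i++] = dW_stem * inv_n;
  grads[i++] = db_stem * inv_n;
  for (int b = 0; b < net.n_blocks; ++b) {
    grads[i++] = dW1[b] * inv_n;
    grads[i++] = db1[b] * inv_n;
    grads[i++] = dW2[b] * inv_n;
    grads[i++] = db2[b] * inv_n;
    grads[i++] = dWs[b] * inv_n;
    grads[i++] = dbs[b] * inv_n;
  }
  grads[i++] = dW_emb * inv_n;
  grads[i++] = db_emb * inv_n;
  grads[i++] = dW_out * inv_n;
  grads[i++] = db_out * inv_n;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// fast row medians for the median-beat computation
// [[Rcpp::export]]
arma::vec row_medians_cpp(const arma::mat& X) {
  return median(X, 1);
}
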