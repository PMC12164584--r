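// Sequence-to-labels network: nucleotide embedding + masked sinusoidal
// positional encoding, two conv/max-pool blocks, stacked multi-head
// self-attention, position-wise dense(1) -> squeeze -> dense(n_targets),
// sigmoid outputs. Forward, exact backprop and an Adam training loop.
//
// Parameter list layout (order is the contract with the R side):
//   embed (5 x D), conv1_W (K*D x F1), conv1_b (1 x F1),
//   conv2_W (K*F1 x F2), conv2_b (1 x F2),
//   per attention layer: Wq, bq, Wk, bk, Wv, bv  (weights C x C, biases 1 x C),
//   head_W (C x 1), head_b (1 x 1),
//   [hid_W (P x H), hid_b (1 x H)] if head_hidden_units > 0,
//   out_W (P or H x T), out_b (1 x T).
// Flattened conv weights use row index k*D + d for W[k, d, f].

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct NetConfig {
  int L, D, K, F1, F2, pool, stride, heads, layers, T, hidden;
  bool ceil_pool, residual;
  int L1, P1, L2, P2;  // derived per-layer position counts
};

static int pooled_len(int n, int p, int s, bool ceil_mode) {
  if (ceil_mode) return (n + s - 1) / s;
  return (n - p) / s + 1;
}

static NetConfig parse_config(const Rcpp::List& cfg) {
  NetConfig c;
  c.L = cfg["window_len"];
  c.D = cfg["embed_dim"];
  c.K = cfg["kernel_size"];
  Rcpp::IntegerVector filt = cfg["conv_filters"];
  c.F1 = filt[0];
  c.F2 = filt[1];
  c.pool = cfg["pool_size"];
  c.stride = cfg["pool_stride"];
  c.heads = cfg["attn_heads"];
  c.layers = cfg["attn_layers"];
  c.T = cfg["n_targets"];
  c.hidden = cfg["head_hidden_units"];
  c.ceil_pool = cfg["ceil_pool"];
  c.residual = cfg["attn_residual"];
  c.L1 = c.L - c.K + 1;
  if (c.L1 < 1) Rcpp::stop("window shorter than kernel");
  c.P1 = pooled_len(c.L1, c.pool, c.stride, c.ceil_pool);
  c.L2 = c.P1 - c.K + 1;
  if (c.L2 < 1) Rcpp::stop("pooled length shorter than kernel");
  c.P2 = pooled_len(c.L2, c.pool, c.stride, c.ceil_pool);
  if (c.F2 % c.heads != 0) Rcpp::stop("attn channels not divisible by heads");
  return c;
}

static std::vector<mat> list_to_params(const Rcpp::List& lst) {
  std::vector<mat> out;
  out.reserve(lst.size());
  for (int i = 0; i < lst.size(); ++i) out.push_back(Rcpp::as<mat>(lst[i]));
  return out;
}

static Rcpp::List params_to_list(const std::vector<mat>& p,
                                 const Rcpp::CharacterVector& names) {
  Rcpp::List out(p.size());
  for (size_t i = 0; i < p.size(); ++i) out[i] = Rcpp::wrap(p[i]);
  out.attr("names") = names;
  return out;
}

static mat positional_encoding_mat(int L, int D) {
  mat pe(L, D);
  for (int p = 0; p < L; ++p) {
    for (int i = 0; 2 * i < D; ++i) {
      double angle = p / std::pow(10000.0, (2.0 * i) / D);
      pe(p, 2 * i) = std::sin(angle);
      if (2 * i + 1 < D) pe(p, 2 * i + 1) = std::cos(angle);
    }
  }
  return pe;
}

// [[Rcpp::export]]
arma::mat cpp_positional_encoding(int seqlen, int dim) {
  return positional_encoding_mat(seqlen, dim);
}

static void im2col(const mat& X, int K, mat& out) {
  const int D = X.n_cols;
  const int Lout = X.n_rows - K + 1;
  out.set_size(Lout, K * D);
  for (int k = 0; k < K; ++k) {
    out.cols(k * D, (k + 1) * D - 1) = X.rows(k, k + Lout - 1);
  }
}

static void col2im_add(const mat& dXc, int K, int D, mat& dX) {
  const int Lout = dXc.n_rows;
  for (int k = 0; k < K; ++k) {
    dX.rows(k, k + Lout - 1) += dXc.cols(k * D, (k + 1) * D - 1);
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv1d(const arma::mat& X, const arma::mat& W_flat,
                     const arma::rowvec& b, int kernel_size,
                     bool relu = true) {
  if ((int)X.n_rows < kernel_size) Rcpp::stop("input shorter than kernel");
  if (W_flat.n_rows != (unsigned)(kernel_size * X.n_cols))
    Rcpp::stop("conv weight shape mismatch");
  mat Xc;
  im2col(X, kernel_size, Xc);
  mat Y = Xc * W_flat;
  Y.each_row() += b;
  if (relu) Y = clamp(Y, 0.0, datum::inf);
  return Y;
}

static mat maxpool_fwd(const mat& Y, int p, int s, bool ceil_mode,
                       umat* argmax) {
  const int n = Y.n_rows, F = Y.n_cols;
  const int m = pooled_len(n, p, s, ceil_mode);
  if (m < 1) Rcpp::stop("pooling produced empty output");
  mat Z(m, F);
  if (argmax) argmax->set_size(m, F);
  for (int t = 0; t < m; ++t) {
    const int a = t * s;
    const int bnd = std::min(a + p, n);
    for (int f = 0; f < F; ++f) {
      double best = Y(a, f);
      int besti = a;
      for (int k = a + 1; k < bnd; ++k) {
        if (Y(k, f) > best) { best = Y(k, f); besti = k; }
      }
      Z(t, f) = best;
      if (argmax) (*argmax)(t, f) = besti;
    }
  }
  return Z;
}

// [[Rcpp::export]]
arma::mat cpp_max_pool1d(const arma::mat& Y, int pool_size, int stride,
                         bool ceil_mode = true) {
  return maxpool_fwd(Y, pool_size, stride, ceil_mode, nullptr);
}

static void softmax_rows(mat& S) {
  for (unsigned i = 0; i < S.n_rows; ++i) {
    rowvec r = S.row(i);
    r -= r.max();
    r = exp(r);
    S.row(i) = r / accu(r);
  }
}

struct AttnCache {
  mat X, Q, K, V, O;
  std::vector<mat> A;  // per-head softmax matrices (P x P)
};

static mat mha_fwd(const mat& X, const mat& Wq, const rowvec& bq,
                   const mat& Wk, const rowvec& bk, const mat& Wv,
                   const rowvec& bv, int heads, bool residual,
                   AttnCache* cache) {
  const int C = X.n_cols;
  const int dk = C / heads;
  mat Q = X * Wq; Q.each_row() += bq;
  mat K = X * Wk; K.each_row() += bk;
  mat V = X * Wv; V.each_row() += bv;
  mat O(X.n_rows, C);
  if (cache) { cache->X = X; cache->Q = Q; cache->K = K; cache->V = V;
               cache->A.resize(heads); }
  const double scale = 1.0 / std::sqrt((double)dk);
  for (int h = 0; h < heads; ++h) {
    const int a = h * dk, b = (h + 1) * dk - 1;
    mat S = Q.cols(a, b) * K.cols(a, b).t() * scale;
    softmax_rows(S);
    O.cols(a, b) = S * V.cols(a, b);
    if (cache) cache->A[h] = std::move(S);
  }
  if (residual) O += X;
  if (cache) cache->O = O;
  return O;
}

// [[Rcpp::export]]
arma::mat cpp_multi_head_attention(const arma::mat& X, const arma::mat& Wq,
                                   const arma::rowvec& bq, const arma::mat& Wk,
                                   const arma::rowvec& bk, const arma::mat& Wv,
                                   const arma::rowvec& bv, int heads,
                                   bool residual = false) {
  if (X.n_cols % heads != 0) Rcpp::stop("channels not divisible by heads");
  return mha_fwd(X, Wq, bq, Wk, bk, Wv, bv, heads, residual, nullptr);
}

struct FwdCache {
  uvec codes;
  vec mask;
  mat X0, Xc1, A1, Z1, Xc2, A2, Z2;
  umat arg1, arg2;
  std::vector<AttnCache> attn;
  mat Xattn_out;      // P2 x C after last attention layer
  vec u;              // squeezed position-wise dense output, length P2
  vec drop;           // inverted-dropout mask applied to u (empty = none)
  rowvec hid;         // hidden activation (if any)
  rowvec probs;       // 1 x T
};

// indices into the parameter vector
struct ParamIdx {
  int embed = 0, c1w = 1, c1b = 2, c2w = 3, c2b = 4;
  int attn0 = 5;                       // 6 per layer from here
  int head_w, head_b, hid_w, hid_b, out_w, out_b;
  ParamIdx(const NetConfig& c) {
    head_w = attn0 + 6 * c.layers;
    head_b = head_w + 1;
    if (c.hidden > 0) {
      hid_w = head_b + 1; hid_b = hid_w + 1;
      out_w = hid_b + 1; out_b = out_w + 1;
    } else {
      hid_w = hid_b = -1;
      out_w = head_b + 1; out_b = out_w + 1;
    }
  }
};

static rowvec forward_one(const ivec& codes, const std::vector<mat>& P,
                          const NetConfig& c, const mat& pe, FwdCache* cc,
                          const vec* drop_mask = nullptr) {
  const ParamIdx ix(c);
  const int L = c.L;
  if ((int)codes.n_elem != L) Rcpp::stop("sequence length != window_len");
  mat X0(L, c.D);
  vec mask(L);
  for (int p = 0; p < L; ++p) {
    const int code = codes[p];
    if (code < 0 || code > 4) Rcpp::stop("nucleotide code outside {0..4}");
    mask[p] = code == 0 ? 0.0 : 1.0;
    X0.row(p) = P[ix.embed].row(code) + mask[p] * pe.row(p);
  }
  mat Xc1;
  im2col(X0, c.K, Xc1);
  mat A1 = Xc1 * P[ix.c1w];
  A1.each_row() += P[ix.c1b].row(0);
  A1 = clamp(A1, 0.0, datum::inf);
  umat arg1, arg2;
  mat Z1 = maxpool_fwd(A1, c.pool, c.stride, c.ceil_pool, cc ? &arg1 : nullptr);
  mat Xc2;
  im2col(Z1, c.K, Xc2);
  mat A2 = Xc2 * P[ix.c2w];
  A2.each_row() += P[ix.c2b].row(0);
  A2 = clamp(A2, 0.0, datum::inf);
  mat Z2 = maxpool_fwd(A2, c.pool, c.stride, c.ceil_pool, cc ? &arg2 : nullptr);

  mat X = Z2;
  if (cc) cc->attn.resize(c.layers);
  for (int l = 0; l < c.layers; ++l) {
    const int o = ix.attn0 + 6 * l;
    X = mha_fwd(X, P[o], P[o + 1].row(0), P[o + 2], P[o + 3].row(0),
                P[o + 4], P[o + 5].row(0), c.heads, c.residual,
                cc ? &cc->attn[l] : nullptr);
  }
  vec u = X * P[ix.head_w].col(0) + P[ix.head_b](0, 0);
  if (drop_mask) u %= *drop_mask;
  rowvec act = u.t();
  rowvec hid;
  if (c.hidden > 0) {
    hid = act * P[ix.hid_w] + P[ix.hid_b].row(0);
    hid = clamp(hid, 0.0, datum::inf);
    act = hid;
  }
  rowvec logits = act * P[ix.out_w] + P[ix.out_b].row(0);
  rowvec probs = 1.0 / (1.0 + exp(-logits));
  if (cc) {
    cc->codes = conv_to<uvec>::from(codes);
    cc->mask = mask; cc->X0 = std::move(X0); cc->Xc1 = std::move(Xc1);
    cc->A1 = std::move(A1); cc->Z1 = std::move(Z1); cc->Xc2 = std::move(Xc2);
    cc->A2 = std::move(A2); cc->Z2 = std::move(Z2);
    cc->arg1 = std::move(arg1); cc->arg2 = std::move(arg2);
    cc->Xattn_out = std::move(X); cc->u = std::move(u);
    if (drop_mask) cc->drop = *drop_mask;
    cc->hid = hid; cc->probs = probs;
  }
  return probs;
}

// backprop one sequence; dlogits is dLoss/dlogits (1 x T); grads accumulated
static void backward_one(const FwdCache& cc, const rowvec& dlogits,
                         const std::vector<mat>& P, const NetConfig& c,
                         std::vector<mat>& G) {
  const ParamIdx ix(c);
  rowvec dact;
  if (c.hidden > 0) {
    G[ix.out_w] += cc.hid.t() * dlogits;
    G[ix.out_b].row(0) += dlogits;
    rowvec dhid = dlogits * P[ix.out_w].t();
    dhid.elem(find(cc.hid == 0)).zeros();
    G[ix.hid_w] += cc.u * dhid;
    G[ix.hid_b].row(0) += dhid;
    dact = dhid * P[ix.hid_w].t();
  } else {
    G[ix.out_w] += cc.u * dlogits;
    G[ix.out_b].row(0) += dlogits;
    dact = dlogits * P[ix.out_w].t();
  }
  vec du = dact.t();  // length P2
  if (cc.drop.n_elem > 0) du %= cc.drop;
  G[ix.head_w].col(0) += cc.Xattn_out.t() * du;
  G[ix.head_b](0, 0) += accu(du);
  mat dX = du * P[ix.head_w].col(0).t();  // P2 x C

  const int dk = c.F2 / c.heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  for (int l = c.layers - 1; l >= 0; --l) {
    const AttnCache& ac = cc.attn[l];
    const int o = ix.attn0 + 6 * l;
    mat dQ(size(ac.Q), fill::zeros), dK(size(ac.K), fill::zeros),
        dV(size(ac.V), fill::zeros);
    for (int h = 0; h < c.heads; ++h) {
      const int a = h * dk, b = (h + 1) * dk - 1;
      const mat& A = ac.A[h];
      mat dO_h = dX.cols(a, b);
      mat dA = dO_h * ac.V.cols(a, b).t();
      dV.cols(a, b) = A.t() * dO_h;
      // softmax backward, row-wise
      vec rs = sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rs);
      dS *= scale;
      dQ.cols(a, b) = dS * ac.K.cols(a, b);
      dK.cols(a, b) = dS.t() * ac.Q.cols(a, b);
    }
    G[o] += ac.X.t() * dQ;
    G[o + 1].row(0) += sum(dQ, 0);
    G[o + 2] += ac.X.t() * dK;
    G[o + 3].row(0) += sum(dK, 0);
    G[o + 4] += ac.X.t() * dV;
    G[o + 5].row(0) += sum(dV, 0);
    mat dXin = dQ * P[o].t() + dK * P[o + 2].t() + dV * P[o + 4].t();
    if (c.residual) dXin += dX;
    dX = std::move(dXin);
  }

  // pool2 backward
  mat dA2(size(cc.A2), fill::zeros);
  for (unsigned t = 0; t < dX.n_rows; ++t)
    for (unsigned f = 0; f < dX.n_cols; ++f)
      dA2(cc.arg2(t, f), f) += dX(t, f);
  dA2.elem(find(cc.A2 == 0)).zeros();  // ReLU gate
  G[ix.c2w] += cc.Xc2.t() * dA2;
  G[ix.c2b].row(0) += sum(dA2, 0);
  mat dXc2 = dA2 * P[ix.c2w].t();
  mat dZ1(size(cc.Z1), fill::zeros);
  col2im_add(dXc2, c.K, c.F1, dZ1);

  // pool1 backward
  mat dA1(size(cc.A1), fill::zeros);
  for (unsigned t = 0; t < dZ1.n_rows; ++t)
    for (unsigned f = 0; f < dZ1.n_cols; ++f)
      dA1(cc.arg1(t, f), f) += dZ1(t, f);
  dA1.elem(find(cc.A1 == 0)).zeros();
  G[ix.c1w] += cc.Xc1.t() * dA1;
  G[ix.c1b].row(0) += sum(dA1, 0);
  mat dXc1 = dA1 * P[ix.c1w].t();
  mat dX0(size(cc.X0), fill::zeros);
  col2im_add(dXc1, c.K, c.D, dX0);

  for (int p = 0; p < c.L; ++p) G[ix.embed].row(cc.codes[p]) += dX0.row(p);
}

// [[Rcpp::export]]
arma::mat cpp_forward(const arma::imat& codes, const Rcpp::List& params,
                      const Rcpp::List& config) {
  const NetConfig c = parse_config(config);
  std::vector<mat> P = list_to_params(params);
  const mat pe = positional_encoding_mat(c.L, c.D);
  mat out(codes.n_rows, c.T);
  for (unsigned i = 0; i < codes.n_rows; ++i) {
    ivec row = codes.row(i).t();
    out.row(i) = forward_one(row, P, c, pe, nullptr);
  }
  return out;
}

static double bce_loss(const mat& probs, const mat& y) {
  const double eps = 1e-12;
  mat p = clamp(probs, eps, 1.0 - eps);
  return -accu(y % log(p) + (1.0 - y) % log(1.0 - p)) / (p.n_rows * p.n_cols);
}

// [[Rcpp::export]]
double cpp_bce(const arma::mat& probs, const arma::mat& labels) {
  return bce_loss(probs, labels);
}

// mean-BCE loss and its gradient w.r.t. every parameter (for gradient
// checks and tests)
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(const arma::imat& codes, const arma::mat& labels,
                         const Rcpp::List& params, const Rcpp::List& config) {
  const NetConfig c = parse_config(config);
  std::vector<mat> P = list_to_params(params);
  const Rcpp::CharacterVector pnames = params.attr("names");
  const mat pe = positional_encoding_mat(c.L, c.D);
  const int N = codes.n_rows;
  std::vector<mat> G(P.size());
  for (size_t i = 0; i < P.size(); ++i) G[i] = zeros(size(P[i]));
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    FwdCache cc;
    ivec row = codes.row(i).t();
    rowvec probs = forward_one(row, P, c, pe, &cc);
    rowvec y = labels.row(i);
    const double eps = 1e-12;
    rowvec pcl = clamp(probs, eps, 1.0 - eps);
    loss += -accu(y % log(pcl) + (1.0 - y) % log(1.0 - pcl)) / c.T;
    rowvec dlogits = (probs - y) / (double)(c.T * N);
    backward_one(cc, dlogits, P, c, G);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss / N,
                            Rcpp::Named("grads") = params_to_list(G, pnames));
}

// [[Rcpp::export]]
Rcpp::List cpp_train(const arma::imat& codes, const arma::mat& labels,
                     const arma::imat& val_codes, const arma::mat& val_labels,
                     const Rcpp::List& params, const Rcpp::List& config,
                     int epochs, int batch_size, double lr, int seed,
                     int patience = 0, double weight_decay = 0.0,
                     double dropout = 0.0) {
  const NetConfig c = parse_config(config);
  std::vector<mat> P = list_to_params(params);
  const Rcpp::CharacterVector pnames = params.attr("names");
  const mat pe = positional_encoding_mat(c.L, c.D);
  const int N = codes.n_rows;
  if (N == 0) Rcpp::stop("empty training set");
  if ((int)labels.n_rows != N) Rcpp::stop("labels/codes row mismatch");

  std::vector<mat> M(P.size()), V(P.size()), G(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    M[i] = zeros(size(P[i]));
    V[i] = zeros(size(P[i]));
    G[i] = zeros(size(P[i]));
  }
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  long step = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::vector<double> train_losses, val_losses;
  Rcpp::List val_prob_log(epochs);
  double best_val = datum::inf;
  int since_best = 0;
  int ran = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle (fixed algorithm for cross-platform determinism)
    for (int i = N - 1; i > 0; --i) {
      std::uniform_int_distribution<int> U(0, i);
      std::swap(order[i], order[U(rng)]);
    }
    double ep_loss = 0.0;
    int n_seen = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int stop_ = std::min(start + batch_size, N);
      const int B = stop_ - start;
      for (auto& g : G) g.zeros();
      for (int b = start; b < stop_; ++b) {
        const int i = order[b];
        FwdCache cc;
        ivec row = codes.row(i).t();
        vec dmask;
        const vec* dm = nullptr;
        if (dropout > 0.0) {
          dmask.set_size(c.P2);
          std::uniform_real_distribution<double> U01(0.0, 1.0);
          const double keep = 1.0 - dropout;
          for (int t = 0; t < c.P2; ++t)
            dmask[t] = U01(rng) < keep ? 1.0 / keep : 0.0;
          dm = &dmask;
        }
        rowvec probs = forward_one(row, P, c, pe, &cc, dm);
        rowvec y = labels.row(i);
        const double eps = 1e-12;
        rowvec pcl = clamp(probs, eps, 1.0 - eps);
        ep_loss += -accu(y % log(pcl) + (1.0 - y) % log(1.0 - pcl)) / c.T;
        // d(mean BCE)/dlogits for this sample, averaged over batch later
        rowvec dlogits = (probs - y) / (double)(c.T * B);
        backward_one(cc, dlogits, P, c, G);
      }
      n_seen += B;
      ++step;
      const double corr = std::sqrt(1.0 - std::pow(b2, (double)step)) /
                          (1.0 - std::pow(b1, (double)step));
      for (size_t i = 0; i < P.size(); ++i) {
        M[i] = b1 * M[i] + (1.0 - b1) * G[i];
        V[i] = b2 * V[i] + (1.0 - b2) * square(G[i]);
        P[i] -= lr * (corr * M[i] / (sqrt(V[i]) + adam_eps) +
                      weight_decay * P[i]);
      }
      Rcpp::checkUserInterrupt();
    }
    train_losses.push_back(ep_loss / n_seen);
    ++ran;

    if (val_codes.n_rows > 0) {
      mat vp(val_codes.n_rows, c.T);
      for (unsigned i = 0; i < val_codes.n_rows; ++i) {
        ivec row = val_codes.row(i).t();
        vp.row(i) = forward_one(row, P, c, pe, nullptr);
      }
      const double vl = bce_loss(vp, val_labels);
      val_losses.push_back(vl);
      val_prob_log[ep] = Rcpp::wrap(vp);
      if (patience > 0) {
        if (vl < best_val - 1e-12) { best_val = vl; since_best = 0; }
        else if (++since_best >= patience) break;
      }
    } else {
      val_losses.push_back(NA_REAL);
      val_prob_log[ep] = R_NilValue;
    }
  }

  Rcpp::List vp_out(ran);
  for (int i = 0; i < ran; ++i) vp_out[i] = val_prob_log[i];
  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(P, pnames),
      Rcpp::Named("train_loss") = train_losses,
      Rcpp::Named("val_loss") = val_losses,
      Rcpp::Named("val_probs") = vp_out);
}
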