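// Transformer encoder forward/backward for peptide -> binding free energy.
//
// Fixed architecture: token embedding + fixed sinusoidal positional
// encoding, N post-norm self-attention blocks (MHA -> add&norm -> FFN ->
// add&norm), then an affine head on the [CLS] latent producing a scalar
// dG per sequence. Gradients are exact analytic backprop; the test suite
// checks them against central finite differences.
//
// Activations use a position-major layout: row t*B + s holds position t
// of sequence s, so each position is a contiguous B-row block and
// attention reduces to T*T block operations instead of per-sequence
// loops.
//
// Two entry points: a list-based one (.nn_core) used for prediction and
// gradient testing, and a flat-vector one (.nn_step_flat) used in the
// training loops, which reads parameters from the packed vector the R
// optimiser maintains (canonical order: embedding; per block Wq,bq,Wk,
// bk,Wv,bv,Wo,bo,ln1_g,ln1_b,W1,c1,W2,c2,ln2_g,ln2_b; head_w; head_b;
// binary offset) and writes the gradient into the same layout without
// intermediate copies.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;

struct LnCache {
  arma::mat xhat;
  arma::vec inv_sd;
};

static arma::mat ln_forward(const arma::mat& X, const arma::vec& g,
                            const arma::vec& b, LnCache& c) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat Xc = X.each_col() - mu;
  arma::vec var = arma::mean(Xc % Xc, 1);
  c.inv_sd = 1.0 / arma::sqrt(var + LN_EPS);
  c.xhat = Xc.each_col() % c.inv_sd;
  arma::mat Y = c.xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

static arma::mat ln_backward(const arma::mat& dY, const LnCache& c,
                             const arma::vec& g, arma::vec& dg,
                             arma::vec& db) {
  dg += arma::sum(dY % c.xhat, 0).t();
  db += arma::sum(dY, 0).t();
  arma::mat dxhat = dY.each_row() % g.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % c.xhat, 1);
  arma::mat dX = dxhat.each_col() - m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.inv_sd;
  return dX;
}

struct LayerParams {
  arma::mat Wq, Wk, Wv, Wo, W1, W2;
  arma::vec bq, bk, bv, bo, c1, c2, g1, b1, g2, b2;
};

struct LayerGrads {
  arma::mat Wq, Wk, Wv, Wo, W1, W2;
  arma::vec bq, bk, bv, bo, c1, c2, g1, b1, g2, b2;
};

struct LayerCache {
  arma::mat Xin, Q, K, V, H, X1, F1, Xout;
  LnCache ln1, ln2;
  arma::cube A; // (B*T) x T x heads
};

struct Net {
  arma::mat emb, pe;
  std::vector<LayerParams> layers;
  arma::vec head_w;
  double head_b;
  int heads, B, T, d, dk;
  double scale;
  IntegerMatrix tokens;
  std::vector<LayerCache> cache;
  arma::mat X0;
  arma::vec dg;

  void forward() {
    const int n = B * T;
    arma::mat X(n, d);
    for (int t = 0; t < T; ++t) {
      arma::uvec ids(B);
      for (int s = 0; s < B; ++s) ids(s) = tokens(s, t);
      X.rows(t * B, t * B + B - 1) = emb.rows(ids);
      X.rows(t * B, t * B + B - 1).each_row() += pe.row(t);
    }
    X0 = X;
    cache.resize(layers.size());
    for (size_t l = 0; l < layers.size(); ++l) {
      const LayerParams& P = layers[l];
      LayerCache& C = cache[l];
      C.Xin = X;
      C.Q = X * P.Wq; C.Q.each_row() += P.bq.t();
      C.K = X * P.Wk; C.K.each_row() += P.bk.t();
      C.V = X * P.Wv; C.V.each_row() += P.bv.t();
      C.H.set_size(n, d);
      C.A.set_size(n, T, heads);
      for (int h = 0; h < heads; ++h) {
        const arma::span ch(h * dk, h * dk + dk - 1);
        arma::mat S(n, T);
        for (int i = 0; i < T; ++i) {
          const arma::span ri(i * B, i * B + B - 1);
          const arma::mat Qi = C.Q(ri, ch);
          for (int j = 0; j < T; ++j) {
            const arma::span rj(j * B, j * B + B - 1);
            S(ri, arma::span(j, j)) =
                scale * arma::sum(Qi % C.K(rj, ch), 1);
          }
        }
        // stable row softmax over the T columns
        arma::vec mx = arma::max(S, 1);
        S.each_col() -= mx;
        arma::mat A = arma::exp(S);
        arma::vec rs = arma::sum(A, 1);
        A.each_col() /= rs;
        C.A.slice(h) = A;
        for (int i = 0; i < T; ++i) {
          const arma::span ri(i * B, i * B + B - 1);
          arma::mat Hi(B, dk, arma::fill::zeros);
          for (int j = 0; j < T; ++j) {
            const arma::span rj(j * B, j * B + B - 1);
            arma::mat Vj = C.V(rj, ch);
            Hi += Vj.each_col() % A(ri, arma::span(j, j));
          }
          C.H(ri, ch) = Hi;
        }
      }
      arma::mat M = C.H * P.Wo;
      M.each_row() += P.bo.t();
      arma::mat R1 = C.Xin + M;
      C.X1 = ln_forward(R1, P.g1, P.b1, C.ln1);
      arma::mat F1pre = C.X1 * P.W1;
      F1pre.each_row() += P.c1.t();
      C.F1 = arma::clamp(F1pre, 0.0, arma::datum::inf); // ReLU
      arma::mat F2 = C.F1 * P.W2;
      F2.each_row() += P.c2.t();
      arma::mat R2 = C.X1 + F2;
      C.Xout = ln_forward(R2, P.g2, P.b2, C.ln2);
      X = C.Xout;
    }
    // [CLS] rows are the first contiguous block (t = 0)
    dg = X.rows(0, B - 1) * head_w + head_b;
  }

  // Backward pass; fills `glayers` (preallocated, zeroed, one per block),
  // `demb`, `d_head_w` (zeroed) and the scalar head-bias gradient.
  double backward(const arma::vec& gdg, arma::mat& demb,
                  std::vector<LayerGrads>& glayers, arma::vec& d_head_w) {
    const int n = B * T;
    const arma::mat& Xtop = layers.empty() ? X0 : cache.back().Xout;
    arma::mat dX(n, d, arma::fill::zeros);
    dX.rows(0, B - 1) = gdg * head_w.t();
    d_head_w += Xtop.rows(0, B - 1).t() * gdg;
    double d_head_b = arma::accu(gdg);

    for (int l = (int)layers.size() - 1; l >= 0; --l) {
      const LayerParams& P = layers[l];
      LayerCache& C = cache[l];
      LayerGrads& G = glayers[l];

      arma::mat dR2 = ln_backward(dX, C.ln2, P.g2, G.g2, G.b2);
      arma::mat dX1 = dR2;
      G.W2 += C.F1.t() * dR2;
      G.c2 += arma::sum(dR2, 0).t();
      arma::mat dF1 = dR2 * P.W2.t();
      dF1 %= arma::conv_to<arma::mat>::from(C.F1 > 0);
      G.W1 += C.X1.t() * dF1;
      G.c1 += arma::sum(dF1, 0).t();
      dX1 += dF1 * P.W1.t();

      arma::mat dR1 = ln_backward(dX1, C.ln1, P.g1, G.g1, G.b1);
      arma::mat dXin = dR1;
      G.Wo += C.H.t() * dR1;
      G.bo += arma::sum(dR1, 0).t();
      arma::mat dH = dR1 * P.Wo.t();

      arma::mat dQ(n, d, arma::fill::zeros), dK(n, d, arma::fill::zeros),
          dV(n, d, arma::fill::zeros);
      for (int h = 0; h < heads; ++h) {
        const arma::span ch(h * dk, h * dk + dk - 1);
        const arma::mat& A = C.A.slice(h);
        arma::mat dA(n, T);
        for (int i = 0; i < T; ++i) {
          const arma::span ri(i * B, i * B + B - 1);
          const arma::mat dHi = dH(ri, ch);
          for (int j = 0; j < T; ++j) {
            const arma::span rj(j * B, j * B + B - 1);
            dA(ri, arma::span(j, j)) = arma::sum(dHi % C.V(rj, ch), 1);
            dV(rj, ch) += dHi.each_col() % A(ri, arma::span(j, j));
          }
        }
        arma::vec rowdot = arma::sum(dA % A, 1);
        arma::mat dS = A % (dA.each_col() - rowdot);
        for (int i = 0; i < T; ++i) {
          const arma::span ri(i * B, i * B + B - 1);
          const arma::mat Qi = C.Q(ri, ch);
          arma::mat dQi(B, dk, arma::fill::zeros);
          for (int j = 0; j < T; ++j) {
            const arma::span rj(j * B, j * B + B - 1);
            const arma::vec ds_ij = dS(ri, arma::span(j, j));
            dQi += scale * (C.K(rj, ch).each_col() % ds_ij);
            dK(rj, ch) += scale * (Qi.each_col() % ds_ij);
          }
          dQ(ri, ch) += dQi;
        }
      }
      G.Wq += C.Xin.t() * dQ;
      G.bq += arma::sum(dQ, 0).t();
      G.Wk += C.Xin.t() * dK;
      G.bk += arma::sum(dK, 0).t();
      G.Wv += C.Xin.t() * dV;
      G.bv += arma::sum(dV, 0).t();
      dXin += dQ * P.Wq.t() + dK * P.Wk.t() + dV * P.Wv.t();
      dX = dXin;
    }

    for (int t = 0; t < T; ++t)
      for (int s = 0; s < B; ++s)
        demb.row(tokens(s, t)) += dX.row(t * B + s);
    return d_head_b;
  }
};

static LayerParams read_layer(List L) {
  LayerParams p;
  p.Wq = as<arma::mat>(L["Wq"]); p.bq = as<arma::vec>(L["bq"]);
  p.Wk = as<arma::mat>(L["Wk"]); p.bk = as<arma::vec>(L["bk"]);
  p.Wv = as<arma::mat>(L["Wv"]); p.bv = as<arma::vec>(L["bv"]);
  p.Wo = as<arma::mat>(L["Wo"]); p.bo = as<arma::vec>(L["bo"]);
  p.g1 = as<arma::vec>(L["ln1_g"]); p.b1 = as<arma::vec>(L["ln1_b"]);
  p.W1 = as<arma::mat>(L["W1"]); p.c1 = as<arma::vec>(L["c1"]);
  p.W2 = as<arma::mat>(L["W2"]); p.c2 = as<arma::vec>(L["c2"]);
  p.g2 = as<arma::vec>(L["ln2_g"]); p.b2 = as<arma::vec>(L["ln2_b"]);
  return p;
}

static Net build_net(List params, IntegerMatrix tokens, int heads) {
  Net net;
  net.emb = as<arma::mat>(params["emb"]);
  net.pe = as<arma::mat>(params["pe"]);
  List layers = params["layers"];
  for (int l = 0; l < layers.size(); ++l)
    net.layers.push_back(read_layer(layers[l]));
  net.head_w = as<arma::vec>(params["head_w"]);
  net.head_b = as<double>(params["head_b"]);
  net.heads = heads;
  net.B = tokens.nrow();
  net.T = tokens.ncol();
  net.d = net.emb.n_cols;
  net.dk = net.d / heads;
  net.scale = 1.0 / std::sqrt((double)net.dk);
  net.tokens = tokens;
  return net;
}

// Plain forward (+ optional backward against a supplied dLoss/d(dG)).
// [[Rcpp::export(name = ".nn_core")]]
List nn_core(List params, IntegerMatrix tokens, int heads,
             NumericVector gdg, bool want_grad) {
  Net net = build_net(params, tokens, heads);
  net.forward();
  if (!want_grad) return List::create(_["dg"] = net.dg);

  arma::mat demb(net.emb.n_rows, net.d, arma::fill::zeros);
  arma::vec d_head_w(net.d, arma::fill::zeros);
  std::vector<LayerGrads> G(net.layers.size());
  for (size_t l = 0; l < G.size(); ++l) {
    G[l].Wq.zeros(net.d, net.d); G[l].bq.zeros(net.d);
    G[l].Wk.zeros(net.d, net.d); G[l].bk.zeros(net.d);
    G[l].Wv.zeros(net.d, net.d); G[l].bv.zeros(net.d);
    G[l].Wo.zeros(net.d, net.d); G[l].bo.zeros(net.d);
    G[l].g1.zeros(net.d); G[l].b1.zeros(net.d);
    G[l].W1.zeros(net.d, net.layers[l].W1.n_cols);
    G[l].c1.zeros(net.layers[l].W1.n_cols);
    G[l].W2.zeros(net.layers[l].W1.n_cols, net.d); G[l].c2.zeros(net.d);
    G[l].g2.zeros(net.d); G[l].b2.zeros(net.d);
  }
  double d_head_b = net.backward(as<arma::vec>(gdg), demb, G, d_head_w);

  List grad_layers(net.layers.size());
  for (size_t l = 0; l < G.size(); ++l) {
    grad_layers[l] = List::create(
        _["Wq"] = G[l].Wq, _["bq"] = G[l].bq, _["Wk"] = G[l].Wk,
        _["bk"] = G[l].bk, _["Wv"] = G[l].Wv, _["bv"] = G[l].bv,
        _["Wo"] = G[l].Wo, _["bo"] = G[l].bo, _["ln1_g"] = G[l].g1,
        _["ln1_b"] = G[l].b1, _["W1"] = G[l].W1, _["c1"] = G[l].c1,
        _["W2"] = G[l].W2, _["c2"] = G[l].c2, _["ln2_g"] = G[l].g2,
        _["ln2_b"] = G[l].b2);
  }
  List grads = List::create(_["emb"] = demb, _["layers"] = grad_layers,
                            _["head_w"] = d_head_w, _["head_b"] = d_head_b);
  return List::create(_["dg"] = net.dg, _["grads"] = grads);
}

// Fused training step on the packed parameter vector. The first
// length(y) rows of `tokens` are binary records (BCE on binding prob
// 1/(1+exp(dG+offset))), the remaining rows carry `targets` (k * MSE).
// Returns the dG vector, the two loss components, and the gradient of
// the total loss packed in the same layout as `theta`.
// [[Rcpp::export(name = ".nn_step_flat")]]
List nn_step_flat(NumericVector theta, NumericMatrix pe, IntegerMatrix tokens,
                  int heads, int n_layers, int dff, int vocab,
                  NumericVector y, NumericVector targets, double k) {
  const int d = pe.ncol();
  double* tp = REAL(theta);
  size_t off = 0;
  auto mat_at = [&](size_t n_r, size_t n_c) {
    arma::mat m(tp + off, n_r, n_c, false, true);
    off += n_r * n_c;
    return m;
  };
  auto vec_at = [&](size_t n_el) {
    arma::vec v(tp + off, n_el, false, true);
    off += n_el;
    return v;
  };

  Net net;
  net.emb = mat_at(vocab, d);
  net.pe = arma::mat(REAL(pe), pe.nrow(), d, false, true);
  for (int l = 0; l < n_layers; ++l) {
    LayerParams p;
    p.Wq = mat_at(d, d); p.bq = vec_at(d);
    p.Wk = mat_at(d, d); p.bk = vec_at(d);
    p.Wv = mat_at(d, d); p.bv = vec_at(d);
    p.Wo = mat_at(d, d); p.bo = vec_at(d);
    p.g1 = vec_at(d); p.b1 = vec_at(d);
    p.W1 = mat_at(d, dff); p.c1 = vec_at(dff);
    p.W2 = mat_at(dff, d); p.c2 = vec_at(d);
    p.g2 = vec_at(d); p.b2 = vec_at(d);
    net.layers.push_back(p);
  }
  net.head_w = vec_at(d);
  const double head_b = tp[off];
  const double offset = tp[off + 1];
  if (off + 2 != (size_t)theta.size()) stop("theta has the wrong length");
  net.head_b = head_b;
  net.heads = heads;
  net.B = tokens.nrow();
  net.T = tokens.ncol();
  net.d = d;
  net.dk = d / heads;
  net.scale = 1.0 / std::sqrt((double)net.dk);
  net.tokens = tokens;

  net.forward();

  const int n_bce = y.size(), n_mse = targets.size();
  if (n_bce + n_mse != net.B) stop("labels + targets must cover the batch");
  arma::vec gdg(net.B, arma::fill::zeros);
  double loss_bce = 0, loss_mse = 0, g_offset = 0;
  if (n_bce > 0) {
    arma::vec dgb = net.dg.subvec(0, n_bce - 1);
    arma::vec p = 1.0 / (1.0 + arma::exp(dgb + offset));
    p = arma::clamp(p, 1e-12, 1 - 1e-12);
    const arma::vec yv = as<arma::vec>(y);
    loss_bce = -arma::mean(yv % arma::log(p) +
                           (1.0 - yv) % arma::log(1.0 - p));
    gdg.subvec(0, n_bce - 1) = (yv - p) / n_bce;
    g_offset = arma::accu(yv - p) / n_bce;
  }
  if (n_mse > 0) {
    arma::vec r = net.dg.subvec(n_bce, net.B - 1) - as<arma::vec>(targets);
    loss_mse = arma::mean(r % r);
    gdg.subvec(n_bce, net.B - 1) = k * 2.0 * r / n_mse;
  }

  arma::mat demb(vocab, d, arma::fill::zeros);
  arma::vec d_head_w(d, arma::fill::zeros);
  std::vector<LayerGrads> G(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    G[l].Wq.zeros(d, d); G[l].bq.zeros(d);
    G[l].Wk.zeros(d, d); G[l].bk.zeros(d);
    G[l].Wv.zeros(d, d); G[l].bv.zeros(d);
    G[l].Wo.zeros(d, d); G[l].bo.zeros(d);
    G[l].g1.zeros(d); G[l].b1.zeros(d);
    G[l].W1.zeros(d, dff); G[l].c1.zeros(dff);
    G[l].W2.zeros(dff, d); G[l].c2.zeros(d);
    G[l].g2.zeros(d); G[l].b2.zeros(d);
  }
  double d_head_b = net.backward(gdg, demb, G, d_head_w);

  // serialize the gradient into the theta layout
  NumericVector grad(theta.size());
  double* gp = REAL(grad);
  size_t goff = 0;
  auto put = [&](const double* src, size_t n_el) {
    std::memcpy(gp + goff, src, n_el * sizeof(double));
    goff += n_el;
  };
  put(demb.memptr(), demb.n_elem);
  for (int l = 0; l < n_layers; ++l) {
    put(G[l].Wq.memptr(), G[l].Wq.n_elem); put(G[l].bq.memptr(), d);
    put(G[l].Wk.memptr(), G[l].Wk.n_elem); put(G[l].bk.memptr(), d);
    put(G[l].Wv.memptr(), G[l].Wv.n_elem); put(G[l].bv.memptr(), d);
    put(G[l].Wo.memptr(), G[l].Wo.n_elem); put(G[l].bo.memptr(), d);
    put(G[l].g1.memptr(), d); put(G[l].b1.memptr(), d);
    put(G[l].W1.memptr(), G[l].W1.n_elem); put(G[l].c1.memptr(), dff);
    put(G[l].W2.memptr(), G[l].W2.n_elem); put(G[l].c2.memptr(), d);
    put(G[l].g2.memptr(), d); put(G[l].b2.memptr(), d);
  }
  put(d_head_w.memptr(), d);
  gp[goff++] = d_head_b;
  gp[goff++] = g_offset;

  return List::create(_["dg"] = net.dg, _["loss_bce"] = loss_bce,
                      _["loss_mse"] = loss_mse, _["grad"] = grad);
}
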