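// Small bidirectional transformer encoder for species sentences.
//
// Post-layer-norm blocks: X1 = LN1(X + Drop(Attn(X))),
// X2 = LN2(X1 + Drop(FFN(X1))). The masked-token decoder is tied to the
// input token embedding (logits = X2 * E' + b); the classifier head is a
// tanh pooling layer over the [CLS] position followed by a linear layer.
// Batches are flattened (variable-length sequences stacked row-wise) so all
// projections run as single GEMMs; attention works per sequence on small
// T x T matrices. Gradients are hand-derived; optimisation is Adam with
// global-norm gradient clipping.
//
// Parameter matrices are bound as Armadillo views over the R-owned memory
// (constructed in member-initializer lists / emplace_back so the advanced
// aux-memory constructors are used and updates happen in place).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::IntegerMatrix;
using Rcpp::IntegerVector;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

static const double LN_EPS = 1e-5;

static std::string nm(const char* base, int l) {
  return std::string(base) + "_" + std::to_string(l + 1);
}

static mat vm(List P, const std::string& n) {
  NumericMatrix x = P[n];
  return mat(x.begin(), x.nrow(), x.ncol(), false, true);
}
static vec vv(List P, const std::string& n) {
  NumericVector x = P[n];
  return vec(x.begin(), x.size(), false, true);
}
struct LayerP {
  mat Wq, Wk, Wv, Wo, W1, W2;
  vec bq, bk, bv, bo, b1, b2, g1, be1, g2, be2;
  LayerP(List P, int l)
    : Wq(vm(P, nm("Wq", l))), Wk(vm(P, nm("Wk", l))),
      Wv(vm(P, nm("Wv", l))), Wo(vm(P, nm("Wo", l))),
      W1(vm(P, nm("W1", l))), W2(vm(P, nm("W2", l))),
      bq(vv(P, nm("bq", l))), bk(vv(P, nm("bk", l))),
      bv(vv(P, nm("bv", l))), bo(vv(P, nm("bo", l))),
      b1(vv(P, nm("b1", l))), b2(vv(P, nm("b2", l))),
      g1(vv(P, nm("ln1g", l))), be1(vv(P, nm("ln1b", l))),
      g2(vv(P, nm("ln2g", l))), be2(vv(P, nm("ln2b", l))) {}
};

struct Model {
  mat tok_emb, pos_emb, Wp, Wc;
  vec out_b, bp, bc;
  std::vector<LayerP> layers;
  int V, H, A, F, L, C;
  Model(List P, int n_layers, int n_heads)
    : tok_emb(vm(P, "tok_emb")), pos_emb(vm(P, "pos_emb")),
      Wp(vm(P, "Wp")), Wc(vm(P, "Wc")),
      out_b(vv(P, "out_b")), bp(vv(P, "bp")), bc(vv(P, "bc")) {
    L = n_layers; A = n_heads;
    V = tok_emb.n_rows; H = tok_emb.n_cols;
    C = Wc.n_cols;
    layers.reserve(L);
    for (int l = 0; l < L; ++l) layers.emplace_back(P, l);
    F = L > 0 ? layers[0].W1.n_cols : 0;
  }
};

// ---- layer norm ------------------------------------------------------------

static void ln_forward(const mat& X, const vec& g, const vec& b,
                       mat& Y, mat& xhat, vec& istd) {
  vec mu = mean(X, 1);
  mat ctr = X.each_col() - mu;
  vec var = mean(square(ctr), 1);
  istd = 1.0 / sqrt(var + LN_EPS);
  xhat = ctr.each_col() % istd;
  Y = xhat.each_row() % g.t();
  Y.each_row() += b.t();
}

static void ln_backward(const mat& dY, const mat& xhat, const vec& istd,
                        const vec& g, mat& dX, vec& dg, vec& db) {
  dg += sum(dY % xhat, 0).t();
  db += sum(dY, 0).t();
  mat dxhat = dY.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  dX = (dxhat.each_col() - m1) - (xhat.each_col() % m2);
  dX.each_col() %= istd;
}

// ---- GELU ------------------------------------------------------------------

static mat gelu(const mat& X) {
  mat Y(X.n_rows, X.n_cols);
  const double is2 = 1.0 / std::sqrt(2.0);
  for (uword i = 0; i < X.n_elem; ++i)
    Y(i) = 0.5 * X(i) * (1.0 + std::erf(X(i) * is2));
  return Y;
}

static mat gelu_grad(const mat& X) {
  mat G(X.n_rows, X.n_cols);
  const double is2 = 1.0 / std::sqrt(2.0);
  const double isq2pi = 1.0 / std::sqrt(2.0 * M_PI);
  for (uword i = 0; i < X.n_elem; ++i) {
    double x = X(i);
    G(i) = 0.5 * (1.0 + std::erf(x * is2)) +
      x * isq2pi * std::exp(-0.5 * x * x);
  }
  return G;
}

// ---- batches ---------------------------------------------------------------

struct LayerCache {
  mat Xin, Q, K, Vv, Oin, X1, F1pre, F1, xhat1, xhat2, drop1, drop2;
  vec istd1, istd2;
  std::vector<cube> P;  // per sequence: T x T x heads
};

struct Batch {
  uvec offset, len;     // per-sequence start row and length in the flat stack
  uvec tok, pos;        // per flat row: token id, position
  int S;
};

static Batch make_batch(const IntegerMatrix& tokens,
                        const IntegerVector& lengths,
                        const uvec& rows) {
  Batch b;
  int n = rows.n_elem;
  b.offset.set_size(n); b.len.set_size(n);
  int S = 0;
  for (int i = 0; i < n; ++i) {
    b.offset(i) = S; b.len(i) = lengths[rows(i)];
    S += lengths[rows(i)];
  }
  b.S = S;
  b.tok.set_size(S); b.pos.set_size(S);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    int row = rows(i);
    for (int t = 0; t < lengths[row]; ++t) {
      b.tok(r) = tokens(row, t);
      b.pos(r) = t;
      ++r;
    }
  }
  return b;
}

static mat encoder_forward(const Model& m, const Batch& b,
                           std::vector<LayerCache>& caches, bool train,
                           double dropout, std::mt19937_64& rng) {
  mat X(b.S, m.H);
  for (int r = 0; r < b.S; ++r)
    X.row(r) = m.tok_emb.row(b.tok(r)) + m.pos_emb.row(b.pos(r));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double keep = 1.0 - dropout;
  int nseq = b.offset.n_elem;
  int dh = m.H / m.A;
  double scale = 1.0 / std::sqrt((double)dh);

  for (int l = 0; l < m.L; ++l) {
    const LayerP& p = m.layers[l];
    LayerCache& c = caches[l];
    c.Xin = X;
    c.Q = X * p.Wq; c.Q.each_row() += p.bq.t();
    c.K = X * p.Wk; c.K.each_row() += p.bk.t();
    c.Vv = X * p.Wv; c.Vv.each_row() += p.bv.t();
    c.Oin.set_size(b.S, m.H);
    c.P.assign(nseq, cube());
    for (int s = 0; s < nseq; ++s) {
      int o = b.offset(s);
      int T = b.len(s);
      cube& Pc = c.P[s];
      Pc.set_size(T, T, m.A);
      for (int a = 0; a < m.A; ++a) {
        mat Qa = c.Q.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1);
        mat Ka = c.K.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1);
        mat Va = c.Vv.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1);
        mat Sc = Qa * Ka.t() * scale;
        Sc.each_col() -= max(Sc, 1);
        mat Pa = exp(Sc);
        Pa.each_col() /= sum(Pa, 1);
        Pc.slice(a) = Pa;
        c.Oin.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1) = Pa * Va;
      }
    }
    mat attn_out = c.Oin * p.Wo;
    attn_out.each_row() += p.bo.t();
    if (train && dropout > 0) {
      c.drop1.set_size(b.S, m.H);
      for (uword i = 0; i < c.drop1.n_elem; ++i)
        c.drop1(i) = U(rng) < keep ? 1.0 / keep : 0.0;
      attn_out %= c.drop1;
    }
    mat X1;
    ln_forward(c.Xin + attn_out, p.g1, p.be1, X1, c.xhat1, c.istd1);
    c.X1 = X1;
    c.F1pre = X1 * p.W1;
    c.F1pre.each_row() += p.b1.t();
    c.F1 = gelu(c.F1pre);
    mat ffn_out = c.F1 * p.W2;
    ffn_out.each_row() += p.b2.t();
    if (train && dropout > 0) {
      c.drop2.set_size(b.S, m.H);
      for (uword i = 0; i < c.drop2.n_elem; ++i)
        c.drop2(i) = U(rng) < keep ? 1.0 / keep : 0.0;
      ffn_out %= c.drop2;
    }
    mat X2;
    ln_forward(X1 + ffn_out, p.g2, p.be2, X2, c.xhat2, c.istd2);
    X = X2;
  }
  return X;
}

// ---- gradients -------------------------------------------------------------

struct LayerG {
  mat Wq, Wk, Wv, Wo, W1, W2;
  vec bq, bk, bv, bo, b1, b2, g1, be1, g2, be2;
};

struct Grads {
  mat tok_emb, pos_emb, Wp, Wc;
  vec out_b, bp, bc;
  std::vector<LayerG> layers;
};

static Grads zero_grads(const Model& m) {
  Grads g;
  g.tok_emb.zeros(m.V, m.H);
  g.pos_emb.zeros(m.pos_emb.n_rows, m.H);
  g.layers.resize(m.L);
  for (int l = 0; l < m.L; ++l) {
    LayerG& p = g.layers[l];
    p.Wq.zeros(m.H, m.H); p.Wk.zeros(m.H, m.H); p.Wv.zeros(m.H, m.H);
    p.Wo.zeros(m.H, m.H);
    p.W1.zeros(m.H, m.F); p.W2.zeros(m.F, m.H);
    p.bq.zeros(m.H); p.bk.zeros(m.H); p.bv.zeros(m.H); p.bo.zeros(m.H);
    p.b1.zeros(m.F); p.b2.zeros(m.H);
    p.g1.zeros(m.H); p.be1.zeros(m.H); p.g2.zeros(m.H); p.be2.zeros(m.H);
  }
  g.out_b.zeros(m.V);
  g.Wp.zeros(m.H, m.H); g.bp.zeros(m.H);
  g.Wc.zeros(m.H, m.Wc.n_cols); g.bc.zeros(m.Wc.n_cols);
  return g;
}

static void encoder_backward(const Model& m, const Batch& b,
                             std::vector<LayerCache>& caches,
                             mat dX, Grads& g, double dropout, bool train) {
  int nseq = b.offset.n_elem;
  int dh = m.H / m.A;
  double scale = 1.0 / std::sqrt((double)dh);
  for (int l = m.L - 1; l >= 0; --l) {
    const LayerP& p = m.layers[l];
    LayerCache& c = caches[l];
    LayerG& gl = g.layers[l];
    mat dz2;
    ln_backward(dX, c.xhat2, c.istd2, p.g2, dz2, gl.g2, gl.be2);
    mat dffn = dz2;
    if (train && dropout > 0) dffn %= c.drop2;
    gl.W2 += c.F1.t() * dffn;
    gl.b2 += sum(dffn, 0).t();
    mat dF1 = dffn * p.W2.t();
    mat dF1pre = dF1 % gelu_grad(c.F1pre);
    gl.W1 += c.X1.t() * dF1pre;
    gl.b1 += sum(dF1pre, 0).t();
    mat dX1 = dz2 + dF1pre * p.W1.t();
    mat dz1;
    ln_backward(dX1, c.xhat1, c.istd1, p.g1, dz1, gl.g1, gl.be1);
    mat dattn = dz1;
    if (train && dropout > 0) dattn %= c.drop1;
    gl.Wo += c.Oin.t() * dattn;
    gl.bo += sum(dattn, 0).t();
    mat dOin = dattn * p.Wo.t();
    mat dQ(b.S, m.H, fill::zeros), dK(b.S, m.H, fill::zeros),
        dV(b.S, m.H, fill::zeros);
    for (int s = 0; s < nseq; ++s) {
      int o = b.offset(s);
      int T = b.len(s);
      for (int a = 0; a < m.A; ++a) {
        mat Qa = c.Q.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1);
        mat Ka = c.K.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1);
        mat Va = c.Vv.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1);
        mat dCtx = dOin.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1);
        const mat& Pa = c.P[s].slice(a);
        mat dP = dCtx * Va.t();
        dV.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1) += Pa.t() * dCtx;
        vec rowdot = sum(dP % Pa, 1);
        mat dS = Pa % (dP.each_col() - rowdot);
        dQ.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1) += dS * Ka * scale;
        dK.submat(o, a * dh, o + T - 1, (a + 1) * dh - 1) +=
          dS.t() * Qa * scale;
      }
    }
    gl.Wq += c.Xin.t() * dQ; gl.bq += sum(dQ, 0).t();
    gl.Wk += c.Xin.t() * dK; gl.bk += sum(dK, 0).t();
    gl.Wv += c.Xin.t() * dV; gl.bv += sum(dV, 0).t();
    dX = dz1 + dQ * p.Wq.t() + dK * p.Wk.t() + dV * p.Wv.t();
  }
  for (int r = 0; r < b.S; ++r) {
    g.tok_emb.row(b.tok(r)) += dX.row(r);
    g.pos_emb.row(b.pos(r)) += dX.row(r);
  }
}

// ---- Adam ------------------------------------------------------------------

// Parameter, first/second-moment views (into R memory) plus matching grads.
struct AdamState {
  std::vector<mat> p, m, v;
  std::vector<mat*> g;
  // emplace with raw aux-memory constructor args so the vector elements are
  // genuine views (a moved/copied aux matrix would silently own fresh memory)
  void emp(std::vector<mat>& dst, SEXP s, bool as_col) {
    if (as_col) {
      NumericVector x(s);
      dst.emplace_back(x.begin(), (uword)x.size(), (uword)1, false, true);
    } else {
      NumericMatrix x(s);
      dst.emplace_back(x.begin(), (uword)x.nrow(), (uword)x.ncol(), false,
                       true);
    }
  }
  void bind_mat(List P, List am, List av, const std::string& n, mat& grad) {
    emp(p, P[n], false); emp(m, am[n], false); emp(v, av[n], false);
    g.push_back(&grad);
  }
  void bind_vec(List P, List am, List av, const std::string& n, vec& grad) {
    emp(p, P[n], true); emp(m, am[n], true); emp(v, av[n], true);
    g.push_back(static_cast<mat*>(&grad));  // arma::vec derives from mat
  }
};

static AdamState adam_bind(List P, List am, List av, const Model& m,
                           Grads& g) {
  AdamState st;
  size_t np = 4 + 16 * m.L + 3;
  st.p.reserve(np); st.m.reserve(np); st.v.reserve(np); st.g.reserve(np);
  st.bind_mat(P, am, av, "tok_emb", g.tok_emb);
  st.bind_mat(P, am, av, "pos_emb", g.pos_emb);
  for (int l = 0; l < m.L; ++l) {
    LayerG& gl = g.layers[l];
    st.bind_mat(P, am, av, nm("Wq", l), gl.Wq);
    st.bind_vec(P, am, av, nm("bq", l), gl.bq);
    st.bind_mat(P, am, av, nm("Wk", l), gl.Wk);
    st.bind_vec(P, am, av, nm("bk", l), gl.bk);
    st.bind_mat(P, am, av, nm("Wv", l), gl.Wv);
    st.bind_vec(P, am, av, nm("bv", l), gl.bv);
    st.bind_mat(P, am, av, nm("Wo", l), gl.Wo);
    st.bind_vec(P, am, av, nm("bo", l), gl.bo);
    st.bind_mat(P, am, av, nm("W1", l), gl.W1);
    st.bind_vec(P, am, av, nm("b1", l), gl.b1);
    st.bind_mat(P, am, av, nm("W2", l), gl.W2);
    st.bind_vec(P, am, av, nm("b2", l), gl.b2);
    st.bind_vec(P, am, av, nm("ln1g", l), gl.g1);
    st.bind_vec(P, am, av, nm("ln1b", l), gl.be1);
    st.bind_vec(P, am, av, nm("ln2g", l), gl.g2);
    st.bind_vec(P, am, av, nm("ln2b", l), gl.be2);
  }
  st.bind_vec(P, am, av, "out_b", g.out_b);
  st.bind_mat(P, am, av, "Wp", g.Wp);
  st.bind_vec(P, am, av, "bp", g.bp);
  st.bind_mat(P, am, av, "Wc", g.Wc);
  st.bind_vec(P, am, av, "bc", g.bc);
  return st;
}

static void adam_step(AdamState& st, double lr, double t, double clip) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double sq = 0;
  for (size_t i = 0; i < st.g.size(); ++i) sq += accu(square(*st.g[i]));
  double norm = std::sqrt(sq);
  double sc = (clip > 0 && norm > clip) ? clip / norm : 1.0;
  double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (size_t i = 0; i < st.g.size(); ++i) {
    mat& G = *st.g[i];
    if (sc != 1.0) G *= sc;
    st.m[i] = b1 * st.m[i] + (1 - b1) * G;
    st.v[i] = b2 * st.v[i] + (1 - b2) * square(G);
    st.p[i] -= lr * (st.m[i] / c1) / (sqrt(st.v[i] / c2) + eps);
    G.zeros();
  }
}

// ---- training --------------------------------------------------------------

// One pass over the corpus. mode 0: masked-token objective; `target` is an
// IntegerMatrix of original ids at selected positions (-1 = ignore).
// mode 1: sequence classification; `target` is an IntegerVector of 0-based
// class ids. Returns the mean per-item loss and the updated Adam step count.
// Learning-rate schedule: linear warmup over warmup_steps, then linear
// decay to zero at total_steps (the step counter adam_t carries over
// between epochs). total_steps <= 0 disables the schedule (constant lr).
// [[Rcpp::export]]
List cpp_train_epoch(List params, List adam_m, List adam_v,
                     IntegerMatrix tokens, SEXP target,
                     IntegerVector lengths, int n_layers, int n_heads,
                     int batch_size, double lr, double dropout, int mode,
                     int seed, double adam_t, double clip,
                     double total_steps, double warmup_steps) {
  Model m(params, n_layers, n_heads);
  Grads g = zero_grads(m);
  AdamState st = adam_bind(params, adam_m, adam_v, m, g);
  std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 17);
  int n = tokens.nrow();
  uvec order = regspace<uvec>(0, n - 1);
  for (int i = n - 1; i > 0; --i) {
    std::uniform_int_distribution<int> d(0, i);
    std::swap(order(i), order(d(rng)));
  }
  IntegerMatrix labels;
  IntegerVector classes;
  if (mode == 0) labels = IntegerMatrix(target);
  else classes = IntegerVector(target);

  double total_loss = 0;
  long total_items = 0;
  double t = adam_t;
  std::vector<LayerCache> caches(m.L);

  for (int start = 0; start < n; start += batch_size) {
    int end = std::min(start + batch_size, n);
    uvec rows = order.subvec(start, end - 1);
    Batch b = make_batch(tokens, lengths, rows);
    mat X = encoder_forward(m, b, caches, true, dropout, rng);
    mat dX(b.S, m.H, fill::zeros);

    if (mode == 0) {
      std::vector<uword> lab_rows;
      std::vector<int> lab_ids;
      for (uword i = 0; i < rows.n_elem; ++i) {
        int row = rows(i);
        for (uword tpos = 0; tpos < b.len(i); ++tpos) {
          int y = labels(row, tpos);
          if (y >= 0) {
            lab_rows.push_back(b.offset(i) + tpos);
            lab_ids.push_back(y);
          }
        }
      }
      int nl = lab_rows.size();
      if (nl == 0) continue;
      uvec li(nl);
      for (int i = 0; i < nl; ++i) li(i) = lab_rows[i];
      mat Xl = X.rows(li);
      mat logits = Xl * m.tok_emb.t();
      logits.each_row() += m.out_b.t();
      logits.each_col() -= max(logits, 1);
      mat P = exp(logits);
      P.each_col() /= sum(P, 1);
      for (int i = 0; i < nl; ++i)
        total_loss -= std::log(P(i, lab_ids[i]) + 1e-12);
      total_items += nl;
      mat dlogits = P;
      for (int i = 0; i < nl; ++i) dlogits(i, lab_ids[i]) -= 1.0;
      dlogits /= (double)nl;
      g.out_b += sum(dlogits, 0).t();
      g.tok_emb += dlogits.t() * Xl;
      mat dXl = dlogits * m.tok_emb;
      for (int i = 0; i < nl; ++i) dX.row(li(i)) = dXl.row(i);
    } else {
      int B = rows.n_elem;
      mat Xc(B, m.H);
      for (int i = 0; i < B; ++i) Xc.row(i) = X.row(b.offset(i));
      mat pre = Xc * m.Wp;
      pre.each_row() += m.bp.t();
      mat pooled = tanh(pre);
      mat logits = pooled * m.Wc;
      logits.each_row() += m.bc.t();
      logits.each_col() -= max(logits, 1);
      mat P = exp(logits);
      P.each_col() /= sum(P, 1);
      for (int i = 0; i < B; ++i)
        total_loss -= std::log(P(i, classes[rows(i)]) + 1e-12);
      total_items += B;
      mat dlogits = P;
      for (int i = 0; i < B; ++i) dlogits(i, classes[rows(i)]) -= 1.0;
      dlogits /= (double)B;
      g.Wc += pooled.t() * dlogits;
      g.bc += sum(dlogits, 0).t();
      mat dpooled = dlogits * m.Wc.t();
      mat dpre = dpooled % (1.0 - square(pooled));
      g.Wp += Xc.t() * dpre;
      g.bp += sum(dpre, 0).t();
      mat dXc = dpre * m.Wp.t();
      for (int i = 0; i < B; ++i) dX.row(b.offset(i)) = dXc.row(i);
    }

    encoder_backward(m, b, caches, dX, g, dropout, true);
    t += 1.0;
    double lr_t = lr;
    if (total_steps > 0) {
      if (t <= warmup_steps && warmup_steps > 0)
        lr_t = lr * t / warmup_steps;
      else
        lr_t = lr * std::max(0.0, (total_steps - t) /
                                    std::max(total_steps - warmup_steps, 1.0));
    }
    adam_step(st, lr_t, t, clip);
  }
  return List::create(Rcpp::Named("loss") = total_loss /
                        std::max<long>(total_items, 1),
                      Rcpp::Named("adam_t") = t);
}

// Loss and analytic gradients over one full batch (no update); used to
// validate the hand-derived backward pass against finite differences.
// [[Rcpp::export]]
List cpp_loss_grads(List params, IntegerMatrix tokens, SEXP target,
                    IntegerVector lengths, int n_layers, int n_heads,
                    int mode) {
  Model m(params, n_layers, n_heads);
  Grads g = zero_grads(m);
  std::mt19937_64 rng(1);
  int n = tokens.nrow();
  uvec rows = regspace<uvec>(0, n - 1);
  Batch b = make_batch(tokens, lengths, rows);
  std::vector<LayerCache> caches(m.L);
  mat X = encoder_forward(m, b, caches, false, 0.0, rng);
  mat dX(b.S, m.H, fill::zeros);
  double loss = 0;
  if (mode == 0) {
    IntegerMatrix labels(target);
    std::vector<uword> lab_rows;
    std::vector<int> lab_ids;
    for (uword i = 0; i < rows.n_elem; ++i)
      for (uword tpos = 0; tpos < b.len(i); ++tpos) {
        int y = labels(rows(i), tpos);
        if (y >= 0) {
          lab_rows.push_back(b.offset(i) + tpos);
          lab_ids.push_back(y);
        }
      }
    int nl = lab_rows.size();
    uvec li(nl);
    for (int i = 0; i < nl; ++i) li(i) = lab_rows[i];
    mat Xl = X.rows(li);
    mat logits = Xl * m.tok_emb.t();
    logits.each_row() += m.out_b.t();
    logits.each_col() -= max(logits, 1);
    mat P = exp(logits);
    P.each_col() /= sum(P, 1);
    for (int i = 0; i < nl; ++i) loss -= std::log(P(i, lab_ids[i]) + 1e-12);
    loss /= nl;
    mat dlogits = P;
    for (int i = 0; i < nl; ++i) dlogits(i, lab_ids[i]) -= 1.0;
    dlogits /= (double)nl;
    g.out_b += sum(dlogits, 0).t();
    g.tok_emb += dlogits.t() * Xl;
    mat dXl = dlogits * m.tok_emb;
    for (int i = 0; i < nl; ++i) dX.row(li(i)) = dXl.row(i);
  } else {
    IntegerVector classes(target);
    int B = rows.n_elem;
    mat Xc(B, m.H);
    for (int i = 0; i < B; ++i) Xc.row(i) = X.row(b.offset(i));
    mat pre = Xc * m.Wp;
    pre.each_row() += m.bp.t();
    mat pooled = tanh(pre);
    mat logits = pooled * m.Wc;
    logits.each_row() += m.bc.t();
    logits.each_col() -= max(logits, 1);
    mat P = exp(logits);
    P.each_col() /= sum(P, 1);
    for (int i = 0; i < B; ++i) loss -= std::log(P(i, classes[i]) + 1e-12);
    loss /= B;
    mat dlogits = P;
    for (int i = 0; i < B; ++i) dlogits(i, classes[i]) -= 1.0;
    dlogits /= (double)B;
    g.Wc += pooled.t() * dlogits;
    g.bc += sum(dlogits, 0).t();
    mat dpooled = dlogits * m.Wc.t();
    mat dpre = dpooled % (1.0 - square(pooled));
    g.Wp += Xc.t() * dpre;
    g.bp += sum(dpre, 0).t();
    mat dXc = dpre * m.Wp.t();
    for (int i = 0; i < B; ++i) dX.row(b.offset(i)) = dXc.row(i);
  }
  encoder_backward(m, b, caches, dX, g, 0.0, false);

  List out;
  out["loss"] = loss;
  List gr;
  gr["tok_emb"] = g.tok_emb; gr["pos_emb"] = g.pos_emb;
  for (int l = 0; l < m.L; ++l) {
    LayerG& gl = g.layers[l];
    gr[nm("Wq", l)] = gl.Wq; gr[nm("bq", l)] = gl.bq;
    gr[nm("Wk", l)] = gl.Wk; gr[nm("bk", l)] = gl.bk;
    gr[nm("Wv", l)] = gl.Wv; gr[nm("bv", l)] = gl.bv;
    gr[nm("Wo", l)] = gl.Wo; gr[nm("bo", l)] = gl.bo;
    gr[nm("W1", l)] = gl.W1; gr[nm("b1", l)] = gl.b1;
    gr[nm("W2", l)] = gl.W2; gr[nm("b2", l)] = gl.b2;
    gr[nm("ln1g", l)] = gl.g1; gr[nm("ln1b", l)] = gl.be1;
    gr[nm("ln2g", l)] = gl.g2; gr[nm("ln2b", l)] = gl.be2;
  }
  gr["out_b"] = g.out_b;
  gr["Wp"] = g.Wp; gr["bp"] = g.bp; gr["Wc"] = g.Wc; gr["bc"] = g.bc;
  out["grads"] = gr;
  return out;
}

// ---- forward-only inference ------------------------------------------------

// mode 0: token logits at positions where want != 0 (row order follows the
// sequence-major scan of `tokens`); mode 1: class logits, one row per
// sequence. Dropout is disabled.
// [[Rcpp::export]]
NumericMatrix cpp_forward(List params, IntegerMatrix tokens,
                          IntegerVector lengths, int n_layers, int n_heads,
                          int mode, IntegerMatrix want) {
  Model m(params, n_layers, n_heads);
  int n = tokens.nrow();
  std::mt19937_64 rng(0);
  int out_cols = (mode == 0) ? m.V : m.C;
  int out_rows = 0;
  if (mode == 0) {
    for (int i = 0; i < n; ++i)
      for (int tpos = 0; tpos < lengths[i]; ++tpos)
        if (want(i, tpos) != 0) ++out_rows;
  } else out_rows = n;
  NumericMatrix out(out_rows, out_cols);
  mat outv(out.begin(), out_rows, out_cols, false, true);
  std::vector<LayerCache> caches(m.L);
  int written = 0;
  const int chunk = 256;
  for (int start = 0; start < n; start += chunk) {
    int end = std::min(start + chunk, n);
    uvec rows = regspace<uvec>(start, end - 1);
    Batch b = make_batch(tokens, lengths, rows);
    mat X = encoder_forward(m, b, caches, false, 0.0, rng);
    if (mode == 0) {
      for (uword i = 0; i < rows.n_elem; ++i) {
        int row = rows(i);
        for (uword tpos = 0; tpos < b.len(i); ++tpos) {
          if (want(row, tpos) != 0) {
            rowvec lg = X.row(b.offset(i) + tpos) * m.tok_emb.t() +
              m.out_b.t();
            outv.row(written++) = lg;
          }
        }
      }
    } else {
      for (uword i = 0; i < rows.n_elem; ++i) {
        rowvec pooled = tanh(X.row(b.offset(i)) * m.Wp + m.bp.t());
        outv.row(written++) = pooled * m.Wc + m.bc.t();
      }
    }
  }
  return out;
}
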