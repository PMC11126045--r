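// Bidirectional LSTM sequence regressor with backprop-through-time and Adam,
// single precision, single thread. The network maps a (time x channels)
// curve stack to a same-length output curve through stacked bidirectional
// LSTM layers, a per-time-step linear read-out, and an optional linear
// parameter head on the final concatenated hidden state.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------------------
// trapezoid-rule causal convolution with ktrans * exp(-kep t) (double; the
// same quadrature the C++ tissue loss uses in single precision)
// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv_exp(Rcpp::NumericVector x, double ktrans,
                                 double kep, double dt) {
  const int n = x.size();
  Rcpp::NumericVector out(n);
  std::vector<double> k(n);
  for (int j = 0; j < n; ++j) k[j] = std::exp(-kep * j * dt);
  for (int t = 0; t < n; ++t) {
    double acc = 0.0;
    for (int j = 0; j <= t; ++j) acc += x[t - j] * k[j];
    acc -= 0.5 * (x[t] * k[0] + x[0] * k[t]);  // trapezoid end corrections
    out[t] = ktrans * dt * acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
struct LayerW {
  fmat W[2], U[2];  // input / recurrent weights per direction (4H x Cin, 4H x H)
  fvec b[2];        // gate biases (4H)
};

struct Net {
  int L = 0, H = 0, C = 0, P = 0, T = 0;
  std::vector<LayerW> lay;
  fvec w_out; float b_out = 0.f;
  fmat Wp; fvec bp;              // parameter head (P x 2H), used when P > 0
  // Adam first/second moments, one slot per tensor above
  std::vector<LayerW> m, v;
  fvec m_wout, v_wout; float m_bout = 0.f, v_bout = 0.f;
  fmat mWp, vWp; fvec mbp, vbp;
  long step = 0;
};

static fmat get_fmat(const Rcpp::List& l, const std::string& nm) {
  return conv_to<fmat>::from(Rcpp::as<mat>(l[nm]));
}
static fvec get_fvec(const Rcpp::List& l, const std::string& nm) {
  return conv_to<fvec>::from(Rcpp::as<vec>(l[nm]));
}

// [[Rcpp::export]]
SEXP cpp_net_create(Rcpp::List weights, int n_layers, int hidden,
                    int in_channels, int n_param_out, int t_len) {
  Rcpp::XPtr<Net> p(new Net(), true);
  Net& nt = *p;
  nt.L = n_layers; nt.H = hidden; nt.C = in_channels; nt.P = n_param_out;
  nt.T = t_len;
  const char* dn[2] = {"f", "b"};
  for (int l = 0; l < nt.L; ++l) {
    LayerW lw, zm, zv;
    for (int d = 0; d < 2; ++d) {
      std::string suf = std::string("_") + std::to_string(l + 1) + "_" + dn[d];
      lw.W[d] = get_fmat(weights, "W" + suf);
      lw.U[d] = get_fmat(weights, "U" + suf);
      lw.b[d] = get_fvec(weights, "b" + suf);
      zm.W[d] = zeros<fmat>(size(lw.W[d])); zv.W[d] = zeros<fmat>(size(lw.W[d]));
      zm.U[d] = zeros<fmat>(size(lw.U[d])); zv.U[d] = zeros<fmat>(size(lw.U[d]));
      zm.b[d] = zeros<fvec>(lw.b[d].n_elem); zv.b[d] = zeros<fvec>(lw.b[d].n_elem);
    }
    nt.lay.push_back(lw); nt.m.push_back(zm); nt.v.push_back(zv);
  }
  nt.w_out = get_fvec(weights, "w_out");
  nt.b_out = (float)Rcpp::as<double>(weights["b_out"]);
  nt.m_wout = zeros<fvec>(nt.w_out.n_elem); nt.v_wout = zeros<fvec>(nt.w_out.n_elem);
  if (nt.P > 0) {
    nt.Wp = get_fmat(weights, "Wp"); nt.bp = get_fvec(weights, "bp");
    nt.mWp = zeros<fmat>(size(nt.Wp)); nt.vWp = zeros<fmat>(size(nt.Wp));
    nt.mbp = zeros<fvec>(nt.bp.n_elem); nt.vbp = zeros<fvec>(nt.bp.n_elem);
  }
  return p;
}

// [[Rcpp::export]]
Rcpp::List cpp_net_weights(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  Net& nt = *p;
  Rcpp::List out;
  const char* dn[2] = {"f", "b"};
  for (int l = 0; l < nt.L; ++l)
    for (int d = 0; d < 2; ++d) {
      std::string suf = std::string("_") + std::to_string(l + 1) + "_" + dn[d];
      out["W" + suf] = conv_to<mat>::from(nt.lay[l].W[d]);
      out["U" + suf] = conv_to<mat>::from(nt.lay[l].U[d]);
      out["b" + suf] = conv_to<vec>::from(nt.lay[l].b[d]);
    }
  out["w_out"] = conv_to<vec>::from(nt.w_out);
  out["b_out"] = (double)nt.b_out;
  if (nt.P > 0) {
    out["Wp"] = conv_to<mat>::from(nt.Wp);
    out["bp"] = conv_to<vec>::from(nt.bp);
  }
  return out;
}

// per-(layer,direction) forward caches; column block t holds batch columns
struct Cache {
  std::vector<fmat> G[2];   // post-activation gates [i f g o] (4H x B*T)
  std::vector<fmat> Cc[2];  // cell states (H x B*T)
  std::vector<fmat> Hh[2];  // hidden states (H x B*T)
  std::vector<fmat> In;     // input of each layer (Cin x B*T)
  fmat out_top;             // top-layer concatenated output (2H x B*T)
};

static inline fmat sigm(const fmat& x) { return 1.0f / (1.0f + exp(-x)); }

// forward through the stack; X is (C x B*T) with block t = inputs at time t
static void forward(Net& nt, const fmat& X, int B, Cache& cc, bool keep) {
  const int T = nt.T, H = nt.H;
  fmat in = X;
  cc.In.clear();
  for (int d = 0; d < 2; ++d) {
    cc.G[d].assign(nt.L, fmat()); cc.Cc[d].assign(nt.L, fmat());
    cc.Hh[d].assign(nt.L, fmat());
  }
  for (int l = 0; l < nt.L; ++l) {
    if (keep) cc.In.push_back(in);
    fmat outl(2 * H, B * T);
    for (int d = 0; d < 2; ++d) {
      fmat Z = nt.lay[l].W[d] * in;          // one big gemm for all t
      Z.each_col() += nt.lay[l].b[d];
      fmat G(4 * H, B * T), Cst(H, B * T), Hst(H, B * T);
      fmat h(H, B, fill::zeros), c(H, B, fill::zeros);
      for (int s = 0; s < T; ++s) {
        int t = (d == 0) ? s : (T - 1 - s);
        fmat z = Z.cols(t * B, t * B + B - 1) + nt.lay[l].U[d] * h;
        fmat gi = sigm(z.rows(0, H - 1));
        fmat gf = sigm(z.rows(H, 2 * H - 1));
        fmat gg = tanh(z.rows(2 * H, 3 * H - 1));
        fmat go = sigm(z.rows(3 * H, 4 * H - 1));
        c = gf % c + gi % gg;
        h = go % tanh(c);
        G.cols(t * B, t * B + B - 1) = join_cols(join_cols(gi, gf), join_cols(gg, go));
        Cst.cols(t * B, t * B + B - 1) = c;
        Hst.cols(t * B, t * B + B - 1) = h;
      }
      outl.rows(d * H, (d + 1) * H - 1) = Hst;
      if (keep) {
        cc.G[d][l] = std::move(G); cc.Cc[d][l] = std::move(Cst);
        cc.Hh[d][l] = std::move(Hst);
      }
    }
    in = std::move(outl);
  }
  cc.out_top = std::move(in);
}

// predicted curve (T x B) from the top-layer features
static fmat readout(const Net& nt, const fmat& out_top, int B) {
  fmat pred(nt.T, B);
  for (int t = 0; t < nt.T; ++t)
    pred.row(t) = nt.w_out.t() * out_top.cols(t * B, t * B + B - 1) + nt.b_out;
  return pred;
}

static fmat param_head(const Net& nt, const fmat& out_top, int B) {
  const int T = nt.T, H = nt.H;
  fmat hfin = join_cols(
      fmat(out_top.submat(0, (T - 1) * B, H - 1, T * B - 1)),
      fmat(out_top.submat(H, 0, 2 * H - 1, B - 1)));
  fmat par = nt.Wp * hfin;
  par.each_col() += nt.bp;
  return par;  // P x B
}

// fractional-sample delay of column p by dtm minutes (zero-filled), plus its
// adjoint used to push tissue-model gradients back onto the predicted curve
static fvec shift_frac(const fvec& p, double dtm, double dt) {
  const int T = p.n_elem;
  double sh = dtm / dt;
  int k = (int)std::floor(sh);
  float w = (float)(sh - k);
  fvec s(T, fill::zeros);
  for (int t = 0; t < T; ++t) {
    int a = t - k, b = t - k - 1;
    float v = 0.f;
    if (a >= 0 && a < T) v += (1.f - w) * p[a];
    if (b >= 0 && b < T) v += w * p[b];
    s[t] = v;
  }
  return s;
}
static void shift_frac_adj(fvec& dp, const fvec& ds, double dtm, double dt) {
  const int T = dp.n_elem;
  double sh = dtm / dt;
  int k = (int)std::floor(sh);
  float w = (float)(sh - k);
  for (int t = 0; t < T; ++t) {
    int a = t - k, b = t - k - 1;
    if (a >= 0 && a < T) dp[a] += (1.f - w) * ds[t];
    if (b >= 0 && b < T) dp[b] += w * ds[t];
  }
}

// compartment-model tissue loss for one record: accumulates the L1 loss of
// each measured curve against the model driven by the predicted AIF and the
// predicted parameters, and the gradients w.r.t. both.
static double tissue_loss_record(const fvec& pred, const fmat& tiss,
                                 const fvec& par_hat, fvec& dpred,
                                 fvec& dpar, double delta, double dt,
                                 double denom) {
  const int T = pred.n_elem, N = tiss.n_cols;
  double loss = 0.0;
  for (int n = 0; n < N; ++n) {
    float kt = par_hat[4 * n], kep = par_hat[4 * n + 1];
    float vp = par_hat[4 * n + 2], dtm = par_hat[4 * n + 3];
    float kep_c = std::min(std::max(kep, 0.f), 60.f);
    double dtm_c = std::min(std::max((double)dtm, 0.0), 0.1);
    bool kep_free = (kep > 0.f && kep < 60.f);
    fvec s = shift_frac(pred, dtm_c, dt);
    std::vector<float> kern(T), dkern(T);
    for (int j = 0; j < T; ++j) {
      kern[j] = std::exp(-kep_c * j * (float)dt);
      dkern[j] = -(float)(j * dt) * kern[j];
    }
    fvec conv(T), dconv_kep(T);
    for (int t = 0; t < T; ++t) {
      float a = 0.f, dk = 0.f;
      for (int j = 0; j <= t; ++j) { a += s[t - j] * kern[j]; dk += s[t - j] * dkern[j]; }
      a  -= 0.5f * (s[t] * kern[0] + s[0] * kern[t]);
      dk -= 0.5f * (s[t] * dkern[0] + s[0] * dkern[t]);
      conv[t] = (float)dt * a;
      dconv_kep[t] = (float)dt * dk;
    }
    fvec r(T), wsign(T);
    double lc = 0.0;
    for (int t = 0; t < T; ++t) {
      r[t] = kt * conv[t] + vp * s[t] - tiss(t, n);
      lc += std::fabs((double)r[t]);
      wsign[t] = (r[t] > 0.f) - (r[t] < 0.f);
    }
    loss += delta * lc / denom;
    const float wfac = (float)(delta / denom);
    // parameter gradients
    float dkt = 0.f, dvp = 0.f, dkep = 0.f;
    for (int t = 0; t < T; ++t) {
      dkt += wsign[t] * conv[t];
      dvp += wsign[t] * s[t];
      dkep += wsign[t] * dconv_kep[t];
    }
    dpar[4 * n]     += wfac * dkt;
    dpar[4 * n + 1] += kep_free ? wfac * kt * dkep : 0.f;
    dpar[4 * n + 2] += wfac * dvp;
    // curve gradient: d conv_t / d s_u = dt * c_j * kern[j], j = t - u
    fvec ds(T, fill::zeros);
    for (int t = 0; t < T; ++t) {
      if (wsign[t] == 0.f) continue;
      float wk = wfac * wsign[t] * kt * (float)dt;
      for (int j = 0; j <= t; ++j) {
        float cj = (j == 0 || j == t) ? 0.5f : 1.f;
        if (t == 0) cj = 0.f;  // zero-width trapezoid
        ds[t - j] += wk * cj * kern[j];
      }
      ds[t] += wfac * wsign[t] * vp;
    }
    shift_frac_adj(dpred, ds, dtm_c, dt);
  }
  return loss;
}

struct Grads {
  std::vector<LayerW> lay;
  fvec w_out; float b_out = 0.f;
  fmat Wp; fvec bp;
};

static void adam_tensor(fmat& w, fmat& m, fmat& v, const fmat& g,
                        float lr, float c1, float c2) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * square(g);
  w -= lr * (m / c1) / (sqrt(v / c2) + 1e-8f);
}
static void adam_vec(fvec& w, fvec& m, fvec& v, const fvec& g,
                     float lr, float c1, float c2) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * square(g);
  w -= lr * (m / c1) / (sqrt(v / c2) + 1e-8f);
}

// one mini-batch: forward, loss, BPTT, Adam update; returns batch loss
static double train_batch(Net& nt, const fmat& X, const fmat& Y,
                          const fmat& Ptrue, const fcube& Tis, int B,
                          double lr, double alpha, double beta, double delta,
                          int kind, double dt) {
  const int T = nt.T, H = nt.H;
  Cache cc;
  forward(nt, X, B, cc, true);
  fmat pred = readout(nt, cc.out_top, B);
  fmat par;
  if (nt.P > 0) par = param_head(nt, cc.out_top, B);

  double loss = 0.0;
  fmat dpred(T, B, fill::zeros);
  fmat dpar;
  if (nt.P > 0) dpar = fmat(nt.P, B, fill::zeros);

  // L1 curve loss (mean over time and batch), weight alpha
  {
    fmat r = pred - Y;
    loss += alpha * accu(abs(r)) / (double)(T * B);
    dpred += (float)(alpha / (T * B)) * sign(r);
  }
  if (kind == 2) {  // + parameter L1 loss
    int N = nt.P / 4;
    fmat r = par - Ptrue;
    loss += beta * accu(abs(r)) / (double)(N * B);
    dpar += (float)(beta / (N * B)) * sign(r);
  }
  if (kind == 3) {  // + compartment-model tissue loss
    int N = Tis.n_cols;
    double denom = (double)N * T * B;
    for (int b = 0; b < B; ++b) {
      fvec pb = pred.col(b), dp(T, fill::zeros), dq(nt.P, fill::zeros);
      loss += tissue_loss_record(pb, Tis.slice(b), par.col(b), dp, dq,
                                 delta, dt, denom);
      dpred.col(b) += dp;
      dpar.col(b) += dq;
    }
  }

  // gradient containers
  Grads g;
  g.lay.resize(nt.L);
  for (int l = 0; l < nt.L; ++l)
    for (int d = 0; d < 2; ++d) {
      g.lay[l].W[d] = zeros<fmat>(size(nt.lay[l].W[d]));
      g.lay[l].U[d] = zeros<fmat>(size(nt.lay[l].U[d]));
      g.lay[l].b[d] = zeros<fvec>(nt.lay[l].b[d].n_elem);
    }
  g.w_out = zeros<fvec>(2 * H);

  // read-out backprop
  fmat dOut(2 * H, B * T, fill::zeros);
  for (int t = 0; t < T; ++t) {
    const fmat ot = cc.out_top.cols(t * B, t * B + B - 1);
    g.w_out += ot * dpred.row(t).t();
    dOut.cols(t * B, t * B + B - 1) += nt.w_out * dpred.row(t);
  }
  g.b_out = accu(dpred);

  // parameter-head backprop
  if (nt.P > 0 && (kind == 2 || kind == 3)) {
    fmat hfin = join_cols(
        fmat(cc.out_top.submat(0, (T - 1) * B, H - 1, T * B - 1)),
        fmat(cc.out_top.submat(H, 0, 2 * H - 1, B - 1)));
    g.Wp = dpar * hfin.t();
    g.bp = sum(dpar, 1);
    fmat dhf = nt.Wp.t() * dpar;  // 2H x B
    dOut.submat(0, (T - 1) * B, H - 1, T * B - 1) += dhf.rows(0, H - 1);
    dOut.submat(H, 0, 2 * H - 1, B - 1) += dhf.rows(H, 2 * H - 1);
  } else if (nt.P > 0) {
    g.Wp = zeros<fmat>(size(nt.Wp));
    g.bp = zeros<fvec>(nt.bp.n_elem);
  }

  // BPTT down the stack
  for (int l = nt.L - 1; l >= 0; --l) {
    const int Cin = nt.lay[l].W[0].n_cols;
    fmat dIn(Cin, B * T, fill::zeros);
    for (int d = 0; d < 2; ++d) {
      fmat dZ(4 * H, B * T, fill::zeros);
      fmat dh_rec(H, B, fill::zeros), dc_rec(H, B, fill::zeros);
      for (int s = T - 1; s >= 0; --s) {
        int t = (d == 0) ? s : (T - 1 - s);
        auto blk = [&](const fmat& M) { return fmat(M.cols(t * B, t * B + B - 1)); };
        fmat G = blk(cc.G[d][l]);
        fmat gi = G.rows(0, H - 1), gf = G.rows(H, 2 * H - 1);
        fmat gg = G.rows(2 * H, 3 * H - 1), go = G.rows(3 * H, 4 * H - 1);
        fmat c = blk(cc.Cc[d][l]);
        fmat tc = tanh(c);
        // previous-step state in processing order
        fmat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
        if (s > 0) {
          int tp = (d == 0) ? s - 1 : (T - s);
          h_prev = cc.Hh[d][l].cols(tp * B, tp * B + B - 1);
          c_prev = cc.Cc[d][l].cols(tp * B, tp * B + B - 1);
        }
        fmat dh = dOut.rows(d * H, (d + 1) * H - 1).cols(t * B, t * B + B - 1)
                  + dh_rec;
        fmat dc = dh % go % (1.0f - square(tc)) + dc_rec;
        fmat dgo = dh % tc;
        fmat dgi = dc % gg;
        fmat dgg = dc % gi;
        fmat dgf = dc % c_prev;
        dc_rec = dc % gf;
        fmat dz = join_cols(
            join_cols(dgi % gi % (1.0f - gi), dgf % gf % (1.0f - gf)),
            join_cols(dgg % (1.0f - square(gg)), dgo % go % (1.0f - go)));
        dZ.cols(t * B, t * B + B - 1) = dz;
        g.lay[l].U[d] += dz * h_prev.t();
        dh_rec = nt.lay[l].U[d].t() * dz;
      }
      g.lay[l].W[d] += dZ * cc.In[l].t();
      g.lay[l].b[d] += sum(dZ, 1);
      dIn += nt.lay[l].W[d].t() * dZ;
    }
    if (l > 0) dOut = std::move(dIn);
  }

  // Adam step
  nt.step += 1;
  float c1 = 1.0f - std::pow(0.9f, (float)nt.step);
  float c2 = 1.0f - std::pow(0.999f, (float)nt.step);
  float flr = (float)lr;
  for (int l = 0; l < nt.L; ++l)
    for (int d = 0; d < 2; ++d) {
      adam_tensor(nt.lay[l].W[d], nt.m[l].W[d], nt.v[l].W[d], g.lay[l].W[d], flr, c1, c2);
      adam_tensor(nt.lay[l].U[d], nt.m[l].U[d], nt.v[l].U[d], g.lay[l].U[d], flr, c1, c2);
      adam_vec(nt.lay[l].b[d], nt.m[l].b[d], nt.v[l].b[d], g.lay[l].b[d], flr, c1, c2);
    }
  adam_vec(nt.w_out, nt.m_wout, nt.v_wout, g.w_out, flr, c1, c2);
  {
    nt.m_bout = 0.9f * nt.m_bout + 0.1f * g.b_out;
    nt.v_bout = 0.999f * nt.v_bout + 0.001f * g.b_out * g.b_out;
    nt.b_out -= flr * (nt.m_bout / c1) / (std::sqrt(nt.v_bout / c2) + 1e-8f);
  }
  if (nt.P > 0 && (kind == 2 || kind == 3)) {
    adam_tensor(nt.Wp, nt.mWp, nt.vWp, g.Wp, flr, c1, c2);
    adam_vec(nt.bp, nt.mbp, nt.vbp, g.bp, flr, c1, c2);
  }
  return loss;
}

// reshape an R array (T x C x n), batch columns `idx`, into (C x B*T)
static fmat pack_batch(const cube& X, const uvec& idx, int T, int C) {
  const int B = idx.n_elem;
  fmat out(C, B * T);
  for (int b = 0; b < B; ++b) {
    const mat sl = X.slice(idx[b]);       // T x C
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < C; ++c)
        out(c, t * B + b) = (float)sl(t, c);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_net_train_epoch(SEXP ptr, const arma::cube& x, const arma::mat& y,
                           const arma::mat& par_true, const arma::cube& tissue,
                           Rcpp::IntegerVector order, int batch_size,
                           double lr, double alpha, double beta, double delta,
                           int kind, double dt) {
  Rcpp::XPtr<Net> p(ptr);
  Net& nt = *p;
  const int T = nt.T, C = nt.C, n = order.size();
  double total = 0.0; int nb = 0;
  for (int s = 0; s < n; s += batch_size) {
    int B = std::min(batch_size, n - s);
    uvec idx(B);
    for (int b = 0; b < B; ++b) idx[b] = order[s + b] - 1;
    fmat X = pack_batch(x, idx, T, C);
    fmat Y(T, B);
    for (int b = 0; b < B; ++b)
      Y.col(b) = conv_to<fvec>::from(y.col(idx[b]));
    fmat Ptr_;
    if (nt.P > 0) {
      Ptr_.set_size(nt.P, B);
      for (int b = 0; b < B; ++b)
        Ptr_.col(b) = conv_to<fvec>::from(par_true.col(idx[b]));
    }
    fcube Tis;
    if (kind == 3) {
      Tis.set_size(T, tissue.n_cols, B);
      for (int b = 0; b < B; ++b)
        Tis.slice(b) = conv_to<fmat>::from(tissue.slice(idx[b]));
    }
    total += train_batch(nt, X, Y, Ptr_, Tis, B, lr, alpha, beta, delta,
                         kind, dt);
    ++nb;
  }
  return total / nb;
}

// [[Rcpp::export]]
Rcpp::List cpp_net_predict(SEXP ptr, const arma::cube& x, int batch_size) {
  Rcpp::XPtr<Net> p(ptr);
  Net& nt = *p;
  const int T = nt.T, C = nt.C, n = x.n_slices;
  mat pred(T, n);
  mat par;
  if (nt.P > 0) par.set_size(nt.P, n);
  Cache cc;
  for (int s = 0; s < n; s += batch_size) {
    int B = std::min(batch_size, n - s);
    uvec idx = regspace<uvec>(s, s + B - 1);
    fmat X = pack_batch(x, idx, T, C);
    forward(nt, X, B, cc, false);
    fmat pr = readout(nt, cc.out_top, B);
    pred.cols(s, s + B - 1) = conv_to<mat>::from(pr);
    if (nt.P > 0)
      par.cols(s, s + B - 1) = conv_to<mat>::from(param_head(nt, cc.out_top, B));
  }
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("par") = par);
}

// mean absolute curve error over a whole split (the validation metric)
// [[Rcpp::export]]
double cpp_net_l1(SEXP ptr, const arma::cube& x, const arma::mat& y,
                  int batch_size) {
  Rcpp::XPtr<Net> p(ptr);
  Net& nt = *p;
  const int T = nt.T, n = x.n_slices;
  double total = 0.0;
  Cache cc;
  for (int s = 0; s < n; s += batch_size) {
    int B = std::min(batch_size, n - s);
    uvec idx = regspace<uvec>(s, s + B - 1);
    fmat X = pack_batch(x, idx, T, nt.C);
    forward(nt, X, B, cc, false);
    fmat pr = readout(nt, cc.out_top, B);
    for (int b = 0; b < B; ++b)
      total += accu(abs(pr.col(b) - conv_to<fvec>::from(y.col(idx[b]))));
  }
  return total / ((double)T * n);
}
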