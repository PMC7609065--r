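// Per-frame sequence classifier: initial 1-D convolution, pre-activation
// residual blocks (BN -> ReLU -> conv -> BN -> ReLU -> conv, additive skip
// with 1x1 projection on filter growth, stride-1 max pooling), bidirectional
// LSTM with output dropout, and a per-frame dense softmax head.
//
// Activations for a batch of B traces of T frames are held as one
// (B*T) x C matrix (sample s occupies rows [s*T, (s+1)*T)), so every
// convolution and the dense head run as a single large GEMM.
// All randomness (dropout) comes from R's RNG so runs are reproducible
// under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::umat;
using arma::uvec;
// single-precision compute types (training in float32, as the reference
// deep-learning stacks do); the R interface remains double
typedef arma::fmat mat;
typedef arma::frowvec rowvec;
typedef arma::fvec vec;
typedef arma::Mat<double> dmat;
typedef arma::Col<double> dvec;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.9f;

struct BNCache {
  mat xhat;
  rowvec invstd;
  rowvec gamma;
};

struct LSTMCache {
  std::vector<mat> I, F, G, O, Ctan, Cprev, Hprev, Xt;
};

// ---- 1-D convolution (same padding, stride 1), batched ---------------------

// X: (B*T) x Cin. Builds the im2col matrix (B*T) x (k*Cin) and multiplies.
static mat im2col(const mat& X, int k, int T, int B) {
  const int Cin = X.n_cols;
  const int pl = (k - 1) / 2;
  mat XC(X.n_rows, k * Cin, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    int t0 = std::max(0, pl - j);
    int t1 = std::min(T - 1, T - 1 + pl - j);
    if (t0 > t1) continue;
    for (int s = 0; s < B; ++s) {
      XC.submat(s * T + t0, j * Cin, s * T + t1, (j + 1) * Cin - 1) =
          X.rows(s * T + t0 + j - pl, s * T + t1 + j - pl);
    }
  }
  return XC;
}

static mat conv_fwd(const mat& X, const mat& W, const rowvec& b, int k,
                    int T, int B, mat* xcol_cache) {
  mat XC = im2col(X, k, T, B);
  mat out = XC * W;
  out.each_row() += b;
  if (xcol_cache) *xcol_cache = std::move(XC);
  return out;
}

static mat conv_bwd(const mat& dOut, const mat& xcol, const mat& W, int k,
                    int Cin, int T, int B, mat& dW, rowvec& db) {
  dW = xcol.t() * dOut;
  db = arma::sum(dOut, 0);
  mat dXC = dOut * W.t();
  const int pl = (k - 1) / 2;
  mat dX(dOut.n_rows, Cin, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    int t0 = std::max(0, pl - j);
    int t1 = std::min(T - 1, T - 1 + pl - j);
    if (t0 > t1) continue;
    for (int s = 0; s < B; ++s) {
      dX.rows(s * T + t0 + j - pl, s * T + t1 + j - pl) +=
          dXC.submat(s * T + t0, j * Cin, s * T + t1, (j + 1) * Cin - 1);
    }
  }
  return dX;
}

// ---- batch normalization (per channel over all rows) -----------------------

static mat bn_fwd(const mat& X, const vec& g, const vec& be, vec& rm, vec& rv,
                  bool training, BNCache* cc) {
  const double N = (double)X.n_rows;
  rowvec mean, var;
  if (training) {
    mean = arma::mean(X, 0);
    var = arma::var(X, 1, 0);  // population variance
    rm = BN_MOMENTUM * rm + (1.0 - BN_MOMENTUM) * mean.t();
    rv = BN_MOMENTUM * rv + (1.0 - BN_MOMENTUM) * var.t();
  } else {
    mean = rm.t();
    var = rv.t();
  }
  rowvec invstd = 1.0 / arma::sqrt(var + BN_EPS);
  mat xhat = X;
  xhat.each_row() -= mean;
  xhat.each_row() %= invstd;
  mat out = xhat;
  out.each_row() %= g.t();
  out.each_row() += be.t();
  if (cc) {
    cc->xhat = std::move(xhat);
    cc->invstd = invstd;
    cc->gamma = g.t();
    return out;
  }
  (void)N;
  return out;
}

static mat bn_bwd(const mat& dY, const BNCache& cc, vec& dg, vec& db) {
  const double N = (double)dY.n_rows;
  rowvec sdy = arma::sum(dY, 0);
  rowvec sdyx = arma::sum(dY % cc.xhat, 0);
  dg = sdyx.t();
  db = sdy.t();
  mat dX = dY;
  dX.each_row() -= sdy / N;
  dX -= cc.xhat % arma::repmat(sdyx / N, dY.n_rows, 1);
  dX.each_row() %= cc.gamma % cc.invstd;
  return dX;
}

// ---- stride-1 max pooling (same padding) -----------------------------------

static mat pool_fwd(const mat& X, int p, int T, int B, umat* idx_cache) {
  const int C = X.n_cols;
  const int pl = (p - 1) / 2;
  mat out(X.n_rows, C);
  umat idx(X.n_rows, C);
  for (int s = 0; s < B; ++s) {
    const int base = s * T;
    for (int c = 0; c < C; ++c) {
      for (int t = 0; t < T; ++t) {
        int lo = std::max(0, t - pl);
        int hi = std::min(T - 1, t - pl + p - 1);
        int am = lo;
        float mv = X(base + lo, c);
        for (int j = lo + 1; j <= hi; ++j) {
          if (X(base + j, c) > mv) { mv = X(base + j, c); am = j; }
        }
        out(base + t, c) = mv;
        idx(base + t, c) = (arma::uword)(base + am);
      }
    }
  }
  if (idx_cache) *idx_cache = std::move(idx);
  return out;
}

static mat pool_bwd(const mat& dY, const umat& idx) {
  mat dX(dY.n_rows, dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    for (arma::uword r = 0; r < dY.n_rows; ++r) {
      dX(idx(r, c), c) += dY(r, c);
    }
  }
  return dX;
}

// ---- LSTM ------------------------------------------------------------------

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// A: (B*T) x Cin. Output written into out columns [col0, col0+H).
static void lstm_fwd(const mat& A, const mat& Wx, const mat& Wh,
                     const rowvec& b, bool fwd, int T, int B, mat& out,
                     int col0, LSTMCache* cc) {
  const int H = Wh.n_rows;
  mat Hp(B, H, arma::fill::zeros), Cp(B, H, arma::fill::zeros);
  uvec ridx(B);
  if (cc) {
    cc->I.resize(T); cc->F.resize(T); cc->G.resize(T); cc->O.resize(T);
    cc->Ctan.resize(T); cc->Cprev.resize(T); cc->Hprev.resize(T);
    cc->Xt.resize(T);
  }
  for (int step = 0; step < T; ++step) {
    const int t = fwd ? step : (T - 1 - step);
    for (int s = 0; s < B; ++s) ridx[s] = s * T + t;
    mat Xt = A.rows(ridx);
    mat Z = Xt * Wx + Hp * Wh;
    Z.each_row() += b;
    const int Hm1 = H - 1;
    mat I = sigm(Z.cols(0, Hm1));
    mat F = sigm(Z.cols(H, 2 * H - 1));
    mat G = arma::tanh(Z.cols(2 * H, 3 * H - 1));
    mat O = sigm(Z.cols(3 * H, 4 * H - 1));
    mat Ct = F % Cp + I % G;
    mat Ctan = arma::tanh(Ct);
    mat Ht = O % Ctan;
    for (int s = 0; s < B; ++s) {
      out.submat(s * T + t, col0, s * T + t, col0 + H - 1) = Ht.row(s);
    }
    if (cc) {
      cc->I[t] = std::move(I); cc->F[t] = std::move(F);
      cc->G[t] = std::move(G); cc->O[t] = std::move(O);
      cc->Ctan[t] = std::move(Ctan); cc->Cprev[t] = Cp;
      cc->Hprev[t] = Hp; cc->Xt[t] = std::move(Xt);
    }
    Hp = std::move(Ht);
    Cp = std::move(Ct);
  }
}

static void lstm_bwd(const mat& dOut, int col0, const LSTMCache& cc,
                     const mat& Wx, const mat& Wh, bool fwd, int T, int B,
                     mat& dWx, mat& dWh, rowvec& db, mat& dA) {
  const int H = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(4 * H);
  mat dHn(B, H, arma::fill::zeros), dCn(B, H, arma::fill::zeros);
  for (int step = T - 1; step >= 0; --step) {
    const int t = fwd ? step : (T - 1 - step);
    mat dHt = dHn;
    for (int s = 0; s < B; ++s) {
      dHt.row(s) += dOut.submat(s * T + t, col0, s * T + t, col0 + H - 1);
    }
    const mat& I = cc.I[t];
    const mat& F = cc.F[t];
    const mat& G = cc.G[t];
    const mat& O = cc.O[t];
    const mat& Ctan = cc.Ctan[t];
    mat dO = dHt % Ctan;
    mat dC = dCn + dHt % O % (1.0 - Ctan % Ctan);
    mat dI = dC % G;
    mat dG = dC % I;
    mat dF = dC % cc.Cprev[t];
    dCn = dC % F;
    mat dZ(B, 4 * H);
    dZ.cols(0, H - 1) = dI % I % (1.0 - I);
    dZ.cols(H, 2 * H - 1) = dF % F % (1.0 - F);
    dZ.cols(2 * H, 3 * H - 1) = dG % (1.0 - G % G);
    dZ.cols(3 * H, 4 * H - 1) = dO % O % (1.0 - O);
    dWx += cc.Xt[t].t() * dZ;
    dWh += cc.Hprev[t].t() * dZ;
    db += arma::sum(dZ, 0);
    dHn = dZ * Wh.t();
    mat dXt = dZ * Wx.t();
    for (int s = 0; s < B; ++s) {
      dA.row(s * T + t) += dXt.row(s);
    }
  }
}

// ---- helpers ---------------------------------------------------------------

static mat getm(const List& L, const std::string& nm) {
  return arma::conv_to<mat>::from(as<dmat>(L[nm]));
}
static vec getv(const List& L, const std::string& nm) {
  return arma::conv_to<vec>::from(as<dvec>(L[nm]));
}
static rowvec getrv(const List& L, const std::string& nm) {
  return arma::conv_to<rowvec>::from(as<dvec>(L[nm]).t());
}
static SEXP putm(const mat& M) { return wrap(arma::conv_to<dmat>::from(M)); }
static SEXP putv(const vec& V) { return wrap(arma::conv_to<dvec>::from(V)); }
static SEXP putrv(const rowvec& V) {
  return wrap(arma::conv_to<dvec>::from(V.t()));
}

// ---- full network pass -----------------------------------------------------

// [[Rcpp::export(name = ".nn_core_cpp")]]
List nn_core_cpp(List params, List rstats, List spec, arma::cube X,
                 Nullable<NumericVector> Yin, bool training, bool want_grad) {
  const IntegerVector filters = spec["filters"];
  const IntegerVector kernels = spec["kernels"];
  const int nb = filters.size();
  const int pool = as<int>(spec["pool"]);
  const int H = as<int>(spec["lstm_units"]);
  const int K = as<int>(spec["n_classes"]);
  const double dropout = training ? as<double>(spec["dropout"]) : 0.0;
  const int T = X.n_rows, B = X.n_slices;
  const int N = T * B;

  // cube (T, C, B) -> big float matrix (B*T, C)
  mat Xb(N, X.n_cols);
  for (int s = 0; s < B; ++s) {
    Xb.rows(s * T, (s + 1) * T - 1) =
        arma::conv_to<mat>::from(X.slice(s));
  }

  mat Y;
  bool have_y = false;
  if (Yin.isNotNull()) {
    NumericVector yv(Yin);
    IntegerVector dim = yv.attr("dim");
    arma::cube Yc(yv.begin(), dim[0], dim[1], dim[2], false);
    Y.set_size(N, dim[1]);
    for (int s = 0; s < B; ++s) {
      Y.rows(s * T, (s + 1) * T - 1) =
          arma::conv_to<mat>::from(Yc.slice(s));
    }
    have_y = true;
  }

  std::vector<mat> blockin(nb), xcolA(nb), xcolB(nb), relu1(nb), relu2(nb);
  std::vector<BNCache> bn1c(nb), bn2c(nb);
  std::vector<umat> poolidx(nb);
  mat xcol0;
  BNCache bnfc;

  List new_rs = clone(rstats);

  const int k0 = kernels[0];
  mat conv0_W = getm(params, "conv0_W");
  mat A = conv_fwd(Xb, conv0_W, getrv(params, "conv0_b"), k0, T, B,
                   want_grad ? &xcol0 : nullptr);

  for (int i = 0; i < nb; ++i) {
    std::string p = "b" + std::to_string(i) + "_";
    const int k = kernels[i];
    const int Cin = A.n_cols, F = filters[i];
    if (want_grad) blockin[i] = A;
    vec rm1 = getv(new_rs, p + "bn1_m"), rv1 = getv(new_rs, p + "bn1_v");
    mat h = bn_fwd(A, getv(params, p + "bn1_g"), getv(params, p + "bn1_b"),
                   rm1, rv1, training, want_grad ? &bn1c[i] : nullptr);
    if (training) { new_rs[p + "bn1_m"] = putv(rm1); new_rs[p + "bn1_v"] = putv(rv1); }
    mat m1 = arma::conv_to<mat>::from(h > 0);
    h %= m1;
    if (want_grad) relu1[i] = std::move(m1);
    h = conv_fwd(h, getm(params, p + "cA_W"), getrv(params, p + "cA_b"), k,
                 T, B, want_grad ? &xcolA[i] : nullptr);
    vec rm2 = getv(new_rs, p + "bn2_m"), rv2 = getv(new_rs, p + "bn2_v");
    h = bn_fwd(h, getv(params, p + "bn2_g"), getv(params, p + "bn2_b"), rm2,
               rv2, training, want_grad ? &bn2c[i] : nullptr);
    if (training) { new_rs[p + "bn2_m"] = putv(rm2); new_rs[p + "bn2_v"] = putv(rv2); }
    mat m2 = arma::conv_to<mat>::from(h > 0);
    h %= m2;
    if (want_grad) relu2[i] = std::move(m2);
    h = conv_fwd(h, getm(params, p + "cB_W"), getrv(params, p + "cB_b"), k,
                 T, B, want_grad ? &xcolB[i] : nullptr);
    if (Cin == F) {
      h += A;
    } else {
      mat sc = A * getm(params, p + "proj_W");
      sc.each_row() += getrv(params, p + "proj_b");
      h += sc;
    }
    A = pool_fwd(h, pool, T, B, want_grad ? &poolidx[i] : nullptr);
  }

  vec rmf = getv(new_rs, "fbn_m"), rvf = getv(new_rs, "fbn_v");
  mat R = bn_fwd(A, getv(params, "fbn_g"), getv(params, "fbn_b"), rmf, rvf,
                 training, want_grad ? &bnfc : nullptr);
  if (training) { new_rs["fbn_m"] = putv(rmf); new_rs["fbn_v"] = putv(rvf); }
  mat mf = arma::conv_to<mat>::from(R > 0);
  R %= mf;

  LSTMCache lcf, lcb;
  mat Wxf = getm(params, "lstm_f_Wx"), Whf = getm(params, "lstm_f_Wh");
  rowvec bf = getrv(params, "lstm_f_b");
  mat Wxb = getm(params, "lstm_b_Wx"), Whb = getm(params, "lstm_b_Wh");
  rowvec bb = getrv(params, "lstm_b_b");
  mat Lc(N, 2 * H);
  lstm_fwd(R, Wxf, Whf, bf, true, T, B, Lc, 0, want_grad ? &lcf : nullptr);
  lstm_fwd(R, Wxb, Whb, bb, false, T, B, Lc, H, want_grad ? &lcb : nullptr);

  mat dmask;
  if (dropout > 0.0) {
    const double keep = 1.0 - dropout;
    dmask.set_size(N, 2 * H);
    for (arma::uword ii = 0; ii < dmask.n_elem; ++ii) {
      dmask(ii) = (unif_rand() < keep) ? (float)(1.0 / keep) : 0.0f;
    }
    Lc %= dmask;
  }

  mat Wd = getm(params, "dense_W");
  mat logits = Lc * Wd;
  logits.each_row() += getrv(params, "dense_b");
  logits.each_col() -= arma::max(logits, 1);
  mat P = arma::exp(logits);
  P.each_col() /= arma::sum(P, 1);

  double loss = 0.0;
  if (have_y) loss = -arma::accu(Y % arma::log(P + 1e-12f)) / (double)N;

  // probabilities back to a double cube (T, K, B) for R
  arma::cube probs(T, K, B);
  for (int s = 0; s < B; ++s) {
    probs.slice(s) =
        arma::conv_to<dmat>::from(P.rows(s * T, (s + 1) * T - 1));
  }

  List out = List::create(_["loss"] = have_y ? wrap(loss) : R_NilValue,
                          _["probs"] = probs, _["run_stats"] = new_rs);
  if (!want_grad || !have_y) return out;

  // ---- backward ----
  List grads;
  mat dlogits = (P - Y) / (float)N;
  grads["dense_W"] = putm(Lc.t() * dlogits);
  grads["dense_b"] = putrv(arma::sum(dlogits, 0));
  mat dLc = dlogits * Wd.t();
  if (dropout > 0.0) dLc %= dmask;

  mat dR(N, R.n_cols, arma::fill::zeros);
  {
    mat dWx, dWh;
    rowvec dbv;
    lstm_bwd(dLc, 0, lcf, Wxf, Whf, true, T, B, dWx, dWh, dbv, dR);
    grads["lstm_f_Wx"] = putm(dWx); grads["lstm_f_Wh"] = putm(dWh);
    grads["lstm_f_b"] = putrv(dbv);
    lstm_bwd(dLc, H, lcb, Wxb, Whb, false, T, B, dWx, dWh, dbv, dR);
    grads["lstm_b_Wx"] = putm(dWx); grads["lstm_b_Wh"] = putm(dWh);
    grads["lstm_b_b"] = putrv(dbv);
  }

  dR %= mf;
  vec dgf, dbef;
  mat dA = bn_bwd(dR, bnfc, dgf, dbef);
  grads["fbn_g"] = putv(dgf);
  grads["fbn_b"] = putv(dbef);

  for (int i = nb - 1; i >= 0; --i) {
    std::string p = "b" + std::to_string(i) + "_";
    const int k = kernels[i];
    const int F = filters[i];
    const int Cin = blockin[i].n_cols;
    mat dPool = pool_bwd(dA, poolidx[i]);
    mat dW;
    rowvec dbv;
    mat dh = conv_bwd(dPool, xcolB[i], getm(params, p + "cB_W"), k, F, T, B,
                      dW, dbv);
    grads[p + "cB_W"] = putm(dW);
    grads[p + "cB_b"] = putrv(dbv);
    dh %= relu2[i];
    vec dg2, db2;
    dh = bn_bwd(dh, bn2c[i], dg2, db2);
    grads[p + "bn2_g"] = putv(dg2);
    grads[p + "bn2_b"] = putv(db2);
    dh = conv_bwd(dh, xcolA[i], getm(params, p + "cA_W"), k, Cin, T, B, dW,
                  dbv);
    grads[p + "cA_W"] = putm(dW);
    grads[p + "cA_b"] = putrv(dbv);
    dh %= relu1[i];
    vec dg1, db1;
    mat dIn = bn_bwd(dh, bn1c[i], dg1, db1);
    grads[p + "bn1_g"] = putv(dg1);
    grads[p + "bn1_b"] = putv(db1);
    if (Cin == F) {
      dIn += dPool;
    } else {
      mat Wp = getm(params, p + "proj_W");
      grads[p + "proj_W"] = putm(blockin[i].t() * dPool);
      grads[p + "proj_b"] = putrv(arma::sum(dPool, 0));
      dIn += dPool * Wp.t();
    }
    dA = std::move(dIn);
  }

  {
    mat dW;
    rowvec dbv;
    conv_bwd(dA, xcol0, conv0_W, k0, Xb.n_cols, T, B, dW, dbv);
    grads["conv0_W"] = putm(dW);
    grads["conv0_b"] = putrv(dbv);
  }

  out["grads"] = grads;
  return out;
}
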