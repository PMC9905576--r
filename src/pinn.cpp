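// Core numerical engine for the physics-informed calibration network.
//
// Layout conventions
//   * A batch of spectra arrives as an L x B matrix (wavelength down the
//     rows).  Internally every activation is stored channels-first as a
//     C x T matrix, where the T columns hold the B samples separated by
//     G = K zeroed "guard" columns (plus G leading ones):
//         column of sample b, position i  =  G + b*(L+G) + i.
//     The guard columns play the role of the zero padding of a "same"
//     convolution, so a convolution becomes one GEMM per kernel tap over
//     the whole batch, with no im2col patch matrix and no per-sample loop:
//         Out.cols(j)  +=  W_t * A.cols(j + t - pl).
//     Cross-sample bleed lands in guard columns, which are re-zeroed after
//     every layer.
//   * Parameters live in one flat vector; unpack order is fixed here and
//     mirrored by pinn_param_layout() on the R side.
//   * The whole pipeline is templated on the element type: training runs in
//     single precision (the conventional choice for network optimisation,
//     and half the memory traffic), while double precision is kept for
//     validation such as finite-difference gradient checks.
//
// Max-pool layers remember their argmax columns; the decoder's un-pooling
// re-uses the matching encoder indices, and backpropagation routes
// gradients through the same columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Cfg {
  uword L;       // input length
  uword K;       // conv kernel length
  uword C1, C2;  // encoder filter counts
  uword P1, P2;  // pool sizes (= strides) of the two encoder pools
  uword HC;      // head conv filters
  uword HPs;     // head pool size
  uword HPt;     // head pool stride
  uword FCW;     // fully-connected width
  uword N;       // number of concentrations
  uword B;       // batch size (set per call)
  uword L1, L2;  // lengths after pool1 / pool2
  uword NW;      // head pool windows
  uword F;       // head features = HC * NW
  double scale;  // input scaling: the network consumes I/scale
  uword G;       // guard width between samples (= K)
  uword T, T1;   // strided column counts at lengths L and L1
};

Cfg make_cfg(const Rcpp::List& cfg, uword B) {
  Cfg c;
  c.L   = cfg["input_length"];
  c.K   = cfg["kernel"];
  c.C1  = cfg["enc_filters1"];
  c.C2  = cfg["enc_filters2"];
  c.P1  = cfg["pool1"];
  c.P2  = cfg["pool2"];
  c.HC  = cfg["head_filters"];
  c.HPs = cfg["head_pool_size"];
  c.HPt = cfg["head_pool_stride"];
  c.FCW = cfg["fc_width"];
  c.N   = cfg["n_outputs"];
  c.scale = cfg.containsElementNamed("input_scale") ?
            (double)cfg["input_scale"] : 1.0;
  c.B   = B;
  if (c.L % (c.P1 * c.P2) != 0)
    Rcpp::stop("input length must be divisible by the pooling strides");
  c.L1 = c.L / c.P1;
  c.L2 = c.L1 / c.P2;
  if (c.L < c.HPs) Rcpp::stop("input shorter than the head pool window");
  c.NW = (c.L - c.HPs) / c.HPt + 1;
  c.F  = c.HC * c.NW;
  c.G  = c.K;
  c.T  = c.G + c.B * (c.L + c.G);
  c.T1 = c.G + c.B * (c.L1 + c.G);
  return c;
}

uword n_params(const Cfg& c) {
  return c.C1 * c.K + c.C1 +
         c.C2 * c.C1 * c.K + c.C2 +
         c.C1 * c.C2 * c.K + c.C1 +
         c.C1 * c.K + 1 +
         c.HC * c.K + c.HC +
         c.FCW * c.F + c.FCW +
         c.N * c.FCW + c.N;
}

template <typename eT>
struct Params {
  Mat<eT> W1, W2, Wd1, Wd2, Wh, Wf1, Wf2;
  Col<eT> b1, b2, bd1, bd2, bh, bf1, bf2;
};

// Copy the flat double vector into typed weight blocks (and back for the
// gradient).  Order defines the package-wide parameter layout.
template <typename eT, typename Blk, typename VecFn>
void walk_params(const Cfg& c, Blk blk, VecFn vecblk, Params<eT>& P) {
  blk(P.W1, c.C1, c.K);          vecblk(P.b1, c.C1);
  blk(P.W2, c.C2, c.C1 * c.K);   vecblk(P.b2, c.C2);
  blk(P.Wd1, c.C1, c.C2 * c.K);  vecblk(P.bd1, c.C1);
  blk(P.Wd2, 1, c.C1 * c.K);     vecblk(P.bd2, 1);
  blk(P.Wh, c.HC, c.K);          vecblk(P.bh, c.HC);
  blk(P.Wf1, c.FCW, c.F);        vecblk(P.bf1, c.FCW);
  blk(P.Wf2, c.N, c.FCW);        vecblk(P.bf2, c.N);
}

template <typename eT>
Params<eT> unpack_params(const double* p, const Cfg& c) {
  Params<eT> P;
  uword o = 0;
  auto blk = [&](Mat<eT>& M, uword r, uword k) {
    M.set_size(r, k);
    for (uword i = 0; i < r * k; ++i) M(i) = (eT)p[o + i];
    o += r * k;
  };
  auto vecblk = [&](Col<eT>& v, uword n) {
    v.set_size(n);
    for (uword i = 0; i < n; ++i) v(i) = (eT)p[o + i];
    o += n;
  };
  walk_params<eT>(c, blk, vecblk, P);
  return P;
}

template <typename eT>
void pack_grads(const Params<eT>& G, double* g, const Cfg& c) {
  uword o = 0;
  auto blk = [&](Mat<eT>& M, uword, uword) {
    for (uword i = 0; i < M.n_elem; ++i) g[o + i] = (double)M(i);
    o += M.n_elem;
  };
  auto vecblk = [&](Col<eT>& v, uword) {
    for (uword i = 0; i < v.n_elem; ++i) g[o + i] = (double)v(i);
    o += v.n_elem;
  };
  walk_params<eT>(c, blk, vecblk, const_cast<Params<eT>&>(G));
}

// Zero the guard columns of a strided activation (leading block plus one
// block after each sample).
template <typename eT>
void zero_guards(Mat<eT>& A, uword L, uword B, uword G) {
  A.cols(0, G - 1).zeros();
  const uword Ls = L + G;
  for (uword b = 0; b < B; ++b)
    A.cols(G + b * Ls + L, G + b * Ls + Ls - 1).zeros();
}

// Scatter an L x B matrix into the data columns of a strided 1 x T row (or
// gather back).
template <typename eT>
void to_strided(const Mat<eT>& X, Mat<eT>& A, uword L, uword B, uword G) {
  A.zeros(1, G + B * (L + G));
  for (uword b = 0; b < B; ++b)
    for (uword i = 0; i < L; ++i)
      A(0, G + b * (L + G) + i) = X(i, b);
}

template <typename eT>
Mat<eT> from_strided(const Mat<eT>& A, uword C, uword L, uword B, uword G) {
  Mat<eT> X(C * L, B);  // rows grouped by position: (c, i) -> c + C*i
  for (uword b = 0; b < B; ++b)
    for (uword i = 0; i < L; ++i)
      for (uword c = 0; c < C; ++c)
        X(c + C * i, b) = A(c, G + b * (L + G) + i);
  return X;
}

// Same-padded convolution as one GEMM per kernel tap.  W is Cout x (Cin*K)
// with tap t in columns [Cin*t, Cin*t + Cin).
template <typename eT>
void conv_forward(const Mat<eT>& A, const Mat<eT>& W, const Col<eT>& b,
                  Mat<eT>& Z, uword Cin, uword K) {
  const sword pl = (sword)((K - 1) / 2);
  const sword T = (sword)A.n_cols;
  Z.zeros(W.n_rows, T);
  for (uword t = 0; t < K; ++t) {
    const sword sh = (sword)t - pl;
    const sword lo = sh < 0 ? -sh : 0;
    const sword hi = sh > 0 ? T - 1 - sh : T - 1;
    Z.cols(lo, hi) += W.cols(Cin * t, Cin * t + Cin - 1) * A.cols(lo + sh, hi + sh);
  }
  Z.each_col() += b;
}

// Gradients of a convolution: weight/bias gradients and (optionally) the
// input gradient.  dZ must have zeroed guard columns.
template <typename eT>
void conv_backward(const Mat<eT>& A, const Mat<eT>& W, const Mat<eT>& dZ,
                   Mat<eT>& dW, Col<eT>& db, Mat<eT>* dA,
                   uword Cin, uword K) {
  const sword pl = (sword)((K - 1) / 2);
  const sword T = (sword)A.n_cols;
  dW.set_size(W.n_rows, W.n_cols);
  if (dA) dA->zeros(Cin, T);
  for (uword t = 0; t < K; ++t) {
    const sword sh = (sword)t - pl;
    const sword lo = sh < 0 ? -sh : 0;
    const sword hi = sh > 0 ? T - 1 - sh : T - 1;
    dW.cols(Cin * t, Cin * t + Cin - 1) =
      dZ.cols(lo, hi) * A.cols(lo + sh, hi + sh).t();
    if (dA)
      dA->cols(lo + sh, hi + sh) += W.cols(Cin * t, Cin * t + Cin - 1).t() * dZ.cols(lo, hi);
  }
  db = sum(dZ, 1);
}

// Shifted-patch helpers for the full-length convolutions, all of which
// have a single channel on one side.  P is T x K with column t holding the
// row `a` shifted by sign*(t - pl); thanks to the guard columns the shifted
// reads never cross sample boundaries, and each column is one contiguous
// copy.
template <typename eT>
void build_patch(const eT* a, Mat<eT>& P, uword T, uword K, int sign) {
  const sword pl = (sword)((K - 1) / 2);
  P.set_size(T, K);
  for (uword t = 0; t < K; ++t) {
    const sword sh = sign * ((sword)t - pl);
    eT* col = P.colptr(t);
    const sword lo = sh < 0 ? -sh : 0;
    const sword hi = sh > 0 ? (sword)T - 1 - sh : (sword)T - 1;
    for (sword j = 0; j < lo; ++j) col[j] = (eT)0;
    std::memcpy(col + lo, a + lo + sh, (hi - lo + 1) * sizeof(eT));
    for (sword j = hi + 1; j < (sword)T; ++j) col[j] = (eT)0;
  }
}

// dst(j) += sum_t Y(j + sign*(t - pl), t) for a T x K matrix Y: the
// tap-summation step of the single-channel convolutions.
template <typename eT>
void add_shifted_cols(const Mat<eT>& Y, eT* dst, uword T, uword K, int sign) {
  const sword pl = (sword)((K - 1) / 2);
  for (uword t = 0; t < K; ++t) {
    const sword sh = sign * ((sword)t - pl);
    const eT* col = Y.colptr(t);
    const sword lo = sh < 0 ? -sh : 0;
    const sword hi = sh > 0 ? (sword)T - 1 - sh : (sword)T - 1;
    for (sword j = lo; j <= hi; ++j) dst[j] += col[j + sh];
  }
}

// Max pooling over the data region of a strided activation; the output is
// strided with the same guard width (guards zero).  IDX records the source
// column of each maximum (ties -> first).
template <typename eT>
void maxpool(const Mat<eT>& A, Mat<eT>& P, umat& IDX, uword C, uword L,
             uword B, uword G, uword size, uword stride, uword NW,
             bool strided_out) {
  const uword Ls = L + G;
  const uword Lo = strided_out ? NW + G : NW;
  P.zeros(C, strided_out ? G + B * Lo : B * Lo);
  IDX.zeros(C, P.n_cols);
  for (uword b = 0; b < B; ++b) {
    for (uword w = 0; w < NW; ++w) {
      const uword c0 = G + b * Ls + w * stride;
      const uword j = strided_out ? G + b * Lo + w : b * NW + w;
      for (uword ch = 0; ch < C; ++ch) {
        eT best = A(ch, c0);
        uword bi = c0;
        for (uword s = 1; s < size; ++s) {
          const eT v = A(ch, c0 + s);
          if (v > best) { best = v; bi = c0 + s; }
        }
        P(ch, j) = best;
        IDX(ch, j) = bi;
      }
    }
  }
}

template <typename eT>
Mat<eT> relu(const Mat<eT>& Z) { return clamp(Z, (eT)0, Datum<eT>::inf); }

template <typename eT>
Mat<eT> relu_mask(const Mat<eT>& Z) { return conv_to<Mat<eT>>::from(Z > (eT)0); }

template <typename eT>
struct Forward {
  Mat<eT> A0, PatchX, Z1, A1, P1out, Z2, U2, Z3, U1, Yd, Z4;
  Mat<eT> xsub, PatchXsub, Z5, P5, Fmat, Z6, A6, C, IpbD, R, D;
  umat idx1, idx2, idx5;
  eT L_rec, L_reg;
};

template <typename eT>
void run_forward(const Params<eT>& P, const Cfg& c, const Mat<eT>& X,
                 const Mat<eT>& I0, eT alpha, eT step, Forward<eT>& f) {
  const uword G = c.G, K = c.K, B = c.B;

  Mat<eT> Xs = X / (eT)c.scale;     // network input in scaled units
  to_strided(Xs, f.A0, c.L, B, G);
  build_patch(f.A0.memptr(), f.PatchX, c.T, K, +1);

  // ---- encoder ----
  f.Z1 = P.W1 * f.PatchX.t();
  f.Z1.each_col() += P.b1;
  f.A1 = relu(f.Z1);
  zero_guards(f.A1, c.L, B, G);
  maxpool(f.A1, f.P1out, f.idx1, c.C1, c.L, B, G, c.P1, c.P1, c.L1, true);

  conv_forward(f.P1out, P.W2, P.b2, f.Z2, c.C1, K);
  Mat<eT> A2 = relu(f.Z2);
  zero_guards(A2, c.L1, B, G);
  Mat<eT> code;
  maxpool(A2, code, f.idx2, c.C2, c.L1, B, G, c.P2, c.P2, c.L2, false);

  // ---- decoder ----
  f.U2.zeros(c.C2, c.T1);
  for (uword j = 0; j < c.L2 * B; ++j)
    for (uword ch = 0; ch < c.C2; ++ch)
      f.U2(ch, f.idx2(ch, j)) = code(ch, j);

  conv_forward(f.U2, P.Wd1, P.bd1, f.Z3, c.C2, K);
  Mat<eT> A3 = relu(f.Z3);
  zero_guards(A3, c.L1, B, G);

  f.U1.zeros(c.C1, c.T);
  {
    const uword Ls1 = c.L1 + G;
    for (uword b = 0; b < B; ++b)
      for (uword w = 0; w < c.L1; ++w)
        for (uword ch = 0; ch < c.C1; ++ch)
          f.U1(ch, f.idx1(ch, G + b * Ls1 + w)) = A3(ch, G + b * Ls1 + w);
  }

  // Final decoder convolution (C1 channels -> the background row).  With
  // Wm(ch, t) = Wd2(0, ch + C1*t), Z4(j) = sum_t (U1^T Wm)(j + t - pl, t).
  Mat<eT> Wm(c.C1, K);
  for (uword t = 0; t < K; ++t)
    for (uword ch = 0; ch < c.C1; ++ch)
      Wm(ch, t) = P.Wd2(0, ch + c.C1 * t);
  f.Yd = f.U1.t() * Wm;                       // T x K
  f.Z4.set_size(1, c.T);
  f.Z4.fill(P.bd2(0));
  add_shifted_cols(f.Yd, f.Z4.memptr(), c.T, K, +1);
  zero_guards(f.Z4, c.L, B, G);               // background, linear output

  // ---- concentration head on the background-subtracted spectrum ----
  f.xsub = f.A0 - f.Z4;
  build_patch(f.xsub.memptr(), f.PatchXsub, c.T, K, +1);
  f.Z5 = P.Wh * f.PatchXsub.t();
  f.Z5.each_col() += P.bh;
  Mat<eT> A5 = relu(f.Z5);
  zero_guards(A5, c.L, B, G);
  maxpool(A5, f.P5, f.idx5, c.HC, c.L, B, G, c.HPs, c.HPt, c.NW, false);

  f.Fmat.set_size(c.F, B);
  for (uword b = 0; b < B; ++b)
    for (uword w = 0; w < c.NW; ++w)
      for (uword ch = 0; ch < c.HC; ++ch)
        f.Fmat(ch + c.HC * w, b) = f.P5(ch, b * c.NW + w);

  f.Z6 = P.Wf1 * f.Fmat;
  f.Z6.each_col() += P.bf1;
  f.A6 = relu(f.Z6);
  f.C = P.Wf2 * f.A6;            // concentrations, linear
  f.C.each_col() += P.bf2;

  // ---- physics-informed loss ----
  // the decoder works in scaled units; the physical background is scale*Z4
  f.IpbD.set_size(c.L, B);
  for (uword b = 0; b < B; ++b)
    for (uword i = 0; i < c.L; ++i)
      f.IpbD(i, b) = (eT)c.scale * f.Z4(0, G + b * (c.L + G) + i);
  f.R = X - I0 * f.C - f.IpbD;
  f.D = (f.IpbD.rows(1, c.L - 1) - f.IpbD.rows(0, c.L - 2)) / step;
  f.L_rec = accu(f.R % f.R) / (eT)B;
  f.L_reg = accu(f.D % f.D) / (eT)B;
}

template <typename eT>
void run_backward(const Params<eT>& P, const Cfg& c, const Mat<eT>& I0,
                  eT alpha, eT step, Forward<eT>& f, Params<eT>& Gr) {
  const uword G = c.G, K = c.K, B = c.B;

  // d loss / d concentrations and d loss / d predicted background
  Mat<eT> dC = (eT)(-2.0 / B) * (I0.t() * f.R);
  Mat<eT> dIpb = (eT)(-2.0 / B) * f.R;
  dIpb.rows(1, c.L - 1) += ((eT)2 * alpha / ((eT)B * step)) * f.D;
  dIpb.rows(0, c.L - 2) -= ((eT)2 * alpha / ((eT)B * step)) * f.D;

  // ---- head backward ----
  Gr.Wf2 = dC * f.A6.t();
  Gr.bf2 = sum(dC, 1);
  Mat<eT> dZ6 = (P.Wf2.t() * dC) % relu_mask(f.Z6);
  Gr.Wf1 = dZ6 * f.Fmat.t();
  Gr.bf1 = sum(dZ6, 1);
  Mat<eT> dF = P.Wf1.t() * dZ6;

  Mat<eT> dA5(c.HC, c.T, fill::zeros);
  for (uword b = 0; b < B; ++b)
    for (uword w = 0; w < c.NW; ++w)
      for (uword ch = 0; ch < c.HC; ++ch)
        dA5(ch, f.idx5(ch, b * c.NW + w)) += dF(ch + c.HC * w, b);

  Mat<eT> dZ5 = dA5 % relu_mask(f.Z5);
  Gr.Wh = dZ5 * f.PatchXsub;
  Gr.bh = sum(dZ5, 1);
  // dxsub(s) = sum_{ch,t} Wh(ch,t) dZ5(ch, s - (t - pl))
  Mat<eT> Yh = dZ5.t() * P.Wh;                // T x K
  Mat<eT> dxsub(1, c.T, fill::zeros);
  add_shifted_cols(Yh, dxsub.memptr(), c.T, K, -1);
  zero_guards(dxsub, c.L, B, G);

  // xsub = input - background, so the head path pushes -dxsub into the
  // background; add the direct reconstruction/smoothness gradient.
  Mat<eT> dZ4 = -dxsub;
  for (uword b = 0; b < B; ++b)
    for (uword i = 0; i < c.L; ++i)
      dZ4(0, G + b * (c.L + G) + i) += (eT)c.scale * dIpb(i, b);

  // ---- decoder backward (final conv via the flipped patch of dZ4) ----
  Mat<eT> PatchZ4;
  build_patch(dZ4.memptr(), PatchZ4, c.T, K, -1);
  Mat<eT> Wm(c.C1, K);
  for (uword t = 0; t < K; ++t)
    for (uword ch = 0; ch < c.C1; ++ch)
      Wm(ch, t) = P.Wd2(0, ch + c.C1 * t);
  Mat<eT> dU1 = Wm * PatchZ4.t();             // C1 x T
  Mat<eT> dWd2m = f.U1 * PatchZ4;             // C1 x K
  Gr.Wd2.set_size(1, c.C1 * K);
  for (uword t = 0; t < K; ++t)
    for (uword ch = 0; ch < c.C1; ++ch)
      Gr.Wd2(0, ch + c.C1 * t) = dWd2m(ch, t);
  Gr.bd2.set_size(1);
  Gr.bd2(0) = accu(dZ4);

  Mat<eT> dA3(c.C1, c.T1, fill::zeros);
  {
    const uword Ls1 = c.L1 + G;
    for (uword b = 0; b < B; ++b)
      for (uword w = 0; w < c.L1; ++w)
        for (uword ch = 0; ch < c.C1; ++ch)
          dA3(ch, G + b * Ls1 + w) = dU1(ch, f.idx1(ch, G + b * Ls1 + w));
  }

  Mat<eT> dZ3 = dA3 % relu_mask(f.Z3);
  Mat<eT> dU2;
  conv_backward(f.U2, P.Wd1, dZ3, Gr.Wd1, Gr.bd1, &dU2, c.C2, K);

  // pool2 then unpool2 with shared indices: the gradient reaches the argmax
  // positions of A2 only.
  Mat<eT> dA2(c.C2, c.T1, fill::zeros);
  for (uword j = 0; j < c.L2 * B; ++j)
    for (uword ch = 0; ch < c.C2; ++ch)
      dA2(ch, f.idx2(ch, j)) += dU2(ch, f.idx2(ch, j));

  // ---- encoder backward ----
  Mat<eT> dZ2 = dA2 % relu_mask(f.Z2);
  zero_guards(dZ2, c.L1, B, G);
  Mat<eT> dP1;
  conv_backward(f.P1out, P.W2, dZ2, Gr.W2, Gr.b2, &dP1, c.C1, K);

  Mat<eT> dA1(c.C1, c.T, fill::zeros);
  {
    const uword Ls1 = c.L1 + G;
    for (uword b = 0; b < B; ++b)
      for (uword w = 0; w < c.L1; ++w)
        for (uword ch = 0; ch < c.C1; ++ch)
          dA1(ch, f.idx1(ch, G + b * Ls1 + w)) += dP1(ch, G + b * Ls1 + w);
  }

  Mat<eT> dZ1 = dA1 % relu_mask(f.Z1);
  Gr.W1 = dZ1 * f.PatchX;
  Gr.b1 = sum(dZ1, 1);
}

template <typename eT>
Rcpp::List core_impl(Rcpp::NumericVector par, const Cfg& c,
                     const Rcpp::NumericMatrix& X_, const Rcpp::NumericMatrix& I0_,
                     double alpha, double step, bool want_grad) {
  Params<eT> P = unpack_params<eT>(par.begin(), c);
  Mat<eT> X(c.L, c.B), I0(c.L, c.N);
  for (uword j = 0; j < c.B; ++j)
    for (uword i = 0; i < c.L; ++i) X(i, j) = (eT)X_(i, j);
  for (uword j = 0; j < c.N; ++j)
    for (uword i = 0; i < c.L; ++i) I0(i, j) = (eT)I0_(i, j);

  static thread_local Forward<eT> f;
  run_forward(P, c, X, I0, (eT)alpha, (eT)step, f);

  Rcpp::List out;
  out["concentrations"] = Rcpp::wrap(conv_to<mat>::from(f.C));
  out["background"]     = Rcpp::wrap(conv_to<mat>::from(f.IpbD));
  out["L_rec"] = (double)f.L_rec;
  out["L_reg"] = (double)f.L_reg;
  out["L_tot"] = (double)f.L_rec + alpha * (double)f.L_reg;

  if (want_grad) {
    Params<eT> Gr;
    run_backward(P, c, I0, (eT)alpha, (eT)step, f, Gr);
    Rcpp::NumericVector grad(par.size());
    pack_grads(Gr, grad.begin(), c);
    out["grad"] = grad;
  }
  return out;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".pinn_core")]]
Rcpp::List pinn_core(Rcpp::NumericVector par, Rcpp::List cfg,
                     Rcpp::NumericMatrix X, Rcpp::NumericMatrix I0,
                     double alpha, double step, bool want_grad,
                     bool use_double = false) {
  Cfg c = make_cfg(cfg, X.ncol());
  if ((uword)X.nrow() != c.L)
    Rcpp::stop("spectra length does not match the model input length");
  if ((uword)I0.nrow() != c.L || (uword)I0.ncol() != c.N)
    Rcpp::stop("reference set does not match the model grid or output width");
  if ((uword)par.size() != n_params(c))
    Rcpp::stop("parameter vector has wrong length");
  return use_double ? core_impl<double>(par, c, X, I0, alpha, step, want_grad)
                    : core_impl<float>(par, c, X, I0, alpha, step, want_grad);
}

//' @noRd
// [[Rcpp::export(name = ".pinn_n_params")]]
int pinn_n_params(Rcpp::List cfg) {
  Cfg c = make_cfg(cfg, 1);
  return (int)n_params(c);
}

//' @noRd
// [[Rcpp::export(name = ".pinn_code_shape")]]
Rcpp::IntegerVector pinn_code_shape(Rcpp::List cfg) {
  Cfg c = make_cfg(cfg, 1);
  return Rcpp::IntegerVector::create((int)c.C2, (int)c.L2);
}
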