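// Compiled core of the 1D convolutional sequence regressor.
//
// One call processes one mini-batch end to end: forward pass, loss, and
// (optionally) the full backward pass. Activations are held as
// single-precision (channels x length*batch) matrices with one
// contiguous block of `length` columns per sample, so convolutions
// become a single sgemm against an im2col matrix (whose trailing row of
// ones fuses the bias), pooling walks contiguous column groups, and the
// flatten into the dense head is a free reshape (channel fastest, then
// pooled position). Dropout masks draw from R's RNG, so results are
// reproducible under set.seed().

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct ConvLayer {
  fmat wf;   // (k*cin + 1) x f ; row c + cin*kk holds w[kk, c, ]; last row bias
  int k, cin, f;
};

ConvLayer conv_from_r(const Rcpp::List& layer) {
  Rcpp::NumericVector w = layer["w"];
  Rcpp::NumericVector b = layer["b"];
  Rcpp::IntegerVector d = w.attr("dim");
  ConvLayer cl;
  cl.k = d[0];
  cl.cin = d[1];
  cl.f = d[2];
  cl.wf.set_size(cl.k * cl.cin + 1, cl.f);
  for (int f = 0; f < cl.f; ++f) {
    for (int c = 0; c < cl.cin; ++c)
      for (int kk = 0; kk < cl.k; ++kk)
        cl.wf(c + cl.cin * kk, f) =
          static_cast<float>(w[kk + cl.k * (c + cl.cin * f)]);
    cl.wf(cl.k * cl.cin, f) = static_cast<float>(b[f]);
  }
  return cl;
}

Rcpp::NumericVector conv_grad_to_r(const fmat& dwf, int k, int cin, int f) {
  Rcpp::NumericVector dw(k * cin * f);
  dw.attr("dim") = Rcpp::IntegerVector::create(k, cin, f);
  for (int ff = 0; ff < f; ++ff)
    for (int c = 0; c < cin; ++c)
      for (int kk = 0; kk < k; ++kk)
        dw[kk + k * (c + cin * ff)] = dwf(c + cin * kk, ff);
  return dw;
}

// im2col for valid convolution, stride 1: ic is (k*cin + 1) x (lout*b)
// with a trailing row of ones.
void im2col(const fmat& a, int bsz, int l, int k, fmat& ic) {
  const int cin = a.n_rows, lout = l - k + 1;
  ic.set_size(k * cin + 1, lout * bsz);
  for (int b = 0; b < bsz; ++b)
    for (int kk = 0; kk < k; ++kk)
      ic.submat(kk * cin, b * lout, kk * cin + cin - 1,
                b * lout + lout - 1) = a.cols(b * l + kk, b * l + kk + lout - 1);
  ic.row(k * cin).ones();
}

struct BlockCache {
  fmat ic;       // im2col of the block input
  fmat z;        // pre-pool convolution output (f x lout*bsz)
  fmat pre;      // pooled pre-ReLU maxima (f x lp*bsz)
  fmat out;      // post-ReLU (and dropout) block output
  fmat dz, dnext; // backward scratch
  Mat<unsigned char> idx; // argmax offset within each pool window
  fmat mask;     // dropout mask (empty if unused)
  int l, lout, lp;
};

// reused across calls: R is single-threaded and reallocation of the
// ~40 MB of activation buffers per mini-batch otherwise dominates the
// runtime of a step
std::vector<BlockCache> g_caches;

} // namespace

// [[Rcpp::export(name = ".cnn_batch_cpp")]]
Rcpp::List cnn_batch_cpp(const Rcpp::NumericMatrix& x,
                         Rcpp::Nullable<Rcpp::NumericMatrix> y,
                         const Rcpp::List& layers,
                         int pool, double dropout,
                         bool training, bool grads_wanted,
                         Rcpp::Nullable<Rcpp::NumericVector> dropout_unifs =
                           R_NilValue) {
  const int bsz = x.nrow(), l0 = x.ncol();
  std::vector<ConvLayer> convs;
  std::vector<std::string> conv_names;
  for (int i = 0; i < layers.size(); ++i) {
    std::string nm = Rcpp::as<std::string>(
      Rcpp::as<Rcpp::CharacterVector>(layers.names())[i]);
    if (nm != "dense") {
      convs.push_back(conv_from_r(layers[i]));
      conv_names.push_back(nm);
    }
  }
  Rcpp::List dense = layers["dense"];
  Rcpp::NumericMatrix wd_r = dense["w"];
  Rcpp::NumericVector bd_r = dense["b"];
  fmat wd(wd_r.nrow(), wd_r.ncol());
  for (int j = 0; j < wd_r.ncol(); ++j)
    for (int i = 0; i < wd_r.nrow(); ++i)
      wd(i, j) = static_cast<float>(wd_r(i, j));
  fvec bd(bd_r.size());
  for (int i = 0; i < bd_r.size(); ++i) bd(i) = static_cast<float>(bd_r[i]);

  // dropout uniforms are pre-drawn in R (one stream position per mask
  // element, consumed in layout order) so training is reproducible
  // under set.seed without per-draw RNG call overhead here
  Rcpp::NumericVector unifs;
  R_xlen_t upos = 0;
  if (training && dropout > 0) {
    if (dropout_unifs.isNull())
      Rcpp::stop("dropout requires pre-drawn uniforms");
    unifs = Rcpp::NumericVector(dropout_unifs);
  }

  // ---- forward ----
  fmat a(1, l0 * bsz);
  for (int b = 0; b < bsz; ++b)
    for (int l = 0; l < l0; ++l)
      a(0, l + l0 * b) = static_cast<float>(x(b, l));

  if (g_caches.size() < convs.size()) g_caches.resize(convs.size());
  int l = l0;
  for (size_t bl = 0; bl < convs.size(); ++bl) {
    ConvLayer& cl = convs[bl];
    BlockCache& cc = g_caches[bl];
    cc.l = l;
    cc.lout = l - cl.k + 1;
    cc.lp = cc.lout / pool;
    im2col(a, bsz, l, cl.k, cc.ic);
    cc.z.set_size(cl.f, cc.lout * bsz);
    cc.z = cl.wf.t() * cc.ic; // f x (lout*bsz)
    const fmat& z = cc.z;
    // pool (width = stride = pool) then ReLU
    cc.pre.set_size(cl.f, cc.lp * bsz);
    cc.idx.set_size(cl.f, cc.lp * bsz);
    for (int b = 0; b < bsz; ++b) {
      for (int lp = 0; lp < cc.lp; ++lp) {
        const int zc0 = b * cc.lout + lp * pool;
        const int oc = b * cc.lp + lp;
        for (int f = 0; f < cl.f; ++f) {
          float best = z(f, zc0);
          unsigned char bj = 0;
          for (int j = 1; j < pool; ++j) {
            const float v = z(f, zc0 + j);
            if (v > best) { best = v; bj = (unsigned char)j; }
          }
          cc.pre(f, oc) = best;
          cc.idx(f, oc) = bj;
        }
      }
    }
    cc.out.set_size(cc.pre.n_rows, cc.pre.n_cols);
    {
      const float* p = cc.pre.memptr();
      float* o = cc.out.memptr();
      for (uword i = 0; i < cc.pre.n_elem; ++i) o[i] = p[i] > 0.0f ? p[i] : 0.0f;
    }
    fmat& out = cc.out;
    if (training && dropout > 0) {
      cc.mask.set_size(cl.f, cc.lp * bsz);
      const float scale = 1.0f / (1.0f - (float)dropout);
      if (upos + (R_xlen_t)cc.mask.n_elem > unifs.size())
        Rcpp::stop("not enough dropout uniforms supplied");
      float* m = cc.mask.memptr();
      const double* u = REAL(unifs) + upos;
      for (uword i = 0; i < cc.mask.n_elem; ++i)
        m[i] = (u[i] >= dropout) ? scale : 0.0f;
      upos += cc.mask.n_elem;
      out %= cc.mask;
    } else {
      cc.mask.reset(); // buffers persist across calls; drop stale masks
    }
    a = out; // plain copy; keeps `a` an owning, resizable matrix
    l = cc.lp;
  }

  // flatten: per-sample contiguous (f x lp) block -> column of length f*lp
  const int flat_dim = convs.back().f * g_caches[convs.size() - 1].lp;
  fmat xf(a.memptr(), flat_dim, bsz, false, true);
  fmat pred = wd.t() * xf; // 2 x bsz
  pred.each_col() += bd;

  Rcpp::NumericMatrix pred_r(bsz, 2);
  for (int b = 0; b < bsz; ++b)
    for (int j = 0; j < 2; ++j) pred_r(b, j) = pred(j, b);

  double loss = NA_REAL;
  fmat resid;
  if (y.isNotNull()) {
    Rcpp::NumericMatrix yr(y);
    resid.set_size(2, bsz);
    for (int b = 0; b < bsz; ++b)
      for (int j = 0; j < 2; ++j)
        resid(j, b) = pred(j, b) - static_cast<float>(yr(b, j));
    loss = accu(conv_to<mat>::from(square(resid))) / (2.0 * bsz);
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("pred") = pred_r,
                                      Rcpp::Named("loss") = loss);
  if (!grads_wanted) return out;
  if (y.isNull()) Rcpp::stop("gradients require targets");

  // ---- backward ----
  fmat dpred = resid * (2.0f / (2.0f * bsz));
  fmat dwd = xf * dpred.t();
  fvec dbd = sum(dpred, 1);
  fmat dxf = wd * dpred; // flat_dim x bsz
  fmat da(dxf.memptr(), convs.back().f,
          g_caches[convs.size() - 1].lp * bsz, false, true);

  Rcpp::List grads;
  fmat da_cur = da;
  for (int bl = (int)convs.size() - 1; bl >= 0; --bl) {
    ConvLayer& cl = convs[bl];
    BlockCache& cc = g_caches[bl];
    if (cc.mask.n_elem) da_cur %= cc.mask;
    // pool+relu backward: route to argmax where the pre-ReLU max was > 0
    cc.dz.set_size(cl.f, cc.lout * bsz);
    cc.dz.zeros();
    fmat& dz = cc.dz;
    for (int b = 0; b < bsz; ++b)
      for (int lp = 0; lp < cc.lp; ++lp) {
        const int oc = b * cc.lp + lp;
        const int zc0 = b * cc.lout + lp * pool;
        for (int f = 0; f < cl.f; ++f)
          if (cc.pre(f, oc) > 0.0f)
            dz(f, zc0 + cc.idx(f, oc)) += da_cur(f, oc);
      }
    fmat dwf = cc.ic * dz.t(); // (k*cin+1) x f
    Rcpp::List g = Rcpp::List::create(
      Rcpp::Named("w") = conv_grad_to_r(dwf, cl.k, cl.cin, cl.f),
      Rcpp::Named("b") = Rcpp::wrap(
        conv_to<std::vector<double>>::from(dwf.row(cl.k * cl.cin))));
    grads[conv_names[bl]] = g;
    if (bl > 0) {
      fmat dic = cl.wf * dz; // (k*cin+1) x (lout*bsz); last row unused
      cc.dnext.set_size(cl.cin, cc.l * bsz);
      cc.dnext.zeros();
      for (int b = 0; b < bsz; ++b)
        for (int kk = 0; kk < cl.k; ++kk)
          cc.dnext.cols(b * cc.l + kk, b * cc.l + kk + cc.lout - 1) +=
            dic.submat(kk * cl.cin, b * cc.lout,
                       kk * cl.cin + cl.cin - 1, b * cc.lout + cc.lout - 1);
      da_cur = cc.dnext;
    }
  }

  Rcpp::NumericMatrix dwd_r(dwd.n_rows, dwd.n_cols);
  for (uword j = 0; j < dwd.n_cols; ++j)
    for (uword i = 0; i < dwd.n_rows; ++i) dwd_r(i, j) = dwd(i, j);
  grads["dense"] = Rcpp::List::create(
    Rcpp::Named("w") = dwd_r,
    Rcpp::Named("b") = Rcpp::wrap(conv_to<std::vector<double>>::from(dbd)));

  out["grads"] = grads;
  return out;
}
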