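// 3D U-Net forward and backward passes, implemented monolithically in C++
// (float32) so that one training sample costs a handful of GEMMs with no
// R-level round trips. Tensors are channel-last, flat (nvox x channels)
// matrices over cubic grids. The im2col buffer is built on a zero-padded
// volume so that every patch column is one contiguous shifted copy; the
// halo rows of the GEMM output are discarded.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// The forward/backward passes allocate and free a few hundred MB of patch
// matrices per training sample. With glibc defaults these blocks are
// mmap()ed and returned to the OS on free, so every step pays the page
// faults again; raising the thresholds keeps them on the heap for reuse.
// [[Rcpp::init]]
void haruspex_malloc_tuning(DllInfo* dll) {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
  (void)dll;
}

namespace {

struct Tensor {
  arma::fmat m; // nvox x C
  int n;        // cubic edge
};

inline size_t vox(int n) { return (size_t)n * n * n; }

arma::fmat r_to_f(const NumericMatrix& w) {
  arma::fmat out(w.nrow(), w.ncol());
  for (int j = 0; j < w.ncol(); ++j)
    for (int i = 0; i < w.nrow(); ++i) out(i, j) = (float)w(i, j);
  return out;
}

// zero-pad a cubic channel-last tensor by 1 voxel on every side
arma::fmat pad1(const arma::fmat& x, int n) {
  const int np = n + 2;
  arma::fmat out(vox(np), x.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < x.n_cols; ++c) {
    const float* src = x.colptr(c);
    float* dst = out.colptr(c);
    for (int z = 0; z < n; ++z)
      for (int y = 0; y < n; ++y)
        std::memcpy(dst + 1 + (size_t)np * ((y + 1) + (size_t)np * (z + 1)),
                    src + (size_t)n * (y + (size_t)n * z), sizeof(float) * n);
  }
  return out;
}

// patch matrix on the padded grid: column (o*C + c) is channel c of the
// padded volume shifted by offset o (one contiguous copy per column)
arma::fmat im2colp(const arma::fmat& xp, int np) {
  const size_t N = vox(np);
  const int C = xp.n_cols;
  arma::fmat Pt(N, (size_t)27 * C, arma::fill::none);
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int o = (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
        const long s = dx + np * (long)(dy + np * (long)dz);
        const size_t len = N - (s < 0 ? -s : s);
        for (int c = 0; c < C; ++c) {
          float* dst = Pt.colptr((size_t)o * C + c);
          const float* src = xp.colptr(c);
          // copy the shifted overlap; zero only the short wrap gap
          if (s >= 0) {
            std::memcpy(dst, src + s, sizeof(float) * len);
            std::memset(dst + len, 0, sizeof(float) * (N - len));
          } else {
            std::memset(dst, 0, sizeof(float) * (N - len));
            std::memcpy(dst - s, src, sizeof(float) * len);
          }
        }
      }
  return Pt;
}

// extract the interior (unpadded) rows of a padded-grid matrix
arma::fmat interior(const arma::fmat& yp, int n) {
  const int np = n + 2;
  arma::fmat out(vox(n), yp.n_cols);
  for (arma::uword c = 0; c < yp.n_cols; ++c) {
    const float* src = yp.colptr(c);
    float* dst = out.colptr(c);
    for (int z = 0; z < n; ++z)
      for (int y = 0; y < n; ++y)
        std::memcpy(dst + (size_t)n * (y + (size_t)n * z),
                    src + 1 + (size_t)np * ((y + 1) + (size_t)np * (z + 1)),
                    sizeof(float) * n);
  }
  return out;
}

// embed an interior-grid matrix into padded-grid rows (zeros in the halo)
arma::fmat embed(const arma::fmat& y, int n) {
  const int np = n + 2;
  arma::fmat out(vox(np), y.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < y.n_cols; ++c) {
    const float* src = y.colptr(c);
    float* dst = out.colptr(c);
    for (int z = 0; z < n; ++z)
      for (int y2 = 0; y2 < n; ++y2)
        std::memcpy(dst + 1 + (size_t)np * ((y2 + 1) + (size_t)np * (z + 1)),
                    src + (size_t)n * (y2 + (size_t)n * z), sizeof(float) * n);
  }
  return out;
}

struct ConvCache {
  arma::fmat Pt;  // patch matrix of the layer input (padded grid)
  arma::fmat y;   // post-activation output (interior grid)
  arma::fmat z;   // normalized pre-bias activations (instance norm)
  arma::fvec inv; // per-channel 1/sqrt(var + eps)
};

const float IN_EPS = 1e-5f;

// same-padded 3^3 convolution with per-channel instance normalization of
// the convolution response (normalized over the spatial grid of the
// sample, no batch statistics) and fused bias + ReLU
Tensor conv3(const Tensor& x, const arma::fmat& W, const arma::fvec& b,
             bool relu, ConvCache* cache) {
  const int n = x.n, np = n + 2;
  arma::fmat xp = pad1(x.m, n);
  arma::fmat Pt = im2colp(xp, np);
  arma::fmat Yp = Pt * W.t(); // Npad x Co
  arma::fmat y = interior(Yp, n);
  const size_t N = vox(n);
  arma::fmat z;
  arma::fvec inv(y.n_cols);
  if (cache) z.set_size(N, y.n_cols);
  for (arma::uword c = 0; c < y.n_cols; ++c) {
    float* col = y.colptr(c);
    double mu = 0;
    for (size_t i = 0; i < N; ++i) mu += col[i];
    mu /= N;
    double var = 0;
    for (size_t i = 0; i < N; ++i) {
      const double d = col[i] - mu;
      var += d * d;
    }
    var /= N;
    const float iv = 1.0f / std::sqrt((float)var + IN_EPS);
    inv[c] = iv;
    const float bc = b[c];
    float* zc = cache ? z.colptr(c) : nullptr;
    for (size_t i = 0; i < N; ++i) {
      const float zv = (col[i] - (float)mu) * iv;
      if (zc) zc[i] = zv;
      float v = zv + bc;
      col[i] = relu && v < 0 ? 0 : v;
    }
  }
  if (cache) {
    cache->Pt = std::move(Pt);
    cache->y = y;
    cache->z = std::move(z);
    cache->inv = inv;
  }
  return Tensor{std::move(y), n};
}

// mirror the kernel for the input-gradient convolution:
// Wflip[(o, ci), co] = W[co, (26 - o) * Ci + ci]
arma::fmat flip_kernel(const arma::fmat& W, int Ci) {
  const int Co = W.n_rows;
  arma::fmat F(27 * Co, Ci);
  for (int o = 0; o < 27; ++o)
    for (int co = 0; co < Co; ++co)
      for (int ci = 0; ci < Ci; ++ci)
        F(o * Co + co, ci) = W(co, (26 - o) * Ci + ci);
  return F;
}

// backward of conv3 (+ fused instance norm, bias, ReLU): gy is modified in
// place; returns grad w.r.t. the layer input and fills gW / gb. The input
// gradient is computed as a correlation with the mirrored kernel, which is
// another same-padded convolution.
Tensor conv3_bw(const ConvCache& cache, const arma::fmat& W, bool relu,
                arma::fmat& gy, int n, int Cin, arma::fmat& gW,
                arma::fvec& gb) {
  if (relu) gy %= arma::conv_to<arma::fmat>::from(cache.y > 0);
  gb = arma::sum(gy, 0).t();
  // instance-norm backward: gu = inv * (gz - mean(gz) - z * mean(gz * z))
  const size_t N = gy.n_rows;
  for (arma::uword c = 0; c < gy.n_cols; ++c) {
    float* g = gy.colptr(c);
    const float* zc = cache.z.colptr(c);
    double m1 = 0, m2 = 0;
    for (size_t i = 0; i < N; ++i) {
      m1 += g[i];
      m2 += (double)g[i] * zc[i];
    }
    m1 /= N;
    m2 /= N;
    const float iv = cache.inv[c];
    for (size_t i = 0; i < N; ++i)
      g[i] = iv * (g[i] - (float)m1 - zc[i] * (float)m2);
  }
  arma::fmat gyp = embed(gy, n);
  gW = gyp.t() * cache.Pt; // Co x 27C
  arma::fmat Pg = im2colp(gyp, n + 2);
  arma::fmat gxp = Pg * flip_kernel(W, Cin);
  return Tensor{interior(gxp, n), n};
}

Tensor maxpool(const Tensor& x, arma::umat* idx) {
  const int n = x.n, m = n / 2;
  const int C = x.m.n_cols;
  Tensor out{arma::fmat(vox(m), C), m};
  if (idx) idx->set_size(vox(m), C);
  for (int c = 0; c < C; ++c) {
    const float* xc = x.m.colptr(c);
    float* yc = out.m.colptr(c);
    for (int z = 0; z < m; ++z)
      for (int y = 0; y < m; ++y)
        for (int xx = 0; xx < m; ++xx) {
          float best = -1e30f;
          size_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t i = (2 * xx + dx) +
                           (size_t)n * ((2 * y + dy) + (size_t)n * (2 * z + dz));
                if (xc[i] > best) {
                  best = xc[i];
                  bi = i;
                }
              }
          size_t o = xx + (size_t)m * (y + (size_t)m * z);
          yc[o] = best;
          if (idx) (*idx)(o, c) = bi;
        }
  }
  return out;
}

Tensor maxpool_bw(const arma::fmat& gy, const arma::umat& idx, int n) {
  const int C = gy.n_cols;
  Tensor out{arma::fmat(vox(n), C, arma::fill::zeros), n};
  for (int c = 0; c < C; ++c) {
    float* gc = out.m.colptr(c);
    const float* gyc = gy.colptr(c);
    for (size_t i = 0; i < gy.n_rows; ++i) gc[idx(i, c)] += gyc[i];
  }
  return out;
}

Tensor upsample(const Tensor& x) {
  const int n = x.n, u = 2 * n;
  const int C = x.m.n_cols;
  Tensor out{arma::fmat(vox(u), C), u};
  for (int c = 0; c < C; ++c) {
    const float* xc = x.m.colptr(c);
    float* yc = out.m.colptr(c);
    for (int z = 0; z < u; ++z)
      for (int y = 0; y < u; ++y) {
        const float* row = xc + (size_t)n * ((y / 2) + (size_t)n * (z / 2));
        float* orow = yc + (size_t)u * (y + (size_t)u * z);
        for (int xx = 0; xx < u; ++xx) orow[xx] = row[xx / 2];
      }
  }
  return out;
}

Tensor upsample_bw(const arma::fmat& gy, int u) {
  const int n = u / 2;
  const int C = gy.n_cols;
  Tensor out{arma::fmat(vox(n), C, arma::fill::zeros), n};
  for (int c = 0; c < C; ++c) {
    const float* gc = gy.colptr(c);
    float* xc = out.m.colptr(c);
    for (int z = 0; z < u; ++z)
      for (int y = 0; y < u; ++y) {
        const float* row = gc + (size_t)u * (y + (size_t)u * z);
        float* orow = xc + (size_t)n * ((y / 2) + (size_t)n * (z / 2));
        for (int xx = 0; xx < u; ++xx) orow[xx / 2] += row[xx];
      }
  }
  return out;
}

struct Net {
  int levels, inputSize, outputSize, base;
  std::vector<std::string> names;
  std::vector<arma::fmat> W;
  std::vector<arma::fvec> b;
  arma::fmat outW; // 4 x C1
  arma::fvec outb;

  int find(const std::string& nm) const {
    for (size_t i = 0; i < names.size(); ++i)
      if (names[i] == nm) return (int)i;
    stop("missing parameter: " + nm);
    return -1;
  }
};

Net load_net(const List& params, const IntegerVector& cfg) {
  Net net;
  net.levels = cfg[0];
  net.inputSize = cfg[1];
  net.outputSize = cfg[2];
  net.base = cfg[3];
  CharacterVector nms = params.names();
  for (int i = 0; i < params.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    if (nm == "out_W") {
      net.outW = r_to_f(as<NumericMatrix>(params[i]));
    } else if (nm == "out_b") {
      NumericVector v = params[i];
      net.outb = arma::fvec(v.size());
      for (int j = 0; j < v.size(); ++j) net.outb[j] = (float)v[j];
    } else if (nm.size() > 2 && nm.substr(nm.size() - 2) == "_W") {
      net.names.push_back(nm.substr(0, nm.size() - 2));
      net.W.push_back(r_to_f(as<NumericMatrix>(params[i])));
      net.b.push_back(arma::fvec());
    }
  }
  // biases by name lookup (order-independent)
  for (size_t k = 0; k < net.names.size(); ++k) {
    std::string bn = net.names[k] + "_b";
    for (int i = 0; i < params.size(); ++i) {
      if (as<std::string>(nms[i]) == bn) {
        NumericVector v = params[i];
        net.b[k] = arma::fvec(v.size());
        for (int j = 0; j < v.size(); ++j) net.b[k][j] = (float)v[j];
      }
    }
  }
  return net;
}

struct ForwardState {
  std::vector<ConvCache> enc1, enc2; // per level
  std::vector<arma::umat> poolidx;
  std::vector<int> enc_n;
  ConvCache bot1, bot2;
  int bot_n;
  std::vector<ConvCache> dec1, dec2;
  std::vector<int> dec_n, dec_nup;
  arma::fmat cropped; // nvox20 x C1
  arma::fmat probs;   // nvox20 x 4
};

// forward pass; fills st when train = true
arma::fmat forward(const Net& net, const arma::fmat& x0, bool train,
                   ForwardState& st) {
  const int L = net.levels;
  Tensor cur{x0, net.inputSize};
  st.enc1.resize(L);
  st.enc2.resize(L);
  st.poolidx.resize(L);
  st.enc_n.resize(L);
  st.dec1.resize(L);
  st.dec2.resize(L);
  st.dec_n.resize(L);
  st.dec_nup.resize(L);
  std::vector<Tensor> skips(L);
  for (int l = 0; l < L; ++l) {
    std::string nm = "enc" + std::to_string(l + 1) + "_";
    int i1 = net.find(nm + "1"), i2 = net.find(nm + "2");
    st.enc_n[l] = cur.n;
    Tensor r1 = conv3(cur, net.W[i1], net.b[i1], true, train ? &st.enc1[l] : nullptr);
    Tensor r2 = conv3(r1, net.W[i2], net.b[i2], true, &st.enc2[l]);
    skips[l] = Tensor{st.enc2[l].y, r2.n}; // share
    cur = maxpool(r2, train ? &st.poolidx[l] : nullptr);
  }
  int ib1 = net.find("bot_1"), ib2 = net.find("bot_2");
  st.bot_n = cur.n;
  Tensor b1 = conv3(cur, net.W[ib1], net.b[ib1], true, train ? &st.bot1 : nullptr);
  Tensor b2 = conv3(b1, net.W[ib2], net.b[ib2], true, train ? &st.bot2 : nullptr);
  cur = std::move(b2);
  for (int l = L - 1; l >= 0; --l) {
    Tensor up = upsample(cur);
    st.dec_nup[l] = up.m.n_cols;
    st.dec_n[l] = up.n;
    arma::fmat ct = arma::join_rows(up.m, skips[l].m);
    Tensor tct{std::move(ct), up.n};
    std::string nm = "dec" + std::to_string(l + 1) + "_";
    int i1 = net.find(nm + "1"), i2 = net.find(nm + "2");
    Tensor d1 = conv3(tct, net.W[i1], net.b[i1], true, train ? &st.dec1[l] : nullptr);
    Tensor d2 = conv3(d1, net.W[i2], net.b[i2], true, train ? &st.dec2[l] : nullptr);
    cur = std::move(d2);
  }
  // center crop to the output cube
  const int n = cur.n, m = (net.inputSize - net.outputSize) / 2,
            no = net.outputSize;
  const int C1 = cur.m.n_cols;
  arma::fmat cropped(vox(no), C1);
  for (int c = 0; c < C1; ++c) {
    const float* src = cur.m.colptr(c);
    float* dst = cropped.colptr(c);
    for (int z = 0; z < no; ++z)
      for (int y = 0; y < no; ++y)
        std::memcpy(dst + (size_t)no * (y + (size_t)no * z),
                    src + m + (size_t)n * ((y + m) + (size_t)n * (z + m)),
                    sizeof(float) * no);
  }
  arma::fmat logits = cropped * net.outW.t(); // nvox20 x 4
  logits.each_row() += net.outb.t();
  arma::fvec mx = arma::max(logits, 1);
  logits.each_col() -= mx;
  arma::fmat e = arma::exp(logits);
  arma::fvec s = arma::sum(e, 1);
  e.each_col() /= s;
  if (train) {
    st.cropped = std::move(cropped);
    st.probs = e;
  }
  return e;
}

NumericVector probs_to_r(const arma::fmat& p, int no) {
  NumericVector out((R_xlen_t)p.n_elem);
  for (arma::uword i = 0; i < p.n_elem; ++i) out[i] = p.memptr()[i];
  out.attr("dim") = IntegerVector::create(no, no, no, 4);
  return out;
}

} // namespace

// forward only: input x is an inputSize^3 numeric array; returns
// outputSize^3 x 4 softmax probabilities
// [[Rcpp::export(name = ".cpp_unet_fw")]]
NumericVector cpp_unet_fw(List params, IntegerVector cfg, NumericVector x) {
  Net net = load_net(params, cfg);
  const size_t N = vox(net.inputSize);
  if ((size_t)x.size() != N) stop("unet_fw: input size mismatch");
  arma::fmat x0(N, 1);
  for (size_t i = 0; i < N; ++i) x0(i, 0) = (float)x[i];
  ForwardState st;
  arma::fmat p = forward(net, x0, false, st);
  return probs_to_r(p, net.outputSize);
}

// forward + backward for one training sample. target: outputSize^3 class
// codes (1..4); weights: outputSize^3 non-negative loss weights;
// classLogW: per-class logit offsets (log of the class loss weights) added
// before the softmax of the training head, so that the emitted
// (offset-free) probabilities stay calibrated posteriors while the
// training objective is the weighted cross-entropy. Returns the loss, the
// training-head probabilities, and the gradient of the loss w.r.t. every
// parameter (same names as `params`).
// [[Rcpp::export(name = ".cpp_unet_fwbw")]]
List cpp_unet_fwbw(List params, IntegerVector cfg, NumericVector x,
                   IntegerVector target, NumericVector weights,
                   NumericVector classLogW) {
  Net net = load_net(params, cfg);
  const size_t N = vox(net.inputSize);
  const size_t No = vox(net.outputSize);
  if ((size_t)x.size() != N) stop("unet_fwbw: input size mismatch");
  if ((size_t)target.size() != No || (size_t)weights.size() != No)
    stop("unet_fwbw: target/weight size mismatch");
  arma::fmat x0(N, 1);
  for (size_t i = 0; i < N; ++i) x0(i, 0) = (float)x[i];
  ForwardState st;
  forward(net, x0, true, st);
  if (classLogW.size() == 4) {
    // training head: re-softmax with the class-weight logit offsets
    arma::fmat lg = arma::log(st.probs + 1e-30f);
    for (int k = 0; k < 4; ++k) lg.col(k) += (float)classLogW[k];
    arma::fvec mx = arma::max(lg, 1);
    lg.each_col() -= mx;
    arma::fmat e2 = arma::exp(lg);
    arma::fvec s2 = arma::sum(e2, 1);
    e2.each_col() /= s2;
    st.probs = e2;
  }

  // weighted cross-entropy and its gradient at the logits
  double sw = 0;
  for (size_t i = 0; i < No; ++i) sw += weights[i];
  double loss = 0;
  arma::fmat gl(No, 4, arma::fill::zeros);
  if (sw > 0) {
    for (size_t i = 0; i < No; ++i) {
      const int t = target[i] - 1;
      const double w = weights[i];
      double pt = st.probs(i, t);
      if (pt < 1e-12) pt = 1e-12;
      loss -= w * std::log(pt);
      if (w > 0)
        for (int k = 0; k < 4; ++k)
          gl(i, k) = (float)(w * (st.probs(i, k) - (k == t ? 1.0 : 0.0)));
    }
    loss /= sw;
    gl /= (float)sw;
  }

  List grads;
  arma::fmat goutW = gl.t() * st.cropped; // 4 x C1
  arma::fvec goutb = arma::sum(gl, 0).t();
  arma::fmat gcrop = gl * net.outW; // nvox20 x C1

  // un-crop into the full level-0 grid
  const int L = net.levels;
  const int n0 = net.inputSize, no = net.outputSize, m = (n0 - no) / 2;
  const int C1 = gcrop.n_cols;
  arma::fmat gcur(vox(n0), C1, arma::fill::zeros);
  for (int c = 0; c < C1; ++c) {
    const float* src = gcrop.colptr(c);
    float* dst = gcur.colptr(c);
    for (int z = 0; z < no; ++z)
      for (int y = 0; y < no; ++y)
        std::memcpy(dst + m + (size_t)n0 * ((y + m) + (size_t)n0 * (z + m)),
                    src + (size_t)no * (y + (size_t)no * z), sizeof(float) * no);
  }

  std::vector<arma::fmat> gW(net.W.size());
  std::vector<arma::fvec> gb(net.b.size());
  std::vector<arma::fmat> gskip(L);
  for (int l = 0; l < L; ++l) {
    std::string nm = "dec" + std::to_string(l + 1) + "_";
    int i1 = net.find(nm + "1"), i2 = net.find(nm + "2");
    int n = st.dec_n[l];
    Tensor g2 = conv3_bw(st.dec2[l], net.W[i2], true, gcur, n,
                         net.W[i2].n_cols / 27, gW[i2], gb[i2]);
    Tensor g1 = conv3_bw(st.dec1[l], net.W[i1], true, g2.m, n,
                         net.W[i1].n_cols / 27, gW[i1], gb[i1]);
    const int nup = st.dec_nup[l];
    arma::fmat gup = g1.m.cols(0, nup - 1);
    gskip[l] = g1.m.cols(nup, g1.m.n_cols - 1);
    Tensor gdown = upsample_bw(gup, n);
    gcur = std::move(gdown.m);
  }
  {
    int i1 = net.find("bot_1"), i2 = net.find("bot_2");
    int n = st.bot_n;
    Tensor g2 = conv3_bw(st.bot2, net.W[i2], true, gcur, n,
                         net.W[i2].n_cols / 27, gW[i2], gb[i2]);
    Tensor g1 = conv3_bw(st.bot1, net.W[i1], true, g2.m, n,
                         net.W[i1].n_cols / 27, gW[i1], gb[i1]);
    gcur = std::move(g1.m);
  }
  for (int l = L - 1; l >= 0; --l) {
    std::string nm = "enc" + std::to_string(l + 1) + "_";
    int i1 = net.find(nm + "1"), i2 = net.find(nm + "2");
    int n = st.enc_n[l];
    Tensor gr2 = maxpool_bw(gcur, st.poolidx[l], n);
    gr2.m += gskip[l];
    Tensor g2 = conv3_bw(st.enc2[l], net.W[i2], true, gr2.m, n,
                         net.W[i2].n_cols / 27, gW[i2], gb[i2]);
    Tensor g1 = conv3_bw(st.enc1[l], net.W[i1], true, g2.m, n,
                         net.W[i1].n_cols / 27, gW[i1], gb[i1]);
    gcur = std::move(g1.m);
  }

  CharacterVector nms(2 * net.names.size() + 2);
  List out(2 * net.names.size() + 2);
  for (size_t k = 0; k < net.names.size(); ++k) {
    NumericMatrix gw(gW[k].n_rows, gW[k].n_cols);
    for (arma::uword j = 0; j < gW[k].n_cols; ++j)
      for (arma::uword i = 0; i < gW[k].n_rows; ++i) gw(i, j) = gW[k](i, j);
    NumericVector gbv(gb[k].n_elem);
    for (arma::uword i = 0; i < gb[k].n_elem; ++i) gbv[i] = gb[k][i];
    out[2 * k] = gw;
    nms[2 * k] = net.names[k] + "_W";
    out[2 * k + 1] = gbv;
    nms[2 * k + 1] = net.names[k] + "_b";
  }
  NumericMatrix gow(4, goutW.n_cols);
  for (arma::uword j = 0; j < goutW.n_cols; ++j)
    for (int i = 0; i < 4; ++i) gow(i, j) = goutW(i, j);
  NumericVector gob(4);
  for (int i = 0; i < 4; ++i) gob[i] = goutb[i];
  out[2 * net.names.size()] = gow;
  nms[2 * net.names.size()] = "out_W";
  out[2 * net.names.size() + 1] = gob;
  nms[2 * net.names.size() + 1] = "out_b";
  out.attr("names") = nms;
  return List::create(_["loss"] = loss,
                      _["probs"] = probs_to_r(st.probs, net.outputSize),
                      _["grads"] = out);
}
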