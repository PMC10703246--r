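// Minimal fully-convolutional U-Net with hand-rolled backpropagation.
//
// Layout conventions (match the R side):
//  * images are cubes (H, W, C), column-major as R arrays;
//  * a 3x3 conv weight is a matrix (Cout, Cin*9); column index
//    cin*9 + (dr+1)*3 + (dc+1) addresses input channel `cin`, row offset
//    `dr`, column offset `dc`; zero padding, stride 1;
//  * the 1x1 head weight is a matrix (1, Cin).
//
// The network: L resolution levels with channel widths channels[0..L-1]
// (level L-1 is the bottleneck), 2x2 max-pooling between levels, nearest
// 2x upsampling + skip concatenation on the way up, ReLU after every 3x3
// conv, sigmoid head, soft Dice loss.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// valid-region bounds for a (dr, dc) kernel offset on an H x W image:
// output pixel (i, j) reads input (i+dr, j+dc); zero padding elsewhere.
static inline void offs_bounds(int H, int W, int dr, int dc, int& i0,
                               int& i1, int& j0, int& j1) {
  i0 = dr < 0 ? 1 : 0; i1 = H - 1 - (dr > 0 ? 1 : 0);
  j0 = dc < 0 ? 1 : 0; j1 = W - 1 - (dc > 0 ? 1 : 0);
}

// Column-major blocking: the outer loop walks output columns so the
// Cout active output (resp. gradient) columns stay cache-resident while
// every input column is streamed once per neighborhood.
static arma::cube conv3_forward(const arma::cube& in, const arma::mat& Wt,
                                const arma::vec& b, bool relu) {
  const int H = in.n_rows, W = in.n_cols, Cin = in.n_slices,
            Cout = Wt.n_rows;
  arma::cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co) out.slice(co).fill(b(co));
  for (int j = 0; j < W; ++j) {
    for (int ci = 0; ci < Cin; ++ci) {
      const arma::mat& sl = in.slice(ci);
      for (int dc = -1; dc <= 1; ++dc) {
        const int jc = j + dc;
        if (jc < 0 || jc >= W) continue;
        const double* pcol = sl.colptr(jc);
        for (int dr = -1; dr <= 1; ++dr) {
          const int i0 = dr < 0 ? 1 : 0, i1 = H - 1 - (dr > 0 ? 1 : 0);
          const int len = i1 - i0 + 1;
          const double* ps = pcol + i0 + dr;
          const arma::uword wcol = ci * 9 + (dr + 1) * 3 + (dc + 1);
          for (int co = 0; co < Cout; ++co) {
            const double w = Wt(co, wcol);
            double* po = out.slice(co).colptr(j) + i0;
            for (int k = 0; k < len; ++k) po[k] += w * ps[k];
          }
        }
      }
    }
  }
  if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return out;
}

// backward through (conv3x3 [+ReLU]); `out` is the stored post-activation
static void conv3_backward(const arma::cube& in, const arma::mat& Wt,
                           const arma::cube& out, arma::cube& dout, bool relu,
                           arma::mat& dW, arma::vec& db, arma::cube& din) {
  const int H = in.n_rows, W = in.n_cols, Cin = in.n_slices,
            Cout = Wt.n_rows;
  if (relu) dout %= arma::conv_to<arma::cube>::from(out > 0.0);
  dW.zeros(Cout, Cin * 9);
  db.set_size(Cout);
  for (int co = 0; co < Cout; ++co) db(co) = arma::accu(dout.slice(co));
  din.zeros(H, W, Cin);
  for (int j = 0; j < W; ++j) {
    for (int ci = 0; ci < Cin; ++ci) {
      const arma::mat& sl = in.slice(ci);
      arma::mat& dsl = din.slice(ci);
      for (int dc = -1; dc <= 1; ++dc) {
        const int jc = j + dc;
        if (jc < 0 || jc >= W) continue;
        const double* pcol = sl.colptr(jc);
        double* gcol = dsl.colptr(jc);
        for (int dr = -1; dr <= 1; ++dr) {
          const int i0 = dr < 0 ? 1 : 0, i1 = H - 1 - (dr > 0 ? 1 : 0);
          const int len = i1 - i0 + 1;
          const double* ps = pcol + i0 + dr;
          double* pg = gcol + i0 + dr;
          const arma::uword wcol = ci * 9 + (dr + 1) * 3 + (dc + 1);
          for (int co = 0; co < Cout; ++co) {
            const double w = Wt(co, wcol);
            const double* pd = dout.slice(co).colptr(j) + i0;
            double acc = 0.0;
            for (int k = 0; k < len; ++k) {
              acc += pd[k] * ps[k];
              pg[k] += w * pd[k];
            }
            dW(co, wcol) += acc;
          }
        }
      }
    }
  }
}

static arma::cube maxpool2(const arma::cube& in, arma::ucube& idx) {
  const arma::uword H = in.n_rows / 2, W = in.n_cols / 2, C = in.n_slices;
  arma::cube out(H, W, C);
  idx.set_size(H, W, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i) {
        double best = -arma::datum::inf; arma::uword bk = 0;
        for (arma::uword k = 0; k < 4; ++k) {
          double v = in(2 * i + k % 2, 2 * j + k / 2, c);
          if (v > best) { best = v; bk = k; }
        }
        out(i, j, c) = best; idx(i, j, c) = bk;
      }
  return out;
}

static arma::cube maxpool2_backward(const arma::cube& dout,
                                    const arma::ucube& idx) {
  const arma::uword H = dout.n_rows, W = dout.n_cols, C = dout.n_slices;
  arma::cube din(2 * H, 2 * W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i) {
        arma::uword k = idx(i, j, c);
        din(2 * i + k % 2, 2 * j + k / 2, c) += dout(i, j, c);
      }
  return din;
}

static arma::cube upsample2(const arma::cube& in) {
  const arma::uword H = in.n_rows, W = in.n_cols, C = in.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& sl = in.slice(c);
    arma::mat& o = out.slice(c);
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i) {
        double v = sl(i, j);
        o(2 * i, 2 * j) = v; o(2 * i + 1, 2 * j) = v;
        o(2 * i, 2 * j + 1) = v; o(2 * i + 1, 2 * j + 1) = v;
      }
  }
  return out;
}

static arma::cube upsample2_backward(const arma::cube& dout) {
  const arma::uword H = dout.n_rows / 2, W = dout.n_cols / 2,
                    C = dout.n_slices;
  arma::cube din(H, W, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i)
        din(i, j, c) = dout(2 * i, 2 * j, c) + dout(2 * i + 1, 2 * j, c) +
                       dout(2 * i, 2 * j + 1, c) + dout(2 * i + 1, 2 * j + 1, c);
  return din;
}

static arma::cube concat(const arma::cube& a, const arma::cube& b) {
  arma::cube out(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  out.slices(0, a.n_slices - 1) = a;
  out.slices(a.n_slices, a.n_slices + b.n_slices - 1) = b;
  return out;
}

struct Weights {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

static Weights unpack(const List& weights) {
  Weights w;
  const int n = weights.size() / 2;
  for (int i = 0; i < n; ++i) {
    w.W.push_back(as<arma::mat>(weights[2 * i]));
    w.b.push_back(as<arma::vec>(weights[2 * i + 1]));
  }
  return w;
}

// Shared forward pass. Caches everything backward needs when `train`.
struct FwdCache {
  std::vector<arma::cube> enc_in, encA, encB;   // per level
  std::vector<arma::ucube> pool_idx;            // levels 0..L-2
  std::vector<arma::cube> up_in, cat, decA, decB; // per decoder level (L-2..0)
  arma::cube head_in;
  arma::mat p;                                  // sigmoid output (H, W)
};

static arma::mat unet_forward(const arma::cube& img, const Weights& w,
                              const arma::ivec& channels, bool train,
                              FwdCache& cc) {
  const int L = channels.n_elem;
  int li = 0;                                   // linear layer index
  arma::cube x = img;
  std::vector<arma::cube> skips;
  for (int lev = 0; lev < L; ++lev) {
    if (train) cc.enc_in.push_back(x);
    arma::cube a = conv3_forward(x, w.W[li], w.b[li], true); ++li;
    if (train) cc.encA.push_back(a);
    arma::cube bq = conv3_forward(a, w.W[li], w.b[li], true); ++li;
    if (train) cc.encB.push_back(bq);
    if (lev < L - 1) {
      skips.push_back(bq);
      arma::ucube idx;
      x = maxpool2(bq, idx);
      if (train) cc.pool_idx.push_back(idx);
    } else {
      x = bq;
    }
  }
  for (int lev = L - 2; lev >= 0; --lev) {
    if (train) cc.up_in.push_back(x);
    arma::cube u = upsample2(x);
    arma::cube cat_ = concat(u, skips[lev]);
    if (train) cc.cat.push_back(cat_);
    arma::cube a = conv3_forward(cat_, w.W[li], w.b[li], true); ++li;
    if (train) cc.decA.push_back(a);
    arma::cube bq = conv3_forward(a, w.W[li], w.b[li], true); ++li;
    if (train) cc.decB.push_back(bq);
    x = bq;
  }
  if (train) cc.head_in = x;
  // 1x1 head
  const arma::uword H = x.n_rows, W = x.n_cols;
  arma::mat logits(H, W, arma::fill::zeros);
  for (arma::uword c = 0; c < x.n_slices; ++c)
    logits += w.W[li](0, c) * x.slice(c);
  logits += w.b[li](0);
  arma::mat p = 1.0 / (1.0 + arma::exp(-logits));
  if (train) cc.p = p;
  return p;
}

// [[Rcpp::export(name = ".unetPredict")]]
NumericMatrix unetPredict(NumericVector img, List weights,
                          IntegerVector channels) {
  IntegerVector dims = img.attr("dim");
  arma::cube im(img.begin(), dims[0], dims[1], dims[2], false);
  Weights w = unpack(weights);
  arma::ivec ch = as<arma::ivec>(channels);
  FwdCache cc;
  arma::mat p = unet_forward(im, w, ch, false, cc);
  return wrap(p);
}

// One image: forward, Dice loss, full backward. Returns loss and gradients
// in the same flat (W1,b1,W2,b2,...) order as `weights`.
// [[Rcpp::export(name = ".unetGrad")]]
List unetGrad(NumericVector img, NumericMatrix truth, List weights,
              IntegerVector channels, double eps) {
  IntegerVector dims = img.attr("dim");
  arma::cube im(img.begin(), dims[0], dims[1], dims[2], false);
  arma::mat t = as<arma::mat>(truth);
  Weights w = unpack(weights);
  arma::ivec ch = as<arma::ivec>(channels);
  const int L = ch.n_elem;
  FwdCache cc;
  arma::mat p = unet_forward(im, w, ch, true, cc);

  const double inter = arma::accu(p % t);
  const double sp = arma::accu(p), st = arma::accu(t);
  const double denom = sp + st + eps;
  const double loss = 1.0 - (2.0 * inter + eps) / denom;
  // d loss / d p, elementwise
  arma::mat dp = -(2.0 * t * denom - (2.0 * inter + eps)) / (denom * denom);
  arma::mat dlogit = dp % p % (1.0 - p);

  const int nlayer = (int)w.W.size();
  std::vector<arma::mat> dW(nlayer);
  std::vector<arma::vec> db(nlayer);
  int li = nlayer - 1;

  // head backward
  {
    const arma::cube& hin = cc.head_in;
    dW[li] = arma::mat(1, hin.n_slices);
    for (arma::uword c = 0; c < hin.n_slices; ++c)
      dW[li](0, c) = arma::accu(dlogit % hin.slice(c));
    db[li] = arma::vec(1);
    db[li](0) = arma::accu(dlogit);
  }
  arma::cube dx(cc.head_in.n_rows, cc.head_in.n_cols, cc.head_in.n_slices);
  for (arma::uword c = 0; c < cc.head_in.n_slices; ++c)
    dx.slice(c) = w.W[li](0, c) * dlogit;
  --li;

  // decoder backward (stored in order lev = L-2 .. 0)
  std::vector<arma::cube> dskip(L - 1);
  for (int k = L - 2; k >= 0; --k) {         // k indexes cc.decX vectors
    int lev = L - 2 - k;                      // actual level of entry k... (entries pushed from high lev to low)
    (void)lev;
    arma::mat dWB; arma::vec dbB; arma::cube da;
    conv3_backward(cc.decA[k], w.W[li], cc.decB[k], dx, true, dWB, dbB, da);
    dW[li] = dWB; db[li] = dbB; --li;
    arma::mat dWA; arma::vec dbA; arma::cube dcat;
    conv3_backward(cc.cat[k], w.W[li], cc.decA[k], da, true, dWA, dbA, dcat);
    dW[li] = dWA; db[li] = dbA; --li;
    // split concat: first part -> upsample path, second -> skip
    arma::uword cu = cc.up_in[k].n_slices;
    arma::cube du = dcat.slices(0, cu - 1);
    // decoder entries were pushed for lev = L-2 down to 0; entry k has level (L-2-k)
    dskip[L - 2 - k] = dcat.slices(cu, dcat.n_slices - 1);
    dx = upsample2_backward(du);
    if (k > 0) {
      // dx now feeds the previous (deeper) decoder output decB[k-1]
      // nothing else to do; loop continues
    }
  }

  // encoder backward, level L-1 (bottleneck) down to 0
  for (int lev = L - 1; lev >= 0; --lev) {
    arma::cube dB;
    if (lev == L - 1) {
      dB = dx;                               // from first decoder upsample
    } else {
      dB = maxpool2_backward(dx, cc.pool_idx[lev]) ;
      dB += dskip[lev];
    }
    arma::mat dWB; arma::vec dbB; arma::cube da;
    conv3_backward(cc.encA[lev], w.W[2 * lev + 1], cc.encB[lev], dB, true,
                   dWB, dbB, da);
    dW[2 * lev + 1] = dWB; db[2 * lev + 1] = dbB;
    arma::mat dWA; arma::vec dbA; arma::cube dinp;
    conv3_backward(cc.enc_in[lev], w.W[2 * lev], cc.encA[lev], da, true,
                   dWA, dbA, dinp);
    dW[2 * lev] = dWA; db[2 * lev] = dbA;
    dx = dinp;                               // grad w.r.t. pooled map of level-1
  }

  List grads(2 * nlayer);
  for (int i = 0; i < nlayer; ++i) {
    grads[2 * i] = wrap(dW[i]);
    grads[2 * i + 1] = wrap(db[i]);
  }
  return List::create(_["loss"] = loss, _["pred"] = wrap(p),
                      _["grads"] = grads);
}
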