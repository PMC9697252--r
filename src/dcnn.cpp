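// Compact CNN engine for 2D slice classification.
//
// Architecture (fixed topology, sizes taken from the weight list built on
// the R side): n conv blocks of [3x3 same-padding conv -> ReLU -> 2x2
// max-pool (stride 2, floor)] followed by one fully connected ReLU layer
// and a softmax output, trained with Adam on the cross-entropy loss.
//
// Activations are stored as (H*W) x C matrices (spatial-major) so that
// im2col columns are contiguous shifted copies and the convolution is a
// single GEMM per layer: A_out = im2col(A_in) * W, with W of shape
// (9*C_in) x C_out. All randomness (shuffling) goes through the R RNG so
// seeded runs are bit-reproducible.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3 kernel with zero same-padding.
// A: (H*W) x C, out: (H*W) x (9*C); column 9*c + k holds channel c shifted
// by offset (di, dj) with k = (di+1) + 3*(dj+1).
static void im2col3(const arma::mat& A, int H, int W, arma::mat& out) {
  const int C = A.n_cols;
  out.zeros(static_cast<size_t>(H) * W, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = (di + 1) + 3 * (dj + 1);
        double* dst = out.colptr(9 * c + k);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        if (i1 <= i0) continue;
        for (int j = j0; j < j1; ++j)
          std::memcpy(dst + i0 + static_cast<size_t>(H) * j,
                      src + (i0 + di) + static_cast<size_t>(H) * (j + dj),
                      (i1 - i0) * sizeof(double));
      }
    }
  }
}

// transpose of im2col3: scatter-accumulate dXc back onto dA
static void col2im3(const arma::mat& dXc, int H, int W, arma::mat& dA) {
  const int C = dA.n_cols;
  dA.zeros();
  for (int c = 0; c < C; ++c) {
    double* dst = dA.colptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = (di + 1) + 3 * (dj + 1);
        const double* src = dXc.colptr(9 * c + k);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            dst[(i + di) + static_cast<size_t>(H) * (j + dj)] +=
              src[i + static_cast<size_t>(H) * j];
      }
    }
  }
}

// 2x2 max pool, stride 2, floor division (odd trailing row/col dropped)
static void maxpool2(const arma::mat& A, int H, int W, arma::mat& out,
                     arma::umat& argmax) {
  const int C = A.n_cols, Ho = H / 2, Wo = W / 2;
  out.set_size(static_cast<size_t>(Ho) * Wo, C);
  argmax.set_size(static_cast<size_t>(Ho) * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int s00 = (2 * i) + H * (2 * j);
        int best = s00;
        double bv = src[s00];
        const int cand[3] = {s00 + 1, s00 + H, s00 + H + 1};
        for (int q = 0; q < 3; ++q)
          if (src[cand[q]] > bv) { bv = src[cand[q]]; best = cand[q]; }
        out(i + static_cast<size_t>(Ho) * j, c) = bv;
        argmax(i + static_cast<size_t>(Ho) * j, c) = best;
      }
    }
  }
}

struct Weights {
  std::vector<arma::mat> Wc;     // (9*Cin) x Cout per conv layer
  std::vector<arma::rowvec> bc;  // Cout per conv layer
  arma::mat Wf; arma::vec bf;    // fc: fcUnits x flat, fcUnits
  arma::mat Wo; arma::vec bo;    // out: K x fcUnits, K
};

static Weights weightsFromList(const List& wl) {
  Weights w;
  List Wc = wl["Wc"], bc = wl["bc"];
  for (int l = 0; l < Wc.size(); ++l) {
    w.Wc.push_back(as<arma::mat>(Wc[l]));
    w.bc.push_back(as<arma::rowvec>(bc[l]));
  }
  w.Wf = as<arma::mat>(wl["Wf"]); w.bf = as<arma::vec>(wl["bf"]);
  w.Wo = as<arma::mat>(wl["Wo"]); w.bo = as<arma::vec>(wl["bo"]);
  return w;
}

static List weightsToList(const Weights& w) {
  List Wc(w.Wc.size()), bc(w.bc.size());
  for (size_t l = 0; l < w.Wc.size(); ++l) {
    Wc[l] = wrap(w.Wc[l]);
    bc[l] = wrap(w.bc[l]);
  }
  return List::create(_["Wc"] = Wc, _["bc"] = bc, _["Wf"] = wrap(w.Wf),
                      _["bf"] = wrap(w.bf), _["Wo"] = wrap(w.Wo),
                      _["bo"] = wrap(w.bo));
}

struct ForwardState {
  std::vector<arma::mat> Xc;      // im2col inputs per conv layer
  std::vector<arma::mat> Aconv;   // post-ReLU conv activations
  std::vector<arma::mat> Apool;   // post-pool activations
  std::vector<arma::umat> argmax;
  std::vector<int> Hc, Wc_, Hp, Wp;
  arma::vec flat, hidden, probs;
};

// forward pass of one image (img: (H*W) x 1 column copied to 1-channel mat)
static void forwardOne(const Weights& w, const arma::mat& img, int H, int W,
                       ForwardState& st, bool keep) {
  const size_t L = w.Wc.size();
  st.Xc.resize(L); st.Aconv.resize(L); st.Apool.resize(L);
  st.argmax.resize(L);
  st.Hc.resize(L); st.Wc_.resize(L); st.Hp.resize(L); st.Wp.resize(L);
  arma::mat A = img;  // (H*W) x 1
  int h = H, wd = W;
  for (size_t l = 0; l < L; ++l) {
    arma::mat Xc;
    im2col3(A, h, wd, Xc);
    arma::mat Z = Xc * w.Wc[l];
    Z.each_row() += w.bc[l];
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    st.Hc[l] = h; st.Wc_[l] = wd;
    arma::mat P; arma::umat am;
    maxpool2(Z, h, wd, P, am);
    h /= 2; wd /= 2;
    st.Hp[l] = h; st.Wp[l] = wd;
    if (keep) { st.Xc[l] = std::move(Xc); st.Aconv[l] = Z; st.argmax[l] = am; }
    st.Apool[l] = P;
    A = st.Apool[l];
  }
  st.flat = arma::vectorise(A);
  arma::vec hpre = w.Wf * st.flat + w.bf;
  st.hidden = arma::clamp(hpre, 0.0, arma::datum::inf);
  arma::vec logits = w.Wo * st.hidden + w.bo;
  logits -= logits.max();
  arma::vec e = arma::exp(logits);
  st.probs = e / arma::accu(e);
}

// backward pass; accumulates gradients for one image
static void backwardOne(const Weights& w, ForwardState& st, int target,
                        Weights& g) {
  const size_t L = w.Wc.size();
  arma::vec dlogits = st.probs;
  dlogits(target) -= 1.0;
  g.Wo += dlogits * st.hidden.t();
  g.bo += dlogits;
  arma::vec dh = w.Wo.t() * dlogits;
  dh.elem(arma::find(st.hidden <= 0.0)).zeros();
  g.Wf += dh * st.flat.t();
  g.bf += dh;
  arma::vec dflat = w.Wf.t() * dh;
  arma::mat dP = arma::reshape(dflat, st.Apool[L - 1].n_rows,
                               st.Apool[L - 1].n_cols);
  for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
    // un-pool
    arma::mat dZ(static_cast<size_t>(st.Hc[l]) * st.Wc_[l],
                 st.Aconv[l].n_cols, arma::fill::zeros);
    for (size_t c = 0; c < dZ.n_cols; ++c)
      for (size_t s = 0; s < dP.n_rows; ++s)
        dZ(st.argmax[l](s, c), c) += dP(s, c);
    // ReLU
    dZ.elem(arma::find(st.Aconv[l] <= 0.0)).zeros();
    g.Wc[l] += st.Xc[l].t() * dZ;
    g.bc[l] += arma::sum(dZ, 0);
    if (l > 0) {
      arma::mat dXc = dZ * w.Wc[l].t();
      arma::mat dA(static_cast<size_t>(st.Hc[l]) * st.Wc_[l],
                   st.Apool[l - 1].n_cols);
      col2im3(dXc, st.Hc[l], st.Wc_[l], dA);
      dP = std::move(dA);
    }
  }
}

static Weights zerosLike(const Weights& w) {
  Weights g;
  for (size_t l = 0; l < w.Wc.size(); ++l) {
    g.Wc.push_back(arma::mat(arma::size(w.Wc[l]), arma::fill::zeros));
    g.bc.push_back(arma::rowvec(w.bc[l].n_elem, arma::fill::zeros));
  }
  g.Wf = arma::mat(arma::size(w.Wf), arma::fill::zeros);
  g.bf = arma::vec(w.bf.n_elem, arma::fill::zeros);
  g.Wo = arma::mat(arma::size(w.Wo), arma::fill::zeros);
  g.bo = arma::vec(w.bo.n_elem, arma::fill::zeros);
  return g;
}

template <typename T>
static void adamStep(T& w, T& m, T& v, const T& grad, double lr, double b1,
                     double b2, double eps, double bc1, double bc2) {
  m = b1 * m + (1.0 - b1) * grad;
  v = b2 * v + (1.0 - b2) * (grad % grad);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

static void adamUpdate(Weights& w, Weights& m, Weights& v, const Weights& g,
                       double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
  for (size_t l = 0; l < w.Wc.size(); ++l) {
    adamStep(w.Wc[l], m.Wc[l], v.Wc[l], g.Wc[l], lr, b1, b2, eps, bc1, bc2);
    adamStep(w.bc[l], m.bc[l], v.bc[l], g.bc[l], lr, b1, b2, eps, bc1, bc2);
  }
  adamStep(w.Wf, m.Wf, v.Wf, g.Wf, lr, b1, b2, eps, bc1, bc2);
  adamStep(w.bf, m.bf, v.bf, g.bf, lr, b1, b2, eps, bc1, bc2);
  adamStep(w.Wo, m.Wo, v.Wo, g.Wo, lr, b1, b2, eps, bc1, bc2);
  adamStep(w.bo, m.bo, v.bo, g.bo, lr, b1, b2, eps, bc1, bc2);
}

static void scaleGrad(Weights& g, double s) {
  for (size_t l = 0; l < g.Wc.size(); ++l) { g.Wc[l] *= s; g.bc[l] *= s; }
  g.Wf *= s; g.bf *= s; g.Wo *= s; g.bo *= s;
}

static void zeroGrad(Weights& g) {
  for (size_t l = 0; l < g.Wc.size(); ++l) { g.Wc[l].zeros(); g.bc[l].zeros(); }
  g.Wf.zeros(); g.bf.zeros(); g.Wo.zeros(); g.bo.zeros();
}

static arma::mat sliceToMat(const arma::cube& X, int idx) {
  arma::mat img(X.n_rows * X.n_cols, 1);
  std::memcpy(img.memptr(), X.slice(idx).memptr(),
              X.n_rows * X.n_cols * sizeof(double));
  return img;
}

// mean cross-entropy and accuracy on a set of images
static void evalSet(const Weights& w, const arma::cube& X,
                    const arma::ivec& y, const std::vector<int>& idx,
                    double& loss, double& acc) {
  ForwardState st;
  double L = 0.0; int correct = 0;
  for (int i : idx) {
    forwardOne(w, sliceToMat(X, i), X.n_rows, X.n_cols, st, false);
    double p = std::max(st.probs(y(i)), 1e-12);
    L += -std::log(p);
    if (static_cast<int>(st.probs.index_max()) == y(i)) ++correct;
  }
  loss = L / idx.size();
  acc = static_cast<double>(correct) / idx.size();
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::cube& X, const arma::ivec& y, List weightList,
                   List cfg) {
  const int N = X.n_slices;
  if (N == 0) stop("empty training set");
  const int epochs = as<int>(cfg["epochs"]);
  const int batch = as<int>(cfg["batchSize"]);
  const double lr = as<double>(cfg["lr"]);
  const double valFrac = as<double>(cfg["valFraction"]);
  const int patience = as<int>(cfg["patience"]);

  Weights w = weightsFromList(weightList);
  Weights m = zerosLike(w), v = zerosLike(w), g = zerosLike(w);

  // split off a validation set (R RNG -> reproducible under set.seed)
  IntegerVector perm = sample(N, N, false);
  const int nVal = std::min(N - 1, static_cast<int>(std::floor(valFrac * N)));
  std::vector<int> valIdx, trIdx;
  for (int i = 0; i < N; ++i) {
    if (i < nVal) valIdx.push_back(perm[i] - 1);
    else trIdx.push_back(perm[i] - 1);
  }
  const int nTr = trIdx.size();

  std::vector<double> logTrain, logVal, logValAcc;
  Weights best = w;
  double bestVal = arma::datum::inf;
  int since = 0, tAdam = 0, ranEpochs = 0;
  ForwardState st;

  for (int ep = 0; ep < epochs; ++ep) {
    IntegerVector ord = sample(nTr, nTr, false);
    double epLoss = 0.0;
    for (int start = 0; start < nTr; start += batch) {
      const int stop_ = std::min(start + batch, nTr);
      zeroGrad(g);
      for (int b = start; b < stop_; ++b) {
        const int i = trIdx[ord[b] - 1];
        forwardOne(w, sliceToMat(X, i), X.n_rows, X.n_cols, st, true);
        epLoss += -std::log(std::max(st.probs(y(i)), 1e-12));
        backwardOne(w, st, y(i), g);
      }
      scaleGrad(g, 1.0 / (stop_ - start));
      adamUpdate(w, m, v, g, lr, ++tAdam);
    }
    logTrain.push_back(epLoss / nTr);
    ++ranEpochs;
    if (nVal > 0) {
      double vl, va;
      evalSet(w, X, y, valIdx, vl, va);
      logVal.push_back(vl);
      logValAcc.push_back(va);
      if (vl < bestVal - 1e-6) { bestVal = vl; best = w; since = 0; }
      else if (++since >= patience) break;
    } else {
      logVal.push_back(NA_REAL);
      logValAcc.push_back(NA_REAL);
      best = w;
    }
    Rcpp::checkUserInterrupt();
  }
  if (nVal > 0 && bestVal < arma::datum::inf) w = best;

  DataFrame log = DataFrame::create(
    _["epoch"] = seq_len(ranEpochs),
    _["train_loss"] = NumericVector(logTrain.begin(), logTrain.end()),
    _["val_loss"] = NumericVector(logVal.begin(), logVal.end()),
    _["val_acc"] = NumericVector(logValAcc.begin(), logValAcc.end()));
  return List::create(_["weights"] = weightsToList(w), _["log"] = log);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(List weightList, const arma::cube& X) {
  Weights w = weightsFromList(weightList);
  const int N = X.n_slices, K = w.bo.n_elem;
  arma::mat out(N, K);
  ForwardState st;
  for (int i = 0; i < N; ++i) {
    forwardOne(w, sliceToMat(X, i), X.n_rows, X.n_cols, st, false);
    out.row(i) = st.probs.t();
  }
  return out;
}
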