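// 1-D convolutional network for waveform-to-scalar regression.
//
// Architecture: n_blocks of [conv(kernel, same padding) -> ReLU -> maxpool/2],
// where each block's input is the channel concatenation of the previous
// block's pooled output and the previous block's input passed through the
// same factor-2 max pool (so lengths match). A two-layer fully connected
// head maps the flattened final activations to one scalar per window.
//
// The whole minibatch is propagated together: the activation of block k is
// stored as a (B * L_k) x C_k matrix (sample i in rows [i*L_k, (i+1)*L_k)),
// so each convolution is a single im2col + GEMM over the batch. All
// arithmetic is double precision and strictly sequential for a fixed
// parameter set, so repeated calls are bit-identical.
//
// The training entry point also differentiates through the per-patient
// affine calibration sv = (raw + out_center) * w_p + b_p and an RMS loss.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>

namespace {

struct Net {
  std::vector<arma::mat> W;  // conv weights, Cout x Cin*K
  std::vector<arma::vec> b;  // conv biases
  arma::mat fc1_w;
  arma::vec fc1_b;
  arma::mat fc2_w;  // 1 x H
  double fc2_b;
  int K;
  bool skip;  // concatenate the pooled block input to the pooled output
};

Net unpack(const Rcpp::List& params, int kernel, bool skip) {
  Net net;
  net.K = kernel;
  net.skip = skip;
  Rcpp::List cw = params["conv_w"], cb = params["conv_b"];
  const int nb = cw.size();
  net.W.reserve(nb);
  net.b.reserve(nb);
  for (int k = 0; k < nb; ++k) {
    net.W.push_back(Rcpp::as<arma::mat>(cw[k]));
    net.b.push_back(Rcpp::as<arma::vec>(cb[k]));
  }
  net.fc1_w = Rcpp::as<arma::mat>(params["fc1_w"]);
  net.fc1_b = Rcpp::as<arma::vec>(params["fc1_b"]);
  net.fc2_w = Rcpp::as<arma::mat>(params["fc2_w"]);
  net.fc2_b = Rcpp::as<arma::vec>(params["fc2_b"])[0];
  return net;
}

// im2col with zero 'same' padding, applied independently to each of the B
// samples stacked in X ((B*L) x C) -> P ((B*L) x C*K)
arma::mat im2col_batch(const arma::mat& X, int K, arma::uword B,
                       arma::uword L) {
  const arma::uword C = X.n_cols;
  const int pad = K / 2;
  arma::mat P(X.n_rows, C * K, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    for (int j = 0; j < K; ++j) {
      const int off = j - pad;  // source row (within sample) = t + off
      double* dst = P.colptr(c * K + j);
      const arma::uword lo = (off < 0) ? static_cast<arma::uword>(-off) : 0;
      const arma::uword hi = (off > 0) ? L - static_cast<arma::uword>(off) : L;
      for (arma::uword i = 0; i < B; ++i) {
        const arma::uword base = i * L;
        for (arma::uword t = lo; t < hi; ++t)
          dst[base + t] = src[base + t + off];
      }
    }
  }
  return P;
}

// transpose of im2col_batch: accumulate dP ((B*L) x C*K) into dX ((B*L) x C)
void col2im_batch_add(arma::mat& dX, const arma::mat& dP, int K,
                      arma::uword B, arma::uword L) {
  const arma::uword C = dX.n_cols;
  const int pad = K / 2;
  for (arma::uword c = 0; c < C; ++c) {
    double* dst = dX.colptr(c);
    for (int j = 0; j < K; ++j) {
      const int off = j - pad;
      const double* src = dP.colptr(c * K + j);
      const arma::uword lo = (off < 0) ? static_cast<arma::uword>(-off) : 0;
      const arma::uword hi = (off > 0) ? L - static_cast<arma::uword>(off) : L;
      for (arma::uword i = 0; i < B; ++i) {
        const arma::uword base = i * L;
        for (arma::uword t = lo; t < hi; ++t)
          dst[base + t + off] += src[base + t];
      }
    }
  }
}

// factor-2 max pool within each sample; idx records the source row
arma::mat maxpool2_batch(const arma::mat& X, arma::umat& idx, arma::uword B,
                         arma::uword L) {
  const arma::uword L2 = L / 2, C = X.n_cols;
  arma::mat Y(B * L2, C);
  idx.set_size(B * L2, C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* dst = Y.colptr(c);
    arma::uword* ix = idx.colptr(c);
    for (arma::uword i = 0; i < B; ++i) {
      const arma::uword bi = i * L, bo = i * L2;
      for (arma::uword t = 0; t < L2; ++t) {
        const arma::uword r0 = bi + 2 * t;
        if (src[r0] >= src[r0 + 1]) { dst[bo + t] = src[r0]; ix[bo + t] = r0; }
        else { dst[bo + t] = src[r0 + 1]; ix[bo + t] = r0 + 1; }
      }
    }
  }
  return Y;
}

struct BlockCache {
  arma::mat P;    // im2col matrix
  arma::mat Z;    // conv pre-activation (B*L) x Cout
  arma::umat ia;  // pooled conv-path argmax rows
  arma::umat is;  // pooled skip-path argmax rows
  arma::uword L;  // spatial length entering the block
  arma::uword Cin;
};

struct BatchCache {
  std::vector<BlockCache> blocks;
  arma::mat F;     // flat_len x B input to the head
  arma::mat Hpre;  // fc_hidden x B
  arma::mat H;
};

// forward for the whole batch; X is input_len x B (one window per column)
arma::vec forward_batch(const arma::mat& X, const Net& net,
                        BatchCache* cache) {
  const int nb = static_cast<int>(net.W.size());
  const arma::uword B = X.n_cols;
  arma::uword L = X.n_rows;
  // stack: (B*L) x 1, sample i in rows [i*L, (i+1)*L)
  arma::mat A = arma::reshape(X, B * L, 1);
  if (cache) cache->blocks.resize(nb);
  for (int k = 0; k < nb; ++k) {
    arma::mat P = im2col_batch(A, net.K, B, L);
    arma::mat Z = P * net.W[k].t();
    Z.each_row() += net.b[k].t();
    arma::mat Zr = Z;
    Zr.clamp(0.0, arma::datum::inf);
    arma::umat ia, is;
    arma::mat Ap = maxpool2_batch(Zr, ia, B, L);
    arma::mat Sp;
    if (net.skip) Sp = maxpool2_batch(A, is, B, L);
    if (cache) {
      BlockCache& bc = cache->blocks[k];
      bc.P = std::move(P);
      bc.Z = std::move(Z);
      bc.ia = std::move(ia);
      bc.is = std::move(is);
      bc.L = L;
      bc.Cin = A.n_cols;
    }
    A = net.skip ? arma::join_rows(Ap, Sp) : std::move(Ap);
    L /= 2;
  }
  // flatten each sample's L x C block (column-major) into one column
  const arma::uword C = A.n_cols, flat = L * C;
  arma::mat F(flat, B);
  for (arma::uword i = 0; i < B; ++i)
    F.col(i) = arma::vectorise(A.rows(i * L, (i + 1) * L - 1));
  arma::mat Hpre = net.fc1_w * F;
  Hpre.each_col() += net.fc1_b;
  arma::mat H = Hpre;
  H.clamp(0.0, arma::datum::inf);
  arma::vec out = (net.fc2_w * H).t() + net.fc2_b;
  if (cache) {
    cache->F = std::move(F);
    cache->Hpre = std::move(Hpre);
    cache->H = std::move(H);
  }
  return out;
}

// backward for the whole batch; dout[i] = dLoss/d(raw output of sample i);
// writes parameter gradients into the named Rcpp list entries
Rcpp::List backward_batch(const Net& net, const BatchCache& cache,
                          const arma::vec& dout, arma::uword B) {
  arma::mat dH = net.fc2_w.t() * dout.t();  // H x B
  dH.elem(arma::find(cache.Hpre <= 0.0)).zeros();
  arma::mat g_fc2_w = dout.t() * cache.H.t();
  const double g_fc2_b = arma::accu(dout);
  arma::mat g_fc1_w = dH * cache.F.t();
  arma::vec g_fc1_b = arma::sum(dH, 1);
  arma::mat dF = net.fc1_w.t() * dH;  // flat x B

  const int nb = static_cast<int>(net.W.size());
  const arma::uword Lfin = cache.blocks[nb - 1].L / 2;
  const arma::uword Cfin = net.b[nb - 1].n_elem +
      (net.skip ? cache.blocks[nb - 1].Cin : 0);
  arma::mat dX(B * Lfin, Cfin);
  for (arma::uword i = 0; i < B; ++i)
    dX.rows(i * Lfin, (i + 1) * Lfin - 1) =
        arma::reshape(dF.col(i), Lfin, Cfin);

  Rcpp::List conv_w(nb), conv_b(nb);
  for (int k = nb - 1; k >= 0; --k) {
    const BlockCache& bc = cache.blocks[k];
    const arma::uword Cout = net.b[k].n_elem;
    const arma::uword rows2 = B * (bc.L / 2);
    // unpool conv path
    arma::mat dZ(B * bc.L, Cout, arma::fill::zeros);
    for (arma::uword c = 0; c < Cout; ++c) {
      double* dst = dZ.colptr(c);
      const arma::uword* ix = bc.ia.colptr(c);
      const double* src = dX.colptr(c);
      for (arma::uword r = 0; r < rows2; ++r) dst[ix[r]] += src[r];
    }
    dZ.elem(arma::find(bc.Z <= 0.0)).zeros();
    conv_w[k] = arma::mat(dZ.t() * bc.P);
    conv_b[k] = arma::vec(arma::sum(dZ, 0).t());
    arma::mat dP = dZ * net.W[k];
    arma::mat dXin(B * bc.L, bc.Cin, arma::fill::zeros);
    col2im_batch_add(dXin, dP, net.K, B, bc.L);
    if (net.skip) {  // unpool skip path
      for (arma::uword c = 0; c < bc.Cin; ++c) {
        double* dst = dXin.colptr(c);
        const arma::uword* ix = bc.is.colptr(c);
        const double* src = dX.colptr(Cout + c);
        for (arma::uword r = 0; r < rows2; ++r) dst[ix[r]] += src[r];
      }
    }
    dX = std::move(dXin);
  }
  return Rcpp::List::create(
      Rcpp::Named("conv_w") = conv_w, Rcpp::Named("conv_b") = conv_b,
      Rcpp::Named("fc1_w") = g_fc1_w, Rcpp::Named("fc1_b") = g_fc1_b,
      Rcpp::Named("fc2_w") = g_fc2_w,
      Rcpp::Named("fc2_b") = arma::vec{g_fc2_b});
}

}  // namespace

//' Raw network outputs for a batch of windows (no calibration applied).
//' @param X matrix input_len x batch of normalized pressure windows.
//' @param params named list of network parameters.
//' @param kernel odd convolution kernel length.
//' @param skip concatenate the pooled block input to the pooled output.
//' @return numeric vector of raw outputs, one per window.
//' @keywords internal
// [[Rcpp::export]]
arma::vec cnn_forward(const arma::mat& X, const Rcpp::List& params,
                      int kernel, bool skip = true) {
  const Net net = unpack(params, kernel, skip);
  if (X.n_cols == 0) return arma::vec();
  return forward_batch(X, net, nullptr);
}

//' One training batch: forward, RMS loss through the per-patient affine
//' calibration, and gradients for every parameter.
//'
//' @param X input_len x batch matrix of normalized windows.
//' @param params named list of network parameters.
//' @param kernel odd convolution kernel length.
//' @param targets reference SV per window (mL).
//' @param pidx 0-based patient index per window.
//' @param isc_w,isc_b per-patient calibration gain and offset.
//' @param out_center constant added to the raw output.
//' @param skip concatenate the pooled block input to the pooled output.
//' @return list with loss, calibrated predictions, and gradients.
//' @keywords internal
// [[Rcpp::export]]
Rcpp::List cnn_train_batch(const arma::mat& X, const Rcpp::List& params,
                           int kernel, const arma::vec& targets,
                           const arma::ivec& pidx, const arma::vec& isc_w,
                           const arma::vec& isc_b, double out_center,
                           bool skip = true) {
  const Net net = unpack(params, kernel, skip);
  const arma::uword B = X.n_cols;
  if (targets.n_elem != B || pidx.n_elem != B)
    Rcpp::stop("targets/pidx length must match batch size");

  BatchCache cache;
  const arma::vec raw = forward_batch(X, net, &cache);
  arma::vec pred(B), w_of(B);
  for (arma::uword i = 0; i < B; ++i) {
    const int p = pidx[i];
    w_of[i] = isc_w[p];
    pred[i] = (raw[i] + out_center) * isc_w[p] + isc_b[p];
  }
  const arma::vec resid = pred - targets;
  const double mse = arma::dot(resid, resid) / B;
  const double loss = std::sqrt(mse);
  if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");

  const double denom = (loss > 0.0) ? (B * loss) : 1.0;
  const arma::vec dpred = resid / denom;  // dLoss/dpred_i
  arma::vec g_w(isc_w.n_elem, arma::fill::zeros);
  arma::vec g_b(isc_b.n_elem, arma::fill::zeros);
  for (arma::uword i = 0; i < B; ++i) {
    const int p = pidx[i];
    g_w[p] += dpred[i] * (raw[i] + out_center);
    g_b[p] += dpred[i];
  }
  Rcpp::List grads = backward_batch(net, cache, dpred % w_of, B);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("pred") = pred,
      Rcpp::Named("grads") = grads, Rcpp::Named("g_isc_w") = g_w,
      Rcpp::Named("g_isc_b") = g_b);
}
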