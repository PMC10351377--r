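// Fast batched forward / backward pass for the dual-branch classifier.
// Mirrors the reference R engine in R/nn-core.R exactly (same layouts,
// same tie-breaking in the max-pool, same loss), with convolutions as
// im2col + GEMM so the heavy work lands in BLAS and no intermediate is
// copied through R.
//
// Layouts (shared with the R reference):
//  - batch conv activations: cube (B, P, C) = sample x position x channel;
//  - im2col matrix: (B*P_out) x (k*C), column ch*k + dj (0-based) holding
//    kernel offset dj of channel ch; row index b + p*B;
//  - conv weights: (k*C) x filters, same row order (cross-correlation);
//  - max-pool width m keeps the earliest position on ties.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct DenseLayer {
  arma::mat W;   // in x out (borrowed from R, no copy)
  arma::rowvec b;
  bool relu;
  DenseLayer(const List& lay) {
    NumericMatrix Wm = lay["W"];
    W = arma::mat(Wm.begin(), Wm.nrow(), Wm.ncol(), false, true);
    b = as<arma::rowvec>(lay["b"]);
    std::string act = as<std::string>(lay["activation"]);
    relu = (act == "relu");
  }
};

struct ConvLayer {
  arma::mat W;   // (k*C) x F
  arma::rowvec b;
  int k, in_ch, filters, pool;
  ConvLayer(const List& lay) {
    NumericMatrix Wm = lay["W"];
    W = arma::mat(Wm.begin(), Wm.nrow(), Wm.ncol(), false, true);
    b = as<arma::rowvec>(lay["b"]);
    k = as<int>(lay["k"]);
    in_ch = as<int>(lay["in_ch"]);
    filters = as<int>(lay["filters"]);
    pool = as<int>(lay["pool"]);
  }
};

struct ConvCache {
  arma::mat Xc;      // im2col input
  arma::mat act;     // post-ReLU activations, only kept when m == 1
  arma::mat out;     // pooled output, (B*Pg) x F (the ReLU mask for m > 1)
  arma::umat am;     // argmax offset j per pooled cell, (B*Pg) x F
  int B = 0, P = 0, P_out = 0, m = 0, Pg = 0;
};

void im2col(const arma::cube& A, int k, arma::mat& Xc) {
  const int B = A.n_rows, P = A.n_cols, C = A.n_slices;
  const int P_out = P - k + 1;
  Xc.set_size((arma::uword)B * P_out, (arma::uword)k * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      Xc.col((arma::uword)c * k + dj) =
        arma::vectorise(A.slice(c).cols(dj, dj + P_out - 1));
    }
  }
}

// forward one conv layer; output cube is (B, Pg, F).  For pooled layers
// the GEMM runs over position chunks and the pooled maximum (plus its
// argmax) is extracted while the chunk is cache-hot, so the full pre-pool
// activation is never materialized.
arma::cube conv_forward(const arma::cube& A, const ConvLayer& lay,
                        ConvCache& cache) {
  const int B = A.n_rows, P = A.n_cols;
  const int k = lay.k, F = lay.filters;
  const int P_out = P - k + 1;
  if (P_out < 1) stop("sequence too short for kernel size %d", k);
  im2col(A, k, cache.Xc);
  cache.B = B; cache.P = P; cache.P_out = P_out;
  const int m = std::min(lay.pool, P_out);
  cache.m = m;
  if (m == 1) {
    cache.Pg = P_out;
    cache.act = cache.Xc * lay.W;
    for (int f = 0; f < F; ++f) {
      double* zf = cache.act.colptr(f);
      const double bf = lay.b[f];
      for (arma::uword r = 0; r < cache.act.n_rows; ++r) {
        const double v = zf[r] + bf;
        zf[r] = v > 0.0 ? v : 0.0;
      }
    }
    arma::cube out(B, P_out, F);
    std::memcpy(out.memptr(), cache.act.memptr(),
                sizeof(double) * cache.act.n_elem);
    return out;
  }
  const int Pg = P_out / m;
  cache.Pg = Pg;
  cache.out.set_size((arma::uword)B * Pg, F);
  cache.am.set_size((arma::uword)B * Pg, F);
  // position-chunk size: a multiple of the pool width keeping the chunk
  // activation buffer around a few MB
  int chunk_g = std::max(1, (1 << 21) / (B * m * F));
  arma::mat buf;
  for (int g0 = 0; g0 < Pg; g0 += chunk_g) {
    const int g1 = std::min(Pg, g0 + chunk_g);
    const arma::uword r0 = (arma::uword)g0 * m * B;
    const arma::uword r1 = (arma::uword)g1 * m * B - 1;
    buf = cache.Xc.rows(r0, r1) * lay.W;
    for (int f = 0; f < F; ++f) {
      double* zf = buf.colptr(f);
      const double bf = lay.b[f];
      double* of = cache.out.colptr(f);
      arma::uword* af = cache.am.colptr(f);
      for (int g = g0; g < g1; ++g) {
        const arma::uword base = (arma::uword)(g - g0) * m * B;
        for (int b = 0; b < B; ++b) {
          double best = zf[base + b] + bf;
          int bj = 0;
          for (int j = 1; j < m; ++j) {
            const double v = zf[base + (arma::uword)j * B + b] + bf;
            if (v > best) { best = v; bj = j; }
          }
          of[(arma::uword)g * B + b] = best > 0.0 ? best : 0.0;
          af[(arma::uword)g * B + b] = bj;
        }
      }
    }
  }
  arma::cube out(B, Pg, F);
  std::memcpy(out.memptr(), cache.out.memptr(),
              sizeof(double) * cache.out.n_elem);
  return out;
}

// backward through one conv layer; dOut is (B, Pg, F); returns dA (B, P, C).
// For pooled layers the gradient is nonzero only at argmax positions: the
// ReLU mask is applied on the compact pooled grid (pooled value > 0 iff
// the pre-pool activation at the argmax was positive) and scattered into
// the full grid for the two GEMMs.
arma::cube conv_backward(const arma::cube& dOut, const ConvLayer& lay,
                         const ConvCache& cache, arma::mat& dW,
                         arma::rowvec& db) {
  const int B = cache.B, P = cache.P, P_out = cache.P_out;
  const int k = lay.k, C = lay.in_ch, F = lay.filters, m = cache.m;
  if (m > 1 && C == 1) {
    // single-input-channel layer (the first conv): the pooled gradient is
    // sparse enough that direct scalar accumulation beats building the
    // full (B*P_out) x F grid for two thin GEMMs
    const int Pg = cache.Pg;
    arma::cube dA(B, P, 1, arma::fill::zeros);
    double* da = dA.memptr();  // (b, p) at p*B + b
    dW.zeros(k, F);
    db.zeros(F);
    const arma::uword nXr = cache.Xc.n_rows;
    for (int f = 0; f < F; ++f) {
      const double* dof = dOut.slice_memptr(f);
      const double* of = cache.out.colptr(f);
      const arma::uword* af = cache.am.colptr(f);
      double* dWf = dW.colptr(f);
      const double* Wf = lay.W.colptr(f);
      double dbf = 0.0;
      for (int g = 0; g < Pg; ++g) {
        for (int b = 0; b < B; ++b) {
          const arma::uword src = (arma::uword)g * B + b;
          if (of[src] <= 0.0) continue;
          const double v = dof[src];
          if (v == 0.0) continue;
          dbf += v;
          const arma::uword pos = (arma::uword)g * m + af[src];
          const arma::uword xrow = pos * B + b;
          for (int dj = 0; dj < k; ++dj) {
            dWf[dj] += v * cache.Xc[(arma::uword)dj * nXr + xrow];
            da[(pos + dj) * B + b] += v * Wf[dj];
          }
        }
      }
      db[f] = dbf;
    }
    return dA;
  }
  arma::mat dZ((arma::uword)B * P_out, F, arma::fill::zeros);
  if (m == 1) {
    std::memcpy(dZ.memptr(), dOut.memptr(), sizeof(double) * dOut.n_elem);
    const double* a = cache.act.memptr();
    double* d = dZ.memptr();
    for (arma::uword i = 0; i < dZ.n_elem; ++i) {
      if (a[i] <= 0.0) d[i] = 0.0;
    }
  } else {
    const int Pg = cache.Pg;
    for (int f = 0; f < F; ++f) {
      double* dzf = dZ.colptr(f);
      const double* dof = dOut.slice_memptr(f);
      const double* of = cache.out.colptr(f);
      const arma::uword* af = cache.am.colptr(f);
      for (int g = 0; g < Pg; ++g) {
        for (int b = 0; b < B; ++b) {
          const arma::uword src = (arma::uword)g * B + b;
          if (of[src] > 0.0) {
            dzf[(arma::uword)(g * m + af[src]) * B + b] = dof[src];
          }
        }
      }
    }
  }
  dW = cache.Xc.t() * dZ;
  db = arma::sum(dZ, 0);
  arma::mat dXc = dZ * lay.W.t();
  arma::cube dA(B, P, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      dA.slice(c).cols(dj, dj + P_out - 1) +=
        arma::reshape(dXc.col((arma::uword)c * k + dj), B, P_out);
    }
  }
  return dA;
}

struct ForwardState {
  std::vector<arma::mat> mlp_in;    // inputs to each dense layer
  std::vector<arma::mat> mlp_act;   // post-activation outputs
  std::vector<ConvCache> conv;
  std::vector<arma::mat> head_in;
  std::vector<arma::mat> head_act;
  arma::cube last_conv;             // output of final conv layer
  arma::mat gap;
  arma::mat H;                      // fusion input
  arma::mat logits, probs;
  int mlp_dim = 0;
};

void forward_pass(const arma::mat& X, const std::vector<DenseLayer>& mlp,
                  const std::vector<ConvLayer>& cnn,
                  const std::vector<DenseLayer>& head, ForwardState& st) {
  const int B = X.n_rows;
  arma::mat A = X;
  st.mlp_in.clear(); st.mlp_act.clear(); st.head_in.clear();
  st.head_act.clear();
  st.conv.assign(cnn.size(), ConvCache());
  for (size_t i = 0; i < mlp.size(); ++i) {
    st.mlp_in.push_back(A);
    A = A * mlp[i].W;
    A.each_row() += mlp[i].b;
    if (mlp[i].relu) A.transform([](double z) { return z > 0.0 ? z : 0.0; });
    st.mlp_act.push_back(A);
  }
  st.mlp_dim = A.n_cols;
  if (!cnn.empty()) {
    arma::cube Ac(const_cast<double*>(X.memptr()), B, X.n_cols, 1, false);
    arma::cube cur = conv_forward(Ac, cnn[0], st.conv[0]);
    for (size_t i = 1; i < cnn.size(); ++i) {
      cur = conv_forward(cur, cnn[i], st.conv[i]);
    }
    st.last_conv = cur;
    st.gap.set_size(B, cur.n_slices);
    for (arma::uword f = 0; f < cur.n_slices; ++f) {
      st.gap.col(f) = arma::sum(cur.slice(f), 1) / (double)cur.n_cols;
    }
    st.H = arma::join_rows(A, st.gap);
  } else {
    st.H = A;
  }
  arma::mat Ah = st.H;
  for (size_t i = 0; i < head.size(); ++i) {
    st.head_in.push_back(Ah);
    Ah = Ah * head[i].W;
    Ah.each_row() += head[i].b;
    if (head[i].relu) Ah.transform([](double z) { return z > 0.0 ? z : 0.0; });
    st.head_act.push_back(Ah);
  }
  st.logits = Ah;
  arma::vec zmax = arma::max(st.logits, 1);
  st.probs = arma::exp(st.logits.each_col() - zmax);
  st.probs.each_col() /= arma::sum(st.probs, 1);
}

NumericVector as_rvec(const arma::rowvec& v) {
  return NumericVector(v.begin(), v.end());
}

std::vector<DenseLayer> dense_layers(const List& layers) {
  std::vector<DenseLayer> out;
  for (int i = 0; i < layers.size(); ++i) out.emplace_back(List(layers[i]));
  return out;
}

std::vector<ConvLayer> conv_layers(SEXP layers) {
  std::vector<ConvLayer> out;
  if (Rf_isNull(layers)) return out;
  List ll(layers);
  for (int i = 0; i < ll.size(); ++i) out.emplace_back(List(ll[i]));
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_nn_forward(NumericMatrix X, List params) {
  arma::mat Xa(X.begin(), X.nrow(), X.ncol(), false, true);
  std::vector<DenseLayer> mlp = dense_layers(params["mlp"]);
  std::vector<ConvLayer> cnn = conv_layers(params["cnn"]);
  std::vector<DenseLayer> head = dense_layers(params["head"]);
  ForwardState st;
  forward_pass(Xa, mlp, cnn, head, st);
  return wrap(st.probs);
}

// [[Rcpp::export]]
List cpp_nn_loss_grad(NumericMatrix X, IntegerVector y, NumericVector w,
                      List params) {
  const int B = X.nrow();
  arma::mat Xa(X.begin(), B, X.ncol(), false, true);
  std::vector<DenseLayer> mlp = dense_layers(params["mlp"]);
  std::vector<ConvLayer> cnn = conv_layers(params["cnn"]);
  std::vector<DenseLayer> head = dense_layers(params["head"]);
  ForwardState st;
  forward_pass(Xa, mlp, cnn, head, st);

  arma::vec wv = as<arma::vec>(w);
  const double wsum = arma::accu(wv);
  arma::vec zmax = arma::max(st.logits, 1);
  arma::vec lse = zmax + arma::log(arma::sum(
      arma::exp(st.logits.each_col() - zmax), 1));
  double loss = 0.0;
  arma::mat dLogits = st.probs;
  for (int i = 0; i < B; ++i) {
    const int yi = y[i];
    loss -= wv[i] * (st.logits(i, yi) - lse[i]);
    dLogits(i, yi) -= 1.0;
  }
  loss /= wsum;
  dLogits.each_col() %= wv / wsum;

  List head_grads(head.size());
  arma::mat dA = dLogits;
  for (int i = (int)head.size() - 1; i >= 0; --i) {
    arma::mat dZ = dA;
    if (head[i].relu) dZ.elem(arma::find(st.head_act[i] <= 0.0)).zeros();
    head_grads[i] = List::create(_["W"] = wrap(arma::mat(st.head_in[i].t() * dZ)),
                                 _["b"] = as_rvec(arma::sum(dZ, 0)));
    dA = dZ * head[i].W.t();
  }

  arma::mat dMLP = dA.cols(0, st.mlp_dim - 1);
  List cnn_grads(cnn.size());
  if (!cnn.empty()) {
    arma::mat dGap = dA.cols(st.mlp_dim, dA.n_cols - 1);
    const int P = st.last_conv.n_cols;
    const int F = st.last_conv.n_slices;
    arma::cube dCur(B, P, F);
    for (int f = 0; f < F; ++f) {
      arma::mat sl(B, P);
      sl.each_col() = dGap.col(f) / (double)P;
      dCur.slice(f) = sl;
    }
    for (int i = (int)cnn.size() - 1; i >= 0; --i) {
      arma::mat dW;
      arma::rowvec db;
      arma::cube dPrev = conv_backward(dCur, cnn[i], st.conv[i], dW, db);
      cnn_grads[i] = List::create(_["W"] = wrap(dW), _["b"] = as_rvec(db));
      dCur = dPrev;
    }
  }

  List mlp_grads(mlp.size());
  arma::mat dAm = dMLP;
  for (int i = (int)mlp.size() - 1; i >= 0; --i) {
    arma::mat dZ = dAm;
    if (mlp[i].relu) dZ.elem(arma::find(st.mlp_act[i] <= 0.0)).zeros();
    mlp_grads[i] = List::create(_["W"] = wrap(arma::mat(st.mlp_in[i].t() * dZ)),
                                _["b"] = as_rvec(arma::sum(dZ, 0)));
    dAm = dZ * mlp[i].W.t();
  }

  List grads = List::create(_["mlp"] = mlp_grads,
                            _["cnn"] = cnn.empty() ? R_NilValue : (SEXP)cnn_grads,
                            _["head"] = head_grads);
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
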