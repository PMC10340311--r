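// GRU sequence-layer forward and backward passes.
//
// Layout: activations are cubes with dimensions (batch B, features F,
// time T); slice t is the (B x F) activation matrix at timestep t.
// Kernels use gate-column blocks [update z | reset r | candidate h]:
//   Wx: (in x 3H), Wh: (H x 3H), b: (3H).
// Cell (z = update, r = reset):
//   z_t = sigmoid(x_t Wx_z + h_{t-1} Wh_z + b_z)
//   r_t = sigmoid(x_t Wx_r + h_{t-1} Wh_r + b_r)
//   c_t = tanh(x_t Wx_h + (r_t . h_{t-1}) Wh_h + b_h)
//   h_t = z_t . h_{t-1} + (1 - z_t) . c_t
// The reverse direction is handled by time-flipping in R.
//
// The forward pass keeps its caches (inputs, gate activations) on the C++
// side behind an external pointer, so only the hidden states cross the
// R/C++ boundary; the input projection x_t Wx is hoisted out of the time
// loop into a single large GEMM.

#include <RcppArmadillo.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GruCache {
  mat Xm;          // (B*T x in), rows [t*B, (t+1)*B) hold timestep t
  cube H, Z, R, C; // (B, H, T)
  uword B, T;
};

// [[Rcpp::export]]
Rcpp::List gru_seq_forward(const arma::cube& X, const arma::mat& Wx,
                           const arma::mat& Wh, const arma::vec& b) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword H = Wh.n_rows;
  if (Wx.n_cols != 3 * H || Wh.n_cols != 3 * H || b.n_elem != 3 * H)
    Rcpp::stop("gru_seq_forward: inconsistent kernel shapes");
  if (X.n_cols != Wx.n_rows)
    Rcpp::stop("gru_seq_forward: input feature mismatch");

  Rcpp::XPtr<GruCache> cache(new GruCache(), true);
  cache->B = B; cache->T = T;
  cache->Xm.set_size(B * T, X.n_cols);
  for (uword t = 0; t < T; ++t) cache->Xm.rows(t * B, (t + 1) * B - 1) = X.slice(t);

  mat A_all = cache->Xm * Wx;          // one large GEMM for the input path
  A_all.each_row() += b.t();

  cache->H.set_size(B, H, T); cache->Z.set_size(B, H, T);
  cache->R.set_size(B, H, T); cache->C.set_size(B, H, T);
  const mat Wh_zr = Wh.cols(0, 2 * H - 1), Wh_h = Wh.cols(2 * H, 3 * H - 1);

  mat hprev(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = A_all.rows(t * B, (t + 1) * B - 1);
    A.cols(0, 2 * H - 1) += hprev * Wh_zr;
    mat z = sigmoid(A.cols(0, H - 1));
    mat r = sigmoid(A.cols(H, 2 * H - 1));
    mat c = tanh(A.cols(2 * H, 3 * H - 1) + (r % hprev) * Wh_h);
    mat h = z % hprev + (1.0 - z) % c;
    cache->Z.slice(t) = z; cache->R.slice(t) = r; cache->C.slice(t) = c;
    cache->H.slice(t) = h;
    hprev = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = cache->H,
                            Rcpp::Named("cache") = cache);
}

// [[Rcpp::export]]
Rcpp::List gru_seq_backward(SEXP cache_ptr, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::cube& dHout) {
  Rcpp::XPtr<GruCache> cache(cache_ptr);
  const uword B = cache->B, T = cache->T;
  const uword H = Wh.n_rows;
  const uword nin = Wx.n_rows;

  const mat Wh_z = Wh.cols(0, H - 1), Wh_r = Wh.cols(H, 2 * H - 1),
            Wh_h = Wh.cols(2 * H, 3 * H - 1);

  // per-timestep gate-preactivation gradients, collected for large GEMMs
  mat dA_all(B * T, 3 * H);
  mat Hp_all(B * T, H);             // h_{t-1} rows, zeros at t = 0
  mat RHp_all(B * T, H);            // r_t . h_{t-1}
  mat dh_carry(B, H, fill::zeros);

  for (uword ti = T; ti-- > 0;) {
    const mat& z = cache->Z.slice(ti);
    const mat& r = cache->R.slice(ti);
    const mat& c = cache->C.slice(ti);
    const mat hprev = (ti == 0) ? mat(B, H, fill::zeros)
                                : mat(cache->H.slice(ti - 1));

    mat dh = dHout.slice(ti) + dh_carry;
    mat dc = dh % (1.0 - z);
    mat dz = dh % (hprev - c);
    mat dah = dc % (1.0 - c % c);
    mat daz = dz % z % (1.0 - z);
    mat drh = dah * Wh_h.t();
    mat dar = (drh % hprev) % r % (1.0 - r);

    dh_carry = dh % z + daz * Wh_z.t() + dar * Wh_r.t() + drh % r;

    const uword r0 = ti * B, r1 = (ti + 1) * B - 1;
    dA_all.submat(r0, 0, r1, H - 1) = daz;
    dA_all.submat(r0, H, r1, 2 * H - 1) = dar;
    dA_all.submat(r0, 2 * H, r1, 3 * H - 1) = dah;
    Hp_all.rows(r0, r1) = hprev;
    RHp_all.rows(r0, r1) = r % hprev;
  }

  mat dX_m = dA_all * Wx.t();
  mat dWx = cache->Xm.t() * dA_all;
  mat dWh(H, 3 * H);
  dWh.cols(0, 2 * H - 1) = Hp_all.t() * dA_all.cols(0, 2 * H - 1);
  dWh.cols(2 * H, 3 * H - 1) = RHp_all.t() * dA_all.cols(2 * H, 3 * H - 1);
  vec db = sum(dA_all, 0).t();

  cube dX(B, nin, T);
  for (uword t = 0; t < T; ++t) dX.slice(t) = dX_m.rows(t * B, (t + 1) * B - 1);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}

// Pin the BLAS thread count (small recurrent GEMMs suffer badly from
// thread-pool synchronization); no-op when the symbol is unavailable.
// [[Rcpp::export]]
bool set_blas_threads(int n) {
#ifndef _WIN32
  typedef void (*setter)(int);
  void* sym = dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (sym == nullptr) sym = dlsym(RTLD_DEFAULT, "goto_set_num_threads");
  if (sym != nullptr) {
    reinterpret_cast<setter>(sym)(n);
    return true;
  }
#endif
  return false;
}
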