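// Batched Adam fitter for the max-snippet logistic model.
//
// All restarts are optimized simultaneously: the weights form an
// (n_features x n_restarts) matrix, so each iteration is a single BLAS-3
// product L = X * W followed by a per-patient, per-restart argmax. The
// gradient of the max-aggregated likelihood flows only through each
// patient's argmax snippet (first index on ties), giving the contribution
// (sigmoid(max_logit) - y) * x_argmax per patient and restart. The bias is
// constant within a restart, so it is added after the max rather than to
// every logit.
//
// Optimization arithmetic can run in single or double precision (single
// matches the float32 arithmetic of mainstream ML frameworks and halves
// memory traffic); initial and final likelihoods are always evaluated in
// double so restart selection and reported NLLs are full precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sigmoid(double m) {
  if (m >= 0.0) return 1.0 / (1.0 + std::exp(-m));
  double e = std::exp(m);
  return e / (1.0 + e);
}

// log(sigmoid(m)), stable for large |m|
static inline double log_sigmoid(double m) {
  if (m >= 0.0) return -std::log1p(std::exp(-m));
  return m - std::log1p(std::exp(m));
}

// unpenalized NLL per restart, double precision
static vec batch_nll(const mat& X, const uvec& pstart, const uvec& pend,
                     const vec& y, const mat& W, const rowvec& b0) {
  const uword P = pstart.n_elem, R = W.n_cols;
  mat L = X * W;
  vec nll(R, fill::zeros);
  for (uword r = 0; r < R; ++r) {
    const double* col = L.colptr(r);
    for (uword p = 0; p < P; ++p) {
      double m = col[pstart[p]];
      for (uword i = pstart[p] + 1; i <= pend[p]; ++i)
        if (col[i] > m) m = col[i];
      m += b0[r];
      nll[r] -= y[p] * log_sigmoid(m) + (1.0 - y[p]) * log_sigmoid(-m);
    }
  }
  return nll;
}

template <typename eT>
static void run_adam(const Mat<eT>& X,
                     const uvec& pstart, const uvec& pend, const vec& y,
                     Mat<eT>& W, Row<eT>& b0,
                     const int n_iterations, const double step_size,
                     const double beta1, const double beta2,
                     const double epsilon, const double l1, const double l2) {
  const uword f = X.n_cols, R = W.n_cols;
  const uword P = pstart.n_elem;
  const eT b1 = (eT)beta1, b2 = (eT)beta2, eps = (eT)epsilon;
  const eT step = (eT)step_size;

  // per-patient feature blocks, contiguous, plus transposes so the
  // gradient gather reads one contiguous column per argmax snippet
  std::vector< Mat<eT> > Xp(P), Xpt(P);
  uword max_np = 0;
  for (uword p = 0; p < P; ++p) {
    Xp[p] = X.rows(pstart[p], pend[p]);
    Xpt[p] = Xp[p].t();
    max_np = std::max(max_np, Xp[p].n_rows);
  }

  Mat<eT> mW(f, R, fill::zeros), vW(f, R, fill::zeros);
  Row<eT> mb(R, fill::zeros), vb(R, fill::zeros);
  Mat<eT> Lbuf(max_np, R);
  Mat<eT> G(f, R);
  Row<eT> gb(R);

  for (int t = 1; t <= n_iterations; ++t) {
    G.zeros();
    gb.zeros();
    for (uword p = 0; p < P; ++p) {
      const uword np = Xp[p].n_rows;
      // small per-patient GEMM into a reused buffer: the logit block
      // stays cache-resident for the argmax scan that follows
      Mat<eT> L(Lbuf.memptr(), np, R, false, true);
      L = Xp[p] * W;
      const eT yp = (eT)y[p];
      for (uword r = 0; r < R; ++r) {
        const eT* col = L.colptr(r);
        // two passes: vectorizable max reduction, then first-index search
        eT m = col[0];
        for (uword i = 1; i < np; ++i) m = col[i] > m ? col[i] : m;
        uword am = 0;
        while (col[am] != m) ++am;
        const eT resid = (eT)sigmoid((double)(m + b0[r])) - yp;
        gb[r] += resid;
        const eT* xcol = Xpt[p].colptr(am);
        eT* gcol = G.colptr(r);
        for (uword j = 0; j < f; ++j) gcol[j] += resid * xcol[j];
      }
    }
    if (l2 > 0.0) G += (eT)(2.0 * l2) * W;
    if (l1 > 0.0) G += (eT)l1 * sign(W);

    const eT c1 = (eT)1 - std::pow(b1, (eT)t);
    const eT c2 = (eT)1 - std::pow(b2, (eT)t);
    mW = b1 * mW + ((eT)1 - b1) * G;
    vW = b2 * vW + ((eT)1 - b2) * square(G);
    mb = b1 * mb + ((eT)1 - b1) * gb;
    vb = b2 * vb + ((eT)1 - b2) * square(gb);
    W -= step * (mW / c1) / (sqrt(vW / c2) + eps);
    b0 -= step * (mb / c1) / (sqrt(vb / c2) + eps);
  }
}

// Hot kernels of the codebook path. Marked for per-function -O3 and
// runtime SIMD dispatch (baseline build plus an AVX2 clone chosen by the
// loader), independent of the site-wide compiler flags.
#if defined(__GNUC__) && !defined(__clang__) && defined(__x86_64__) && \
    defined(__gnu_linux__)
#define MSNIP_HOT \
  __attribute__((optimize("O3", "unroll-loops"), \
                 target_clones("default", "avx2")))
#else
#define MSNIP_HOT
#endif

template <typename eT> struct hot_kernels {
  MSNIP_HOT static void copy(eT* __restrict a, const eT* __restrict s,
                             const int R) {
    for (int r = 0; r < R; ++r) a[r] = s[r];
  }
  MSNIP_HOT static void add(eT* __restrict a, const eT* __restrict s,
                            const int R) {
    for (int r = 0; r < R; ++r) a[r] += s[r];
  }
  MSNIP_HOT static void blend_max(eT* __restrict mx,
                                  unsigned int* __restrict am,
                                  const eT* __restrict a, const int R,
                                  const unsigned int i) {
    for (int r = 0; r < R; ++r) {
      const bool hit = a[r] > mx[r];
      mx[r] = hit ? a[r] : mx[r];
      am[r] = hit ? i : am[r];
    }
  }
};

// Codebook fast path. Every supported encoding is a position-wise lookup:
// the feature block of position j is one of A codebook rows (A <= 20), so
// logit(i, r) = b0[r] + sum_j S_j[code(i, j), r] where S_j = B W_j is a
// tiny (A x R) product recomputed once per iteration. This removes the
// large GEMM entirely; the per-snippet work is k contiguous vector adds
// over the restart dimension.
template <typename eT>
static void run_adam_codes(const Mat<eT>& X, const umat& codes,
                           const Mat<eT>& B,
                           const uvec& pstart, const uvec& pend, const vec& y,
                           Mat<eT>& W, Row<eT>& b0,
                           const int n_iterations, const double step_size,
                           const double beta1, const double beta2,
                           const double epsilon, const double l1,
                           const double l2) {
  const uword f = X.n_cols, R = W.n_cols;
  const uword P = pstart.n_elem;
  const uword k = codes.n_cols;
  const uword w = B.n_cols;            // features per position
  const eT b1 = (eT)beta1, b2 = (eT)beta2, eps = (eT)epsilon;
  const eT step = (eT)step_size;

  // transposed per-patient feature blocks for the gradient gather
  std::vector< Mat<eT> > Xpt(P);
  for (uword p = 0; p < P; ++p)
    Xpt[p] = Mat<eT>(X.rows(pstart[p], pend[p])).t();

  Mat<eT> mW(f, R, fill::zeros), vW(f, R, fill::zeros);
  Row<eT> mb(R, fill::zeros), vb(R, fill::zeros);
  Mat<eT> G(f, R);
  Row<eT> gb(R);
  std::vector< Mat<eT> > St(k);        // R x A per position
  Col<eT> acc(R), mx(R);
  std::vector<unsigned int> am(R);     // per-restart argmax, reused

  for (int t = 1; t <= n_iterations; ++t) {
    for (uword j = 0; j < k; ++j)
      St[j] = Mat<eT>(B * W.rows(j * w, (j + 1) * w - 1)).t();
    G.zeros();
    gb.zeros();
    for (uword p = 0; p < P; ++p) {
      const uword np = pend[p] - pstart[p] + 1;
      eT* mxp = mx.memptr();
      unsigned int* amp = am.data();
      for (uword i = 0; i < np; ++i) {
        const uword row = pstart[p] + i;
        eT* a = acc.memptr();
        hot_kernels<eT>::copy(a, St[0].colptr(codes(row, 0)), (int)R);
        for (uword j = 1; j < k; ++j)
          hot_kernels<eT>::add(a, St[j].colptr(codes(row, j)), (int)R);
        if (i == 0) {
          hot_kernels<eT>::copy(mxp, a, (int)R);
          std::fill(am.begin(), am.end(), 0u);
        } else {
          hot_kernels<eT>::blend_max(mxp, amp, a, (int)R, (unsigned int)i);
        }
      }
      const eT yp = (eT)y[p];
      for (uword r = 0; r < R; ++r) {
        const eT resid = (eT)sigmoid((double)(mxp[r] + b0[r])) - yp;
        gb[r] += resid;
        const eT* xcol = Xpt[p].colptr(amp[r]);
        eT* gcol = G.colptr(r);
        for (uword j = 0; j < f; ++j) gcol[j] += resid * xcol[j];
      }
    }
    if (l2 > 0.0) G += (eT)(2.0 * l2) * W;
    if (l1 > 0.0) G += (eT)l1 * sign(W);

    const eT c1 = (eT)1 - std::pow(b1, (eT)t);
    const eT c2 = (eT)1 - std::pow(b2, (eT)t);
    mW = b1 * mW + ((eT)1 - b1) * G;
    vW = b2 * vW + ((eT)1 - b2) * square(G);
    mb = b1 * mb + ((eT)1 - b1) * gb;
    vb = b2 * vb + ((eT)1 - b2) * square(gb);
    W -= step * (mW / c1) / (sqrt(vW / c2) + eps);
    b0 -= step * (mb / c1) / (sqrt(vb / c2) + eps);
  }
}

// [[Rcpp::export(name = ".fit_restarts_cpp")]]
Rcpp::List fit_restarts_cpp(const arma::mat& X,
                            const arma::ivec& patient_index, // 1-based, sorted
                            const arma::vec& y,
                            const arma::mat& W0,
                            const int n_iterations,
                            const double step_size,
                            const double beta1,
                            const double beta2,
                            const double epsilon,
                            const double l1,
                            const double l2,
                            const bool single_precision,
                            const arma::umat& codes,
                            const arma::mat& codebook) {
  const uword n = X.n_rows, R = W0.n_cols;
  const uword P = y.n_elem;
  if ((uword)patient_index.n_elem != n)
    Rcpp::stop("patient_index length must match nrow(X)");

  // contiguous row ranges per patient (encode_cohort sorts by patient)
  uvec pstart(P), pend(P);
  {
    uword p = 0;
    pstart[0] = 0;
    for (uword i = 1; i < n; ++i) {
      if (patient_index[i] != patient_index[i - 1]) {
        pend[p] = i - 1;
        ++p;
        if (p >= P) Rcpp::stop("patient_index inconsistent with labels");
        pstart[p] = i;
      }
    }
    pend[p] = n - 1;
    if (p != P - 1) Rcpp::stop("patient_index must cover every patient");
  }

  rowvec b0_init(R, fill::zeros);
  vec nll_init = batch_nll(X, pstart, pend, y, W0, b0_init);

  mat W_final(X.n_cols, R);
  rowvec b0_final(R);
  const bool use_codes = codes.n_rows == n && codes.n_cols > 0;
  if (use_codes &&
      codes.n_cols * codebook.n_cols != X.n_cols)
    Rcpp::stop("codes/codebook inconsistent with feature count");
  if (single_precision) {
    fmat Xs = conv_to<fmat>::from(X);
    fmat W = conv_to<fmat>::from(W0);
    frowvec b0(R, fill::zeros);
    if (use_codes) {
      fmat B = conv_to<fmat>::from(codebook);
      run_adam_codes<float>(Xs, codes, B, pstart, pend, y, W, b0,
                            n_iterations, step_size, beta1, beta2, epsilon,
                            l1, l2);
    } else {
      run_adam<float>(Xs, pstart, pend, y, W, b0, n_iterations,
                      step_size, beta1, beta2, epsilon, l1, l2);
    }
    W_final = conv_to<mat>::from(W);
    b0_final = conv_to<rowvec>::from(b0);
  } else {
    mat W = W0;
    rowvec b0(R, fill::zeros);
    if (use_codes) {
      run_adam_codes<double>(X, codes, codebook, pstart, pend, y, W, b0,
                             n_iterations, step_size, beta1, beta2, epsilon,
                             l1, l2);
    } else {
      run_adam<double>(X, pstart, pend, y, W, b0, n_iterations,
                       step_size, beta1, beta2, epsilon, l1, l2);
    }
    W_final = W;
    b0_final = b0;
  }

  vec nll_final = batch_nll(X, pstart, pend, y, W_final, b0_final);

  return Rcpp::List::create(
    Rcpp::Named("W") = W_final,
    Rcpp::Named("b0") = Rcpp::NumericVector(b0_final.begin(), b0_final.end()),
    Rcpp::Named("nll_final") = nll_final,
    Rcpp::Named("nll_init") = nll_init);
}
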