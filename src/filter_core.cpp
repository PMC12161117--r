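#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR single pass with initial state w.
// The fixed-order template keeps the state in registers, which matters at
// cohort scale (millions of samples per subject).
template <int NW>
static void df2t_fixed(const double *b, const double *a, double *win,
                       double *x, int n) {
  double w[NW];
  for (int k = 0; k < NW; ++k) w[k] = win[k];
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + w[0];
    for (int k = 0; k < NW - 1; ++k)
      w[k] = b[k + 1] * xt + w[k + 1] - a[k + 1] * yt;
    w[NW - 1] = b[NW] * xt - a[NW] * yt;
    x[t] = yt;
  }
  for (int k = 0; k < NW; ++k) win[k] = w[k];
}

static void df2t_pass(const std::vector<double> &b, const std::vector<double> &a,
                      std::vector<double> &w, double *x, int n) {
  const int nw = (int)w.size();
  switch (nw) {
    case 2: df2t_fixed<2>(b.data(), a.data(), w.data(), x, n); return;
    case 4: df2t_fixed<4>(b.data(), a.data(), w.data(), x, n); return;
    case 6: df2t_fixed<6>(b.data(), a.data(), w.data(), x, n); return;
    case 8: df2t_fixed<8>(b.data(), a.data(), w.data(), x, n); return;
    default: break;
  }
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + (nw > 0 ? w[0] : 0.0);
    for (int k = 0; k < nw - 1; ++k)
      w[k] = b[k + 1] * xt + w[k + 1] - a[k + 1] * yt;
    if (nw > 0) w[nw - 1] = b[nw] * xt - a[nw] * yt;
    x[t] = yt;
  }
}

// Single forward pass, zero initial conditions (exposed for oracle tests).
// [[Rcpp::export(name = ".iir_df2t")]]
NumericVector iir_df2t(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na) - 1;
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0), w(nw, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y = clone(x);
  df2t_pass(bb, aa, w, REAL(y), n);
  return y;
}

// Zero-phase (forward-backward) filtering of every column (byrow = false)
// or row (byrow = true) of X, with odd reflection padding of npad samples
// per side and steady-state initial conditions zi (scaled by the first
// padded sample) at the start of each pass, suppressing start-up transients
// for filters with non-zero DC gain.
// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericVector b, NumericVector a, NumericVector zi,
                           NumericMatrix X, int npad, bool byrow = false) {
  const int n = byrow ? X.ncol() : X.nrow();
  const int nser = byrow ? X.nrow() : X.ncol();
  const int nb = b.size(), na = a.size();
  const int nw = std::max(nb, na) - 1;
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (npad > n - 1) npad = n - 1;
  if (npad < 0) npad = 0;
  const int m = n + 2 * npad;
  NumericMatrix out(X.nrow(), X.ncol());
  std::vector<double> buf(m), x(n), w(nw);
  for (int j = 0; j < nser; ++j) {
    if (byrow) for (int t = 0; t < n; ++t) x[t] = X(j, t);
    else for (int t = 0; t < n; ++t) x[t] = X(t, j);
    for (int k = 0; k < npad; ++k) buf[k] = 2.0 * x[0] - x[npad - k];
    for (int t = 0; t < n; ++t) buf[npad + t] = x[t];
    for (int k = 0; k < npad; ++k) buf[npad + n + k] = 2.0 * x[n - 1] - x[n - 2 - k];
    for (int k = 0; k < nw; ++k) w[k] = zi[k] * buf[0];
    df2t_pass(bb, aa, w, buf.data(), m);
    std::reverse(buf.begin(), buf.end());
    for (int k = 0; k < nw; ++k) w[k] = zi[k] * buf[0];
    df2t_pass(bb, aa, w, buf.data(), m);
    std::reverse(buf.begin(), buf.end());
    if (byrow) for (int t = 0; t < n; ++t) out(j, t) = buf[npad + t];
    else for (int t = 0; t < n; ++t) out(t, j) = buf[npad + t];
  }
  return out;
}

// Pairwise phase lag index from a channels x samples phase matrix:
// |mean over samples of sgn(wrap(phi_a - phi_b))| with the difference
// wrapped to (-pi, pi] and sgn(0) = 0.
// [[Rcpp::export(name = ".pli_pairs")]]
NumericMatrix pli_pairs(NumericMatrix P) {
  const int nch = P.nrow(), n = P.ncol();
  const double PI2 = 2.0 * M_PI;
  NumericMatrix out(nch, nch);
  for (int a = 0; a < nch - 1; ++a) {
    for (int b = a + 1; b < nch; ++b) {
      double acc = 0.0;
      for (int t = 0; t < n; ++t) {
        double d = P(a, t) - P(b, t);
        d -= PI2 * std::ceil((d - M_PI) / PI2);
        acc += (d > 0.0) - (d < 0.0);
      }
      const double v = std::fabs(acc / n);
      out(a, b) = v;
      out(b, a) = v;
    }
  }
  return out;
}
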