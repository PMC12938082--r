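#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cascade of 4 biquad sections (direct form II transposed) per channel,
// followed by windowed RMS integration.  Coefficients per channel are laid
// out as a 20-element row: (b0,b1,b2,a1,a2) x 4 sections, a0 normalised to 1.
// Returns an n_channels x n_frames matrix of per-window RMS magnitudes.
// Single pass over time; per sample every channel's fused 4-section cascade
// advances (independent recurrences across channels pipeline well), and the
// squared output is accumulated into each integration window covering the
// sample.
// [[Rcpp::export(name = ".gammatone_bank_rms")]]
NumericMatrix gammatone_bank_rms(NumericVector x, NumericMatrix coefs,
                                 int win, int hop) {
  const int n = x.size();
  const int nch = coefs.nrow();
  if (coefs.ncol() != 20) stop("coefs must have 20 columns (4 biquads)");
  if (win <= 0 || hop <= 0) stop("win and hop must be positive");
  const int nframes = (n >= win) ? (n - win) / hop + 1 : 0;
  NumericMatrix out(nch, nframes);
  // flat copies for fast access: coefficients channel-major
  std::vector<double> cf(nch * 20);
  for (int ch = 0; ch < nch; ++ch)
    for (int k = 0; k < 20; ++k) cf[ch * 20 + k] = coefs(ch, k);
  std::vector<double> state(nch * 8, 0.0);  // z1,z2 per section per channel
  std::vector<double> y2(nch);
  double* acc = out.begin();  // column-major nch x nframes
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    for (int ch = 0; ch < nch; ++ch) {
      const double* c = &cf[ch * 20];
      double* z = &state[ch * 8];
      double v = xi;
      for (int s = 0; s < 4; ++s) {
        const double yi = c[5 * s] * v + z[2 * s];
        z[2 * s] = c[5 * s + 1] * v - c[5 * s + 3] * yi + z[2 * s + 1];
        z[2 * s + 1] = c[5 * s + 2] * v - c[5 * s + 4] * yi;
        v = yi;
      }
      y2[ch] = v * v;
    }
    const int f_hi = std::min(i / hop, nframes - 1);
    const int f_lo = (i - win + 1 > 0) ? (i - win + 1 + hop - 1) / hop : 0;
    for (int f = f_lo; f <= f_hi; ++f) {
      double* col = acc + (size_t)f * nch;
      for (int ch = 0; ch < nch; ++ch) col[ch] += y2[ch];
    }
  }
  for (int f = 0; f < nframes; ++f)
    for (int ch = 0; ch < nch; ++ch)
      out(ch, f) = std::sqrt(out(ch, f) / win);
  return out;
}

// Classic DTW with symmetric steps {(1,0),(0,1),(1,1)} and |a_i - b_j| local
// cost; two-row dynamic programme.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<double> prev(m), cur(m);
  prev[0] = std::fabs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::fabs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::fabs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      const double c = std::fabs(a[i] - b[j]);
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
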