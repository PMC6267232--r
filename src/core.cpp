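#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled phase-oscillator simulation (Kuramoto model with explicit phase lag).
//
// theta_i(t+1) = theta_i(t) + omega_i
//                + sum_j K_ij * sin(theta_j(t) - theta_i(t) - lag)
//                + phaseNoiseSd * N(0,1)
//
// K_ij = kappa for i != j both inside the designated sub-network,
//        background otherwise.  The all-to-all sums are computed through the
//        complex mean field, so each step costs O(N) rather than O(N^2):
//   sum_j K_ij sin(theta_j - theta_i - lag)
//     = Im( e^{-i(theta_i + lag)} * [ bg*(S - e^{i theta_i})
//                                     + (kappa-bg)*(S_R - e^{i theta_i}) 1_{i in R} ] )
// with S = sum_j e^{i theta_j}, S_R the same sum over the sub-network.
//
// The phase noise is pre-drawn in R (nRois x (burnIn + nSteps), already
// scaled), keeping all randomness under R's RNG / set.seed().
// Returns the phase matrix (nRois x nSteps) *after* discarding burnIn steps.
// [[Rcpp::export]]
NumericMatrix simOscillatorPhasesCpp(int nRois, int nSteps, int burnIn,
                                     NumericVector omega, IntegerVector rsnIdx,
                                     double kappa, double background,
                                     double lag, NumericMatrix noise,
                                     NumericVector theta0) {
  if (omega.size() != nRois || theta0.size() != nRois)
    stop("omega/theta0 length must equal nRois");
  if (noise.nrow() != nRois || noise.ncol() != burnIn + nSteps)
    stop("noise must be nRois x (burnIn + nSteps)");
  std::vector<bool> inR(nRois, false);
  for (int k = 0; k < rsnIdx.size(); ++k) {
    int i = rsnIdx[k] - 1;  // 1-based from R
    if (i < 0 || i >= nRois) stop("rsn index out of range");
    inR[i] = true;
  }
  const double cosLag = std::cos(lag), sinLag = std::sin(lag);
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> cs(nRois), sn(nRois);
  NumericMatrix out(nRois, nSteps);
  for (int t = -burnIn; t < nSteps; ++t) {
    double sumC = 0.0, sumS = 0.0, sumCr = 0.0, sumSr = 0.0;
    for (int i = 0; i < nRois; ++i) {
      cs[i] = std::cos(theta[i]);
      sn[i] = std::sin(theta[i]);
      sumC += cs[i];
      sumS += sn[i];
      if (inR[i]) { sumCr += cs[i]; sumSr += sn[i]; }
    }
    for (int i = 0; i < nRois; ++i) {
      if (t >= 0) out(i, t) = theta[i];
      double cre = background * (sumC - cs[i]);
      double cim = background * (sumS - sn[i]);
      if (inR[i]) {
        cre += (kappa - background) * (sumCr - cs[i]);
        cim += (kappa - background) * (sumSr - sn[i]);
      }
      // sin(theta_i + lag), cos(theta_i + lag) from the stored sincos
      double sinIL = sn[i] * cosLag + cs[i] * sinLag;
      double cosIL = cs[i] * cosLag - sn[i] * sinLag;
      double coupling = cim * cosIL - cre * sinIL;
      theta[i] += omega[i] + coupling + noise(i, t + burnIn);
    }
  }
  return out;
}

// Phase lag index for all unordered ROI pairs of a phase matrix (N x T).
//
// PLI_ij = | mean_t sign( sin(phi_i(t) - phi_j(t)) ) |
//
// sign(sin(.)) realizes the (-pi, pi] wrapping with the sign(0) = 0
// convention at wrapped differences of exactly 0 or pi.  Expanded as
// sin(a-b) = sin a cos b - cos a sin b with per-sample sincos precomputed,
// so the pair loop is multiply/compare only.
// [[Rcpp::export]]
NumericMatrix pliMatrixCpp(NumericMatrix phases) {
  const int n = phases.nrow(), T = phases.ncol();
  if (n < 2) stop("need at least 2 ROIs");
  if (T < 2) stop("need at least 2 samples");
  // ROI-major layout so each pair loop streams two contiguous arrays
  std::vector<double> cs((size_t)n * T), sn((size_t)n * T);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) {
      cs[(size_t)i * T + t] = std::cos(phases(i, t));
      sn[(size_t)i * T + t] = std::sin(phases(i, t));
    }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    const double *ci = &cs[(size_t)i * T], *si = &sn[(size_t)i * T];
    for (int j = i + 1; j < n; ++j) {
      const double *cj = &cs[(size_t)j * T], *sj = &sn[(size_t)j * T];
      long s = 0;
      for (int t = 0; t < T; ++t) {
        double d = si[t] * cj[t] - ci[t] * sj[t];
        s += (d > 0.0) - (d < 0.0);
      }
      double v = std::fabs((double)s) / T;
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
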