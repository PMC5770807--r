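#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-class LDA decoding of one condition pair in one region.
//
// a, b: 3 x T x n arrays of component scores (raw trials).
// permA, permB: n x R 1-based permutation matrices; each column is one
//   randomization's trial order. Trials are split into n_pseudo contiguous
//   groups (larger groups first) and averaged into pseudo-trials.
// testA, testB: R-vectors of 1-based held-out pseudo-trial indices.
// ridge: covariance regularization, S + ridge * tr(S)/3 * I.
//
// Per randomization and time bin: fit the pooled-covariance linear
// discriminant on the 2*(n_pseudo-1) training pseudo-trials, classify the two
// held-out pseudo-trials. Returns per-bin accuracy over all test
// classifications and the mean unit-normalized discriminant normal.

static inline bool solve3(const double S[6], const double d[3], double w[3]) {
  // S symmetric packed: [0]=xx [1]=xy [2]=xz [3]=yy [4]=yz [5]=zz
  double a = S[0], b = S[1], c = S[2], e = S[3], f = S[4], g = S[5];
  double A =  e * g - f * f;
  double B = -(b * g - c * f);
  double C =  b * f - c * e;
  double det = a * A + b * B + c * C;
  if (std::fabs(det) < 1e-300) return false;
  double D =  a * g - c * c;
  double E = -(a * f - b * c);
  double F =  a * e - b * b;
  w[0] = (A * d[0] + B * d[1] + C * d[2]) / det;
  w[1] = (B * d[0] + D * d[1] + E * d[2]) / det;
  w[2] = (C * d[0] + E * d[1] + F * d[2]) / det;
  return true;
}

// [[Rcpp::export]]
List lda_decode_pair(NumericVector a, NumericVector b,
                     IntegerMatrix permA, IntegerMatrix permB,
                     IntegerVector testA, IntegerVector testB,
                     int n_pseudo, double ridge) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  if (da.size() != 3 || db.size() != 3 || da[0] != 3 || db[0] != 3)
    stop("score arrays must be 3 x T x n");
  int T = da[1], nA = da[2], nB = db[2];
  if (db[1] != T) stop("time axes differ");
  int R = permA.ncol();
  if (permB.ncol() != R || testA.size() != R || testB.size() != R)
    stop("randomization inputs are inconsistent");
  int P = n_pseudo;
  if (nA < P || nB < P) stop("need at least n_pseudo trials per condition");

  // group sizes, larger first
  std::vector<int> szA(P), szB(P);
  for (int g = 0; g < P; ++g) {
    szA[g] = nA / P + (g < nA % P ? 1 : 0);
    szB[g] = nB / P + (g < nB % P ? 1 : 0);
  }

  const double *pa = REAL(a), *pb = REAL(b);
  std::vector<double> psA(3 * T * P), psB(3 * T * P);
  NumericVector acc(T);
  NumericMatrix wsum(3, T);
  int n_train = 2 * (P - 1);

  for (int r = 0; r < R; ++r) {
    // pseudo-trial means for this randomization
    std::fill(psA.begin(), psA.end(), 0.0);
    std::fill(psB.begin(), psB.end(), 0.0);
    int off = 0;
    for (int g = 0; g < P; ++g) {
      for (int j = 0; j < szA[g]; ++j) {
        int tr = permA(off + j, r) - 1;
        const double *src = pa + (size_t)tr * 3 * T;
        double *dst = &psA[(size_t)g * 3 * T];
        for (int k = 0; k < 3 * T; ++k) dst[k] += src[k];
      }
      double inv = 1.0 / szA[g];
      double *dst = &psA[(size_t)g * 3 * T];
      for (int k = 0; k < 3 * T; ++k) dst[k] *= inv;
      off += szA[g];
    }
    off = 0;
    for (int g = 0; g < P; ++g) {
      for (int j = 0; j < szB[g]; ++j) {
        int tr = permB(off + j, r) - 1;
        const double *src = pb + (size_t)tr * 3 * T;
        double *dst = &psB[(size_t)g * 3 * T];
        for (int k = 0; k < 3 * T; ++k) dst[k] += src[k];
      }
      double inv = 1.0 / szB[g];
      double *dst = &psB[(size_t)g * 3 * T];
      for (int k = 0; k < 3 * T; ++k) dst[k] *= inv;
      off += szB[g];
    }
    int ta = testA[r] - 1, tb = testB[r] - 1;

    for (int t = 0; t < T; ++t) {
      double sumA[3] = {0, 0, 0}, sumB[3] = {0, 0, 0};
      double outA[6] = {0, 0, 0, 0, 0, 0}, outB[6] = {0, 0, 0, 0, 0, 0};
      double xa[3], xb[3];
      for (int g = 0; g < P; ++g) {
        const double *x = &psA[(size_t)g * 3 * T + (size_t)t * 3];
        if (g == ta) { xa[0] = x[0]; xa[1] = x[1]; xa[2] = x[2]; continue; }
        sumA[0] += x[0]; sumA[1] += x[1]; sumA[2] += x[2];
        outA[0] += x[0] * x[0]; outA[1] += x[0] * x[1]; outA[2] += x[0] * x[2];
        outA[3] += x[1] * x[1]; outA[4] += x[1] * x[2]; outA[5] += x[2] * x[2];
      }
      for (int g = 0; g < P; ++g) {
        const double *x = &psB[(size_t)g * 3 * T + (size_t)t * 3];
        if (g == tb) { xb[0] = x[0]; xb[1] = x[1]; xb[2] = x[2]; continue; }
        sumB[0] += x[0]; sumB[1] += x[1]; sumB[2] += x[2];
        outB[0] += x[0] * x[0]; outB[1] += x[0] * x[1]; outB[2] += x[0] * x[2];
        outB[3] += x[1] * x[1]; outB[4] += x[1] * x[2]; outB[5] += x[2] * x[2];
      }
      double nA9 = P - 1, nB9 = P - 1;
      double mA[3], mB[3];
      for (int k = 0; k < 3; ++k) { mA[k] = sumA[k] / nA9; mB[k] = sumB[k] / nB9; }
      // pooled within-class covariance over the training pseudo-trials
      double S[6];
      S[0] = (outA[0] - nA9 * mA[0] * mA[0] + outB[0] - nB9 * mB[0] * mB[0]);
      S[1] = (outA[1] - nA9 * mA[0] * mA[1] + outB[1] - nB9 * mB[0] * mB[1]);
      S[2] = (outA[2] - nA9 * mA[0] * mA[2] + outB[2] - nB9 * mB[0] * mB[2]);
      S[3] = (outA[3] - nA9 * mA[1] * mA[1] + outB[3] - nB9 * mB[1] * mB[1]);
      S[4] = (outA[4] - nA9 * mA[1] * mA[2] + outB[4] - nB9 * mB[1] * mB[2]);
      S[5] = (outA[5] - nA9 * mA[2] * mA[2] + outB[5] - nB9 * mB[2] * mB[2]);
      double denom = n_train - 2;
      for (int k = 0; k < 6; ++k) S[k] /= denom;
      double tr3 = (S[0] + S[3] + S[5]) / 3.0;
      double lam = ridge * (tr3 > 0 ? tr3 : 1.0);
      S[0] += lam; S[3] += lam; S[5] += lam;
      double d[3] = {mA[0] - mB[0], mA[1] - mB[1], mA[2] - mB[2]};
      double w[3];
      if (!solve3(S, d, w)) {
        // fully degenerate draw: fall back to the mean-difference direction
        w[0] = d[0]; w[1] = d[1]; w[2] = d[2];
      }
      double cthr = 0.5 * (w[0] * (mA[0] + mB[0]) + w[1] * (mA[1] + mB[1]) +
                           w[2] * (mA[2] + mB[2]));
      double sa = w[0] * xa[0] + w[1] * xa[1] + w[2] * xa[2] - cthr;
      double sb = w[0] * xb[0] + w[1] * xb[1] + w[2] * xb[2] - cthr;
      if (sa > 0) acc[t] += 1.0;
      if (sb <= 0) acc[t] += 1.0;
      double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
      if (nw > 0) {
        wsum(0, t) += w[0] / nw; wsum(1, t) += w[1] / nw; wsum(2, t) += w[2] / nw;
      }
    }
  }

  NumericMatrix wout(3, T);
  for (int t = 0; t < T; ++t) {
    acc[t] /= 2.0 * R;
    double nw = std::sqrt(wsum(0, t) * wsum(0, t) + wsum(1, t) * wsum(1, t) +
                          wsum(2, t) * wsum(2, t));
    if (nw > 0) {
      wout(0, t) = wsum(0, t) / nw;
      wout(1, t) = wsum(1, t) / nw;
      wout(2, t) = wsum(2, t) / nw;
    }
  }
  return List::create(_["accuracy"] = acc, _["weights"] = wout,
                      _["n_train"] = n_train, _["n_test"] = 2);
}
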