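#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Residues are encoded in R as 1..A (A = alphabet size, X last); 0 marks a gap
// inside profile matrices. All scoring matrices arrive as numeric A x A.

// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                    double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  // affine gaps: a gap of length L costs gap_open + L * gap_extend
  std::vector<double> M(m + 1, 0.0), Ix(m + 1, R_NegInf), Iy(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diagM = 0.0, diagIx = R_NegInf, diagIy = R_NegInf; // cell (i-1, 0)
    M[0] = 0.0; Ix[0] = R_NegInf; Iy[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      double upM = M[j], upIx = Ix[j], upIy = Iy[j]; // cell (i-1, j)
      double s = submat(a[i - 1] - 1, b[j - 1] - 1);
      double from = std::max(diagM, std::max(diagIx, diagIy));
      double newM = std::max(0.0, from + s);
      double newIx = std::max(upM - gap_open - gap_extend, upIx - gap_extend);
      double newIy = std::max(M[j - 1] - gap_open - gap_extend, Iy[j - 1] - gap_extend);
      diagM = upM; diagIx = upIx; diagIy = upIy;
      M[j] = newM; Ix[j] = newIx; Iy[j] = newIy;
      if (newM > best) best = newM;
    }
  }
  return best;
}

// Mean substitution score between column ci of profile A and cj of profile B:
// sum of submat over non-gap residue pairs divided by (nrowA * nrowB).
static inline double col_score(const IntegerMatrix &A, int ci,
                               const IntegerMatrix &B, int cj,
                               const NumericMatrix &S) {
  double acc = 0.0;
  for (int r = 0; r < A.nrow(); ++r) {
    int x = A(r, ci);
    if (x == 0) continue;
    for (int q = 0; q < B.nrow(); ++q) {
      int y = B(q, cj);
      if (y == 0) continue;
      acc += S(x - 1, y - 1);
    }
  }
  return acc / ((double)A.nrow() * (double)B.nrow());
}

// Global (Needleman-Wunsch) profile-profile alignment with affine gaps,
// terminal gaps penalized. Returns ops: 1 = column pair, 2 = column from A
// against gap, 3 = column from B against gap (ops ordered left to right).
// [[Rcpp::export(name = ".pp_align_cpp")]]
IntegerVector pp_align_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix submat,
                           double gap_open, double gap_extend) {
  int n = A.ncol(), m = B.ncol();
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  // traceback: 0 from M, 1 from Ix (gap in B, consume A col), 2 from Iy
  IntegerMatrix tbM(n + 1, m + 1), tbIx(n + 1, m + 1), tbIy(n + 1, m + 1);
  M(0, 0) = 0; Ix(0, 0) = R_NegInf; Iy(0, 0) = R_NegInf;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = R_NegInf; Iy(i, 0) = R_NegInf;
    Ix(i, 0) = -gap_open - i * gap_extend; tbIx(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = R_NegInf; Ix(0, j) = R_NegInf;
    Iy(0, j) = -gap_open - j * gap_extend; tbIy(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = col_score(A, i - 1, B, j - 1, submat);
      double c0 = M(i - 1, j - 1), c1 = Ix(i - 1, j - 1), c2 = Iy(i - 1, j - 1);
      int arg = 0; double v = c0;
      if (c1 > v) { v = c1; arg = 1; }
      if (c2 > v) { v = c2; arg = 2; }
      M(i, j) = v + s; tbM(i, j) = arg;
      double o0 = M(i - 1, j) - gap_open - gap_extend;
      double o1 = Ix(i - 1, j) - gap_extend;
      if (o0 >= o1) { Ix(i, j) = o0; tbIx(i, j) = 0; }
      else          { Ix(i, j) = o1; tbIx(i, j) = 1; }
      double p0 = M(i, j - 1) - gap_open - gap_extend;
      double p2 = Iy(i, j - 1) - gap_extend;
      if (p0 >= p2) { Iy(i, j) = p0; tbIy(i, j) = 0; }
      else          { Iy(i, j) = p2; tbIy(i, j) = 2; }
    }
  }
  int state = 0; double v = M(n, m);
  if (Ix(n, m) > v) { v = Ix(n, m); state = 1; }
  if (Iy(n, m) > v) { v = Iy(n, m); state = 2; }
  std::vector<int> ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) { ops.push_back(1); state = tbM(i, j); --i; --j; }
    else if (state == 1) { ops.push_back(2); state = tbIx(i, j); --i; }
    else { ops.push_back(3); state = tbIy(i, j); --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double mx = std::max(a, b);
  return mx + std::log(std::exp(a - mx) + std::exp(b - mx));
}

// Scaled linear-space forward for the local profile HMM. Parameters arrive
// as probabilities / odds (exponentiated once per model by the caller):
// odds: (A+1) x M matrix, odds(a-1, k-1) = match emission odds of residue a
// in node k (row A, 0-indexed row 20 for X, is all 1); row A+1 unused.
// pInto*: probabilities into node k at R position k (see R-side layout);
// pMI/pII at position k+1 give the transition out of node k. Per sequence
// row the DP values are rescaled by the row maximum and one log accumulates,
// so the result matches the log-space sum within double precision.
// [[Rcpp::export(name = ".phmm_forward_scaled_cpp")]]
double phmm_forward_scaled_cpp(IntegerVector codes, NumericMatrix odds,
                               NumericVector pMM, NumericVector pMI,
                               NumericVector pMD, NumericVector pIM,
                               NumericVector pII, NumericVector pDM,
                               NumericVector pDD,
                               double pEntry, NumericVector pExit) {
  int L = codes.size(), M = odds.ncol();
  std::vector<double> FM(M + 1, 0.0), FI(M + 1, 0.0), FD(M + 1, 0.0);
  std::vector<double> pMv(M + 1), pIv(M + 1), pDv(M + 1);
  double logscale = 0.0, total = R_NegInf, entry_adj = pEntry;
  for (int j = 0; j < L; ++j) {
    pMv = FM; pIv = FI; pDv = FD;
    int a = codes[j] - 1; // 0-based residue row in odds
    for (int k = 1; k <= M; ++k) {
      double acc = entry_adj;
      if (k > 1)
        acc += pMv[k - 1] * pMM[k - 1] + pIv[k - 1] * pIM[k - 1] +
               pDv[k - 1] * pDM[k - 1];
      FM[k] = odds(a, k - 1) * acc;
      FI[k] = (k < M) ? (pMv[k] * pMI[k] + pIv[k] * pII[k]) : 0.0;
    }
    FD[1] = 0.0;
    for (int k = 2; k <= M; ++k)
      FD[k] = FM[k - 1] * pMD[k - 1] + FD[k - 1] * pDD[k - 1];
    double contrib = FD[M];
    for (int k = 1; k <= M; ++k) contrib += FM[k] * pExit[k - 1];
    if (contrib > 0.0)
      total = lse2(total, std::log(contrib) + logscale);
    double mx = 0.0;
    for (int k = 1; k <= M; ++k) {
      if (FM[k] > mx) mx = FM[k];
      if (FI[k] > mx) mx = FI[k];
      if (FD[k] > mx) mx = FD[k];
    }
    if (mx > 0.0) {
      double inv = 1.0 / mx;
      for (int k = 1; k <= M; ++k) { FM[k] *= inv; FI[k] *= inv; FD[k] *= inv; }
      logscale += std::log(mx);
    } else {
      std::fill(FM.begin(), FM.end(), 0.0);
      std::fill(FI.begin(), FI.end(), 0.0);
      std::fill(FD.begin(), FD.end(), 0.0);
    }
    entry_adj = pEntry * std::exp(-logscale);
  }
  return total;
}

// Profile HMM forward log-odds (natural log). Local (unihit) architecture:
// uniform entry B->M_k (prob 1/M); exit M_k->E with prob 1/(M-k+1), core
// transitions out of M_k pre-scaled by the caller with (1 - exit_k);
// D_M -> E with prob 1. Flanking residues outside the matched segment emit
// from the background at zero log-odds cost. Insert emissions equal the
// background, so insert emission log-odds are zero.
// em: L x M matrix of match emission log-odds em(j, k) for residue x_j in
// match state k+1. lMM/lMI/lMD: scaled log transitions out of node k (1-based
// index k = 1..M-1 used). lIM/lII out of insert k (k = 1..M-1). lDM/lDD out of
// delete k (k = 2..M-1 used for D->, entries k index node). lEntry: log(1/M).
// lExit[k]: log exit prob from M_k.
// [[Rcpp::export(name = ".phmm_forward_cpp")]]
double phmm_forward_cpp(NumericMatrix em, NumericVector lMM, NumericVector lMI,
                        NumericVector lMD, NumericVector lIM, NumericVector lII,
                        NumericVector lDM, NumericVector lDD,
                        double lEntry, NumericVector lExit) {
  int L = em.nrow(), M = em.ncol();
  std::vector<double> FM(M + 1, R_NegInf), FI(M + 1, R_NegInf), FD(M + 1, R_NegInf);
  std::vector<double> pM(M + 1), pI(M + 1), pD(M + 1);
  double total = R_NegInf;
  for (int j = 1; j <= L; ++j) {
    pM = FM; pI = FI; pD = FD;
    // deletes depend on current-row M/D at k-1: fill M and I first from
    // previous row, then D sweep.
    for (int k = 1; k <= M; ++k) {
      double acc = lEntry; // fresh entry, prefix emitted by N flank at cost 0
      if (k > 1) {
        acc = lse2(acc, pM[k - 1] + lMM[k - 1]);
        acc = lse2(acc, pI[k - 1] + lIM[k - 1]);
        acc = lse2(acc, pD[k - 1] + lDM[k - 1]);
      }
      FM[k] = em(j - 1, k - 1) + acc;
      if (k < M)
        FI[k] = lse2(pM[k] + lMI[k], pI[k] + lII[k]);
      else
        FI[k] = R_NegInf;
    }
    FD[1] = R_NegInf;
    for (int k = 2; k <= M; ++k)
      FD[k] = lse2(FM[k - 1] + lMD[k - 1], FD[k - 1] + lDD[k - 1]);
    // exit after consuming j residues; suffix emitted by C flank at cost 0
    for (int k = 1; k <= M; ++k) total = lse2(total, FM[k] + lExit[k - 1]);
    total = lse2(total, FD[M]); // D_M -> E, prob 1
  }
  return total;
}

// Viterbi companion: same architecture, max instead of sum; returns best
// log-odds and the state path encoded as 3*k + s (s: 0=M, 1=I, 2=D, node k).
// [[Rcpp::export(name = ".phmm_viterbi_cpp")]]
List phmm_viterbi_cpp(NumericMatrix em, NumericVector lMM, NumericVector lMI,
                      NumericVector lMD, NumericVector lIM, NumericVector lII,
                      NumericVector lDM, NumericVector lDD,
                      double lEntry, NumericVector lExit) {
  int L = em.nrow(), M = em.ncol();
  NumericMatrix VM(L + 1, M + 1), VI(L + 1, M + 1), VD(L + 1, M + 1);
  IntegerMatrix tM(L + 1, M + 1), tI(L + 1, M + 1), tD(L + 1, M + 1);
  std::fill(VM.begin(), VM.end(), R_NegInf);
  std::fill(VI.begin(), VI.end(), R_NegInf);
  std::fill(VD.begin(), VD.end(), R_NegInf);
  // traceback codes: 0 entry, 1 from M, 2 from I, 3 from D
  for (int j = 1; j <= L; ++j) {
    for (int k = 1; k <= M; ++k) {
      double best = lEntry; int arg = 0;
      if (k > 1) {
        double c;
        c = VM(j - 1, k - 1) + lMM[k - 1]; if (c > best) { best = c; arg = 1; }
        c = VI(j - 1, k - 1) + lIM[k - 1]; if (c > best) { best = c; arg = 2; }
        c = VD(j - 1, k - 1) + lDM[k - 1]; if (c > best) { best = c; arg = 3; }
      }
      VM(j, k) = em(j - 1, k - 1) + best; tM(j, k) = arg;
      if (k < M) {
        double c1 = VM(j - 1, k) + lMI[k], c2 = VI(j - 1, k) + lII[k];
        if (c1 >= c2) { VI(j, k) = c1; tI(j, k) = 1; }
        else          { VI(j, k) = c2; tI(j, k) = 2; }
      }
    }
    for (int k = 2; k <= M; ++k) {
      double c1 = VM(j, k - 1) + lMD[k - 1], c3 = VD(j, k - 1) + lDD[k - 1];
      if (c1 >= c3) { VD(j, k) = c1; tD(j, k) = 1; }
      else          { VD(j, k) = c3; tD(j, k) = 3; }
    }
  }
  double best = R_NegInf; int bj = -1, bk = -1, bs = -1;
  for (int j = 1; j <= L; ++j) {
    for (int k = 1; k <= M; ++k) {
      double c = VM(j, k) + lExit[k - 1];
      if (c > best) { best = c; bj = j; bk = k; bs = 0; }
    }
    double c = VD(j, M);
    if (c > best) { best = c; bj = j; bk = M; bs = 2; }
  }
  std::vector<int> path;
  if (best > R_NegInf) {
    int j = bj, k = bk, s = bs;
    while (true) {
      path.push_back(3 * k + s);
      if (s == 0) { // match
        int tb = tM(j, k);
        if (tb == 0) break;
        s = tb - 1; --j; --k;
      } else if (s == 1) { // insert
        int tb = tI(j, k);
        s = tb - 1; --j;
      } else { // delete
        int tb = tD(j, k);
        s = tb - 1; --k;
      }
    }
    std::reverse(path.begin(), path.end());
  }
  return List::create(_["logodds"] = best, _["path"] = wrap(path));
}
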