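#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine gap convention used throughout: a gap run of length k costs
// open + (k - 1) * extend (the first gap position pays `open`).
// Residue codes are 1-based into the matrix columns; the matrices passed
// from R carry a trailing neutral column/row (score 0) for unknown residues,
// so codes are always valid indices here.

static const double NEG = -1e30;

// ---------------------------------------------------------------------------
// Global alignment of a sequence to a position-specific scoring profile.
// States: M (residue emitted at a profile column), I (insertion: residue
// consumed, no column), D (deletion: column consumed, gap in sequence).
// I<->D transitions are disallowed. All residues and all columns must be
// consumed (true global alignment).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List pssm_align_global_cpp(NumericMatrix emis, IntegerVector seq,
                           double gap_open, double gap_extend) {
  int n = seq.size();      // residues
  int m = emis.nrow();     // profile columns
  std::vector<double> M((n + 1) * (m + 1), NEG), I((n + 1) * (m + 1), NEG),
      D((n + 1) * (m + 1), NEG);
  // pointer codes: 0=M, 1=I, 2=D (predecessor state); -1 = start
  std::vector<signed char> pM((n + 1) * (m + 1), -1), pI((n + 1) * (m + 1), -1),
      pD((n + 1) * (m + 1), -1);
  auto ix = [m](int i, int j) { return i * (m + 1) + j; };

  M[ix(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    I[ix(i, 0)] = (i == 1) ? -gap_open : I[ix(i - 1, 0)] - gap_extend;
    pI[ix(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    D[ix(0, j)] = (j == 1) ? -gap_open : D[ix(0, j - 1)] - gap_extend;
    pD[ix(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    int a = seq[i - 1];  // 1-based residue code
    for (int j = 1; j <= m; ++j) {
      // M
      double dM = M[ix(i - 1, j - 1)], dI = I[ix(i - 1, j - 1)],
             dD = D[ix(i - 1, j - 1)];
      double best = dM; signed char p = 0;
      if (dI > best) { best = dI; p = 1; }
      if (dD > best) { best = dD; p = 2; }
      if (best > NEG / 2) {
        M[ix(i, j)] = best + emis(j - 1, a - 1);
        pM[ix(i, j)] = p;
      }
      // I (from M or I at (i-1, j))
      double oM = M[ix(i - 1, j)] - gap_open;
      double oI = I[ix(i - 1, j)] - gap_extend;
      if (oM >= oI) { I[ix(i, j)] = oM; pI[ix(i, j)] = 0; }
      else          { I[ix(i, j)] = oI; pI[ix(i, j)] = 1; }
      // D (from M or D at (i, j-1))
      double gM = M[ix(i, j - 1)] - gap_open;
      double gD = D[ix(i, j - 1)] - gap_extend;
      if (gM >= gD) { D[ix(i, j)] = gM; pD[ix(i, j)] = 0; }
      else          { D[ix(i, j)] = gD; pD[ix(i, j)] = 2; }
    }
  }
  double sM = M[ix(n, m)], sI = I[ix(n, m)], sD = D[ix(n, m)];
  double score = sM; int state = 0;
  if (sI > score) { score = sI; state = 1; }
  if (sD > score) { score = sD; state = 2; }

  // Traceback: record, for each profile column, the 1-based residue index
  // matched to it (0 = deletion). Insertions consume residues silently.
  IntegerVector trace(m, 0);
  int i = n, j = m, st = state;
  while (i > 0 || j > 0) {
    if (st == 0) {           // match consumed (i, j)
      signed char p = pM[ix(i, j)];
      trace[j - 1] = i;
      --i; --j; st = p;
    } else if (st == 1) {    // insertion consumed residue i
      signed char p = pI[ix(i, j)];
      --i; st = p;
    } else {                 // deletion consumed column j
      signed char p = pD[ix(i, j)];
      trace[j - 1] = 0;
      --j; st = p;
    }
    if (st < 0) break;
  }
  return List::create(_["score"] = score, _["trace"] = trace);
}

// Score-only batch version (two rolling rows, no traceback).
// [[Rcpp::export]]
NumericVector pssm_score_batch_cpp(NumericMatrix emis, List seqs,
                                   double gap_open, double gap_extend) {
  int m = emis.nrow();
  int nseq = seqs.size();
  const double* emp = emis.begin();  // column-major: emis(j, a) = emp[a*m + j]
  NumericVector out(nseq);
  std::vector<double> Mp(m + 1), Ip(m + 1), Dp(m + 1), Mc(m + 1), Ic(m + 1),
      Dc(m + 1);
  for (int s = 0; s < nseq; ++s) {
    IntegerVector seqv = seqs[s];
    std::vector<int> seq(seqv.begin(), seqv.end());
    int n = (int)seq.size();
    for (int j = 0; j <= m; ++j) { Mp[j] = NEG; Ip[j] = NEG; Dp[j] = NEG; }
    Mp[0] = 0.0;
    for (int j = 1; j <= m; ++j)
      Dp[j] = (j == 1) ? -gap_open : Dp[j - 1] - gap_extend;
    for (int i = 1; i <= n; ++i) {
      Mc[0] = NEG; Dc[0] = NEG;
      Ic[0] = (i == 1) ? -gap_open : Ip[0] - gap_extend;
      const double* ecol = emp + (size_t)(seq[i - 1] - 1) * m - 1;
      const double *mp = Mp.data(), *ip = Ip.data(), *dp = Dp.data();
      double* mc = Mc.data(); double* ic = Ic.data(); double* dc = Dc.data();
      double dprev = dc[0], mprev = mc[0];
      for (int j = 1; j <= m; ++j) {
        double best = mp[j - 1];
        if (ip[j - 1] > best) best = ip[j - 1];
        if (dp[j - 1] > best) best = dp[j - 1];
        double mcj = (best > NEG / 2) ? best + ecol[j] : NEG;
        mc[j] = mcj;
        double oM = mp[j] - gap_open, oI = ip[j] - gap_extend;
        ic[j] = (oM >= oI) ? oM : oI;
        double gM = mprev - gap_open, gD = dprev - gap_extend;
        dprev = (gM >= gD) ? gM : gD;
        dc[j] = dprev;
        mprev = mcj;
      }
      std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
    }
    double sc = Mp[m];
    if (Ip[m] > sc) sc = Ip[m];
    if (Dp[m] > sc) sc = Dp[m];
    out[s] = sc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local alignment of a sequence against a profile (Smith-Waterman over
// PSSM emissions). Returns optimal score and the residue/column envelope
// (1-based inclusive) of the optimal path. Path starts are restricted to
// match states (score reset in M only), as usual for local alignment.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List pssm_align_local_cpp(NumericMatrix emis, IntegerVector seq,
                          double gap_open, double gap_extend) {
  int n = seq.size(), m = emis.nrow();
  std::vector<double> Mp(m + 1, 0), Ip(m + 1, NEG), Dp(m + 1, NEG),
      Mc(m + 1), Ic(m + 1), Dc(m + 1);
  // origin (start cell) of the best path through each cell, encoded i*1e6+j
  std::vector<long> oMp(m + 1, 0), oIp(m + 1, 0), oDp(m + 1, 0),
      oMc(m + 1), oIc(m + 1), oDc(m + 1);
  double best = 0; long bestOrigin = 0; int bi = 0, bj = 0;
  Mp.assign(m + 1, NEG); Mp[0] = NEG;  // row 0: no match possible
  for (int j = 0; j <= m; ++j) { Mp[j] = NEG; Ip[j] = NEG; Dp[j] = NEG; }
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Ic[0] = NEG; Dc[0] = NEG;
    oMc[0] = 0; oIc[0] = 0; oDc[0] = 0;
    int a = seq[i - 1];
    for (int j = 1; j <= m; ++j) {
      double e = emis(j - 1, a - 1);
      // M: extend from diagonal or start fresh here
      double dM = Mp[j - 1], dI = Ip[j - 1], dD = Dp[j - 1];
      double pv = dM; long org = oMp[j - 1];
      if (dI > pv) { pv = dI; org = oIp[j - 1]; }
      if (dD > pv) { pv = dD; org = oDp[j - 1]; }
      if (pv < 0) { pv = 0; org = (long)i * 1000000L + j; }  // fresh start
      Mc[j] = pv + e; oMc[j] = org;
      double oMv = Mp[j] - gap_open, oIv = Ip[j] - gap_extend;
      if (oMv >= oIv) { Ic[j] = oMv; oIc[j] = oMp[j]; }
      else            { Ic[j] = oIv; oIc[j] = oIp[j]; }
      double gMv = Mc[j - 1] - gap_open, gDv = Dc[j - 1] - gap_extend;
      if (gMv >= gDv) { Dc[j] = gMv; oDc[j] = oMc[j - 1]; }
      else            { Dc[j] = gDv; oDc[j] = oDp[j - 1]; }
      if (Mc[j] > best) { best = Mc[j]; bestOrigin = oMc[j]; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
    std::swap(oMp, oMc); std::swap(oIp, oIc); std::swap(oDp, oDc);
  }
  int si = (int)(bestOrigin / 1000000L), sj = (int)(bestOrigin % 1000000L);
  return List::create(_["score"] = best, _["seq_start"] = si,
                      _["seq_end"] = bi, _["col_start"] = sj,
                      _["col_end"] = bj);
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment between two sequences under a substitution
// matrix. Returns score and 1-based inclusive bounds in both sequences.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  std::vector<double> Mp(m + 1, NEG), Ip(m + 1, NEG), Dp(m + 1, NEG),
      Mc(m + 1), Ic(m + 1), Dc(m + 1);
  std::vector<long> oMp(m + 1, 0), oIp(m + 1, 0), oDp(m + 1, 0),
      oMc(m + 1), oIc(m + 1), oDc(m + 1);
  double best = 0; long bestOrigin = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Ic[0] = NEG; Dc[0] = NEG;
    oMc[0] = 0; oIc[0] = 0; oDc[0] = 0;
    for (int j = 1; j <= m; ++j) {
      double e = sub(a[i - 1] - 1, b[j - 1] - 1);
      double dM = Mp[j - 1], dI = Ip[j - 1], dD = Dp[j - 1];
      double pv = dM; long org = oMp[j - 1];
      if (dI > pv) { pv = dI; org = oIp[j - 1]; }
      if (dD > pv) { pv = dD; org = oDp[j - 1]; }
      if (pv < 0) { pv = 0; org = (long)i * 1000000L + j; }
      Mc[j] = pv + e; oMc[j] = org;
      double oMv = Mp[j] - gap_open, oIv = Ip[j] - gap_extend;
      if (oMv >= oIv) { Ic[j] = oMv; oIc[j] = oMp[j]; }
      else            { Ic[j] = oIv; oIc[j] = oIp[j]; }
      double gMv = Mc[j - 1] - gap_open, gDv = Dc[j - 1] - gap_extend;
      if (gMv >= gDv) { Dc[j] = gMv; oDc[j] = oMc[j - 1]; }
      else            { Dc[j] = gDv; oDc[j] = oDp[j - 1]; }
      if (Mc[j] > best) { best = Mc[j]; bestOrigin = oMc[j]; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
    std::swap(oMp, oMc); std::swap(oIp, oIc); std::swap(oDp, oDc);
  }
  int si = (int)(bestOrigin / 1000000L), sj = (int)(bestOrigin % 1000000L);
  return List::create(_["score"] = best, _["a_start"] = si, _["a_end"] = bi,
                      _["b_start"] = sj, _["b_end"] = bj);
}

// Score-only Smith-Waterman of one query against many targets.
// [[Rcpp::export]]
NumericVector sw_score_batch_cpp(IntegerVector a, List targets,
                                 NumericMatrix sub, double gap_open,
                                 double gap_extend) {
  int n = a.size();
  int nt = targets.size();
  int nr = sub.nrow();
  const double* subp = sub.begin();
  NumericVector out(nt);
  // per-query-residue lookup rows: row[i][r] = sub(a_i, r), stride-1 access
  std::vector<double> rows((size_t)n * nr);
  for (int i = 0; i < n; ++i)
    for (int r = 0; r < nr; ++r)
      rows[(size_t)i * nr + r] = subp[(size_t)r * nr + (a[i] - 1)];
  for (int t = 0; t < nt; ++t) {
    IntegerVector bv = targets[t];
    int m = bv.size();
    std::vector<int> b(m);
    for (int j = 0; j < m; ++j) b[j] = bv[j] - 1;
    std::vector<double> Mp(m + 1, NEG), Ip(m + 1, NEG), Dp(m + 1, NEG),
        Mc(m + 1), Ic(m + 1), Dc(m + 1);
    double best = 0;
    for (int i = 1; i <= n; ++i) {
      Mc[0] = NEG; Ic[0] = NEG; Dc[0] = NEG;
      const double* srow = rows.data() + (size_t)(i - 1) * nr;
      const double *mp = Mp.data(), *ip = Ip.data(), *dp = Dp.data();
      double* mc = Mc.data(); double* ic = Ic.data(); double* dc = Dc.data();
      double mprev = mc[0], dprev = dc[0];
      for (int j = 1; j <= m; ++j) {
        double pv = mp[j - 1];
        if (ip[j - 1] > pv) pv = ip[j - 1];
        if (dp[j - 1] > pv) pv = dp[j - 1];
        if (pv < 0) pv = 0;
        double mcj = pv + srow[b[j - 1]];
        mc[j] = mcj;
        double oMv = mp[j] - gap_open, oIv = ip[j] - gap_extend;
        ic[j] = (oMv >= oIv) ? oMv : oIv;
        double gMv = mprev - gap_open, gDv = dprev - gap_extend;
        dprev = (gMv >= gDv) ? gMv : gDv;
        dc[j] = dprev;
        if (mcj > best) best = mcj;
        mprev = mcj;
      }
      std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
    }
    out[t] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Needleman-Wunsch global alignment with full traceback; terminal gaps are
// penalised like internal ones. Returns aligned residue-index vectors with
// 0 marking a gap.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG), I((n + 1) * (m + 1), NEG),
      D((n + 1) * (m + 1), NEG);
  std::vector<signed char> pM((n + 1) * (m + 1), -1),
      pI((n + 1) * (m + 1), -1), pD((n + 1) * (m + 1), -1);
  auto ix = [m](int i, int j) { return i * (m + 1) + j; };
  M[ix(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    I[ix(i, 0)] = (i == 1) ? -gap_open : I[ix(i - 1, 0)] - gap_extend;
    pI[ix(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    D[ix(0, j)] = (j == 1) ? -gap_open : D[ix(0, j - 1)] - gap_extend;
    pD[ix(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = sub(a[i - 1] - 1, b[j - 1] - 1);
      double dM = M[ix(i - 1, j - 1)], dI = I[ix(i - 1, j - 1)],
             dD = D[ix(i - 1, j - 1)];
      double bv = dM; signed char p = 0;
      if (dI > bv) { bv = dI; p = 1; }
      if (dD > bv) { bv = dD; p = 2; }
      if (bv > NEG / 2) { M[ix(i, j)] = bv + e; pM[ix(i, j)] = p; }
      double oMv = M[ix(i - 1, j)] - gap_open,
             oIv = I[ix(i - 1, j)] - gap_extend;
      if (oMv >= oIv) { I[ix(i, j)] = oMv; pI[ix(i, j)] = 0; }
      else            { I[ix(i, j)] = oIv; pI[ix(i, j)] = 1; }
      double gMv = M[ix(i, j - 1)] - gap_open,
             gDv = D[ix(i, j - 1)] - gap_extend;
      if (gMv >= gDv) { D[ix(i, j)] = gMv; pD[ix(i, j)] = 0; }
      else            { D[ix(i, j)] = gDv; pD[ix(i, j)] = 2; }
    }
  }
  double sM = M[ix(n, m)], sI = I[ix(n, m)], sD = D[ix(n, m)];
  double score = sM; int st = 0;
  if (sI > score) { score = sI; st = 1; }
  if (sD > score) { score = sD; st = 2; }
  std::vector<int> ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0) {
      signed char p = pM[ix(i, j)];
      ra.push_back(i); rb.push_back(j); --i; --j; st = p;
    } else if (st == 1) {
      signed char p = pI[ix(i, j)];
      ra.push_back(i); rb.push_back(0); --i; st = p;
    } else {
      signed char p = pD[ix(i, j)];
      ra.push_back(0); rb.push_back(j); --j; st = p;
    }
    if (st < 0) break;
  }
  IntegerVector A(ra.size()), B(rb.size());
  int L = (int)ra.size();
  for (int k = 0; k < L; ++k) { A[k] = ra[L - 1 - k]; B[k] = rb[L - 1 - k]; }
  return List::create(_["score"] = score, _["a_aln"] = A, _["b_aln"] = B);
}
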