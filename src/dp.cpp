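// Dynamic programming kernels for profile HMM scoring.
//
// Conventions shared with the R wrappers:
//   - sequences arrive as 0-based integer codes, 0..19 canonical residues,
//     20 = X (scores 0 bits / odds 1 at every position);
//   - emission score matrices are M x 21 in bits (log2 odds vs background);
//   - transition vectors are indexed by source position k (0-based), so
//     tmm[k] is the M_{k+1} -> M_{k+2} transition in 1-based terms;
//   - all scores are log2 (bits) unless a function works in the odds domain.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEGINF = -std::numeric_limits<double>::infinity();

// log2(2^a + 2^b), exact
static inline double ls2(double a, double b) {
  if (a == NEGINF) return b;
  if (b == NEGINF) return a;
  double mx = a > b ? a : b;
  double mn = a > b ? b : a;
  return mx + std::log1p(std::exp2(mn - mx)) / M_LN2;
}

// ---------------------------------------------------------------------------
// MSV, full precision serial version.  Single O(M) row; multihit ungapped
// model: match-match transitions cost 0, entry uniform, exit probability 1.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_msv_score(NumericMatrix s, IntegerVector seq, double entry_msv,
                     double loop2, double move2, double nulltr) {
  const int M = s.nrow(), L = seq.size();
  std::vector<double> cur(M, NEGINF), prev(M, NEGINF);
  double xN = 0.0, xB = move2, xJ = NEGINF, xC = NEGINF;
  const double lee = -1.0; // log2 t(E->J) = log2 t(E->C) = log2 0.5

  for (int i = 0; i < L; ++i) {
    const int x = seq[i];
    double xE = NEGINF;
    for (int k = 0; k < M; ++k) {
      double diag = (k > 0) ? prev[k - 1] : NEGINF;
      double ent = xB + entry_msv;
      double v = (diag > ent ? diag : ent) + s(k, x);
      cur[k] = v;
      if (v > xE) xE = v;
    }
    std::swap(cur, prev);
    xJ = std::max(xJ + loop2, xE + lee);
    xC = std::max(xC + loop2, xE + lee);
    xN += loop2;
    xB = std::max(xN + move2, xJ + move2);
  }
  return xC + move2 - nulltr;
}

// ---------------------------------------------------------------------------
// MSV filter: striped, saturated unsigned-byte arithmetic (emulated).
// Emission costs arrive striped: row index r = q*V + v holds the cost for
// cell k with q = k mod Q, v = k div Q (0-based); sentinel cells cost 255.
// NN/CC/JJ transitions are scored as zero cost; the flanking-loop constant
// and the null model terms are restored by the R wrapper at termination.
// ---------------------------------------------------------------------------

static inline int sadd_u8(int a, int b) { int v = a + b; return v > 255 ? 255 : v; }
static inline int ssub_u8(int a, int b) { int v = a - b; return v < 0 ? 0 : v; }

// [[Rcpp::export]]
List cpp_msv_filter(IntegerMatrix em, int Q, int V, IntegerVector seq,
                    int base, int bias, int tjb, int tbm, int tec) {
  const int L = seq.size();
  std::vector<int> dp(Q * V, 0), mpv(V, 0), tmp(V, 0);
  const int tjbm = sadd_u8(tjb, tbm);
  int xJ = 0;
  int xB = ssub_u8(base, tjbm);
  bool overflow = false;

  for (int i = 0; i < L; ++i) {
    const int x = seq[i];
    int xE = 0;
    // mpv: previous row's last vector, right-shifted one lane (0 shifted in)
    for (int v = V - 1; v >= 1; --v) mpv[v] = dp[(Q - 1) * V + (v - 1)];
    mpv[0] = 0;
    for (int q = 0; q < Q; ++q) {
      for (int v = 0; v < V; ++v) {
        int sv = mpv[v] > xB ? mpv[v] : xB;
        sv = sadd_u8(sv, bias);
        sv = ssub_u8(sv, em(q * V + v, x));
        tmp[v] = dp[q * V + v];
        dp[q * V + v] = sv;
        if (sv > xE) xE = sv;
      }
      for (int v = 0; v < V; ++v) mpv[v] = tmp[v];
    }
    if (xE >= 255 - bias) { overflow = true; break; }
    xJ = std::max(xJ, ssub_u8(xE, tec));
    xB = ssub_u8(std::max(base, xJ), tjbm);
  }
  return List::create(_["raw"] = xJ, _["overflow"] = overflow);
}

// ---------------------------------------------------------------------------
// Gapped Viterbi, full precision, O(M) memory.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_viterbi_score(NumericMatrix s, IntegerVector seq,
                         NumericVector tmm, NumericVector tmi, NumericVector tmd,
                         NumericVector tim, NumericVector tii,
                         NumericVector tdm, NumericVector tdd,
                         NumericVector entry, double loop2, double move2,
                         double nulltr) {
  const int M = s.nrow(), L = seq.size();
  std::vector<double> m(M, NEGINF), ii_(M, NEGINF), d(M, NEGINF);
  std::vector<double> mp(M, NEGINF), ip(M, NEGINF), dp(M, NEGINF);
  double xN = 0.0, xB = move2, xJ = NEGINF, xC = NEGINF;
  const double lee = -1.0;

  for (int i = 0; i < L; ++i) {
    const int x = seq[i];
    double xE = NEGINF;
    for (int k = 0; k < M; ++k) {
      double best = xB + entry[k];
      if (k > 0) {
        double a = mp[k - 1] + tmm[k - 1];
        double b = ip[k - 1] + tim[k - 1];
        double c = dp[k - 1] + tdm[k - 1];
        if (a > best) best = a;
        if (b > best) best = b;
        if (c > best) best = c;
      }
      m[k] = best + s(k, x);
      if (m[k] > xE) xE = m[k];
      ii_[k] = (k < M - 1)
        ? std::max(mp[k] + tmi[k], ip[k] + tii[k])
        : NEGINF;
      d[k] = (k > 0)
        ? std::max(m[k - 1] + tmd[k - 1], d[k - 1] + tdd[k - 1])
        : NEGINF;
    }
    std::swap(m, mp); std::swap(ii_, ip); std::swap(d, dp);
    xJ = std::max(xJ + loop2, xE + lee);
    xC = std::max(xC + loop2, xE + lee);
    xN += loop2;
    xB = std::max(xN + move2, xJ + move2);
  }
  return xC + move2 - nulltr;
}

// ---------------------------------------------------------------------------
// Viterbi filter: saturated signed 16-bit words, 1/500-bit units, offset
// 12000.  Emission words arrive striped (same layout as the byte filter,
// sentinel -32768) and are read through the stripe index map; the delete
// chain along a row is resolved by a serialized pass in cell order.
// NN/CC/JJ loops are scored as zero cost; every match/insert emission is
// pre-adjusted by adj_w ~ -500*log2(L/(L+3)) so that the exact flanking-loop
// total can be restored in floating point at termination.
// ---------------------------------------------------------------------------

static inline int sat_w(int v) { return v > 32767 ? 32767 : (v < -32768 ? -32768 : v); }
static inline int wadd(int a, int b) { return sat_w(a + b); }

// [[Rcpp::export]]
List cpp_viterbi_filter(IntegerMatrix em, int Q, int V, IntegerVector seq,
                        IntegerVector tmm, IntegerVector tmi, IntegerVector tmd,
                        IntegerVector tim, IntegerVector tii,
                        IntegerVector tdm, IntegerVector tdd,
                        IntegerVector entry, int move_w, int ee_w, int adj_w,
                        int base) {
  const int NI = -32768;
  const int M = entry.size(), L = seq.size();
  std::vector<int> m(M, NI), ii_(M, NI), d(M, NI);
  std::vector<int> mp(M, NI), ip(M, NI), dp(M, NI);
  int xN = base, xB = wadd(xN, move_w), xJ = NI, xC = NI;
  bool overflow = false;

  for (int i = 0; i < L; ++i) {
    const int x = seq[i];
    int xE = NI;
    for (int k = 0; k < M; ++k) {
      int best = wadd(xB, entry[k]);
      if (k > 0) {
        int a = wadd(mp[k - 1], tmm[k - 1]);
        int b = wadd(ip[k - 1], tim[k - 1]);
        int c = wadd(dp[k - 1], tdm[k - 1]);
        if (a > best) best = a;
        if (b > best) best = b;
        if (c > best) best = c;
      }
      const int r = (k % Q) * V + k / Q; // stripe index map
      m[k] = wadd(wadd(best, em(r, x)), adj_w);
      if (m[k] > xE) xE = m[k];
      ii_[k] = (k < M - 1)
        ? wadd(std::max(wadd(mp[k], tmi[k]), wadd(ip[k], tii[k])), adj_w)
        : NI;
      d[k] = (k > 0)
        ? std::max(wadd(m[k - 1], tmd[k - 1]), wadd(d[k - 1], tdd[k - 1]))
        : NI;
    }
    std::swap(m, mp); std::swap(ii_, ip); std::swap(d, dp);
    if (xE >= 32767) { overflow = true; break; }
    xJ = std::max(xJ, wadd(xE, ee_w));         // JJ loop costs 0
    xC = std::max(xC, wadd(xE, ee_w));         // CC loop costs 0
    xB = std::max(wadd(xN, move_w), wadd(xJ, move_w)); // NN loop costs 0
  }
  const int raw = wadd(xC, move_w);
  return List::create(_["raw"] = raw, _["overflow"] = overflow);
}

// ---------------------------------------------------------------------------
// Forward / Backward, generic log-domain reference (exact log-sum-exp).
// Both return the total model log-odds before null-transition subtraction
// ("total") together with the special-state columns needed for endpoint
// posterior decoding.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_forward_generic(NumericMatrix s, IntegerVector seq,
                         NumericVector tmm, NumericVector tmi, NumericVector tmd,
                         NumericVector tim, NumericVector tii,
                         NumericVector tdm, NumericVector tdd,
                         NumericVector entry, double loop2, double move2,
                         double nulltr) {
  const int M = s.nrow(), L = seq.size();
  std::vector<double> m(M, NEGINF), ii_(M, NEGINF), d(M, NEGINF);
  std::vector<double> mp(M, NEGINF), ip(M, NEGINF), dp(M, NEGINF);
  NumericVector xNs(L + 1), xBs(L + 1), xEs(L + 1), xJs(L + 1), xCs(L + 1);
  double xN = 0.0, xB = move2, xJ = NEGINF, xC = NEGINF;
  const double lee = -1.0;
  xNs[0] = xN; xBs[0] = xB; xEs[0] = NEGINF; xJs[0] = NEGINF; xCs[0] = NEGINF;

  for (int i = 0; i < L; ++i) {
    const int x = seq[i];
    double xE = NEGINF;
    for (int k = 0; k < M; ++k) {
      double v = xB + entry[k];
      if (k > 0) {
        v = ls2(v, mp[k - 1] + tmm[k - 1]);
        v = ls2(v, ip[k - 1] + tim[k - 1]);
        v = ls2(v, dp[k - 1] + tdm[k - 1]);
      }
      m[k] = v + s(k, x);
      xE = ls2(xE, m[k]);
      ii_[k] = (k < M - 1)
        ? ls2(mp[k] + tmi[k], ip[k] + tii[k])
        : NEGINF;
      d[k] = (k > 0)
        ? ls2(m[k - 1] + tmd[k - 1], d[k - 1] + tdd[k - 1])
        : NEGINF;
    }
    std::swap(m, mp); std::swap(ii_, ip); std::swap(d, dp);
    xJ = ls2(xJ + loop2, xE + lee);
    xC = ls2(xC + loop2, xE + lee);
    xN += loop2;
    xB = ls2(xN + move2, xJ + move2);
    xNs[i + 1] = xN; xBs[i + 1] = xB; xEs[i + 1] = xE;
    xJs[i + 1] = xJ; xCs[i + 1] = xC;
  }
  const double total = xC + move2;
  return List::create(_["total"] = total, _["score"] = total - nulltr,
                      _["logN"] = xNs, _["logB"] = xBs, _["logE"] = xEs,
                      _["logJ"] = xJs, _["logC"] = xCs);
}

// [[Rcpp::export]]
List cpp_backward_generic(NumericMatrix s, IntegerVector seq,
                          NumericVector tmm, NumericVector tmi, NumericVector tmd,
                          NumericVector tim, NumericVector tii,
                          NumericVector tdm, NumericVector tdd,
                          NumericVector entry, double loop2, double move2,
                          double nulltr) {
  const int M = s.nrow(), L = seq.size();
  std::vector<double> bm(M, NEGINF), bi(M, NEGINF), bd(M, NEGINF);
  std::vector<double> bmn(M, NEGINF), bin(M, NEGINF), bdn(M, NEGINF);
  NumericVector xNs(L + 1), xBs(L + 1), xEs(L + 1), xJs(L + 1), xCs(L + 1);
  const double lee = -1.0;

  // boundary at i = L (all residues emitted)
  double xC = move2, xJ = NEGINF, xB = NEGINF, xN = NEGINF;
  double xE = lee + xC;
  for (int k = 0; k < M; ++k) { bmn[k] = xE; bin[k] = NEGINF; bdn[k] = NEGINF; }
  xNs[L] = xN; xBs[L] = xB; xEs[L] = xE; xJs[L] = xJ; xCs[L] = xC;

  for (int i = L - 1; i >= 0; --i) {
    const int x = seq[i]; // residue i+1 in 1-based terms
    double xC_new = loop2 + xC;
    double xB_new = NEGINF;
    for (int k = 0; k < M; ++k)
      xB_new = ls2(xB_new, entry[k] + s(k, x) + bmn[k]);
    double xJ_new = ls2(loop2 + xJ, move2 + xB_new);
    double xN_new = ls2(loop2 + xN, move2 + xB_new);
    double xE_new = ls2(lee + xC_new, lee + xJ_new);

    for (int k = M - 1; k >= 0; --k) {
      double vm = xE_new; // local exit, probability 1
      if (k < M - 1) {
        vm = ls2(vm, tmm[k] + s(k + 1, x) + bmn[k + 1]);
        vm = ls2(vm, tmi[k] + bin[k]);
        vm = ls2(vm, tmd[k] + bd[k + 1]);
        bi[k] = ls2(tii[k] + bin[k], tim[k] + s(k + 1, x) + bmn[k + 1]);
        bd[k] = ls2(tdm[k] + s(k + 1, x) + bmn[k + 1], tdd[k] + bd[k + 1]);
      } else {
        bi[k] = NEGINF;
        bd[k] = NEGINF;
      }
      bm[k] = vm;
    }
    std::swap(bm, bmn); std::swap(bi, bin); std::swap(bd, bdn);
    xC = xC_new; xJ = xJ_new; xB = xB_new; xN = xN_new; xE = xE_new;
    xNs[i] = xN; xBs[i] = xB; xEs[i] = xE; xJs[i] = xJ; xCs[i] = xC;
  }
  const double total = xN; // S -> N with probability 1
  return List::create(_["total"] = total, _["score"] = total - nulltr,
                      _["logN"] = xNs, _["logB"] = xBs, _["logE"] = xEs,
                      _["logJ"] = xJs, _["logC"] = xCs);
}

// ---------------------------------------------------------------------------
// Forward / Backward "parser" implementations: odds-ratio domain with sparse
// rescaling.  op is the M x 21 matrix of emission odds ratios e/f; transition
// arguments are probabilities.  A row is rescaled (dividing every value in
// the row by the E cell value, forward; by the B cell value, backward) when
// the trigger cell exceeds `thresh`.  Scale factors are accumulated in log2.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_forward_parser(NumericMatrix op, IntegerVector seq,
                        NumericVector tmm, NumericVector tmi, NumericVector tmd,
                        NumericVector tim, NumericVector tii,
                        NumericVector tdm, NumericVector tdd,
                        NumericVector entry, double loopp, double movep,
                        double nulltr, double thresh) {
  const int M = op.nrow(), L = seq.size();
  std::vector<double> m(M, 0.0), ii_(M, 0.0), d(M, 0.0);
  std::vector<double> mp(M, 0.0), ip(M, 0.0), dp(M, 0.0);
  NumericVector logB(L + 1), logE(L + 1), scalelog(L + 1);
  double xN = 1.0, xB = movep, xJ = 0.0, xC = 0.0;
  double cumlog = 0.0;
  int nrescale = 0;
  logB[0] = std::log2(xB); logE[0] = NEGINF; scalelog[0] = 0.0;

  for (int i = 0; i < L; ++i) {
    const int x = seq[i];
    double xE = 0.0;
    for (int k = 0; k < M; ++k) {
      double v = xB * entry[k];
      if (k > 0)
        v += mp[k - 1] * tmm[k - 1] + ip[k - 1] * tim[k - 1]
           + dp[k - 1] * tdm[k - 1];
      m[k] = v * op(k, x);
      xE += m[k];
      ii_[k] = (k < M - 1) ? (mp[k] * tmi[k] + ip[k] * tii[k]) : 0.0;
      d[k] = (k > 0) ? (m[k - 1] * tmd[k - 1] + d[k - 1] * tdd[k - 1]) : 0.0;
    }
    xJ = xJ * loopp + xE * 0.5;
    xC = xC * loopp + xE * 0.5;
    xN = xN * loopp;
    xB = xN * movep + xJ * movep;
    double slog = 0.0;
    if (xE > thresh) {
      const double sc = xE;
      for (int k = 0; k < M; ++k) { m[k] /= sc; ii_[k] /= sc; d[k] /= sc; }
      xJ /= sc; xC /= sc; xN /= sc; xB /= sc; xE = 1.0;
      slog = std::log2(sc);
      cumlog += slog;
      ++nrescale;
    }
    scalelog[i + 1] = slog;
    logE[i + 1] = (xE > 0 ? std::log2(xE) : NEGINF) + cumlog;
    logB[i + 1] = (xB > 0 ? std::log2(xB) : NEGINF) + cumlog;
    std::swap(m, mp); std::swap(ii_, ip); std::swap(d, dp);
  }
  const double total = std::log2(xC * movep) + cumlog;
  return List::create(_["total"] = total, _["score"] = total - nulltr,
                      _["logB"] = logB, _["logE"] = logE,
                      _["scalelog"] = scalelog, _["nrescale"] = nrescale);
}

// [[Rcpp::export]]
List cpp_backward_parser(NumericMatrix op, IntegerVector seq,
                         NumericVector tmm, NumericVector tmi, NumericVector tmd,
                         NumericVector tim, NumericVector tii,
                         NumericVector tdm, NumericVector tdd,
                         NumericVector entry, double loopp, double movep,
                         double nulltr, double thresh) {
  const int M = op.nrow(), L = seq.size();
  std::vector<double> bm(M, 0.0), bi(M, 0.0), bd(M, 0.0);
  std::vector<double> bmn(M, 0.0), bin(M, 0.0), bdn(M, 0.0);
  NumericVector logB(L + 1), logE(L + 1), scalelog(L + 1);
  double cumlog = 0.0;
  int nrescale = 0;

  double xC = movep, xJ = 0.0, xB = 0.0, xN = 0.0;
  double xE = 0.5 * xC;
  for (int k = 0; k < M; ++k) { bmn[k] = xE; bin[k] = 0.0; bdn[k] = 0.0; }
  logB[L] = NEGINF; logE[L] = std::log2(xE); scalelog[L] = 0.0;

  for (int i = L - 1; i >= 0; --i) {
    const int x = seq[i];
    double xC_new = loopp * xC;
    double xB_new = 0.0;
    for (int k = 0; k < M; ++k) xB_new += entry[k] * op(k, x) * bmn[k];
    double xJ_new = loopp * xJ + movep * xB_new;
    double xN_new = loopp * xN + movep * xB_new;
    double xE_new = 0.5 * xC_new + 0.5 * xJ_new;

    for (int k = M - 1; k >= 0; --k) {
      double vm = xE_new;
      if (k < M - 1) {
        vm += tmm[k] * op(k + 1, x) * bmn[k + 1]
            + tmi[k] * bin[k]
            + tmd[k] * bd[k + 1];
        bi[k] = tii[k] * bin[k] + tim[k] * op(k + 1, x) * bmn[k + 1];
        bd[k] = tdm[k] * op(k + 1, x) * bmn[k + 1] + tdd[k] * bd[k + 1];
      } else {
        bi[k] = 0.0;
        bd[k] = 0.0;
      }
      bm[k] = vm;
    }
    xC = xC_new; xJ = xJ_new; xB = xB_new; xN = xN_new; xE = xE_new;
    double slog = 0.0;
    if (xB > thresh) {
      const double sc = xB;
      for (int k = 0; k < M; ++k) { bm[k] /= sc; bi[k] /= sc; bd[k] /= sc; }
      xC /= sc; xJ /= sc; xN /= sc; xE /= sc; xB = 1.0;
      slog = std::log2(sc);
      cumlog += slog;
      ++nrescale;
    }
    scalelog[i] = slog;
    logB[i] = (xB > 0 ? std::log2(xB) : NEGINF) + cumlog;
    logE[i] = (xE > 0 ? std::log2(xE) : NEGINF) + cumlog;
    std::swap(bm, bmn); std::swap(bi, bin); std::swap(bd, bdn);
  }
  const double total = (xN > 0 ? std::log2(xN) : NEGINF) + cumlog;
  return List::create(_["total"] = total, _["score"] = total - nulltr,
                      _["logB"] = logB, _["logE"] = logE,
                      _["scalelog"] = scalelog, _["nrescale"] = nrescale);
}
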