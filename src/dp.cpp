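#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Base encoding shared with the R side: 0=A, 1=C, 2=G, 3=T/U, 4=N.
// pe holds the pair energies c(GC, AU, GU); a positive return value marks a
// non-pairing combination (N never pairs).
static inline double pair_energy(int x, int y, const double *pe) {
  if ((x == 2 && y == 1) || (x == 1 && y == 2)) return pe[0];
  if ((x == 0 && y == 3) || (x == 3 && y == 0)) return pe[1];
  if ((x == 2 && y == 3) || (x == 3 && y == 2)) return pe[2];
  return 1.0;
}

// Minimum-energy nested (pseudoknot-free) secondary structure with simple
// additive pair energies and a minimum hairpin loop. Ties are resolved toward
// fewer pairs, then toward the unpaired branch / smallest pairing partner, so
// the traceback is deterministic.
// [[Rcpp::export]]
List nussinov_fold_cpp(IntegerVector seq, int min_loop, NumericVector pair_e) {
  const int n = seq.size();
  if (n > 6000) stop("sequence too long for folding (limit 6000 nt)");
  if (n == 0)
    return List::create(_["energy"] = 0.0, _["structure"] = "",
                        _["n_pairs"] = 0);
  const double *pe = REAL(pair_e);
  std::vector<double> E((size_t)n * n, 0.0);
  std::vector<int> P((size_t)n * n, 0);
  std::vector<int> C((size_t)n * n, -1); // -1: j unpaired; k>=0: pair (k, j)
#define IDX(i, j) ((size_t)(i) * n + (j))
  // precompute, per j, the sorted pairable partners k < j - min_loop and
  // their energies, so the inner DP loop touches only true candidates
  std::vector<std::vector<int> > partner(n);
  std::vector<std::vector<double> > penergy(n);
  for (int j = 0; j < n; ++j) {
    for (int k = 0; k <= j - min_loop - 1; ++k) {
      const double e = pair_energy(seq[k], seq[j], pe);
      if (e < 0) {
        partner[j].push_back(k);
        penergy[j].push_back(e);
      }
    }
  }
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double be = E[IDX(i, j - 1)];
      int bp = P[IDX(i, j - 1)];
      int bc = -1;
      const std::vector<int> &ks = partner[j];
      const std::vector<double> &es = penergy[j];
      // first candidate k >= i
      size_t t = std::lower_bound(ks.begin(), ks.end(), i) - ks.begin();
      const double *Ei = &E[IDX(i, 0)];
      const int *Pi = &P[IDX(i, 0)];
      for (; t < ks.size(); ++t) {
        const int k = ks[t];
        const double left = (k > i) ? Ei[k - 1] : 0.0;
        const double mid = (j - k >= 2) ? E[IDX(k + 1, j - 1)] : 0.0;
        const double cand = left + mid + es[t];
        if (cand > be + 1e-9) continue;
        const int lp = (k > i) ? Pi[k - 1] : 0;
        const int mp = (j - k >= 2) ? P[IDX(k + 1, j - 1)] : 0;
        const int cp = lp + mp + 1;
        if (cand < be - 1e-9 || cp < bp) {
          be = cand; bp = cp; bc = k;
        }
      }
      E[IDX(i, j)] = be;
      P[IDX(i, j)] = bp;
      C[IDX(i, j)] = bc;
    }
  }
  std::string st(n, '.');
  int npairs = 0;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    const int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j <= i) continue;
    const int c = C[IDX(i, j)];
    if (c < 0) {
      stack.push_back(std::make_pair(i, j - 1));
    } else {
      st[c] = '(';
      st[j] = ')';
      ++npairs;
      if (c > i) stack.push_back(std::make_pair(i, c - 1));
      if (j - c >= 2) stack.push_back(std::make_pair(c + 1, j - 1));
    }
  }
  const double en = E[IDX(0, n - 1)];
#undef IDX
  return List::create(_["energy"] = en, _["structure"] = st,
                      _["n_pairs"] = npairs);
}

// Ungapped antiparallel hybridization scan between two sequences. For every
// alignment offset (anti-diagonal i + j = const in original coordinates) the
// energy is the sum of pair energies over maximal runs of >= min_run
// consecutive paired positions; shorter runs contribute nothing. Returns the
// most negative offset energy.
// [[Rcpp::export]]
List hybrid_scan_cpp(IntegerVector a, IntegerVector b, NumericVector pair_e,
                     int min_run) {
  const int n = a.size(), m = b.size();
  const double *pe = REAL(pair_e);
  double best = 0.0;
  int best_off = 0;
  for (int off = -(m - 1); off <= n - 1; ++off) {
    const int i0 = std::max(0, off), i1 = std::min(n - 1, off + m - 1);
    double total = 0.0, run = 0.0;
    int runlen = 0;
    for (int i = i0; i <= i1; ++i) {
      const int t = i - off;            // index into reversed b
      const double e = pair_energy(a[i], b[m - 1 - t], pe);
      if (e < 0) {
        run += e;
        ++runlen;
      } else {
        if (runlen >= min_run) total += run;
        run = 0.0;
        runlen = 0;
      }
    }
    if (runlen >= min_run) total += run;
    if (total < best) {
      best = total;
      best_off = off;
    }
  }
  return List::create(_["dg"] = best, _["offset"] = best_off);
}

// Banded affine-gap Smith-Waterman restricted to |(i - j) - diag| <= band.
// Used for gapped extension around a k-mer seed diagonal. Returns the best
// local alignment's score, match count, column count and 1-based spans.
// [[Rcpp::export]]
List banded_sw_cpp(IntegerVector q, IntegerVector s, int diag, int band,
                   double match, double mismatch, double gap_open,
                   double gap_ext) {
  const int n = q.size(), m = s.size(), W = 2 * band + 1;
  const double NEG = -1e30;
  // state 0 = H (match/mismatch), 1 = X (gap in subject, consumes query),
  // 2 = Y (gap in query, consumes subject)
  std::vector<double> H((size_t)(m + 1) * W, NEG), X((size_t)(m + 1) * W, NEG),
      Y((size_t)(m + 1) * W, NEG);
  std::vector<signed char> PH((size_t)(m + 1) * W, -1),
      PX((size_t)(m + 1) * W, -1), PY((size_t)(m + 1) * W, -1);
#define ID(j, r) ((size_t)(j) * W + (r))
  double best = 0.0;
  int bj = -1, br = -1;
  for (int j = 0; j <= m; ++j) {
    for (int r = 0; r < W; ++r) {
      const int i = j + diag - band + r;
      if (i < 0 || i > n) continue;
      if (i == 0 || j == 0) {
        H[ID(j, r)] = 0.0;
        PH[ID(j, r)] = 0;
        continue;
      }
      // H: diagonal move from (i-1, j-1) -> [j-1][r]
      const double sub =
          (q[i - 1] == s[j - 1] && q[i - 1] != 4) ? match : mismatch;
      double hh = 0.0;
      signed char ph = 0;
      const double pH = H[ID(j - 1, r)], pX = X[ID(j - 1, r)],
                   pY = Y[ID(j - 1, r)];
      if (pH > NEG / 2 && pH + sub > hh) { hh = pH + sub; ph = 1; }
      if (pX > NEG / 2 && pX + sub > hh) { hh = pX + sub; ph = 2; }
      if (pY > NEG / 2 && pY + sub > hh) { hh = pY + sub; ph = 3; }
      H[ID(j, r)] = hh;
      PH[ID(j, r)] = ph;
      // X: from (i-1, j) -> [j][r-1]
      if (r > 0) {
        const double oH = H[ID(j, r - 1)], oX = X[ID(j, r - 1)];
        double xx = NEG;
        signed char px = -1;
        if (oH > NEG / 2 && oH - gap_open - gap_ext > xx) {
          xx = oH - gap_open - gap_ext; px = 1;
        }
        if (oX > NEG / 2 && oX - gap_ext > xx) { xx = oX - gap_ext; px = 2; }
        X[ID(j, r)] = xx;
        PX[ID(j, r)] = px;
      }
      // Y: from (i, j-1) -> [j-1][r+1]
      if (r < W - 1) {
        const double oH = H[ID(j - 1, r + 1)], oY = Y[ID(j - 1, r + 1)];
        double yy = NEG;
        signed char py = -1;
        if (oH > NEG / 2 && oH - gap_open - gap_ext > yy) {
          yy = oH - gap_open - gap_ext; py = 1;
        }
        if (oY > NEG / 2 && oY - gap_ext > yy) { yy = oY - gap_ext; py = 3; }
        Y[ID(j, r)] = yy;
        PY[ID(j, r)] = py;
      }
      if (H[ID(j, r)] > best) {
        best = H[ID(j, r)];
        bj = j;
        br = r;
      }
    }
  }
  int matches = 0, columns = 0;
  int qend = 0, send = 0, qstart = 0, sstart = 0;
  if (bj >= 0) {
    int j = bj, r = br, state = 0;
    qend = bj + diag - band + br;
    send = bj;
    int lastqi = qend, lastsj = send; // last consumed 1-based positions
    while (j >= 0 && r >= 0 && r < W) {
      const int i = j + diag - band + r;
      if (state == 0) {
        const signed char p = PH[ID(j, r)];
        if (p == 0) break; // zero-valued local start: alignment begins after
        ++columns;
        if (q[i - 1] == s[j - 1] && q[i - 1] != 4) ++matches;
        lastqi = i;
        lastsj = j;
        state = p - 1;
        j -= 1; // diagonal move to (i-1, j-1); band offset unchanged
      } else if (state == 1) { // X consumes q[i] against a gap
        const signed char p = PX[ID(j, r)];
        ++columns;
        lastqi = i;
        state = p - 1;
        r -= 1; // to (i-1, j)
      } else { // Y consumes s[j] against a gap
        const signed char p = PY[ID(j, r)];
        ++columns;
        lastsj = j;
        state = p - 1;
        j -= 1;
        r += 1; // to (i, j-1)
      }
    }
    qstart = lastqi;
    sstart = lastsj;
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = columns, _["qstart"] = qstart,
                      _["qend"] = qend, _["sstart"] = sstart,
                      _["send"] = send);
#undef ID
}
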