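#include <Rcpp.h>
using namespace Rcpp;

// Seed-weighted Smith-Waterman over antiparallel complementarity.
//
// The miRNA is aligned reversed (3'->5') against the UTR (5'->3'), so a
// column of the alignment pairs miRNA base (original position n-i+1) with
// a UTR base. Pair scores: Watson-Crick wc, G:U wobble gu, otherwise mm;
// scores of columns whose miRNA position falls in [seed_lo, seed_hi]
// (1-based from the 5' end) are multiplied by seed_scale. Affine gaps:
// the first gapped position of a run costs gap_open, each further one
// gap_extend. Bases are encoded A=0, C=1, G=2, U=3.

static inline double pair_score(int m, int u, double wc, double gu,
                                double mm) {
  int s = m + u;
  if (s == 3) return wc;  // codes sum to 3 only for A/U and C/G
  if (s == 5) return gu;  // G(2)+U(3)
  return mm;
}

// [[Rcpp::export]]
List align_duplex_cpp(IntegerVector mir, IntegerVector utr, double wc,
                      double gu, double mm, double gap_open,
                      double gap_extend, int seed_lo, int seed_hi,
                      double seed_scale) {
  const int n = mir.size();
  const int m = utr.size();
  const double NEG = -1e18;

  // DP matrices over (i = reversed miRNA pos, j = UTR pos), 1-based with
  // a zero border. M ends in a paired column, X in a gap consuming the
  // miRNA, Y in a gap consuming the UTR.
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  // traceback: predecessor state 0=start, 1=M, 2=X, 3=Y
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 0);

#define IDX(i, j) ((i) * (m + 1) + (j))

  double best = 0.0;

  for (int i = 1; i <= n; ++i) {
    // original miRNA 5'-based position of row i
    int pos5 = n - i + 1;
    double w = (pos5 >= seed_lo && pos5 <= seed_hi) ? seed_scale : 1.0;
    for (int j = 1; j <= m; ++j) {
      double s = w * pair_score(mir[n - i], utr[j - 1], wc, gu, mm);

      // M: pair column
      double dM = M[IDX(i - 1, j - 1)];
      double dX = X[IDX(i - 1, j - 1)];
      double dY = Y[IDX(i - 1, j - 1)];
      double prev = 0.0;
      unsigned char tb = 0;
      if (dM > prev) { prev = dM; tb = 1; }
      if (dX > prev) { prev = dX; tb = 2; }
      if (dY > prev) { prev = dY; tb = 3; }
      M[IDX(i, j)] = s + prev;
      tbM[IDX(i, j)] = tb;
      if (M[IDX(i, j)] > best) best = M[IDX(i, j)];

      // X: gap in the UTR (consumes miRNA base i)
      double xo = M[IDX(i - 1, j)] + gap_open;
      double xs = Y[IDX(i - 1, j)] + gap_open;
      double xe = X[IDX(i - 1, j)] + gap_extend;
      if (xo >= xs && xo >= xe) { X[IDX(i, j)] = xo; tbX[IDX(i, j)] = 1; }
      else if (xe >= xs)        { X[IDX(i, j)] = xe; tbX[IDX(i, j)] = 2; }
      else                      { X[IDX(i, j)] = xs; tbX[IDX(i, j)] = 3; }

      // Y: gap in the miRNA (consumes UTR base j)
      double yo = M[IDX(i, j - 1)] + gap_open;
      double ys = X[IDX(i, j - 1)] + gap_open;
      double ye = Y[IDX(i, j - 1)] + gap_extend;
      if (yo >= ys && yo >= ye) { Y[IDX(i, j)] = yo; tbY[IDX(i, j)] = 1; }
      else if (ye >= ys)        { Y[IDX(i, j)] = ye; tbY[IDX(i, j)] = 3; }
      else                      { Y[IDX(i, j)] = ys; tbY[IDX(i, j)] = 2; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["empty"] = true);
  }

  // Collect all end cells achieving the maximum, traceback each, and pick
  // the candidate with the smallest UTR start, then the smallest UTR end
  // (shortest), then the smallest miRNA row start.
  int b_start_j = m + 1, b_end_j = -1, b_start_i = n + 1, b_end_i = -1;
  std::vector<int> b_ops;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (M[IDX(i, j)] != best) continue;
      // traceback from (i, j) in state M
      std::vector<int> ops;  // 0 = pair, 1 = gap-in-UTR, 2 = gap-in-miRNA
      int ci = i, cj = j;
      int state = 1;
      while (state != 0) {
        if (state == 1) {
          ops.push_back(0);
          state = tbM[IDX(ci, cj)];
          --ci; --cj;
        } else if (state == 2) {
          ops.push_back(1);
          state = tbX[IDX(ci, cj)];
          --ci;
        } else {
          ops.push_back(2);
          state = tbY[IDX(ci, cj)];
          --cj;
        }
      }
      int start_i = ci + 1, start_j = cj + 1;
      bool better = false;
      if (start_j < b_start_j) better = true;
      else if (start_j == b_start_j) {
        if (j < b_end_j) better = true;
        else if (j == b_end_j && start_i < b_start_i) better = true;
      }
      if (better) {
        b_start_j = start_j; b_end_j = j;
        b_start_i = start_i; b_end_i = i;
        std::reverse(ops.begin(), ops.end());
        b_ops = ops;
      }
    }
  }

#undef IDX

  return List::create(
    _["score"] = best, _["empty"] = false,
    // 0-based half-open intervals on the reversed-miRNA and UTR axes
    _["mir_rev_start"] = b_start_i - 1, _["mir_rev_end"] = b_end_i,
    _["utr_start"] = b_start_j - 1, _["utr_end"] = b_end_j,
    _["ops"] = IntegerVector(b_ops.begin(), b_ops.end()));
}

// Best local alignment score for every (miRNA, UTR) pair, score-only
// rolling-row DP (no traceback). Same recurrences as align_duplex_cpp.
// [[Rcpp::export]]
NumericMatrix scan_scores_cpp(List mirs, List utrs, double wc, double gu,
                              double mm, double gap_open,
                              double gap_extend, int seed_lo, int seed_hi,
                              double seed_scale) {
  const int nm = mirs.size();
  const int nu = utrs.size();
  const double NEG = -1e18;
  NumericMatrix out(nm, nu);

  for (int a = 0; a < nm; ++a) {
    IntegerVector mir = mirs[a];
    const int n = mir.size();
    // per-row seed weight and reversed base
    std::vector<double> wrow(n);
    std::vector<int> mrow(n);
    for (int i = 1; i <= n; ++i) {
      int pos5 = n - i + 1;
      wrow[i - 1] = (pos5 >= seed_lo && pos5 <= seed_hi) ? seed_scale : 1.0;
      mrow[i - 1] = mir[n - i];
    }
    for (int b = 0; b < nu; ++b) {
      IntegerVector utr = utrs[b];
      const int m = utr.size();
      std::vector<double> Mp(m + 1, NEG), Xp(m + 1, NEG), Yp(m + 1, NEG);
      std::vector<double> Mc(m + 1, NEG), Xc(m + 1, NEG), Yc(m + 1, NEG);
      double best = 0.0;
      for (int i = 1; i <= n; ++i) {
        const double w = wrow[i - 1];
        const int mb = mrow[i - 1];
        Mc[0] = NEG; Xc[0] = NEG; Yc[0] = NEG;
        for (int j = 1; j <= m; ++j) {
          double s = w * pair_score(mb, utr[j - 1], wc, gu, mm);
          double prev = 0.0;
          if (Mp[j - 1] > prev) prev = Mp[j - 1];
          if (Xp[j - 1] > prev) prev = Xp[j - 1];
          if (Yp[j - 1] > prev) prev = Yp[j - 1];
          double Mij = s + prev;
          Mc[j] = Mij;
          if (Mij > best) best = Mij;
          double xo = Mp[j] + gap_open;
          double xs = Yp[j] + gap_open;
          double xe = Xp[j] + gap_extend;
          Xc[j] = xo >= xs ? (xo >= xe ? xo : xe) : (xs >= xe ? xs : xe);
          double yo = Mc[j - 1] + gap_open;
          double ys = Xc[j - 1] + gap_open;
          double ye = Yc[j - 1] + gap_extend;
          Yc[j] = yo >= ys ? (yo >= ye ? yo : ye) : (ys >= ye ? ys : ye);
        }
        std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
      }
      out(a, b) = best;
    }
  }
  return out;
}
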