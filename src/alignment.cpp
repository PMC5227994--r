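#include <Rcpp.h>
using namespace Rcpp;

// Bases are coded 0=A, 1=C, 2=G, 3=T, 4=N throughout. N emits/matches nothing.

//' Local alignment of a coded read against a position-specific score matrix.
//'
//' Smith-Waterman with affine gaps over a profile of match columns; the read
//' is local, the profile is local. N positions emit score 0 in any column.
//' Returns the best score and the half-open read interval of the best path.
//' @noRd
// [[Rcpp::export(name = ".pssm_local_score")]]
double pssm_local_score(IntegerVector read, NumericMatrix pssm,
                        double gap_open, double gap_extend) {
  const int m = read.size();
  const int L = pssm.nrow();
  const double NEG = -1e30;
  // emissions transposed to base-major contiguous layout: emit[4*j + b]
  std::vector<double> emit((size_t)L * 4);
  for (int j = 0; j < L; ++j)
    for (int b = 0; b < 4; ++b) emit[(size_t)4 * j + b] = pssm(j, b);

  std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  const int *rd = INTEGER(read);
  double best = 0.0;
  for (int j = 1; j <= L; ++j) {
    const double *ej = &emit[(size_t)4 * (j - 1)];
    Mc[0] = 0.0; Xc[0] = NEG; Yc[0] = NEG;
    for (int i = 1; i <= m; ++i) {
      const int b = rd[i - 1];
      const double e = (b < 4) ? ej[b] : 0.0;
      double d = Mp[i - 1];
      if (Xp[i - 1] > d) d = Xp[i - 1];
      if (Yp[i - 1] > d) d = Yp[i - 1];
      if (d < 0.0) d = 0.0;
      const double mij = d + e;
      Mc[i] = mij;
      const double xo = Mc[i - 1] + gap_open, xe = Xc[i - 1] + gap_extend;
      Xc[i] = xo >= xe ? xo : xe;
      const double yo = Mp[i] + gap_open, ye = Yp[i] + gap_extend;
      Yc[i] = yo >= ye ? yo : ye;
      if (mij > best) best = mij;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return best;
}

// [[Rcpp::export(name = ".pssm_local_align")]]
List pssm_local_align(IntegerVector read, NumericMatrix pssm,
                      double gap_open, double gap_extend) {
  const int m = read.size();        // read positions (rows)
  const int L = pssm.nrow();        // profile columns
  const double NEG = -1e30;

  // DP over columns j = 1..L; rows i = 1..m. M = match state ending at (i,j);
  // X = gap in profile (read consumed); Y = gap in read (profile consumed).
  // Track the read start of the best local path through each cell.
  std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<int> sMp(m + 1), sXp(m + 1, 0), sYp(m + 1, 0);
  std::vector<int> sMc(m + 1), sXc(m + 1), sYc(m + 1);
  for (int i = 0; i <= m; ++i) sMp[i] = i; // empty path starts where it stands

  double best = 0.0;
  int best_end = 0, best_start = 0;

  for (int j = 1; j <= L; ++j) {
    Mc[0] = 0.0; Xc[0] = NEG; Yc[0] = NEG;
    sMc[0] = 0; sXc[0] = 0; sYc[0] = 0;
    for (int i = 1; i <= m; ++i) {
      const int b = read[i - 1];
      const double emit = (b >= 0 && b < 4) ? pssm(j - 1, b) : 0.0;

      // M: diagonal from best of (M, X, Y) at (i-1, j-1), or restart (score 0)
      double dM = Mp[i - 1], dX = Xp[i - 1], dY = Yp[i - 1];
      double dbest = dM; int dsrc = sMp[i - 1];
      if (dX > dbest) { dbest = dX; dsrc = sXp[i - 1]; }
      if (dY > dbest) { dbest = dY; dsrc = sYp[i - 1]; }
      if (dbest < 0.0) { dbest = 0.0; dsrc = i - 1; } // local restart
      Mc[i] = dbest + emit; sMc[i] = dsrc;

      // X: consume read base i against a gap in the profile (same column j)
      double xo = Mc[i - 1] + gap_open, xe = Xc[i - 1] + gap_extend;
      if (xo >= xe) { Xc[i] = xo; sXc[i] = sMc[i - 1]; }
      else          { Xc[i] = xe; sXc[i] = sXc[i - 1]; }

      // Y: consume profile column j against a gap in the read (same row i)
      double yo = Mp[i] + gap_open, ye = Yp[i] + gap_extend;
      if (yo >= ye) { Yc[i] = yo; sYc[i] = sMp[i]; }
      else          { Yc[i] = ye; sYc[i] = sYp[i]; }

      if (Mc[i] > best) { best = Mc[i]; best_end = i; best_start = sMc[i]; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    std::swap(sMp, sMc); std::swap(sXp, sXc); std::swap(sYp, sYc);
  }

  return List::create(_["score"] = best,
                      _["read_start"] = best_start,   // 0-based
                      _["read_end"] = best_end);      // half-open
}

//' Semi-global alignment: read end-to-end, reference infix (free overhangs).
//'
//' Unit costs (match +1, mismatch -1, indel -1). The reference is restricted
//' to the half-open window [wstart, wend) chosen by the caller (banding).
//' Identity = matches / alignment columns spanning the read; N never matches.
//' @noRd
// [[Rcpp::export(name = ".semiglobal_identity")]]
List semiglobal_identity(IntegerVector read, IntegerVector ref,
                         int wstart, int wend) {
  const int m = read.size();
  if (wstart < 0) wstart = 0;
  if (wend > ref.size()) wend = ref.size();
  const int n = wend - wstart;
  if (n <= 0 || m == 0)
    return List::create(_["identity"] = 0.0, _["matches"] = 0,
                        _["columns"] = m, _["score"] = R_NegInf);
  const int NEG = -1000000000;

  // S[i][j]: best score aligning read[0..i) to a suffix of ref-window[.., j).
  // Row 0 free (reference prefix unpenalized). Traceback kept for identity.
  std::vector<int> prev(n + 1, 0), cur(n + 1);
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0); // 1 diag 2 up 3 left
  for (int i = 1; i <= m; ++i) {
    cur[0] = prev[0] - 1;
    tb[(size_t)i * (n + 1)] = 2;
    const int rb = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int fb = ref[wstart + j - 1];
      const bool is_match = (rb == fb) && rb < 4;
      int d = prev[j - 1] + (is_match ? 1 : -1);
      int u = prev[j] - 1;       // gap in reference (read consumed)
      int l = cur[j - 1] - 1;    // gap in read (reference consumed)
      int s = d; unsigned char t = 1;
      if (u > s) { s = u; t = 2; }
      if (l > s) { s = l; t = 3; }
      if (s < NEG) s = NEG;
      cur[j] = s; tb[(size_t)i * (n + 1) + j] = t;
    }
    std::swap(prev, cur);
  }

  // Best end anywhere on the last row (free reference suffix).
  int best = prev[0], jend = 0;
  for (int j = 1; j <= n; ++j) if (prev[j] > best) { best = prev[j]; jend = j; }

  // Traceback from (m, jend) to row 0; count matches and columns.
  int i = m, j = jend, matches = 0, columns = 0;
  while (i > 0) {
    unsigned char t = tb[(size_t)i * (n + 1) + j];
    if (t == 1) {
      const int rb = read[i - 1], fb = ref[wstart + j - 1];
      if (rb == fb && rb < 4) ++matches;
      --i; --j; ++columns;
    } else if (t == 2) {
      --i; ++columns;
    } else {
      --j; ++columns;
    }
  }

  double identity = columns > 0 ? (double)matches / (double)columns : 0.0;
  return List::create(_["identity"] = identity, _["matches"] = matches,
                      _["columns"] = columns, _["score"] = best);
}
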