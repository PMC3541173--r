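#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// a, b: integer-encoded residues (1..20, 0 = ambiguity; ambiguity scores 0
// against anything). submat: 20x20 substitution scores. A gap run of length
// k costs gap_open + k * gap_extend (penalties passed as positive numbers).
// The reported alignment ends at the first best-scoring cell in row-major
// order; traceback prefers diagonal over vertical over horizontal, which
// minimises gap count among equal-scoring paths.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double gi = gap_open + gap_extend;

  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbIx(n + 1, m + 1), tbIy(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = 0; Ix(i, j) = NEG; Iy(i, j) = NEG; }

  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == 0 || b[j - 1] == 0)
                     ? 0.0
                     : submat(a[i - 1] - 1, b[j - 1] - 1);
      // M: align a_i with b_j; may start fresh (0)
      double dM = M(i - 1, j - 1), dIx = Ix(i - 1, j - 1), dIy = Iy(i - 1, j - 1);
      double pm = 0; int tb = 0;           // 0 = start
      if (dM > pm) { pm = dM; tb = 1; }    // 1 = from M
      if (dIx > pm) { pm = dIx; tb = 2; }  // 2 = from Ix
      if (dIy > pm) { pm = dIy; tb = 3; }  // 3 = from Iy
      M(i, j) = s + pm; tbM(i, j) = tb;

      // Ix: a_i aligned to gap (vertical)
      double vM = M(i - 1, j) - gi, vI = Ix(i - 1, j) - gap_extend;
      if (vM >= vI) { Ix(i, j) = vM; tbIx(i, j) = 1; }
      else          { Ix(i, j) = vI; tbIx(i, j) = 2; }

      // Iy: b_j aligned to gap (horizontal)
      double hM = M(i, j - 1) - gi, hI = Iy(i, j - 1) - gap_extend;
      if (hM >= hI) { Iy(i, j) = hM; tbIy(i, j) = 1; }
      else          { Iy(i, j) = hI; tbIy(i, j) = 3; }

      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  std::vector<int> pa, pb; // residue index or 0 for gap, reversed
  if (best > 0) {
    int i = bi, j = bj, state = 1; // 1=M, 2=Ix, 3=Iy
    while (i > 0 || j > 0) {
      if (state == 1) {
        int tb = tbM(i, j);
        pa.push_back(i); pb.push_back(j);
        --i; --j;
        if (tb == 0) break;
        state = tb;
      } else if (state == 2) {
        int tb = tbIx(i, j);
        pa.push_back(i); pb.push_back(0);
        --i; state = tb;
      } else {
        int tb = tbIy(i, j);
        pa.push_back(0); pb.push_back(j);
        --j; state = tb;
      }
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = best > 0 ? best : 0.0,
                      _["path_a"] = wrap(pa), _["path_b"] = wrap(pb));
}

// Global (Needleman-Wunsch-Gotoh) affine alignment on a precomputed
// column-vs-column score matrix S (n x m). End gaps are penalised. Returns
// the aligned column index paths (0 = gap). Used for profile-profile merges
// in progressive multiple alignment.
// [[Rcpp::export]]
List nw_affine_path_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const double gi = gap_open + gap_extend;

  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbIx(n + 1, m + 1), tbIy(n + 1, m + 1);
  M(0, 0) = 0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = -gi - gap_extend * (i - 1); tbIx(i, 0) = 2;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = -gi - gap_extend * (j - 1); tbIy(0, j) = 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dM = M(i - 1, j - 1), dIx = Ix(i - 1, j - 1), dIy = Iy(i - 1, j - 1);
      double pm = dM; int tb = 1;
      if (dIx > pm) { pm = dIx; tb = 2; }
      if (dIy > pm) { pm = dIy; tb = 3; }
      M(i, j) = S(i - 1, j - 1) + pm; tbM(i, j) = tb;

      double vM = M(i - 1, j) - gi, vI = Ix(i - 1, j) - gap_extend;
      if (vM >= vI) { Ix(i, j) = vM; tbIx(i, j) = 1; }
      else          { Ix(i, j) = vI; tbIx(i, j) = 2; }

      double hM = M(i, j - 1) - gi, hI = Iy(i, j - 1) - gap_extend;
      if (hM >= hI) { Iy(i, j) = hM; tbIy(i, j) = 1; }
      else          { Iy(i, j) = hI; tbIy(i, j) = 3; }
    }
  }
  int state = 1; double sc = M(n, m);
  if (Ix(n, m) > sc) { sc = Ix(n, m); state = 2; }
  if (Iy(n, m) > sc) { sc = Iy(n, m); state = 3; }

  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 1) {
      pa.push_back(i); pb.push_back(j);
      state = tbM(i, j); --i; --j;
    } else if (state == 2) {
      pa.push_back(i); pb.push_back(0);
      state = tbIx(i, j); --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = tbIy(i, j); --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = sc, _["path_a"] = wrap(pa),
                      _["path_b"] = wrap(pb));
}
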