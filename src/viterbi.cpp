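#include <Rcpp.h>
using namespace Rcpp;

// Local Viterbi scoring of a sequence against a profile HMM, in bits.
//
// seq: integer-encoded residues (1..20, 0 = ambiguity; ambiguity emits at
//   background, log-odds contribution 0).
// lod: M x 20 match-emission log-odds (log2 e/bg). Insert emissions equal
//   the background, so their log-odds term is 0.
// trans: M x 7 log2 transition probabilities, columns
//   MM, MI, MD, IM, II, DM, DD (row j = state j; -Inf where undefined).
// entry: length-M log2 entry probabilities (begin -> M_j).
// exit_: length-M log2 exit probabilities (M_j -> end).
//
// The path must emit at least one residue from a match state; flanking
// residues outside the aligned core are free (background). Paths cannot end
// in insert or delete states.
// [[Rcpp::export]]
double viterbi_score_cpp(IntegerVector seq, NumericMatrix lod,
                         NumericMatrix trans, NumericVector entry,
                         NumericVector exit_) {
  const int L = seq.size(), M = lod.nrow();
  const double NEG = -1e30;
  std::vector<double> VM(M + 1, NEG), VI(M + 1, NEG), VD(M + 1, NEG);
  std::vector<double> nVM(M + 1, NEG), nVI(M + 1, NEG), nVD(M + 1, NEG);

  double best = NEG;
  for (int i = 1; i <= L; ++i) {
    const int r = seq[i - 1];
    for (int j = 1; j <= M; ++j) {
      const double em = (r == 0) ? 0.0 : lod(j - 1, r - 1);
      double p = entry[j - 1];
      if (j > 1) {
        const double fM = VM[j - 1] + trans(j - 2, 0); // MM from j-1
        const double fI = VI[j - 1] + trans(j - 2, 3); // IM from I_{j-1}
        const double fD = VD[j - 1] + trans(j - 2, 5); // DM from D_{j-1}
        if (fM > p) p = fM;
        if (fI > p) p = fI;
        if (fD > p) p = fD;
      }
      nVM[j] = em + p;

      // insert I_j (defined for j < M): emission at background (0 bits)
      if (j < M) {
        const double iM = VM[j] + trans(j - 1, 1); // MI
        const double iI = VI[j] + trans(j - 1, 4); // II
        nVI[j] = (iM > iI) ? iM : iI;
      } else {
        nVI[j] = NEG;
      }
    }
    // deletes advance within the current row
    for (int j = 2; j <= M; ++j) {
      const double dM = nVM[j - 1] + trans(j - 2, 2); // MD
      const double dD = nVD[j - 1] + trans(j - 2, 6); // DD
      nVD[j] = (dM > dD) ? dM : dD;
    }
    nVD[1] = NEG;

    for (int j = 1; j <= M; ++j) {
      const double e = nVM[j] + exit_[j - 1];
      if (e > best) best = e;
    }
    std::swap(VM, nVM); std::swap(VI, nVI); std::swap(VD, nVD);
    std::fill(nVM.begin(), nVM.end(), NEG);
    std::fill(nVI.begin(), nVI.end(), NEG);
    std::fill(nVD.begin(), nVD.end(), NEG);
  }
  return best;
}
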