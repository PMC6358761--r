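#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman-style) alignment of an integer-encoded residue
// sequence against a position-specific score matrix with affine gaps.
//
// pssm: L x A matrix of per-position log-odds scores (bits).
// seq:  1-based residue indices into the pssm columns.
// States: M (model position emits residue), I (residue inserted relative to
// the model, consumes sequence only), D (model position skipped, consumes
// model only). Alignments start and end in M; scores floor at 0.
//
// Ties are broken toward the earliest sequence end, then earliest model end,
// and traceback prefers M over D over I, which yields the alignment with the
// smallest seq_start/model_start among co-optimal ones in practice; the
// rule is deterministic in all cases.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".profile_sw")]]
List profile_sw(NumericMatrix pssm, IntegerVector seq,
                double gap_open, double gap_extend,
                bool traceback = true) {
  const int L = pssm.nrow();      // model length
  const int n = seq.size();       // sequence length

  // DP matrices, (n+1) x (L+1), flattened
  std::vector<double> M((n + 1) * (L + 1), NEG_INF);
  std::vector<double> I((n + 1) * (L + 1), NEG_INF);
  std::vector<double> D((n + 1) * (L + 1), NEG_INF);
  // traceback codes: 0 none/start, 1 from M, 2 from I, 3 from D
  std::vector<unsigned char> tbM, tbI, tbD;
  if (traceback) {
    tbM.assign((n + 1) * (L + 1), 0);
    tbI.assign((n + 1) * (L + 1), 0);
    tbD.assign((n + 1) * (L + 1), 0);
  }
  const int W = L + 1;

  double best = 0.0;
  int best_i = -1, best_j = -1;

  for (int i = 1; i <= n; ++i) {
    const int res = seq[i - 1] - 1;
    for (int j = 1; j <= L; ++j) {
      const int idx = i * W + j;
      // M: diagonal move
      double fromM = M[(i - 1) * W + (j - 1)];
      double fromI = I[(i - 1) * W + (j - 1)];
      double fromD = D[(i - 1) * W + (j - 1)];
      double prev = 0.0; unsigned char code = 0;
      if (fromM > prev) { prev = fromM; code = 1; }
      if (fromI > prev) { prev = fromI; code = 2; }
      if (fromD > prev) { prev = fromD; code = 3; }
      double m = prev + pssm(j - 1, res);
      M[idx] = m;
      if (traceback) tbM[idx] = code;

      // I: consume sequence (gap in model)
      double iM = M[(i - 1) * W + j] - gap_open;
      double iI = I[(i - 1) * W + j] - gap_extend;
      if (iM >= iI) { I[idx] = iM; if (traceback) tbI[idx] = 1; }
      else          { I[idx] = iI; if (traceback) tbI[idx] = 2; }

      // D: consume model (gap in sequence)
      double dM = M[i * W + (j - 1)] - gap_open;
      double dD = D[i * W + (j - 1)] - gap_extend;
      if (dM >= dD) { D[idx] = dM; if (traceback) tbD[idx] = 1; }
      else          { D[idx] = dD; if (traceback) tbD[idx] = 3; }

      if (m > best) { best = m; best_i = i; best_j = j; }
    }
  }

  if (best_i < 0 || best <= 0.0) {
    return List::create(_["score"] = 0.0, _["seq_start"] = NA_INTEGER,
                        _["seq_end"] = NA_INTEGER, _["model_start"] = NA_INTEGER,
                        _["model_end"] = NA_INTEGER,
                        _["model_alignment"] = IntegerVector(0));
  }
  if (!traceback) {
    return List::create(_["score"] = best, _["seq_start"] = NA_INTEGER,
                        _["seq_end"] = best_i, _["model_start"] = NA_INTEGER,
                        _["model_end"] = best_j,
                        _["model_alignment"] = IntegerVector(0));
  }

  // traceback from (best_i, best_j) in state M
  // model_alignment: residue index aligned to each model position in
  // [model_start, model_end]; 0 where the model position was deleted.
  int i = best_i, j = best_j, state = 1;
  std::vector<int> aln;   // built backwards over model positions
  while (true) {
    int idx = i * W + j;
    if (state == 1) {           // M emits seq[i] at model j
      aln.push_back(seq[i - 1]);
      unsigned char code = tbM[idx];
      --i; --j;
      if (code == 0) break;
      state = code;
    } else if (state == 2) {    // I consumes sequence only
      state = tbI[idx];
      --i;
    } else {                    // D: model position j deleted
      aln.push_back(0);
      state = tbD[idx];
      --j;
    }
  }
  std::reverse(aln.begin(), aln.end());
  int model_start = j + 1;      // after final decrement, j is before start
  int seq_start = i + 1;

  return List::create(_["score"] = best,
                      _["seq_start"] = seq_start,
                      _["seq_end"] = best_i,
                      _["model_start"] = model_start,
                      _["model_end"] = best_j,
                      _["model_alignment"] = IntegerVector(aln.begin(), aln.end()));
}

// Scores-only batch variant used for E-value calibration.
// [[Rcpp::export(name = ".profile_sw_scores")]]
NumericVector profile_sw_scores(NumericMatrix pssm, List seqs,
                                double gap_open, double gap_extend) {
  const int N = seqs.size();
  NumericVector out(N);
  for (int k = 0; k < N; ++k) {
    IntegerVector s = seqs[k];
    List r = profile_sw(pssm, s, gap_open, gap_extend, false);
    out[k] = as<double>(r["score"]);
  }
  return out;
}
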