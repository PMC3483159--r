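#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh three-state DP).
//
// A gap of length g costs gap_open + g * gap_extend, so a gap's first
// position costs gap_open + gap_extend and each further position gap_extend.
//
// States: H = best local score ending at (i, j); F = ending with a gap in J
// (consuming I, vertical); E = ending with a gap in I (consuming J,
// horizontal). Sequences arrive 0-based integer-encoded.

static const int NEG = -1000000000;

// Score-only DP with rolling arrays; O(n) memory. S is the substitution
// matrix flattened row-major with stride A (alphabet size).
static int sw_score_only(const int* si, int m, const int* sj, int n,
                         const int* S, int A, int go, int ge) {
  const int open_cost = go + ge;
  std::vector<int> Hrow(n + 1, 0), Fcol(n + 1, NEG / 2);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int* Srow = S + (size_t)si[i - 1] * A;
    int diag = Hrow[0];
    int Ecur = NEG / 2;
    for (int j = 1; j <= n; ++j) {
      int eo = Hrow[j - 1] - open_cost;
      Ecur = std::max(eo, Ecur - ge);
      int fo = Hrow[j] - open_cost;
      int f = std::max(fo, Fcol[j] - ge);
      Fcol[j] = f;
      int h = diag + Srow[sj[j - 1]];
      if (Ecur > h) h = Ecur;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = Hrow[j];
      Hrow[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

static std::vector<int> flatten_rowmajor(const IntegerMatrix& S) {
  const int A = S.nrow();
  std::vector<int> out((size_t)A * S.ncol());
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < S.ncol(); ++j) out[(size_t)i * S.ncol() + j] = S(i, j);
  return out;
}

// [[Rcpp::export(rng = false)]]
int sw_score_cpp(IntegerVector seq_i, IntegerVector seq_j,
                 IntegerMatrix score_matrix, int gap_open, int gap_extend) {
  std::vector<int> S = flatten_rowmajor(score_matrix);
  return sw_score_only(INTEGER(seq_i), seq_i.size(), INTEGER(seq_j),
                       seq_j.size(), S.data(), score_matrix.ncol(),
                       gap_open, gap_extend);
}

// Full DP with traceback. Tie-breaking (deterministic paths):
//  - in H: diagonal over gap-in-J (vertical) over gap-in-I (horizontal);
//  - in E/F: gap open over gap extend (shorter gaps);
//  - end cell: max H, ties to smallest i+j, then smallest i.
// [[Rcpp::export(rng = false)]]
List sw_align_cpp(IntegerVector seq_i, IntegerVector seq_j,
                  IntegerMatrix score_matrix, int gap_open, int gap_extend) {
  const int m = seq_i.size(), n = seq_j.size();
  const int open_cost = gap_open + gap_extend;
  const int* si = INTEGER(seq_i);
  const int* sj = INTEGER(seq_j);

  std::vector<int> H((size_t)(m + 1) * (n + 1), 0),
      E((size_t)(m + 1) * (n + 1), NEG), F((size_t)(m + 1) * (n + 1), NEG);
  // traceback codes: H: 0 none, 1 diag-continue, 2 diag-start, 3 from F, 4 from E
  //                  E/F: 1 open, 2 extend
  std::vector<unsigned char> tbH(H.size(), 0), tbE(H.size(), 0), tbF(H.size(), 0);
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const size_t ij = idx(i, j);
      int eo = H[idx(i, j - 1)] - open_cost;
      int eext = (E[idx(i, j - 1)] <= NEG / 2) ? NEG : E[idx(i, j - 1)] - gap_extend;
      if (eo >= eext) { E[ij] = eo; tbE[ij] = 1; } else { E[ij] = eext; tbE[ij] = 2; }
      int fo = H[idx(i - 1, j)] - open_cost;
      int fext = (F[idx(i - 1, j)] <= NEG / 2) ? NEG : F[idx(i - 1, j)] - gap_extend;
      if (fo >= fext) { F[ij] = fo; tbF[ij] = 1; } else { F[ij] = fext; tbF[ij] = 2; }
      const int hprev = H[idx(i - 1, j - 1)];
      const int dscore = hprev + score_matrix(si[i - 1], sj[j - 1]);
      int h = 0; unsigned char code = 0;
      if (dscore >= h) { h = dscore; code = (hprev > 0) ? 1 : 2; }
      if (F[ij] > h) { h = F[ij]; code = 3; }
      if (E[ij] > h) { h = E[ij]; code = 4; }
      if (h <= 0) { h = 0; code = 0; }
      H[ij] = h; tbH[ij] = code;
      if (h > best || (h == best && best > 0 &&
                       (i + j < bi + bj || (i + j == bi + bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["start_i"] = NA_INTEGER,
                        _["start_j"] = NA_INTEGER, _["end_i"] = NA_INTEGER,
                        _["end_j"] = NA_INTEGER,
                        _["path"] = IntegerVector(0),
                        _["step_scores"] = IntegerVector(0));
  }

  // Traceback from (bi, bj) in state H; steps collected in reverse.
  // step codes: 1 match/mismatch, 2 gap-in-J (consumes I), 3 gap-in-I (consumes J)
  std::vector<int> steps, incs;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = F, 2 = E
  for (;;) {
    if (state == 0) {
      unsigned char c = tbH[idx(i, j)];
      if (c == 0) break;
      if (c == 1 || c == 2) {
        steps.push_back(1);
        incs.push_back(score_matrix(si[i - 1], sj[j - 1]));
        --i; --j;
        if (c == 2) break;
      } else if (c == 3) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // F: gap in J, consumes I
      unsigned char c = tbF[idx(i, j)];
      steps.push_back(2);
      incs.push_back(c == 1 ? -open_cost : -gap_extend);
      --i;
      if (c == 1) state = 0;
    } else { // E: gap in I, consumes J
      unsigned char c = tbE[idx(i, j)];
      steps.push_back(3);
      incs.push_back(c == 1 ? -open_cost : -gap_extend);
      --j;
      if (c == 1) state = 0;
    }
  }
  const int start_i = i + 1, start_j = j + 1;
  std::reverse(steps.begin(), steps.end());
  std::reverse(incs.begin(), incs.end());
  return List::create(_["score"] = best, _["start_i"] = start_i,
                      _["start_j"] = start_j, _["end_i"] = bi,
                      _["end_j"] = bj,
                      _["path"] = IntegerVector(steps.begin(), steps.end()),
                      _["step_scores"] = IntegerVector(incs.begin(), incs.end()));
}

// Simulate iid sequence pairs from the two compositions and return each
// pair's optimal local score. Uses R's RNG so set.seed() governs results.
// [[Rcpp::export]]
IntegerVector simulate_maxima_cpp(int reps, int m, int n,
                                  NumericVector probs_i, NumericVector probs_j,
                                  IntegerMatrix score_matrix, int gap_open,
                                  int gap_extend) {
  const int A = probs_i.size();
  std::vector<double> cum_i(A), cum_j(A);
  double s = 0;
  for (int a = 0; a < A; ++a) { s += probs_i[a]; cum_i[a] = s; }
  cum_i[A - 1] = 1.0;
  s = 0;
  for (int a = 0; a < A; ++a) { s += probs_j[a]; cum_j[a] = s; }
  cum_j[A - 1] = 1.0;

  IntegerVector out(reps);
  std::vector<int> si(m), sj(n);
  std::vector<int> S = flatten_rowmajor(score_matrix);
  const int Acols = score_matrix.ncol();
  for (int r = 0; r < reps; ++r) {
    for (int t = 0; t < m; ++t) {
      double u = unif_rand();
      int a = 0;
      while (a < A - 1 && u > cum_i[a]) ++a;
      si[t] = a;
    }
    for (int t = 0; t < n; ++t) {
      double u = unif_rand();
      int a = 0;
      while (a < A - 1 && u > cum_j[a]) ++a;
      sj[t] = a;
    }
    out[r] = sw_score_only(si.data(), m, sj.data(), n, S.data(), Acols,
                           gap_open, gap_extend);
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
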