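#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman). A gap of length L costs
// gap_open + L * gap_extend (both arguments are negative, blastn-style).
//
// sw_best_end: score-only scan with O(m) memory, used to locate the best
// hit on long references. The outer loop runs over the reference so that
// score ties keep the smallest reference end coordinate (then the smallest
// query end), making the scan deterministic.

// [[Rcpp::export]]
List sw_best_end(std::string query, std::string ref, int match, int mismatch,
                 int gap_open, int gap_extend) {
  const int m = (int)query.size(), n = (int)ref.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const int NEG = INT_MIN / 4;
  // H[i], E[i] hold column j-1 values for rows >= i and column j for rows < i
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0, best_i = 0, best_j = 0;
  for (int j = 1; j <= n; ++j) {
    int diag = 0;        // H[i-1][j-1]
    int h_up = 0;        // H[i-1][j] (current column, previous row)
    int Fcol = NEG;      // F(i,j): gap consuming query bases, within column j
    const char rj = ref[j - 1];
    for (int i = 1; i <= m; ++i) {
      const int s = (query[i - 1] == rj) ? match : mismatch;
      const int hprev = H[i];  // H[i][j-1]
      const int e = std::max(hprev + gap_open + gap_extend, E[i] + gap_extend);
      Fcol = std::max(h_up + gap_open + gap_extend, Fcol + gap_extend);
      int h = diag + s;
      if (h < 0) h = 0;
      if (e > h) h = e;
      if (Fcol > h) h = Fcol;
      H[i] = h;
      E[i] = e;
      diag = hprev;
      h_up = h;
      if (h > best) { best = h; best_i = i; best_j = j; }
    }
  }
  return List::create(_["score"] = best, _["query_end"] = best_i,
                      _["ref_end"] = best_j);
}

// Full alignment with traceback. Intended for moderate problem sizes
// (the detector calls it on a reference window around the end coordinate
// found by sw_best_end). Returns coordinates (1-based inclusive), column
// counts and match/gap statistics of the optimal local alignment. Ties in
// cell values resolve diagonal > vertical (query gap) > horizontal,
// which yields the shortest alignment among equals.

// [[Rcpp::export]]
List sw_align_full(std::string query, std::string ref, int match, int mismatch,
                   int gap_open, int gap_extend) {
  const int m = (int)query.size(), n = (int)ref.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const int NEG = INT_MIN / 4;
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  auto at = [&](int i, int j) { return i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int j = 1; j <= n; ++j) {
    for (int i = 1; i <= m; ++i) {
      const int s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      int e = std::max(H[at(i - 1, j)] + gap_open + gap_extend,
                       E[at(i - 1, j)] + gap_extend);  // gap in ref (consumes query)
      int f = std::max(H[at(i, j - 1)] + gap_open + gap_extend,
                       F[at(i, j - 1)] + gap_extend);  // gap in query (consumes ref)
      int h = std::max(0, H[at(i - 1, j - 1)] + s);
      h = std::max(h, std::max(e, f));
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj)
  int i = bi, j = bj;
  int matches = 0, mismatches = 0, gap_cols = 0, gap_runs = 0, cols = 0;
  int state = 0;  // 0 = H, 1 = E (gap consuming query), 2 = F (gap consuming ref)
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == 0) break;
      const int s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      if (i > 0 && j > 0 && h == H[at(i - 1, j - 1)] + s) {
        if (query[i - 1] == ref[j - 1]) ++matches; else ++mismatches;
        ++cols; --i; --j;
      } else if (h == E[at(i, j)]) {
        state = 1;
      } else if (h == F[at(i, j)]) {
        state = 2;
      } else {
        break;  // h == 0 handled above; defensive
      }
    } else if (state == 1) {
      ++cols; ++gap_cols;
      if (E[at(i, j)] == H[at(i - 1, j)] + gap_open + gap_extend) {
        ++gap_runs; --i; state = 0;
      } else {
        --i;
      }
    } else {
      ++cols; ++gap_cols;
      if (F[at(i, j)] == H[at(i, j - 1)] + gap_open + gap_extend) {
        ++gap_runs; --j; state = 0;
      } else {
        --j;
      }
    }
  }
  return List::create(
      _["score"] = best, _["query_start"] = i + 1, _["query_end"] = bi,
      _["ref_start"] = j + 1, _["ref_end"] = bj, _["aligned_length"] = cols,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gap_count"] = gap_cols, _["gap_runs"] = gap_runs);
}
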