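#include <Rcpp.h>
using namespace Rcpp;

// Best approximate occurrence of `pattern` in each read by Hamming distance.
//
// Semantics (fixed by the filtering contract):
//   * 'N' in the pattern matches any base;
//   * 'N' in the read is a mismatch unless the pattern base is 'N';
//   * best hit = fewest mismatches, ties broken by smallest offset;
//   * offsets below `min_start` (0-based) are not considered;
//   * reads shorter than min_start + |pattern| yield (-2, -1) = "skipped".
//
// Returns an n x 2 integer matrix: column 0 = 0-based offset (-1 = no hit
// within budget, -2 = read too short), column 1 = mismatch count (-1 if none).
// [[Rcpp::export]]
IntegerMatrix hamming_scan(CharacterVector reads, std::string pattern,
                           int max_mismatch, int min_start = 0) {
  const int n = reads.size();
  const int m = pattern.size();
  IntegerMatrix out(n, 2);
  if (m == 0) stop("empty pattern");
  if (max_mismatch < 0) stop("max_mismatch must be >= 0");
  if (min_start < 0) stop("min_start must be >= 0");

  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    const int L = LENGTH(STRING_ELT(reads, i));
    int best_pos = -1, best_mm = -1;
    if (L < min_start + m) {
      out(i, 0) = -2; out(i, 1) = -1;
      continue;
    }
    const int cutoff0 = (best_mm < 0) ? max_mismatch : best_mm - 1;
    (void)cutoff0;
    for (int s = min_start; s + m <= L; ++s) {
      // strictly better than current best, and within budget
      const int cutoff = (best_mm < 0) ? max_mismatch : best_mm - 1;
      if (cutoff < 0) break;  // best_mm == 0: cannot improve
      int mm = 0;
      for (int j = 0; j < m; ++j) {
        const char p = pattern[j];
        if (p == 'N') continue;
        if (r[s + j] != p) {
          if (++mm > cutoff) break;
        }
      }
      if (mm <= cutoff) { best_pos = s; best_mm = mm; }
    }
    out(i, 0) = best_pos;
    out(i, 1) = best_mm;
  }
  colnames(out) = CharacterVector::create("pos", "mismatches");
  return out;
}
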