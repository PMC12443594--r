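#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Banded Smith-Waterman local alignment with linear gap penalty.
// Diagonal d = j(ref) - i(read); only cells with |d - d0| <= band are filled.
// band < 0 disables the band (full dynamic programming).
// Coordinates in the result are 0-based, end-exclusive.
// [[Rcpp::export]]
List sw_banded(std::string read, std::string ref, int d0, int band,
               int match = 2, int mismatch = -2, int gap = 3) {
  const int n = (int)read.size();
  const int m = (int)ref.size();
  // H[(i)*(m+1)+j], traceback: 0 stop, 1 diag, 2 up (gap in ref), 3 left
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> T((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i + d0 - band);
      jhi = std::min(m, i + d0 + band);
      if (jlo > jhi) continue;
    }
    for (int j = jlo; j <= jhi; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      int sub = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      int diag = H[idx - (m + 1) - 1] + sub;
      int up = H[idx - (m + 1)] - gap;
      int left = H[idx - 1] - gap;
      int h = 0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (up > h) { h = up; t = 2; }
      if (left > h) { h = left; t = 3; }
      H[idx] = h; T[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  int i = bi, j = bj, matches = 0, alen = 0;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    unsigned char t = T[idx];
    if (t == 0 || H[idx] == 0) break;
    if (t == 1) {
      if (read[i - 1] == ref[j - 1]) ++matches;
      --i; --j;
    } else if (t == 2) {
      --i;
    } else {
      --j;
    }
    ++alen;
  }
  return List::create(
    _["score"] = best, _["matches"] = matches, _["aln_len"] = alen,
    _["read_start"] = i, _["read_end"] = bi,
    _["ref_start"] = j, _["ref_end"] = bj);
}
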