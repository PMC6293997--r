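#include <Rcpp.h>
using namespace Rcpp;

// Best segment within a 0/1 match vector, scored like an ungapped aligner
// (match +1, mismatch -3) so extension stops at a divergence boundary
// instead of padding with chance matches up to the identity floor.
// A segment [l, r] (0-based, both ends matching) is valid when
// matches / (r - l + 1) >= min_ident and r - l + 1 >= min_len.
// Returns 1-based {start, end, matches}, or {0,0,0} when none qualifies.
static void best_segment_core(const int *m, int n, double min_ident,
                              int min_len, int *out) {
  const int mm_pen = 3;
  int best_score = 0, best_matches = 0, best_l = -1, best_r = -1;
  for (int l = 0; l < n; ++l) {
    if (!m[l]) continue;
    int matches = 0, score = 0;
    for (int r = l; r < n; ++r) {
      if (m[r]) {
        ++matches;
        ++score;
      } else {
        score -= mm_pen;
      }
      if (!m[r]) continue;
      int len = r - l + 1;
      if (len < min_len) continue;
      if ((double)matches < min_ident * (double)len) continue;
      if (score > best_score ||
          (score == best_score && matches > best_matches)) {
        best_score = score;
        best_matches = matches;
        best_l = l;
        best_r = r;
      }
    }
  }
  if (best_l < 0) {
    out[0] = out[1] = out[2] = 0;
  } else {
    out[0] = best_l + 1;
    out[1] = best_r + 1;
    out[2] = best_matches;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_best_segment(IntegerVector match, double min_ident,
                               int min_len) {
  IntegerVector out(3);
  best_segment_core(INTEGER(match), match.size(), min_ident, min_len,
                    INTEGER(out));
  return out;
}

// Batched candidate evaluation for the seed-and-extend mapper.
// For candidate i the read reads[i] is placed on refs[ref_idx[i]] so that
// read base p (1-based) sits at reference position diag[i] + p.  Returns a
// matrix with one row per candidate: read start, read end (1-based within
// the read), matched bases (0,0,0 when no qualifying segment).
// [[Rcpp::export]]
IntegerMatrix cpp_eval_candidates(CharacterVector reads, CharacterVector refs,
                                  IntegerVector ref_idx, IntegerVector diag,
                                  double min_ident, int min_len) {
  int nc = reads.size();
  IntegerMatrix out(nc, 3);
  std::vector<int> m;
  for (int i = 0; i < nc; ++i) {
    const char *rd = CHAR(STRING_ELT(reads, i));
    const char *rf = CHAR(STRING_ELT(refs, ref_idx[i] - 1));
    int rl = (int)std::strlen(rd);
    int fl = (int)std::strlen(rf);
    int d = diag[i];
    // read positions whose reference partner exists
    int p0 = std::max(1, 1 - d);        // 1-based read pos
    int p1 = std::min(rl, fl - d);
    int n = p1 - p0 + 1;
    if (n < min_len) continue;
    m.assign(n, 0);
    for (int p = p0; p <= p1; ++p)
      m[p - p0] = (rd[p - 1] == rf[d + p - 1]) ? 1 : 0;
    int seg[3];
    best_segment_core(m.data(), n, min_ident, min_len, seg);
    if (seg[0] > 0) {
      out(i, 0) = seg[0] + p0 - 1;
      out(i, 1) = seg[1] + p0 - 1;
      out(i, 2) = seg[2];
    }
  }
  return out;
}

// Longest suffix(a)/prefix(b) overlap of length >= min_ov with at most
// floor(L / mm_per) mismatches.  Returns {L, mismatches} or {0, 0}.
// [[Rcpp::export]]
IntegerVector cpp_best_overlap(std::string a, std::string b, int min_ov,
                               int mm_per) {
  int la = (int)a.size(), lb = (int)b.size();
  IntegerVector out(2);
  for (int L = std::min(la, lb); L >= min_ov; --L) {
    int allowed = (mm_per > 0) ? L / mm_per : 0;
    int mm = 0;
    const char *pa = a.c_str() + (la - L);
    const char *pb = b.c_str();
    for (int i = 0; i < L; ++i) {
      if (pa[i] != pb[i] && ++mm > allowed) break;
    }
    if (mm <= allowed) {
      out[0] = L;
      out[1] = mm;
      return out;
    }
  }
  return out;
}

// Hamming mismatches between equal-length strings.
// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  int n = (int)std::min(a.size(), b.size());
  int mm = 0;
  for (int i = 0; i < n; ++i)
    if (a[i] != b[i]) ++mm;
  mm += (int)(std::max(a.size(), b.size()) - (size_t)n);
  return mm;
}
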