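#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Bases encoded 0=A, 1=C, 2=G, 3=T, 4=N.
// An ORF is ATG..stop (inclusive), no internal in-frame stop, fully inside
// the sequence. Codons containing N are treated as non-stop, non-start.

static inline bool is_stop(int a, int b, int c) {
  // TAA, TAG, TGA
  return a == 3 && ((b == 0 && (c == 0 || c == 2)) || (b == 2 && c == 0));
}
static inline bool is_atg(int a, int b, int c) {
  return a == 0 && b == 3 && c == 2;
}

// Best qualifying ORF in the 3 forward frames of seq[0..n-1]: overlaps
// [lo, hi] (0-based inclusive), spans at least min_nt nucleotides, and among
// candidates (every ATG start in every stop-bounded segment) minimizes
// |length - target_nt|, tie-broken by longer then leftmost. Random flanks
// can hold a chance in-frame ATG upstream of the true start, so "longest"
// would systematically overshoot; closest-to-reference-length is the
// canonical deterministic choice. Returns true and fills orf_start/orf_end.
static bool best_orf(const std::vector<int>& seq, int n, int lo, int hi,
                     int min_nt, int target_nt, bool require_atg,
                     int& orf_start, int& orf_end) {
  int best_dev = -1, best_len = -1, bs = -1, be = -1;
  std::vector<int> starts;
  for (int f = 0; f < 3; ++f) {
    starts.clear();  // ATG codon starts since the last stop
    for (int p = f; p + 2 < n; p += 3) {
      int a = seq[p], b = seq[p + 1], c = seq[p + 2];
      if (is_stop(a, b, c)) {
        int e = p + 2;
        for (size_t i = 0; i < starts.size(); ++i) {
          int s = starts[i];
          int len = e - s + 1;
          if (len < min_nt || s > hi || e < lo) continue;
          int dev = len > target_nt ? len - target_nt : target_nt - len;
          if (best_dev < 0 || dev < best_dev ||
              (dev == best_dev && (len > best_len ||
                                   (len == best_len && s < bs)))) {
            best_dev = dev; best_len = len; bs = s; be = e;
          }
        }
        starts.clear();
      } else if (is_atg(a, b, c) || (!require_atg && starts.empty())) {
        starts.push_back(p);
      }
    }
  }
  if (best_len < 0) return false;
  orf_start = bs; orf_end = be;
  return true;
}

// Enumerate every single-base edit within the window and report those whose
// edited context contains an ORF of >= min_orf_nt overlapping the annotated
// CDS. Coordinates in/out are 1-based; insertion positions are junctions
// ("insert after position p", p in 0..n).
// [[Rcpp::export(name = ".scan_edits_cpp")]]
DataFrame scan_edits_cpp(IntegerVector seq, int cds_start, int cds_end,
                         int win_start, int win_end, int min_orf_nt,
                         int target_orf_nt, bool require_atg = true) {
  int n = seq.size();
  if (win_start < 1) win_start = 1;
  if (win_end > n) win_end = n;
  if (win_start > win_end) stop("empty edit window");

  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int> buf;
  buf.reserve(n + 1);

  std::vector<int> kind, pos, alt, o_start, o_end;

  int lo0 = cds_start - 1, hi0 = cds_end - 1;  // 0-based CDS interval
  int os, oe;

  // substitutions
  for (int p = win_start - 1; p <= win_end - 1; ++p) {
    for (int b = 0; b < 4; ++b) {
      if (b == s[p]) continue;
      buf = s;
      buf[p] = b;
      if (best_orf(buf, n, lo0, hi0, min_orf_nt, target_orf_nt, require_atg, os, oe)) {
        kind.push_back(1); pos.push_back(p + 1); alt.push_back(b);
        o_start.push_back(os + 1); o_end.push_back(oe + 1);
      }
    }
  }

  // insertions: junction j means "after position j" (j = win_start-1 .. win_end)
  for (int j = win_start - 1; j <= win_end; ++j) {
    int lo = lo0 + (j < lo0 + 1 ? 1 : 0);      // j < cds_start (1-based j >= ...)
    int hi = hi0 + (j < hi0 + 1 ? 1 : 0);
    for (int b = 0; b < 4; ++b) {
      buf.resize(0);
      buf.insert(buf.end(), s.begin(), s.begin() + j);
      buf.push_back(b);
      buf.insert(buf.end(), s.begin() + j, s.end());
      if (best_orf(buf, n + 1, lo, hi, min_orf_nt, target_orf_nt, require_atg, os, oe)) {
        kind.push_back(2); pos.push_back(j); alt.push_back(b);
        o_start.push_back(os + 1); o_end.push_back(oe + 1);
      }
    }
  }

  // deletions
  for (int p = win_start - 1; p <= win_end - 1; ++p) {
    int lo = lo0 - (p < lo0 ? 1 : 0);
    int hi = hi0 - (p <= hi0 ? 1 : 0);
    if (hi < lo) hi = lo;
    buf.resize(0);
    buf.insert(buf.end(), s.begin(), s.begin() + p);
    buf.insert(buf.end(), s.begin() + p + 1, s.end());
    if (best_orf(buf, n - 1, lo, hi, min_orf_nt, target_orf_nt, require_atg, os, oe)) {
      kind.push_back(3); pos.push_back(p + 1); alt.push_back(-1);
      o_start.push_back(os + 1); o_end.push_back(oe + 1);
    }
  }

  return DataFrame::create(_["kind"] = kind, _["pos"] = pos, _["alt"] = alt,
                           _["orf_start"] = o_start, _["orf_end"] = o_end);
}
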