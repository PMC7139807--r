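#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Candidate tandem loci by positional self-comparison: for each period d,
// score[i] = +match if seq[i] == seq[i+d] (both unambiguous) else -mismatch,
// and maximal-scoring segments >= min_score are reported.  Segments are
// emitted greedily: a running segment is closed when the score drops
// `min_score` below its running maximum (x-drop), then restarted.
// [[Rcpp::export]]
DataFrame cpp_tandem_scan(IntegerVector codes, int max_period,
                          int match, int mismatch, int min_score) {
  long n = codes.size();
  std::vector<uint8_t> x(n);
  for (long i = 0; i < n; ++i) x[i] = (uint8_t)codes[i];
  std::vector<int> o_start, o_end, o_period, o_score;

  for (int d = 1; d <= max_period && d < n; ++d) {
    long cur = 0, curstart = 0, peak = 0;
    long peakpos = -1;
    for (long i = 0; i + d < n; ++i) {
      int sc = (x[i] < 4 && x[i] == x[i + d]) ? match : -mismatch;
      if (cur <= 0) { cur = 0; curstart = i; peak = 0; peakpos = -1; }
      cur += sc;
      if (cur > peak) { peak = cur; peakpos = i; }
      bool closing = (peak - cur >= min_score) || (i + d == n - 1);
      if (closing && peak >= min_score && peakpos >= 0) {
        // segment covers positions curstart .. peakpos + d (array spans
        // both copies of the final compared pair)
        o_start.push_back((int)curstart + 1);
        o_end.push_back((int)(peakpos + d) + 1);
        o_period.push_back(d);
        o_score.push_back((int)peak);
        cur = 0; peak = 0; peakpos = -1; curstart = i + 1;
      } else if (closing) {
        cur = 0; peak = 0; peakpos = -1; curstart = i + 1;
      }
    }
  }
  return DataFrame::create(_["start"] = o_start, _["end"] = o_end,
                           _["period"] = o_period, _["score"] = o_score);
}

// Wraparound local alignment of a region against a cyclic pattern
// (Smith-Waterman with the pattern column wrapping d -> 1).  Returns the
// best segment's score, region bounds and the number of pattern positions
// consumed along the optimal path (copy number = consumed / d).
// [[Rcpp::export]]
List cpp_wraparound_align(IntegerVector region_codes, IntegerVector pat_codes,
                          int match, int mismatch, int indel) {
  int n = region_codes.size(), d = pat_codes.size();
  std::vector<uint8_t> r(n), p(d);
  for (int i = 0; i < n; ++i) r[i] = (uint8_t)region_codes[i];
  for (int j = 0; j < d; ++j) p[j] = (uint8_t)pat_codes[j];

  // H over region rows i=1..n, pattern columns j=1..d; start[i][j] = region
  // start of the path; pcount = pattern positions consumed.
  std::vector<int> Hp(d + 1, 0), Hc(d + 1, 0);
  std::vector<int> Sp(d + 1, 0), Sc(d + 1, 0);       // path start (0-based row)
  std::vector<int> Pp(d + 1, 0), Pc(d + 1, 0);       // pattern consumed
  int best = 0, besti = 0, beststart = 0, bestp = 0;

  for (int i = 1; i <= n; ++i) {
    // column 0 duplicates column d of the same row (wraparound); iterate
    // twice so intra-row wrap (horizontal from column d to 1) propagates.
    for (int pass = 0; pass < 2; ++pass) {
      Hc[0] = Hc[d]; Sc[0] = Sc[d]; Pc[0] = Pc[d];
      if (pass == 0) { Hc[0] = Hp[d]; Sc[0] = Sp[d]; Pc[0] = Pp[d]; }
      for (int j = 1; j <= d; ++j) {
        int sub = (r[i - 1] < 4 && r[i - 1] == p[j - 1]) ? match : -mismatch;
        int hd = (j == 1 ? Hp[d] : Hp[j - 1]) + sub;   // diag (wraps via col 0)
        int sd = (j == 1 ? Sp[d] : Sp[j - 1]);
        int pd = (j == 1 ? Pp[d] : Pp[j - 1]) + 1;
        int hu = Hp[j] - indel;                        // gap in pattern
        int su = Sp[j], pu = Pp[j];
        int hl = Hc[j - 1] - indel;                    // gap in region
        int sl = Sc[j - 1], pl = Pc[j - 1] + 1;
        int h = 0, st = i - 1, pc = 0;                 // fresh start
        if (hd > h) { h = hd; st = sd; pc = pd; }
        if (hu > h) { h = hu; st = su; pc = pu; }
        if (hl > h) { h = hl; st = sl; pc = pl; }
        if (pass == 1 && Hc[j] >= h) continue;         // keep better of passes
        Hc[j] = h; Sc[j] = st; Pc[j] = pc;
        if (h > best) { best = h; besti = i; beststart = st; bestp = pc; }
      }
    }
    std::swap(Hp, Hc); std::swap(Sp, Sc); std::swap(Pp, Pc);
  }
  return List::create(_["score"] = best,
                      _["start"] = beststart + 1,
                      _["end"] = besti,
                      _["pattern_consumed"] = bestp);
}
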