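#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <unordered_map>
#include <set>
#include <tuple>
#include <vector>

using namespace Rcpp;

// Nucleotide codes: A=0 C=1 G=2 T=3 N=4.  N never matches anything.

static const int NEG = INT_MIN / 4;

static inline int subst(uint8_t a, uint8_t b, int match, int mismatch) {
  return (a == b && a < 4) ? match : mismatch;
}

struct ExtRes {
  int dq = 0, ds = 0, score = 0;
  int matches = 0, mismatches = 0, gapopens = 0, gapcols = 0;
};

// Traceback codes packed per cell:
//   bits 0-1: H predecessor (0 = origin/dead, 1 = diagonal, 2 = E, 3 = F)
//   bit 2:    E at this cell extends an existing horizontal gap (else opens)
//   bit 3:    F at this cell extends an existing vertical gap (else opens)
struct TBRow {
  int lo = 0;
  std::vector<uint8_t> tb;
};

// Gapped x-drop extension of prefixes of Q and S where Q[i] = q[qoff+i*step],
// S[j] = s[soff+j*step].  A gap of length L costs go + L*ge.  Cells whose
// best state falls more than X below the running maximum are pruned; the
// band adapts per row.  Returns the best-scoring prefix pair plus column
// statistics recovered by traceback.
// When diag_min > INT_MIN/2 the alignment is confined to cells whose
// global diagonal  base_diag + dsign*(j - i)  stays >= diag_min (used to
// keep plus-strand self-alignments strictly off the self-identity
// diagonal).
static void xdrop_extend(const uint8_t* q, long qoff, int qn,
                         const uint8_t* s, long soff, int sn,
                         int step, int match, int mismatch, int go, int ge,
                         int X, int base_diag, int dsign, int diag_min,
                         ExtRes& out) {
  out = ExtRes();
  if (qn <= 0 || sn <= 0) return;

  std::vector<int> Hprev(sn + 1, NEG), Hcur(sn + 1, NEG);
  std::vector<int> Fprev(sn + 1, NEG), Fcur(sn + 1, NEG);
  std::vector<TBRow> rows;
  int best = 0, bi = 0, bj = 0;

  // row 0: pure horizontal gap run
  {
    TBRow r0; r0.lo = 0;
    Hprev[0] = 0; Fprev[0] = NEG; r0.tb.push_back(0);
    int E = NEG;
    int j;
    for (j = 1; j <= sn; ++j) {
      int e_open = Hprev[j - 1] == NEG ? NEG : Hprev[j - 1] - go - ge;
      int e_ext = (E == NEG) ? NEG : E - ge;
      E = std::max(e_open, e_ext);
      if (E == NEG || E < best - X) break;
      if (base_diag + dsign * j < diag_min) break;
      Hprev[j] = E; Fprev[j] = NEG;
      uint8_t code = 2;
      if (e_ext >= e_open) code |= 4;
      r0.tb.push_back(code);
    }
    for (; j <= sn && j <= 2; ++j) Hprev[j] = NEG;  // safety fill
    rows.push_back(std::move(r0));
  }
  int prev_lo = 0, prev_hi = (int)rows[0].tb.size() - 1;

  for (int i = 1; i <= qn; ++i) {
    TBRow row;
    int lo = prev_lo;
    row.lo = lo;
    int new_lo = -1, new_hi = -2;
    int E = NEG;
    uint8_t qc = q[qoff + (long)(i - 1) * step];
    bool started = false;
    for (int j = lo; j <= sn; ++j) {
      int Hup = (j >= prev_lo && j <= prev_hi) ? Hprev[j] : NEG;
      int Fup = (j >= prev_lo && j <= prev_hi) ? Fprev[j] : NEG;
      int f_open = (Hup == NEG) ? NEG : Hup - go - ge;
      int f_ext = (Fup == NEG) ? NEG : Fup - ge;
      int F = std::max(f_open, f_ext);
      int Hleft = (j > lo && started) ? Hcur[j - 1] : NEG;
      int e_open = (Hleft == NEG) ? NEG : Hleft - go - ge;
      int e_ext = (E == NEG) ? NEG : E - ge;
      E = std::max(e_open, e_ext);
      int diag = NEG;
      if (j >= 1 && j - 1 >= prev_lo && j - 1 <= prev_hi && Hprev[j - 1] != NEG)
        diag = Hprev[j - 1] + subst(qc, s[soff + (long)(j - 1) * step], match, mismatch);
      int H = diag; uint8_t src = 1;
      if (E != NEG && E > H) { H = E; src = 2; }
      if (F != NEG && F > H) { H = F; src = 3; }
      if (diag == NEG && src == 1) { H = NEG; src = 0; }

      if (base_diag + dsign * (j - i) < diag_min) { H = NEG; E = NEG; F = NEG; }
      int cellmax = std::max(H, std::max(E, F));
      if (cellmax == NEG || cellmax < best - X) {
        E = NEG;
        Hcur[j] = NEG; Fcur[j] = NEG;
        if (started) {
          if (j > new_hi + 2 && j > prev_hi + 1) break;  // far past live band
          row.tb.push_back(0);
        } else {
          row.lo = j + 1;
        }
        if (j > prev_hi + 1 && !started) break;
        continue;
      }
      started = true;
      if (new_lo < 0) new_lo = j;
      new_hi = j;
      uint8_t code = src;
      if (e_ext >= e_open) code |= 4;
      if (f_ext >= f_open) code |= 8;
      Hcur[j] = H; Fcur[j] = F;
      row.tb.push_back(code);
      if (H != NEG && H > best) { best = H; bi = i; bj = j; }
    }
    if (!started) break;
    rows.push_back(std::move(row));
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    prev_lo = new_lo; prev_hi = new_hi;
  }

  // traceback from (bi, bj)
  out.dq = bi; out.ds = bj; out.score = best;
  int i = bi, j = bj, state = 0;               // 0=H 1=E 2=F
  while (i > 0 || j > 0) {
    if ((size_t)i >= rows.size()) break;       // safety
    const TBRow& r = rows[i];
    int idx = j - r.lo;
    if (idx < 0 || (size_t)idx >= r.tb.size()) break;
    uint8_t code = r.tb[idx];
    if (state == 0) {
      int src = code & 3;
      if (src == 0) break;
      if (src == 1) {
        uint8_t a = q[qoff + (long)(i - 1) * step];
        uint8_t b = s[soff + (long)(j - 1) * step];
        if (a == b && a < 4) out.matches++; else out.mismatches++;
        --i; --j;
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {                   // E: gap column consuming subject
      out.gapcols++;
      bool ext = (code & 4) != 0;
      --j;
      if (!ext) { out.gapopens++; state = 0; }
    } else {                                   // F: gap column consuming query
      out.gapcols++;
      bool ext = (code & 8) != 0;
      --i;
      if (!ext) { out.gapopens++; state = 0; }
    }
  }
}

// Seed-and-extend local alignment of one strand.  Coordinates in the
// returned data frame are 1-based inclusive.  self_period > 0 suppresses
// seeds on diagonals that are multiples of that period (the trivial
// self-identity diagonal of a self-comparison, and its copy when the
// subject is a doubled circular sequence).
// [[Rcpp::export]]
DataFrame cpp_seed_extend(IntegerVector qcodes, IntegerVector scodes,
                          int match, int mismatch, int gap_open,
                          int gap_extend, int word, int xdrop,
                          int min_score, int self_period, bool upper_only) {
  long qn = qcodes.size(), sn = scodes.size();
  std::vector<uint8_t> q(qn), s(sn);
  for (long i = 0; i < qn; ++i) q[i] = (uint8_t)qcodes[i];
  for (long i = 0; i < sn; ++i) s[i] = (uint8_t)scodes[i];

  std::unordered_map<uint64_t, std::vector<int>> table;
  if (sn >= word) {
    uint64_t mask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
    uint64_t w = 0; int run = 0;
    for (long j = 0; j < sn; ++j) {
      if (s[j] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | s[j]) & mask;
      if (++run >= word) table[w].push_back((int)(j - word + 1));
    }
  }

  std::vector<int> last_qend(qn + sn + 2, -1);
  std::set<std::tuple<int,int,int,int>> seen;
  std::vector<int> o_qs, o_qe, o_ss, o_se, o_score, o_len, o_mm, o_go, o_gc, o_ma;

  if (qn >= word && sn >= word) {
    uint64_t mask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
    uint64_t w = 0; int run = 0;
    for (long i = 0; i < qn; ++i) {
      if (q[i] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | q[i]) & mask;
      if (++run < word) continue;
      int qpos = (int)(i - word + 1);
      auto it = table.find(w);
      if (it == table.end()) continue;
      for (int spos : it->second) {
        if (upper_only && spos <= qpos) continue;
        if (self_period > 0 && ((long)spos - qpos) % self_period == 0) continue;
        long diag = (long)qpos - spos + sn;
        if (qpos <= last_qend[diag]) continue;
        int bd = spos - qpos;
        int dmin = upper_only ? 1 : INT_MIN / 2;
        ExtRes back, fwd;
        xdrop_extend(q.data(), (long)qpos - 1, qpos,
                     s.data(), (long)spos - 1, spos,
                     -1, match, mismatch, gap_open, gap_extend, xdrop,
                     bd, -1, dmin, back);
        xdrop_extend(q.data(), (long)qpos + word, (int)(qn - qpos - word),
                     s.data(), (long)spos + word, (int)(sn - spos - word),
                     +1, match, mismatch, gap_open, gap_extend, xdrop,
                     bd, +1, dmin, fwd);
        int score = back.score + word * match + fwd.score;
        int qs = qpos - back.dq, qe = qpos + word - 1 + fwd.dq;
        int ss = spos - back.ds, se = spos + word - 1 + fwd.ds;
        last_qend[diag] = qe;
        if (score < min_score) continue;
        auto key = std::make_tuple(qs, qe, ss, se);
        if (!seen.insert(key).second) continue;
        int ma = back.matches + word + fwd.matches;
        int mm = back.mismatches + fwd.mismatches;
        int gc = back.gapcols + fwd.gapcols;
        int gop = back.gapopens + fwd.gapopens;
        o_qs.push_back(qs + 1); o_qe.push_back(qe + 1);
        o_ss.push_back(ss + 1); o_se.push_back(se + 1);
        o_score.push_back(score);
        o_len.push_back(ma + mm + gc);
        o_ma.push_back(ma); o_mm.push_back(mm);
        o_go.push_back(gop); o_gc.push_back(gc);
      }
    }
  }

  return DataFrame::create(
    _["qstart"] = o_qs, _["qend"] = o_qe,
    _["sstart"] = o_ss, _["send"] = o_se,
    _["score"] = o_score, _["length"] = o_len,
    _["matches"] = o_ma, _["mismatches"] = o_mm,
    _["gapopens"] = o_go, _["gapcols"] = o_gc);
}
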