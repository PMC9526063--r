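// Core alignment engines: wraparound dynamic programming against a cyclic
// monomer (tandem-array scoring), k-mer recurrence candidate scan, the
// greedy X-drop tandem-array detector, and a word-seeded affine-gap local
// aligner used by the family-clustering stage.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <climits>
#include <cstdint>
#include <set>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}
static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

// ---------------------------------------------------------------------------
// Wraparound global alignment of `seg` against unlimited tandem copies of
// `mon`.  Column index wraps modulo the monomer length; start and end phase
// are free.  Linear gap costs.  Two passes per row propagate the wrapped
// horizontal (monomer-deletion) dependency.
// ---------------------------------------------------------------------------

struct WrapStats {
  long score;
  double copies;
  double identity;   // percent
  std::string consensus;
  long matches;
  long columns;
};

static const int NEG_INF = INT_MIN / 4;

// score-only row recurrence shared by extension and full alignment
static inline void wrap_row(const std::vector<int>& prev, std::vector<int>& cur,
                            char segBase, const std::string& mon,
                            int ms, int mp, int ip,
                            std::vector<uint8_t>* tb) {
  const int p = (int)mon.size();
  for (int j = 0; j < p; ++j) cur[j] = NEG_INF;
  for (int pass = 0; pass < 2; ++pass) {
    for (int j = 0; j < p; ++j) {
      const int jm1 = (j == 0) ? p - 1 : j - 1;
      const int sub = (base_code(segBase) >= 0 && segBase == mon[j]) ? ms : -mp;
      int best = prev[jm1] + sub;      // diagonal
      uint8_t t = 1;
      const int up = prev[j] - ip;     // gap in monomer (insertion in segment)
      if (up > best) { best = up; t = 2; }
      const int left = cur[jm1] - ip;  // gap in segment (monomer char deleted)
      if (left > best) { best = left; t = 3; }
      if (best > cur[j]) {
        cur[j] = best;
        if (tb) (*tb)[j] = t;
      }
    }
  }
}

// Full alignment with traceback: statistics + per-column majority consensus.
static WrapStats wrap_align_full(const std::string& seg, const std::string& mon,
                                 int ms, int mp, int ip) {
  const long n = (long)seg.size();
  const int p = (int)mon.size();
  WrapStats out{0, 0.0, 100.0, mon, 0, 0};
  if (p == 0) stop("monomer must be non-empty");
  if (n == 0) return out;

  std::vector<int> prev(p, 0), cur(p, 0);
  // traceback matrix: rows 1..n, p columns
  std::vector<uint8_t> tb((size_t)n * p, 0);
  std::vector<uint8_t> moves(p, 1);
  for (long i = 1; i <= n; ++i) {
    wrap_row(prev, cur, seg[i - 1], mon, ms, mp, ip, &moves);
    std::copy(moves.begin(), moves.end(), tb.begin() + (size_t)(i - 1) * p);
    std::swap(prev, cur);
  }
  // best end column
  int jend = 0;
  for (int j = 1; j < p; ++j) if (prev[j] > prev[jend]) jend = j;
  out.score = prev[jend];

  // traceback
  std::vector<std::array<long, 4>> counts(p, {0, 0, 0, 0});
  long i = n;
  int j = jend;
  long matches = 0, columns = 0, consumed = 0;
  while (i > 0) {
    const uint8_t t = tb[(size_t)(i - 1) * p + j];
    const int jm1 = (j == 0) ? p - 1 : j - 1;
    if (t == 1) {            // diagonal
      ++columns; ++consumed;
      const int c = base_code(seg[i - 1]);
      if (c >= 0) counts[j][c]++;
      if (base_code(seg[i - 1]) >= 0 && seg[i - 1] == mon[j]) ++matches;
      --i; j = jm1;
    } else if (t == 2) {     // gap in monomer
      ++columns;
      --i;
    } else {                 // gap in segment
      ++columns; ++consumed;
      j = jm1;
    }
  }
  out.matches = matches;
  out.columns = columns;
  out.identity = columns > 0 ? 100.0 * (double)matches / (double)columns : 100.0;
  out.copies = (double)consumed / (double)p;
  std::string cons(mon);
  for (int jj = 0; jj < p; ++jj) {
    long tot = counts[jj][0] + counts[jj][1] + counts[jj][2] + counts[jj][3];
    if (tot == 0) continue;  // uncovered column keeps the monomer base
    int arg = 0;
    for (int b = 1; b < 4; ++b) if (counts[jj][b] > counts[jj][arg]) arg = b;
    cons[jj] = CODE2BASE[arg];
  }
  out.consensus = cons;
  return out;
}

// Score-only greedy extension: align growing prefixes of `s` (length cap n)
// against cyclic `mon`, return the prefix length maximising the score, with
// X-drop termination.
static void wrap_extend(const char* s, long n, const std::string& mon,
                        int ms, int mp, int ip, int xdrop,
                        long& bestLen, long& bestScore) {
  const int p = (int)mon.size();
  std::vector<int> prev(p, 0), cur(p, 0);
  bestLen = 0; bestScore = 0;
  for (long i = 1; i <= n; ++i) {
    wrap_row(prev, cur, s[i - 1], mon, ms, mp, ip, nullptr);
    std::swap(prev, cur);
    int rowBest = prev[0];
    for (int j = 1; j < p; ++j) if (prev[j] > rowBest) rowBest = prev[j];
    if (rowBest > bestScore) { bestScore = rowBest; bestLen = i; }
    if (rowBest < bestScore - xdrop) break;
  }
}

// [[Rcpp::export]]
List cpp_wrap_align(std::string segment, std::string monomer,
                    int match, int mismatch, int indel) {
  if (monomer.empty()) stop("monomer must be non-empty");
  WrapStats w = wrap_align_full(segment, monomer, match, mismatch, indel);
  return List::create(_["score"] = (double)w.score,
                      _["copy_number"] = w.copies,
                      _["percent_identity"] = w.identity,
                      _["consensus"] = w.consensus,
                      _["matches"] = (double)w.matches,
                      _["columns"] = (double)w.columns);
}

// ---------------------------------------------------------------------------
// k-mer recurrence candidates
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_find_candidates(std::string seq, int k, int min_period,
                              int max_period) {
  const long n = (long)seq.size();
  std::vector<double> outPos;
  std::vector<int> outPeriod;
  if (n >= 2 && k >= 1 && k <= 31) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::unordered_map<uint64_t, long> last;
    std::unordered_map<uint64_t, long> lastEmit;  // key: period, val: anchor pos
    last.reserve(n > 1000 ? (size_t)n : 1024);
    uint64_t h = 0;
    int run = 0;  // valid bases accumulated
    for (long i = 0; i < n; ++i) {
      const int c = base_code(seq[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      const long pos = i - k + 1;  // k-mer start
      auto it = last.find(h);
      if (it != last.end()) {
        const long d = pos - it->second;
        if (d >= min_period && d <= max_period) {
          const long anchor = it->second;
          auto le = lastEmit.find((uint64_t)d);
          if (le == lastEmit.end() || anchor - le->second >= d) {
            outPos.push_back((double)anchor);
            outPeriod.push_back((int)d);
            lastEmit[(uint64_t)d] = anchor;
          }
        }
        it->second = pos;
      } else {
        last.emplace(h, pos);
      }
    }
  }
  return DataFrame::create(_["pos"] = outPos, _["period"] = outPeriod);
}

// ---------------------------------------------------------------------------
// Tandem-array detector for one sequence
// ---------------------------------------------------------------------------

struct Hit {
  long start, end;     // 0-based half-open
  int period;
  long score;
  double copies;
  double identity;
  std::string cons;
};

// [[Rcpp::export]]
DataFrame cpp_detect_seq(std::string seq, int k, int match, int mismatch,
                         int indel, int min_score, int min_period,
                         int max_period, double min_copies, int xdrop,
                         int max_multiple, double ident_delta) {
  const long n = (long)seq.size();
  DataFrame cand = cpp_find_candidates(seq, k, min_period, max_period);
  NumericVector cpos = cand["pos"];
  IntegerVector cper = cand["period"];
  const R_xlen_t nc = cpos.size();

  // process candidates in ascending (period, pos) order
  std::vector<R_xlen_t> ord(nc);
  for (R_xlen_t i = 0; i < nc; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (cper[a] != cper[b]) return cper[a] < cper[b];
    return cpos[a] < cpos[b];
  });

  std::vector<Hit> hits;
  // hits at the currently processed period, sorted by start
  std::vector<std::pair<long, size_t>> samePeriod;
  int curPeriod = -1;
  // (covering-hit start, candidate period) pairs already probed and rejected
  std::set<std::pair<long, int>> probedFail;

  const std::string rev(seq.rbegin(), seq.rend());

  for (R_xlen_t oi = 0; oi < (R_xlen_t)ord.size(); ++oi) {
    const long pos = (long)cpos[ord[oi]];
    const int d = cper[ord[oi]];
    if (d != curPeriod) {
      curPeriod = d;
      samePeriod.clear();
      for (size_t h = 0; h < hits.size(); ++h)
        if (hits[h].period == d) samePeriod.push_back({hits[h].start, h});
      std::sort(samePeriod.begin(), samePeriod.end());
    }
    // skip if an accepted hit at this period already covers the anchor
    {
      bool covered = false;
      auto it = std::upper_bound(samePeriod.begin(), samePeriod.end(),
                                 std::make_pair(pos, SIZE_MAX));
      for (auto jt = samePeriod.begin(); jt != it; ++jt)
        if (hits[jt->second].end > pos) { covered = true; break; }
      if (covered) continue;
    }
    if (pos + d > n) continue;
    std::string mon = seq.substr(pos, d);
    if (mon.find_first_not_of("ACGT") != std::string::npos) continue;

    // does the candidate monomer window overlap a hit whose period
    // (near-)divides d?  (anchors can sit a few bp outside the hit)
    long coverIdx = -1;
    for (size_t h = 0; h < hits.size(); ++h) {
      const Hit& H = hits[h];
      const long ov = std::min(H.end, pos + d) - std::max(H.start, pos);
      if (2 * ov >= d && H.period < d) {
        const int m = (int)std::lround((double)d / H.period);
        if (m >= 2 && std::abs(d - m * H.period) <= 2) {
          if (coverIdx < 0 || H.period < hits[coverIdx].period) coverIdx = (long)h;
        }
      }
    }
    if (coverIdx >= 0) {
      const Hit& B = hits[coverIdx];
      const int m = (int)std::lround((double)d / B.period);
      if (m > max_multiple) continue;
      const std::pair<long, int> key{B.start, d};
      if (probedFail.count(key)) continue;
      // quick identity probe on a window of the covering interval: keep the
      // longer period only if it explains the array better
      const long blen = B.end - B.start;
      const long wlen = std::min(blen, (long)20 * d);
      const long ws = B.start + (blen - wlen) / 2;
      WrapStats probe = wrap_align_full(seq.substr(ws, wlen), mon,
                                        match, mismatch, indel);
      if (probe.identity <= B.identity + ident_delta) {
        probedFail.insert(key);
        continue;
      }
      std::string segment = seq.substr(B.start, blen);
      WrapStats a = wrap_align_full(segment, mon, match, mismatch, indel);
      WrapStats b = wrap_align_full(segment, a.consensus, match, mismatch, indel);
      if (b.score >= min_score && b.copies >= min_copies &&
          b.identity > B.identity + ident_delta) {
        // same-period overlap resolution against existing d-hits
        bool worse = false;
        std::vector<size_t> shed;
        for (auto& sp : samePeriod) {
          const Hit& H = hits[sp.second];
          if (H.period == d && H.start < B.end && B.start < H.end) {
            if (H.score >= b.score) { worse = true; break; }
            shed.push_back(sp.second);
          }
        }
        if (!worse) {
          if (!shed.empty()) {
            std::sort(shed.begin(), shed.end(), std::greater<size_t>());
            for (size_t idx : shed) hits.erase(hits.begin() + idx);
          }
          hits.push_back({B.start, B.end, d, b.score, b.copies, b.identity,
                          a.consensus});
          samePeriod.clear();
          for (size_t h = 0; h < hits.size(); ++h)
            if (hits[h].period == d) samePeriod.push_back({hits[h].start, h});
          std::sort(samePeriod.begin(), samePeriod.end());
        }
      } else {
        probedFail.insert(key);
      }
      continue;
    }

    // greedy X-drop extension right from pos and left from pos
    long rLen = 0, rScore = 0, lLen = 0, lScore = 0;
    wrap_extend(seq.data() + pos, n - pos, mon, match, mismatch, indel,
                xdrop, rLen, rScore);
    {
      std::string monRev(mon.rbegin(), mon.rend());
      wrap_extend(rev.data() + (n - pos), pos, monRev, match, mismatch, indel,
                  xdrop, lLen, lScore);
    }
    if (lScore + rScore < min_score) continue;
    const long s0 = pos - lLen, e0 = pos + rLen;
    // too short to hold min_copies monomer copies even with indel slack
    if ((double)(e0 - s0) < 0.8 * min_copies * d) continue;
    std::string segment = seq.substr(s0, e0 - s0);
    WrapStats a = wrap_align_full(segment, mon, match, mismatch, indel);
    WrapStats b = wrap_align_full(segment, a.consensus, match, mismatch, indel);
    if (b.score < min_score || b.copies < min_copies) continue;

    // same-period overlap resolution: keep the best-scoring hit
    bool dropMine = false;
    std::vector<size_t> toDrop;
    for (auto& sp : samePeriod) {
      const Hit& H = hits[sp.second];
      if (H.period != d) continue;
      if (H.start < e0 && s0 < H.end) {
        if (H.score >= b.score) { dropMine = true; break; }
        toDrop.push_back(sp.second);
      }
    }
    if (dropMine) continue;
    if (!toDrop.empty()) {
      std::sort(toDrop.begin(), toDrop.end(), std::greater<size_t>());
      for (size_t idx : toDrop) hits.erase(hits.begin() + idx);
      samePeriod.clear();
      for (size_t h = 0; h < hits.size(); ++h)
        if (hits[h].period == d) samePeriod.push_back({hits[h].start, h});
    }
    hits.push_back({s0, e0, d, b.score, b.copies, b.identity, a.consensus});
    samePeriod.push_back({s0, hits.size() - 1});
    std::sort(samePeriod.begin(), samePeriod.end());
  }

  // final redundancy pass: drop a longer-period hit when a (near-)divisor
  // period explains the same locus at least as well — genuine higher-order
  // structure survives because it improves identity by > ident_delta
  {
    std::vector<bool> drop(hits.size(), false);
    for (size_t a = 0; a < hits.size(); ++a) {
      for (size_t b = 0; b < hits.size(); ++b) {
        if (a == b || drop[b]) continue;
        const Hit& hi = hits[a];
        const Hit& lo = hits[b];
        if (lo.period >= hi.period) continue;
        const int m = (int)std::lround((double)hi.period / lo.period);
        if (m < 2 || std::abs(hi.period - m * lo.period) > 2) continue;
        const long ov = std::min(hi.end, lo.end) - std::max(hi.start, lo.start);
        if (5 * ov < 4 * (hi.end - hi.start)) continue;  // <80% of the longer
        if (hi.identity <= lo.identity + ident_delta) drop[a] = true;
      }
    }
    std::vector<Hit> kept;
    for (size_t a = 0; a < hits.size(); ++a)
      if (!drop[a]) kept.push_back(hits[a]);
    hits.swap(kept);
  }

  const size_t H = hits.size();
  NumericVector start(H), end(H), score(H), copies(H), ident(H);
  IntegerVector period(H);
  CharacterVector cons(H);
  for (size_t h = 0; h < H; ++h) {
    start[h] = (double)hits[h].start;
    end[h] = (double)hits[h].end;
    period[h] = hits[h].period;
    score[h] = (double)hits[h].score;
    copies[h] = hits[h].copies;
    ident[h] = hits[h].identity;
    cons[h] = hits[h].cons;
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["period"] = period, _["copy_number"] = copies,
                           _["percent_identity"] = ident, _["score"] = score,
                           _["base_seq"] = cons,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Word-seeded affine-gap local alignment (Smith-Waterman extension gated on
// a shared exact word).  Gap of length L costs gap_open + L * gap_extend.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_seeded_local_align(std::string q, std::string s, int match,
                            int mismatch, int gap_open, int gap_extend,
                            int word_size) {
  const long m = (long)q.size(), n = (long)s.size();
  List none = List::create(_["score"] = 0.0, _["qstart"] = NA_INTEGER,
                           _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                           _["send"] = NA_INTEGER, _["length"] = 0);
  if (m == 0 || n == 0) return none;

  // seed gate: require at least one shared exact word
  if (word_size > 0 && m >= word_size && n >= word_size && word_size <= 31) {
    const uint64_t mask = (1ULL << (2 * word_size)) - 1;
    std::unordered_map<uint64_t, char> words;
    uint64_t h = 0; int run = 0;
    for (long i = 0; i < m; ++i) {
      const int c = base_code(q[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= word_size) words[h] = 1;
    }
    bool seeded = false;
    h = 0; run = 0;
    for (long i = 0; i < n && !seeded; ++i) {
      const int c = base_code(s[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= word_size && words.count(h)) seeded = true;
    }
    if (!seeded) return none;
  } else if (word_size > 0 && (m < word_size || n < word_size)) {
    return none;
  }

  // affine SW; tb codes: 0 stop, 1 diag, 2 from-X (gap in s dir), 3 from-Y
  std::vector<int> Mrow(n + 1, 0), Xrow(n + 1, NEG_INF), Mprev(n + 1, 0),
      Xprev(n + 1, NEG_INF);
  std::vector<uint8_t> tbM((size_t)(m + 1) * (n + 1), 0),
      tbX((size_t)(m + 1) * (n + 1), 0), tbY((size_t)(m + 1) * (n + 1), 0);
  long bi = 0, bj = 0; int best = 0; uint8_t bmat = 0;
  for (long i = 1; i <= m; ++i) {
    int Y = NEG_INF;  // gap in query within the row
    Mrow[0] = 0; Xrow[0] = NEG_INF;
    for (long j = 1; j <= n; ++j) {
      // X: gap in subject (consume query): from M[i-1][j] open, X[i-1][j] extend
      int xo = Mprev[j] - gap_open - gap_extend;
      int xe = Xprev[j] - gap_extend;
      int X = std::max(xo, xe);
      tbX[(size_t)i * (n + 1) + j] = (xo >= xe) ? 1 : 2;
      // Y: gap in query (consume subject)
      int yo = Mrow[j - 1] - gap_open - gap_extend;
      int ye = Y - gap_extend;
      Y = std::max(yo, ye);
      tbY[(size_t)i * (n + 1) + j] = (yo >= ye) ? 1 : 3;
      // M
      const bool eq = base_code(q[i - 1]) >= 0 && q[i - 1] == s[j - 1];
      int diag = Mprev[j - 1] + (eq ? match : -mismatch);
      int Mv = diag; uint8_t t = 1;
      if (X > Mv) { Mv = X; t = 2; }
      if (Y > Mv) { Mv = Y; t = 3; }
      if (Mv < 0) { Mv = 0; t = 0; }
      Mrow[j] = Mv; Xrow[j] = X;
      tbM[(size_t)i * (n + 1) + j] = t;
      if (Mv > best) { best = Mv; bi = i; bj = j; bmat = 1; }
    }
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev);
    // Y row values are not carried between rows (row-local), nothing to swap
  }
  if (best <= 0) return none;

  // traceback for coordinates
  long i = bi, j = bj; uint8_t mat = 1; long len = 0;
  const long qe = bi, se = bj;
  long qs = bi, ss = bj;
  while (i > 0 && j > 0) {
    if (mat == 1) {
      const uint8_t t = tbM[(size_t)i * (n + 1) + j];
      if (t == 0) break;
      if (t == 1) { qs = i; ss = j; --i; --j; ++len; }
      else if (t == 2) mat = 2;
      else mat = 3;
    } else if (mat == 2) {
      const uint8_t t = tbX[(size_t)i * (n + 1) + j];
      --i; ++len;
      mat = (t == 1) ? 1 : 2;
    } else {
      const uint8_t t = tbY[(size_t)i * (n + 1) + j];
      --j; ++len;
      mat = (t == 1) ? 1 : 3;
    }
  }
  return List::create(_["score"] = (double)best, _["qstart"] = (int)qs,
                      _["qend"] = (int)qe, _["sstart"] = (int)ss,
                      _["send"] = (int)se, _["length"] = (double)len);
}
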