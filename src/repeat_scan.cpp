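// Seed-and-extend scanner for maximal repeat pairs.
//
// Finds all maximal pairs (copy1, copy2) of length >= min_len with at most
// max_mm mismatches, where copy2 is an exact-orientation copy (forward), the
// reverse complement (palindromic) or the plain reversal (reverse) of copy1.
// A pair is maximal when extending the window by one base on either side
// would add a mismatch beyond the budget or run off the sequence. Pairs whose
// two copies overlap (tandem arrays, fold-back palindromes) are dropped:
// those belong to the SSR / secondary-structure domain, not to dispersed
// repeats. Exact seeds of length seed_k are hashed; any true hit contains an
// exact run of at least ceil((min_len - max_mm)/(max_mm + 1)) bases, so
// seed_k <= 7 is lossless for the default 30 bp / 3 mismatch criteria.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int code_of(char ch) {
  switch (ch) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

struct ScanCtx {
  const std::vector<int>* code;
  int n, kind;            // 1 forward, 2 palindromic, 3 reverse
  long long line;         // diagonal d (forward) or antidiagonal c
  int lo, hi;             // valid copy1-side position range on this line
};

static inline bool match_at(const ScanCtx& cx, int a) {
  const std::vector<int>& code = *cx.code;
  int ca = code[a];
  if (ca < 0) return false;
  int b = (cx.kind == 1) ? a + (int)cx.line : (int)cx.line - a;
  int cb = code[b];
  if (cb < 0) return false;
  if (cx.kind == 2) return ca == 3 - cb;
  return ca == cb;
}

// [[Rcpp::export]]
DataFrame cpp_maximal_pairs(std::string seq, int kind, int min_len,
                            int max_mm, int seed_k) {
  int n = (int)seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = code_of(seq[i]);

  std::vector<int> rs1, re1, rs2, re2, rmm;
  if (n < min_len || seed_k < 1 || seed_k > 31) {
    return DataFrame::create(_["start1"] = rs1, _["end1"] = re1,
                             _["start2"] = rs2, _["end2"] = re2,
                             _["mismatches"] = rmm);
  }

  // k-mer keys (base-4); key < 0 marks a window containing N
  int nk = n - seed_k + 1;
  std::vector<int64_t> fkey(nk, -1);
  for (int i = 0; i < nk; ++i) {
    int64_t key = 0; bool ok = true;
    for (int t = 0; t < seed_k; ++t) {
      int c = code[i + t];
      if (c < 0) { ok = false; break; }
      key = (key << 2) | c;
    }
    if (ok) fkey[i] = key;
  }
  std::unordered_map<int64_t, std::vector<int> > index;
  index.reserve(nk * 2);
  for (int i = 0; i < nk; ++i)
    if (fkey[i] >= 0) index[fkey[i]].push_back(i);

  std::unordered_set<long long> seen_run, seen_win;
  ScanCtx cx; cx.code = &code; cx.n = n; cx.kind = kind;

  auto process_seed = [&](long long line, int seed_a, int lo, int hi) {
    cx.line = line; cx.lo = lo; cx.hi = hi;
    if (seed_a < lo || seed_a > hi) return;
    // extend the exact run containing the seed
    int s = seed_a, e = seed_a;
    while (s - 1 >= lo && match_at(cx, s - 1)) --s;
    while (e + 1 <= hi && match_at(cx, e + 1)) ++e;
    long long runkey = line * (long long)(n + 2) + s;
    if (!seen_run.insert(runkey).second) return;

    // nearest max_mm+1 mismatch positions on each side
    std::vector<int> Lm, Rm;
    for (int a = s - 1; a >= lo && (int)Lm.size() <= max_mm; --a)
      if (!match_at(cx, a)) Lm.push_back(a);
    for (int a = e + 1; a <= hi && (int)Rm.size() <= max_mm; ++a)
      if (!match_at(cx, a)) Rm.push_back(a);

    for (int t = 0; t <= max_mm; ++t) {
      int w1 = (t < (int)Lm.size()) ? Lm[t] + 1 : lo;
      int rr = max_mm - t;
      int w2 = (rr < (int)Rm.size()) ? Rm[rr] - 1 : hi;
      int mm = std::min(t, (int)Lm.size()) + std::min(rr, (int)Rm.size());
      int len = w2 - w1 + 1;
      if (len < min_len) continue;
      // disjoint copies only
      if (kind == 1) { if (len > (int)line) continue; }
      else           { if (2LL * w2 >= line) continue; }
      long long wkey = line * (long long)(n + 2) + w1;
      if (!seen_win.insert(wkey).second) continue;
      int a2, b2;
      if (kind == 1) { a2 = w1 + (int)line; b2 = w2 + (int)line; }
      else           { a2 = (int)(line - w2); b2 = (int)(line - w1); }
      rs1.push_back(w1 + 1); re1.push_back(w2 + 1);
      rs2.push_back(a2 + 1); re2.push_back(b2 + 1);
      rmm.push_back(mm);
    }
  };

  if (kind == 1) {
    long long nseen = 0;
    for (auto& kv : index) {
      std::vector<int>& v = kv.second;
      size_t m = v.size();
      for (size_t a = 0; a + 1 < m; ++a) {
        for (size_t b = a + 1; b < m; ++b) {
          int d = v[b] - v[a];
          if (d < min_len) continue;   // overlapping copies can never reach min_len
          process_seed((long long)d, v[a], 0, n - 1 - d);
        }
      }
      if (((nseen += m) & 0xFFFFF) < (long long)m)
        Rcpp::checkUserInterrupt();
    }
  } else {
    for (int i = 0; i < nk; ++i) {
      if (fkey[i] < 0) continue;
      int64_t tkey = 0;
      if (kind == 2) {          // reverse complement of the k-mer
        for (int t = seed_k - 1; t >= 0; --t)
          tkey = (tkey << 2) | (3 - code[i + t]);
      } else {                  // plain reversal
        for (int t = seed_k - 1; t >= 0; --t)
          tkey = (tkey << 2) | code[i + t];
      }
      auto it = index.find(tkey);
      if (it == index.end()) continue;
      for (int j : it->second) {
        if (j < i) continue;    // symmetric relation: each pair once
        long long c = (long long)i + j + seed_k - 1;
        int lo = (int)std::max(0LL, c - (n - 1));
        int hi = (int)std::min((long long)(n - 1), c);
        process_seed(c, i, lo, hi);
      }
      if ((i & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    }
  }

  return DataFrame::create(_["start1"] = rs1, _["end1"] = re1,
                           _["start2"] = rs2, _["end2"] = re2,
                           _["mismatches"] = rmm);
}
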