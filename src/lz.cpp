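#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Suffix array by prefix doubling (O(n log^2 n)); alphabet {0,1}.
static std::vector<int> suffixArray(const IntegerVector& s) {
  const int n = s.size();
  std::vector<int> sa(n), rank_(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rank_[i] = s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
      const int ra = a + k < n ? rank_[a + k] : -1;
      const int rb = b + k < n ? rank_[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai: lcp[i] = longest common prefix of suffixes sa[i-1] and sa[i].
static std::vector<int> kasaiLcp(const IntegerVector& s,
                                 const std::vector<int>& sa,
                                 std::vector<int>& pos) {
  const int n = s.size();
  std::vector<int> lcp(n, 0);
  pos.assign(n, 0);
  for (int i = 0; i < n; ++i) pos[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (pos[i] > 0) {
      const int j = sa[pos[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[pos[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// Longest previous factor: LPF[p] = length of the longest prefix of the
// suffix at p that also occurs starting at some position < p (overlap into
// the suffix itself allowed). Computed by deleting suffixes from the
// suffix-array neighbour list in order of decreasing start position.
static std::vector<int> longestPreviousFactor(const IntegerVector& s) {
  const int n = s.size();
  std::vector<int> pos;
  std::vector<int> sa = suffixArray(s);
  std::vector<int> lcp = kasaiLcp(s, sa, pos);
  std::vector<int> prev(n), next(n), lpf(n, 0);
  for (int t = 0; t < n; ++t) { prev[t] = t - 1; next[t] = t + 1; }
  for (int i = n - 1; i >= 0; --i) {
    const int t = pos[i];
    const int lcpPrev = (prev[t] >= 0) ? lcp[t] : 0;
    const int lcpNext = (next[t] < n) ? lcp[next[t]] : 0;
    lpf[i] = std::max(lcpPrev, lcpNext);
    if (next[t] < n) {
      lcp[next[t]] = std::min(lcpPrev, lcpNext);
      prev[next[t]] = prev[t];
    }
    if (prev[t] >= 0) next[prev[t]] = next[t];
  }
  return lpf;
}

// Lempel-Ziv 1976 exhaustive-history word count. Each new word is the
// shortest extension of the longest prefix of the remaining sequence that
// already occurs at an earlier start; a trailing reproducible suffix
// counts as one final word.
// [[Rcpp::export]]
int lz76_count_cpp(const IntegerVector& s) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  if (n == 1) return 1;
  std::vector<int> lpf = longestPreviousFactor(s);
  int p = 0, c = 0;
  while (p < n) {
    int len = lpf[p] + 1;
    if (p + len > n) len = n - p;
    p += len;
    ++c;
  }
  return c;
}

// Reference implementation of the same parsing: the Kaspar-Schuster scan,
// O(n * match length). Used as an internal cross-check in the tests.
// [[Rcpp::export]]
int lz76_count_ks_cpp(const IntegerVector& s) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  for (;;) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// LZ78 incremental-dictionary phrase count: phrases grow until unseen,
// the unseen extension enters the dictionary; a trailing incomplete
// phrase counts as one word.
// [[Rcpp::export]]
int lz78_count_cpp(const IntegerVector& s) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  std::unordered_set<std::string> dict;
  std::string w;
  int c = 0;
  for (int t = 0; t < n; ++t) {
    w.push_back(s[t] ? '1' : '0');
    if (dict.find(w) == dict.end()) {
      dict.insert(w);
      ++c;
      w.clear();
    }
  }
  if (!w.empty()) ++c;
  return c;
}
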