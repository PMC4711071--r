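// Integer-text primitives shared by the match engine and the normalizer:
// suffix array (prefix doubling), LCP (Kasai), maximal exact match
// enumeration, union-find column construction, and the all-genome longest
// common substring used for circular normalization.
//
// Text encoding contract (set up on the R side): A,C,G,T -> 1..4; every N
// and every inter-genome sentinel gets its own unique code >= 5, so an N
// never equals anything (including another N) and matches never cross
// genome boundaries. gid is the 1-based genome index (0 for sentinels),
// gpos the 1-based position within the genome (0 for sentinels).

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static std::vector<int> build_suffix_array(const std::vector<int>& t) {
  int n = static_cast<int>(t.size());
  std::vector<int> sa(n), rnk(n), tmp(n);
  {
    std::vector<std::pair<int, int> > v(n);
    for (int i = 0; i < n; ++i) v[i] = std::make_pair(t[i], i);
    std::sort(v.begin(), v.end());
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i > 0 && v[i].first != v[i - 1].first) ++r;
      rnk[v[i].second] = r;
    }
  }
  for (int i = 0; i < n; ++i) sa[i] = i;
  if (n <= 1) return sa;
  for (int k = 1;; k <<= 1) {
    struct Cmp {
      const std::vector<int>& rnk;
      int k, n;
      Cmp(const std::vector<int>& r, int k_, int n_) : rnk(r), k(k_), n(n_) {}
      bool operator()(int a, int b) const {
        if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
        int ra = a + k < n ? rnk[a + k] : -1;
        int rb = b + k < n ? rnk[b + k] : -1;
        return ra < rb;
      }
    } cmp(rnk, k, n);
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// lcp[i] = longest common prefix of suffixes sa[i-1] and sa[i]; lcp[0] = 0.
static std::vector<int> lcp_kasai(const std::vector<int>& t,
                                  const std::vector<int>& sa) {
  int n = static_cast<int>(t.size());
  std::vector<int> rank_(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && t[i + h] == t[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// All maximal exact matches of length >= m between positions of different
// genomes. A pair of suffixes (p, q) is a MEM start iff lcp(p, q) >= m
// (right-maximality is implied by lcp being exact) and the preceding
// characters differ (left-maximality; unique codes make boundaries and Ns
// differ from everything). Pairs are scanned inside lcp >= m runs of the
// suffix array, so work is proportional to the candidate pairs.
// [[Rcpp::export]]
List mems_sa_cpp(IntegerVector code, IntegerVector gid, IntegerVector gpos,
                 int m) {
  int n = code.size();
  std::vector<int> t(code.begin(), code.end());
  std::vector<int> sa = build_suffix_array(t);
  std::vector<int> lcp = lcp_kasai(t, sa);
  std::vector<int> ga, sta, gb, stb, len;
  for (int i = 0; i + 1 < n; ++i) {
    int minl = INT_MAX;
    for (int j = i + 1; j < n; ++j) {
      if (lcp[j] < minl) minl = lcp[j];
      if (minl < m) break;
      int p = sa[i], q = sa[j];
      if (gid[p] == 0 || gid[q] == 0) continue;
      if (gid[p] == gid[q]) continue;
      if (p > 0 && q > 0 && t[p - 1] == t[q - 1]) continue;
      if (gid[p] > gid[q]) std::swap(p, q);
      ga.push_back(gid[p]);
      sta.push_back(gpos[p]);
      gb.push_back(gid[q]);
      stb.push_back(gpos[q]);
      len.push_back(minl);
    }
  }
  return List::create(_["ga"] = wrap(ga), _["start_a"] = wrap(sta),
                      _["gb"] = wrap(gb), _["start_b"] = wrap(stb),
                      _["length"] = wrap(len));
}

struct DSU {
  std::vector<int> p;
  std::vector<int> r;
  explicit DSU(int n) : p(n), r(n, 0) {
    for (int i = 0; i < n; ++i) p[i] = i;
  }
  int find(int x) {
    while (p[x] != x) {
      p[x] = p[p[x]];
      x = p[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) return;
    if (r[a] < r[b]) std::swap(a, b);
    p[b] = a;
    if (r[a] == r[b]) ++r[a];
  }
};

// Union-find over n global positions; each match unions its aligned bases.
// a and b are 0-based global start positions. Returns dense 1-based
// component ids, numbered in order of first appearance along the genomes.
// [[Rcpp::export]]
IntegerVector uf_components_cpp(int n, IntegerVector a, IntegerVector b,
                                IntegerVector len) {
  DSU d(n);
  int nm = a.size();
  for (int k = 0; k < nm; ++k) {
    int pa = a[k], pb = b[k], L = len[k];
    for (int i = 0; i < L; ++i) d.unite(pa + i, pb + i);
  }
  IntegerVector out(n);
  std::vector<int> lab(n, 0);
  int nxt = 0;
  for (int i = 0; i < n; ++i) {
    int r = d.find(i);
    if (lab[r] == 0) lab[r] = ++nxt;
    out[i] = lab[r];
  }
  return out;
}

// Longest substring present in every genome: slide minimal windows over the
// suffix array that cover all ngen genomes; the window's common prefix
// length is the min LCP inside it (monotone deque). Every minimal window is
// reported so the caller can apply its own tie-break.
// [[Rcpp::export]]
List lcs_windows_cpp(IntegerVector code, IntegerVector gid,
                     IntegerVector gpos, int ngen) {
  int n = code.size();
  std::vector<int> t(code.begin(), code.end());
  std::vector<int> sa = build_suffix_array(t);
  std::vector<int> lcp = lcp_kasai(t, sa);
  std::vector<int> cnt(ngen + 1, 0);
  int have = 0, l = 0;
  std::deque<int> dq;  // lcp indices in (l, r], increasing lcp values
  std::vector<int> wdepth, wgid, wpos;
  for (int r = 0; r < n; ++r) {
    if (r > 0) {
      while (!dq.empty() && lcp[dq.back()] >= lcp[r]) dq.pop_back();
      dq.push_back(r);
    }
    int gr = gid[sa[r]];
    if (gr > 0 && cnt[gr]++ == 0) ++have;
    while (have == ngen) {
      int gl = gid[sa[l]];
      bool removable = (gl == 0) || (cnt[gl] > 1);
      if (!removable) break;
      if (gl > 0) --cnt[gl];
      ++l;
      while (!dq.empty() && dq.front() <= l) dq.pop_front();
    }
    if (have == ngen && l < r) {
      while (!dq.empty() && dq.front() <= l) dq.pop_front();
      int depth = dq.empty() ? 0 : lcp[dq.front()];
      if (depth > 0) {
        wdepth.push_back(depth);
        wgid.push_back(gid[sa[l]]);
        wpos.push_back(gpos[sa[l]]);
      }
    }
  }
  return List::create(_["depth"] = wrap(wdepth), _["gid"] = wrap(wgid),
                      _["gpos"] = wrap(wpos));
}
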