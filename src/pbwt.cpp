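#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Range-max structure (sparse table) over the divergence array.  Rebuilt at
// every site; queries are O(1).
class RangeMax {
  std::vector<std::vector<int>> tab;
  std::vector<int> lg;

public:
  void build(const std::vector<int> &v) {
    int n = (int)v.size();
    lg.assign(n + 1, 0);
    for (int i = 2; i <= n; ++i) lg[i] = lg[i / 2] + 1;
    int K = lg[n] + 1;
    tab.assign(K, std::vector<int>());
    tab[0] = v;
    for (int j = 1; j < K; ++j) {
      tab[j].resize(n);
      for (int i = 0; i + (1 << j) <= n; ++i)
        tab[j][i] = std::max(tab[j - 1][i], tab[j - 1][i + (1 << (j - 1))]);
    }
  }
  // max over v[l..r], inclusive; requires l <= r
  int query(int l, int r) const {
    int j = lg[r - l + 1];
    return std::max(tab[j][l], tab[j][r - (1 << j) + 1]);
  }
};

// One PBWT step: from the state before site k (prefix array a, divergence d,
// d[0] == k) and the symbols of column k (indexed by original row), produce
// the state before site k+1.  Sequences are stably bucketed by symbol in
// ascending order; the new divergence of the t-th entry is k+1 for the first
// entry of its symbol class and otherwise the maximum old divergence over the
// half-open gap back to the previous entry of the same class.  Symbols may be
// any non-negative integers (the compressed panel uses {0,1}; the
// ground-truth interim panel uses per-row sentinel symbols for heterozygous
// cells so that they can never match).
static void advance_step(std::vector<int> &a, std::vector<int> &d, int k,
                         const int *col, RangeMax &rm,
                         std::vector<int> &na, std::vector<int> &nd,
                         std::vector<int> &order) {
  int M = (int)a.size();
  rm.build(d);
  order.resize(M);
  for (int i = 0; i < M; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int x, int y) { return col[a[x]] < col[a[y]]; });
  na.resize(M);
  nd.resize(M);
  for (int t = 0; t < M; ++t) {
    int i = order[t];
    bool first = (t == 0) || (col[a[order[t - 1]]] != col[a[i]]);
    if (first) {
      nd[t] = k + 1;
    } else {
      // stability => old positions increase within a symbol class
      nd[t] = rm.query(order[t - 1] + 1, i);
    }
    na[t] = a[i];
  }
  a.swap(na);
  d.swap(nd);
}

// [[Rcpp::export]]
List pbwt_advance_cpp(IntegerVector a0, IntegerVector d0, int k,
                      IntegerVector column) {
  int M = a0.size();
  std::vector<int> a(a0.begin(), a0.end()), d(d0.begin(), d0.end());
  std::vector<int> na, nd, order;
  RangeMax rm;
  advance_step(a, d, k, INTEGER(column), rm, na, nd, order);
  return List::create(_["a"] = IntegerVector(a.begin(), a.end()),
                      _["d"] = IntegerVector(d.begin(), d.end()),
                      _["k"] = k + 1);
}

struct BlockSink {
  std::vector<int> start, end;
  std::vector<std::vector<int>> members;
  void emit(int s, int e, std::vector<int> rows) {
    std::sort(rows.begin(), rows.end());
    start.push_back(s);
    end.push_back(e);
    members.push_back(std::move(rows));
  }
};

// Width-maximal scan.  At every end position e >= L the PBWT-sorted entries
// are partitioned into runs separated by entries whose divergence exceeds
// e - L; a run of >= W entries is a candidate block with start = max internal
// divergence, and it is reported as soon as it fails to survive intact to the
// next end position (or at e = N).
static void scan_width(const IntegerMatrix &X, int L, int W, BlockSink &out) {
  int M = X.nrow(), N = X.ncol();
  std::vector<int> a(M), d(M, 0), na, nd, order;
  for (int i = 0; i < M; ++i) a[i] = i;
  RangeMax rm;

  struct Cand {
    int s;
    std::vector<int> rows;
  };
  std::vector<Cand> prev, cur;
  std::vector<int> runid(M);
  bool have_prev = false;

  for (int e = 1; e <= N; ++e) {
    advance_step(a, d, e - 1, &X[(R_xlen_t)(e - 1) * M], rm, na, nd, order);
    if (e < L) continue;

    cur.clear();
    int nruns = 0;
    int i = 0;
    while (i < M) {
      int j = i, s = -1;
      while (j + 1 < M && d[j + 1] <= e - L) {
        ++j;
        if (d[j] > s) s = d[j];
      }
      for (int t = i; t <= j; ++t) runid[a[t]] = nruns;
      if (j - i + 1 >= W) {
        Cand c;
        c.s = s;
        c.rows.assign(a.begin() + i, a.begin() + j + 1);
        cur.push_back(std::move(c));
      }
      ++nruns;
      i = j + 1;
    }

    if (have_prev) {
      for (auto &c : prev) {
        int rid = runid[c.rows[0]];
        bool intact = true;
        for (int r : c.rows)
          if (runid[r] != rid) {
            intact = false;
            break;
          }
        if (!intact) out.emit(c.s, e - 1, c.rows);
      }
    }
    prev.swap(cur);
    have_prev = true;
  }
  if (have_prev)
    for (auto &c : prev) out.emit(c.s, N, c.rows);
}

// Length-maximal scan.  At every end position e the nested maximal intervals
// of the divergence array (interval value = max internal divergence = block
// start) are enumerated; an interval of >= W rows spanning >= L sites is
// reported when no >= W subset can be extended one site to the left (no child
// segment of >= W rows) nor to the right (no symbol at column e shared by
// >= W member rows).
static void scan_length(const IntegerMatrix &X, int L, int W, BlockSink &out) {
  int M = X.nrow(), N = X.ncol();
  if (M < 2) return;
  std::vector<int> a(M), d(M, 0), na, nd, order;
  for (int i = 0; i < M; ++i) a[i] = i;
  RangeMax rm;
  std::vector<std::pair<int, int>> stack;
  std::vector<int> splits, syms;

  for (int e = 1; e <= N; ++e) {
    advance_step(a, d, e - 1, &X[(R_xlen_t)(e - 1) * M], rm, na, nd, order);
    if (e < L) continue;

    stack.clear();
    stack.push_back({0, M - 1});
    while (!stack.empty()) {
      int i = stack.back().first, j = stack.back().second;
      stack.pop_back();
      int s = -1;
      for (int t = i + 1; t <= j; ++t)
        if (d[t] > s) s = d[t];
      splits.clear();
      for (int t = i + 1; t <= j; ++t)
        if (d[t] == s) splits.push_back(t);

      int size = j - i + 1;
      if (size >= W && e - s >= L) {
        bool leftext = false;
        if (s > 0) {
          int segb = i;
          for (int t : splits) {
            if (t - segb >= W) leftext = true;
            segb = t;
          }
          if (j - segb + 1 >= W) leftext = true;
        }
        bool rightext = false;
        if (e < N) {
          syms.clear();
          const int *cole = &X[(R_xlen_t)e * M];
          for (int t = i; t <= j; ++t) syms.push_back(cole[a[t]]);
          std::sort(syms.begin(), syms.end());
          int best = 1, runl = 1;
          for (size_t t = 1; t < syms.size(); ++t) {
            runl = (syms[t] == syms[t - 1]) ? runl + 1 : 1;
            if (runl > best) best = runl;
          }
          if (best >= W) rightext = true;
        }
        if (!leftext && !rightext) {
          std::vector<int> rows(a.begin() + i, a.begin() + j + 1);
          out.emit(s, e, std::move(rows));
        }
      }
      // recurse into child segments
      int segb = i;
      for (int t : splits) {
        if (t - 1 - segb >= 1) stack.push_back({segb, t - 1});
        segb = t;
      }
      if (j - segb >= 1) stack.push_back({segb, j});
    }
  }
}

// [[Rcpp::export]]
List pbwt_scan_cpp(IntegerMatrix X, int L, int W, std::string objective) {
  BlockSink out;
  if (objective == "width")
    scan_width(X, L, W, out);
  else if (objective == "length")
    scan_length(X, L, W, out);
  else
    stop("unknown objective '%s'", objective.c_str());
  int B = (int)out.start.size();
  List mem(B);
  for (int b = 0; b < B; ++b)
    mem[b] = IntegerVector(out.members[b].begin(), out.members[b].end());
  return List::create(_["start"] = IntegerVector(out.start.begin(), out.start.end()),
                      _["end"] = IntegerVector(out.end.begin(), out.end.end()),
                      _["members"] = mem);
}
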