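// FM-index core and difference-bound inexact search.
//
// Symbol codes: A=0, C=1, G=2, T=3; 4 is the sentinel in BWT context and an
// ambiguous base (N) in query context.  All coordinates are 0-based half-open.

#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <algorithm>
#include <vector>
#include <queue>

using namespace Rcpp;

static const uint64_t EVEN_BITS = 0x5555555555555555ULL;

// ---------------------------------------------------------------------------
// FM-index view over the R-side list representation
// ---------------------------------------------------------------------------

struct FMView {
  const int* bwt;        // length nb = n + 1, values 0..3 plus one 4 (sentinel)
  int nb;
  int sentinel_row;
  const int* C;          // length 4, count of text symbols strictly smaller
  const int* cp;         // checkpoint matrix, column-major ncp x 4
  int ncp;
  int occ_stride;
  const uint64_t* words; // 2-bit packed bwt, sentinel slot packed as 0
  int sa_stride;
  const int* sa_samples; // SA values at rows r with r % sa_stride == 0
  int n_samples;

  // count of code c in packed slots [from, to) of one word
  static inline int word_count(uint64_t w, int c, int from, int to) {
    uint64_t pat = EVEN_BITS * (uint64_t)c; // c replicated in every 2-bit slot
    uint64_t x = w ^ pat;
    uint64_t eq = (~x) & ((~x) >> 1) & EVEN_BITS; // bit 2j set iff slot j == c
    uint64_t mask = EVEN_BITS;
    if (to < 32) mask &= (1ULL << (2 * to)) - 1ULL;
    if (from > 0) mask &= ~((1ULL << (2 * from)) - 1ULL);
    return __builtin_popcountll(eq & mask);
  }

  // count of code c in bwt[from, to), counting the sentinel slot as code 0
  inline int count_range_packed(int from, int to, int c) const {
    if (from >= to) return 0;
    int w0 = from / 32, w1 = (to - 1) / 32;
    if (w0 == w1) return word_count(words[w0], c, from - 32 * w0, to - 32 * w0);
    int cnt = word_count(words[w0], c, from - 32 * w0, 32);
    for (int w = w0 + 1; w < w1; ++w) cnt += word_count(words[w], c, 0, 32);
    cnt += word_count(words[w1], c, 0, to - 32 * w1);
    return cnt;
  }

  // occurrences of c in bwt[0, p), sentinel excluded
  inline int occ(int c, int p) const {
    int k = p / occ_stride;
    int base = k * occ_stride;
    int cnt = cp[k + (size_t)c * ncp];
    if (p > base) {
      cnt += count_range_packed(base, p, c);
      if (c == 0 && sentinel_row >= base && sentinel_row < p) cnt -= 1;
    }
    return cnt;
  }

  inline void ext(int low, int high, int c, int& l2, int& h2) const {
    l2 = C[c] + occ(c, low);
    h2 = C[c] + occ(c, high);
  }

  inline int lf(int r) const { // row of the one-shorter suffix; bwt[r] != 4
    int c = bwt[r];
    return C[c] + occ(c, r);
  }

  int sa_at(int r) const {
    int t = 0;
    while (r % sa_stride != 0) {
      if (bwt[r] == 4) return t; // SA[r] == 0
      r = lf(r);
      ++t;
    }
    return sa_samples[r / sa_stride] + t;
  }
};

static FMView fm_view(const List& fm) {
  FMView v;
  IntegerVector bwt = fm["bwt"];
  v.bwt = INTEGER(bwt);
  v.nb = bwt.size();
  v.sentinel_row = as<int>(fm["sentinel_row"]);
  IntegerVector C = fm["C"];
  v.C = INTEGER(C);
  IntegerMatrix cp = fm["occ_cp"];
  v.cp = INTEGER(cp);
  v.ncp = cp.nrow();
  v.occ_stride = as<int>(fm["occ_stride"]);
  RawVector words = fm["bwt_words"];
  v.words = reinterpret_cast<const uint64_t*>(RAW(words));
  v.sa_stride = as<int>(fm["sa_stride"]);
  IntegerVector sam = fm["sa_samples"];
  v.sa_samples = INTEGER(sam);
  v.n_samples = sam.size();
  return v;
}

// ---------------------------------------------------------------------------
// Construction
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_suffix_array(IntegerVector text) {
  int n = text.size();
  const int* t = INTEGER(text);
  std::vector<int> sa(n + 1);
  for (int i = 0; i <= n; ++i) sa[i] = i;
  std::sort(sa.begin(), sa.end(), [&](int a, int b) {
    for (;;) {
      if (a == n) return b != n;
      if (b == n) return false;
      if (t[a] != t[b]) return t[a] < t[b];
      ++a; ++b;
    }
  });
  return IntegerVector(sa.begin(), sa.end());
}

// [[Rcpp::export]]
IntegerVector cpp_bwt_from_sa(IntegerVector text, IntegerVector sa) {
  int nb = sa.size();
  IntegerVector out(nb);
  for (int i = 0; i < nb; ++i)
    out[i] = (sa[i] == 0) ? 4 : text[sa[i] - 1];
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_occ_checkpoints(IntegerVector bwt, int stride) {
  int nb = bwt.size();
  int ncp = nb / stride + 1;
  IntegerMatrix cp(ncp, 4);
  int cnt[4] = {0, 0, 0, 0};
  int k = 0;
  for (int p = 0; p <= nb; ++p) {
    if (p % stride == 0) {
      for (int c = 0; c < 4; ++c) cp(k, c) = cnt[c];
      ++k;
    }
    if (p < nb && bwt[p] < 4) cnt[bwt[p]]++;
  }
  return cp;
}

// [[Rcpp::export]]
RawVector cpp_pack_bwt_words(IntegerVector bwt) {
  int nb = bwt.size();
  int nw = (nb + 31) / 32;
  RawVector out(nw * 8);
  uint64_t* w = reinterpret_cast<uint64_t*>(RAW(out));
  for (int i = 0; i < nw; ++i) w[i] = 0;
  for (int p = 0; p < nb; ++p) {
    int c = bwt[p] == 4 ? 0 : bwt[p];
    w[p / 32] |= (uint64_t)c << (2 * (p % 32));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_invert_bwt(IntegerVector bwt) {
  int nb = bwt.size();
  int nsent = 0, srow = -1;
  for (int i = 0; i < nb; ++i)
    if (bwt[i] == 4) { ++nsent; srow = i; }
  if (nsent != 1) stop("BWT must contain exactly one sentinel, found %d", nsent);
  // full rank tables (construction-time oracle; small inputs)
  int C[5] = {0, 0, 0, 0, 0};
  std::vector<int> rank((size_t)nb);
  int cnt[5] = {0, 0, 0, 0, 0};
  for (int i = 0; i < nb; ++i) {
    int c = bwt[i];
    rank[i] = cnt[c]++;
  }
  // C over order sentinel < A < C < G < T
  int tot = 1; // sentinel first
  int Cc[4];
  for (int c = 0; c < 4; ++c) { Cc[c] = tot; tot += cnt[c]; }
  (void)C; (void)srow;
  int n = nb - 1;
  IntegerVector text(n);
  int r = 0; // row of the sentinel suffix, SA[0] = n
  for (int k = n - 1; k >= 0; --k) {
    int c = bwt[r];
    text[k] = c;
    r = Cc[c] + rank[r];
  }
  return text;
}

// ---------------------------------------------------------------------------
// Queries
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_occ(List fm, int symbol, int position) {
  FMView v = fm_view(fm);
  if (position < 0 || position > v.nb)
    stop("occ position out of range [0, %d]", v.nb);
  return v.occ(symbol, position);
}

// [[Rcpp::export]]
IntegerVector cpp_backward_ext(List fm, int low, int high, int symbol) {
  FMView v = fm_view(fm);
  int l2, h2;
  v.ext(low, high, symbol, l2, h2);
  return IntegerVector::create(l2, h2);
}

// [[Rcpp::export]]
IntegerVector cpp_exact_search(List fm, IntegerVector query) {
  FMView v = fm_view(fm);
  int low = 0, high = v.nb;
  for (int i = query.size() - 1; i >= 0; --i) {
    int c = query[i];
    if (c > 3) { low = high = 0; break; }
    v.ext(low, high, c, low, high);
    if (low >= high) { low = high = 0; break; }
  }
  return IntegerVector::create(low, high);
}

// [[Rcpp::export]]
IntegerVector cpp_sa_lookup(List fm, IntegerVector rows) {
  FMView v = fm_view(fm);
  IntegerVector out(rows.size());
  for (int i = 0; i < rows.size(); ++i) {
    int r = rows[i];
    if (r < 0 || r >= v.nb) stop("SA row %d out of range [0, %d]", r, v.nb - 1);
    out[i] = v.sa_at(r);
  }
  return out;
}

// Per-position lower bound on differences, computed by a restart-on-empty
// prefix walk over the reverse-text index.
// [[Rcpp::export]]
IntegerVector cpp_lower_bound(List fm_rev, IntegerVector query) {
  FMView v = fm_view(fm_rev);
  int m = query.size();
  IntegerVector d(m);
  int low = 0, high = v.nb, z = 0;
  for (int i = 0; i < m; ++i) {
    int c = query[i];
    if (c > 3) {
      low = high = -1; // force restart: N occurs nowhere
    } else {
      v.ext(low, high, c, low, high);
    }
    if (low >= high) {
      ++z;
      low = 0; high = v.nb;
    }
    d[i] = z;
  }
  return d;
}

// ---------------------------------------------------------------------------
// Difference-bound inexact search
// ---------------------------------------------------------------------------

struct SearchOpts {
  int z;
  bool gaps;
  int max_gapo, max_gape;
  int pen_mm, pen_go, pen_ge;
  int k_end;       // no gaps within this many bases of either read end
  bool subopt;     // keep hits with n_diff <= best + 1
};

static SearchOpts parse_opts(const List& opts, int z) {
  SearchOpts o;
  o.z = z;
  o.max_gapo = as<int>(opts["max_gap_opens"]);
  o.max_gape = as<int>(opts["max_gap_extensions"]);
  o.gaps = as<bool>(opts["gap_open_allowed"]) && o.max_gapo > 0;
  o.pen_mm = as<int>(opts["pen_mismatch"]);
  o.pen_go = as<int>(opts["pen_gap_open"]);
  o.pen_ge = as<int>(opts["pen_gap_extend"]);
  o.k_end = as<int>(opts["no_indel_end"]);
  o.subopt = as<bool>(opts["report_suboptimal"]);
  return o;
}

enum { ST_M = 0, ST_I = 1, ST_D = 2 };

struct Hit {
  int i, low, high, state, mm, go, ge, ins_b, del_b, score;
  bool operator<(const Hit& o) const {
    if (i != o.i) return i < o.i;
    if (low != o.low) return low < o.low;
    if (high != o.high) return high < o.high;
    if (state != o.state) return state < o.state;
    if (mm != o.mm) return mm < o.mm;
    if (go != o.go) return go < o.go;
    if (ge != o.ge) return ge < o.ge;
    if (ins_b != o.ins_b) return ins_b < o.ins_b;
    return del_b < o.del_b;
  }
  bool operator==(const Hit& o) const {
    return i == o.i && low == o.low && high == o.high && state == o.state &&
           mm == o.mm && go == o.go && ge == o.ge && ins_b == o.ins_b &&
           del_b == o.del_b;
  }
};

struct DfsCtx {
  FMView fm;
  const int* q;
  int m;
  const int* d; // lower bound for prefix q[0..i-1] is d[i-1]; 0 when i == 0
  SearchOpts opt;
  int i_target;
  int best; // best completed n_diff so far (INT_MAX if none)
  std::vector<Hit> out;
  int cur_frames, peak_frames;
  long long nodes, node_cap;

  inline int allowed() const {
    if (best == INT_MAX) return opt.z;
    return opt.subopt ? std::min(opt.z, best + 1) : best;
  }
  inline int lb(int i) const { return i > 0 ? d[i - 1] : 0; }
};

struct ChildOp {
  int pen;      // added penalty
  int cls;      // 0 match, 1 mismatch, 2 insertion, 3 deletion
  int sym;      // symbol extended with (-1 for insertion)
  bool open;    // gap open (vs extend)
};

static void dfs_rec(DfsCtx& ctx, int i, int low, int high, int state,
                    int mm, int go, int ge, int ins_b, int del_b, int score) {
  int nd = mm + go + ge;
  if (nd > ctx.allowed()) return;
  if (nd + ctx.lb(i) > ctx.allowed()) return;
  if (++ctx.nodes > ctx.node_cap)
    stop("search node budget exceeded; raise max_nodes or lower max_diff");

  if (i == ctx.i_target) {
    Hit h = {i, low, high, state, mm, go, ge, ins_b, del_b, score};
    ctx.out.push_back(h);
    if (i == 0 && nd < ctx.best) ctx.best = nd;
    return;
  }

  const SearchOpts& o = ctx.opt;
  int c = ctx.q[i - 1];
  int m = ctx.m, k = o.k_end;
  bool ins_ok = o.gaps && (i - 1 >= k) && (i <= m - k);
  bool del_ok = o.gaps && (i >= k) && (i <= m - k);

  ChildOp ops[12];
  int nops = 0;
  if (c <= 3) ops[nops++] = {0, 0, c, false};
  for (int s = 0; s < 4; ++s)
    if (s != c) ops[nops++] = {o.pen_mm, 1, s, false};
  if (ins_ok) {
    if (state == ST_I && ge < o.max_gape) ops[nops++] = {o.pen_ge, 2, -1, false};
    if (state == ST_M && go < o.max_gapo) ops[nops++] = {o.pen_go, 2, -1, true};
  }
  if (del_ok) {
    if (state == ST_D && ge < o.max_gape)
      for (int s = 0; s < 4; ++s) ops[nops++] = {o.pen_ge, 3, s, false};
    if (state == ST_M && go < o.max_gapo)
      for (int s = 0; s < 4; ++s) ops[nops++] = {o.pen_go, 3, s, true};
  }
  // best-first child order: ascending added penalty; ties by class
  // (exact, mismatch, insertion, deletion) then symbol order A<C<G<T
  std::stable_sort(ops, ops + nops, [](const ChildOp& a, const ChildOp& b) {
    if (a.pen != b.pen) return a.pen < b.pen;
    if (a.cls != b.cls) return a.cls < b.cls;
    return a.sym < b.sym;
  });

  for (int j = 0; j < nops; ++j) {
    const ChildOp& op = ops[j];
    if (op.cls == 2) { // insertion: consume query base, keep interval
      ctx.cur_frames++;
      ctx.peak_frames = std::max(ctx.peak_frames, ctx.cur_frames);
      dfs_rec(ctx, i - 1, low, high, ST_I, mm, go + (op.open ? 1 : 0),
              ge + (op.open ? 0 : 1), ins_b + 1, del_b, score + op.pen);
      ctx.cur_frames--;
    } else {
      int l2, h2;
      ctx.fm.ext(low, high, op.sym, l2, h2);
      if (l2 >= h2) continue;
      if (op.cls == 3) { // deletion: consume reference base only
        dfs_rec(ctx, i, l2, h2, ST_D, mm, go + (op.open ? 1 : 0),
                ge + (op.open ? 0 : 1), ins_b, del_b + 1, score + op.pen);
      } else {
        ctx.cur_frames++;
        ctx.peak_frames = std::max(ctx.peak_frames, ctx.cur_frames);
        dfs_rec(ctx, i - 1, l2, h2, ST_M, mm + (op.cls == 1 ? 1 : 0), go, ge,
                ins_b, del_b, score + op.pen);
        ctx.cur_frames--;
      }
    }
  }
}

static List hits_to_list(std::vector<Hit>& hits, int peak, int best) {
  std::sort(hits.begin(), hits.end());
  hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
  int nh = hits.size();
  IntegerMatrix mat(nh, 10);
  colnames(mat) = CharacterVector::create("i", "low", "high", "state", "n_mm",
                                          "n_gapo", "n_gape", "n_ins_b",
                                          "n_del_b", "score");
  for (int r = 0; r < nh; ++r) {
    const Hit& h = hits[r];
    mat(r, 0) = h.i;    mat(r, 1) = h.low;   mat(r, 2) = h.high;
    mat(r, 3) = h.state; mat(r, 4) = h.mm;   mat(r, 5) = h.go;
    mat(r, 6) = h.ge;   mat(r, 7) = h.ins_b; mat(r, 8) = h.del_b;
    mat(r, 9) = h.score;
  }
  return List::create(_["hits"] = mat, _["peak_nodes"] = peak,
                      _["best"] = best == INT_MAX ? NA_INTEGER : best);
}

// Bounded DFS from an arbitrary resume node down to query index i_target.
// node = (i, low, high, state, n_mm, n_gapo, n_gape, n_ins_b, n_del_b, score).
// [[Rcpp::export]]
List cpp_dfs_segment(List fm, IntegerVector query, IntegerVector dbound,
                     IntegerVector node, int i_target, List opts, int z,
                     int best_in, double node_cap) {
  DfsCtx ctx;
  ctx.fm = fm_view(fm);
  ctx.q = INTEGER(query);
  ctx.m = query.size();
  ctx.d = INTEGER(dbound);
  ctx.opt = parse_opts(opts, z);
  ctx.i_target = i_target;
  ctx.best = best_in < 0 ? INT_MAX : best_in;
  ctx.cur_frames = 1;
  ctx.peak_frames = 1;
  ctx.nodes = 0;
  ctx.node_cap = (long long)node_cap;
  dfs_rec(ctx, node[0], node[1], node[2], node[3], node[4], node[5], node[6],
          node[7], node[8], node[9]);
  return hits_to_list(ctx.out, ctx.peak_frames, ctx.best);
}

// ---------------------------------------------------------------------------
// BFS reference implementation (frontier queue, best-score-first)
// ---------------------------------------------------------------------------

struct BfsNode {
  int i, low, high, state, mm, go, ge, ins_b, del_b, score;
  long long seq;
};
struct BfsCmp {
  bool operator()(const BfsNode& a, const BfsNode& b) const {
    if (a.score != b.score) return a.score > b.score; // min-heap on score
    return a.seq > b.seq;                             // FIFO tie-break
  }
};

// [[Rcpp::export]]
List cpp_bfs(List fm, IntegerVector query, IntegerVector dbound, List opts,
             int z, double frontier_cap) {
  FMView v = fm_view(fm);
  SearchOpts o = parse_opts(opts, z);
  const int* q = INTEGER(query);
  const int* d = INTEGER(dbound);
  int m = query.size();
  int best = INT_MAX;
  size_t peak = 0;
  long long seq = 0;
  std::vector<Hit> hits;
  std::priority_queue<BfsNode, std::vector<BfsNode>, BfsCmp> pq;
  pq.push({m, 0, v.nb, ST_M, 0, 0, 0, 0, 0, 0, seq++});
  peak = 1;

  auto allowed = [&]() {
    if (best == INT_MAX) return o.z;
    return o.subopt ? std::min(o.z, best + 1) : best;
  };
  auto lb = [&](int i) { return i > 0 ? d[i - 1] : 0; };

  while (!pq.empty()) {
    BfsNode nd = pq.top();
    pq.pop();
    int ndiff = nd.mm + nd.go + nd.ge;
    if (ndiff > allowed() || ndiff + lb(nd.i) > allowed()) continue;
    if (nd.i == 0) {
      hits.push_back({0, nd.low, nd.high, nd.state, nd.mm, nd.go, nd.ge,
                      nd.ins_b, nd.del_b, nd.score});
      if (ndiff < best) best = ndiff;
      continue;
    }
    int c = q[nd.i - 1];
    int k = o.k_end, i = nd.i;
    bool ins_ok = o.gaps && (i - 1 >= k) && (i <= m - k);
    bool del_ok = o.gaps && (i >= k) && (i <= m - k);
    auto push = [&](BfsNode child) {
      int cd = child.mm + child.go + child.ge;
      if (cd > allowed() || cd + lb(child.i) > allowed()) return;
      child.seq = seq++;
      pq.push(child);
      if (pq.size() > (size_t)frontier_cap)
        stop("BFS frontier exceeded %0.f stored nodes", frontier_cap);
      peak = std::max(peak, pq.size());
    };
    for (int s = 0; s < 4; ++s) {
      int l2, h2;
      v.ext(nd.low, nd.high, s, l2, h2);
      if (l2 < h2) {
        bool mis = (s != c);
        push({i - 1, l2, h2, ST_M, nd.mm + (mis ? 1 : 0), nd.go, nd.ge,
              nd.ins_b, nd.del_b, nd.score + (mis ? o.pen_mm : 0), 0});
      }
      if (del_ok && l2 < h2) {
        if (nd.state == ST_M && nd.go < o.max_gapo)
          push({i, l2, h2, ST_D, nd.mm, nd.go + 1, nd.ge, nd.ins_b,
                nd.del_b + 1, nd.score + o.pen_go, 0});
        if (nd.state == ST_D && nd.ge < o.max_gape)
          push({i, l2, h2, ST_D, nd.mm, nd.go, nd.ge + 1, nd.ins_b,
                nd.del_b + 1, nd.score + o.pen_ge, 0});
      }
    }
    if (ins_ok) {
      if (nd.state == ST_M && nd.go < o.max_gapo)
        push({i - 1, nd.low, nd.high, ST_I, nd.mm, nd.go + 1, nd.ge,
              nd.ins_b + 1, nd.del_b, nd.score + o.pen_go, 0});
      if (nd.state == ST_I && nd.ge < o.max_gape)
        push({i - 1, nd.low, nd.high, ST_I, nd.mm, nd.go, nd.ge + 1,
              nd.ins_b + 1, nd.del_b, nd.score + o.pen_ge, 0});
    }
  }
  return hits_to_list(hits, (int)peak, best);
}
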