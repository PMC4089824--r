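// Core parsimony machinery: Hartigan (degree-general Fitch) lengths,
// uniform-cost Sankoff edge analysis (ambiguity / forced changes),
// Wagner stepwise addition, TBR branch swapping and exhaustive enumeration.
//
// Character data arrive as bitmask matrices (bit s set <=> state s allowed
// at that tip); missing / inapplicable cells carry the full observed-state
// mask of their column, which makes them optimization-neutral.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <deque>
#include <string>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

static const int BIG = 100000000;

// ---------------------------------------------------------------------------
// Rooted trees from ape edge matrices (1-based ids; tips 1..nTip)
// ---------------------------------------------------------------------------

struct Rooted {
  int nNode, nTip, root;
  std::vector<std::vector<int>> kids;  // 0-based
  std::vector<int> parent;
  std::vector<int> post;               // children-before-parents order
};

static Rooted buildRooted(const IntegerMatrix& edge, int nTip) {
  int nNode = nTip;
  for (int i = 0; i < edge.nrow(); i++)
    nNode = std::max(nNode, std::max(edge(i, 0), edge(i, 1)));
  Rooted t;
  t.nNode = nNode; t.nTip = nTip;
  t.kids.assign(nNode, {});
  t.parent.assign(nNode, -1);
  for (int i = 0; i < edge.nrow(); i++) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    if (p < 0 || c < 0 || p >= nNode || c >= nNode) stop("bad edge matrix");
    t.kids[p].push_back(c);
    t.parent[c] = p;
  }
  t.root = -1;
  for (int v = nTip; v < nNode; v++)
    if (!t.kids[v].empty() && t.parent[v] < 0) { t.root = v; break; }
  if (t.root < 0) stop("no root found in edge matrix");
  std::vector<int> stk = { t.root };
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    t.post.push_back(v);
    for (int c : t.kids[v]) stk.push_back(c);
  }
  std::reverse(t.post.begin(), t.post.end());
  return t;
}

// Hartigan pass for one character; returns unweighted step count.
static int hartiganChar(const Rooted& t, const IntegerMatrix& masks, int chr,
                        int nStates, std::vector<uint16_t>& S) {
  int cost = 0;
  for (int v : t.post) {
    if (t.kids[v].empty()) { S[v] = (uint16_t) masks(v, chr); continue; }
    int cnt[16] = {0};
    for (int k : t.kids[v]) {
      uint16_t m = S[k];
      for (int s = 0; s < nStates; s++) if ((m >> s) & 1) cnt[s]++;
    }
    int K = 0;
    for (int s = 0; s < nStates; s++) if (cnt[s] > K) K = cnt[s];
    uint16_t m = 0;
    for (int s = 0; s < nStates; s++) if (cnt[s] == K) m |= (uint16_t)(1 << s);
    S[v] = m;
    cost += (int) t.kids[v].size() - K;
  }
  return cost;
}

// [[Rcpp::export]]
List c_hartigan(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                IntegerVector weights, int nStates) {
  Rooted t = buildRooted(edge, nTip);
  int nChar = masks.ncol();
  IntegerVector per(nChar);
  std::vector<uint16_t> S(t.nNode);
  double total = 0;
  for (int c = 0; c < nChar; c++) {
    per[c] = hartiganChar(t, masks, c, nStates, S);
    total += (double) per[c] * weights[c];
  }
  return List::create(_["per_char"] = per, _["total"] = total);
}

// ---------------------------------------------------------------------------
// Uniform-cost Sankoff up/down pass: per-edge forced-change flags, derived
// state sets, per-node MPR state sets.  Degree-general (works on polytomies).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List c_edge_analysis(IntegerMatrix edge, int nTip, IntegerMatrix masks, int nStates) {
  Rooted t = buildRooted(edge, nTip);
  int nChar = masks.ncol(), nE = edge.nrow(), nN = t.nNode;
  IntegerVector perLen(nChar);
  IntegerMatrix forced(nE, nChar), zeromin(nE, nChar),
                derived(nE, nChar), fromSt(nE, nChar), nodeSets(nN, nChar);
  std::vector<int> childOf(nE);
  for (int i = 0; i < nE; i++) childOf[i] = edge(i, 1) - 1;

  std::vector<int> down(nN * nStates), up(nN * nStates), U(nN * nStates),
                   sumW(nN * nStates), w(nN * nStates), mind(nN);
  std::vector<int> pre(t.post.rbegin(), t.post.rend());  // parents first

  for (int chr = 0; chr < nChar; chr++) {
    // down pass
    for (int v : t.post) {
      if (t.kids[v].empty()) {
        int m = masks(v, chr);
        for (int s = 0; s < nStates; s++)
          down[v * nStates + s] = ((m >> s) & 1) ? 0 : BIG;
      } else {
        for (int s = 0; s < nStates; s++) sumW[v * nStates + s] = 0;
        for (int k : t.kids[v]) {
          int mk = BIG;
          for (int s = 0; s < nStates; s++) mk = std::min(mk, down[k * nStates + s]);
          mind[k] = mk;
          for (int s = 0; s < nStates; s++) {
            w[k * nStates + s] = std::min(down[k * nStates + s], mk + 1);
            sumW[v * nStates + s] += w[k * nStates + s];
          }
        }
        for (int s = 0; s < nStates; s++) down[v * nStates + s] = sumW[v * nStates + s];
      }
    }
    int tot = BIG;
    for (int s = 0; s < nStates; s++) tot = std::min(tot, down[t.root * nStates + s]);
    perLen[chr] = tot;

    // up pass: U[c][s] = cost of tree minus subtree(c), parent of c in state s
    for (int s = 0; s < nStates; s++) up[t.root * nStates + s] = 0;
    for (int v : pre) {
      for (int k : t.kids[v]) {
        int mu = BIG;
        for (int s = 0; s < nStates; s++) {
          U[k * nStates + s] = up[v * nStates + s] + sumW[v * nStates + s] - w[k * nStates + s];
          mu = std::min(mu, U[k * nStates + s]);
        }
        for (int s = 0; s < nStates; s++)
          up[k * nStates + s] = std::min(U[k * nStates + s], mu + 1);
      }
    }
    // node MPR sets
    for (int v = 0; v < nN; v++) {
      if (t.kids[v].empty() && t.parent[v] < 0) { nodeSets(v, chr) = 0; continue; }
      int m = 0;
      for (int s = 0; s < nStates; s++) {
        int upv = (v == t.root) ? 0 : up[v * nStates + s];
        if (down[v * nStates + s] < BIG && upv < BIG &&
            down[v * nStates + s] + upv == tot) m |= (1 << s);
      }
      nodeSets(v, chr) = m;
    }
    // per-edge analysis
    for (int e = 0; e < nE; e++) {
      int c = childOf[e];
      int minU1 = BIG, minU2 = BIG, cntU = 0, minD1 = BIG, minD2 = BIG, cntD = 0;
      for (int s = 0; s < nStates; s++) {
        int u = U[c * nStates + s];
        if (u < minU1) { minU2 = minU1; minU1 = u; cntU = 1; }
        else if (u == minU1) cntU++;
        else if (u < minU2) minU2 = u;
        int d = down[c * nStates + s];
        if (d < minD1) { minD2 = minD1; minD1 = d; cntD = 1; }
        else if (d == minD1) cntD++;
        else if (d < minD2) minD2 = d;
      }
      int A = BIG;
      for (int s = 0; s < nStates; s++) {
        int u = U[c * nStates + s], d = down[c * nStates + s];
        if (u < BIG && d < BIG) A = std::min(A, u + d);
      }
      zeromin(e, chr) = (A == tot) ? 1 : 0;
      forced(e, chr)  = (A > tot) ? 1 : 0;
      int dm = 0, fm = 0;
      for (int s = 0; s < nStates; s++) {
        int d = down[c * nStates + s];
        if (d < BIG) {
          int uExcl = (U[c * nStates + s] == minU1 && cntU == 1) ? minU2 : minU1;
          if (uExcl < BIG && d + uExcl + 1 == tot) dm |= (1 << s);
        }
        int u = U[c * nStates + s];
        if (u < BIG) {
          int dExcl = (down[c * nStates + s] == minD1 && cntD == 1) ? minD2 : minD1;
          if (dExcl < BIG && u + dExcl + 1 == tot) fm |= (1 << s);
        }
      }
      derived(e, chr) = dm;
      fromSt(e, chr)  = fm;
    }
  }
  return List::create(_["per_char"] = perLen, _["forced"] = forced,
                      _["zero_min"] = zeromin, _["derived"] = derived,
                      _["from"] = fromSt, _["node_sets"] = nodeSets);
}

// ---------------------------------------------------------------------------
// Unrooted binary trees for search: leaves 0..nTip-1, internals nTip..2nTip-3
// ---------------------------------------------------------------------------

struct UTree {
  int nTip;
  std::vector<std::array<int, 3>> nb;  // -1 = empty slot; slots kept compact
};

static void addN(UTree& T, int v, int u) {
  for (int j = 0; j < 3; j++) if (T.nb[v][j] < 0) { T.nb[v][j] = u; return; }
  stop("internal error: node full");
}
static void delN(UTree& T, int v, int u) {
  for (int j = 0; j < 3; j++) if (T.nb[v][j] == u) {
    for (int k = j; k < 2; k++) T.nb[v][k] = T.nb[v][k + 1];
    T.nb[v][2] = -1;
    return;
  }
  stop("internal error: neighbor absent");
}
static int degreeOf(const UTree& T, int v) {
  int d = 0;
  for (int j = 0; j < 3; j++) if (T.nb[v][j] >= 0) d++;
  return d;
}

static UTree fromApeEdge(const IntegerMatrix& edge, int nTip) {
  int nNode = nTip;
  for (int i = 0; i < edge.nrow(); i++)
    nNode = std::max(nNode, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int>> adj(nNode);
  for (int i = 0; i < edge.nrow(); i++) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    adj[p].push_back(c); adj[c].push_back(p);
  }
  // suppress a degree-2 root (rooted binary input)
  for (int v = nTip; v < nNode; v++) {
    if (adj[v].size() == 2) {
      int a = adj[v][0], b = adj[v][1];
      adj[v].clear();
      std::replace(adj[a].begin(), adj[a].end(), v, b);
      std::replace(adj[b].begin(), adj[b].end(), v, a);
    }
  }
  UTree T; T.nTip = nTip;
  T.nb.assign(2 * nTip - 2, { -1, -1, -1 });
  std::vector<int> map(nNode, -1);
  for (int v = 0; v < nTip; v++) map[v] = v;
  int next = nTip;
  for (int v = nTip; v < nNode; v++)
    if (adj[v].size() == 3) map[v] = next++;
  if (next != 2 * nTip - 2) stop("tree is not a binary unrooted topology");
  for (int v = 0; v < nNode; v++) {
    if (map[v] < 0) continue;
    if (v < nTip && adj[v].size() != 1) stop("tip of degree != 1");
    for (size_t j = 0; j < adj[v].size(); j++) T.nb[map[v]][j] = map[adj[v][j]];
  }
  return T;
}

static IntegerMatrix toApeEdge(const UTree& T) {
  int nTip = T.nTip, nE = 2 * nTip - 3;
  IntegerMatrix edge(nE, 2);
  int root = T.nb[0][0];  // internal neighbor of leaf 0 becomes the basal node
  std::vector<int> map(2 * nTip - 2, -1);
  for (int v = 0; v < nTip; v++) map[v] = v + 1;
  int nextId = nTip + 1, row = 0;
  std::vector<std::pair<int, int>> stk = { { -1, root } };
  while (!stk.empty()) {
    auto pc = stk.back(); stk.pop_back();
    int par = pc.first, v = pc.second;
    if (v >= nTip) map[v] = nextId++;
    if (par >= 0) { edge(row, 0) = map[par]; edge(row, 1) = map[v]; row++; }
    if (v >= nTip)
      for (int j = 2; j >= 0; j--) {
        int u = T.nb[v][j];
        if (u >= 0 && u != par) stk.push_back({ v, u });
      }
  }
  if (row != nE) stop("internal error: edge conversion");
  return edge;
}

// Fitch length of a binary unrooted tree, weighted total.
static double fitchLenU(const UTree& T, const IntegerMatrix& masks,
                        const IntegerVector& weights) {
  int nTip = T.nTip, nChar = masks.ncol();
  int root = T.nb[0][0];
  // postorder from root, parent = leaf 0 side
  std::vector<int> parent(2 * nTip - 2, -2), order;
  parent[root] = 0;
  std::vector<int> stk = { root };
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    order.push_back(v);
    if (v >= nTip)
      for (int j = 0; j < 3; j++) {
        int u = T.nb[v][j];
        if (u >= 0 && u != parent[v]) { parent[u] = v; stk.push_back(u); }
      }
  }
  std::reverse(order.begin(), order.end());
  std::vector<uint16_t> S(2 * nTip - 2);
  double total = 0;
  for (int c = 0; c < nChar; c++) {
    int cost = 0;
    for (int v : order) {
      if (v < nTip) { S[v] = (uint16_t) masks(v, c); continue; }
      uint16_t m = 0xFFFF; bool first = true;
      for (int j = 0; j < 3; j++) {
        int u = T.nb[v][j];
        if (u < 0 || u == parent[v]) continue;
        if (first) { m = S[u]; first = false; }
        else {
          uint16_t inter = m & S[u];
          if (inter) m = inter; else { m |= S[u]; cost++; }
        }
      }
      S[v] = m;
    }
    uint16_t rootm = S[root];
    if (!((uint16_t) masks(0, c) & rootm)) cost++;
    total += (double) cost * weights[c];
  }
  return total;
}

// ---------------------------------------------------------------------------
// Directed Fitch state sets over a component (for TBR / Wagner evaluation)
// ---------------------------------------------------------------------------

struct CompFitch {
  std::vector<std::pair<int, int>> edges;  // (parent-side, child-side), DFS order
  std::vector<uint16_t> rootset;           // edges x nChar: set when rooting on edge
  double L;                                // weighted component length
  int singleton;                           // leaf id when the component is one leaf
};

// adjacency passed as UTree-like nb array; 'start' must be a leaf of the component
static void compFitch(const std::vector<std::array<int, 3>>& nb, int nTip, int start,
                      const IntegerMatrix& masks, const IntegerVector& weights,
                      CompFitch& out) {
  int nChar = masks.ncol();
  out.edges.clear(); out.L = 0; out.singleton = -1;
  if (nb[start][0] < 0) { out.singleton = start; return; }
  // DFS from start
  int maxN = (int) nb.size();
  std::vector<int> parent(maxN, -2), order;
  parent[start] = -1;
  std::vector<int> stk = { start };
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    order.push_back(v);
    for (int j = 0; j < 3; j++) {
      int u = nb[v][j];
      if (u >= 0 && u != parent[v] && parent[u] == -2) { parent[u] = v; stk.push_back(u); }
    }
  }
  for (int v : order)
    if (v != start) out.edges.push_back({ parent[v], v });
  int nE = (int) out.edges.size();
  // up masks: subtree on child side (indexed per node), down masks per node
  std::vector<uint16_t> up(maxN * nChar), dn(maxN * nChar);
  std::vector<int> postorder(order.rbegin(), order.rend());
  for (int c = 0; c < nChar; c++) {
    int cost = 0;
    for (int v : postorder) {
      if (v == start) continue;
      if (v < nTip) { up[v * nChar + c] = (uint16_t) masks(v, c); continue; }
      uint16_t m = 0; bool first = true;
      for (int j = 0; j < 3; j++) {
        int u = nb[v][j];
        if (u < 0 || u == parent[v]) continue;
        if (first) { m = up[u * nChar + c]; first = false; }
        else {
          uint16_t inter = m & up[u * nChar + c];
          if (inter) m = inter; else { m |= up[u * nChar + c]; cost++; }
        }
      }
      up[v * nChar + c] = m;
    }
    // root contribution at the start leaf
    int cs = nb[start][0];
    if (!((uint16_t) masks(start, c) & up[cs * nChar + c])) cost++;
    out.L += (double) cost * weights[c];
    // down masks, preorder; the start leaf feeds its single neighbor directly
    dn[start * nChar + c] = (uint16_t) masks(start, c);
    dn[cs * nChar + c] = (uint16_t) masks(start, c);
    for (int v : order) {
      if (v < nTip) continue;
      // children of v
      for (int j = 0; j < 3; j++) {
        int u = nb[v][j];
        if (u < 0 || u == parent[v]) continue;
        // combine parent-down with siblings' up
        uint16_t m = dn[v * nChar + c]; bool first = false;
        for (int k = 0; k < 3; k++) {
          int w2 = nb[v][k];
          if (w2 < 0 || w2 == u || w2 == parent[v]) continue;
          uint16_t o = up[w2 * nChar + c];
          uint16_t inter = m & o;
          if (inter) m = inter; else m |= o;
          (void) first;
        }
        dn[u * nChar + c] = m;
      }
    }
  }
  out.rootset.assign((size_t) nE * nChar, 0);
  for (int e = 0; e < nE; e++) {
    int p = out.edges[e].first, v = out.edges[e].second;
    for (int c = 0; c < nChar; c++) {
      uint16_t a = up[v * nChar + c], b = dn[v * nChar + c];
      uint16_t inter = a & b;
      out.rootset[(size_t) e * nChar + c] = inter ? inter : (uint16_t)(a | b);
      (void) p;
    }
  }
}

// ---------------------------------------------------------------------------
// Wagner stepwise addition
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix c_wagner(IntegerMatrix masks, IntegerVector weights,
                       IntegerVector order0, int nStates) {
  int nTip = masks.nrow(), nChar = masks.ncol();
  if (nTip < 4) stop("need at least 4 taxa");
  UTree T; T.nTip = nTip;
  T.nb.assign(2 * nTip - 2, { -1, -1, -1 });
  int hub = nTip;
  for (int j = 0; j < 3; j++) { addN(T, hub, order0[j]); addN(T, order0[j], hub); }
  int nextInternal = nTip + 1;
  CompFitch cf;
  for (int k = 3; k < nTip; k++) {
    int leaf = order0[k];
    compFitch(T.nb, nTip, order0[0], masks, weights, cf);
    int bestE = -1; double bestLen = 0;
    for (size_t e = 0; e < cf.edges.size(); e++) {
      double delta = 0;
      for (int c = 0; c < nChar; c++)
        if (!(cf.rootset[e * nChar + c] & (uint16_t) masks(leaf, c)))
          delta += weights[c];
      double len = cf.L + delta;
      if (bestE < 0 || len < bestLen) { bestE = (int) e; bestLen = len; }
    }
    int p = cf.edges[bestE].first, v = cf.edges[bestE].second, nn = nextInternal++;
    delN(T, p, v); delN(T, v, p);
    addN(T, nn, p); addN(T, p, nn);
    addN(T, nn, v); addN(T, v, nn);
    addN(T, nn, leaf); addN(T, leaf, nn);
  }
  return toApeEdge(T);
}

// ---------------------------------------------------------------------------
// Split keys (canonical topology identity over leaf bitsets)
// ---------------------------------------------------------------------------

static std::string splitKeyU(const UTree& T) {
  int nTip = T.nTip;
  if (nTip > 64) stop("split keys support at most 64 leaves");
  uint64_t all = (nTip == 64) ? ~0ULL : ((1ULL << nTip) - 1);
  int root = T.nb[0][0];
  std::vector<int> parent(2 * nTip - 2, -2), order;
  parent[root] = 0;
  std::vector<int> stk = { root };
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    order.push_back(v);
    if (v >= nTip)
      for (int j = 0; j < 3; j++) {
        int u = T.nb[v][j];
        if (u >= 0 && u != parent[v]) { parent[u] = v; stk.push_back(u); }
      }
  }
  std::reverse(order.begin(), order.end());
  std::vector<uint64_t> below(2 * nTip - 2, 0), keys;
  for (int v : order) {
    if (v < nTip) { below[v] = 1ULL << v; continue; }
    for (int j = 0; j < 3; j++) {
      int u = T.nb[v][j];
      if (u >= 0 && u != parent[v]) below[v] |= below[u];
    }
    uint64_t side = below[v];
    if (side & 1ULL) side = all & ~side;
    int pc = __builtin_popcountll(side);
    if (pc >= 2 && pc <= nTip - 2) keys.push_back(side);
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  std::string s;
  s.reserve(keys.size() * 8);
  for (uint64_t k : keys)
    for (int b = 0; b < 8; b++) s.push_back((char)((k >> (8 * b)) & 0xFF));
  return s;
}

// [[Rcpp::export]]
CharacterVector c_split_key(IntegerMatrix edge, int nTip) {
  UTree T = fromApeEdge(edge, nTip);
  std::string k = splitKeyU(T);
  std::string hex;
  const char* d = "0123456789abcdef";
  for (unsigned char ch : k) { hex.push_back(d[ch >> 4]); hex.push_back(d[ch & 15]); }
  return CharacterVector::create(hex);
}

// ---------------------------------------------------------------------------
// TBR search
// ---------------------------------------------------------------------------

// helper: cut edge (u,v) in adjacency, suppress endpoints of degree 2
static void cutAndSuppress(std::vector<std::array<int, 3>>& nb, int nTip, int u, int v) {
  UTree tmp; tmp.nTip = nTip; tmp.nb = nb;
  delN(tmp, u, v); delN(tmp, v, u);
  for (int x : { u, v }) {
    if (x >= nTip && degreeOf(tmp, x) == 2) {
      int a = tmp.nb[x][0], b = tmp.nb[x][1];
      delN(tmp, x, a); delN(tmp, x, b);
      delN(tmp, a, x); delN(tmp, b, x);
      addN(tmp, a, b); addN(tmp, b, a);
    }
  }
  nb = tmp.nb;
}

// find a leaf of the component containing 'node'
static int findLeaf(const std::vector<std::array<int, 3>>& nb, int nTip, int node) {
  if (node < nTip) return node;
  std::vector<int> stk = { node };
  std::vector<char> seen(nb.size(), 0);
  seen[node] = 1;
  while (!stk.empty()) {
    int x = stk.back(); stk.pop_back();
    if (x < nTip) return x;
    for (int j = 0; j < 3; j++) {
      int y = nb[x][j];
      if (y >= 0 && !seen[y]) { seen[y] = 1; stk.push_back(y); }
    }
  }
  stop("component without leaf");
}

// reconnect after a bisection at (u,v): comp1 reattaches on its edge e1 using
// the freed internal node u, comp2 on e2 using v (singleton components attach
// their lone leaf directly; the matching endpoint was a leaf, so its internal
// partner is the one freed node needed).
static UTree reconnect(int nTip, int u, int v,
                       const std::vector<std::array<int, 3>>& nbCut,
                       const CompFitch& f1, const CompFitch& f2,
                       int e1, int e2) {
  UTree N; N.nTip = nTip; N.nb = nbCut;
  int a1, a2;
  if (f1.singleton >= 0) a1 = f1.singleton;
  else {
    int p = f1.edges[e1].first, c = f1.edges[e1].second;
    delN(N, p, c); delN(N, c, p);
    addN(N, u, p); addN(N, p, u);
    addN(N, u, c); addN(N, c, u);
    a1 = u;
  }
  if (f2.singleton >= 0) a2 = f2.singleton;
  else {
    int p = f2.edges[e2].first, c = f2.edges[e2].second;
    delN(N, p, c); delN(N, c, p);
    addN(N, v, p); addN(N, p, v);
    addN(N, v, c); addN(N, c, v);
    a2 = v;
  }
  addN(N, a1, a2); addN(N, a2, a1);
  return N;
}

// enumerate undirected edges of T deterministically (DFS from leaf 0)
static std::vector<std::pair<int, int>> edgesOf(const UTree& T) {
  int nTip = T.nTip;
  std::vector<std::pair<int, int>> E;
  std::vector<int> parent(2 * nTip - 2, -2);
  parent[0] = -1;
  std::vector<int> stk = { 0 };
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    for (int j = 0; j < 3; j++) {
      int u = T.nb[v][j];
      if (u >= 0 && u != parent[v] && parent[u] == -2) {
        parent[u] = v;
        E.push_back({ v, u });
        stk.push_back(u);
      }
    }
  }
  return E;
}

struct SearchState {
  std::vector<UTree> pool;
  std::vector<std::string> keys;
  std::unordered_set<std::string> keyset;
  std::deque<int> queue;
  double best = 1e18;
  bool hitCap = false;
  int hold;
};

static bool tryAdd(SearchState& S, const UTree& t, double len) {
  // returns true when len improved the pool (reset happened)
  if (len < S.best - 1e-9) {
    S.best = len;
    S.pool.clear(); S.keys.clear(); S.keyset.clear(); S.queue.clear();
    S.pool.push_back(t);
    S.keys.push_back(splitKeyU(t));
    S.keyset.insert(S.keys.back());
    S.queue.push_back(0);
    return true;
  }
  if (len > S.best + 1e-9) return false;
  if ((int) S.pool.size() >= S.hold) { S.hitCap = true; return false; }
  std::string k = splitKeyU(t);
  if (S.keyset.count(k)) return false;
  S.pool.push_back(t);
  S.keys.push_back(k);
  S.keyset.insert(k);
  S.queue.push_back((int) S.pool.size() - 1);
  return false;
}

// [[Rcpp::export]]
List c_tbr_search(List starts, int nTip, IntegerMatrix masks, IntegerVector weights,
                  int hold, int nStates, double maxRounds) {
  int nChar = masks.ncol();
  SearchState S; S.hold = hold;
  for (int i = 0; i < starts.size(); i++) {
    UTree t = fromApeEdge(as<IntegerMatrix>(starts[i]), nTip);
    tryAdd(S, t, fitchLenU(t, masks, weights));
  }
  double rounds = 0;
  CompFitch f1, f2;
  while (!S.queue.empty() && rounds < maxRounds) {
    Rcpp::checkUserInterrupt();
    rounds += 1;
    int idx = S.queue.front(); S.queue.pop_front();
    UTree T = S.pool[idx];  // copy: pool may be cleared on improvement
    std::vector<std::pair<int, int>> E = edgesOf(T);
    bool improved = false;
    for (size_t ei = 0; ei < E.size() && !improved; ei++) {
      int u = E[ei].first, v = E[ei].second;
      std::vector<std::array<int, 3>> nbCut = T.nb;
      cutAndSuppress(nbCut, nTip, u, v);
      // a suppressed internal endpoint is isolated: reach its component
      // through one of its former neighbors; leaf endpoints are their own
      // singleton component.
      int c1node = u, c2node = v;
      if (u >= nTip && nbCut[u][0] < 0) {
        for (int j = 0; j < 3; j++) {
          int w2 = T.nb[u][j];
          if (w2 >= 0 && w2 != v) { c1node = w2; break; }
        }
      }
      if (v >= nTip && nbCut[v][0] < 0) {
        for (int j = 0; j < 3; j++) {
          int w2 = T.nb[v][j];
          if (w2 >= 0 && w2 != u) { c2node = w2; break; }
        }
      }
      int leaf1 = findLeaf(nbCut, nTip, c1node);
      int leaf2 = findLeaf(nbCut, nTip, c2node);
      compFitch(nbCut, nTip, leaf1, masks, weights, f1);
      compFitch(nbCut, nTip, leaf2, masks, weights, f2);
      double base = f1.L + f2.L;
      double m1 = (f1.singleton >= 0) ? 1 : (double) f1.edges.size();
      double m2 = (f2.singleton >= 0) ? 1 : (double) f2.edges.size();
      for (int e1 = 0; e1 < (int) m1 && !improved; e1++) {
        const uint16_t* rs1 = (f1.singleton >= 0) ? nullptr : &f1.rootset[(size_t) e1 * nChar];
        for (int e2 = 0; e2 < (int) m2 && !improved; e2++) {
          const uint16_t* rs2 = (f2.singleton >= 0) ? nullptr : &f2.rootset[(size_t) e2 * nChar];
          double delta = 0;
          for (int c = 0; c < nChar; c++) {
            uint16_t a = rs1 ? rs1[c] : (uint16_t) masks(f1.singleton, c);
            uint16_t b = rs2 ? rs2[c] : (uint16_t) masks(f2.singleton, c);
            if (!(a & b)) delta += weights[c];
          }
          double len = base + delta;
          if (len > S.best + 1e-9) continue;
          UTree N = reconnect(nTip, u, v, nbCut, f1, f2,
                              (f1.singleton >= 0) ? -1 : e1,
                              (f2.singleton >= 0) ? -1 : e2);
          if (tryAdd(S, N, len)) improved = true;
        }
      }
    }
  }
  List trees(S.pool.size());
  for (size_t i = 0; i < S.pool.size(); i++) trees[i] = toApeEdge(S.pool[i]);
  return List::create(_["best_length"] = S.best, _["trees"] = trees,
                      _["hit_cap"] = S.hitCap,
                      _["closed"] = S.queue.empty());
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration (small n)
// ---------------------------------------------------------------------------

static void exhaustRec(UTree& T, int k, int nextInternal,
                       const IntegerMatrix& masks, const IntegerVector& weights,
                       double& best, std::vector<UTree>& opt, double& count,
                       int keepMax) {
  int nTip = T.nTip;
  if (k == nTip) {
    count += 1;
    double len = fitchLenU(T, masks, weights);
    if (len < best - 1e-9) { best = len; opt.clear(); }
    if (std::abs(len - best) <= 1e-9 && (int) opt.size() < keepMax) opt.push_back(T);
    return;
  }
  std::vector<std::pair<int, int>> E = edgesOf(T);
  for (auto& e : E) {
    int p = e.first, v = e.second, nn = nextInternal;
    delN(T, p, v); delN(T, v, p);
    addN(T, nn, p); addN(T, p, nn);
    addN(T, nn, v); addN(T, v, nn);
    addN(T, nn, k); addN(T, k, nn);
    exhaustRec(T, k + 1, nextInternal + 1, masks, weights, best, opt, count, keepMax);
    delN(T, nn, p); delN(T, p, nn);
    delN(T, nn, v); delN(T, v, nn);
    delN(T, nn, k); delN(T, k, nn);
    addN(T, p, v); addN(T, v, p);
  }
}

// [[Rcpp::export]]
List c_exhaustive(IntegerMatrix masks, IntegerVector weights, int nStates, int keepMax) {
  int nTip = masks.nrow();
  if (nTip < 4) stop("need at least 4 taxa");
  if (nTip > 10) stop("exhaustive search limited to 10 taxa");
  UTree T; T.nTip = nTip;
  T.nb.assign(2 * nTip - 2, { -1, -1, -1 });
  int hub = nTip;
  for (int j = 0; j < 3; j++) { addN(T, hub, j); addN(T, j, hub); }
  double best = 1e18, count = 0;
  std::vector<UTree> opt;
  exhaustRec(T, 3, nTip + 1, masks, weights, best, opt, count, keepMax);
  List trees(opt.size());
  for (size_t i = 0; i < opt.size(); i++) trees[i] = toApeEdge(opt[i]);
  return List::create(_["best_length"] = best, _["trees"] = trees,
                      _["n_topologies"] = count);
}

// [[Rcpp::export]]
double c_fitch_total(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                     IntegerVector weights) {
  UTree T = fromApeEdge(edge, nTip);
  return fitchLenU(T, masks, weights);
}
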