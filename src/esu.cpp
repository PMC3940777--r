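#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive connected-subgraph enumeration (ESU) with orbit-touch
// accumulation. Every connected node subset of size 2..maxK is visited
// exactly once; the induced adjacency bitmask of the (sorted) subset is
// looked up in per-size tables that map each labelled mask to the global
// orbit index of every node position and every pair position. All orbit
// codes arriving from R are 0-based; -1 marks "no orbit" (disconnected
// mask, or a bridge edge orbit with no node-pair counterpart).

namespace {

struct EsuState {
  int n, maxK;
  const std::vector<std::vector<int> > *adj;
  std::vector<bool> adjBit;            // n*n adjacency test
  std::vector<IntegerMatrix> nodeLUT;  // [k], 2^C(k,2) x k
  std::vector<IntegerMatrix> edgeLUT;  // [k], 2^C(k,2) x C(k,2)
  std::vector<IntegerMatrix> nonEdgeLUT;
  std::vector<int> pairFromEdge;       // edge orbit -> pair orbit or -1
  std::vector<double> nodeGDV, edgeGDV, pairGDV;
  std::vector<long long> edgeId;       // n*n -> row in edgeGDV, -1 if none
  int nNodeOrb, nEdgeOrb, nPairOrb;
  bool wantNode, wantEdge, wantPair;
  std::vector<bool> blocked;           // in subgraph or neighbour of it
  long long counter;

  bool isEdge(int u, int v) const {
    return adjBit[(size_t)u * n + v];
  }
  size_t pairRow(int u, int v) const { // u < v
    return (size_t)u * (2 * (size_t)n - u - 1) / 2 + (v - u - 1);
  }

  void process(const std::vector<int> &sub) {
    int k = (int)sub.size();
    int s[5];
    for (int i = 0; i < k; ++i) s[i] = sub[i];
    std::sort(s, s + k);
    int mask = 0, p = 0;
    for (int j = 1; j < k; ++j)
      for (int i = 0; i < j; ++i, ++p)
        if (isEdge(s[i], s[j])) mask |= (1 << p);
    if (wantNode) {
      const IntegerMatrix &lut = nodeLUT[k];
      for (int i = 0; i < k; ++i) {
        int orb = lut(mask, i);
        nodeGDV[(size_t)s[i] * nNodeOrb + orb] += 1.0;
      }
    }
    if (k >= 3 && (wantEdge || wantPair)) {
      const IntegerMatrix &el = edgeLUT[k];
      const IntegerMatrix &nel = nonEdgeLUT[k];
      p = 0;
      for (int j = 1; j < k; ++j)
        for (int i = 0; i < j; ++i, ++p) {
          if (mask & (1 << p)) {
            int eo = el(mask, p);
            if (wantEdge) {
              long long row = edgeId[(size_t)s[i] * n + s[j]];
              edgeGDV[(size_t)row * nEdgeOrb + eo] += 1.0;
            }
            if (wantPair) {
              int po = pairFromEdge[eo];
              if (po >= 0)
                pairGDV[pairRow(s[i], s[j]) * nPairOrb + po] += 1.0;
            }
          } else if (wantPair) {
            int po = nel(mask, p);
            pairGDV[pairRow(s[i], s[j]) * nPairOrb + po] += 1.0;
          }
        }
    }
  }

  void extend(std::vector<int> &sub, std::vector<int> &ext, int v) {
    if ((int)sub.size() >= 2) process(sub);
    if ((int)sub.size() == maxK) return;
    if (++counter % 65536 == 0) Rcpp::checkUserInterrupt();
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> ext2 = ext;
      for (int u : (*adj)[w])
        if (u > v && !blocked[u]) ext2.push_back(u);
      sub.push_back(w);
      std::vector<int> newly;
      for (int u : (*adj)[w])
        if (!blocked[u]) { blocked[u] = true; newly.push_back(u); }
      extend(sub, ext2, v);
      sub.pop_back();
      for (int u : newly) blocked[u] = false;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".esuCount")]]
List esuCount(List adjList, int n, int maxK,
              List nodeLUT, List edgeLUT, List nonEdgeLUT,
              IntegerVector pairFromEdge, IntegerMatrix edges,
              int nNodeOrb, int nEdgeOrb, int nPairOrb,
              bool wantNode, bool wantEdge, bool wantPair) {
  EsuState st;
  st.n = n; st.maxK = maxK; st.counter = 0;
  st.nNodeOrb = nNodeOrb; st.nEdgeOrb = nEdgeOrb; st.nPairOrb = nPairOrb;
  st.wantNode = wantNode; st.wantEdge = wantEdge; st.wantPair = wantPair;

  std::vector<std::vector<int> > adj(n);
  for (int v = 0; v < n; ++v) {
    IntegerVector nb = adjList[v];
    adj[v].assign(nb.begin(), nb.end());
  }
  st.adj = &adj;
  st.adjBit.assign((size_t)n * n, false);
  int nE = edges.nrow();
  st.edgeId.assign((size_t)n * n, -1);
  for (int e = 0; e < nE; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    st.adjBit[(size_t)u * n + v] = st.adjBit[(size_t)v * n + u] = true;
    st.edgeId[(size_t)u * n + v] = st.edgeId[(size_t)v * n + u] = e;
  }
  st.nodeLUT.resize(maxK + 1); st.edgeLUT.resize(maxK + 1);
  st.nonEdgeLUT.resize(maxK + 1);
  for (int k = 2; k <= maxK; ++k) {
    st.nodeLUT[k] = as<IntegerMatrix>(nodeLUT[k - 1]);
    st.edgeLUT[k] = as<IntegerMatrix>(edgeLUT[k - 1]);
    st.nonEdgeLUT[k] = as<IntegerMatrix>(nonEdgeLUT[k - 1]);
  }
  st.pairFromEdge.assign(pairFromEdge.begin(), pairFromEdge.end());

  size_t nPairs = (size_t)n * (n - 1) / 2;
  if (wantNode) st.nodeGDV.assign((size_t)n * nNodeOrb, 0.0);
  if (wantEdge) st.edgeGDV.assign((size_t)nE * nEdgeOrb, 0.0);
  if (wantPair) st.pairGDV.assign(nPairs * nPairOrb, 0.0);
  st.blocked.assign(n, false);

  std::vector<int> sub, ext;
  for (int v = 0; v < n; ++v) {
    sub.clear(); sub.push_back(v);
    ext.clear();
    std::fill(st.blocked.begin(), st.blocked.end(), false);
    st.blocked[v] = true;
    for (int u : adj[v]) {
      st.blocked[u] = true;
      if (u > v) ext.push_back(u);
    }
    st.extend(sub, ext, v);
  }

  List out;
  if (wantNode) {
    NumericMatrix m(nNodeOrb, n);  // filled column-wise then transposed in R
    std::copy(st.nodeGDV.begin(), st.nodeGDV.end(), m.begin());
    out["node"] = m;
  }
  if (wantEdge) {
    NumericMatrix m(nEdgeOrb, nE);
    std::copy(st.edgeGDV.begin(), st.edgeGDV.end(), m.begin());
    out["edge"] = m;
  }
  if (wantPair) {
    NumericMatrix m(nPairOrb, (R_xlen_t)nPairs);
    std::copy(st.pairGDV.begin(), st.pairGDV.end(), m.begin());
    out["pair"] = m;
  }
  return out;
}
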