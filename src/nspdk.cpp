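#include <Rcpp.h>
#include <vector>
#include <map>
#include <queue>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <string>
using namespace Rcpp;

// Neighborhood-subgraph pairwise-distance (NSPDK-style) features with
// Weisfeiler-Lehman label refinement for neighborhood canonicalization.
// For every unordered node pair (u, v) at shortest-path distance d <=
// `distance` and every radius r <= `radius`, the WL labels of u and v at
// refinement depth r are hashed together with (r, d) into 2^hash_bits
// buckets; bucket counts are L2-normalized. The hash (FNV-1a, fixed seed)
// makes vectors deterministic across processes and invariant under node
// relabeling.

namespace {

const uint64_t FNV_OFFSET = 1469598103934665603ULL;
const uint64_t FNV_PRIME = 1099511628211ULL;

inline uint64_t fnv_bytes(uint64_t h, const void *data, size_t n) {
  const unsigned char *p = (const unsigned char *)data;
  for (size_t i = 0; i < n; ++i) { h ^= p[i]; h *= FNV_PRIME; }
  return h;
}
inline uint64_t fnv_u64(uint64_t h, uint64_t x) { return fnv_bytes(h, &x, 8); }
inline uint64_t fnv_str(const std::string &s) {
  return fnv_bytes(FNV_OFFSET, s.data(), s.size());
}

} // namespace

// [[Rcpp::export]]
List nspdk_cpp(CharacterVector node_labels, IntegerMatrix edges,
               CharacterVector edge_labels, int radius, int distance,
               int hash_bits) {
  const int n = node_labels.size();
  const int ne = edges.nrow();
  const uint64_t mask = (hash_bits >= 64) ? ~0ULL : ((1ULL << hash_bits) - 1);

  std::vector<std::vector<std::pair<int, int>>> adj(n); // (neighbor, edge id)
  std::vector<uint64_t> elab(ne);
  for (int e = 0; e < ne; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[a].push_back(std::make_pair(b, e));
    adj[b].push_back(std::make_pair(a, e));
    elab[e] = fnv_str(std::string(edge_labels[e]));
  }

  // WL refinement: labs[r][u]
  std::vector<std::vector<uint64_t>> labs(radius + 1,
                                          std::vector<uint64_t>(n));
  for (int u = 0; u < n; ++u)
    labs[0][u] = fnv_str(std::string(node_labels[u]));
  for (int r = 1; r <= radius; ++r) {
    std::vector<uint64_t> msgs;
    for (int u = 0; u < n; ++u) {
      msgs.clear();
      for (size_t t = 0; t < adj[u].size(); ++t) {
        uint64_t m = fnv_u64(fnv_u64(FNV_OFFSET, elab[adj[u][t].second]),
                             labs[r - 1][adj[u][t].first]);
        msgs.push_back(m);
      }
      std::sort(msgs.begin(), msgs.end());
      uint64_t h = fnv_u64(FNV_OFFSET, labs[r - 1][u]);
      for (size_t t = 0; t < msgs.size(); ++t) h = fnv_u64(h, msgs[t]);
      labs[r][u] = h;
    }
  }

  // bounded BFS from every node; accumulate pair features for v >= u order
  // induced by first visit (unordered pairs counted once via v-loop below)
  std::map<uint64_t, double> counts;
  std::vector<int> dist(n);
  for (int u = 0; u < n; ++u) {
    std::fill(dist.begin(), dist.end(), -1);
    std::queue<int> q;
    q.push(u); dist[u] = 0;
    while (!q.empty()) {
      int x = q.front(); q.pop();
      if (dist[x] >= distance) continue;
      for (size_t t = 0; t < adj[x].size(); ++t) {
        int y = adj[x][t].first;
        if (dist[y] < 0) { dist[y] = dist[x] + 1; q.push(y); }
      }
    }
    for (int v = u; v < n; ++v) {
      if (dist[v] < 0 || dist[v] > distance) continue;
      for (int r = 0; r <= radius; ++r) {
        uint64_t a = labs[r][u], b = labs[r][v];
        uint64_t lo = std::min(a, b), hi = std::max(a, b);
        uint64_t h = FNV_OFFSET;
        h = fnv_u64(h, lo); h = fnv_u64(h, hi);
        h = fnv_u64(h, (uint64_t)r); h = fnv_u64(h, (uint64_t)dist[v]);
        counts[h & mask] += 1.0;
      }
    }
  }

  double norm = 0.0;
  for (std::map<uint64_t, double>::iterator it = counts.begin();
       it != counts.end(); ++it)
    norm += it->second * it->second;
  norm = std::sqrt(norm);

  IntegerVector idx(counts.size());
  NumericVector val(counts.size());
  int p = 0;
  for (std::map<uint64_t, double>::iterator it = counts.begin();
       it != counts.end(); ++it, ++p) {
    idx[p] = (int)it->first;
    val[p] = (norm > 0) ? it->second / norm : 0.0;
  }
  return List::create(_["index"] = idx, _["value"] = val);
}

// [[Rcpp::export]]
std::string hash64_cpp(std::string x) {
  char buf[17];
  uint64_t h = fnv_str(x);
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
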