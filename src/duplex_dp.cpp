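#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Seed-anchored k-best intermolecular duplex dynamic program.
//
// A duplex is an ordered chain of base pairs (i, j), i strictly increasing
// into sequence 1 (5'->3'), j strictly decreasing into sequence 2 (5'->3')
// (antiparallel), with at most max_loop unpaired nucleotides between
// consecutive pairs on each side, terminated by a pair at both ends.
// Energy is additive: sum of pair energies plus loop_penalty per enclosed
// unpaired nucleotide (both sides). A duplex is valid only if it contains a
// run of >= seed_len stacked pairs whose positions all lie in the
// "qualifying" region (the site cores for positives, the unmasked context
// for negatives). Masked positions never pair.
//
// State: (i, j, s) where s in 0..seed_len tracks the current run of stacked
// qualifying pairs, capped; s == seed_len is absorbing ("has seed").
// k-best lists per state give the exact global top-k over all distinct
// pair chains (a chain is identified by its pair set).

namespace {

struct Entry {
  double energy;
  int prev_state;   // -1 when the chain starts here
  int prev_entry;
  int fi, fj;       // first pair of the chain (tie-breaking)
  int npairs;
};

inline double pair_energy(int a, int b, double e_gc, double e_au, double e_gu) {
  // codes: A=0, C=1, G=2, U=3; anything else never pairs
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return e_gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return e_au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return e_gu;
  return NA_REAL;
}

} // namespace

// [[Rcpp::export]]
List duplex_dp_cpp(IntegerVector s1, IntegerVector s2,
                   LogicalVector mask1, LogicalVector mask2,
                   LogicalVector qual1, LogicalVector qual2,
                   int seed_len, int max_loop, double loop_penalty,
                   double e_gc, double e_au, double e_gu, int k) {
  const int n1 = s1.size(), n2 = s2.size();
  const int S = seed_len;            // s == S means "seed satisfied"
  const int NS = S + 1;
  if (n1 == 0 || n2 == 0 || k <= 0) return List::create();

  // legal pair energies, NA where illegal or masked
  std::vector<double> pe((size_t)n1 * n2, NA_REAL);
  for (int i = 0; i < n1; ++i) {
    if (mask1[i]) continue;
    for (int j = 0; j < n2; ++j) {
      if (mask2[j]) continue;
      pe[(size_t)i * n2 + j] = pair_energy(s1[i], s2[j], e_gc, e_au, e_gu);
    }
  }

  std::vector<std::vector<Entry>> st((size_t)n1 * n2 * NS);
  std::vector<Entry> cand[64]; // per target s' scratch (NS <= 64 guaranteed by caller)

  auto push_topk = [&](std::vector<Entry> &lst, const Entry &e) {
    lst.push_back(e);
  };

  for (int ip = 0; ip < n1; ++ip) {
    for (int jp = n2 - 1; jp >= 0; --jp) {
      double ep = pe[(size_t)ip * n2 + jp];
      if (ISNA(ep)) continue;
      bool q = qual1[ip] && qual2[jp];
      for (int s = 0; s < NS; ++s) cand[s].clear();

      // chain starting at (ip, jp)
      {
        int s0 = q ? 1 : 0;
        if (s0 >= S) s0 = S;
        Entry e{ep, -1, -1, ip, jp, 1};
        push_topk(cand[s0], e);
      }
      // extend a chain ending at (ip - di, jp + dj)
      for (int di = 1; di <= max_loop + 1; ++di) {
        int i = ip - di;
        if (i < 0) break;
        for (int dj = 1; dj <= max_loop + 1; ++dj) {
          int j = jp + dj;
          if (j >= n2) break;
          if (ISNA(pe[(size_t)i * n2 + j])) continue;
          bool stacked = (di == 1 && dj == 1);
          double cost = ep + loop_penalty * ((di - 1) + (dj - 1));
          size_t base = ((size_t)i * n2 + j) * NS;
          for (int s = 0; s < NS; ++s) {
            const std::vector<Entry> &src = st[base + s];
            if (src.empty()) continue;
            int sp;
            if (s == S) sp = S;
            else if (q) { sp = stacked ? s + 1 : 1; if (sp >= S) sp = S; }
            else sp = 0;
            for (size_t m = 0; m < src.size(); ++m) {
              Entry e{src[m].energy + cost, (int)(base + s), (int)m,
                      src[m].fi, src[m].fj, src[m].npairs + 1};
              push_topk(cand[sp], e);
            }
          }
        }
      }
      size_t out_base = ((size_t)ip * n2 + jp) * NS;
      for (int s = 0; s < NS; ++s) {
        std::vector<Entry> &c = cand[s];
        if (c.empty()) continue;
        std::stable_sort(c.begin(), c.end(),
                         [](const Entry &a, const Entry &b) { return a.energy < b.energy; });
        if ((int)c.size() > k) c.resize(k);
        st[out_base + s] = c;
      }
    }
  }

  // collect every seeded chain terminus; global top-k
  struct Ref { double energy; int fi, fj, li, lj, npairs; size_t state; int entry; };
  std::vector<Ref> refs;
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j) {
      size_t sid = ((size_t)i * n2 + j) * NS + S;
      const std::vector<Entry> &lst = st[sid];
      for (size_t m = 0; m < lst.size(); ++m)
        refs.push_back(Ref{lst[m].energy, lst[m].fi, lst[m].fj, i, j,
                           lst[m].npairs, sid, (int)m});
    }
  std::stable_sort(refs.begin(), refs.end(), [](const Ref &a, const Ref &b) {
    if (a.energy != b.energy) return a.energy < b.energy;
    if (a.fi != b.fi) return a.fi < b.fi;
    if (a.fj != b.fj) return a.fj < b.fj;
    if (a.li != b.li) return a.li < b.li;
    return a.lj < b.lj;
  });
  int nout = std::min((int)refs.size(), k);

  List out(nout);
  for (int r = 0; r < nout; ++r) {
    const Ref &rf = refs[r];
    IntegerMatrix pairs(rf.npairs, 2);
    size_t sid = rf.state;
    int m = rf.entry;
    int row = rf.npairs - 1;
    while (sid != (size_t)-1) {
      const Entry &e = st[sid][m];
      int pj = (int)((sid / NS) % n2);
      int pi = (int)(sid / NS / n2);
      pairs(row, 0) = pi;
      pairs(row, 1) = pj;
      --row;
      if (e.prev_state < 0) break;
      sid = (size_t)e.prev_state;
      m = e.prev_entry;
    }
    out[r] = List::create(_["pairs"] = pairs, _["energy"] = rf.energy);
  }
  return out;
}
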