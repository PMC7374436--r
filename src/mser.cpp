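// Maximally stable extremal regions via union-find immersion.
//
// Pixels are merged in order of increasing gray level; each component root
// keeps a chain of (level, area) snapshots. A snapshot's variation is the
// one-sided relative area growth over `delta` gray levels,
//   psi(t) = (A(t + delta) - A(t)) / A(t),
// and a region is emitted where psi is a local minimum along its chain,
// psi <= max_var, and the area lies within [min_area, max_area]. Nested
// emissions that differ by less than `min_diversity` in relative area keep
// only the more stable one.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int level;
  int area;
  int parent;  // snapshot of the containing component at a higher level
  int child;   // previous snapshot of the same (surviving) chain
  int seed;    // 0-based pixel index guaranteed to lie in the component
  double psi;
  bool chain_cont;  // parent continues this chain (not a merge absorption)
};

struct UF {
  std::vector<int> parent;
  explicit UF(int n) : parent(n, -2) {}  // -2 = not yet added
  int find(int x) {
    int r = x;
    while (parent[r] >= 0) r = parent[r];
    while (parent[x] >= 0) {
      int nxt = parent[x];
      parent[x] = r;
      x = nxt;
    }
    return r;
  }
};

}  // namespace

// [[Rcpp::export]]
DataFrame mser_tree_cpp(IntegerMatrix img, int delta, double max_var,
                        int min_area, int max_area, double min_diversity) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  // counting sort of pixels by gray level
  std::vector<int> count(257, 0);
  for (int i = 0; i < n; ++i) ++count[img[i] + 1];
  for (int v = 1; v <= 256; ++v) count[v] += count[v - 1];
  std::vector<int> order(n);
  {
    std::vector<int> pos(count.begin(), count.end() - 1);
    for (int i = 0; i < n; ++i) order[pos[img[i]]++] = i;
  }

  UF uf(n);
  std::vector<int> area(n, 0), last_node(n, -1), seed_of(n, -1);
  std::vector<Node> nodes;
  nodes.reserve(n / 4 + 16);
  std::vector<char> dirty(n, 0);
  std::vector<int> dirty_roots;
  // chains absorbed during the current level: (last snapshot, member pixel)
  std::vector<std::pair<int, int> > pending;

  int idx = 0;
  for (int v = 0; v <= 255; ++v) {
    // add all pixels of value v
    for (; idx < n && img[order[idx]] == v; ++idx) {
      int p = order[idx];
      uf.parent[p] = -1;
      area[p] = 1;
      seed_of[p] = p;
      int root = p;
      int pr = p % nr, pc = p / nr;
      static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
      static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
      for (int k = 0; k < 8; ++k) {
        int rr = pr + DR[k], cc = pc + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int q = rr + cc * nr;
        if (uf.parent[q] == -2) continue;  // neighbour not yet added
        int rq = uf.find(q), rp = uf.find(root);
        if (rq == rp) continue;
        // larger component survives; ties keep the lower root index
        int win = rq, lose = rp;
        if (area[rp] > area[rq] ||
            (area[rp] == area[rq] && rp < rq)) {
          win = rp;
          lose = rq;
        }
        if (last_node[lose] >= 0)
          pending.push_back(std::make_pair(last_node[lose], win));
        uf.parent[lose] = win;
        area[win] += area[lose];
        root = win;
      }
      int r = uf.find(root);
      if (!dirty[r]) {
        dirty[r] = 1;
        dirty_roots.push_back(r);
      }
    }
    // snapshot every component that changed at this level
    for (size_t i = 0; i < dirty_roots.size(); ++i) {
      int r = uf.find(dirty_roots[i]);
      if (last_node[r] >= 0 && nodes[last_node[r]].level == v) continue;
      Node nd;
      nd.level = v;
      nd.area = area[r];
      nd.parent = -1;
      nd.child = last_node[r];
      nd.seed = seed_of[r];
      nd.psi = R_PosInf;
      nd.chain_cont = false;
      int id = (int)nodes.size();
      if (nd.child >= 0) {
        nodes[nd.child].parent = id;
        nodes[nd.child].chain_cont = true;
      }
      nodes.push_back(nd);
      last_node[r] = id;
    }
    for (size_t i = 0; i < dirty_roots.size(); ++i) dirty[uf.find(dirty_roots[i])] = 0;
    dirty_roots.clear();
    // absorbed chains point at the snapshot of the component that ate them
    for (size_t i = 0; i < pending.size(); ++i) {
      int r = uf.find(pending[i].second);
      nodes[pending[i].first].parent = last_node[r];
    }
    pending.clear();
  }

  const int nn = (int)nodes.size();
  // variation psi(t) = (A(t + delta) - A(t)) / A(t), areas piecewise constant
  for (int i = 0; i < nn; ++i) {
    int up = i;
    int target = nodes[i].level + delta;
    while (nodes[up].parent >= 0 && nodes[nodes[up].parent].level <= target)
      up = nodes[up].parent;
    nodes[i].psi = (double)(nodes[up].area - nodes[i].area) / nodes[i].area;
  }

  std::vector<char> emit(nn, 0);
  for (int i = 0; i < nn; ++i) {
    const Node &nd = nodes[i];
    if (nd.area < min_area || nd.area > max_area) continue;
    if (nd.psi > max_var) continue;
    if (nd.child >= 0 && nodes[nd.child].psi < nd.psi) continue;
    if (nd.parent >= 0 && nd.chain_cont && nodes[nd.parent].psi < nd.psi)
      continue;
    emit[i] = 1;
  }
  // diversity: drop the less stable of two nested, nearly identical regions
  for (int i = 0; i < nn; ++i) {
    if (!emit[i]) continue;
    int up = i;
    while (nodes[up].chain_cont && nodes[up].parent >= 0) {
      up = nodes[up].parent;
      double rel = (double)(nodes[up].area - nodes[i].area) / nodes[up].area;
      if (rel >= min_diversity) break;
      if (emit[up]) {
        if (nodes[up].psi <= nodes[i].psi) emit[i] = 0; else emit[up] = 0;
      }
      if (!emit[i]) break;
    }
  }

  std::vector<int> seed_row, seed_col, level, area_out;
  std::vector<double> stab;
  for (int i = 0; i < nn; ++i) {
    if (!emit[i]) continue;
    seed_row.push_back(nodes[i].seed % nr + 1);
    seed_col.push_back(nodes[i].seed / nr + 1);
    level.push_back(nodes[i].level);
    area_out.push_back(nodes[i].area);
    stab.push_back(nodes[i].psi);
  }
  return DataFrame::create(
      _["seed_row"] = wrap(seed_row), _["seed_col"] = wrap(seed_col),
      _["level"] = wrap(level), _["area"] = wrap(area_out),
      _["stability"] = wrap(stab));
}
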