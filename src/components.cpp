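#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-connected neighbourhood offsets
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Label 8-connected foreground components in raster order of first pixel.
// [[Rcpp::export]]
List label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> sizes;
  std::queue<std::pair<int, int> > q;
  int lab = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++lab;
      int sz = 0;
      labels(r, c) = lab;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        ++sz;
        for (int k = 0; k < 8; ++k) {
          int rr = p.first + DR[k], cc = p.second + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && labels(rr, cc) == 0) {
            labels(rr, cc) = lab;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
      sizes.push_back(sz);
    }
  }
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// Flood fill over {q <= level} from a seed; returns 1-based (row, col) pairs.
// [[Rcpp::export]]
IntegerMatrix flood_le_cpp(IntegerMatrix img, int seed_row, int seed_col,
                           int level) {
  int nr = img.nrow(), nc = img.ncol();
  if (seed_row < 1 || seed_row > nr || seed_col < 1 || seed_col > nc)
    stop("seed outside image");
  int sr = seed_row - 1, sc = seed_col - 1;
  if (img(sr, sc) > level) stop("seed pixel above flood level");
  LogicalMatrix vis(nr, nc);
  std::vector<int> rows, cols;
  std::queue<std::pair<int, int> > q;
  vis(sr, sc) = true;
  q.push(std::make_pair(sr, sc));
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    rows.push_back(p.first + 1);
    cols.push_back(p.second + 1);
    for (int k = 0; k < 8; ++k) {
      int rr = p.first + DR[k], cc = p.second + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!vis(rr, cc) && img(rr, cc) <= level) {
        vis(rr, cc) = true;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  int n = rows.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}
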