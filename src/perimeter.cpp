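#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Weighted boundary-step perimeter of labelled objects.
//
// The outer contour of each object is followed with Moore (8-connected)
// neighbour tracing and the contour length is the sum of step weights:
// 1 for orthogonal steps, sqrt(2) for diagonal steps. Single-pixel objects
// have no steps and return 0 (degenerate; callers report circularity as NA).
// Holes do not contribute (outer contour only).

// clockwise Moore neighbourhood starting East; x = column, y = row
static const int DX[8] = {1, 1, 0, -1, -1, -1, 0, 1};
static const int DY[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const double W[8] = {1.0, M_SQRT2, 1.0, M_SQRT2,
                            1.0, M_SQRT2, 1.0, M_SQRT2};

// [[Rcpp::export]]
NumericVector cpp_label_perimeters(IntegerMatrix labels, IntegerVector ids) {
  const int nr = labels.nrow(), nc = labels.ncol();
  std::unordered_map<int, std::pair<int, int> > start; // id -> (row, col)
  std::unordered_map<int, long> npx;
  // column-major scan: first occurrence has background to the W and N
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int v = labels(r, c);
      if (v > 0) {
        if (!start.count(v)) start[v] = std::make_pair(r, c);
        ++npx[v];
      }
    }
  }
  NumericVector out(ids.size(), NA_REAL);
  for (int k = 0; k < ids.size(); ++k) {
    int id = ids[k];
    if (!start.count(id)) continue;
    if (npx[id] == 1) { out[k] = 0.0; continue; }
    const int sr = start[id].first, sc = start[id].second;
    // enter the start pixel "from the West" (background by scan order)
    int px = sc, py = sr;
    int back = 4; // direction index of the backtrack neighbour (W)
    double per = 0.0;
    int first_move = -1;
    long guard = 8 * npx[id] + 8;
    while (guard-- > 0) {
      int move = -1;
      for (int t = 1; t <= 8; ++t) {
        int d = (back + t) % 8;
        int nx = px + DX[d], ny = py + DY[d];
        if (nx >= 0 && nx < nc && ny >= 0 && ny < nr &&
            labels(ny, nx) == id) {
          move = d;
          break;
        }
      }
      if (move < 0) break; // isolated pixel (cannot happen: npx > 1)
      // stop when we re-enter the start pixel with the same first move
      if (px == sc && py == sr && first_move >= 0 && move == first_move)
        break;
      if (first_move < 0) first_move = move;
      per += W[move];
      px += DX[move];
      py += DY[move];
      // new backtrack: direction from the new pixel towards the previous
      // pixel, advanced one position clockwise past it
      back = (move + 4 + 1) % 8;
    }
    out[k] = per;
  }
  return out;
}
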