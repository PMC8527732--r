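#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Zhang-Suen thinning of a binary mask. Returns a mask whose foreground is an
// (approximately) one-pixel-wide, 8-connected skeleton. Border pixels are
// treated as background neighbours.
// [[Rcpp::export(name = ".cpp_thin")]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img(clone(mask));
  std::vector<int> kill;
  kill.reserve(1024);

  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c) ? 1 : 0;
  };

  bool outer_changed = true;
  while (outer_changed) {
  outer_changed = false;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(r + nr * c);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (int idx : kill) img[idx] = false;
      }
    }
  }

  // Zhang-Suen can leave solid 2x2 corners at staircase junctions; remove
  // one deletable member of each such block, then rerun the thinning
  // passes until the joint fixed point (making the operator idempotent).
  bool block_changed = true;
  while (block_changed) {
    block_changed = false;
    for (int c = 0; c + 1 < nc; ++c) {
      for (int r = 0; r + 1 < nr; ++r) {
        if (!(img(r, c) && img(r + 1, c) && img(r, c + 1) &&
              img(r + 1, c + 1)))
          continue;
        const int rs[4] = {r, r + 1, r, r + 1};
        const int cs[4] = {c, c, c + 1, c + 1};
        bool deleted = false;
        for (int k = 0; k < 4; ++k) {
          int rr = rs[k], cc = cs[k];
          int p2 = at(rr - 1, cc), p3 = at(rr - 1, cc + 1),
              p4 = at(rr, cc + 1), p5 = at(rr + 1, cc + 1),
              p6 = at(rr + 1, cc), p7 = at(rr + 1, cc - 1),
              p8 = at(rr, cc - 1), p9 = at(rr - 1, cc - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          // single neighbour arc (a == 1) keeps connectivity; b <= 7
          // admits junction-adjacent corners that the thinning passes skip
          if (a == 1 && b >= 2 && b <= 7) {
            img(rr, cc) = false;
            block_changed = true;
            deleted = true;
            break;
          }
        }
        if (!deleted) {
          // 4-way junction hub: no member is safely deletable, but the
          // one-pixel-wide invariant wins; drop the member with the
          // fewest neighbours outside the block (least branch damage).
          int best_k = 0, best_out = 9;
          for (int k = 0; k < 4; ++k) {
            int rr = rs[k], cc = cs[k];
            int outside = 0;
            for (int dr2 = -1; dr2 <= 1; ++dr2)
              for (int dc2 = -1; dc2 <= 1; ++dc2) {
                if (dr2 == 0 && dc2 == 0) continue;
                int r2 = rr + dr2, c2 = cc + dc2;
                bool in_block = (r2 == r || r2 == r + 1) &&
                                (c2 == c || c2 == c + 1);
                if (!in_block && at(r2, c2)) ++outside;
              }
            if (outside < best_out) { best_out = outside; best_k = k; }
          }
          img(rs[best_k], cs[best_k]) = false;
          block_changed = true;
        }
      }
    }
    if (block_changed) outer_changed = true;
  }
  }  // outer fixed-point loop
  return img;
}

// 4-connected flood fill over `open` starting from (row0, col0) (0-based).
// Returns the connected component of open pixels containing the start.
// [[Rcpp::export(name = ".cpp_flood_fill")]]
LogicalMatrix cpp_flood_fill(LogicalMatrix open, int row0, int col0) {
  int nr = open.nrow(), nc = open.ncol();
  LogicalMatrix out(nr, nc);
  if (row0 < 0 || row0 >= nr || col0 < 0 || col0 >= nc || !open(row0, col0))
    return out;
  std::queue<int> q;
  q.push(row0 + nr * col0);
  out(row0, col0) = true;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!open(r2, c2) || out(r2, c2)) continue;
      out(r2, c2) = true;
      q.push(r2 + nr * c2);
    }
  }
  return out;
}
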