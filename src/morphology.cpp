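#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// 8-connectivity offsets (row, col)
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Grayscale morphological reconstruction by dilation of `marker` under `mask`,
// 8-connected, using Vincent's hybrid algorithm (two raster scans + FIFO queue).
// Requires marker <= mask pointwise; enforced by clamping.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical dimensions");
  NumericMatrix J = clone(marker);
  for (int k = 0; k < nr * nc; ++k)
    if (J[k] > mask[k]) J[k] = mask[k];

  // forward scan (column-major): already-visited neighbours
  // N+ = {(r-1,c-1),(r,c-1),(r+1,c-1),(r-1,c)}
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      if (c > 0) {
        if (r > 0 && J(r - 1, c - 1) > m) m = J(r - 1, c - 1);
        if (J(r, c - 1) > m) m = J(r, c - 1);
        if (r < nr - 1 && J(r + 1, c - 1) > m) m = J(r + 1, c - 1);
      }
      if (r > 0 && J(r - 1, c) > m) m = J(r - 1, c);
      J(r, c) = std::min(m, mask(r, c));
    }
  }

  // backward scan with mirrored neighbourhood; queue boundary pixels
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      if (c < nc - 1) {
        if (r > 0 && J(r - 1, c + 1) > m) m = J(r - 1, c + 1);
        if (J(r, c + 1) > m) m = J(r, c + 1);
        if (r < nr - 1 && J(r + 1, c + 1) > m) m = J(r + 1, c + 1);
      }
      if (r < nr - 1 && J(r + 1, c) > m) m = J(r + 1, c);
      J(r, c) = std::min(m, mask(r, c));
      // enqueue if some N- neighbour could still be raised
      const double jp = J(r, c);
      bool push = false;
      if (c < nc - 1) {
        for (int dr = -1; dr <= 1 && !push; ++dr) {
          int rr = r + dr;
          if (rr < 0 || rr >= nr) continue;
          if (J(rr, c + 1) < jp && J(rr, c + 1) < mask(rr, c + 1)) push = true;
        }
      }
      if (!push && r < nr - 1 && J(r + 1, c) < jp && J(r + 1, c) < mask(r + 1, c))
        push = true;
      if (push) fifo.push(r + c * nr);
    }
  }

  while (!fifo.empty()) {
    const int p = fifo.front();
    fifo.pop();
    const int r = p % nr, c = p / nr;
    const double jp = J(r, c);
    for (int k = 0; k < 8; ++k) {
      const int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < jp && J(rr, cc) < mask(rr, cc)) {
        J(rr, cc) = std::min(jp, mask(rr, cc));
        fifo.push(rr + cc * nr);
      }
    }
  }
  return J;
}

// Regional maxima: 8-connected plateaus of constant value strictly greater
// than every neighbouring pixel. Returns a logical matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> visited(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> plateau;
  std::queue<int> q;

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      const int p0 = r0 + c0 * nr;
      if (visited[p0]) continue;
      const double v = img(r0, c0);
      plateau.clear();
      bool isMax = true;
      visited[p0] = 1;
      q.push(p0);
      while (!q.empty()) {
        const int p = q.front();
        q.pop();
        plateau.push_back(p);
        const int r = p % nr, c = p / nr;
        for (int k = 0; k < 8; ++k) {
          const int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const double w = img(rr, cc);
          if (w > v) {
            isMax = false;
          } else if (w == v) {
            const int pp = rr + cc * nr;
            if (!visited[pp]) {
              visited[pp] = 1;
              q.push(pp);
            }
          }
        }
      }
      if (isMax)
        for (size_t i = 0; i < plateau.size(); ++i) out[plateau[i]] = true;
    }
  }
  return out;
}

static inline int reflect_idx(int i, int n) {
  // symmetric (half-sample) reflection: -1 -> 0, -2 -> 1, n -> n-1, ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Two-level adaptive median filter (window grows from 3x3 to smax x smax).
// Level A: if the window median is strictly between the window min and max,
// go to level B, else grow the window; at smax return the median.
// Level B: keep the centre pixel if it is strictly between min and max,
// else return the median. Reflect padding at the borders.
// [[Rcpp::export]]
NumericMatrix cpp_adaptive_median(NumericMatrix img, int smax) {
  const int nr = img.nrow(), nc = img.ncol();
  if (smax < 3 || smax % 2 == 0) stop("smax must be odd and >= 3");
  NumericMatrix out(nr, nc);
  std::vector<double> win;
  win.reserve(static_cast<size_t>(smax) * smax);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double z = img(r, c);
      double res = z;
      for (int s = 3; s <= smax; s += 2) {
        const int h = s / 2;
        win.clear();
        for (int dc = -h; dc <= h; ++dc) {
          const int cc = reflect_idx(c + dc, nc);
          for (int dr = -h; dr <= h; ++dr)
            win.push_back(img(reflect_idx(r + dr, nr), cc));
        }
        const size_t mid = win.size() / 2;
        std::nth_element(win.begin(), win.begin() + mid, win.end());
        const double zmed = win[mid];
        const double zmin = *std::min_element(win.begin(), win.end());
        const double zmax = *std::max_element(win.begin(), win.end());
        if (zmin < zmed && zmed < zmax) {          // level A passed
          res = (zmin < z && z < zmax) ? z : zmed; // level B
          break;
        }
        res = zmed; // value if the window caps out at smax
      }
      out(r, c) = res;
    }
  }
  return out;
}

// 8-connected labelling of a binary mask; labels are 1..K in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      q.push(r0 + c0 * nr);
      while (!q.empty()) {
        const int p = q.front();
        q.pop();
        const int r = p % nr, c = p / nr;
        for (int k = 0; k < 8; ++k) {
          const int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}
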