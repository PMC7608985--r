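#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Raster conventions shared with the R side: masks are H x W logical
// matrices, pixel (x, y) with 0-based x = column, y = row lives at
// matrix[y + 1, x + 1].

// 8-neighbourhood in counterclockwise order (rows grow downward):
// E, NE, N, NW, W, SW, S, SE
static const int DR[8] = {0, -1, -1, -1, 0, 1, 1, 1};
static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix labels(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; j++) {
    for (int i = 0; i < H; i++) {
      if (!mask(i, j) || labels(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * H);
      labels(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int d = 0; d < 8; d++) {
          if (connectivity == 4 && (d % 2) == 1) continue;
          int ni = pi + DR[d], nj = pj + DC[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && labels(ni, nj) == 0) {
            labels(ni, nj) = next;
            stack.push_back(ni + nj * H);
          }
        }
      }
    }
  }
  labels.attr("n") = next;
  return labels;
}

// Outer-border following of one labelled component (Suzuki & Abe's follow
// step restricted to the outer border; holes are not traced). Returns the
// border pixel sequence as an n x 2 matrix of 0-based (x, y).
// [[Rcpp::export]]
IntegerMatrix cpp_trace_outer_border(IntegerMatrix labels, int lab) {
  const int H = labels.nrow(), W = labels.ncol();
  int si = -1, sj = -1;
  for (int i = 0; i < H && si < 0; i++)
    for (int j = 0; j < W; j++)
      if (labels(i, j) == lab) { si = i; sj = j; break; }
  if (si < 0) return IntegerMatrix(0, 2);

  auto at = [&](int i, int j) {
    return i >= 0 && i < H && j >= 0 && j < W && labels(i, j) == lab;
  };

  // Start pixel is topmost-then-leftmost, so its west neighbour is outside
  // the component. Search clockwise from west for the first member pixel.
  int i1 = -1, j1 = -1;
  for (int k = 0; k < 8; k++) {
    int d = ((4 - k) % 8 + 8) % 8;
    int ni = si + DR[d], nj = sj + DC[d];
    if (at(ni, nj)) { i1 = ni; j1 = nj; break; }
  }
  if (i1 < 0) {  // isolated pixel
    IntegerMatrix out(1, 2);
    out(0, 0) = sj; out(0, 1) = si;
    return out;
  }

  std::vector<std::pair<int, int> > border;
  int i2 = i1, j2 = j1, i3 = si, j3 = sj;
  long guard = 8L * H * W + 16;
  while (guard-- > 0) {
    int dprev = -1;
    for (int k = 0; k < 8; k++)
      if (DR[k] == i2 - i3 && DC[k] == j2 - j3) { dprev = k; break; }
    int i4 = -1, j4 = -1;
    for (int k = 1; k <= 8; k++) {
      int d = (dprev + k) % 8;
      int ni = i3 + DR[d], nj = j3 + DC[d];
      if (at(ni, nj)) { i4 = ni; j4 = nj; break; }
    }
    border.push_back(std::make_pair(i3, j3));
    if (i4 == si && j4 == sj && i3 == i1 && j3 == j1) break;
    i2 = i3; j2 = j3; i3 = i4; j3 = j4;
  }

  IntegerMatrix out((int)border.size(), 2);
  for (int k = 0; k < (int)border.size(); k++) {
    out(k, 0) = border[k].second;
    out(k, 1) = border[k].first;
  }
  return out;
}

static void draw_line(LogicalMatrix &out, int x0, int y0, int x1, int y1) {
  const int H = out.nrow(), W = out.ncol();
  int dx = std::abs(x1 - x0), sx = x0 < x1 ? 1 : -1;
  int dy = -std::abs(y1 - y0), sy = y0 < y1 ? 1 : -1;
  int err = dx + dy;
  while (true) {
    if (y0 >= 0 && y0 < H && x0 >= 0 && x0 < W) out(y0, x0) = true;
    if (x0 == x1 && y0 == y1) break;
    int e2 = 2 * err;
    if (e2 >= dy) { err += dy; x0 += sx; }
    if (e2 <= dx) { err += dx; y0 += sy; }
  }
}

// Rasterize a closed polygon (vertices at pixel centres, 0-based x/y) into
// an H x W mask: even-odd scanline interior plus Bresenham-drawn edges, so
// border pixels always belong to the region and interior holes are filled
// when the polygon is an outer border trace.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_polygon(NumericMatrix verts, int width, int height) {
  LogicalMatrix out(height, width);
  const int n = verts.nrow();
  if (n == 0) return out;
  for (int k = 0; k < n; k++) {
    int k2 = (k + 1) % n;
    draw_line(out,
              (int)std::lround(verts(k, 0)), (int)std::lround(verts(k, 1)),
              (int)std::lround(verts(k2, 0)), (int)std::lround(verts(k2, 1)));
  }
  if (n < 3) return out;
  std::vector<double> xs;
  for (int y = 0; y < height; y++) {
    xs.clear();
    for (int k = 0; k < n; k++) {
      int k2 = (k + 1) % n;
      double x1 = verts(k, 0), y1 = verts(k, 1);
      double x2 = verts(k2, 0), y2 = verts(k2, 1);
      if ((y1 > y) != (y2 > y))
        xs.push_back(x1 + (y - y1) * (x2 - x1) / (y2 - y1));
    }
    std::sort(xs.begin(), xs.end());
    for (size_t m = 0; m + 1 < xs.size(); m += 2) {
      int xa = (int)std::ceil(xs[m]);
      int xb = (int)std::floor(xs[m + 1]);
      if (xa < 0) xa = 0;
      if (xb > width - 1) xb = width - 1;
      for (int x = xa; x <= xb; x++) out(y, x) = true;
    }
  }
  return out;
}

// Rasterize an open polyline (1-px Bresenham strokes between consecutive
// vertices).
// [[Rcpp::export]]
LogicalMatrix cpp_draw_polyline(NumericMatrix verts, int width, int height) {
  LogicalMatrix out(height, width);
  const int n = verts.nrow();
  for (int k = 0; k + 1 < n; k++)
    draw_line(out,
              (int)std::lround(verts(k, 0)), (int)std::lround(verts(k, 1)),
              (int)std::lround(verts(k + 1, 0)), (int)std::lround(verts(k + 1, 1)));
  return out;
}
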