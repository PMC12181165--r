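#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary matrix (row = y, col = x).
// connectivity: 8 for foreground objects, 4 for background/hole analysis.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& mask, int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 1, 0, 0};
  const int dx4[4] = {0, 0, -1, 1};
  const int n_nb = (connectivity == 8) ? 8 : 4;
  const int* dy = (connectivity == 8) ? dy8 : dy4;
  const int* dx = (connectivity == 8) ? dx8 : dx4;

  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      stack.push_back(y + x * H);
      lab(y, x) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cy = idx % H, cx = idx / H;
        for (int k = 0; k < n_nb; ++k) {
          int ny = cy + dy[k], nx = cx + dx[k];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back(ny + nx * H);
          }
        }
      }
    }
  }
  return lab;
}

static inline int px(const IntegerMatrix& m, int y, int x) {
  if (y < 0 || y >= m.nrow() || x < 0 || x >= m.ncol()) return 0;
  return m(y, x) != 0 ? 1 : 0;
}

// Guo-Hall thinning (1989), two sub-iterations, run to fixed point.
// Reduces a binary mask to an 8-connected, 1-pixel-wide skeleton while
// preserving connectivity and endpoints of elongated shapes.
// [[Rcpp::export(name = ".thin_mask")]]
IntegerMatrix thin_mask(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img = clone(mask);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) img(y, x) = img(y, x) != 0 ? 1 : 0;

  bool changed = true;
  std::vector<std::pair<int, int> > del;
  del.reserve(1024);
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (int x = 0; x < W; ++x) {
        for (int y = 0; y < H; ++y) {
          if (img(y, x) == 0) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = px(img, y - 1, x);
          int p3 = px(img, y - 1, x + 1);
          int p4 = px(img, y, x + 1);
          int p5 = px(img, y + 1, x + 1);
          int p6 = px(img, y + 1, x);
          int p7 = px(img, y + 1, x - 1);
          int p8 = px(img, y, x - 1);
          int p9 = px(img, y - 1, x - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = iter == 0 ? ((p6 | p7 | (!p9)) & p8) : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            del.push_back(std::make_pair(y, x));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i)
        img(del[i].first, del[i].second) = 0;
    }
  }
  return img;
}

// Per-pixel count of 8-neighbours that are foreground; -1 where background.
// Degree 1 pixels are skeleton endpoints, >= 3 are branch points.
// [[Rcpp::export(name = ".nb_degree")]]
IntegerMatrix nb_degree(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix deg(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (mask(y, x) == 0) {
        deg(y, x) = -1;
        continue;
      }
      int d = 0;
      for (int ddy = -1; ddy <= 1; ++ddy)
        for (int ddx = -1; ddx <= 1; ++ddx)
          if ((ddy || ddx) && px(mask, y + ddy, x + ddx)) ++d;
      deg(y, x) = d;
    }
  }
  return deg;
}
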