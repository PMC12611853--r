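// Small binary-image utilities with explicit border semantics:
// pixels outside the image count as background (0); the median filter
// uses symmetric (reflection) padding.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_erode(IntegerMatrix m, LogicalMatrix se) {
  int H = m.nrow(), W = m.ncol();
  int ah = se.nrow() / 2, aw = se.ncol() / 2;
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int keep = 1;
      for (int dj = -aw; dj <= aw && keep; ++dj)
        for (int di = -ah; di <= ah; ++di) {
          if (!se(di + ah, dj + aw)) continue;
          int ii = i + di, jj = j + dj;
          int v = (ii >= 0 && ii < H && jj >= 0 && jj < W) ? m(ii, jj) : 0;
          if (!v) { keep = 0; break; }
        }
      out(i, j) = keep;
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_dilate(IntegerMatrix m, LogicalMatrix se) {
  int H = m.nrow(), W = m.ncol();
  int ah = se.nrow() / 2, aw = se.ncol() / 2;
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!m(i, j)) continue;
      for (int dj = -aw; dj <= aw; ++dj)
        for (int di = -ah; di <= ah; ++di) {
          if (!se(di + ah, dj + aw)) continue;
          int ii = i + di, jj = j + dj;
          if (ii >= 0 && ii < H && jj >= 0 && jj < W) out(ii, jj) = 1;
        }
    }
  return out;
}

// Connected-component labeling (BFS), connectivity 4 or 8.
// Labels are assigned in row-major discovery order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix m, int conn) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  int d8i[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int d8j[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nd = (conn == 8) ? 8 : 4;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (!m(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int t = 0; t < nd; ++t) {
          int ii = p.first + d8i[t], jj = p.second + d8j[t];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (m(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  lab.attr("n") = next;
  return lab;
}

static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int win) {
  int H = x.nrow(), W = x.ncol();
  int a = win / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf((size_t)win * win);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      size_t k = 0;
      for (int dj = -a; dj <= a; ++dj)
        for (int di = -a; di <= a; ++di)
          buf[k++] = x(reflect(i + di, H), reflect(j + dj, W));
      size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(i, j) = med;
    }
  return out;
}
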