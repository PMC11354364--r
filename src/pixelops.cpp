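#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// reflect an index into [0, n): half-sample symmetric (edge pixel duplicated)
static inline int refl(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    else       i = 2 * n - i - 1;
  }
  return i;
}

// Local Shannon entropy (bits) over a disk of lattice offsets dy^2+dx^2 <= r^2,
// reflect padding. Histogram slides down each column; the entropy is recomputed
// from the full 256-bin histogram at every pixel (order-independent, so results
// are bitwise identical under image flips).
// [[Rcpp::export]]
NumericMatrix cpp_local_entropy(const IntegerMatrix& img, int radius) {
  const int H = img.nrow(), W = img.ncol(), r = radius;
  if (r < 1) stop("radius must be >= 1");
  NumericMatrix out(H, W);

  // half-height of the disk column at horizontal offset dx
  std::vector<int> wy(2 * r + 1);
  int n = 0;
  for (int dx = -r; dx <= r; ++dx) {
    wy[dx + r] = (int)std::floor(std::sqrt((double)r * r - (double)dx * dx));
    n += 2 * wy[dx + r] + 1;
  }

  // L[c] = c * log2(c); H = log2(n) - sum(L[hist]) / n
  std::vector<double> L(n + 1);
  L[0] = 0.0;
  for (int c = 1; c <= n; ++c) L[c] = (double)c * std::log2((double)c);
  const double log2n = std::log2((double)n);

  // reflected index lookup tables: rows[i + r] == refl(i, H) for i in [-r, H+r)
  std::vector<int> rows(H + 2 * r), cols(W + 2 * r);
  for (int i = -r; i < H + r; ++i) rows[i + r] = refl(i, H);
  for (int i = -r; i < W + r; ++i) cols[i + r] = refl(i, W);
  const int* rt = rows.data() + r;
  const int* ct = cols.data() + r;
  const int* px = INTEGER(img);
  double* o = REAL(out);

  std::vector<int> hist(256);
  std::vector<const int*> colptr(2 * r + 1);  // column base pointers per dx
  for (int x = 0; x < W; ++x) {
    std::fill(hist.begin(), hist.end(), 0);
    for (int dx = -r; dx <= r; ++dx)
      colptr[dx + r] = px + (size_t)ct[x + dx] * H;
    // initialise at (y = 0, x)
    for (int dx = -r; dx <= r; ++dx) {
      const int* col = colptr[dx + r];
      const int w = wy[dx + r];
      for (int dy = -w; dy <= w; ++dy)
        hist[col[rt[dy]]]++;
    }
    double* ocol = o + (size_t)x * H;
    for (int y = 0; y < H; ++y) {
      if (y > 0) { // slide window down one row
        for (int dx = -r; dx <= r; ++dx) {
          const int* col = colptr[dx + r];
          const int w = wy[dx + r];
          hist[col[rt[y - 1 - w]]]--;
          hist[col[rt[y + w]]]++;
        }
      }
      double s = 0.0;
      for (int c = 0; c < 256; ++c) s += L[hist[c]];
      double h = log2n - s / (double)n;
      // snap float residue to an exact 0 (a single-bin histogram has H = 0;
      // the smallest real entropy, counts (n-1, 1), is far above 1e-12)
      ocol[y] = (h > 1e-12) ? h : 0.0;
    }
  }
  return out;
}

// Connected-component labelling of a logical matrix, connectivity 4 or 8.
// Labels are 1..k in scan order; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  const int ndir = (connectivity == 4) ? 4 : 8;
  const int dys[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dxs[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> stack;
  int next = 0;
  for (int x = 0; x < W; ++x) for (int y = 0; y < H; ++y) {
    if (!mask(y, x) || lab(y, x) != 0) continue;
    lab(y, x) = ++next;
    stack.push_back(y + x * H);
    while (!stack.empty()) {
      const int p = stack.back(); stack.pop_back();
      const int py = p % H, px = p / H;
      for (int d = 0; d < ndir; ++d) {
        const int qy = py + dys[d], qx = px + dxs[d];
        if (qy < 0 || qy >= H || qx < 0 || qx >= W) continue;
        if (mask(qy, qx) && lab(qy, qx) == 0) {
          lab(qy, qx) = next;
          stack.push_back(qy + qx * H);
        }
      }
    }
  }
  return lab;
}

// Binary dilation by a disk (dy^2+dx^2 <= r^2); pixels outside the frame are
// background. Uses per-row prefix sums, one pass per disk row.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disk(const LogicalMatrix& mask, int radius) {
  const int H = mask.nrow(), W = mask.ncol(), r = radius;
  if (r < 0) stop("radius must be >= 0");
  LogicalMatrix out(H, W);
  if (r == 0) { for (int i = 0; i < H * W; ++i) out[i] = mask[i]; return out; }
  // prefix sums per row: P[y][x+1] = number of true pixels in mask[y, 0..x]
  std::vector<int> P((size_t)H * (W + 1), 0);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      P[(size_t)y * (W + 1) + x + 1] = P[(size_t)y * (W + 1) + x] + (mask(y, x) ? 1 : 0);
  for (int dy = -r; dy <= r; ++dy) {
    const int w = (int)std::floor(std::sqrt((double)r * r - (double)dy * dy));
    for (int y = 0; y < H; ++y) {
      const int ys = y + dy;
      if (ys < 0 || ys >= H) continue;
      const int* row = &P[(size_t)ys * (W + 1)];
      for (int x = 0; x < W; ++x) {
        if (out(y, x)) continue;
        const int lo = (x - w < 0) ? 0 : x - w;
        const int hi = (x + w >= W) ? W - 1 : x + w;
        if (row[hi + 1] - row[lo] > 0) out(y, x) = true;
      }
    }
  }
  return out;
}
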