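#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of a scratch buffer; averages the two middle values for even counts
// (matches stats::median) so R-side brute-force oracles agree bit for bit.
static double buffer_median(std::vector<double> &buf) {
  const size_t n = buf.size();
  const size_t mid = n / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
  double hi = buf[mid];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + mid);
  return (lo + hi) / 2.0;
}

// Disk median filter restricted to pixels sharing the centre pixel's label.
// Pixels whose label equals `exclude` pass through unchanged and never enter
// any footprint. The footprint (centre distance <= radius) is truncated at
// the image border; no padding values are invented.
// [[Rcpp::export(name = ".masked_median_cpp")]]
NumericMatrix masked_median_cpp(NumericMatrix img, IntegerMatrix labels,
                                int radius, int exclude) {
  const int nr = img.nrow(), nc = img.ncol();
  if (labels.nrow() != nr || labels.ncol() != nc)
    stop("image and label rasters must share one shape");
  if (radius < 0) stop("radius must be non-negative");

  // precompute disk offsets
  std::vector<int> dr, dc;
  const int r2 = radius * radius;
  for (int i = -radius; i <= radius; ++i)
    for (int j = -radius; j <= radius; ++j)
      if (i * i + j * j <= r2) { dr.push_back(i); dc.push_back(j); }
  const int nOff = (int)dr.size();

  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(nOff);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int lab = labels(r, c);
      if (lab == exclude) { out(r, c) = img(r, c); continue; }
      buf.clear();
      for (int k = 0; k < nOff; ++k) {
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (labels(rr, cc) != lab) continue;
        buf.push_back(img(rr, cc));
      }
      out(r, c) = buf.empty() ? img(r, c) : buffer_median(buf);
    }
  }
  return out;
}

// ---- union-find connected-component labelling -------------------------------

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];  // path halving
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass union-find labelling of a logical mask. connectivity is 4 or 8.
// Returns an integer matrix with 0 for background and components numbered
// 1..k in raster-scan order of their first pixel.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // dummy so labels start at 1

  // first pass: provisional labels, column-major scan (R layout)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) { lab(r, c) = 0; continue; }
      int best = 0;
      // previously visited neighbours in column-major order
      const int pr[4] = { r - 1, r - 1, r,     r + 1 };
      const int pc[4] = { c,     c - 1, c - 1, c - 1 };
      const int nNb = (connectivity == 8) ? 4 : 2;
      const int use[4] = { 1, connectivity == 8 ? 1 : 0, 1,
                           connectivity == 8 ? 1 : 0 };
      (void)nNb;
      for (int k = 0; k < 4; ++k) {
        if (!use[k]) continue;
        const int rr = pr[k], cc = pc[k];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        const int l = lab(rr, cc);
        if (l == 0) continue;
        if (best == 0) best = l;
        else uf_union(parent, best, l);
      }
      if (best == 0) {
        best = (int)parent.size();
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }

  // second pass: resolve roots and renumber consecutively
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (newlab[root] == 0) newlab[root] = ++next;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}
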