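#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// CRC-32 (IEEE 802.3, reflected), needed for ZIP local file headers.
static uint32_t crc_table[256];
static bool crc_init = false;

static void init_crc() {
  for (uint32_t i = 0; i < 256; ++i) {
    uint32_t c = i;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
    crc_table[i] = c;
  }
  crc_init = true;
}

// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(RawVector x, double init = 0) {
  if (!crc_init) init_crc();
  uint32_t c = (uint32_t)init ^ 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    c = crc_table[(c ^ x[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}

// Binary morphology (dilation/erosion) with an arbitrary structuring element
// and zero-padded borders: pixels outside the frame count as background, so
// erosion shrinks objects at the frame edge (the convention of the standard
// scientific image stacks).
// [[Rcpp::export(name = ".binary_morph")]]
LogicalMatrix binary_morph(LogicalMatrix mask, IntegerMatrix kern,
                           bool dilate) {
  int nr = mask.nrow(), nc = mask.ncol();
  int ry = (kern.nrow() - 1) / 2, rx = (kern.ncol() - 1) / 2;
  std::vector<int> da, db;
  for (int b = 0; b < kern.ncol(); ++b)
    for (int a = 0; a < kern.nrow(); ++a)
      if (kern(a, b)) { da.push_back(a - ry); db.push_back(b - rx); }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!dilate && !mask(i, j)) { out(i, j) = FALSE; continue; }
      bool v = !dilate;
      for (size_t k = 0; k < da.size(); ++k) {
        int ii = i + da[k], jj = j + db[k];
        bool m = ii >= 0 && ii < nr && jj >= 0 && jj < nc && mask(ii, jj);
        if (dilate && m) { v = true; break; }
        if (!dilate && !m) { v = false; break; }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Connected-component labeling of a binary matrix by iterative flood fill.
// connectivity: 4 (orthogonal) or 8 (orthogonal + diagonal).
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int ndir = (connectivity == 8) ? 8 : 4;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int cur = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++cur;
      stack.push_back(i + j * nr);
      lab(i, j) = cur;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int d = 0; d < ndir; ++d) {
          int qi = pi + dr[d], qj = pj + dc[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = cur;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
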