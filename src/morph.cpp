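#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Low-level binary-image morphology used by the segmentation and
// shape-classification code. All matrices are column-major (R layout);
// pixel (i, j) = (row, col).

// 8-connected component labelling (iterative flood fill).
// Returns an integer matrix, 0 = background, components numbered from 1
// in column-major discovery order; attribute "n" carries the count.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) && lab(i, j) == 0) {
        ++cur;
        lab(i, j) = cur;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          const int p = stack.back(); stack.pop_back();
          const int pi = p % nr, pj = p / nr;
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              const int qi = pi + di, qj = pj + dj;
              if (qi >= 0 && qi < nr && qj >= 0 && qj < nc &&
                  mask(qi, qj) && lab(qi, qj) == 0) {
                lab(qi, qj) = cur;
                stack.push_back(qi + qj * nr);
              }
            }
          }
        }
      }
    }
  }
  lab.attr("n") = cur;
  return lab;
}

// Fill interior holes: background is flood-filled (4-connected) from the
// image border; any unreached background pixel is a hole and is set TRUE.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> reached(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if ((i == 0 || i == nr - 1 || j == 0 || j == nc - 1) &&
          !mask(i, j) && !reached[i + j * nr]) {
        reached[i + j * nr] = 1;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          const int p = stack.back(); stack.pop_back();
          const int pi = p % nr, pj = p / nr;
          const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
          for (int k = 0; k < 4; ++k) {
            const int qi = pi + di[k], qj = pj + dj[k];
            if (qi >= 0 && qi < nr && qj >= 0 && qj < nc &&
                !mask(qi, qj) && !reached[qi + qj * nr]) {
              reached[qi + qj * nr] = 1;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !reached[i + j * nr];
  return out;
}

static inline int nb(const LogicalMatrix& m, int i, int j) {
  // safe accessor treating out-of-range as background
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-px skeleton.
// [[Rcpp::export(name = ".thin_mask")]]
LogicalMatrix thin_mask(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          // neighbours P2..P9 clockwise starting at north
          const int p2 = nb(img, i - 1, j),     p3 = nb(img, i - 1, j + 1);
          const int p4 = nb(img, i, j + 1),     p5 = nb(img, i + 1, j + 1);
          const int p6 = nb(img, i + 1, j),     p7 = nb(img, i + 1, j - 1);
          const int p8 = nb(img, i, j - 1),     p9 = nb(img, i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k] % nr, kill[k] / nr) = false;
    }
  }
  return img;
}

// Chamfer (3,4)/3 distance transform: distance from each foreground pixel
// to the nearest background pixel, approximating Euclidean distance in px.
// [[Rcpp::export(name = ".chamfer_dist")]]
NumericMatrix chamfer_dist(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e9, a = 1.0, b = 4.0 / 3.0;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? BIG : 0.0;
  // forward pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i > 0)           v = std::min(v, d(i - 1, j) + a);
      if (j > 0)           v = std::min(v, d(i, j - 1) + a);
      if (i > 0 && j > 0)  v = std::min(v, d(i - 1, j - 1) + b);
      if (i < nr - 1 && j > 0) v = std::min(v, d(i + 1, j - 1) + b);
      d(i, j) = v;
    }
  }
  // backward pass
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i < nr - 1)          v = std::min(v, d(i + 1, j) + a);
      if (j < nc - 1)          v = std::min(v, d(i, j + 1) + a);
      if (i < nr - 1 && j < nc - 1) v = std::min(v, d(i + 1, j + 1) + b);
      if (i > 0 && j < nc - 1) v = std::min(v, d(i - 1, j + 1) + b);
      d(i, j) = v;
    }
  }
  // edge of image counts as boundary at half-pixel distance beyond
  return d;
}
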