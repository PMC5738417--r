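// Grayscale morphological reconstruction by dilation (Vincent 1993,
// hybrid raster-scan + FIFO algorithm, 8-connectivity). Used by the
// segmenter's opening-by-reconstruction step, where a pure-R geodesic
// iteration is orders of magnitude too slow.

#include <Rcpp.h>
#include <queue>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker,
                                       NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have the same shape");
  NumericMatrix I(clone(marker));

  // clamp marker under mask
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (I(i, j) > mask(i, j)) I(i, j) = mask(i, j);

  // forward raster scan: neighbours already visited (N+)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = I(i, j);
      if (i > 0 && I(i - 1, j) > m) m = I(i - 1, j);
      if (j > 0) {
        if (I(i, j - 1) > m) m = I(i, j - 1);
        if (i > 0 && I(i - 1, j - 1) > m) m = I(i - 1, j - 1);
        if (i < nr - 1 && I(i + 1, j - 1) > m) m = I(i + 1, j - 1);
      }
      I(i, j) = std::min(m, mask(i, j));
    }
  }

  // backward raster scan (N-) + seed queue
  std::queue<int> fifo;
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      double m = I(i, j);
      if (i < nr - 1 && I(i + 1, j) > m) m = I(i + 1, j);
      if (j < nc - 1) {
        if (I(i, j + 1) > m) m = I(i, j + 1);
        if (i < nr - 1 && I(i + 1, j + 1) > m) m = I(i + 1, j + 1);
        if (i > 0 && I(i - 1, j + 1) > m) m = I(i - 1, j + 1);
      }
      I(i, j) = std::min(m, mask(i, j));
      // enqueue if a N- neighbour could still grow
      bool enq = false;
      const double v = I(i, j);
      if (i < nr - 1 && I(i + 1, j) < v && I(i + 1, j) < mask(i + 1, j)) enq = true;
      if (!enq && j < nc - 1) {
        if (I(i, j + 1) < v && I(i, j + 1) < mask(i, j + 1)) enq = true;
        else if (i < nr - 1 && I(i + 1, j + 1) < v &&
                 I(i + 1, j + 1) < mask(i + 1, j + 1)) enq = true;
        else if (i > 0 && I(i - 1, j + 1) < v &&
                 I(i - 1, j + 1) < mask(i - 1, j + 1)) enq = true;
      }
      if (enq) fifo.push(i + j * nr);
    }
  }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!fifo.empty()) {
    const int p = fifo.front();
    fifo.pop();
    const int i = p % nr, j = p / nr;
    const double v = I(i, j);
    for (int k = 0; k < 8; ++k) {
      const int qi = i + di[k], qj = j + dj[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (I(qi, qj) < v && I(qi, qj) < mask(qi, qj)) {
        I(qi, qj) = std::min(v, mask(qi, qj));
        fifo.push(qi + qj * nr);
      }
    }
  }
  return I;
}

// Iterated 3x3 grayscale erosion (approximate disk of radius `radius`).
// [[Rcpp::export]]
NumericMatrix cpp_erode_disk(NumericMatrix x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix a(clone(x)), b(nr, nc);
  for (int it = 0; it < radius; ++it) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double m = a(i, j);
        const int i0 = std::max(i - 1, 0), i1 = std::min(i + 1, nr - 1);
        const int j0 = std::max(j - 1, 0), j1 = std::min(j + 1, nc - 1);
        for (int jj = j0; jj <= j1; ++jj)
          for (int ii = i0; ii <= i1; ++ii)
            if (a(ii, jj) < m) m = a(ii, jj);
        b(i, j) = m;
      }
    }
    std::swap(a, b);
  }
  return a;
}
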