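#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Uniform cell-list index over a 2D point set. Cells are sized so that the
// expected occupancy is a few points; queries expand square rings of cells
// until the current k-th best distance is certified against the ring bound.
namespace {

struct CellGrid {
  int nx, ny;
  double x0, y0, cw, ch;
  std::vector<int> cell_start;   // CSR layout: points of cell c are order[cell_start[c] .. cell_start[c+1])
  std::vector<int> order;
  const double *x, *y;
  int n;

  CellGrid(const double *x_, const double *y_, int n_, double pts_per_cell)
      : x(x_), y(y_), n(n_) {
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    double w = std::max(xmax - xmin, 1e-12), h = std::max(ymax - ymin, 1e-12);
    // aim for ~pts_per_cell points per cell, respecting the box aspect ratio
    double target = std::max(1.0, n / pts_per_cell);
    double aspect = w / h;
    // cap each axis at `target` cells so near-degenerate (collinear) point
    // sets cannot blow up one axis to millions of cells
    nx = std::max(1, std::min((int)target,
                              (int)std::floor(std::sqrt(target * aspect))));
    ny = std::max(1, std::min((int)target,
                              (int)std::floor(std::sqrt(target / aspect))));
    x0 = xmin; y0 = ymin;
    cw = w / nx; ch = h / ny;

    std::vector<int> counts(nx * ny + 1, 0);
    std::vector<int> cell_of(n);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)((x[i] - x0) / cw)));
      int cy = std::min(ny - 1, std::max(0, (int)((y[i] - y0) / ch)));
      cell_of[i] = cy * nx + cx;
      ++counts[cell_of[i] + 1];
    }
    for (size_t c = 1; c < counts.size(); ++c) counts[c] += counts[c - 1];
    cell_start = counts;
    order.resize(n);
    std::vector<int> cursor(cell_start.begin(), cell_start.end() - 1);
    for (int i = 0; i < n; ++i) order[cursor[cell_of[i]]++] = i;
  }

  inline int cx_of(double px) const {
    return std::min(nx - 1, std::max(0, (int)((px - x0) / cw)));
  }
  inline int cy_of(double py) const {
    return std::min(ny - 1, std::max(0, (int)((py - y0) / ch)));
  }

  // k smallest squared distances from (px,py) to indexed points, excluding
  // point index `self` (-1 for none). Returns ascending squared distances.
  void query(double px, double py, int k, int self, std::vector<double> &out) const {
    std::priority_queue<double> heap;  // max-heap of current k best d2
    int cx = cx_of(px), cy = cy_of(py);
    int max_ring = std::max(nx, ny);
    double cmin = std::min(cw, ch);
    for (int ring = 0; ring <= max_ring; ++ring) {
      // certified lower bound on distance to any cell at Chebyshev ring L
      if ((int)heap.size() == k) {
        double bound = (ring - 1) * cmin;
        if (ring >= 1 && bound > 0 && heap.top() <= bound * bound) break;
      }
      int xlo = cx - ring, xhi = cx + ring, ylo = cy - ring, yhi = cy + ring;
      bool any = false;
      for (int gy = std::max(ylo, 0); gy <= std::min(yhi, ny - 1); ++gy) {
        for (int gx = std::max(xlo, 0); gx <= std::min(xhi, nx - 1); ++gx) {
          // only the ring boundary (interior already scanned)
          if (ring > 0 && gx != xlo && gx != xhi && gy != ylo && gy != yhi) continue;
          any = true;
          int c = gy * nx + gx;
          for (int p = cell_start[c]; p < cell_start[c + 1]; ++p) {
            int j = order[p];
            if (j == self) continue;
            double dx = x[j] - px, dy = y[j] - py;
            double d2 = dx * dx + dy * dy;
            if ((int)heap.size() < k) heap.push(d2);
            else if (d2 < heap.top()) { heap.pop(); heap.push(d2); }
          }
        }
      }
      if (!any && (int)heap.size() == k) break;
      // the whole grid has been scanned: nothing further to find
      if (xlo <= 0 && ylo <= 0 && xhi >= nx - 1 && yhi >= ny - 1) break;
    }
    out.resize(heap.size());
    for (int i = (int)heap.size() - 1; i >= 0; --i) { out[i] = heap.top(); heap.pop(); }
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".knn_self")]]
NumericMatrix knn_self(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (n != (int)y.size()) stop("x and y lengths differ");
  if (k < 1) stop("k must be >= 1");
  if (n <= k) stop("need at least k + 1 points");
  CellGrid grid(REAL(x), REAL(y), n, 4.0);
  NumericMatrix out(n, k);
  std::vector<double> best;
  for (int i = 0; i < n; ++i) {
    grid.query(x[i], y[i], k, i, best);
    for (int j = 0; j < k; ++j) out(i, j) = std::sqrt(best[j]);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".nn_cross")]]
NumericVector nn_cross(NumericVector xq, NumericVector yq,
                       NumericVector xr, NumericVector yr) {
  int nq = xq.size(), nr = xr.size();
  if (nr == 0) return NumericVector(nq, R_PosInf);
  CellGrid grid(REAL(xr), REAL(yr), nr, 4.0);
  NumericVector out(nq);
  std::vector<double> best;
  for (int i = 0; i < nq; ++i) {
    grid.query(xq[i], yq[i], 1, -1, best);
    out[i] = std::sqrt(best[0]);
  }
  return out;
}
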