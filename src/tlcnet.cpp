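#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sutherland-Hodgman clip of a convex polygon by the half-plane
// { x : (x - m) . n <= 0 }.
static void clip_halfplane(std::vector<double> &px, std::vector<double> &py,
                           double mx, double my, double nx, double ny) {
  const std::size_t n = px.size();
  if (n == 0) return;
  std::vector<double> qx, qy;
  qx.reserve(n + 4);
  qy.reserve(n + 4);
  for (std::size_t a = 0; a < n; ++a) {
    std::size_t b = (a + 1) % n;
    double da = (px[a] - mx) * nx + (py[a] - my) * ny;
    double db = (px[b] - mx) * nx + (py[b] - my) * ny;
    bool ina = da <= 0.0, inb = db <= 0.0;
    if (ina) {
      qx.push_back(px[a]);
      qy.push_back(py[a]);
    }
    if (ina != inb) {
      double t = da / (da - db);
      qx.push_back(px[a] + t * (px[b] - px[a]));
      qy.push_back(py[a] + t * (py[b] - py[a]));
    }
  }
  px.swap(qx);
  py.swap(qy);
}

static double polygon_area(const std::vector<double> &px,
                           const std::vector<double> &py) {
  const std::size_t n = px.size();
  if (n < 3) return 0.0;
  double s = 0.0;
  for (std::size_t a = 0; a < n; ++a) {
    std::size_t b = (a + 1) % n;
    s += px[a] * py[b] - px[b] * py[a];
  }
  return std::fabs(s) * 0.5;
}

//' @name voronoi_cell_areas_cpp
//' @title Areas of Voronoi cells clipped to a rectangle
//' @description For each site, intersects the bounding rectangle with the
//'   half-planes of the perpendicular bisectors towards every other site,
//'   visiting sites in order of increasing distance and stopping once no
//'   farther site can cut the current cell. Coincident sites share a cell
//'   (their bisector is skipped).
//' @keywords internal
// [[Rcpp::export]]
NumericVector voronoi_cell_areas_cpp(NumericMatrix pts, double xmin,
                                     double xmax, double ymin, double ymax) {
  const int n = pts.nrow();
  NumericVector areas(n);
  std::vector<int> ord(n);
  std::vector<double> d2(n);

  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1);
    for (int j = 0; j < n; ++j) {
      double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi;
      d2[j] = dx * dx + dy * dy;
      ord[j] = j;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d2[a] < d2[b]; });

    std::vector<double> px = {xmin, xmax, xmax, xmin};
    std::vector<double> py = {ymin, ymin, ymax, ymax};

    for (int s = 0; s < n; ++s) {
      int j = ord[s];
      if (j == i || d2[j] <= 0.0) continue;
      // farthest cell vertex from the site bounds which bisectors can cut
      double r2 = 0.0;
      for (std::size_t a = 0; a < px.size(); ++a) {
        double dx = px[a] - xi, dy = py[a] - yi;
        double v = dx * dx + dy * dy;
        if (v > r2) r2 = v;
      }
      if (d2[j] > 4.0 * r2) break;  // bisector at d/2 > max radius: no cut
      double nx = pts(j, 0) - xi, ny = pts(j, 1) - yi;
      double mx = xi + 0.5 * nx, my = yi + 0.5 * ny;
      clip_halfplane(px, py, mx, my, nx, ny);
      if (px.size() < 3) break;
    }
    areas[i] = polygon_area(px, py);
  }
  return areas;
}

//' @name stress_cpp
//' @title Residual-sum-of-squares stress of an embedding
//' @description sqrt of the sum over unordered pairs of squared differences
//'   between target distances and embedded Euclidean distances. Pairs with a
//'   non-finite target distance are skipped.
//' @keywords internal
// [[Rcpp::export]]
double stress_cpp(NumericVector coords, NumericMatrix dmat, int D) {
  const int N = dmat.nrow();
  double s = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = dmat(i, j);
      if (!std::isfinite(d)) continue;
      double e2 = 0.0;
      for (int w = 0; w < D; ++w) {
        double diff = coords[i + w * N] - coords[j + w * N];
        e2 += diff * diff;
      }
      double r = d - std::sqrt(e2);
      s += r * r;
    }
  }
  return std::sqrt(s);
}
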