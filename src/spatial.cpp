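// Uniform-grid spatial index for nearest-ball queries (clearance, lining
// contacts) and the confined flood fill that labels surface vertices.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

struct Grid {
  double x0[3], cell;
  int dim[3];
  std::vector<std::vector<int> > bins;
  const NumericMatrix *C;

  void build(const NumericMatrix &centers, double cellSize) {
    C = &centers;
    int n = centers.nrow();
    cell = cellSize;
    double hi[3];
    for (int j = 0; j < 3; ++j) { x0[j] = centers(0, j); hi[j] = centers(0, j); }
    for (int i = 1; i < n; ++i)
      for (int j = 0; j < 3; ++j) {
        if (centers(i, j) < x0[j]) x0[j] = centers(i, j);
        if (centers(i, j) > hi[j]) hi[j] = centers(i, j);
      }
    for (int j = 0; j < 3; ++j) {
      dim[j] = std::max(1, (int)std::floor((hi[j] - x0[j]) / cell) + 1);
      dim[j] = std::min(dim[j], 128);
      // keep cell size consistent with clamped dims
    }
    // recompute effective cell so the grid still covers the box
    for (int j = 0; j < 3; ++j) {
      double span = hi[j] - x0[j];
      if (span > cell * dim[j]) cell = span / dim[j] + 1e-9;
    }
    bins.assign((size_t)dim[0] * dim[1] * dim[2], std::vector<int>());
    for (int i = 0; i < n; ++i) bins[cellOf(centers(i, 0), centers(i, 1), centers(i, 2))].push_back(i);
  }

  inline int clampi(int v, int lo, int hi_) const {
    return v < lo ? lo : (v > hi_ ? hi_ : v);
  }
  inline size_t cellOf(double x, double y, double z) const {
    int ix = clampi((int)std::floor((x - x0[0]) / cell), 0, dim[0] - 1);
    int iy = clampi((int)std::floor((y - x0[1]) / cell), 0, dim[1] - 1);
    int iz = clampi((int)std::floor((z - x0[2]) / cell), 0, dim[2] - 1);
    return ((size_t)ix * dim[1] + iy) * dim[2] + iz;
  }

  // min over balls of (|q - c_i| - r_i); maxR = max ball radius
  double nearestGap(const double *q, const NumericVector &radii,
                    double maxR) const {
    int iq[3];
    for (int j = 0; j < 3; ++j)
      iq[j] = (int)std::floor((q[j] - x0[j]) / cell);
    double best = std::numeric_limits<double>::infinity();
    int offs = 0;  // queries may fall outside the grid box
    for (int j = 0; j < 3; ++j) {
      if (iq[j] < 0) offs = std::max(offs, -iq[j]);
      if (iq[j] > dim[j] - 1) offs = std::max(offs, iq[j] - (dim[j] - 1));
    }
    int maxShell = dim[0] + dim[1] + dim[2] + offs + 2;
    for (int k = 0; k <= maxShell; ++k) {
      // lower bound on center distance for cells in shell k
      double bound;
      if (k == 0) bound = 0.0;
      else {
        // distance from q to nearest face of the shell-k cube boundary,
        // conservatively (k-1) whole cells beyond the cell borders
        bound = (k - 1) * cell;
        double inCell = std::numeric_limits<double>::infinity();
        for (int j = 0; j < 3; ++j) {
          double lo = x0[j] + iq[j] * cell, hi = lo + cell;
          inCell = std::min(inCell, std::min(q[j] - lo, hi - q[j]));
        }
        if (inCell > 0) bound += inCell;
        if (bound < 0) bound = 0;
      }
      if (bound - maxR >= best) break;
      for (int dx = -k; dx <= k; ++dx) {
        int ix = iq[0] + dx;
        if (ix < 0 || ix >= dim[0]) continue;
        for (int dy = -k; dy <= k; ++dy) {
          int iy = iq[1] + dy;
          if (iy < 0 || iy >= dim[1]) continue;
          bool face = (std::abs(dx) == k || std::abs(dy) == k);
          for (int dz = -k; dz <= k; ++dz) {
            if (!face && std::abs(dz) != k) continue;  // shell cells only
            int iz = iq[2] + dz;
            if (iz < 0 || iz >= dim[2]) continue;
            const std::vector<int> &bin =
                bins[((size_t)ix * dim[1] + iy) * dim[2] + iz];
            for (int i : bin) {
              double d2 = 0;
              for (int j = 0; j < 3; ++j) {
                double d = q[j] - (*C)(i, j);
                d2 += d * d;
              }
              double gap = std::sqrt(d2) - radii[i];
              if (gap < best) best = gap;
            }
          }
        }
      }
    }
    return best;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_nearest_gap")]]
NumericVector cpp_nearest_gap(NumericMatrix queries, NumericMatrix centers,
                              NumericVector radii) {
  if (centers.nrow() == 0) stop("empty ball set");
  if (centers.nrow() != radii.size()) stop("centers/radii length mismatch");
  double maxR = 0;
  for (double r : radii) maxR = std::max(maxR, r);
  Grid g;
  g.build(centers, std::max(2.0, 2.0 * maxR));
  int m = queries.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double q[3] = {queries(i, 0), queries(i, 1), queries(i, 2)};
    out[i] = g.nearestGap(q, radii, maxR);
  }
  return out;
}

// Confined flood fill for surface-vertex labelling: from every bulk-solvent
// vertex A (ball radius rA), BFS over edges traversable by the probe r_B,
// visiting only vertices within rA + d_s of A.  Non-bulk vertices reached
// this way are surface vertices.
// [[Rcpp::export(name = ".cpp_surface_fill")]]
LogicalVector cpp_surface_fill(IntegerMatrix edges, NumericVector edgeMinCl,
                               NumericMatrix vpos, LogicalVector isBulk,
                               NumericVector bulkRadius, double rB,
                               double ds) {
  int V = vpos.nrow(), E = edges.nrow();
  // CSR adjacency over traversable edges
  std::vector<int> deg(V, 0);
  for (int e = 0; e < E; ++e)
    if (edgeMinCl[e] >= rB) {
      ++deg[edges(e, 0) - 1];
      ++deg[edges(e, 1) - 1];
    }
  std::vector<int> off(V + 1, 0);
  for (int v = 0; v < V; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(off[V]);
  std::vector<int> fill(off.begin(), off.end() - 1);
  for (int e = 0; e < E; ++e)
    if (edgeMinCl[e] >= rB) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      adj[fill[a]++] = b;
      adj[fill[b]++] = a;
    }
  std::vector<int> mark(V, -1);
  std::vector<int> queue;
  LogicalVector surface(V, false);
  for (int A = 0; A < V; ++A) {
    if (!isBulk[A]) continue;
    double lim = bulkRadius[A] + ds;
    double lim2 = lim * lim;
    queue.clear();
    queue.push_back(A);
    mark[A] = A;
    while (!queue.empty()) {
      int v = queue.back();
      queue.pop_back();
      for (int k = off[v]; k < off[v + 1]; ++k) {
        int w = adj[k];
        if (mark[w] == A) continue;
        double d2 = 0;
        for (int j = 0; j < 3; ++j) {
          double d = vpos(w, j) - vpos(A, j);
          d2 += d * d;
        }
        if (d2 > lim2) continue;
        mark[w] = A;
        if (!isBulk[w]) surface[w] = true;
        queue.push_back(w);
      }
    }
  }
  return surface;
}

// Trapezoidal cost integral along each Voronoi edge.  For edges whose three
// defining sites are real balls, the clearance along the edge equals
// (distance to any defining center) - ballRadius; the minimum over the three
// is used for numerical safety.  Edges involving far dummy sites get their
// clearance from the global grid query.
// [[Rcpp::export(name = ".cpp_edge_costs")]]
NumericVector cpp_edge_costs(IntegerMatrix edges, IntegerMatrix edgeSites,
                             NumericMatrix vpos, NumericMatrix sites,
                             double ballRadius, NumericMatrix centers,
                             NumericVector radii, double n, double rmax) {
  int E = edges.nrow();
  NumericVector out(E);
  double maxR = 0;
  for (double r : radii) maxR = std::max(maxR, r);
  Grid g;
  g.build(centers, std::max(2.0, 2.0 * maxR));
  for (int e = 0; e < E; ++e) {
    const int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    double p0[3], dvec[3], L2 = 0;
    for (int j = 0; j < 3; ++j) {
      p0[j] = vpos(a, j);
      dvec[j] = vpos(b, j) - vpos(a, j);
      L2 += dvec[j] * dvec[j];
    }
    double L = std::sqrt(L2);
    if (L <= 0) { out[e] = 0; continue; }
    int T = std::max(8, (int)std::ceil(L / 0.1));
    bool realSites = edgeSites(e, 0) > 0;
    double s1[3], s2[3], s3[3];
    if (realSites) {
      for (int j = 0; j < 3; ++j) {
        s1[j] = sites(edgeSites(e, 0) - 1, j);
        s2[j] = sites(edgeSites(e, 1) - 1, j);
        s3[j] = sites(edgeSites(e, 2) - 1, j);
      }
    }
    double sum = 0;
    for (int t = 0; t <= T; ++t) {
      double q[3];
      double f = (double)t / T;
      for (int j = 0; j < 3; ++j) q[j] = p0[j] + f * dvec[j];
      double r;
      if (realSites) {
        double dmin = std::numeric_limits<double>::infinity();
        for (const double *s : {s1, s2, s3}) {
          double d2 = 0;
          for (int j = 0; j < 3; ++j) {
            double d = q[j] - s[j];
            d2 += d * d;
          }
          dmin = std::min(dmin, d2);
        }
        r = std::sqrt(dmin) - ballRadius;
      } else {
        r = g.nearestGap(q, radii, maxR);
      }
      if (r < 0.1) r = 0.1;
      if (r > rmax) r = rmax;
      double w = (t == 0 || t == T) ? 0.5 : 1.0;
      sum += w / std::pow(r, n);
    }
    out[e] = sum * (L / T);
  }
  return out;
}
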