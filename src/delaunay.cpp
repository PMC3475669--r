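// Incremental 3D Delaunay triangulation (Bowyer-Watson) for the Voronoi
// skeleton of the equal-radius ball representation.  Inputs are expected to
// be pre-perturbed (no four co-planar / five co-spherical sites); on a
// degeneracy the routine returns status != 0 and the caller re-perturbs.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];      // vertex indices, positively oriented
  int nb[4];     // neighbour opposite v[i], -1 = none
  double cc[3];  // circumcenter
  double r2;     // squared circumradius
  bool alive;
};

inline double orient3d(const double *a, const double *b, const double *c,
                       const double *d) {
  double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
         adz * (bdx * cdy - bdy * cdx);
}

// circumcenter of 4 points; returns false when (near-)degenerate
bool circumsphere(const double *a, const double *b, const double *c,
                  const double *d, double *cc, double &r2) {
  double m[3][3], rhs[3];
  const double *pts[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    rhs[i] = 0.0;
    for (int j = 0; j < 3; ++j) {
      m[i][j] = 2.0 * (pts[i][j] - a[j]);
      rhs[i] += pts[i][j] * pts[i][j] - a[j] * a[j];
    }
  }
  double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
               m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
               m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (std::fabs(det) < 1e-12) return false;
  double inv = 1.0 / det;
  cc[0] = inv * (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                 m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
                 m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2]));
  cc[1] = inv * (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
                 rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                 m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]));
  cc[2] = inv * (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
                 m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
                 rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]));
  double dx = a[0] - cc[0], dy = a[1] - cc[1], dz = a[2] - cc[2];
  r2 = dx * dx + dy * dy + dz * dz;
  return true;
}

class Triangulation {
public:
  std::vector<double> pts;  // (n+4) * 3, super-tetra vertices appended
  std::vector<Tet> tets;
  int n;        // number of input points
  int status;   // 0 ok, 1 degenerate
  std::vector<int> stamp;
  int stampVal;

  const double *P(int i) const { return &pts[3 * (size_t)i]; }

  bool makeTet(int a, int b, int c, int d, Tet &t) {
    if (orient3d(P(a), P(b), P(c), P(d)) < 0) std::swap(c, d);
    if (orient3d(P(a), P(b), P(c), P(d)) <= 0) return false;
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.nb[0] = t.nb[1] = t.nb[2] = t.nb[3] = -1;
    t.alive = true;
    return circumsphere(P(a), P(b), P(c), P(d), t.cc, t.r2);
  }

  inline bool inSphere(const Tet &t, const double *p) const {
    double dx = p[0] - t.cc[0], dy = p[1] - t.cc[1], dz = p[2] - t.cc[2];
    return dx * dx + dy * dy + dz * dz < t.r2 * (1.0 + 1e-12);
  }

  // walk toward p from tetra `from`; returns containing tetra or -1
  int locate(int from, const double *p) {
    int cur = from, steps = 0, limit = (int)tets.size() * 4 + 1000;
    unsigned rng = 12345u;
    while (steps++ < limit) {
      const Tet &t = tets[cur];
      int moved = -1;
      rng = rng * 1664525u + 1013904223u;
      int off = (int)(rng % 4u);
      for (int k = 0; k < 4; ++k) {
        int f = (k + off) & 3;
        int fa = t.v[(f + 1) & 3], fb = t.v[(f + 2) & 3], fc = t.v[(f + 3) & 3];
        double sref = orient3d(P(fa), P(fb), P(fc), P(t.v[f]));
        double sp = orient3d(P(fa), P(fb), P(fc), p);
        if (sref * sp < 0) {
          if (t.nb[f] < 0) return -1;  // outside hull (cannot happen in super-tet)
          moved = t.nb[f];
          break;
        }
      }
      if (moved < 0) return cur;
      cur = moved;
    }
    // walk failed (numerical cycling): linear scan
    for (size_t i = 0; i < tets.size(); ++i)
      if (tets[i].alive && inSphere(tets[i], p)) return (int)i;
    return -1;
  }

  void insert(int ip) {
    const double *p = P(ip);
    int t0 = locate(lastTet, p);
    if (t0 < 0 || !tets[t0].alive) { status = 1; return; }
    // cavity: BFS over circumsphere-violating neighbours
    ++stampVal;
    std::vector<int> cavity, queue;
    queue.push_back(t0);
    stamp[t0] = stampVal;
    while (!queue.empty()) {
      int t = queue.back(); queue.pop_back();
      cavity.push_back(t);
      for (int f = 0; f < 4; ++f) {
        int nb = tets[t].nb[f];
        if (nb >= 0 && tets[nb].alive && stamp[nb] != stampVal &&
            inSphere(tets[nb], p)) {
          stamp[nb] = stampVal;
          queue.push_back(nb);
        }
      }
    }
    // boundary faces
    struct BFace { int a, b, c, outer; };
    std::vector<BFace> faces;
    for (int t : cavity) {
      for (int f = 0; f < 4; ++f) {
        int nb = tets[t].nb[f];
        if (nb < 0 || stamp[nb] != stampVal) {
          BFace bf;
          bf.a = tets[t].v[(f + 1) & 3];
          bf.b = tets[t].v[(f + 2) & 3];
          bf.c = tets[t].v[(f + 3) & 3];
          bf.outer = nb;
          faces.push_back(bf);
        }
      }
    }
    for (int t : cavity) tets[t].alive = false;
    // retriangulate: one new tetra per boundary face
    std::map<std::pair<int, int>, std::pair<int, int> > edgeMap;
    std::vector<int> created;
    for (const BFace &bf : faces) {
      Tet nt;
      if (!makeTet(ip, bf.a, bf.b, bf.c, nt)) { status = 1; return; }
      int id;
      tets.push_back(nt);
      id = (int)tets.size() - 1;
      stamp.push_back(0);
      created.push_back(id);
      // face opposite the new point (index of ip in nt.v)
      int ipi = 0;
      for (int k = 0; k < 4; ++k) if (tets[id].v[k] == ip) ipi = k;
      tets[id].nb[ipi] = bf.outer;
      if (bf.outer >= 0) {
        Tet &ot = tets[bf.outer];
        for (int f = 0; f < 4; ++f) {
          // neighbour face of outer tetra not containing its opposite vertex:
          // identify by matching the three shared vertices
          int fa = ot.v[(f + 1) & 3], fb = ot.v[(f + 2) & 3],
              fc = ot.v[(f + 3) & 3];
          int match = 0;
          for (int x : {fa, fb, fc})
            if (x == bf.a || x == bf.b || x == bf.c) ++match;
          if (match == 3) { ot.nb[f] = id; break; }
        }
      }
      // internal faces: contain ip and an edge of the boundary face
      for (int k = 0; k < 4; ++k) {
        if (tets[id].v[k] == ip) continue;
        int e1 = -1, e2 = -1;
        for (int m = 0; m < 4; ++m) {
          if (m == k || tets[id].v[m] == ip) continue;
          if (e1 < 0) e1 = tets[id].v[m]; else e2 = tets[id].v[m];
        }
        std::pair<int, int> key(std::min(e1, e2), std::max(e1, e2));
        auto it = edgeMap.find(key);
        if (it == edgeMap.end()) {
          edgeMap[key] = std::make_pair(id, k);
        } else {
          tets[id].nb[k] = it->second.first;
          tets[it->second.first].nb[it->second.second] = id;
          edgeMap.erase(it);
        }
      }
    }
    if (!edgeMap.empty()) { status = 1; return; }
    lastTet = created.empty() ? 0 : created.back();
  }

  int lastTet;

  void build(const NumericMatrix &x) {
    n = x.nrow();
    status = 0;
    pts.resize(3 * (size_t)(n + 4));
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 3; ++j) pts[3 * (size_t)i + j] = x(i, j);
    // super-tetra around the bounding sphere
    double c[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 3; ++j) c[j] += x(i, j);
    for (int j = 0; j < 3; ++j) c[j] /= n;
    double R = 1.0;
    for (int i = 0; i < n; ++i) {
      double d2 = 0;
      for (int j = 0; j < 3; ++j) {
        double d = x(i, j) - c[j];
        d2 += d * d;
      }
      if (d2 > R) R = d2;
    }
    R = std::sqrt(R) * 100.0 + 100.0;
    const double dir[4][3] = {{1, 1, 1}, {1, -1, -1}, {-1, 1, -1}, {-1, -1, 1}};
    for (int k = 0; k < 4; ++k)
      for (int j = 0; j < 3; ++j)
        pts[3 * (size_t)(n + k) + j] = c[j] + 3.0 * R * dir[k][j];
    Tet t0;
    if (!makeTet(n, n + 1, n + 2, n + 3, t0)) { status = 1; return; }
    tets.push_back(t0);
    stamp.assign(1, 0);
    stampVal = 0;
    lastTet = 0;
    for (int i = 0; i < n && status == 0; ++i) insert(i);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_delaunay")]]
List cpp_delaunay(NumericMatrix pts) {
  Triangulation tr;
  tr.build(pts);
  if (tr.status != 0)
    return List::create(_["status"] = tr.status);
  int m = 0;
  for (const Tet &t : tr.tets)
    if (t.alive && t.v[0] < tr.n && t.v[1] < tr.n && t.v[2] < tr.n &&
        t.v[3] < tr.n)
      ++m;
  IntegerMatrix tet(m, 4);
  NumericMatrix cc(m, 3);
  NumericVector cr2(m);
  int r = 0;
  for (const Tet &t : tr.tets) {
    if (!(t.alive && t.v[0] < tr.n && t.v[1] < tr.n && t.v[2] < tr.n &&
          t.v[3] < tr.n))
      continue;
    int v[4] = {t.v[0], t.v[1], t.v[2], t.v[3]};
    std::sort(v, v + 4);
    for (int j = 0; j < 4; ++j) tet(r, j) = v[j] + 1;  // 1-based for R
    for (int j = 0; j < 3; ++j) cc(r, j) = t.cc[j];
    cr2[r] = t.r2;
    ++r;
  }
  return List::create(_["status"] = 0, _["tetra"] = tet,
                      _["circumcenter"] = cc, _["circumradius2"] = cr2);
}
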