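#ifndef MICROMIX_LATTICE_CORE_H
#define MICROMIX_LATTICE_CORE_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>

// Shared on-lattice cell machinery used by both simulators.
//
// Sites live on an X * Y * Z grid, periodic in x and y, with z = 0 the
// colonization surface.  Each occupied site holds exactly one cell and every
// cell rests either on the surface or on another cell (no floating cells).
// Division follows the side-budding rule: a mother buds toward the nearest
// empty coplanar site within its confinement radius, shifting the
// intervening chain of cells outward by one step; if the confinement
// neighborhood is full it buds upward, pushing the column above it up.

namespace micromix {

struct Cell {
  int pop;        // population / strain id (1-based)
  int x, y, z;
  bool alive;
  double quota;   // accumulated limiting nutrient (diffusion model), fmole
  double birth;   // simulation hours
};

struct Lattice {
  int X, Y, Z;
  std::vector<int> site;   // site -> cell index + 1, or 0 when empty
  std::vector<Cell> cells;

  Lattice(int X_, int Y_, int Z_) : X(X_), Y(Y_), Z(Z_),
    site(static_cast<size_t>(X_) * Y_ * Z_, 0) {}

  inline size_t idx(int x, int y, int z) const {
    return static_cast<size_t>(x) + static_cast<size_t>(X) *
           (static_cast<size_t>(y) + static_cast<size_t>(Y) * z);
  }
  inline int wrapx(int x) const { x %= X; return x < 0 ? x + X : x; }
  inline int wrapy(int y) const { y %= Y; return y < 0 ? y + Y : y; }
  inline int at(int x, int y, int z) const { return site[idx(x, y, z)]; }
  inline bool empty_at(int x, int y, int z) const { return at(x, y, z) == 0; }

  int add_cell(int pop, int x, int y, int z, bool alive = true,
               double quota = 0.0, double birth = 0.0) {
    Cell c{pop, x, y, z, alive, quota, birth};
    cells.push_back(c);
    site[idx(x, y, z)] = static_cast<int>(cells.size());
    return static_cast<int>(cells.size()) - 1;
  }

  void move_cell(int ci, int x, int y, int z) {
    Cell &c = cells[ci];
    site[idx(c.x, c.y, c.z)] = 0;
    c.x = x; c.y = y; c.z = z;
    site[idx(x, y, z)] = ci + 1;
  }

  // Drop a cell straight down until it rests on another cell or the surface.
  void settle(int ci) {
    Cell &c = cells[ci];
    int z = c.z;
    while (z > 0 && empty_at(c.x, c.y, z - 1)) --z;
    if (z != c.z) move_cell(ci, c.x, c.y, z);
  }
};

// Live-cell occupancy fractions per population in the cubic three-axial
// interaction neighborhood of halfwidth l around (x,y,z): wrapped in x,y,
// clipped at the z bounds.  Denominator is the clipped cube size.
inline void occupancy_counts(const Lattice &lat, int x, int y, int z, int l,
                             int npop, std::vector<int> &counts,
                             int &cube_sites) {
  std::fill(counts.begin(), counts.end(), 0);
  int zlo = std::max(0, z - l), zhi = std::min(lat.Z - 1, z + l);
  cube_sites = (2 * l + 1) * (2 * l + 1) * (zhi - zlo + 1);
  for (int dz = zlo; dz <= zhi; ++dz)
    for (int dy = -l; dy <= l; ++dy) {
      int yy = lat.wrapy(y + dy);
      for (int dx = -l; dx <= l; ++dx) {
        int ci = lat.at(lat.wrapx(x + dx), yy, dz);
        if (ci > 0) {
          const Cell &c = lat.cells[ci - 1];
          if (c.alive && c.pop >= 1 && c.pop <= npop) ++counts[c.pop - 1];
        }
      }
    }
}

// Nearest empty site in the same z-plane within Euclidean distance n of
// (x,y); ties broken uniformly at random with R's RNG.  Returns true and
// fills (tx,ty) when found.
inline bool nearest_empty_coplanar(const Lattice &lat, int x, int y, int z,
                                   int n, int &tx, int &ty) {
  double best = 1e30;
  int nties = 0;
  for (int dy = -n; dy <= n; ++dy)
    for (int dx = -n; dx <= n; ++dx) {
      if (dx == 0 && dy == 0) continue;
      double d2 = static_cast<double>(dx) * dx + static_cast<double>(dy) * dy;
      if (d2 > static_cast<double>(n) * n + 1e-9) continue;
      int xx = lat.wrapx(x + dx), yy = lat.wrapy(y + dy);
      if (!lat.empty_at(xx, yy, z)) continue;
      if (d2 < best - 1e-9) {
        best = d2; nties = 1; tx = xx; ty = yy;
      } else if (std::fabs(d2 - best) <= 1e-9) {
        ++nties;
        // reservoir sampling keeps the choice uniform over ties
        if (unif_rand() < 1.0 / nties) { tx = xx; ty = yy; }
      }
    }
  return nties > 0;
}

// Integer Bresenham path from (x0,y0) toward the wrapped displacement
// (dx,dy), excluding the start point.  Coordinates are wrapped.
inline void bresenham_path(const Lattice &lat, int x0, int y0, int dx, int dy,
                           std::vector<std::pair<int, int> > &path) {
  path.clear();
  int sx = dx > 0 ? 1 : -1, sy = dy > 0 ? 1 : -1;
  int ax = std::abs(dx), ay = std::abs(dy);
  int x = 0, y = 0, err = ax - ay;
  while (x != dx || y != dy) {
    int e2 = 2 * err;
    if (e2 > -ay) { err -= ay; x += sx; }
    if (e2 < ax)  { err += ax; y += sy; }
    path.push_back(std::make_pair(lat.wrapx(x0 + x), lat.wrapy(y0 + y)));
  }
}

// Minimal signed wrapped displacement from a to b along a periodic axis.
inline int wrapped_delta(int a, int b, int n) {
  int d = b - a;
  if (d > n / 2) d -= n;
  if (d < -n / 2) d += n;
  return d;
}

// Place a daughter of cell `mi`.  If (tx,ty) is a valid empty coplanar
// target, cells along the straight lattice path from the mother toward the
// target shift one step outward and the daughter takes the site adjacent to
// the mother on that path; a shifted cell landing on empty space settles
// down.  With no target (has_target false) the mother's column above it
// shifts up one and the daughter takes the site directly above the mother.
// Returns the daughter's cell index, or -1 on z overflow.
inline int place_daughter(Lattice &lat, int mi, bool has_target, int tx,
                          int ty, int pop, double quota, double birth) {
  const Cell m = lat.cells[mi];
  if (has_target) {
    int dx = wrapped_delta(m.x, tx, lat.X);
    int dy = wrapped_delta(m.y, ty, lat.Y);
    std::vector<std::pair<int, int> > path;
    bresenham_path(lat, m.x, m.y, dx, dy, path);
    // chain runs to the first empty site on the path (the target, unless a
    // nearer path site happens to be free)
    size_t e = 0;
    while (e < path.size() &&
           !lat.empty_at(path[e].first, path[e].second, m.z)) ++e;
    if (e == path.size()) e = path.size() - 1;  // defensive; target is empty
    for (size_t k = e; k >= 1; --k) {
      int ci = lat.at(path[k - 1].first, path[k - 1].second, m.z) - 1;
      lat.move_cell(ci, path[k].first, path[k].second, m.z);
    }
    int di = lat.add_cell(pop, path[0].first, path[0].second, m.z, true,
                          quota, birth);
    // only the cell that moved onto the previously empty site can float
    int last = lat.at(path[e].first, path[e].second, m.z) - 1;
    if (last >= 0 && last != di) lat.settle(last);
    lat.settle(di);
    return di;
  }
  // vertical push-up
  int zt = m.z;
  while (zt + 1 < lat.Z && !lat.empty_at(m.x, m.y, zt + 1)) ++zt;
  if (zt + 1 >= lat.Z) return -1;  // column full: overflow
  for (int z = zt; z > m.z; --z) {
    int ci = lat.at(m.x, m.y, z) - 1;
    lat.move_cell(ci, m.x, m.y, z + 1);
  }
  return lat.add_cell(pop, m.x, m.y, m.z + 1, true, quota, birth);
}

// Divide cell mi using the standard rearrangement rules (nearest empty
// coplanar within radius n, else push up).  Returns daughter index or -1 on
// overflow.
inline int divide_cell(Lattice &lat, int mi, int n, double quota,
                       double birth) {
  const Cell &m = lat.cells[mi];
  int tx = 0, ty = 0;
  bool found = nearest_empty_coplanar(lat, m.x, m.y, m.z, n, tx, ty);
  return place_daughter(lat, mi, found, tx, ty, m.pop, quota, birth);
}

// Signed population codes (+pop live, -pop dead) as an R array.
inline Rcpp::IntegerVector lattice_to_array(const Lattice &lat) {
  Rcpp::IntegerVector out(lat.site.size());
  for (size_t i = 0; i < lat.site.size(); ++i) {
    int ci = lat.site[i];
    out[i] = ci == 0 ? 0 : (lat.cells[ci - 1].alive ? lat.cells[ci - 1].pop
                                                    : -lat.cells[ci - 1].pop);
  }
  out.attr("dim") = Rcpp::IntegerVector::create(lat.X, lat.Y, lat.Z);
  return out;
}

inline Lattice lattice_from_array(const Rcpp::IntegerVector &arr) {
  Rcpp::IntegerVector d = arr.attr("dim");
  Lattice lat(d[0], d[1], d[2]);
  for (int z = 0; z < lat.Z; ++z)
    for (int y = 0; y < lat.Y; ++y)
      for (int x = 0; x < lat.X; ++x) {
        int v = arr[lat.idx(x, y, z)];
        if (v != 0) lat.add_cell(std::abs(v), x, y, z, v > 0);
      }
  return lat;
}

// 90th-percentile (type 7) of per-column heights; height = 1 + topmost
// occupied z, 0 for empty columns.
inline double height_p90(const Lattice &lat) {
  std::vector<double> h(static_cast<size_t>(lat.X) * lat.Y, 0.0);
  size_t k = 0;
  for (int y = 0; y < lat.Y; ++y)
    for (int x = 0; x < lat.X; ++x, ++k)
      for (int z = lat.Z - 1; z >= 0; --z)
        if (!lat.empty_at(x, y, z)) { h[k] = z + 1; break; }
  std::sort(h.begin(), h.end());
  double pos = 0.9 * (h.size() - 1);
  size_t lo = static_cast<size_t>(std::floor(pos));
  double frac = pos - lo;
  if (lo + 1 >= h.size()) return h[lo];
  return h[lo] * (1 - frac) + h[lo + 1] * frac;
}

}  // namespace micromix

#endif
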