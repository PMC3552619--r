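#include "lattice_core.h"
using namespace Rcpp;
using namespace micromix;

// Nutrient bookkeeping is done in amounts (fmole) per diffusion grid.
// Concentrations are in uM; amount = conc * volume * 1e-6 with volume in
// um^3 (1 uM = 1e-6 fmole/um^3).
static const double CONV = 1e-6;

namespace {

struct Geometry {
  int Gx, Gy, Gz;      // community grids
  int Ax, Ay, Az;      // agarose grids (Az may be 0: no agarose zone)
  double gc_um, ga_um; // grid edges, um
  double Vc, Va;       // grid volumes, um^3
  int lat_ratio;       // ga/gc (agarose grids per community grid, laterally)
  size_t cidx(int x, int y, int z) const {
    return static_cast<size_t>(x) + static_cast<size_t>(Gx) *
           (static_cast<size_t>(y) + static_cast<size_t>(Gy) * z);
  }
  size_t aidx(int x, int y, int z) const {
    return static_cast<size_t>(x) + static_cast<size_t>(Ax) *
           (static_cast<size_t>(y) + static_cast<size_t>(Ay) * z);
  }
};

inline int wrapi(int v, int n) { v %= n; return v < 0 ? v + n : v; }

// One explicit (FTCS) diffusion substep on amounts for a single nutrient.
// Community: periodic x/y, no-flux top, coupled to agarose below.
// Agarose: periodic x/y, no-flux bottom.  Interface fluxes use the
// harmonic-mean diffusion constant over the community-grid contact area, so
// mass is conserved exactly.  instant = replace community internal diffusion
// by uniform redistribution over all community grids.
struct Scratch {
  std::vector<double> Cc, dAc, Ca, dAa;
};

void ftcs_substep(std::vector<double> &Ac, std::vector<double> &Aa,
                  const Geometry &g, double Dc, double Da, double dt,
                  bool instant, Scratch &scr) {
  const size_t nc = Ac.size(), na = Aa.size();
  scr.Cc.resize(nc); scr.dAc.assign(nc, 0.0);
  std::vector<double> &Cc = scr.Cc, &dAc = scr.dAc;
  for (size_t i = 0; i < nc; ++i) Cc[i] = Ac[i] / (g.Vc * CONV);

  if (!instant && Dc > 0) {
    const double fc = Dc * g.gc_um * dt * CONV;
    for (int z = 0; z < g.Gz; ++z)
      for (int y = 0; y < g.Gy; ++y)
        for (int x = 0; x < g.Gx; ++x) {
          size_t i = g.cidx(x, y, z);
          // +x and +y faces (periodic), +z internal face
          size_t jx = g.cidx(wrapi(x + 1, g.Gx), y, z);
          double q = fc * (Cc[jx] - Cc[i]);
          dAc[i] += q; dAc[jx] -= q;
          size_t jy = g.cidx(x, wrapi(y + 1, g.Gy), z);
          q = fc * (Cc[jy] - Cc[i]);
          dAc[i] += q; dAc[jy] -= q;
          if (z + 1 < g.Gz) {
            size_t jz = g.cidx(x, y, z + 1);
            q = fc * (Cc[jz] - Cc[i]);
            dAc[i] += q; dAc[jz] -= q;
          }
        }
  }

  if (na > 0) {
    scr.Ca.resize(na); scr.dAa.assign(na, 0.0);
    std::vector<double> &Ca = scr.Ca, &dAa = scr.dAa;
    for (size_t i = 0; i < na; ++i) Ca[i] = Aa[i] / (g.Va * CONV);
    if (Da > 0) {
      const double fa = Da * g.ga_um * dt * CONV;
      for (int z = 0; z < g.Az; ++z)
        for (int y = 0; y < g.Ay; ++y)
          for (int x = 0; x < g.Ax; ++x) {
            size_t i = g.aidx(x, y, z);
            size_t jx = g.aidx(wrapi(x + 1, g.Ax), y, z);
            double q = fa * (Ca[jx] - Ca[i]);
            dAa[i] += q; dAa[jx] -= q;
            size_t jy = g.aidx(x, wrapi(y + 1, g.Ay), z);
            q = fa * (Ca[jy] - Ca[i]);
            dAa[i] += q; dAa[jy] -= q;
            if (z + 1 < g.Az) {
              size_t jz = g.aidx(x, y, z + 1);
              q = fa * (Ca[jz] - Ca[i]);
              dAa[i] += q; dAa[jz] -= q;
            }
          }
    }
    // interface: agarose z = Az-1 is the top layer, community z = 0 sits on it
    double Dh = (Dc > 0 && Da > 0) ? 2.0 * Dc * Da / (Dc + Da) : 0.0;
    if (Dh > 0) {
      const double area = g.gc_um * g.gc_um;
      const double dz = 0.5 * (g.gc_um + g.ga_um);
      const double fi = Dh * area / dz * dt * CONV;
      for (int y = 0; y < g.Gy; ++y)
        for (int x = 0; x < g.Gx; ++x) {
          size_t ic = g.cidx(x, y, 0);
          size_t ia = g.aidx(x / g.lat_ratio, y / g.lat_ratio, g.Az - 1);
          double q = fi * (Ca[ia] - Cc[ic]);
          dAc[ic] += q; dAa[ia] -= q;
        }
    }
    for (size_t i = 0; i < na; ++i) Aa[i] += dAa[i];
  }
  for (size_t i = 0; i < nc; ++i) Ac[i] += dAc[i];

  if (instant) {
    double tot = 0.0;
    for (size_t i = 0; i < nc; ++i) tot += Ac[i];
    double each = tot / nc;
    for (size_t i = 0; i < nc; ++i) Ac[i] = each;
  }
}

}  // namespace

// [[Rcpp::export]]
List diffuse_field_cpp(NumericVector comm, NumericVector agar, double D_comm,
                       double D_agar, double gc_um, double ga_um, double dt,
                       int nsub, bool instant) {
  IntegerVector dc = comm.attr("dim");
  Geometry g;
  g.Gx = dc[0]; g.Gy = dc[1]; g.Gz = dc[2];
  g.gc_um = gc_um; g.ga_um = ga_um;
  g.Vc = gc_um * gc_um * gc_um; g.Va = ga_um * ga_um * ga_um;
  std::vector<double> Ac(comm.begin(), comm.end());
  std::vector<double> Aa;
  if (agar.size() > 0) {
    IntegerVector da = agar.attr("dim");
    g.Ax = da[0]; g.Ay = da[1]; g.Az = da[2];
    g.lat_ratio = static_cast<int>(std::lround(ga_um / gc_um));
    if (g.Ax * g.lat_ratio != g.Gx || g.Ay * g.lat_ratio != g.Gy)
      stop("agarose and community lateral grids are not commensurate");
    Aa.assign(agar.begin(), agar.end());
  } else {
    g.Ax = g.Ay = g.Az = 0; g.lat_ratio = 1;
  }
  Scratch scr;
  for (int s = 0; s < nsub; ++s)
    ftcs_substep(Ac, Aa, g, D_comm, D_agar, dt, instant, scr);
  NumericVector outc(Ac.begin(), Ac.end());
  outc.attr("dim") = comm.attr("dim");
  NumericVector outa(Aa.begin(), Aa.end());
  if (agar.size() > 0) outa.attr("dim") = agar.attr("dim");
  return List::create(_["community"] = outc, _["agarose"] = outa);
}

// Michaelis-Menten uptake and release for one substep, exposed for unit
// testing.  Operates on a single community field per nutrient; cells are
// mapped to grids by integer division of their coordinates.  Per-grid uptake
// is capped at the available amount and shared pro rata.
// [[Rcpp::export]]
List uptake_release_cpp(IntegerVector arr, List fields, NumericMatrix strains,
                        int gc, double gc_um, double dt, double t_hr,
                        double release_factor) {
  Lattice lat = lattice_from_array(arr);
  int ns = strains.nrow();
  int nnut = fields.size();
  IntegerVector d = as<IntegerVector>(as<NumericVector>(fields[0]).attr("dim"));
  int Gx = d[0], Gy = d[1], Gz = d[2];
  size_t ngrid = static_cast<size_t>(Gx) * Gy * Gz;
  double Vg = gc_um * gc_um * gc_um;

  std::vector<std::vector<double> > A(nnut);
  for (int k = 0; k < nnut; ++k) {
    NumericVector f = fields[k];
    A[k].assign(f.begin(), f.end());
  }
  // per-grid live-cell counts per strain
  std::vector<std::vector<int> > ncell(ns, std::vector<int>(ngrid, 0));
  std::vector<size_t> cell_grid(lat.cells.size());
  for (size_t ci = 0; ci < lat.cells.size(); ++ci) {
    const Cell &c = lat.cells[ci];
    size_t gidx = static_cast<size_t>(c.x / gc) +
        static_cast<size_t>(Gx) * (static_cast<size_t>(c.y / gc) +
        static_cast<size_t>(Gy) * (c.z / gc));
    cell_grid[ci] = gidx;
    if (c.alive) ++ncell[c.pop - 1][gidx];
  }
  // per-grid per-strain uptake achieved this substep (fmole per cell)
  std::vector<std::vector<double> > got(ns, std::vector<double>(ngrid, 0.0));
  double u_total = 0.0, q_total = 0.0;

  for (int k = 0; k < nnut; ++k) {
    for (size_t gidx = 0; gidx < ngrid; ++gidx) {
      double S = A[k][gidx] / (Vg * CONV);
      double demand = 0.0;
      for (int s = 0; s < ns; ++s) {
        if (static_cast<int>(strains(s, 0)) != k + 1 || ncell[s][gidx] == 0)
          continue;
        double u = strains(s, 2) * S / (S + strains(s, 3)) * dt;
        got[s][gidx] = u;
        demand += u * ncell[s][gidx];
      }
      if (demand <= 0) continue;
      double f = demand > A[k][gidx] ? A[k][gidx] / demand : 1.0;
      for (int s = 0; s < ns; ++s)
        if (static_cast<int>(strains(s, 0)) == k + 1) got[s][gidx] *= f;
      A[k][gidx] -= demand * f;
      u_total += demand * f;
    }
    // live release into the releasing cell's grid
    for (int s = 0; s < ns; ++s) {
      if (static_cast<int>(strains(s, 1)) != k + 1) continue;
      int mode = static_cast<int>(strains(s, 6));
      if (mode == 1 || (mode == 2 && t_hr >= strains(s, 7))) {
        double q = strains(s, 8) * release_factor * dt;
        for (size_t ci = 0; ci < lat.cells.size(); ++ci)
          if (lat.cells[ci].alive && lat.cells[ci].pop == s + 1) {
            A[k][cell_grid[ci]] += q;
            q_total += q;
          }
      }
    }
  }
  List out_fields(nnut);
  for (int k = 0; k < nnut; ++k) {
    NumericVector f(A[k].begin(), A[k].end());
    f.attr("dim") = as<NumericVector>(fields[k]).attr("dim");
    out_fields[k] = f;
  }
  // site-parallel increments: qinc[x,y,z] for the cell occupying that site
  NumericVector qinc(static_cast<R_xlen_t>(lat.site.size()));
  for (size_t ci = 0; ci < lat.cells.size(); ++ci) {
    const Cell &c = lat.cells[ci];
    if (c.alive)
      qinc[lat.idx(c.x, c.y, c.z)] = got[c.pop - 1][cell_grid[ci]];
  }
  qinc.attr("dim") = arr.attr("dim");
  return List::create(_["fields"] = out_fields, _["quota_increment"] = qinc,
                      _["uptake_total"] = u_total, _["release_total"] = q_total);
}

// One division/death update at the cell time-step, exposed for unit testing.
// quota is a site-parallel numeric array (fmole of the limiting nutrient held
// by the cell occupying that site).  Cells are visited in deterministic site
// order (x fastest, then y, then z).  Returns the updated lattice and quota
// arrays plus a table of release events (x,y,z,nutrient,amount).
// [[Rcpp::export]]
List cell_update_cpp(IntegerVector arr, NumericVector quota,
                     NumericMatrix strains, double dt_cell_hr, int n_conf,
                     double t_hr, double release_factor) {
  Lattice lat = lattice_from_array(arr);
  RNGScope scope;
  for (size_t ci = 0; ci < lat.cells.size(); ++ci) {
    const Cell &c = lat.cells[ci];
    lat.cells[ci].quota = quota[lat.idx(c.x, c.y, c.z)];
  }
  std::vector<double> ev_x, ev_y, ev_z, ev_nut, ev_amt;
  size_t ncell0 = lat.cells.size();
  int divisions = 0, deaths = 0;
  for (size_t ci = 0; ci < ncell0; ++ci) {
    if (!lat.cells[ci].alive) continue;
    int s = lat.cells[ci].pop - 1;
    int mode = static_cast<int>(strains(s, 6));
    bool death_on = !(mode == 0 && t_hr < strains(s, 7));
    double dr = death_on ? strains(s, 5) : 0.0;
    if (dr > 0 && unif_rand() < dr * dt_cell_hr) {
      Cell &c = lat.cells[ci];
      c.alive = false;
      ++deaths;
      int rn = static_cast<int>(strains(s, 1));
      if (mode == 0 && rn > 0) {
        ev_x.push_back(c.x + 1); ev_y.push_back(c.y + 1);
        ev_z.push_back(c.z + 1); ev_nut.push_back(rn);
        ev_amt.push_back(strains(s, 9) * release_factor);
      }
      int cn = static_cast<int>(strains(s, 0));
      if (cn > 0 && c.quota > 0) {
        ev_x.push_back(c.x + 1); ev_y.push_back(c.y + 1);
        ev_z.push_back(c.z + 1); ev_nut.push_back(cn);
        ev_amt.push_back(c.quota);
      }
      c.quota = 0.0;
      continue;
    }
    double alpha = strains(s, 4);
    if (alpha > 0 && lat.cells[ci].quota >= alpha) {
      int di = divide_cell(lat, static_cast<int>(ci), n_conf, 0.0, t_hr);
      if (di < 0)
        stop("z overflow: column (%d,%d) is full", lat.cells[ci].x + 1,
             lat.cells[ci].y + 1);
      lat.cells[ci].quota -= alpha;
      ++divisions;
    }
  }
  NumericVector qout(quota.size());
  for (size_t ci = 0; ci < lat.cells.size(); ++ci) {
    const Cell &c = lat.cells[ci];
    qout[lat.idx(c.x, c.y, c.z)] = c.quota;
  }
  qout.attr("dim") = arr.attr("dim");
  int nev = static_cast<int>(ev_x.size());
  NumericMatrix events(nev, 5);
  for (int i = 0; i < nev; ++i) {
    events(i, 0) = ev_x[i]; events(i, 1) = ev_y[i]; events(i, 2) = ev_z[i];
    events(i, 3) = ev_nut[i]; events(i, 4) = ev_amt[i];
  }
  colnames(events) = CharacterVector::create("x", "y", "z", "nutrient",
                                             "amount");
  return List::create(_["lattice"] = lattice_to_array(lat),
                      _["quota"] = qout, _["events"] = events,
                      _["divisions"] = divisions, _["deaths"] = deaths);
}

// Full diffusion-model run.  strains columns:
//  0 consume nutrient (1-based, 0 none), 1 release nutrient, 2 v_m (fmole/s),
//  3 K_M = K_MM (uM), 4 alpha (fmole), 5 death rate (per hr), 6 release mode
//  (0 on_death, 1 live_constant, 2 live_after_delay), 7 delay (hr), 8 rho
//  (fmole/s), 9 beta death pulse (fmole), 10 initial quota (fmole).
// For on_death strains the delay postpones the onset of death (and hence of
// release); for live_after_delay it gates constant live release.
// [[Rcpp::export]]
List diffusion_run_cpp(IntegerVector arr, NumericMatrix strains, int n_nut,
                       NumericVector D_comm, NumericVector D_agar,
                       NumericVector S0_agar, NumericVector S0_comm,
                       int gc, int ga, int Za, double cell_um, double dt_u,
                       double dt_cell, double t_end_hr, int n_conf,
                       int variant, double release_factor, int record_every,
                       int snapshot_every, double stop_height) {
  Lattice lat = lattice_from_array(arr);
  RNGScope scope;
  int ns = strains.nrow();
  if (ns > 16) stop("at most 16 strains are supported");
  Geometry g;
  g.Gx = lat.X / gc; g.Gy = lat.Y / gc; g.Gz = lat.Z / gc;
  if (g.Gx * gc != lat.X || g.Gy * gc != lat.Y || g.Gz * gc != lat.Z)
    stop("community dims must be divisible by the community grid width");
  g.gc_um = gc * cell_um; g.ga_um = ga * cell_um;
  g.Vc = g.gc_um * g.gc_um * g.gc_um; g.Va = g.ga_um * g.ga_um * g.ga_um;
  g.lat_ratio = ga / gc;
  if (Za > 0) {
    if (g.lat_ratio * gc != ga)
      stop("agarose grid width must be a multiple of the community grid width");
    g.Ax = lat.X / ga; g.Ay = lat.Y / ga; g.Az = Za;
    if (g.Ax * ga != lat.X || g.Ay * ga != lat.Y)
      stop("domain width must be divisible by the agarose grid width");
  } else {
    g.Ax = g.Ay = g.Az = 0;
  }
  size_t ngrid = static_cast<size_t>(g.Gx) * g.Gy * g.Gz;
  size_t nagar = static_cast<size_t>(g.Ax) * g.Ay * g.Az;

  // conservative 3D FTCS stability (the 1D bound (nc)^2/2D is necessary but
  // not sufficient for a 3D stencil)
  for (int k = 0; k < n_nut; ++k) {
    if (D_comm[k] > 0 && dt_u > g.gc_um * g.gc_um / (6.0 * D_comm[k]))
      stop("dt_u=%g s violates the community diffusion stability bound %g s",
           dt_u, g.gc_um * g.gc_um / (6.0 * D_comm[k]));
    if (Za > 0 && D_agar[k] > 0 &&
        dt_u > g.ga_um * g.ga_um / (6.0 * D_agar[k]))
      stop("dt_u=%g s violates the agarose diffusion stability bound %g s",
           dt_u, g.ga_um * g.ga_um / (6.0 * D_agar[k]));
  }

  std::vector<std::vector<double> > Ac(n_nut,
      std::vector<double>(ngrid, 0.0));
  std::vector<std::vector<double> > Aa(n_nut,
      std::vector<double>(nagar, 0.0));
  for (int k = 0; k < n_nut; ++k) {
    for (size_t i = 0; i < ngrid; ++i) Ac[k][i] = S0_comm[k] * g.Vc * CONV;
    for (size_t i = 0; i < nagar; ++i) Aa[k][i] = S0_agar[k] * g.Va * CONV;
  }

  // which nutrients are released by any strain (for the instant variant)
  std::vector<bool> instant_nut(n_nut, false);
  if (variant == 1)
    for (int s = 0; s < ns; ++s)
      if (static_cast<int>(strains(s, 1)) > 0)
        instant_nut[static_cast<int>(strains(s, 1)) - 1] = true;
  double relf = variant == 2 ? release_factor : 1.0;

  for (size_t ci = 0; ci < lat.cells.size(); ++ci)
    lat.cells[ci].quota = strains(lat.cells[ci].pop - 1, 10);

  std::vector<double> cum_released(n_nut, 0.0), cum_consumed(n_nut, 0.0);
  int nsub = static_cast<int>(std::lround(dt_cell / dt_u));
  int nblocks = static_cast<int>(std::ceil(t_end_hr * 3600.0 / dt_cell));

  // recorded series
  std::vector<double> t_rec, h_rec;
  std::vector<std::vector<double> > live_rec, dead_rec, free_rec, quo_rec,
      rel_rec, con_rec;
  List snapshots;
  std::vector<double> snap_t;

  std::vector<std::vector<int> > n_cons(ns), n_rel(ns);
  std::vector<std::vector<double> > inc(ns);
  for (int s = 0; s < ns; ++s) {
    n_cons[s].assign(ngrid, 0);
    n_rel[s].assign(ngrid, 0);
    inc[s].assign(ngrid, 0.0);
  }
  std::vector<size_t> cell_grid;
  std::vector<size_t> occupied;   // grids with any live cell

  auto rebuild_counts = [&](double t_hr) {
    for (int s = 0; s < ns; ++s) {
      std::fill(n_cons[s].begin(), n_cons[s].end(), 0);
      std::fill(n_rel[s].begin(), n_rel[s].end(), 0);
    }
    occupied.clear();
    cell_grid.resize(lat.cells.size());
    std::vector<char> seen(ngrid, 0);
    for (size_t ci = 0; ci < lat.cells.size(); ++ci) {
      const Cell &c = lat.cells[ci];
      size_t gidx = static_cast<size_t>(c.x / gc) +
          static_cast<size_t>(g.Gx) * (static_cast<size_t>(c.y / gc) +
          static_cast<size_t>(g.Gy) * (c.z / gc));
      cell_grid[ci] = gidx;
      if (!c.alive) continue;
      int s = c.pop - 1;
      if (static_cast<int>(strains(s, 0)) > 0) ++n_cons[s][gidx];
      int mode = static_cast<int>(strains(s, 6));
      if (static_cast<int>(strains(s, 1)) > 0 &&
          (mode == 1 || (mode == 2 && t_hr >= strains(s, 7))))
        ++n_rel[s][gidx];
      if (!seen[gidx]) { seen[gidx] = 1; occupied.push_back(gidx); }
    }
  };

  auto record = [&](double t_hr) {
    t_rec.push_back(t_hr);
    h_rec.push_back(height_p90(lat));
    std::vector<double> lv(ns, 0.0), dd(ns, 0.0);
    std::vector<double> quo(n_nut, 0.0);
    for (size_t ci = 0; ci < lat.cells.size(); ++ci) {
      const Cell &c = lat.cells[ci];
      if (c.alive) {
        lv[c.pop - 1] += 1;
        int cn = static_cast<int>(strains(c.pop - 1, 0));
        if (cn > 0) quo[cn - 1] += c.quota;
      } else dd[c.pop - 1] += 1;
    }
    std::vector<double> fr(n_nut, 0.0);
    for (int k = 0; k < n_nut; ++k) {
      for (size_t i = 0; i < ngrid; ++i) fr[k] += Ac[k][i];
      for (size_t i = 0; i < nagar; ++i) fr[k] += Aa[k][i];
    }
    live_rec.push_back(lv); dead_rec.push_back(dd);
    free_rec.push_back(fr); quo_rec.push_back(quo);
    rel_rec.push_back(cum_released); con_rec.push_back(cum_consumed);
  };

  rebuild_counts(0.0);
  record(0.0);
  if (snapshot_every > 0) {
    snapshots.push_back(lattice_to_array(lat));
    snap_t.push_back(0.0);
  }

  Scratch scr;
  for (int blk = 1; blk <= nblocks; ++blk) {
    double t_hr = (blk - 1) * dt_cell / 3600.0;
    // diffusion / uptake / release substeps
    for (int sub = 0; sub < nsub; ++sub) {
      for (int k = 0; k < n_nut; ++k) {
        // aggregated uptake per occupied grid
        for (size_t oi = 0; oi < occupied.size(); ++oi) {
          size_t gidx = occupied[oi];
          double S = Ac[k][gidx] / (g.Vc * CONV);
          double demand = 0.0;
          double per_cell[16];
          for (int s = 0; s < ns; ++s) {
            per_cell[s] = 0.0;
            if (static_cast<int>(strains(s, 0)) != k + 1 ||
                n_cons[s][gidx] == 0) continue;
            double u = strains(s, 2) * S / (S + strains(s, 3)) * dt_u;
            per_cell[s] = u;
            demand += u * n_cons[s][gidx];
          }
          if (demand <= 0) continue;
          double f = demand > Ac[k][gidx] ? Ac[k][gidx] / demand : 1.0;
          Ac[k][gidx] -= demand * f;
          for (int s = 0; s < ns; ++s)
            if (per_cell[s] > 0) inc[s][gidx] += per_cell[s] * f;
        }
        // constant live release
        for (int s = 0; s < ns; ++s) {
          if (static_cast<int>(strains(s, 1)) != k + 1) continue;
          int mode = static_cast<int>(strains(s, 6));
          if (mode != 1 && mode != 2) continue;
          double q = strains(s, 8) * relf * dt_u;
          if (q <= 0) continue;
          for (size_t oi = 0; oi < occupied.size(); ++oi) {
            size_t gidx = occupied[oi];
            if (n_rel[s][gidx] > 0) {
              Ac[k][gidx] += q * n_rel[s][gidx];
              cum_released[k] += q * n_rel[s][gidx];
            }
          }
        }
        ftcs_substep(Ac[k], Aa[k], g, D_comm[k], D_agar[k], dt_u,
                     instant_nut[k], scr);
      }
    }
    t_hr = blk * dt_cell / 3600.0;

    // cell update: apply accumulated uptake, then death and division in
    // cell-id order
    size_t ncell0 = lat.cells.size();
    for (size_t ci = 0; ci < ncell0; ++ci) {
      Cell &c = lat.cells[ci];
      if (!c.alive) continue;
      int s = c.pop - 1;
      if (static_cast<int>(strains(s, 0)) > 0)
        c.quota += inc[s][cell_grid[ci]];
    }
    for (int s = 0; s < ns; ++s) std::fill(inc[s].begin(), inc[s].end(), 0.0);

    double dt_cell_hr = dt_cell / 3600.0;
    for (size_t ci = 0; ci < ncell0; ++ci) {
      if (!lat.cells[ci].alive) continue;
      int s = lat.cells[ci].pop - 1;
      int mode = static_cast<int>(strains(s, 6));
      bool death_on = !(mode == 0 && t_hr < strains(s, 7));
      double dr = death_on ? strains(s, 5) : 0.0;
      if (dr > 0 && unif_rand() < dr * dt_cell_hr) {
        Cell &c = lat.cells[ci];
        c.alive = false;
        size_t gidx = cell_grid[ci];
        int rn = static_cast<int>(strains(s, 1));
        if (mode == 0 && rn > 0) {
          double pulse = strains(s, 9) * relf;
          Ac[rn - 1][gidx] += pulse;
          cum_released[rn - 1] += pulse;
        }
        int cn = static_cast<int>(strains(s, 0));
        // unspent quota returns to the pool (recycled, not newly released)
        if (cn > 0 && c.quota > 0) Ac[cn - 1][gidx] += c.quota;
        c.quota = 0.0;
        continue;
      }
      double alpha = strains(s, 4);
      if (alpha > 0 && lat.cells[ci].quota >= alpha) {
        int di = divide_cell(lat, static_cast<int>(ci), n_conf, 0.0, t_hr);
        if (di < 0)
          stop("z overflow at t=%.1f hr: increase the community height", t_hr);
        lat.cells[ci].quota -= alpha;
        int cn = static_cast<int>(strains(s, 0));
        if (cn > 0) cum_consumed[cn - 1] += alpha;
      }
    }

    rebuild_counts(t_hr);
    bool done = blk == nblocks;
    if (!done && stop_height > 0 && blk % 10 == 0 &&
        height_p90(lat) >= stop_height)
      done = true;
    if (record_every > 0 && (blk % record_every == 0 || done))
      record(t_hr);
    if (snapshot_every > 0 && (blk % snapshot_every == 0 || done)) {
      snapshots.push_back(lattice_to_array(lat));
      snap_t.push_back(t_hr);
    }
    if (blk % 10 == 0) Rcpp::checkUserInterrupt();
    if (done) break;
  }

  int nrec = static_cast<int>(t_rec.size());
  NumericMatrix live(nrec, ns), dead(nrec, ns);
  NumericMatrix freem(nrec, n_nut), quom(nrec, n_nut), relm(nrec, n_nut),
      conm(nrec, n_nut);
  for (int i = 0; i < nrec; ++i) {
    for (int s = 0; s < ns; ++s) {
      live(i, s) = live_rec[i][s];
      dead(i, s) = dead_rec[i][s];
    }
    for (int k = 0; k < n_nut; ++k) {
      freem(i, k) = free_rec[i][k];
      quom(i, k) = quo_rec[i][k];
      relm(i, k) = rel_rec[i][k];
      conm(i, k) = con_rec[i][k];
    }
  }
  List fields(n_nut), afields(n_nut);
  for (int k = 0; k < n_nut; ++k) {
    NumericVector f(Ac[k].begin(), Ac[k].end());
    f.attr("dim") = IntegerVector::create(g.Gx, g.Gy, g.Gz);
    fields[k] = f;
    NumericVector fa(Aa[k].begin(), Aa[k].end());
    if (nagar > 0) fa.attr("dim") = IntegerVector::create(g.Ax, g.Ay, g.Az);
    afields[k] = fa;
  }
  return List::create(
      _["lattice"] = lattice_to_array(lat),
      _["time"] = wrap(t_rec),
      _["live"] = live, _["dead"] = dead,
      _["height_p90"] = wrap(h_rec),
      _["free_nutrient"] = freem, _["quota_total"] = quom,
      _["cum_released"] = relm, _["cum_consumed"] = conm,
      _["community_fields"] = fields, _["agarose_fields"] = afields,
      _["snapshots"] = snapshots, _["snapshot_times"] = wrap(snap_t));
}
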