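#include "lattice_core.h"
using namespace Rcpp;
using namespace micromix;

// [[Rcpp::export]]
NumericVector occ_fractions_cpp(IntegerVector arr, int x, int y, int z,
                                int l, int npop) {
  Lattice lat = lattice_from_array(arr);
  if (x < 1 || x > lat.X || y < 1 || y > lat.Y || z < 1 || z > lat.Z)
    stop("site (%d,%d,%d) outside lattice dims", x, y, z);
  std::vector<int> counts(npop);
  int cube = 0;
  occupancy_counts(lat, x - 1, y - 1, z - 1, l, npop, counts, cube);
  NumericVector phi(npop);
  for (int i = 0; i < npop; ++i) phi[i] = static_cast<double>(counts[i]) / cube;
  phi.attr("cube_sites") = cube;
  return phi;
}

// [[Rcpp::export]]
IntegerVector nearest_empty_cpp(IntegerVector arr, int x, int y, int z,
                                int n) {
  Lattice lat = lattice_from_array(arr);
  if (lat.empty_at(x - 1, y - 1, z - 1))
    stop("focal site is not occupied");
  int tx = 0, ty = 0;
  RNGScope scope;
  bool found = nearest_empty_coplanar(lat, x - 1, y - 1, z - 1, n, tx, ty);
  if (!found) return IntegerVector(0);
  return IntegerVector::create(tx + 1, ty + 1, z);
}

// [[Rcpp::export]]
List place_daughter_cpp(IntegerVector arr, IntegerVector mother,
                        Nullable<IntegerVector> target) {
  Lattice lat = lattice_from_array(arr);
  int mx = mother[0] - 1, my = mother[1] - 1, mz = mother[2] - 1;
  int ci = lat.at(mx, my, mz);
  if (ci == 0) stop("mother site is not occupied");
  int mi = ci - 1;
  int di;
  if (target.isNotNull()) {
    IntegerVector t(target);
    if (!lat.empty_at(t[0] - 1, t[1] - 1, t[2] - 1))
      stop("target site is not empty");
    if (t[2] != mother[2]) stop("target must be coplanar with the mother");
    di = place_daughter(lat, mi, true, t[0] - 1, t[1] - 1,
                        lat.cells[mi].pop, 0.0, 0.0);
  } else {
    di = place_daughter(lat, mi, false, 0, 0, lat.cells[mi].pop, 0.0, 0.0);
  }
  if (di < 0)
    stop("z overflow: column (%d,%d) is full to the lattice top",
         mother[0], mother[1]);
  const Cell &d = lat.cells[di];
  return List::create(_["lattice"] = lattice_to_array(lat),
                      _["daughter"] = IntegerVector::create(d.x + 1, d.y + 1,
                                                            d.z + 1));
}

// Fitness-model simulation loop.  r0: basal fitness per population (per hr);
// rmat: npop x npop interaction coefficients r_ij (effect of j on i, per hr).
// Stops when the live count first reaches 2^stop_generations times the
// initial count, when the 90th-percentile height reaches stop_height (cell
// layers), or after max_steps.
// [[Rcpp::export]]
List fitness_run_cpp(IntegerVector arr, int npop, NumericVector r0,
                     NumericMatrix rmat, double chi, int l, int n, double dt,
                     double stop_generations, double stop_height,
                     int max_steps, int record_every, int snapshot_every,
                     bool synchronous) {
  Lattice lat = lattice_from_array(arr);
  RNGScope scope;
  size_t n0 = 0;
  for (size_t i = 0; i < lat.cells.size(); ++i)
    if (lat.cells[i].alive) ++n0;
  if (n0 == 0) stop("initial lattice holds no live cells");
  double target_count = stop_generations > 0
      ? std::pow(2.0, stop_generations) * static_cast<double>(n0) : R_PosInf;

  std::vector<double> t_rec, h_rec;
  std::vector<std::vector<double> > cnt_rec;
  List snapshots;
  std::vector<double> snap_t;
  std::vector<int> counts_now(npop, 0);
  for (size_t i = 0; i < lat.cells.size(); ++i)
    ++counts_now[lat.cells[i].pop - 1];

  std::vector<int> cnt(npop);
  int cube = 0;
  bool stalled = false;
  int step = 0;
  double gens_reached = 0.0;

  auto record = [&](double t) {
    t_rec.push_back(t);
    h_rec.push_back(height_p90(lat));
    std::vector<double> row(npop);
    for (int p = 0; p < npop; ++p) row[p] = counts_now[p];
    cnt_rec.push_back(row);
  };
  record(0.0);
  if (snapshot_every > 0) {
    snapshots.push_back(lattice_to_array(lat));
    snap_t.push_back(0.0);
  }

  for (step = 1; step <= max_steps; ++step) {
    // fresh uniform permutation of the cells alive at the start of the step
    size_t ncell = lat.cells.size();
    std::vector<int> order(ncell);
    for (size_t i = 0; i < ncell; ++i) order[i] = static_cast<int>(i);
    for (size_t i = ncell; i > 1; --i) {
      size_t j = static_cast<size_t>(unif_rand() * i);
      if (j >= i) j = i - 1;
      std::swap(order[i - 1], order[j]);
    }
    // with synchronous updates all rates come from the pre-step state
    std::vector<double> pre_rate;
    if (synchronous) {
      pre_rate.resize(ncell, 0.0);
      for (size_t ci = 0; ci < ncell; ++ci) {
        const Cell &c = lat.cells[ci];
        if (!c.alive) continue;
        occupancy_counts(lat, c.x, c.y, c.z, l, npop, cnt, cube);
        double phi_i = static_cast<double>(cnt[c.pop - 1]) / cube;
        double phi_tot = 0.0, inter = 0.0;
        for (int p = 0; p < npop; ++p) {
          double phi_p = static_cast<double>(cnt[p]) / cube;
          phi_tot += phi_p;
          if (p != c.pop - 1) inter += rmat(c.pop - 1, p) * phi_p * (1 - phi_i);
        }
        double r = (r0[c.pop - 1] + inter) * (1 - chi * phi_tot);
        pre_rate[ci] = r < 0 ? 0 : r;
      }
    }
    int divisions = 0;
    for (size_t k = 0; k < ncell; ++k) {
      int ci = order[k];
      const Cell &c = lat.cells[ci];
      if (!c.alive) continue;
      double r;
      if (synchronous) {
        r = pre_rate[ci];
      } else {
        occupancy_counts(lat, c.x, c.y, c.z, l, npop, cnt, cube);
        double phi_i = static_cast<double>(cnt[c.pop - 1]) / cube;
        double phi_tot = 0.0, inter = 0.0;
        for (int p = 0; p < npop; ++p) {
          double phi_p = static_cast<double>(cnt[p]) / cube;
          phi_tot += phi_p;
          if (p != c.pop - 1) inter += rmat(c.pop - 1, p) * phi_p * (1 - phi_i);
        }
        r = (r0[c.pop - 1] + inter) * (1 - chi * phi_tot);
        if (r < 0) r = 0;
      }
      if (unif_rand() < r * dt) {
        int pop = c.pop;   // divide_cell may reallocate the cell store
        int di = divide_cell(lat, ci, n, 0.0, step * dt);
        if (di < 0)
          stop("z overflow during step %d: increase the lattice Z dimension",
               step);
        ++counts_now[pop - 1];
        ++divisions;
      }
    }
    double total = 0.0;
    for (int p = 0; p < npop; ++p) total += counts_now[p];
    gens_reached = std::log2(total / static_cast<double>(n0));
    bool done = total >= target_count;
    if (record_every > 0 && (step % record_every == 0 || done))
      record(step * dt);
    if (snapshot_every > 0 && (step % snapshot_every == 0 || done)) {
      snapshots.push_back(lattice_to_array(lat));
      snap_t.push_back(step * dt);
    }
    if (done) break;
    if (stop_height > 0 && height_p90(lat) >= stop_height) break;
    if (divisions == 0 && step == max_steps) stalled = true;
    if (step % 20 == 0) Rcpp::checkUserInterrupt();
  }
  if (step > max_steps) step = max_steps;

  NumericMatrix counts(static_cast<int>(cnt_rec.size()), npop);
  for (size_t i = 0; i < cnt_rec.size(); ++i)
    for (int p = 0; p < npop; ++p) counts(static_cast<int>(i), p) = cnt_rec[i][p];
  return List::create(
      _["lattice"] = lattice_to_array(lat),
      _["time"] = wrap(t_rec),
      _["counts"] = counts,
      _["height_p90"] = wrap(h_rec),
      _["steps"] = step,
      _["generations"] = gens_reached,
      _["stalled"] = stalled,
      _["snapshots"] = snapshots,
      _["snapshot_times"] = wrap(snap_t));
}
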