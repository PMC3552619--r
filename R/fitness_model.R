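#' Interaction-based growth rate of a focal cell
#'
#' Growth rate of a focal cell of population `i` given the occupancy
#' fractions of all populations in its interaction neighborhood:
#'
#' \deqn{r_i = [r_{i0} + \sum_{j \ne i} r_{ij}\,\phi_j (1-\phi_i)]
#'             \, [1 - \chi \sum_k \phi_k]}
#'
#' The first bracket is the basal fitness plus the fitness effects conferred
#' by partner populations (increasing with partner abundance, discounted by
#' intra-population competition for the partner); the second bracket is the
#' crowding penalty for intra- and inter-population competition for shared
#' resources.  Negative rates clamp to zero: the fitness model has no death,
#' so strong inhibition manifests as growth arrest.
#'
#' @param phi numeric vector of per-population occupancy fractions (in
#'   `[0,1]`, summing to at most 1), as from [occupancy_fractions()].
#' @param focal_pop index of the focal cell's population.
#' @param r0 numeric vector of basal fitnesses (per hour).
#' @param rmat square interaction matrix; `rmat[i, j]` is the per-hour effect
#'   of population j on population i, zero diagonal.
#' @param chi crowding coefficient in `[0,1]` (default 0.8).
#' @return growth rate per hour.
#' @examples
#' growth_rate(c(0.25, 0.5), 1, r0 = c(0.04, 0.04),
#'             rmat = matrix(c(0, 0.4, 0.4, 0), 2), chi = 0.8)
#' @export
growth_rate <- function(phi, focal_pop, r0, rmat, chi = 0.8) {
  if (any(phi < 0 | phi > 1) || sum(phi) > 1 + 1e-9)
    stop("occupancy fractions must lie in [0,1] and sum to at most 1")
  stopifnot(nrow(rmat) == length(phi), all(diag(rmat) == 0),
            chi >= 0, chi <= 1)
  i <- focal_pop
  inter <- sum(rmat[i, -i] * phi[-i]) * (1 - phi[i])
  max(0, (r0[i] + inter) * (1 - chi * sum(phi)))
}

#' Convert a per-partner-cell fitness effect to an interaction coefficient
#'
#' Interaction magnitudes are often stated as the fitness effect conferred by
#' each single partner cell present in the interaction neighborhood.  Since
#' the neighborhood of halfwidth `l` holds `(2l+1)^3` sites, the matrix
#' coefficient is `effect_per_cell * (2l+1)^3` (343 for `l = 3`), so that one
#' partner cell (`phi_j = 1/(2l+1)^3`) contributes `effect_per_cell` to the
#' bracketed rate.
#'
#' @param effect_per_cell per-hour fitness effect of one partner cell.
#' @param l interaction halfwidth in sites (default 3).
#' @export
per_cell_effect_to_rij <- function(effect_per_cell, l = 3) {
  effect_per_cell * (2 * l + 1)^3
}

#' Simulation parameters for the fitness model
#'
#' @param chi crowding coefficient (default 0.8).
#' @param l interaction halfwidth in sites (default 3).
#' @param n confinement radius in sites (default 2).
#' @param dt hours per step; `NULL` (default) selects `dt` so that the
#'   maximum attainable division probability per step is 0.1.
#' @param update `"sequential"` (each cell divides using the neighborhood at
#'   its own update, the individual-based convention) or `"synchronous"`
#'   (all rates from the pre-step state).
#' @return a list of class `fitness_params`.
#' @export
fitness_params <- function(chi = 0.8, l = 3, n = 2, dt = NULL,
                           update = c("sequential", "synchronous")) {
  stopifnot(chi >= 0, chi <= 1, l >= 1, n >= 1)
  structure(list(chi = chi, l = l, n = n, dt = dt,
                 update = match.arg(update)),
            class = "fitness_params")
}

# maximum attainable rate over the feasible (phi_i, phi_rest) simplex,
# evaluated on a grid; used to auto-select dt
max_attainable_rate <- function(r0, rmat, chi) {
  g <- seq(0, 1, by = 0.01)
  best <- 0
  for (i in seq_along(r0)) {
    rpos <- max(c(rmat[i, -i], 0))
    for (pi in g) {
      pj <- g[g <= 1 - pi + 1e-12]
      r <- (r0[i] + rpos * pj * (1 - pi)) * (1 - chi * (pi + pj))
      best <- max(best, r, 0)
    }
  }
  best
}

#' Seed a lattice with randomly placed cells
#'
#' Places cells uniformly at random without collision on the surface plane
#' `z = 1`, emulating random deposition of a dilute inoculum.
#'
#' @param dims lattice dimensions `c(X, Y, Z)`.
#' @param density total cells per mm^2 of surface.
#' @param ratio relative abundances per population (normalized internally).
#' @param site_size site edge in micrometres (default 5).
#' @return a [cell_lattice()].
#' @examples
#' lat <- seed_lattice(c(100, 100, 50), density = 500, ratio = c(1, 1))
#' live_cell_count(lat)
#' @export
seed_lattice <- function(dims, density, ratio = c(1, 1), site_size = 5) {
  lat <- cell_lattice(dims, site_size)
  area_mm2 <- prod(dims[1:2]) * (site_size / 1000)^2
  ntot <- round(density * area_mm2)
  if (ntot > prod(dims[1:2]))
    stop("requested density exceeds the capacity of the surface plane")
  if (ntot == 0) return(lat)
  p <- ratio / sum(ratio)
  counts <- floor(ntot * p)
  rem <- ntot - sum(counts)
  if (rem > 0) {
    extra <- order(ntot * p - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sites <- sample.int(prod(dims[1:2]), ntot)
  pops <- rep(seq_along(counts), counts)
  plane <- integer(prod(dims[1:2]))
  plane[sites] <- pops[sample.int(ntot)]
  lat$sites[, , 1] <- plane
  lat
}

#' Run the fitness model
#'
#' Individual-based simulation of interacting populations on a lattice.  At
#' every time step each live cell, visited in a fresh random order, divides
#' with probability `r_i * dt`, where `r_i` is its [growth_rate()] from the
#' occupancy fractions of its interaction neighborhood; daughters are placed
#' by the side-budding / push-up rearrangement rules.
#'
#' @param init a seeded [cell_lattice()] (e.g. from [seed_lattice()]).
#' @param r0 per-population basal fitnesses (per hour).
#' @param rmat interaction matrix (per hour), zero diagonal; see
#'   [per_cell_effect_to_rij()] for per-cell magnitudes.
#' @param params a [fitness_params()].
#' @param stop list with any of `generations` (stop when the live count
#'   first reaches `2^G` times the initial count), `height` (90th-percentile
#'   height in cell layers), `steps` (hard cap, default 5000).
#' @param record_every record counts and heights every this many steps.
#' @param snapshot_every store full lattice snapshots every this many steps
#'   (0 = none; the final lattice is always returned).
#' @return an object of class `fitness_run`: list with elements `lattice`
#'   (final [cell_lattice()]), `time` (hours), `counts` (matrix, one column
#'   per population), `height_p90` (cell layers), `generations`, `dt`,
#'   `snapshots` and `snapshot_times`.
#' @examples
#' lat <- seed_lattice(c(30, 30, 40), density = 500)
#' run <- run_fitness(lat, r0 = c(0.04, 0.04),
#'                    rmat = matrix(0, 2, 2),
#'                    stop = list(generations = 2))
#' run$generations
#' @export
run_fitness <- function(init, r0, rmat = NULL, params = fitness_params(),
                        stop = list(generations = 10), record_every = 1,
                        snapshot_every = 0) {
  npop <- length(r0)
  if (is.null(rmat)) rmat <- matrix(0, npop, npop)
  stopifnot(nrow(rmat) == npop, ncol(rmat) == npop, all(diag(rmat) == 0),
            all(r0 >= 0))
  if (max(abs(init$sites)) > npop)
    base::stop("lattice holds population codes beyond length(r0)")
  dt <- params$dt
  if (is.null(dt)) {
    rmax <- max_attainable_rate(r0, rmat, params$chi)
    if (rmax <= 0)
      base::stop("all attainable rates are zero; supply dt explicitly")
    dt <- 0.1 / rmax
  }
  gens <- if (is.null(stop$generations)) -1 else stop$generations
  hmax <- if (is.null(stop$height)) -1 else stop$height
  smax <- if (is.null(stop$steps)) 5000L else stop$steps
  res <- fitness_run_cpp(init$sites, npop, r0, rmat, params$chi,
                         as.integer(params$l), as.integer(params$n), dt,
                         gens, hmax, as.integer(smax),
                         as.integer(record_every), as.integer(snapshot_every),
                         params$update == "synchronous")
  if (res$stalled)
    warning("community stopped growing before reaching the stop condition")
  structure(
    list(lattice = as_cell_lattice(res$lattice, init$site_size),
         time = res$time,
         counts = res$counts,
         height_p90 = res$height_p90,
         steps = res$steps,
         generations = res$generations,
         dt = dt,
         snapshots = lapply(res$snapshots, as_cell_lattice,
                            site_size = init$site_size),
         snapshot_times = res$snapshot_times),
    class = "fitness_run")
}

#' @export
print.fitness_run <- function(x, ...) {
  cat(sprintf("<fitness_run: %d steps (dt=%.3g hr), %.2f generations, %d live cells>\n",
              x$steps, x$dt, x$generations, live_cell_count(x$lattice)))
  invisible(x)
}

#' Advance the fitness model by a single step
#'
#' @inheritParams run_fitness
#' @return a [cell_lattice()] after one division round.
#' @export
fitness_step <- function(init, r0, rmat = NULL, params = fitness_params()) {
  if (is.null(params$dt))
    stop("fitness_step requires an explicit dt in fitness_params()")
  run_fitness(init, r0, rmat, params,
              stop = list(steps = 1), record_every = 0)$lattice
}

#' Write the count trajectory of a run to CSV
#'
#' @param run a `fitness_run` (or diffusion run) object with `time` and
#'   `counts`.
#' @param path output file.
#' @export
write_counts_csv <- function(run, path) {
  df <- data.frame(time_hr = run$time, run$counts)
  names(df)[-1] <- paste0("pop", seq_len(ncol(run$counts)))
  df$height_p90 <- run$height_p90
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
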