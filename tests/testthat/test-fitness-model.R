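test_that("growth rate evaluates the interaction formula and clamps at zero", {
  z <- matrix(0, 2, 2)
  # isolated cell: basal fitness
  expect_equal(growth_rate(c(0, 0), 1, c(0.05, 0.04), z), 0.05)

  # crowding only: 0.05 * (1 - 0.8) = 0.01
  expect_equal(growth_rate(c(0.5, 0.5), 1, c(0.05, 0.04), z, chi = 0.8),
               0.01)

  # full formula: [0.04 + 0.4*0.5*0.75] * [1 - 0.8*0.75] = 0.19 * 0.4
  m <- matrix(c(0, 0.4, 0, 0), 2, byrow = TRUE)
  expect_equal(growth_rate(c(0.25, 0.5), 1, c(0.04, 0.04), m, chi = 0.8),
               0.076)

  # strong inhibition clamps to zero (growth arrest, no death)
  inh <- matrix(c(0, -2, 0, 0), 2, byrow = TRUE)
  expect_equal(growth_rate(c(0.1, 0.5), 1, c(0.04, 0.04), inh), 0)

  expect_error(growth_rate(c(1.4, 0), 1, c(0.05, 0.04), z), "fractions")

  # per-cell conversion: one partner cell in a 7^3 cube confers the stated
  # per-cell effect
  rij <- per_cell_effect_to_rij(0.001, l = 3)
  expect_equal(rij, 0.343)
  expect_equal(rij * (1 / 343), 0.001)
})

test_that("seeded lattices match density arithmetic", {
  set.seed(8)
  expect_equal(live_cell_count(seed_lattice(c(40, 40, 5), 0)), 0)
  lat <- seed_lattice(c(100, 100, 5), 500)
  expect_equal(live_cell_count(lat), 125)
  expect_equal(sort(pop_counts(lat)), c(62, 63))
  conf <- seed_lattice(c(10, 10, 3), 40000)
  expect_true(all(conf$sites[, , 1] != 0))
  expect_error(seed_lattice(c(10, 10, 3), 80000), "capacity")
})

test_that("division frequency of isolated cells is binomial at r dt", {
  # many isolated cells, far enough apart that neighborhoods are empty
  dims <- c(200, 200, 3)
  lat <- cell_lattice(dims)
  sp <- seq(4, 200, by = 8)
  for (x in sp) for (y in sp) lat$sites[x, y, 1] <- 1L
  n0 <- live_cell_count(lat)     # 625 isolated cells
  p <- 0.05
  set.seed(13)
  divs <- 0; trials <- 0
  for (rep in 1:16) {
    out <- fitness_step(lat, r0 = 0.05, rmat = matrix(0, 1, 1),
                        params = fitness_params(dt = 1))
    divs <- divs + live_cell_count(out) - n0
    trials <- trials + n0
  }
  expect_equal(divs / trials, p, tolerance = 3 * sqrt(p * (1 - p) / trials) / p)
})

test_that("zero rates leave the lattice unchanged", {
  set.seed(2)
  lat <- seed_lattice(c(20, 20, 3), 2000, ratio = 1)
  expect_warning(
    out <- fitness_step(lat, r0 = 0, rmat = matrix(0, 1, 1),
                        params = fitness_params(dt = 1)),
    "stopped growing")
  expect_identical(out$sites, lat$sites)
})

test_that("generation stop doubles the population the stated number of times", {
  set.seed(4)
  lat <- seed_lattice(c(30, 30, 30), 1000)
  n0 <- live_cell_count(lat)
  run <- run_fitness(lat, r0 = c(0.04, 0.04), stop = list(generations = 2))
  expect_gte(live_cell_count(run$lattice), 4 * n0)
  expect_gte(run$generations, 2)
})

test_that("equal-fitness neutral competition conserves the expected ratio", {
  set.seed(17)
  finals <- replicate(60, {
    lat <- seed_lattice(c(15, 15, 20), 4000)   # 225 sites, 22 cells
    run <- run_fitness(lat, r0 = c(0.04, 0.04),
                       stop = list(generations = 3), record_every = 0)
    cnt <- pop_counts(run$lattice)
    cnt[1] / sum(cnt)
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.5), 4 * se + 0.01)
})

test_that("a beneficial interaction raises the recipient's growth", {
  # paired seeds: same inoculum with and without the benefit
  gains <- sapply(1:5, function(seed) {
    set.seed(seed)
    lat <- seed_lattice(c(25, 25, 40), 4000)
    m <- matrix(0, 2, 2); m[1, 2] <- per_cell_effect_to_rij(0.001)
    set.seed(seed + 1000)
    with_b <- run_fitness(lat, c(0.04, 0.04), m,
                          stop = list(steps = 40), record_every = 0)
    set.seed(seed + 1000)
    without <- run_fitness(lat, c(0.04, 0.04),
                           stop = list(steps = 40), record_every = 0,
                           params = fitness_params(dt = with_b$dt))
    live_cell_count(with_b$lattice, 1) - live_cell_count(without$lattice, 1)
  })
  expect_gte(mean(gains > 0), 0.8)
  expect_gt(mean(gains), 0)
})

test_that("well-mixed simulations track the mean-field ratio dynamics", {
  # l spanning the whole plane approximates the mean-field limit;
  # commensalism G[~+]R drives phi_G toward its stable fixed point.  The
  # agreement is approximate: neighborhoods at the growth front are not
  # saturated, which slightly favors the fitter population.
  set.seed(23)
  p <- pair_params("~+", 0.1, 0.04, 0.08)
  st <- analyze_steady_state(p)     # phi_G* = sqrt(0.06/0.08) = 0.866
  lat <- seed_lattice(c(20, 20, 80), 4000)
  m <- matrix(0, 2, 2)
  m[2, 1] <- p$r_int   # population 2 = R benefits from 1 = G
  run <- run_fitness(lat, r0 = c(p$r_g0, p$r_r0), m,
                     params = fitness_params(l = 20, chi = 0.8),
                     stop = list(generations = 8), record_every = 10)
  frac <- run$counts[, 1] / rowSums(run$counts)
  # the fraction moves from 0.5 toward the fixed point and settles near it
  expect_gt(tail(frac, 1), 0.7)
  expect_lt(abs(tail(frac, 1) - st$phi_star), 0.15)
})

test_that("fitness runs are reproducible under a fixed seed", {
  cfg <- function() {
    lat <- seed_lattice(c(20, 20, 20), 2000)
    run_fitness(lat, c(0.04, 0.05), stop = list(generations = 2))
  }
  set.seed(31); a <- cfg()
  set.seed(31); b <- cfg()
  expect_identical(a$lattice$sites, b$lattice$sites)
  expect_identical(a$counts, b$counts)
})

test_that("synchronous updates implement the pre-step neighborhood contract", {
  set.seed(37)
  lat <- seed_lattice(c(20, 20, 10), 4000)
  out <- run_fitness(lat, c(0.04, 0.04),
                     params = fitness_params(dt = 1, update = "synchronous"),
                     stop = list(steps = 5), record_every = 0)
  expect_gt(live_cell_count(out$lattice), live_cell_count(lat))
  validate_lattice(out$lattice)
})
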