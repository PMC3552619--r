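test_that("stability bounds reproduce the worst-case step limits", {
  # 50 um grids at D = 360 um^2/s: diffusion bound 2500/720 s
  rep1 <- check_stability(0.5, nc = 50, D = 360, v_m = 2.5e-4, k_mm = 1)
  expect_equal(rep1$bound_diffusion, 2500 / 720)
  # engineered-strain kinetics: worst-case uptake bound ~0.5 s
  expect_equal(rep1$bound_uptake, 0.5, tolerance = 0.01)
  expect_true(rep1$pass)
  # doubling D halves the diffusion bound
  rep2 <- check_stability(0.5, nc = 50, D = 720, v_m = 2.5e-4, k_mm = 1)
  expect_equal(rep2$bound_diffusion, rep1$bound_diffusion / 2)
  expect_false(check_stability(5, nc = 50, D = 360, v_m = 2.5e-4,
                               k_mm = 1)$pass)
})

test_that("a 50 um diffusion grid holds 10 cells per edge", {
  expect_equal(50 / 5, 10)
  cfg <- diffusion_config("cooperative")
  expect_equal(cfg$width_cells %% cfg$gc, 0)
  expect_equal(cfg$ga %% cfg$gc, 0)
})

test_that("diffusion conserves mass and leaves uniform fields unchanged", {
  comm <- array(2, dim = c(8, 8, 6))
  agar <- array(0.5, dim = c(2, 2, 8))
  f <- nutrient_field(comm, agar, gc_um = 30, ga_um = 120,
                      D_comm = 100, D_agar = 360)
  tot <- field_total(f)
  f2 <- diffuse_step(f, 0.5, nsub = 400)
  expect_equal(field_total(f2), tot)
  # concentrations equilibrate across the interface over time
  expect_lt(max(field_concentration(f2)) - min(field_concentration(f2)),
            2 - 0.5)

  fu <- nutrient_field(array(3, dim = c(6, 6, 6)), NULL, gc_um = 40)
  fu2 <- diffuse_step(fu, 0.5, nsub = 100)
  expect_equal(field_concentration(fu2),
               field_concentration(fu))

  # a point source in the community crosses the interface without loss
  comm0 <- array(0, dim = c(8, 8, 6)); comm0[4, 4, 1] <- 50
  fp <- nutrient_field(comm0, array(0, dim = c(2, 2, 8)), gc_um = 30,
                       ga_um = 120, D_comm = 360, D_agar = 360)
  fp2 <- diffuse_step(fp, 0.1, nsub = 2000)
  expect_equal(field_total(fp2), field_total(fp))
  expect_gt(sum(fp2$agarose), 0)
})

test_that("a resolved sine mode decays at the heat-equation rate", {
  n <- 32; g <- 50; D <- 360
  k <- 2 * pi / (n * g)
  x <- (seq_len(n) - 0.5) * g
  f <- nutrient_field(array(1 + 0.5 * sin(k * x), dim = c(n, 1, 1)), NULL,
                      gc_um = g, D_comm = D)
  nsub <- 400; dt <- 0.5
  f2 <- diffuse_step(f, dt, nsub = nsub)
  amp <- (max(field_concentration(f2)) - min(field_concentration(f2))) / 2
  expect_equal(amp, 0.5 * exp(-D * k^2 * nsub * dt), tolerance = 0.01)
})

test_that("uptake follows Michaelis-Menten kinetics with pro-rata capping", {
  mk_field <- function(conc) nutrient_field(array(conc, dim = c(2, 2, 2)),
                                            NULL, gc_um = 25)
  strains <- list(strain_spec(1, consumes = 1, v_m = 2.5e-4, k_m = 1))
  lat <- cell_lattice(c(10, 10, 10))
  lat$sites[1:5, 1:2, 1] <- 1L    # 10 cells, all in grid (1,1,1)

  # S = 0: no uptake
  res0 <- uptake_and_release(lat, list(mk_field(0)), strains, dt_u = 1)
  expect_equal(res0$uptake_total, 0)

  # S = K_MM: half-maximal per-cell uptake
  res1 <- uptake_and_release(lat, list(mk_field(1)), strains, dt_u = 1)
  expect_equal(res1$quota_increment[1, 1, 1], 2.5e-4 / 2)
  expect_equal(res1$uptake_total, 10 * 2.5e-4 / 2)

  # S >> K_MM: the grid loses 10 * v_m * dt
  res2 <- uptake_and_release(lat, list(mk_field(1e5)), strains, dt_u = 1)
  expect_equal(res2$uptake_total, 10 * 2.5e-4, tolerance = 1e-4)

  # nearly empty grid: uptake capped at the available amount, shared
  tiny <- nutrient_field(array(0, dim = c(2, 2, 2)), NULL, gc_um = 25)
  tiny$community[1, 1, 1] <- 1e-6
  res3 <- uptake_and_release(lat, list(tiny), strains, dt_u = 1e3)
  expect_equal(res3$uptake_total, 1e-6)
  expect_true(all(res3$fields[[1]]$community >= 0))
  expect_equal(res3$quota_increment[5, 2, 1], 1e-7)

  expect_error(uptake_and_release(lat, list(mk_field(1)),
                                  list(strain_spec(1, consumes = 3)), 1),
               "unknown nutrient")
})

test_that("constant live release injects rho per cell into the grid", {
  lat <- cell_lattice(c(10, 10, 10))
  lat$sites[1:5, 1, 1] <- 1L
  f <- nutrient_field(array(0, dim = c(2, 2, 2)), NULL, gc_um = 25)
  strains <- list(strain_spec(1, releases = 1, v_m = 0, rho = 2e-5,
                              release_mode = "live_constant"))
  res <- uptake_and_release(lat, list(f), strains, dt_u = 2)
  expect_equal(res$release_total, 5 * 2e-5 * 2)
  # delayed release is silent before the delay and active after
  strains2 <- list(strain_spec(1, releases = 1, v_m = 0, rho = 2e-5,
                               release_mode = "live_after_delay",
                               release_delay = 10))
  expect_equal(uptake_and_release(lat, list(f), strains2, 2,
                                  t_hr = 5)$release_total, 0)
  expect_gt(uptake_and_release(lat, list(f), strains2, 2,
                               t_hr = 15)$release_total, 0)
})

test_that("cell updates divide on quota, split it, and kill at rate d", {
  strains <- list(strain_spec(1, consumes = 1, alpha = 2, death_rate = 0))
  lat <- cell_lattice(c(8, 8, 8))
  lat$sites[4, 4, 1] <- 1L
  q <- array(0, dim = c(8, 8, 8))

  # quota below alpha: nothing happens
  q[4, 4, 1] <- 1.5
  res <- cell_update(lat, q, strains, dt_cell = 360)
  expect_equal(res$divisions, 0)

  # quota 2.5 >= alpha 2: divide, mother keeps 0.5, daughter starts empty
  q[4, 4, 1] <- 2.5
  set.seed(5)
  res2 <- cell_update(lat, q, strains, dt_cell = 360)
  expect_equal(res2$divisions, 1)
  expect_equal(live_cell_count(res2$lattice), 2)
  expect_equal(sum(res2$quota), 0.5)

  # death is binomial at d * dt_cell and dead cells stay in place
  latm <- cell_lattice(c(50, 50, 3))
  latm$sites[, , 1] <- 1L               # 2500 cells
  qm <- array(0, dim = c(50, 50, 3))
  dstrain <- list(strain_spec(1, consumes = 1, alpha = 1e9,
                              death_rate = 0.1))
  set.seed(6)
  deaths <- 0; trials <- 0
  for (r in 1:4) {
    res3 <- cell_update(latm, qm, dstrain, dt_cell = 360)  # p = 0.01
    deaths <- deaths + res3$deaths
    trials <- trials + 2500
  }
  p <- 0.1 * 0.1
  expect_equal(deaths / trials, p,
               tolerance = 3 * sqrt(p * (1 - p) / trials) / p)
  expect_equal(sum(res3$lattice$sites < 0), res3$deaths)
  expect_equal(live_cell_count(res3$lattice), 2500 - res3$deaths)

  # an on-death releaser emits its beta pulse at its own site
  rel <- list(strain_spec(1, consumes = 1, releases = 2, alpha = 1e9,
                          death_rate = 0.9, beta = 8))
  latr <- cell_lattice(c(4, 4, 2)); latr$sites[2, 3, 1] <- 1L
  qr <- array(0.7, dim = c(4, 4, 2))
  set.seed(9)
  res4 <- cell_update(latr, qr, rel, dt_cell = 3600)
  expect_equal(res4$deaths, 1)
  ev <- as.data.frame(res4$events)
  expect_setequal(ev$amount, c(8, 0.7))   # beta pulse + recycled quota
  expect_equal(unique(ev$x), 2)
})

test_that("a short cooperative run conserves nutrient mass exactly", {
  set.seed(14)
  cfg <- diffusion_config("cooperative", width_um = 120)
  r <- run_diffusion(cfg, t_end_hr = 24, record_every_hr = 2)
  for (k in 1:2) {
    bal <- r$free_nutrient[, k] + r$quota_total[, k] +
      r$cum_consumed[, k] - r$cum_released[, k]
    expect_lt(max(abs(bal - bal[1])), 1e-9 * max(1, max(r$cum_released[, k])))
  }
  validate_lattice(r$lattice)
})

test_that("realized division frequency matches Monod uptake at saturating S", {
  # saturating nutrient everywhere: each cell accumulates quota at v_m and
  # divides every alpha/v_m seconds, a division frequency of v_m/alpha
  set.seed(15)
  cfg <- diffusion_config("competitive", width_um = 120, density = 2000,
                          S0_agar = 1000)
  cfg$S0_comm <- 1000
  for (i in 1:2) {
    cfg$strains[[i]]$death_rate <- 0
    cfg$strains[[i]]$initial_quota <- 0
  }
  r <- run_diffusion(cfg, t_end_hr = 12, record_every_hr = 0.5)
  t <- r$time
  n <- rowSums(r$live)
  sel <- which(t >= 2 & t <= 12)
  divisions <- n[max(sel)] - n[min(sel)]
  cell_hours <- sum(diff(t[sel]) * (n[sel][-1] + n[sel][-length(sel)]) / 2)
  freq <- divisions / cell_hours
  # in exponential growth the per-cell-hour division frequency is
  # ln(2) / doubling time, with doubling time alpha / v_m at saturation
  v_m <- cfg$strains[[1]]$v_m; alpha <- cfg$strains[[1]]$alpha
  expect_equal(freq, log(2) * v_m * 3600 / alpha, tolerance = 0.1)
})

test_that("the commensal community follows the supplier-consumer narrative", {
  set.seed(16)
  cfg <- diffusion_config("commensal")
  r <- run_diffusion(cfg, t_end_hr = 150, record_every_hr = 5)
  n <- length(r$time)
  # supplier growth stops once agarose lysine is exhausted
  lys_left <- r$free_nutrient[n, 1] / r$free_nutrient[1, 1]
  expect_lt(lys_left, 0.1)
  supplier <- r$live[, 1] + r$dead[, 1]
  late_gain <- supplier[which.min(abs(r$time - 90))] /
    supplier[which.min(abs(r$time - 45))]
  expect_lt(late_gain, 1.2)
  # the consumer ends up outnumbering the supplier
  expect_gt(r$live[n, 2] + r$dead[n, 2], r$live[n, 1] + r$dead[n, 1])
})

test_that("identical competitive strains split the final community evenly", {
  set.seed(18)
  cfg <- diffusion_config("competitive", density = 2000)
  r <- run_diffusion(cfg, t_end_hr = 60)
  n <- length(r$time)
  tot <- r$live[n, ] + r$dead[n, ]
  expect_lt(abs(tot[1] - tot[2]) / sum(tot), 0.15)
})

test_that("diffusion runs are reproducible and variants guard their presets", {
  cfg <- diffusion_config("cooperative", width_um = 120)
  set.seed(19); a <- run_diffusion(cfg, t_end_hr = 12)
  set.seed(19); b <- run_diffusion(cfg, t_end_hr = 12)
  expect_identical(a$lattice$sites, b$lattice$sites)
  expect_identical(a$free_nutrient, b$free_nutrient)

  expect_error(run_diffusion(diffusion_config("competitive"),
                             variant = "instant_distribution"),
               "cooperative")
  # excessive release at factor 1 is bit-identical to the baseline
  set.seed(19)
  c1 <- run_diffusion(cfg, t_end_hr = 12, variant = "excessive_release",
                      release_factor = 1)
  expect_identical(c1$lattice$sites, a$lattice$sites)
  expect_identical(c1$free_nutrient, a$free_nutrient)
})

test_that("instant redistribution conserves mass", {
  set.seed(20)
  cfg <- diffusion_config("cooperative", width_um = 120)
  r <- run_diffusion(cfg, t_end_hr = 24, variant = "instant_distribution")
  for (k in 1:2) {
    bal <- r$free_nutrient[, k] + r$quota_total[, k] +
      r$cum_consumed[, k] - r$cum_released[, k]
    expect_lt(max(abs(bal - bal[1])), 1e-9 * max(1, max(r$cum_released[, k])))
  }
})
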