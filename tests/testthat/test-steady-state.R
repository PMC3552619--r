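test_that("fitness difference evaluates the mean-field forms", {
  coop <- pair_params("coop", 0.3, 0.3, 0.5)
  expect_equal(fitness_difference(0.5, coop), 0)

  coop2 <- pair_params("coop", 0.3, 0.4, 0.5)
  expect_equal(fitness_difference(0, coop2), 0.3 - 0.4 + 0.5)
  # cooperation: quadratic and linear forms coincide exactly
  for (phi in seq(0, 1, by = 0.1))
    expect_equal(fitness_difference(phi, coop2, "quadratic"),
                 fitness_difference(phi, coop2, "linear"))

  comp <- pair_params("~~", 0.35, 0.3)
  expect_equal(fitness_difference(c(0, 0.5, 1), comp), rep(0.05, 3))

  expect_error(fitness_difference(1.2, coop), "\\[0, 1\\]")
})

test_that("steady-state analysis reproduces the closed-form fixed points", {
  # symmetric cooperation
  r <- analyze_steady_state(pair_params("coop", 0.3, 0.3, 0.5))
  expect_equal(r$phi_star, 0.5)
  expect_equal(r$stability, "globally_stable")

  # asymmetric cooperation: (0.3 - 0.4 + 0.5) / (2 * 0.5) = 0.4
  r2 <- analyze_steady_state(pair_params("coop", 0.3, 0.4, 0.5))
  expect_equal(r2$phi_star, 0.4)

  # weak interaction fails the existence condition r_int > |dr|
  r3 <- analyze_steady_state(pair_params("coop", 0.3, 0.4, 0.05))
  expect_false(r3$exists)
  expect_true(is.na(r3$phi_star))

  # mutual antagonism mirrors cooperation but is unstable
  r4 <- analyze_steady_state(pair_params("--", 0.3, 0.4, 0.5))
  expect_equal(r4$phi_star, (0.4 - 0.3 + 0.5) / 1)
  expect_equal(r4$stability, "unstable")

  # exploitation: no real fixed point when r_int > 2 (r_G0 - r_R0)
  r5 <- analyze_steady_state(pair_params("-+", 0.3 + 0.4 * 0.5, 0.3, 0.5))
  expect_false(r5$exists)  # dg = 0.4 r_int violates r_int < 2 dg

  # exploitation inside the window: upper root stable, lower is the basin
  p6 <- pair_params("-+", 0.4, 0.1, 0.5)   # dg = 0.3, r_int in (0.3, 0.6)
  r6 <- analyze_steady_state(p6)
  expect_true(r6$exists)
  expect_equal(r6$phi_star, 0.5 + sqrt(0.3 / 1 - 0.25))
  expect_equal(r6$phi_crit, 0.5 - sqrt(0.3 / 1 - 0.25))
  expect_equal(r6$stability, "locally_stable")

  # linear form reproduces the typeset commensalism/amensalism rows
  expect_equal(analyze_steady_state(pair_params("~+", 0.4, 0.3, 0.5),
                                    form = "linear")$phi_star, 0.2)
  expect_equal(analyze_steady_state(pair_params("~-", 0.3, 0.4, 0.5),
                                    form = "linear")$phi_star, 0.2)
  # full form yields the square-root fixed points
  expect_equal(analyze_steady_state(pair_params("~+", 0.4, 0.3,
                                                0.5))$phi_star,
               sqrt(0.2))
})

test_that("fixed points agree with a brute-force root scan for random draws", {
  set.seed(99)
  types <- c("~~", "++", "~+", "~-", "--", "-+")
  grid <- seq(1e-6, 1 - 1e-6, length.out = 20001)
  n_checked <- 0
  for (i in 1:1000) {
    ty <- sample(types, 1)
    p <- pair_params(ty, runif(1, 0.01, 0.5), runif(1, 0.01, 0.5),
                     if (ty == "~~") 0 else runif(1, 0.01, 1))
    res <- analyze_steady_state(p)
    fd <- fitness_difference(grid, p)
    sgn <- sign(fd)
    cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    roots <- vapply(cross, function(k)
      stats::uniroot(function(x) fitness_difference(x, p),
                     c(grid[k], grid[k + 1]), tol = 1e-12)$root, numeric(1))
    if (res$exists && p$type != "~~") {
      expect_true(any(abs(roots - res$phi_star) < 1e-6),
                  info = sprintf("%s phi*=%g", ty, res$phi_star))
      # stability label matches the slope of the fitness difference
      eps <- 1e-5
      slope <- (fitness_difference(min(res$phi_star + eps, 1), p) -
                fitness_difference(max(res$phi_star - eps, 0), p))
      if (res$stability == "unstable") expect_gt(slope, 0)
      else expect_lt(slope, 0)
      if (!is.na(res$phi_crit))
        expect_true(any(abs(roots - res$phi_crit) < 1e-6))
      n_checked <- n_checked + 1
    } else if (p$type != "~~") {
      # no interior sign change when no fixed point is reported
      expect_equal(length(roots), 0, info = ty)
    }
  }
  expect_gt(n_checked, 100)
})

test_that("ratio dynamics converge to stable fixed points and flee unstable ones", {
  p <- pair_params("coop", 0.3, 0.4, 0.5)  # phi* = 0.4
  # a fixed point stays fixed
  tr0 <- ratio_dynamics(0.4, p, horizon = 200)
  expect_lt(max(abs(tr0$phi_g - 0.4)), 1e-9)
  # convergence from both sides
  for (start in c(0.1, 0.9)) {
    tr <- ratio_dynamics(start, p, horizon = 2000)
    expect_lt(abs(tail(tr$phi_g, 1) - 0.4), 1e-3)
    # monotone approach
    d <- diff(tr$phi_g)
    expect_true(all(d >= -1e-12) || all(d <= 1e-12))
  }
  # commensalism converges to its full-form fixed point
  pc <- pair_params("~+", 0.4, 0.3, 0.5)
  st <- analyze_steady_state(pc)
  trc <- ratio_dynamics(0.9, pc, horizon = 3000)
  expect_lt(abs(tail(trc$phi_g, 1) - st$phi_star), 1e-3)

  # strong mutual antagonism diverges away from the interior fixed point
  pa <- pair_params("--", 0.3, 0.3, 0.6)   # phi* = 0.5, unstable
  up <- ratio_dynamics(0.55, pa, horizon = 2000)
  dn <- ratio_dynamics(0.45, pa, horizon = 2000)
  expect_gt(tail(up$phi_g, 1), 0.99)
  expect_lt(tail(dn$phi_g, 1), 0.01)

  # exploitation: starts below the critical fraction collapse to 0,
  # starts above converge to phi*
  pe <- pair_params("-+", 0.4, 0.1, 0.5)
  se <- analyze_steady_state(pe)
  lo <- ratio_dynamics(se$phi_crit - 0.05, pe, horizon = 4000)
  hi <- ratio_dynamics(se$phi_crit + 0.05, pe, horizon = 4000)
  expect_lt(tail(lo$phi_g, 1), 0.01)
  expect_lt(abs(tail(hi$phi_g, 1) - se$phi_star), 1e-3)

  # absurd step size is rejected
  expect_error(ratio_dynamics(0.2, pair_params("--", 0.5, 0.5, 50),
                              horizon = 1000, dt = 500), "step")
})
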