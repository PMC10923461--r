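test_that("the closed-form cycle reproduces the reference frequencies", {
  sol_plain <- gd_constant_solution(3.6, default_dp, with_reset = FALSE)
  expect_equal(sol_plain$f_net, 290.7, tolerance = 0.5 / 290.7)
  expect_equal(sol_plain$T, 3.44, tolerance = 0.05 / 3.44)
  sol_reset <- gd_constant_solution(3.6, default_dp, with_reset = TRUE)
  expect_equal(sol_reset$f_net, 235.8, tolerance = 0.5 / 235.8)
  expect_equal(sol_reset$T, 4.24, tolerance = 0.05 / 4.24)
  # identities within the assembled solution
  expect_equal(sol_reset$T, sol_reset$t_off + default_dp$delta)
  expect_equal(sol_reset$f_unit, sol_reset$s * sol_reset$f_net)
  expect_lt(sol_reset$mu_min, sol_plain$mu_min)
})

test_that("existence bounds gate the closed form with named reasons", {
  expect_equal(gd_existence_bounds(default_dp)$IE_lower, 0.56,
               tolerance = 1e-3)
  expect_error(gd_mu_max(0.4, default_dp), "drive below oscillation onset",
               class = "ripplenet_no_oscillation")
  weak <- dimensionless_params(K = 0.1)
  expect_error(gd_mu_max(5, weak), "coupling too weak",
               class = "ripplenet_no_oscillation")
  bad <- gd_constant_solution(0.4, default_dp)
  expect_false(bad$valid)
  expect_match(bad$reason, "oscillation onset")
})

test_that("mu_max is independent of mu_min and below the drive", {
  expect_false("mu_min" %in% names(formals(gd_mu_max)))
  for (IE in c(3, 5, 8)) expect_lt(gd_mu_max(IE, default_dp), IE)
  # delta -> 0 limit with K fixed
  p0 <- dimensionless_params(delta = 1e-9)
  lim <- 1 - sqrt(2 * 0.04 * log(5 / sqrt(2 * pi * 0.04)))
  expect_equal(gd_mu_max(5, p0), lim, tolerance = 1e-6)
})

test_that("saturation follows the Gaussian tail", {
  expect_equal(gd_saturation(1, default_dp), 0.5)
  expect_equal(gd_saturation(1 + 3 * sqrt(0.04), default_dp), 0.9987,
               tolerance = 1e-4)
  expect_lt(gd_saturation(-10, default_dp), 1e-10)
  # monotone in mu_max
  mm <- seq(0, 2, by = 0.1)
  expect_true(all(diff(gd_saturation(mm, default_dp)) > 0))
})

test_that("the population reset shifts the mean by the fired fraction", {
  expect_equal(gd_mu_reset(0.8, 0, default_dp), 0.8)
  expect_equal(gd_mu_reset(0.8, 1, default_dp), 0.8 - 1)  # V_T - V_R = 1
  s <- gd_saturation(0.9, default_dp)
  expect_equal(gd_mu_reset(0.9, s, default_dp), 0.9 - s)
})

test_that("the inhibition bracket vanishes with the coupling", {
  # formal K -> 0 limit of the downstroke: pure relaxation plus drive
  p <- default_dp
  mu_max <- gd_mu_max(3.6, p)
  p0 <- p; p0$K <- 0
  expect_equal(ripplenet:::gd_inhibition_term(3.6, mu_max, p0), 0)
})

test_that("cycle quantities are monotone across the applicability range", {
  rng <- gd_applicability_range(default_dp)
  grid <- seq(rng$IE_min, rng$IE_max, length.out = 60)
  sols <- lapply(grid, gd_constant_solution, params = default_dp)
  s <- vapply(sols, `[[`, 0, "s")
  mm <- vapply(sols, `[[`, 0, "mu_max")
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(mm) > 0))
  # mu_min decreases with drive over most of the range; it flattens and
  # turns up only close to full synchrony
  sub <- grid <= rng$IE_min + 0.8 * (rng$IE_full - rng$IE_min)
  mn <- vapply(sols, `[[`, 0, "mu_min")[sub]
  expect_true(all(diff(mn) < 0))
})

test_that("full-synchrony drive exceeds the simulation estimate and scales", {
  IEfull <- gd_full_synchrony_drive(default_dp)
  expect_gt(IEfull, 8.9)         # the closed form slightly overestimates
  expect_lt(IEfull, 11)
  # vanishing noise: full synchrony at the threshold scale
  expect_equal(gd_full_synchrony_drive(dimensionless_params(D = 1e-10)), 1,
               tolerance = 1e-3)
  # stronger coupling or noise require stronger drive
  expect_gt(gd_full_synchrony_drive(dimensionless_params(K = 10)), IEfull)
  expect_gt(gd_full_synchrony_drive(dimensionless_params(D = 0.08)), IEfull)
})

test_that("the applicability range matches the reference bounds", {
  rng <- gd_applicability_range(default_dp)
  expect_false(rng$empty)
  expect_equal(rng$IE_min, 2.85, tolerance = 0.02)
  expect_equal(rng$IE_max, rng$IE_full)   # constraint (a) binds by default
  expect_equal(rng$limiting, "single_spike")
})

test_that("performance scores satisfy their definitions", {
  rng <- gd_applicability_range(default_dp)
  grid <- seq(rng$IE_min, rng$IE_full, by = 0.1)
  f_th <- vapply(grid, function(IE)
    gd_constant_solution(IE, default_dp)$f_net, 0)
  # theory compared against itself: zero error, full coverage
  sc <- gd_performance_scores(grid, f_th, IE_crit_sim = 1.48,
                              IE_full_sim = rng$IE_full, default_dp)
  expect_equal(sc$chi_err, 0, tolerance = 1e-12)
  expect_equal(sc$chi_appl,
               (rng$IE_full - rng$IE_min) / (rng$IE_full - 1.48),
               tolerance = 1e-6)
  expect_equal(sc$chi_p, sc$chi_appl * (1 - sc$chi_err))
  # a uniformly 10% high simulation curve
  sc2 <- gd_performance_scores(grid, f_th * 1.1, 1.48, rng$IE_full,
                               default_dp)
  expect_equal(sc2$chi_err, 0.1 / 1.1, tolerance = 1e-6)
})

test_that("the theory tracks simulated network frequencies across drives", {
  pp <- physical_params(N = 1000)
  drives <- c(3.5, 4.5, 5.5, 6.5, 8)
  f_sim <- vapply(drives, function(IE) {
    sim <- simulate_network(
      pp, constant_drive(drive_to_physical(IE, pp), 1050, units = "nA"),
      seed = 14)
    network_frequency_psd(sim)$f_net
  }, 0)
  # network frequency decreases with drive in this range
  expect_true(all(diff(f_sim) < 0))
  f_th <- vapply(drives, function(IE)
    gd_constant_solution(IE, to_dimensionless(pp))$f_net, 0)
  # agreement to roughly fifteen percent across the sparse-synchrony range
  expect_true(all(abs(f_sim - f_th) / f_sim < 0.18))
  expect_lt(median(abs(f_sim - f_th) / f_sim), 0.15)
})
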