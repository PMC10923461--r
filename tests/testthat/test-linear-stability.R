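test_that("the parabolic cylinder function matches closed forms and
           high-precision reference values", {
  z <- c(-1.3, 0.4, 2.2)
  expect_equal(Re(vapply(z, function(zz) pcf_d(0, zz), complex(1))),
               exp(-z^2 / 4), tolerance = 1e-13)
  d_m1 <- exp(z^2 / 4) * sqrt(pi / 2) * ripplenet:::erfc(z / sqrt(2))
  expect_equal(Re(vapply(z, function(zz) pcf_d(-1, zz), complex(1))),
               d_m1, tolerance = 1e-12)
  # frozen values from an independent arbitrary-precision computation
  refs <- list(
    list(nu = -9.59i, z = -1.6,
         val = complex(real = -32876.361787509586,
                       imaginary = -25441.436188140456)),
    list(nu = -1 - 9.59i, z = -1.6,
         val = complex(real = -15488.179910568794,
                       imaginary = 4481.2901419496802)),
    list(nu = -2.3i, z = 3.4,
         val = complex(real = -0.065439173035216073,
                       imaginary = -0.014032770256876893)),
    list(nu = 0.7 - 0.3i, z = 0.9,
         val = complex(real = 0.85568759639335136,
                       imaginary = 0.053120927826941559)))
  for (r in refs)
    expect_lt(Mod(pcf_d(r$nu, r$z) - r$val) / Mod(r$val), 1e-10)
})

test_that("lambert_w_log matches pracma on both branches and tiny arguments", {
  expect_equal(lambert_w_log(log(2), 1), pracma::lambertWp(2),
               tolerance = 1e-12)
  expect_equal(lambert_w_log(log(0.2), -1, "0"), pracma::lambertWp(-0.2),
               tolerance = 1e-10)
  expect_equal(lambert_w_log(log(0.2), -1, "-1"), pracma::lambertWn(-0.2),
               tolerance = 1e-9)
  # log-space arguments far beyond double range
  w <- lambert_w_log(5000, 1)
  expect_equal(w + log(w), 5000, tolerance = 1e-9)
  w2 <- lambert_w_log(-5000, -1, "-1")
  expect_equal(-w2 - log(-w2), 5000, tolerance = 1e-9)
  expect_true(is.na(lambert_w_log(-0.5, -1, "0")))   # below -1/e
})

test_that("the f-I curve has the deterministic and subthreshold limits", {
  # vanishing noise, suprathreshold: deterministic LIF rate
  p_small <- dimensionless_params(D = 1e-6)
  f_det <- 1000 / (10 * log((3 - 0) / (3 - 1)))
  expect_equal(lif_rate(3, p_small), f_det, tolerance = 1e-3)
  # strongly subthreshold: essentially silent
  expect_lt(lif_rate(0.3, dimensionless_params(D = 0.01)), 1e-6)
  # monotone increasing
  I <- seq(0.5, 3, by = 0.25)
  expect_true(all(diff(lif_rate(I, default_dp)) > 0))
})

test_that("the f-I curve matches an uncoupled spiking simulation", {
  p <- dimensionless_params(N = 500, K = 0)
  sim <- simulate_network(p, constant_drive(0.9, 2550), seed = 3)
  emp <- unit_stats(sim)$f_unit
  expect_equal(emp, lif_rate(0.9, p), tolerance = 0.02)
})

test_that("the stationary state is self-consistent and inhibition lowers it", {
  st <- stationary_state(1.48, default_dp)
  expect_equal(st$I0, 1.48 - 5 * 10 * st$r0 / 1000, tolerance = 1e-6)
  expect_equal(st$r0, lif_rate(st$I0, default_dp), tolerance = 1e-6)
  # K = 0 reduces to the bare f-I curve
  p0 <- dimensionless_params(K = 0)
  expect_equal(stationary_state(1.48, p0)$r0, lif_rate(1.48, p0),
               tolerance = 1e-8)
  # the rate decreases with coupling at fixed drive
  r_k <- vapply(c(0, 2, 5, 10), function(K)
    stationary_state(1.48, dimensionless_params(K = K))$r0, 0)
  expect_true(all(diff(r_k) < 0))
})

test_that("the susceptibility has the static limit and conjugate symmetry", {
  st <- stationary_state(1.48, default_dp)
  g0 <- susceptibility(1e-9, st, default_dp)
  fd <- (lif_rate(st$I0 + 1e-5, default_dp) -
         lif_rate(st$I0 - 1e-5, default_dp)) / 2e-5 / 1000
  expect_equal(Re(g0), fd, tolerance = 1e-4)
  expect_lt(abs(Im(g0)), 1e-6)
  om <- 2 * pi * 0.3    # 300 Hz in rad/ms
  expect_equal(susceptibility(-om, st, default_dp),
               Conj(susceptibility(om, st, default_dp)), tolerance = 1e-10)
  # low-pass decay at high frequency
  expect_lt(Mod(susceptibility(2 * pi * 5, st, default_dp)),
            Mod(susceptibility(2 * pi * 0.3, st, default_dp)))
})

test_that("the Hopf point matches the reference bifurcation values", {
  hp <- hopf_point(default_pp)
  expect_equal(hp$I_ext_crit, 0.19, tolerance = 0.05)
  expect_equal(hp$IE_crit, 1.48, tolerance = 0.05)
  expect_equal(hp$f_net, 305, tolerance = 0.05)
  expect_equal(hp$f_unit, 16, tolerance = 0.05)
  expect_equal(hp$s, 0.05, tolerance = 0.15)
  # amplitude and phase conditions hold at the solution (same parameter
  # set the solver used: the converted physical one, D = 0.0406)
  dp <- to_dimensionless(default_pp)
  st <- stationary_state(hp$IE_crit, dp)
  g <- susceptibility(hp$omega, st, dp)
  expect_equal(dp$K * dp$tau_m * Mod(g), 1, tolerance = 1e-3)
  ph <- pi + Arg(g) - hp$omega * dp$delta
  expect_lt(abs(((ph + pi) %% (2 * pi)) - pi), 1e-5)
  # the drift theory's validity begins well above the Hopf point
  expect_lt(gd_existence_bounds(default_dp)$IE_lower, hp$IE_crit)
})

test_that("finite networks oscillate near the predicted frequency above
           threshold and not below", {
  pp <- physical_params(N = 1000)
  below <- simulate_network(pp, constant_drive(0.10, 1050, units = "nA"),
                            seed = 21)
  res_b <- network_frequency_psd(below)
  above <- simulate_network(pp, constant_drive(0.26, 1050, units = "nA"),
                            seed = 21)
  res_a <- network_frequency_psd(above)
  expect_true(res_a$valid)
  expect_lt(abs(res_a$f_net - 305) / 305, 0.15)
  # below threshold: no comparably sharp spectral peak
  if (res_b$valid) expect_gt(res_a$power / median(res_a$psd$power),
                             res_b$power / median(res_b$psd$power))
})
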