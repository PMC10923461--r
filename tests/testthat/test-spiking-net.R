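test_that("uncoupled noiseless units fire at the deterministic LIF rate", {
  p <- dimensionless_params(N = 40, K = 0, D = 1e-12)
  IE <- 2
  sim <- simulate_network(p, constant_drive(IE, 400), dt = 0.01, seed = 1)
  period <- p$tau_m * log((IE - p$V_R) / (IE - p$V_T))
  f_expect <- 1000 / period
  f_emp <- unit_stats(sim, discard = 50)$f_unit
  expect_equal(f_emp, f_expect, tolerance = 0.01)
  # every unit perfectly periodic
  expect_lt(unit_stats(sim)$cv_isi, 1e-6)
})

test_that("spike counts are conserved through the rate pipeline", {
  sim <- simulate_network(dimensionless_params(N = 150),
                          constant_drive(4, 300), dt = 0.02, seed = 7)
  n_spk <- nrow(sim$spikes)
  expect_equal(sum(sim$counts), n_spk)
  expect_equal(sum(sim$rate$raw) * sim$N * sim$dt / 1000, n_spk)
  # smoothing preserves the area up to boundary flux (half a kernel's worth
  # of rate can cross each edge of the recording)
  expect_equal(sum(sim$rate$smooth) * sim$N * sim$dt / 1000, n_spk,
               tolerance = 0.01)
})

test_that("Gaussian smoothing is normalized and has the semigroup property", {
  dt <- 0.01
  x <- rep(3.7, 5000)
  expect_equal(smooth_rate(x, 0.3, dt), x, tolerance = 1e-12)
  set.seed(5)
  y <- pmax(rnorm(6000, 50, 10), 0)
  twice <- smooth_rate(smooth_rate(y, 0.3, dt), 0.3, dt)
  once <- smooth_rate(y, 0.3 * sqrt(2), dt)
  i <- 500:5500
  expect_equal(twice[i], once[i], tolerance = 1e-5)
  # a single spike becomes a unit-area Gaussian bump (area in count units)
  z <- rep(0, 4000); z[2000] <- 1 / (100 * dt) * 1000   # one spike, N = 100
  sm <- smooth_rate(z, 0.3, dt)
  expect_equal(sum(sm) * 100 * dt / 1000, 1, tolerance = 1e-9)
})

test_that("the C++ core matches a step-by-step R reference on one seed", {
  dp <- dimensionless_params(N = 200)
  IE_level <- drive_to_dimensionless(0.55, default_pp)
  n_steps <- 20000L; dt <- 0.01
  counts_ref <- r_reference_sim(dp, rep(IE_level, n_steps), n_steps, dt,
                                seed = 99)
  sim <- simulate_network(dp, constant_drive(IE_level, n_steps * dt),
                          dt = dt, seed = 99)
  r_ref <- sum(counts_ref) / dp$N / (n_steps * dt) * 1000
  r_cpp <- sum(sim$counts) / dp$N / (n_steps * dt) * 1000
  # same seed sequence: agreement well within 3 SE of the mean unit rate
  unit_rates <- tabulate(sim$spikes$unit, dp$N) / (n_steps * dt) * 1000
  se <- sd(unit_rates) / sqrt(dp$N)
  expect_lt(abs(r_ref - r_cpp), 3 * se)
})

test_that("network frequency is robust to halving dt and network size", {
  pp <- physical_params(N = 1000)
  f <- vapply(c(0.01, 0.02), function(dt) {
    sim <- simulate_network(pp, constant_drive(0.55, 1050, units = "nA"),
                            dt = dt, seed = 4)
    network_frequency_psd(sim)$f_net
  }, 0)
  expect_lt(abs(f[1] - f[2]) / f[1], 0.02)
  sim_small <- simulate_network(physical_params(N = 200),
                                constant_drive(0.55, 1050, units = "nA"),
                                seed = 4)
  f_small <- network_frequency_psd(sim_small)$f_net
  expect_lt(abs(f_small - f[1]) / f[1], 0.06)
})

test_that("the drive sweep reproduces the four dynamical regimes", {
  pp <- physical_params(N = 500)
  run <- function(I_nA, dur = 1050) {
    sim <- simulate_network(pp, constant_drive(I_nA, dur, units = "nA"),
                            seed = 8)
    fn <- network_frequency_psd(sim)
    us <- unit_stats(sim)
    list(f_net = fn$f_net, valid = fn$valid, f_unit = us$f_unit,
         cv = us$cv_isi,
         s = if (fn$valid) saturation(us$f_unit, fn$f_net) else NA)
  }
  async <- run(0.15, dur = 3050)  # below the bifurcation; long run so each
                                  # unit has enough ISIs for a stable CV
  sparse <- run(0.55)      # sparse synchrony
  full <- run(1.25)        # near full synchrony
  multi <- run(1.80)       # multiple spikes per cycle
  # asynchronous irregular: near-Poisson units (short trains bias the CV
  # estimate slightly below 1)
  expect_gt(async$cv, 0.75)
  # sparse synchrony: ripple-band rhythm, units fire in a fraction of cycles
  expect_true(sparse$valid)
  expect_gt(sparse$f_net, 140); expect_lt(sparse$f_net, 220)
  expect_lt(sparse$s, 1)
  expect_gt(sparse$cv, 0.25); expect_lt(sparse$cv, 0.75)
  # full synchrony: saturation near one
  expect_gt(full$s, 0.9); expect_lt(full$s, 1.1)
  # multiple spikes per cycle beyond full synchrony
  expect_gt(multi$s, 1.1)
  expect_gt(multi$cv, full$cv)
})

test_that("average cycle extraction needs enough cycles and recovers the noise SD", {
  pp <- physical_params(N = 500)
  sim <- simulate_network(pp, constant_drive(0.55, 650, units = "nA"),
                          seed = 12, record_snapshots = TRUE,
                          snapshot_every = 0.25)
  avg <- average_cycle(sim, n_bins = 21)
  expect_equal(length(avg$rate), 21)
  expect_gt(avg$n_cycles, 10)
  # between population spikes the voltage SD relaxes from above towards
  # sqrt(D), the free long-time value; reset-induced bimodality and the
  # finite bin width keep the minimum somewhat above the asymptote
  D <- to_dimensionless(pp)$D
  expect_gt(min(avg$sd_v), 0.95 * sqrt(D))
  expect_lt(min(avg$sd_v), 1.35 * sqrt(D))
  expect_gt(max(avg$sd_v), 1.15 * min(avg$sd_v))   # cycle modulation
  short <- simulate_network(pp, constant_drive(0.55, 80, units = "nA"),
                            seed = 12)
  expect_error(average_cycle(short), "cycles")
})

test_that("same seed gives identical simulations", {
  p <- dimensionless_params(N = 100)
  s1 <- simulate_network(p, constant_drive(4, 200), dt = 0.02, seed = 31)
  s2 <- simulate_network(p, constant_drive(4, 200), dt = 0.02, seed = 31)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$rate$raw, s2$rate$raw)
  s3 <- simulate_network(p, constant_drive(4, 200), dt = 0.02, seed = 32)
  expect_false(identical(s1$spikes, s3$spikes))
})
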