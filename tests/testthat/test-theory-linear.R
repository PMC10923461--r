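test_that("the linear-drive cycle degenerates to the constant-drive one", {
  p <- default_dp
  IE <- 3.6
  sol <- gd_constant_solution(IE, p, with_reset = TRUE)
  # m = 0 reduces every operation exactly / to quadrature accuracy
  expect_equal(gd_mu_max_linear(IE, 0, p), sol$mu_max, tolerance = 1e-12)
  cyc0 <- gd_cycle_map(IE, sol$mu_min, 0, p)
  expect_equal(cyc0$t_off, sol$t_off, tolerance = 1e-10)
  expect_lt(abs(cyc0$mu_min_next - sol$mu_min) / abs(sol$mu_min), 1e-3)
  # |m| -> 0 continuity at 1e-4 per ms
  for (m in c(1e-4, -1e-4)) {
    mm <- as.numeric(gd_mu_max_linear(IE, m, p))
    expect_lt(abs(mm - sol$mu_max) / sol$mu_max, 1e-3)
    tf <- gd_t_off_linear(IE, sol$mu_min, mm, m, p)
    expect_lt(abs(tf - sol$t_off) / sol$t_off, 1e-3)
  }
})

test_that("the Lambert-W rise time solves the transcendental equation", {
  p <- default_dp
  for (m in c(0.4, -0.4, 0.05, -0.05)) {
    mu_min <- gd_mu_min(3.6, p, TRUE)
    mu_max <- as.numeric(gd_mu_max_linear(3.6, m, p))
    tf <- gd_t_off_linear(3.6, mu_min, mu_max, m, p)
    # direct substitution into the upstroke trajectory
    IE0 <- 3.6 - m * tf
    mu_at <- 3.6 - m * p$tau_m +
      (m * p$tau_m + mu_min - IE0) * exp(-tf / p$tau_m)
    expect_equal(mu_at, mu_max, tolerance = 1e-10, label = paste("m =", m))
  }
  expect_equal(gd_t_off_linear(3.6, 0.5, 0.5, 0.4, default_dp), 0)
})

test_that("low-drive rising cycles can lack a transient solution", {
  p <- default_dp
  mu_max <- as.numeric(gd_mu_max_linear(2, 0.4, p))
  expect_error(gd_t_off_linear(2, -3, mu_max, 0.4, p),
               class = "ripplenet_no_transient")
})

test_that("slope perturbs the peak against the drive direction", {
  p <- default_dp
  for (IE in c(4, 5, 7)) {
    m_inf <- gd_mu_max(IE, p)
    expect_lt(as.numeric(gd_mu_max_linear(IE, 0.4, p)), m_inf)
    expect_gt(as.numeric(gd_mu_max_linear(IE, -0.4, p)), m_inf)
  }
})

test_that("the perturbative peak agrees with the root to second order", {
  p <- default_dp
  errs <- vapply(c(0.4, 0.2, 0.1), function(m) {
    full <- as.numeric(gd_mu_max_linear(5, m, p, method = "root"))
    pert <- gd_mu_max_linear(5, m, p, method = "perturbative")
    abs(full - pert)
  }, 0)
  # halving m shrinks the discrepancy roughly quadratically
  expect_gt(errs[1] / errs[2], 2.5)
  expect_gt(errs[2] / errs[3], 2.5)
})

test_that("cycle-end state deviates from the asymptote in the slope direction", {
  p <- default_dp
  # the first-order sign rule; at low drive it requires a moderate slope
  # (fast ramps at the low-drive edge are beyond the linearised argument)
  cases <- rbind(expand.grid(IE = c(4, 5, 7), m = 0.2),
                 expand.grid(IE = c(5, 7), m = 0.4))
  for (i in seq_len(nrow(cases))) {
    IE <- cases$IE[i]; m <- cases$m[i]
    mn_inf <- gd_mu_min(IE, p, TRUE)
    up <- gd_cycle_map(IE, mn_inf, m, p)
    dn <- gd_cycle_map(IE, mn_inf, -m, p)
    expect_gt(up$mu_min_next, mn_inf)
    expect_lt(dn$mu_min_next, mn_inf)
    # starting at the asymptotic minimum: rising drive lengthens the
    # upstroke, falling drive shortens it (drive was lower/higher earlier)
    t_inf <- gd_constant_solution(IE, p)$t_off
    expect_gt(up$t_off, t_inf)
    expect_lt(dn$t_off, t_inf)
  }
})

test_that("doubling the quadrature panels leaves the cycle end unchanged", {
  p <- default_dp
  mm <- as.numeric(gd_mu_max_linear(5, 0.4, p))
  a <- ripplenet:::gd_mu_min_next(5, 0.4, mm, p, n_panels = 200)
  b <- ripplenet:::gd_mu_min_next(5, 0.4, mm, p, n_panels = 400)
  expect_lt(abs(a - b), 1e-6)
})

test_that("chained cycles reproduce the hysteresis sign law", {
  ch <- gd_chain_cycles(make_spw_drive(0.74, 8.9, 0.4), default_dp)
  up <- ch[ch$phase == "up" & ch$has_ref, ]
  dn <- ch[ch$phase == "down" & ch$has_ref, ]
  expect_gte(nrow(up), 3); expect_gte(nrow(dn), 2)
  # rising: instantaneous above asymptotic; falling: below (<= 1 exception)
  expect_lte(sum(up$f_inst < up$f_ref), 1)
  expect_lte(sum(dn$f_inst > dn$f_ref), 1)
  # consecutive cycles are matched in drive
  m <- attr(ch, "slope_m")
  for (i in seq_len(nrow(up) - 1))
    expect_equal(up$I_hat[i] + m * default_dp$delta,
                 up$I_hat[i + 1] - m * up$t_off[i + 1], tolerance = 1e-4)
  # the final falling cycle survives below the range where cycles can start
  expect_true(any(!ch$has_ref[ch$phase == "down"]))
  last <- ch[nrow(ch), ]
  expect_lt(last$I_hat, gd_applicability_range(default_dp)$IE_min)
})

test_that("the theoretical IFA slope is negative and speed-dependent", {
  chis <- vapply(c(0.4, 0.2, 0.1), function(m)
    gd_ifa_theory(make_spw_drive(0.74, 8.9, m), default_dp)$chi_ifa, 0)
  expect_true(all(chis < 0))
  # |chi| shrinks monotonically for slower ramps
  expect_true(all(diff(abs(chis)) < 0))
})

test_that("the IFA decomposition holds for the symmetric double ramp", {
  # regression over deviations from the asymptotic reference carries the
  # slope; the reference's own covariance with time is comparatively small
  ch <- gd_chain_cycles(make_spw_drive(0.74, 8.9, 0.4), default_dp)
  ok <- ch$has_ref
  t <- ch$t_mid[ok]; f <- ch$f_inst[ok]; fr <- ch$f_ref[ok]
  chi <- cov(f, t) / var(t)
  chi_dev <- cov(f - fr, t) / var(t)
  chi_ref <- cov(fr, t) / var(t)
  expect_equal(chi, chi_dev + chi_ref, tolerance = 1e-10)
  expect_lt(abs(chi_ref), 0.45 * abs(chi))
})

test_that("theory-vs-simulation error scores behave as defined", {
  ch <- gd_chain_cycles(make_spw_drive(0.74, 8.9, 0.4), default_dp)
  self <- data.frame(t = ch$t_mid, f = ch$f_inst, valid = TRUE)
  expect_equal(theory_sim_error(ch, self), 0, tolerance = 1e-12)
  high <- transform(self, f = f / 1.1)   # theory uniformly 10% above "sim"
  expect_equal(theory_sim_error(ch, high), 0.1, tolerance = 1e-12)
  far <- transform(self, t = t + 1000)
  expect_error(theory_sim_error(ch, far), "overlap")
})
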