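# Transient cycle theory for linearly changing drive: the per-cycle map
# (I_hat, mu_min, m) -> (f_inst, t_off, mu_max, mu_reset, mu_min'), cycle
# chaining over the sharp wave-like double ramp, the theoretical IFA slope,
# and the theory-vs-simulation error.
#
# Each cycle is anchored at the end of its population spike: the reference
# drive I_hat is the drive at time t_off, so the drive during the cycle is
# I_E(t) = I_hat + m (t - t_off).

#' Cycle peak under linearly changing drive
#'
#' Solves the transcendental peak condition for drive changing at slope `m`
#' around the reference level `I_hat`, seeded at the constant-drive peak
#' \eqn{\mu_{max}^\infty(\hat I_E)}. When the bracketing root search fails
#' the first-order perturbative value \eqn{\mu_{max}^\infty + m \hat\mu} is
#' returned with attribute `perturbative = TRUE`. For rising drive the peak
#' lies slightly below its asymptotic value, and slightly above for falling
#' drive.
#'
#' @param I_hat reference drive (at the end of the population spike).
#' @param m drive slope, per ms.
#' @param params a `dimensionless_params` (or physical, converted).
#' @param method `"root"` (default; falls back to perturbative) or
#'   `"perturbative"` (first order in `m`).
#' @return the cycle peak `mu_max`; errors of class
#'   `ripplenet_no_oscillation` propagate from the constant-drive seed.
#' @export
gd_mu_max_linear <- function(I_hat, m, params,
                             method = c("root", "perturbative")) {
  method <- match.arg(method)
  p <- as_dimensionless(params)
  mu_inf <- gd_mu_max(I_hat, p)
  if (m == 0) return(mu_inf)
  if (method == "perturbative")
    return(mu_inf + m * gd_mu_hat(I_hat, p))
  e1 <- exp(p$delta / p$tau_m)
  F <- function(mu) {
    arg <- p$V_T - I_hat - (mu - I_hat) * e1 -
      m * (p$tau_m * e1 - (p$delta + p$tau_m))
    I_hat - mu - p$K * ((I_hat - mu) * e1 - m * p$tau_m * (e1 - 1)) /
      sqrt(2 * pi * p$D) * exp(-arg^2 / (2 * p$D))
  }
  half <- max(5 * abs(m) * abs(gd_mu_hat(I_hat, p)), 0.05)
  lo <- mu_inf - half
  hi <- min(I_hat - 1e-9, mu_inf + half)
  if (is.finite(F(lo)) && is.finite(F(hi)) && F(lo) * F(hi) < 0) {
    uniroot(F, c(lo, hi), tol = 1e-12)$root
  } else {
    structure(mu_inf + m * gd_mu_hat(I_hat, p), perturbative = TRUE)
  }
}

# first-order sensitivity of the cycle peak to the drive slope, computed as
# -dF/dm / dF/dmu at (mu_max_inf, m = 0) by central differences of the
# smooth peak condition
gd_mu_hat <- function(I_hat, p) {
  mu_inf <- gd_mu_max(I_hat, p)
  e1 <- exp(p$delta / p$tau_m)
  F <- function(mu, m) {
    arg <- p$V_T - I_hat - (mu - I_hat) * e1 -
      m * (p$tau_m * e1 - (p$delta + p$tau_m))
    I_hat - mu - p$K * ((I_hat - mu) * e1 - m * p$tau_m * (e1 - 1)) /
      sqrt(2 * pi * p$D) * exp(-arg^2 / (2 * p$D))
  }
  h_mu <- 1e-6
  h_m <- 1e-6
  dF_dmu <- (F(mu_inf + h_mu, 0) - F(mu_inf - h_mu, 0)) / (2 * h_mu)
  dF_dm <- (F(mu_inf, h_m) - F(mu_inf, -h_m)) / (2 * h_m)
  -dF_dm / dF_dmu
}

#' Upstroke duration under linearly changing drive
#'
#' Closed form via the Lambert W function:
#' \deqn{t_{off} = -\tau_m W\Bigl(\tfrac{\hat I_E - m\tau_m -
#'   \mu_{max}}{m\tau_m}\, e^{-1 + (\hat I_E - \mu_{min})/(m\tau_m)}\Bigr)
#'   + \tfrac{\hat I_E - m\tau_m - \mu_{min}}{m}.}
#' The physical branch is the principal branch for rising drive and the
#' lower branch for falling drive (the argument of W tends to `+inf` resp.
#' `0^-` as `m -> 0`, and only these branches recover the constant-drive
#' rise time in that limit); the argument is evaluated in log space so that
#' the limit is numerically reachable. For rising drive at low reference
#' drive the argument can drop below `-1/e`: no transient solution exists
#' and a classed error (`ripplenet_no_transient`) is signalled.
#'
#' @inheritParams gd_mu_max_linear
#' @param mu_min initial mean membrane potential of the cycle.
#' @param mu_max cycle peak (from [gd_mu_max_linear()]).
#' @return upstroke duration, ms.
#' @export
gd_t_off_linear <- function(I_hat, mu_min, mu_max, m, params) {
  p <- as_dimensionless(params)
  if (!(I_hat > mu_max) || mu_min >= mu_max) {
    if (isTRUE(all.equal(mu_min, mu_max))) return(0)
    if (mu_min > mu_max) stop("ordering violated: mu_min > mu_max")
  }
  if (abs(m) < 1e-12) return(gd_t_off(mu_min, mu_max, I_hat, p))
  A <- I_hat - m * p$tau_m - mu_max
  P <- (I_hat - m * p$tau_m - mu_min) / m
  if (A == 0) return(P)
  log_y <- log(abs(A) / abs(m * p$tau_m)) + P / p$tau_m
  u <- lambert_w_log(log_y, sign(A / m), if (m > 0) "0" else "-1")
  if (is.na(u))
    stop(structure(
      class = c("ripplenet_no_transient", "error", "condition"),
      list(message = sprintf(
        "no transient solution: Lambert-W argument below -1/e (I_hat = %g, mu_min = %g, m = %g)",
        I_hat, mu_min, m), call = NULL)))
  t_off <- P - p$tau_m * u
  if (!is.finite(t_off) || t_off <= 0)
    stop(structure(
      class = c("ripplenet_no_transient", "error", "condition"),
      list(message = "no positive upstroke solution", call = NULL)))
  t_off
}

#' One transient cycle under linearly changing drive
#'
#' The per-cycle map: given the reference drive `I_hat`, the initial mean
#' membrane potential `mu_min` and the drive slope `m`, computes the cycle
#' peak, the upstroke duration, the instantaneous network frequency
#' `f_inst = 1/(t_off + delta)`, the saturation and reset, and the mean
#' membrane potential `mu_min_next` reached at the end of the cycle (the
#' initial condition of the next cycle), by trapezoid quadrature of the
#' downstroke integral split into the stationary feedback part and the
#' slope-proportional correction.
#'
#' @inheritParams gd_t_off_linear
#' @param n_panels quadrature panels (composite Simpson, even count) for the
#'   downstroke integral; doubling the default changes `mu_min_next` by less
#'   than 1e-6.
#' @return list with `I_hat`, `m`, `mu_min`, `mu_max`, `s`, `mu_reset`,
#'   `t_off`, `T`, `f_inst` (Hz), `f_unit` (Hz), `mu_min_next`.
#' @export
gd_cycle_map <- function(I_hat, mu_min, m, params, n_panels = 200) {
  p <- as_dimensionless(params)
  mu_max <- as.numeric(gd_mu_max_linear(I_hat, m, p))
  t_off <- gd_t_off_linear(I_hat, mu_min, mu_max, m, p)
  s <- gd_saturation(mu_max, p)
  mu_reset <- gd_mu_reset(mu_max, s, p)
  mu_min_next <- gd_mu_min_next(I_hat, m, mu_max, p, n_panels)
  T <- t_off + p$delta
  list(I_hat = I_hat, m = m, mu_min = mu_min, mu_max = mu_max, s = s,
       mu_reset = mu_reset, t_off = t_off, T = T, f_inst = 1000 / T,
       f_unit = s * 1000 / T, mu_min_next = mu_min_next)
}

# downstroke quadrature: integrand uses the same trajectory conventions as
# the closed constant-drive form (single-K term linearised, K^2 term
# exponential-completed-square then linearised) so that m = 0 reproduces
# gd_mu_min() to trapezoid accuracy
gd_mu_min_next <- function(I_hat, m, mu_max, p, n_panels = 200) {
  beta <- I_hat - mu_max
  e1 <- exp(p$delta / p$tau_m)
  e2 <- exp(2 * p$delta / p$tau_m)
  s <- gd_saturation(mu_max, p)
  mu_reset <- gd_mu_reset(mu_max, s, p)
  bp <- p$V_T - I_hat
  cc <- bp^2 * (1 - e1)^2 / (e2 + 1)
  Aco <- beta * sqrt(1 + e2)
  Bco <- bp * (e1 + 1) / sqrt(1 + e2)
  tt <- seq(0, p$delta, length.out = n_panels + 1)
  x <- p$delta - tt                       # lag of the more recent density
  p1 <- exp(-(p$V_T - mu_max + beta * x / p$tau_m)^2 / (2 * p$D)) /
    sqrt(2 * pi * p$D)
  q <- 1 + x / p$tau_m
  P2 <- exp(-(cc + (Aco * q + Bco)^2) / (2 * p$D)) / (2 * pi * p$D)
  I_stat <- I_hat - p$K * p1 * beta * exp(x / p$tau_m) +
    p$K^2 * P2 * beta * exp((x + p$delta) / p$tau_m)
  I_m <- m * (tt + p$K * p1 * x - p$K^2 * P2 * (x + p$delta))
  v <- (I_stat + I_m) * exp(-(p$delta - tt) / p$tau_m) / p$tau_m
  h <- p$delta / n_panels               # composite Simpson (n_panels even)
  w <- c(1, rep(c(4, 2), length.out = n_panels - 1), 1)
  mu_reset * exp(-p$delta / p$tau_m) + sum(w * v) * h / 3
}

# one cycle with self-consistent reference drive: I_hat = d_start + m t_off
run_chain_cycle <- function(d_start, mu_min, m, p, tol = 1e-6,
                            max_iter = 100) {
  t_off <- 2.5
  cyc <- NULL
  for (i in seq_len(max_iter)) {
    I_hat <- d_start + m * t_off
    cyc <- tryCatch(gd_cycle_map(I_hat, mu_min, m, p),
                    ripplenet_no_oscillation = function(e) NULL,
                    ripplenet_no_transient = function(e) NULL)
    if (is.null(cyc)) return(NULL)
    if (abs(cyc$t_off - t_off) < tol) return(cyc)
    t_off <- cyc$t_off
  }
  stop(sprintf("cycle fixed-point iteration did not converge (d_start = %g)",
               d_start))
}

# forward chain at slope m from start drive d0 and entry state mu0,
# stopping at the drive level d_stop or when cycles become invalid
chain_forward <- function(m, d0, mu0, d_stop, p, sub_bound, max_cycles = 100) {
  rows <- list()
  t <- 0; d <- d0; mu <- mu0
  for (i in seq_len(max_cycles)) {
    if (!is.finite(mu) || mu > sub_bound) break
    cyc <- run_chain_cycle(d, mu, m, p)
    if (is.null(cyc)) break
    rows[[i]] <- data.frame(
      idx = i, t0 = t, t1 = t + cyc$T, t_off_abs = t + cyc$t_off,
      d_start = d, I_hat = cyc$I_hat, mu_min = cyc$mu_min,
      mu_max = cyc$mu_max, s = cyc$s, t_off = cyc$t_off,
      f_inst = cyc$f_inst, f_unit = cyc$f_unit,
      mu_min_next = cyc$mu_min_next)
    t <- t + cyc$T
    d <- cyc$I_hat + m * p$delta
    mu <- cyc$mu_min_next
    if ((m > 0 && d >= d_stop - 1e-9) || (m < 0 && d <= d_stop + 1e-9))
      break
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Chain transient cycles over a sharp wave-like double-ramp drive
#'
#' Builds the theoretical trajectory of consecutive oscillation cycles under
#' the symmetric double-ramp drive. The rising-ramp chain starts at the
#' lowest applicable drive (entry state: the asymptotic cycle minimum of the
#' start drive, expressing the hysteresis of the pre-event state) and its
#' start drive is tuned, within one cycle of the earliest entry, so that the
#' last cycle's end aligns as closely as the discrete cycle family permits
#' with the moment the drive reaches the plateau. The falling-ramp chain
#' starts from the asymptotic plateau state and runs until no further valid
#' cycle exists. Cycle times are reported on the drive's absolute time axis
#' (plateau included); a cycle is flagged `has_ref = FALSE` when the drive
#' leaves the constant-drive theory's applicability range at any point
#' during the cycle, in which case no asymptotic reference frequency exists
#' for it.
#'
#' @param drive a dimensionless [make_spw_drive()] profile (its `baseline`,
#'   `plateau`, `slope_m`, `t_baseline`, `t_plateau` attributes define the
#'   ramp geometry).
#' @inheritParams gd_mu_max_linear
#' @return an object of class `cycle_chain`: data frame with one row per
#'   cycle (`phase` = `"up"`/`"down"`, times `t0`, `t1`, `t_mid`, reference
#'   drive `I_hat`, extrema, `f_inst`, `f_ref` (asymptotic reference, NA
#'   when absent), `has_ref`), with the chain metadata in attributes.
#' @examples
#' \donttest{
#' p <- dimensionless_params()
#' d <- make_spw_drive(0.74, 8.9, 0.4)
#' ch <- gd_chain_cycles(d, p)
#' }
#' @export
gd_chain_cycles <- function(drive, params) {
  p <- as_dimensionless(params)
  base <- attr(drive, "baseline"); plateau <- attr(drive, "plateau")
  m <- attr(drive, "slope_m"); t_base <- attr(drive, "t_baseline")
  t_plat <- attr(drive, "t_plateau")
  if (is.null(base) || is.null(plateau) || is.null(m))
    stop("drive must be a sharp wave profile from make_spw_drive()")
  sub_bound <- p$V_T - 3 * sqrt(p$D)
  rng <- gd_applicability_range(p)
  t_ramp <- (plateau - base) / m
  entry <- function(d1) {
    mu <- tryCatch(gd_mu_min(d1, p, with_reset = TRUE),
                   ripplenet_no_oscillation = function(e) NA_real_)
    if (!is.finite(mu) || mu > sub_bound) NA_real_ else mu
  }
  up_chain <- function(d1) {
    mu1 <- entry(d1)
    if (is.na(mu1)) return(NULL)
    chain_forward(m, d1, mu1, plateau, p, sub_bound)
  }
  resid <- function(d1) {
    ch <- up_chain(d1)
    if (is.null(ch)) return(NA_real_)
    (d1 - base) / m + ch$t1[nrow(ch)] - t_ramp
  }
  d_lo <- max(rng$IE_min, gd_existence_bounds(p)$IE_lower) + 0.01
  ch0 <- up_chain(d_lo)
  if (is.null(ch0)) stop("no valid rising-ramp cycle found")
  span <- m * (ch0$t1[1] - ch0$t0[1])
  d1s <- seq(d_lo, d_lo + span, length.out = 50)
  rs <- vapply(d1s, resid, 0)
  d1 <- d1s[which.min(abs(rs))]
  up <- up_chain(d1)
  up$phase <- "up"
  up_shift <- t_base + (d1 - base) / m
  for (col in c("t0", "t1", "t_off_abs")) up[[col]] <- up[[col]] + up_shift
  dn <- chain_forward(-m, plateau, gd_mu_min(plateau, p, TRUE), base, p,
                      sub_bound)
  if (!is.null(dn)) {
    dn$phase <- "down"
    dn_shift <- t_base + t_ramp + t_plat
    for (col in c("t0", "t1", "t_off_abs")) dn[[col]] <- dn[[col]] + dn_shift
  }
  ch <- rbind(up, dn)
  ch$t_mid <- (ch$t0 + ch$t1) / 2
  # drive range covered by each cycle; the asymptotic reference exists only
  # if the whole cycle stays inside the applicability range
  slope <- ifelse(ch$phase == "up", m, -m)
  d_min_cycle <- pmin(ch$d_start, ch$I_hat + slope * p$delta)
  ch$has_ref <- d_min_cycle >= rng$IE_min &
    pmax(ch$d_start, ch$I_hat + slope * p$delta) <= rng$IE_max + 1e-9
  ch$f_ref <- NA_real_
  ok <- ch$has_ref
  ch$f_ref[ok] <- vapply(ch$I_hat[ok], function(IE)
    gd_constant_solution(IE, p, TRUE)$f_net, 0)
  rownames(ch) <- NULL
  structure(ch, class = c("cycle_chain", "data.frame"),
            params = p, d1 = d1, align_residual = rs[which.min(abs(rs))],
            baseline = base, plateau = plateau, slope_m = m,
            t_baseline = t_base, t_plateau = t_plat)
}

#' Theoretical IFA slope from a cycle chain
#'
#' Ordinary least-squares regression of the chained instantaneous
#' frequencies on their cycle times, pooling the rising- and falling-ramp
#' cycles (the plateau contributes no cycles; its duration separates the two
#' chains on the time axis). Cycles without an asymptotic reference
#' (`has_ref = FALSE`) are excluded: outside the applicability range the
#' comparison of instantaneous and asymptotic dynamics that defines IFA is
#' not available.
#'
#' @param chain a `cycle_chain`, or a [make_spw_drive()] profile (the chain
#'   is then built first).
#' @inheritParams gd_mu_max_linear
#' @return an `ifa_fit` (see [ifa_slope()]) with the chain attached as
#'   attribute `chain`.
#' @export
gd_ifa_theory <- function(chain, params = NULL) {
  if (inherits(chain, "drive_profile")) {
    stopifnot(!is.null(params))
    chain <- gd_chain_cycles(chain, params)
  }
  pts <- data.frame(t = chain$t_mid[chain$has_ref],
                    f = chain$f_inst[chain$has_ref])
  fit <- ifa_slope(pts)
  attr(fit, "chain") <- chain
  fit
}

#' Mean relative error between theoretical and simulated instantaneous
#' frequencies
#'
#' For every chained theory cycle, the simulated instantaneous frequencies
#' within `window` ms of the cycle time are averaged; the score is the mean
#' relative deviation of the theory from these local simulation averages,
#' over cycles with at least one simulation point in the window.
#'
#' @param chain a `cycle_chain` (times on the drive's absolute axis).
#' @param series an `inst_freq_series` or list of them, from simulations of
#'   the same drive.
#' @param window half-width of the matching window, ms (default 1.5).
#' @return the mean relative error (dimensionless fraction).
#' @export
theory_sim_error <- function(chain, series, window = 1.5) {
  if (is.data.frame(series)) series <- list(series)
  pts <- do.call(rbind, lapply(series, function(s)
    as.data.frame(s)[s$valid, c("t", "f")]))
  errs <- vapply(seq_len(nrow(chain)), function(i) {
    sel <- abs(pts$t - chain$t_mid[i]) <= window
    if (!any(sel)) return(NA_real_)
    f_sim <- mean(pts$f[sel])
    abs(chain$f_inst[i] - f_sim) / f_sim
  }, 0)
  errs <- errs[!is.na(errs)]
  if (!length(errs)) stop("no overlap between theory cycles and simulation points")
  mean(errs)
}
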