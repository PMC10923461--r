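# Closed-form Gaussian-drift cycle theory for constant drive: local extrema
# of the mean membrane potential, saturation, population reset, rise time,
# network and unit frequencies, applicability range and performance scores.
#
# The oscillation cycle is split into an upstroke of duration t_off during
# which the mean relaxes from mu_min towards the drive until the delayed
# inhibition stops it at mu_max, and a downstroke of exactly one delay during
# which the residual inhibition pushes the mean back down to mu_min. The
# period is T = t_off + delta and f_net = 1/T.

# log of the coupling-vs-noise ratio entering mu_max; existence of the
# oscillatory solution requires it to be non-negative
log_coupling_ratio <- function(p) {
  log(p$K * exp(p$delta / p$tau_m) / sqrt(2 * pi * p$D))
}

no_oscillation <- function(reason) {
  structure(class = c("ripplenet_no_oscillation", "error", "condition"),
            list(message = reason, call = NULL))
}

#' Oscillation-existence bounds of the constant-drive theory
#'
#' The closed form for the cycle peak exists only for sufficiently strong
#' coupling, \eqn{K \ge \sqrt{2\pi D} e^{-\Delta/\tau_m}}, and sufficiently
#' strong drive,
#' \eqn{I_E \ge V_T - \sqrt{2 D \ln[K e^{\Delta/\tau_m}/\sqrt{2\pi D}]}};
#' below the drive bound the mean settles into its fixed point and no
#' oscillation occurs. The drive bound is the analytical estimate of the DDE
#' bifurcation.
#'
#' @param params a `dimensionless_params` (or physical, converted).
#' @return list with `K_min` and `IE_lower`.
#' @examples
#' gd_existence_bounds(dimensionless_params())$IE_lower  # ~0.56
#' @export
gd_existence_bounds <- function(params) {
  p <- as_dimensionless(params)
  lcr <- log_coupling_ratio(p)
  list(K_min = sqrt(2 * pi * p$D) * exp(-p$delta / p$tau_m),
       IE_lower = if (lcr >= 0) p$V_T - sqrt(2 * p$D * lcr) else NA_real_)
}

#' Cycle peak of the mean membrane potential
#'
#' Closed form for the local maximum reached at the end of the population
#' spike,
#' \deqn{\mu_{max} = I_E - e^{-\Delta/\tau_m}\bigl[I_E - V_T +
#'   \sqrt{2D\ln(K e^{\Delta/\tau_m}/\sqrt{2\pi D})}\bigr].}
#' The peak is independent of the cycle's starting value `mu_min`: it is set
#' entirely by the feedback inhibition generated in the last two delay
#' windows of the upstroke.
#'
#' @inheritParams gd_existence_bounds
#' @param I_E constant dimensionless drive.
#' @return `mu_max` (`< I_E`). Signals a classed error
#'   (`ripplenet_no_oscillation`) naming the violated bound when the
#'   existence conditions fail.
#' @export
gd_mu_max <- function(I_E, params) {
  p <- as_dimensionless(params)
  lcr <- log_coupling_ratio(p)
  if (lcr < 0)
    stop(no_oscillation(sprintf(
      "coupling too weak for oscillations: K = %g < sqrt(2 pi D) exp(-delta/tau_m) = %g",
      p$K, sqrt(2 * pi * p$D) * exp(-p$delta / p$tau_m))))
  IE_lower <- p$V_T - sqrt(2 * p$D * lcr)
  if (I_E < IE_lower)
    stop(no_oscillation(sprintf(
      "drive below oscillation onset: I_E = %g < %g; mean settles at the fixed point",
      I_E, IE_lower)))
  I_E - exp(-p$delta / p$tau_m) * (I_E - p$V_T + sqrt(2 * p$D * lcr))
}

#' Saturation from the cycle peak
#'
#' The suprathreshold mass of the Gaussian density at the end of the
#' population spike -- the fraction of units that fired in the cycle:
#' \eqn{s = (1 - \mathrm{erf}[(V_T - \mu_{max})/\sqrt{2D}])/2}.
#'
#' @param mu_max cycle peak of the mean membrane potential.
#' @inheritParams gd_existence_bounds
#' @return saturation in (0, 1), monotone increasing in `mu_max`.
#' @export
gd_saturation <- function(mu_max, params) {
  p <- as_dimensionless(params)
  0.5 * (1 - erf((p$V_T - mu_max) / sqrt(2 * p$D)))
}

#' Population reset level
#'
#' Resetting the suprathreshold (fired) portion of the Gaussian by
#' `V_T - V_R` and re-averaging gives the post-spike mean
#' \eqn{\mu_{reset} = \mu_{max} - (V_T - V_R) s}.
#'
#' @inheritParams gd_saturation
#' @param s saturation of the cycle.
#' @return `mu_reset <= mu_max`, with equality iff `s = 0`.
#' @export
gd_mu_reset <- function(mu_max, s, params) {
  p <- as_dimensionless(params)
  mu_max - (p$V_T - p$V_R) * s
}

# shared inhibitory-feedback bracket of the downstroke integral; the single-K
# erf term uses the linearised upstroke trajectory, the K^2 term completes
# the square in the exponential trajectory before linearising (conventions
# chosen to match the closed-form downstroke result exactly)
gd_inhibition_term <- function(I_E, mu_max, p) {
  e1 <- exp(p$delta / p$tau_m)
  e2 <- exp(2 * p$delta / p$tau_m)
  sqD <- sqrt(2 * p$D)
  phi <- function(t)
    (p$V_T - mu_max + (I_E - mu_max) * (p$delta - t) / p$tau_m) / sqD
  cc <- (p$V_T - I_E)^2 * (1 - e1)^2 / (e2 + 1)
  psi <- function(t)
    (-(I_E - mu_max) * (e2 + 1) * (p$tau_m + p$delta - t) +
       p$tau_m * (I_E - p$V_T) * (e1 + 1)) /
    (sqrt(2 * p$D * (e2 + 1)) * p$tau_m)
  0.5 * p$K * ((erf(phi(0)) - erf(phi(p$delta))) -
    p$K / sqrt(2 * pi * p$D) * exp(-cc / (2 * p$D)) * e1 / sqrt(e2 + 1) *
      (erf(psi(p$delta)) - erf(psi(0))))
}

#' Cycle minimum of the mean membrane potential
#'
#' Integrates the delayed inhibitory feedback over the downstroke (one delay
#' window after the population spike ends) starting from `mu_max` (without
#' reset) or `mu_reset` (with the phenomenological population reset):
#' initial-condition relaxation plus drive charging minus the erf-expressed
#' inhibition integral.
#'
#' @inheritParams gd_mu_max
#' @param with_reset start the downstroke from the population-reset level.
#' @return `mu_min`; the with-reset value is always the lower one.
#' @export
gd_mu_min <- function(I_E, params, with_reset = TRUE) {
  p <- as_dimensionless(params)
  mu_max <- gd_mu_max(I_E, p)
  init <- if (with_reset)
    gd_mu_reset(mu_max, gd_saturation(mu_max, p), p) else mu_max
  edel <- exp(-p$delta / p$tau_m)
  init * edel + I_E * (1 - edel) - gd_inhibition_term(I_E, mu_max, p)
}

#' Upstroke duration
#'
#' Rise time of the mean membrane potential from `mu_min` to `mu_max` under
#' exponential relaxation towards the drive:
#' \eqn{t_{off} = \tau_m \ln[(I_E - \mu_{min})/(I_E - \mu_{max})]}.
#'
#' @param mu_min,mu_max cycle extrema (`mu_min <= mu_max < I_E`).
#' @inheritParams gd_mu_max
#' @return rise time, ms.
#' @export
gd_t_off <- function(mu_min, mu_max, I_E, params) {
  p <- as_dimensionless(params)
  if (!(I_E > mu_max) || mu_min > mu_max)
    stop("ordering violated: need mu_min <= mu_max < I_E")
  p$tau_m * log((I_E - mu_min) / (I_E - mu_max))
}

#' Full constant-drive cycle solution
#'
#' Assembles the closed-form cycle: `mu_max`, saturation, `mu_reset`,
#' `mu_min`, `t_off`, period `T = t_off + delta`, network frequency
#' `f_net = 1000/T` Hz and unit rate `f_unit = s f_net`.
#'
#' @inheritParams gd_mu_min
#' @return an object of class `cycle_solution` (also a one-row data frame
#'   via [as.data.frame()]): list with fields `I_E`, `mu_max`, `s`,
#'   `mu_reset`, `mu_min`, `t_off`, `T`, `f_net`, `f_unit`, `with_reset`,
#'   `valid`, `reason`.
#' @examples
#' gd_constant_solution(3.6, dimensionless_params())$f_net        # ~290.3
#' gd_constant_solution(3.6, dimensionless_params(), TRUE)$f_net  # ~235.8
#' @export
gd_constant_solution <- function(I_E, params, with_reset = TRUE) {
  p <- as_dimensionless(params)
  out <- tryCatch({
    mu_max <- gd_mu_max(I_E, p)
    s <- gd_saturation(mu_max, p)
    mu_reset <- gd_mu_reset(mu_max, s, p)
    mu_min <- gd_mu_min(I_E, p, with_reset)
    t_off <- gd_t_off(mu_min, mu_max, I_E, p)
    T <- t_off + p$delta
    list(I_E = I_E, mu_max = mu_max, s = s, mu_reset = mu_reset,
         mu_min = mu_min, t_off = t_off, T = T, f_net = 1000 / T,
         f_unit = s * 1000 / T, with_reset = with_reset, valid = TRUE,
         reason = NA_character_)
  }, ripplenet_no_oscillation = function(e) {
    list(I_E = I_E, mu_max = NA_real_, s = NA_real_, mu_reset = NA_real_,
         mu_min = NA_real_, t_off = NA_real_, T = NA_real_,
         f_net = NA_real_, f_unit = NA_real_, with_reset = with_reset,
         valid = FALSE, reason = conditionMessage(e))
  })
  class(out) <- "cycle_solution"
  out
}

#' @export
print.cycle_solution <- function(x, ...) {
  if (!x$valid) {
    cat("No oscillatory solution:", x$reason, "\n")
  } else {
    cat(sprintf(
      "Cycle at I_E = %g (%s reset): f_net = %.1f Hz, s = %.3f, T = %.3f ms\n",
      x$I_E, if (x$with_reset) "with" else "without", x$f_net, x$s, x$T))
    cat(sprintf("  mu_min = %.3f, mu_max = %.3f, mu_reset = %.3f, t_off = %.3f ms\n",
                x$mu_min, x$mu_max, x$mu_reset, x$t_off))
  }
  invisible(x)
}

#' @export
as.data.frame.cycle_solution <- function(x, ...) {
  as.data.frame(unclass(x)[c("I_E", "mu_max", "s", "mu_reset", "mu_min",
                             "t_off", "T", "f_net", "f_unit", "valid")])
}

#' Closed-form drive at full synchrony
#'
#' Drive level at which (approximate) full synchrony is reached, defined by
#' the cycle peak clearing threshold by three standard deviations
#' (`s = 0.9987`):
#' \deqn{I_E^{full} = V_T + \sqrt{D}\,\frac{3 +
#'   e^{-\Delta/\tau_m}\sqrt{2\ln(K e^{\Delta/\tau_m}/\sqrt{2\pi D})}}
#'   {1 - e^{-\Delta/\tau_m}}.}
#' The closed form slightly overestimates the simulated point of full
#' synchrony but shares its parameter dependencies (stronger coupling or
#' noise require stronger drive).
#'
#' @inheritParams gd_existence_bounds
#' @return `I_E^full` (dimensionless).
#' @export
gd_full_synchrony_drive <- function(params) {
  p <- as_dimensionless(params)
  lcr <- log_coupling_ratio(p)
  if (lcr < 0)
    stop(no_oscillation("coupling too weak for oscillations"))
  edel <- exp(-p$delta / p$tau_m)
  p$V_T + sqrt(p$D) * (3 + edel * sqrt(2 * lcr)) / (1 - edel)
}

#' Applicability range of the constant-drive theory
#'
#' The drift-based theory applies where (a) units spike at most once per
#' cycle (`I_E <= I_E^full`) and (b) the Gaussian is sufficiently
#' subthreshold between population spikes
#' (`mu_min(I_E) + 3 sqrt(D) <= V_T`). The lower edge `IE_min` is found by
#' root-finding constraint (b) on the closed form; the upper edge is
#' `I_E^full` unless (b) also binds from above (extreme high-noise,
#' weak-coupling corners).
#'
#' @inheritParams gd_mu_min
#' @param tol root-finding tolerance on the drive.
#' @return list with `IE_min`, `IE_max`, `IE_full`, and `limiting`
#'   (constraint tags for the upper edge: `"single_spike"` or
#'   `"subthreshold"`). Empty ranges are flagged with `empty = TRUE`.
#' @examples
#' gd_applicability_range(dimensionless_params())$IE_min  # ~2.84
#' @export
gd_applicability_range <- function(params, with_reset = TRUE, tol = 1e-4) {
  p <- as_dimensionless(params)
  IE_full <- gd_full_synchrony_drive(p)
  lb <- gd_existence_bounds(p)$IE_lower
  g <- function(IE) gd_mu_min(IE, p, with_reset) + 3 * sqrt(p$D) - p$V_T
  lo <- lb + 1e-6
  if (g(IE_full) > 0) {
    return(list(IE_min = NA_real_, IE_max = NA_real_, IE_full = IE_full,
                limiting = NA_character_, empty = TRUE))
  }
  IE_min <- if (g(lo) <= 0) lo else
    uniroot(g, c(lo, IE_full), tol = tol)$root
  # constraint (b) from above: scan for a reascent of mu_min below IE_full
  grid <- seq(IE_min, IE_full, length.out = 50)
  gv <- vapply(grid, g, 0)
  reascent <- which(gv > 1e-8 & seq_along(gv) > 2)
  if (length(reascent)) {
    i <- reascent[1]
    IE_max <- uniroot(g, c(grid[i - 1], grid[i]), tol = tol)$root
    limiting <- "subthreshold"
  } else {
    IE_max <- IE_full
    limiting <- "single_spike"
  }
  list(IE_min = IE_min, IE_max = IE_max, IE_full = IE_full,
       limiting = limiting, empty = FALSE)
}

#' Theory-vs-simulation performance scores
#'
#' Quantifies how well the cycle theory captures a simulated network
#' frequency curve: `chi_err` is the mean relative frequency error on the
#' grid `IE_min + 0.1 i` restricted to
#' `[IE_min, min(IE_max, IE_full_sim)]`; `chi_appl` is the fraction of the
#' relevant simulated range (bifurcation to full synchrony) covered by the
#' theory; `chi_p = chi_appl (1 - chi_err)`.
#'
#' @param sim_drives,sim_f_net simulated drive levels and network
#'   frequencies (Hz); interpolated onto the evaluation grid.
#' @param IE_crit_sim,IE_full_sim simulated bifurcation and full-synchrony
#'   drives.
#' @inheritParams gd_mu_min
#' @return list with `chi_err`, `chi_appl`, `chi_p`, all in `[0, 1]`.
#' @export
gd_performance_scores <- function(sim_drives, sim_f_net, IE_crit_sim,
                                  IE_full_sim, params, with_reset = TRUE) {
  p <- as_dimensionless(params)
  rng <- gd_applicability_range(p, with_reset)
  if (rng$empty) stop("empty applicability range")
  hi <- min(rng$IE_max, IE_full_sim)
  grid <- seq(rng$IE_min, hi, by = 0.1)
  if (!length(grid)) stop("empty evaluation grid")
  f_sim <- approx(sim_drives, sim_f_net, grid, rule = 2)$y
  f_th <- vapply(grid, function(IE)
    gd_constant_solution(IE, p, with_reset)$f_net, 0)
  chi_err <- mean(abs(f_sim - f_th) / f_sim)
  chi_appl <- (hi - rng$IE_min) / (IE_full_sim - IE_crit_sim)
  chi_appl <- min(max(chi_appl, 0), 1)
  chi_err <- min(max(chi_err, 0), 1)
  list(chi_err = chi_err, chi_appl = chi_appl,
       chi_p = chi_appl * (1 - chi_err))
}
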