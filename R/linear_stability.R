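# Stationary state of the mean-field network and the Hopf bifurcation of the
# spiking network, via the exact LIF susceptibility under Gaussian white
# noise.

#' Stationary firing rate of an LIF neuron (f-I curve)
#'
#' Siegert-type mean first-passage rate of a leaky integrate-and-fire neuron
#' with constant dimensionless drive `I` and Gaussian white noise of
#' variance `D`:
#' \deqn{f_{LIF}(I) = \Bigl(\tau_m \sqrt\pi
#'   \int_{(I-V_T)/\sqrt{2D}}^{(I-V_R)/\sqrt{2D}} e^{x^2}\mathrm{erfc}(x)\,dx
#'   + \tau_{ref}\Bigr)^{-1}.}
#' The integrand is evaluated through the scaled complementary error
#' function for numerical stability (with an asymptotic-series tail where
#' double-precision `exp(x^2)` would overflow), and integrated adaptively.
#'
#' @param I total dimensionless drive (vectorised).
#' @param params a `dimensionless_params` (or physical, converted);
#'   `tau_ref` defaults to 0.
#' @return firing rate in Hz.
#' @export
lif_rate <- function(I, params) {
  p <- as_dimensionless(params)
  vapply(I, function(Ii) {
    lo <- (Ii - p$V_T) / sqrt(2 * p$D)
    hi <- (Ii - p$V_R) / sqrt(2 * p$D)
    if (lo < -26) return(0)   # erfcx overflows; rate is astronomically small
    val <- integrate(erfcx_safe, lo, hi, rel.tol = 1e-10,
                     stop.on.error = FALSE)
    if (val$message != "OK" && val$message != "roundoff error was detected")
      stop("f-I quadrature failed: ", val$message)
    1000 / (p$tau_m * sqrt(pi) * val$value + p$tau_ref)
  }, 0)
}

#' Self-consistent stationary state of the coupled network
#'
#' In the asynchronous stationary state the total drive is the external
#' drive minus the inhibitory feedback of the stationary rate:
#' `I0 = I_E - K tau_m r0` with `r0 = f_LIF(I0)`. Since the f-I curve is
#' increasing, the fixed point is found by bisection.
#'
#' @param I_E external dimensionless drive.
#' @inheritParams lif_rate
#' @param tol self-consistency tolerance on `I0`.
#' @return an object of class `stationary_state`: list with `r0` (Hz),
#'   `I0`, `I_E`.
#' @export
stationary_state <- function(I_E, params, tol = 1e-8) {
  p <- as_dimensionless(params)
  r_ms <- function(I) lif_rate(I, p) / 1000       # 1/ms
  g <- function(I0) I_E - p$K * p$tau_m * r_ms(I0) - I0
  lo <- I_E - p$K * p$tau_m * r_ms(I_E)           # r0 <= f_LIF(I_E)
  I0 <- if (g(lo) <= 0) lo else uniroot(g, c(lo, I_E), tol = tol)$root
  structure(list(r0 = lif_rate(I0, p), I0 = I0, I_E = I_E),
            class = "stationary_state")
}

#' @export
print.stationary_state <- function(x, ...) {
  cat(sprintf("Stationary state at I_E = %g: r0 = %.2f Hz, I0 = %.4f\n",
              x$I_E, x$r0, x$I0))
  invisible(x)
}

#' LIF susceptibility under Gaussian white noise
#'
#' Linear rate response \eqn{\tilde G(\omega)} of an LIF neuron to a weak
#' periodic modulation of its drive, evaluated with complex-order parabolic
#' cylinder functions \eqn{D_{-i\omega\tau_m-1}, D_{-i\omega\tau_m}} at the
#' standardised distances of the operating point from threshold and reset
#' (the complex conjugate convention, matching a perturbation
#' \eqn{e^{i\omega t}} with physical time in ms).
#'
#' @param omega angular frequency, rad/ms (vectorised).
#' @param state a `stationary_state` giving the operating point.
#' @inheritParams lif_rate
#' @return complex susceptibility in (1/ms) per unit dimensionless drive;
#'   at `omega = 0` it equals the slope of the f-I curve.
#' @export
susceptibility <- function(omega, state, params) {
  p <- as_dimensionless(params)
  stopifnot(inherits(state, "stationary_state"))
  r0 <- state$r0 / 1000                 # 1/ms
  if (r0 <= 0) stop("susceptibility requires a positive stationary rate")
  zT <- (state$I0 - p$V_T) / sqrt(p$D)
  zR <- (state$I0 - p$V_R) / sqrt(p$D)
  delta <- (p$V_R^2 - p$V_T^2 + 2 * state$I0 * (p$V_T - p$V_R)) / (4 * p$D)
  vapply(omega, function(om) {
    iw <- 1i * om * p$tau_m             # dimensionless frequency
    num <- pcf_d(-iw - 1, zT) - exp(delta) * pcf_d(-iw - 1, zR)
    den <- pcf_d(-iw, zT) -
      exp(delta) * exp(-1i * om * p$tau_ref) * pcf_d(-iw, zR)
    (r0 / sqrt(p$D)) * (iw / (iw + 1)) * num / den
  }, complex(1))
}

# signed phase-condition residual, wrapped to (-pi, pi]
hopf_phase_residual <- function(omega, state, p) {
  g <- susceptibility(omega, state, p)
  r <- pi + Arg(g) - omega * p$delta
  ((r + pi) %% (2 * pi)) - pi
}

# solve the phase condition for omega within the scan band; NA if no root
hopf_omega <- function(state, p, f_band, f_step = 2) {
  oms <- 2 * pi * seq(f_band[1], f_band[2], by = f_step) / 1000  # rad/ms
  pr <- vapply(oms, hopf_phase_residual, 0, state = state, p = p)
  sgn <- pr[-1] * pr[-length(pr)]
  cross <- which(sgn < 0 & abs(diff(pr)) < pi)  # skip wrap jumps
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  uniroot(hopf_phase_residual, c(oms[i], oms[i + 1]), state = state, p = p,
          tol = 1e-10)$root
}

#' Hopf bifurcation of the spiking network from linear stability analysis
#'
#' Locates the critical external drive at which the asynchronous stationary
#' state loses stability to a coherent network oscillation, by solving the
#' amplitude and phase conditions
#' \deqn{1 = K\tau_m|\tilde G(\omega)|, \qquad
#'   0 = \pi + \arg\tilde G(\omega) - \omega\Delta}
#' on the LIF susceptibility: for each candidate drive the phase condition
#' is solved for `omega` (grid scan plus bisection over `f_band`), then the
#' drive is bisected on the amplitude condition.
#'
#' @inheritParams lif_rate
#' @param IE_range dimensionless drive interval bracketing the bifurcation.
#' @param f_band frequency scan band, Hz.
#' @param tol bisection tolerance on the drive.
#' @return an object of class `hopf_point`: list with `IE_crit`
#'   (dimensionless), `I_ext_crit` (nA, when a physical scale is available),
#'   `f_net` (Hz), `f_unit` (Hz, the stationary rate at the critical
#'   drive), `s` (saturation at the bifurcation), `omega` (rad/ms).
#' @examples
#' \donttest{
#' hopf_point(physical_params())   # I_ext ~0.19 nA, f_net ~305 Hz
#' }
#' @export
hopf_point <- function(params, IE_range = c(0.8, 2.5),
                       f_band = c(100, 600), tol = 1e-4) {
  p <- as_dimensionless(params)
  amp_res <- function(IE) {
    st <- stationary_state(IE, p)
    om <- hopf_omega(st, p, f_band)
    if (is.na(om)) return(NA_real_)
    p$K * p$tau_m * Mod(susceptibility(om, st, p)) - 1
  }
  lo <- IE_range[1]; hi <- IE_range[2]
  flo <- amp_res(lo); fhi <- amp_res(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("IE_range does not bracket the Hopf bifurcation (or no phase root in f_band)")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- amp_res(mid)
    if (is.na(fm)) stop("phase condition lost a root during bisection")
    if (fm * flo <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  IE_crit <- (lo + hi) / 2
  st <- stationary_state(IE_crit, p)
  om <- hopf_omega(st, p, f_band)
  f_net <- om / (2 * pi) * 1000
  sc <- attr(p, "scale")
  I_ext <- if (inherits(params, "physical_params")) {
    drive_to_physical(IE_crit, params)
  } else if (!is.null(sc)) {
    IE_crit * sc$C * (sc$V_thr - sc$E_leak) / (1000 * p$tau_m)
  } else NA_real_
  structure(list(IE_crit = IE_crit, I_ext_crit = I_ext, f_net = f_net,
                 f_unit = st$r0, s = st$r0 / f_net, omega = om),
            class = "hopf_point")
}

#' @export
print.hopf_point <- function(x, ...) {
  cat(sprintf("Hopf bifurcation: I_E_crit = %.3f%s\n", x$IE_crit,
              if (is.finite(x$I_ext_crit))
                sprintf(" (I_ext = %.3f nA)", x$I_ext_crit) else ""))
  cat(sprintf("  f_net = %.1f Hz, f_unit = %.1f Hz, s = %.3f\n",
              x$f_net, x$f_unit, x$s))
  invisible(x)
}
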