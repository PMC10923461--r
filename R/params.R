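# Parameter sets: physical (experimental units) and dimensionless (voltage in
# units of the rest-to-threshold distance), and the exact conversion between
# them.

#' Physical parameters of the interneuron network
#'
#' Constructs the parameter set of the spiking network in physical units:
#' `N` leaky integrate-and-fire interneurons with membrane time constant
#' `tau_m` (ms), capacitance `C` (pF), resting potential `E_leak` (mV), spike
#' threshold `V_thr` (mV), reset `V_reset` (mV), all-to-all inhibitory pulse
#' coupling of strength `J` (mV) arriving after a synaptic delay `delta` (ms),
#' and Gaussian white background noise whose long-time free membrane-potential
#' standard deviation is `sigma_V` (mV). Defaults are the model's standard
#' parameter set.
#'
#' @param N number of interneurons.
#' @param tau_m membrane time constant, ms.
#' @param C membrane capacitance, pF.
#' @param E_leak resting potential, mV.
#' @param V_thr spike threshold, mV.
#' @param V_reset reset potential, mV.
#' @param J inhibitory coupling strength, mV.
#' @param delta synaptic delay, ms.
#' @param sigma_V noise strength (SD of the free membrane potential), mV.
#' @return an object of class `physical_params`.
#' @seealso [to_dimensionless()], [drive_to_dimensionless()]
#' @examples
#' p <- physical_params()
#' to_dimensionless(p)$K   # 5
#' @export
physical_params <- function(N = 10000L, tau_m = 10, C = 100, E_leak = -65,
                            V_thr = -52, V_reset = -65, J = 65, delta = 1.2,
                            sigma_V = 2.62) {
  stopifnot(N >= 1, tau_m > 0, C > 0, delta > 0, sigma_V >= 0,
            V_reset <= V_thr)
  p <- list(N = as.integer(N), tau_m = tau_m, C = C, E_leak = E_leak,
            V_thr = V_thr, V_reset = V_reset, J = J, delta = delta,
            sigma_V = sigma_V)
  class(p) <- c("physical_params", "ripple_params")
  p
}

#' Dimensionless parameters of the interneuron network
#'
#' Parameter set after rescaling voltage to units of the rest-to-threshold
#' distance: threshold `V_T = 1`, rescaled reset `V_R`, coupling `K`, and
#' noise variance `D`. Times (`tau_m`, `delta`) stay in ms. The defaults are
#' the standard dimensionless set (`K = 5`, `D = 0.04`, `V_R = 0`); note that
#' converting the physical defaults yields the unrounded
#' `D = (2.62/13)^2 = 0.0406`, both representations being in common use.
#'
#' @param V_R dimensionless reset potential (`< 1`).
#' @param K dimensionless inhibitory coupling strength (`>= 0`).
#' @param D dimensionless noise variance (`> 0`).
#' @param tau_m membrane time constant, ms.
#' @param delta synaptic delay, ms.
#' @param N number of interneurons.
#' @param tau_ref absolute refractory period, ms. The network model has none;
#'   the parameter exists only because the stationary f-I curve
#'   ([lif_rate()]) carries a refractory term. Default 0.
#' @return an object of class `dimensionless_params` with fixed `V_T = 1`.
#' @export
dimensionless_params <- function(V_R = 0, K = 5, D = 0.04, tau_m = 10,
                                 delta = 1.2, N = 10000L, tau_ref = 0) {
  stopifnot(K >= 0, D > 0, V_R < 1, tau_m > 0, delta > 0, N >= 1,
            tau_ref >= 0)
  p <- list(V_T = 1, V_R = V_R, K = K, D = D, tau_m = tau_m, delta = delta,
            N = as.integer(N), tau_ref = tau_ref)
  class(p) <- c("dimensionless_params", "ripple_params")
  p
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Physical network parameters:\n")
  cat(sprintf("  N = %d, tau_m = %g ms, C = %g pF\n", x$N, x$tau_m, x$C))
  cat(sprintf("  E_leak = %g mV, V_thr = %g mV, V_reset = %g mV\n",
              x$E_leak, x$V_thr, x$V_reset))
  cat(sprintf("  J = %g mV, delta = %g ms, sigma_V = %g mV\n",
              x$J, x$delta, x$sigma_V))
  invisible(x)
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat("Dimensionless network parameters:\n")
  cat(sprintf("  V_T = 1, V_R = %g, K = %g, D = %g\n", x$V_R, x$K, x$D))
  cat(sprintf("  tau_m = %g ms, delta = %g ms, N = %d, tau_ref = %g ms\n",
              x$tau_m, x$delta, x$N, x$tau_ref))
  invisible(x)
}

#' Convert between physical and dimensionless parameter sets
#'
#' `to_dimensionless()` rescales voltages by the rest-to-threshold distance
#' `V_thr - E_leak`: `V_R = (V_reset - E_leak)/(V_thr - E_leak)`,
#' `K = J/(V_thr - E_leak)`, `D = (sigma_V/(V_thr - E_leak))^2`.
#' `to_physical()` inverts the map using the scale anchors stored on the
#' dimensionless object (or supplied explicitly).
#'
#' @param p a `physical_params` object.
#' @return `to_dimensionless()`: a `dimensionless_params` object carrying the
#'   scale anchors (`E_leak`, `V_thr`, `C`) as attributes for the inverse map.
#' @export
to_dimensionless <- function(p) {
  stopifnot(inherits(p, "physical_params"))
  dV <- p$V_thr - p$E_leak
  if (dV <= 0) stop("degenerate voltage scale: V_thr must exceed E_leak")
  dp <- dimensionless_params(
    V_R = (p$V_reset - p$E_leak) / dV,
    K = p$J / dV,
    D = (p$sigma_V / dV)^2,
    tau_m = p$tau_m, delta = p$delta, N = p$N)
  attr(dp, "scale") <- list(E_leak = p$E_leak, V_thr = p$V_thr, C = p$C)
  dp
}

#' @rdname to_dimensionless
#' @param dp a `dimensionless_params` object.
#' @param E_leak,V_thr,C scale anchors; taken from `attr(dp, "scale")` when
#'   missing.
#' @export
to_physical <- function(dp, E_leak = NULL, V_thr = NULL, C = NULL) {
  stopifnot(inherits(dp, "dimensionless_params"))
  sc <- attr(dp, "scale")
  if (is.null(E_leak)) E_leak <- sc$E_leak
  if (is.null(V_thr)) V_thr <- sc$V_thr
  if (is.null(C)) C <- sc$C
  if (is.null(E_leak) || is.null(V_thr) || is.null(C))
    stop("scale anchors (E_leak, V_thr, C) required to recover physical units")
  dV <- V_thr - E_leak
  physical_params(N = dp$N, tau_m = dp$tau_m, C = C, E_leak = E_leak,
                  V_thr = V_thr, V_reset = E_leak + dp$V_R * dV,
                  J = dp$K * dV, delta = dp$delta,
                  sigma_V = sqrt(dp$D) * dV)
}

#' Convert an external drive between nA and dimensionless units
#'
#' The rescaled external drive is
#' \eqn{I_E = \tau_m I_{ext} / (C (V_{thr} - E_{leak}))}, i.e. the steady-state
#' depolarisation the current would cause, in rest-to-threshold units. With
#' `I_ext` in nA, `tau_m` in ms, `C` in pF and voltages in mV the conversion
#' factor is `1000 * tau_m / (C * (V_thr - E_leak))`.
#'
#' @param I_ext external drive, nA (vectorised).
#' @param p a `physical_params` object supplying the scale.
#' @return dimensionless drive.
#' @examples
#' drive_to_dimensionless(0.19, physical_params())  # ~1.46
#' @export
drive_to_dimensionless <- function(I_ext, p) {
  stopifnot(inherits(p, "physical_params"))
  1000 * p$tau_m * I_ext / (p$C * (p$V_thr - p$E_leak))
}

#' @rdname drive_to_dimensionless
#' @param I_E dimensionless drive (vectorised).
#' @export
drive_to_physical <- function(I_E, p) {
  stopifnot(inherits(p, "physical_params"))
  I_E * p$C * (p$V_thr - p$E_leak) / (1000 * p$tau_m)
}

# coerce any ripple_params to dimensionless, converting if physical
as_dimensionless <- function(params) {
  if (inherits(params, "dimensionless_params")) return(params)
  if (inherits(params, "physical_params")) return(to_dimensionless(params))
  stop("params must be physical_params or dimensionless_params")
}

#' Read and write parameter sets as flat key-value files
#'
#' One `key = value` pair per line; lines starting with `#` are comments.
#' The `kind` key records whether the set is physical or dimensionless.
#'
#' @param p a parameter object.
#' @param path file path.
#' @return `read_params()` returns the reconstructed parameter object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  kind <- if (inherits(p, "physical_params")) "physical" else "dimensionless"
  keys <- setdiff(names(p), "V_T")
  lines <- c(
    "# ripplenet parameter set (times in ms, voltages in mV, C in pF)",
    paste("kind =", kind),
    vapply(keys, function(k) sprintf("%s = %.17g", k, p[[k]]), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  kind <- vals[keys == "kind"]
  args <- as.list(as.numeric(vals[keys != "kind"]))
  names(args) <- keys[keys != "kind"]
  if (identical(kind, "physical")) do.call(physical_params, args)
  else do.call(dimensionless_params, args)
}
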