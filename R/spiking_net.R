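# Spiking-network simulation front end and population-rate utilities.

#' Simulate the delayed-pulse-coupled noisy LIF interneuron network
#'
#' Euler--Maruyama integration of the fully connected inhibitory network.
#' Physical parameter sets and nA drive profiles are converted to
#' dimensionless units on entry, so a single code path serves both forms of
#' the model. A unit crossing threshold at the end of a step emits a spike
#' timestamped at that step and is reset within the same step (the model has
#' no refractory period); each spike is broadcast to all `N` units
#' (self-coupling included) as a voltage decrement `K/N` arriving exactly one
#' synaptic delay later. Initial voltages are uniform on `[V_R, V_T]`.
#'
#' @param params a `physical_params` or `dimensionless_params` object.
#' @param drive a [drive_profile()]; nA profiles require physical `params`.
#' @param duration simulation length, ms; defaults to the drive span.
#' @param dt integration step, ms (default 0.01). The synaptic delay must be
#'   an integer multiple of `dt`; it is rounded with a warning otherwise.
#' @param seed integer seed; recorded in the result.
#' @param record_snapshots record full membrane-potential snapshots (needed
#'   by [average_cycle()]'s voltage histograms).
#' @param snapshot_every snapshot stride, ms.
#' @param sigma_t Gaussian smoothing width for the smoothed rate, ms.
#' @return an object of class `sim_result`: list with `spikes` (data frame
#'   `unit`, `time`), `rate` (data frame `t`, `raw`, `smooth`, in spikes/s),
#'   `mean_v` (per-step population mean potential), `counts` (per-step spike
#'   counts), `dt`, `N`, `seed`, `params`, `drive`, and optional `snapshots`.
#' @examples
#' p <- dimensionless_params(N = 100)
#' sim <- simulate_network(p, constant_drive(4, 300), dt = 0.02, seed = 1)
#' @export
simulate_network <- function(params, drive, duration = NULL, dt = 0.01,
                             seed = 1L, record_snapshots = FALSE,
                             snapshot_every = 1, sigma_t = 0.3) {
  dp <- as_dimensionless(params)
  if (drive$units == "nA") {
    if (!inherits(params, "physical_params"))
      stop("an nA drive profile requires physical parameters")
    drive_d <- drive_as_dimensionless(drive, params)
  } else drive_d <- drive
  if (is.null(duration)) duration <- diff(drive_span(drive_d))
  stopifnot(dt > 0, duration >= dp$delta)
  delay_steps <- dp$delta / dt
  if (abs(delay_steps - round(delay_steps)) > 1e-8)
    warning("synaptic delay rounded to an integer number of steps")
  delay_steps <- as.integer(round(delay_steps))
  n_steps <- as.integer(round(duration / dt))
  t_grid <- (seq_len(n_steps) - 1) * dt + drive_span(drive_d)[1]
  I_E <- eval_drive(drive_d, t_grid)
  set.seed(seed)
  raw <- sim_lif_cpp(dp$N, n_steps, dt, dp$tau_m, dp$K, dp$D, dp$V_R,
                     delay_steps, I_E, record_snapshots,
                     as.integer(max(1, round(snapshot_every / dt))))
  rate_raw <- population_rate(raw$count, dp$N, dt)
  res <- list(
    spikes = data.frame(unit = raw$spike_unit, time = raw$spike_time),
    rate = data.frame(t = t_grid - t_grid[1],
                      raw = rate_raw,
                      smooth = smooth_rate(rate_raw, sigma_t, dt)),
    mean_v = raw$mean_v, counts = raw$count,
    dt = dt, N = dp$N, seed = seed, duration = duration,
    params = dp, drive = drive_d, sigma_t = sigma_t)
  if (record_snapshots) {
    res$snapshots <- raw$snapshots
    res$snapshot_t <- raw$snapshot_steps * dt
  }
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "LIF network simulation: N = %d, %g ms at dt = %g ms, %d spikes, seed %d\n",
    x$N, x$duration, x$dt, nrow(x$spikes), x$seed))
  invisible(x)
}

#' Empirical population rate
#'
#' The population activity is the per-step spike count divided by `N` and the
#' bin width: `r = n_spk / (N dt)`, returned in spikes/s (times in ms).
#' `sum(r) * N * dt / 1000` recovers the total spike count exactly.
#'
#' @param counts integer vector of per-step population spike counts, or a
#'   `sim_result`.
#' @param N population size.
#' @param dt bin width, ms.
#' @return numeric vector of rates, spikes/s.
#' @export
population_rate <- function(counts, N, dt) {
  if (inherits(counts, "sim_result")) {
    N <- counts$N; dt <- counts$dt; counts <- counts$counts
  }
  counts / (N * dt) * 1000
}

#' Gaussian-smoothed population rate
#'
#' Discrete convolution with a normalized Gaussian kernel truncated at
#' `+/- 5 sigma_t`; the kernel sums to one, so away from the edges the total
#' area (spike count) is preserved.
#'
#' @param rate rate time series (spikes/s).
#' @param sigma_t kernel standard deviation, ms.
#' @param dt sample interval, ms.
#' @return smoothed rate, same length.
#' @export
smooth_rate <- function(rate, sigma_t, dt) {
  stopifnot(sigma_t > 0)
  half <- max(1L, ceiling(5 * sigma_t / dt))
  x <- (-half:half) * dt
  k <- exp(-x^2 / (2 * sigma_t^2))
  k <- k / sum(k)
  n <- length(rate)
  padded <- c(rep(rate[1], half), rate, rep(rate[n], half))
  as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + n)]
}

# analytic signal via FFT (Hilbert transform helper)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x - mean(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Average oscillation cycle of a constant-drive simulation
#'
#' Segments the simulation into individual cycles at a fixed phase of the
#' analytic signal (Hilbert transform) of the population mean membrane
#' potential, then averages the population rate, the mean potential, and --
#' when snapshots were recorded -- the membrane-potential histogram over
#' `n_bins` equally spaced samples per cycle.
#'
#' @param sim a `sim_result` from a constant-drive run.
#' @param n_bins samples per cycle (default 21).
#' @param discard initial transient to exclude, ms (default 50).
#' @param v_breaks histogram breaks for voltage snapshots.
#' @return an object of class `cycle_average`: list with `phase_frac` (bin
#'   centres as cycle fraction), `rate`, `mean_v`, `sd_v` (per-bin SD of the
#'   voltage distribution, snapshots required), `v_hist` (bins x breaks
#'   matrix, optional), `n_cycles`.
#' @export
average_cycle <- function(sim, n_bins = 21, discard = 50,
                          v_breaks = seq(-8, 1.5, by = 0.05)) {
  stopifnot(inherits(sim, "sim_result"))
  keep <- sim$rate$t >= discard
  mv <- sim$mean_v[keep]
  t0 <- sim$rate$t[keep]
  ph <- Arg(analytic_signal(mv))
  # cycle boundaries: upward crossings of phase -pi (wrap points)
  wraps <- which(diff(ph) < -pi)
  if (length(wraps) < 11) stop("fewer than 10 complete cycles")
  rate <- sim$rate$raw[keep]
  acc_r <- matrix(0, length(wraps) - 1, n_bins)
  acc_v <- matrix(0, length(wraps) - 1, n_bins)
  for (i in seq_len(length(wraps) - 1)) {
    idx <- wraps[i]:(wraps[i + 1] - 1)
    pos <- seq(idx[1], idx[length(idx)], length.out = n_bins)
    acc_r[i, ] <- approx(idx, rate[idx], pos)$y
    acc_v[i, ] <- approx(idx, mv[idx], pos)$y
  }
  out <- list(phase_frac = (seq_len(n_bins) - 0.5) / n_bins,
              rate = colMeans(acc_r), mean_v = colMeans(acc_v),
              n_cycles = length(wraps) - 1)
  if (!is.null(sim$snapshots)) {
    snap_t <- sim$snapshot_t
    ok <- snap_t >= discard
    st <- snap_t[ok]
    sv <- sim$snapshots[, ok, drop = FALSE]
    # assign each snapshot to a cycle-phase bin
    bounds <- t0[wraps]
    ci <- findInterval(st, bounds)
    valid <- ci >= 1 & ci < length(bounds)
    frac <- (st[valid] - bounds[ci[valid]]) /
      (bounds[ci[valid] + 1] - bounds[ci[valid]])
    bin <- pmin(pmax(ceiling(frac * n_bins), 1), n_bins)
    sd_v <- rep(NA_real_, n_bins)
    hist_m <- matrix(NA_real_, n_bins, length(v_breaks) - 1)
    for (b in seq_len(n_bins)) {
      cols <- which(valid)[bin == b]
      if (!length(cols)) next
      vals <- as.numeric(sv[, cols])
      sd_v[b] <- sd(vals)
      hist_m[b, ] <- hist(pmin(pmax(vals, v_breaks[1]),
                               v_breaks[length(v_breaks)]),
                          breaks = v_breaks, plot = FALSE)$density
    }
    out$sd_v <- sd_v
    out$v_hist <- hist_m
    out$v_breaks <- v_breaks
  }
  class(out) <- "cycle_average"
  out
}

#' Write a spike raster and rates as columnar text
#'
#' @param sim a `sim_result`.
#' @param dir output directory.
#' @param stem file-name stem.
#' @return the directory, invisibly. Writes `<stem>_spikes.tsv`
#'   (`unit`, `t_ms`), `<stem>_rate.tsv` (`t_ms`, `rate_hz`,
#'   `rate_smooth_hz`) and a JSON sidecar with run metadata.
#' @export
write_sim_result <- function(sim, dir, stem = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(sim$spikes, file.path(dir, paste0(stem, "_spikes.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  rt <- data.frame(t_ms = sim$rate$t, rate_hz = sim$rate$raw,
                   rate_smooth_hz = sim$rate$smooth)
  write.table(rt, file.path(dir, paste0(stem, "_rate.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(N = sim$N, dt = sim$dt, seed = sim$seed,
               duration = sim$duration,
               params = unclass(sim$params)[c("V_R", "K", "D", "tau_m",
                                              "delta")],
               n_spikes = nrow(sim$spikes))
  jsonlite::write_json(meta, file.path(dir, paste0(stem, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
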