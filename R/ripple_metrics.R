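# Ripple quantification: network frequency, unit statistics, saturation,
# instantaneous-frequency estimators, and the IFA slope.

#' Network frequency from the power spectral density
#'
#' The asymptotic network frequency under constant drive is the location of
#' the dominant peak in a Welch-averaged power spectral density of the
#' population rate (DC excluded). A flat spectrum -- dominant peak not
#' standing out above the spectral background -- is flagged invalid.
#'
#' @param rate population-rate time series (spikes/s), or a `sim_result`.
#' @param dt sample interval, ms (taken from the `sim_result` if given).
#' @param discard initial transient to exclude, ms.
#' @param segment_length Welch segment length, ms.
#' @param f_range frequency search band, Hz.
#' @param peak_snr minimum ratio of peak power to the median in-band power
#'   for the estimate to be considered valid.
#' @return list with `f_net` (Hz), `valid`, `power`, and the averaged `psd`
#'   data frame (`f`, `power`).
#' @export
network_frequency_psd <- function(rate, dt = NULL, discard = 50,
                                  segment_length = 500,
                                  f_range = c(30, 1000), peak_snr = 5) {
  if (inherits(rate, "sim_result")) {
    dt <- rate$dt
    rate <- rate$rate$raw
  }
  stopifnot(!is.null(dt))
  k <- min(round(discard / dt), length(rate) - 1)
  if (k > 0) rate <- rate[-seq_len(k)]
  nseg <- max(1L, floor(length(rate) / round(segment_length / dt)))
  seglen <- floor(length(rate) / nseg)
  fs <- 1000 / dt                      # Hz
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seglen) / (seglen + 1)))  # Hann
  acc <- NULL
  for (i in seq_len(nseg)) {
    x <- rate[((i - 1) * seglen + 1):(i * seglen)]
    x <- (x - mean(x)) * win
    P <- Mod(fft(x))^2 / seglen
    half <- seq_len(floor(seglen / 2))
    acc <- if (is.null(acc)) P[half] else acc + P[half]
  }
  acc <- acc / nseg
  f <- (seq_along(acc) - 1) * fs / seglen
  inband <- f >= f_range[1] & f <= f_range[2]
  psd <- data.frame(f = f[inband], power = acc[inband])
  ipk <- which.max(psd$power)
  valid <- psd$power[ipk] > peak_snr * median(psd$power)
  list(f_net = if (valid) psd$f[ipk] else NA_real_,
       valid = valid, power = psd$power[ipk], psd = psd)
}

#' Single-unit firing statistics
#'
#' Mean unit firing rate (spikes per unit per second) and the coefficient of
#' variation of interspike intervals, computed per unit over its own ISIs and
#' averaged across units with at least two ISIs.
#'
#' @param spikes data frame with columns `unit` and `time` (ms), or a
#'   `sim_result`.
#' @param duration analysed duration, ms.
#' @param N number of units.
#' @param discard initial transient to exclude, ms.
#' @return list with `f_unit` (Hz), `cv_isi`, `n_units_cv`.
#' @export
unit_stats <- function(spikes, duration = NULL, N = NULL, discard = 50) {
  if (inherits(spikes, "sim_result")) {
    duration <- spikes$duration
    N <- spikes$N
    spikes <- spikes$spikes
  }
  stopifnot(!is.null(duration), !is.null(N))
  spikes <- spikes[spikes$time >= discard, , drop = FALSE]
  dur <- duration - discard
  f_unit <- nrow(spikes) / N / dur * 1000
  cvs <- vapply(split(spikes$time, spikes$unit), function(tt) {
    if (length(tt) < 3) return(NA_real_)
    isi <- diff(sort(tt))
    sd(isi) / mean(isi)
  }, 0)
  cvs <- cvs[!is.na(cvs)]
  list(f_unit = f_unit,
       cv_isi = if (length(cvs)) mean(cvs) else NA_real_,
       n_units_cv = length(cvs))
}

#' Saturation: fraction of units firing per population cycle
#'
#' @param f_unit mean unit firing rate, Hz.
#' @param f_net network oscillation frequency, Hz (`> 0`).
#' @return `f_unit / f_net`.
#' @export
saturation <- function(f_unit, f_net) {
  stopifnot(all(f_net > 0))
  f_unit / f_net
}

#' Drive level of full synchrony from a simulated saturation curve
#'
#' Linear interpolation of the saturation curve to `s = 1`. If the lowest
#' drive already saturates, that drive is returned; if the curve never
#' reaches 1, the call is rejected.
#'
#' @param drives drive levels (any consistent units), increasing.
#' @param saturations saturation values at `drives`.
#' @return interpolated drive level with `s = 1`.
#' @export
full_synchrony_point <- function(drives, saturations) {
  stopifnot(length(drives) == length(saturations), length(drives) >= 1)
  o <- order(drives)
  drives <- drives[o]; saturations <- saturations[o]
  if (saturations[1] >= 1) return(drives[1])
  above <- which(saturations >= 1)
  if (!length(above)) stop("saturation curve does not bracket s = 1")
  i <- above[1]
  w <- (1 - saturations[i - 1]) / (saturations[i] - saturations[i - 1])
  drives[i - 1] + w * (drives[i] - drives[i - 1])
}

# complex-Morlet continuous wavelet transform power via FFT convolution.
# omega0 sets the time-frequency trade-off; omega0 = 6 resolves a 200 Hz
# burst with ~5 ms time smearing.
morlet_cwt_power <- function(x, dt, freqs, omega0 = 6) {
  n <- length(x)
  X <- fft(x)
  ang <- 2 * pi * (seq_len(n) - 1) / n            # rad/sample
  ang[ang > pi] <- ang[ang > pi] - 2 * pi
  P <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    scale <- omega0 / (2 * pi * freqs[k] * dt / 1000)   # samples
    # Morlet in frequency domain: exp(-(scale*ang - omega0)^2/2)
    H <- sqrt(2 * pi * scale) * exp(-0.5 * (scale * ang - omega0)^2)
    H[ang < 0] <- 0
    w <- fft(X * H, inverse = TRUE) / n
    P[k, ] <- Mod(w)^2
  }
  P
}

#' Instantaneous frequency from a wavelet spectrogram
#'
#' Continuous estimate of the instantaneous ripple frequency: at each time
#' step, the frequency above `f_min` with maximal instantaneous power in a
#' complex-Morlet wavelet spectrogram. A point is valid when its power
#' exceeds the mean near-DC power over the baseline window plus four baseline
#' standard deviations.
#'
#' @param rate population-rate time series (spikes/s), or a `sim_result`
#'   (the smoothed rate is used).
#' @param dt sample interval, ms.
#' @param baseline_window length-2 vector, ms: window of baseline-only
#'   activity preceding the event, used for the power threshold.
#' @param f_min lower cutoff for the frequency search, Hz (default 70,
#'   excluding the slow sharp wave component).
#' @param f_max upper limit of the analysed band, Hz.
#' @param f_step frequency resolution, Hz.
#' @param downsample analyse the rate at this stride to keep the transform
#'   cheap (default picks ~0.2 ms resolution).
#' @param omega0 Morlet time-frequency parameter.
#' @param threshold explicit power threshold overriding the baseline rule
#'   (useful for sustained oscillations without a quiescent baseline).
#' @return an object of class `inst_freq_series`: data frame with columns
#'   `t` (ms), `f` (Hz), `power`, `valid`; estimator and thresholds stored as
#'   attributes.
#' @export
inst_freq_spectrogram <- function(rate, dt = NULL,
                                  baseline_window = c(0, 200), f_min = 70,
                                  f_max = 350, f_step = 2,
                                  downsample = NULL, omega0 = 6,
                                  threshold = NULL) {
  if (inherits(rate, "sim_result")) {
    dt <- rate$dt
    rate <- rate$rate$smooth
  }
  stopifnot(!is.null(dt))
  if (is.null(downsample)) downsample <- max(1L, round(0.2 / dt))
  idx <- seq(1, length(rate), by = downsample)
  x <- rate[idx]
  dts <- dt * downsample
  t <- (idx - 1) * dt
  freqs <- seq(max(f_step, 2), f_max, by = f_step)
  P <- morlet_cwt_power(x, dts, freqs, omega0)
  sel <- freqs >= f_min
  imax <- apply(P[sel, , drop = FALSE], 2, which.max)
  fhat <- freqs[sel][imax]
  pow <- P[sel, , drop = FALSE][cbind(imax, seq_along(imax))]
  if (is.null(threshold)) {
    # zero-frequency power: a DC-centred Gaussian low-pass with the same
    # width (and gain) as the f_min wavelet, capturing the local mean rate
    n <- length(x)
    X <- fft(x)
    ang <- 2 * pi * (seq_len(n) - 1) / n
    ang[ang > pi] <- ang[ang > pi] - 2 * pi
    scale0 <- omega0 / (2 * pi * f_min * dts / 1000)
    H0 <- sqrt(2 * pi * scale0) * exp(-0.5 * (scale0 * ang)^2)
    p0_all <- Mod(fft(X * H0, inverse = TRUE) / n)^2
    # trim the window edges by three low-pass widths: the circular FFT
    # leaks the event (and the trace end) into the baseline there
    pad <- 3 * scale0 * dts
    bl <- t >= baseline_window[1] + pad & t <= baseline_window[2] - pad
    if (!any(bl))
      bl <- t >= baseline_window[1] & t <= baseline_window[2]
    p0 <- p0_all[bl]
    thr <- mean(p0) + 4 * sd(p0)
  } else thr <- threshold
  out <- data.frame(t = t, f = fhat, power = pow, valid = pow > thr)
  attr(out, "estimator") <- "spectrogram"
  attr(out, "threshold") <- thr
  class(out) <- c("inst_freq_series", "data.frame")
  out
}

#' Instantaneous frequency from peak-to-peak distances
#'
#' Discrete estimate of the instantaneous ripple frequency: local maxima of
#' the smoothed population rate exceeding the baseline mean rate plus four
#' baseline standard deviations are detected, and each consecutive pair of
#' peaks contributes one frequency `1/(t2 - t1)` assigned to the pair's
#' midpoint (a time-reversal-symmetric convention, as required by the IFA
#' analysis).
#'
#' @inheritParams inst_freq_spectrogram
#' @param min_separation minimal distance between detected peaks, ms.
#' @param threshold explicit rate threshold overriding the baseline rule.
#' @return an `inst_freq_series` (possibly empty when fewer than two peaks
#'   are found); the peak times are stored in the `peaks` attribute.
#' @export
inst_freq_peaks <- function(rate, dt = NULL, baseline_window = c(0, 200),
                            min_separation = 1.5, threshold = NULL) {
  if (inherits(rate, "sim_result")) {
    dt <- rate$dt
    rate <- rate$rate$smooth
  }
  stopifnot(!is.null(dt))
  t <- (seq_along(rate) - 1) * dt
  if (is.null(threshold)) {
    bl <- t >= baseline_window[1] & t <= baseline_window[2]
    thr <- mean(rate[bl]) + 4 * sd(rate[bl])
  } else thr <- threshold
  w <- max(1L, round(min_separation / 2 / dt))
  n <- length(rate)
  cand <- which(rate > thr)
  cand <- cand[cand > w & cand <= n - w]
  is_pk <- vapply(cand, function(i) {
    seg <- rate[(i - w):(i + w)]
    rate[i] >= max(seg) && rate[i] > seg[1] && rate[i] > seg[2 * w + 1]
  }, TRUE)
  pk <- cand[is_pk]
  # enforce separation (keep the higher of close pairs)
  if (length(pk) > 1) {
    keep <- rep(TRUE, length(pk))
    last <- 1
    for (i in 2:length(pk)) {
      if ((pk[i] - pk[last]) * dt < min_separation) {
        if (rate[pk[i]] > rate[pk[last]]) { keep[last] <- FALSE; last <- i }
        else keep[i] <- FALSE
      } else last <- i
    }
    pk <- pk[keep]
  }
  if (length(pk) < 2) {
    out <- data.frame(t = numeric(0), f = numeric(0), power = numeric(0),
                      valid = logical(0))
  } else {
    tp <- t[pk]
    out <- data.frame(t = (tp[-1] + tp[-length(tp)]) / 2,
                      f = 1000 / diff(tp),
                      power = pmin(rate[pk[-1]], rate[pk[-length(pk)]]),
                      valid = TRUE)
  }
  attr(out, "estimator") <- "peak-to-peak"
  attr(out, "threshold") <- thr
  attr(out, "peaks") <- if (length(pk)) t[pk] else numeric(0)
  class(out) <- c("inst_freq_series", "data.frame")
  out
}

#' IFA slope: linear regression of instantaneous frequency on time
#'
#' Pools the valid points of one or more instantaneous-frequency series
#' (typically from repeated simulations with different noise realizations of
#' the same sharp wave-like drive) and fits
#' \eqn{f(t) \approx \chi_{IFA} t + c} by ordinary least squares;
#' \eqn{\chi_{IFA} = Cov(\hat f, \hat t)/Var(\hat t)}. A negative slope
#' indicates intra-ripple frequency accommodation.
#'
#' @param series an `inst_freq_series`, a data frame with columns `t`, `f`
#'   (and optionally `valid`), or a list of such objects.
#' @return an object of class `ifa_fit`: list with `chi_ifa` (Hz/ms),
#'   `intercept` (Hz), `n_points`, `n_series`.
#' @export
ifa_slope <- function(series) {
  if (is.data.frame(series)) series <- list(series)
  pts <- do.call(rbind, lapply(series, function(s) {
    s <- as.data.frame(s)[, c("t", "f", if ("valid" %in% names(s)) "valid")]
    if ("valid" %in% names(s)) s <- s[s$valid, c("t", "f")]
    s
  }))
  if (nrow(pts) < 3) stop("need at least 3 pooled valid points")
  if (var(pts$t) == 0) stop("degenerate times: Var(t) = 0")
  fit <- lm(f ~ t, data = pts)
  out <- list(chi_ifa = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              n_points = nrow(pts), n_series = length(series))
  class(out) <- "ifa_fit"
  out
}

#' @export
print.ifa_fit <- function(x, ...) {
  cat(sprintf("IFA fit: chi_IFA = %.3f Hz/ms (intercept %.1f Hz, %d points from %d series)\n",
              x$chi_ifa, x$intercept, x$n_points, x$n_series))
  invisible(x)
}
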