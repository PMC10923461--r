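# External-drive time courses: piecewise-linear profiles, in particular the
# symmetric double-ramp model of sharp wave-associated input.

#' Piecewise-linear drive profile
#'
#' A drive profile is an ordered list of contiguous segments, each linearly
#' interpolated between its endpoint values. Profiles carry a units flag
#' (`"dimensionless"` or `"nA"`) so that simulator and theory code can check
#' they are fed consistently scaled drive.
#'
#' @param t_start,t_end segment start/end times, ms.
#' @param v_start,v_end drive values at the segment endpoints.
#' @param units `"dimensionless"` or `"nA"`.
#' @return an object of class `drive_profile`.
#' @seealso [make_spw_drive()], [constant_drive()], [eval_drive()]
#' @export
drive_profile <- function(t_start, t_end, v_start, v_end,
                          units = c("dimensionless", "nA")) {
  units <- match.arg(units)
  stopifnot(length(t_start) == length(t_end),
            length(v_start) == length(v_end),
            length(t_start) == length(v_start))
  o <- order(t_start)
  seg <- data.frame(t_start = t_start[o], t_end = t_end[o],
                    v_start = v_start[o], v_end = v_end[o])
  if (any(seg$t_end <= seg$t_start))
    stop("each segment must have t_end > t_start")
  if (nrow(seg) > 1 &&
      any(abs(seg$t_start[-1] - seg$t_end[-nrow(seg)]) > 1e-9))
    stop("segments must be contiguous and non-overlapping")
  structure(list(segments = seg, units = units), class = "drive_profile")
}

#' Constant drive over a time window
#'
#' @param value drive level.
#' @param duration window length, ms (profile spans `[0, duration]`).
#' @inheritParams drive_profile
#' @return a `drive_profile`.
#' @export
constant_drive <- function(value, duration,
                           units = c("dimensionless", "nA")) {
  drive_profile(0, duration, value, value, match.arg(units))
}

#' Sharp wave-like double-ramp drive
#'
#' Builds the symmetric piecewise-linear model of transient sharp
#' wave-associated input: a baseline held for `t_baseline`, a linear rise at
#' slope `+slope_m` up to `plateau`, a plateau of length `t_plateau`, and a
#' linear fall at `-slope_m` back to baseline, followed by a final baseline
#' segment of length `t_tail`. The profile is exactly time-symmetric about
#' the plateau midpoint.
#'
#' @param baseline baseline drive level (conventionally half the critical
#'   drive of the Hopf bifurcation).
#' @param plateau plateau drive level (conventionally the point of full
#'   synchrony).
#' @param slope_m ramp slope, drive units per ms (`> 0`).
#' @param t_baseline baseline duration before the ramp, ms (default 200).
#' @param t_plateau plateau duration, ms (default 20).
#' @param t_tail trailing baseline duration, ms (default 20).
#' @inheritParams drive_profile
#' @return a `drive_profile` with attributes `baseline`, `plateau`,
#'   `slope_m`, `t_baseline`, `t_plateau` used by the cycle-chaining theory.
#' @examples
#' d <- make_spw_drive(0.74, 8.9, 0.4)
#' eval_drive(d, 200 + (8.9 - 0.74) / 0.4 + 10)  # plateau value
#' @export
make_spw_drive <- function(baseline, plateau, slope_m, t_baseline = 200,
                           t_plateau = 20, t_tail = 20,
                           units = c("dimensionless", "nA")) {
  units <- match.arg(units)
  if (slope_m <= 0) stop("slope_m must be positive")
  if (plateau <= baseline) stop("plateau must exceed baseline")
  t_ramp <- (plateau - baseline) / slope_m
  t1 <- t_baseline
  t2 <- t1 + t_ramp
  t3 <- t2 + t_plateau
  t4 <- t3 + t_ramp
  d <- drive_profile(
    t_start = c(0, t1, t2, t3, t4),
    t_end   = c(t1, t2, t3, t4, t4 + t_tail),
    v_start = c(baseline, baseline, plateau, plateau, baseline),
    v_end   = c(baseline, plateau, plateau, baseline, baseline),
    units = units)
  attr(d, "baseline") <- baseline
  attr(d, "plateau") <- plateau
  attr(d, "slope_m") <- slope_m
  attr(d, "t_baseline") <- t_baseline
  attr(d, "t_plateau") <- t_plateau
  d
}

#' Evaluate a drive profile
#'
#' Piecewise-linear interpolation, exact at the knots. Times outside the
#' profile's span are rejected.
#'
#' @param d a `drive_profile`.
#' @param t times, ms (vectorised).
#' @return drive values at `t`.
#' @export
eval_drive <- function(d, t) {
  stopifnot(inherits(d, "drive_profile"))
  sp <- drive_span(d)
  if (any(t < sp[1] - 1e-9 | t > sp[2] + 1e-9))
    stop(sprintf("t outside drive span [%g, %g]", sp[1], sp[2]))
  seg <- d$segments
  idx <- findInterval(pmin(pmax(t, sp[1]), sp[2]), seg$t_start,
                      rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  w <- (t - seg$t_start[idx]) / (seg$t_end[idx] - seg$t_start[idx])
  w <- pmin(pmax(w, 0), 1)
  seg$v_start[idx] + w * (seg$v_end[idx] - seg$v_start[idx])
}

#' @rdname eval_drive
#' @return `drive_span()`: numeric length-2 vector `(t_min, t_max)`.
#' @export
drive_span <- function(d) {
  c(d$segments$t_start[1], d$segments$t_end[nrow(d$segments)])
}

#' @export
print.drive_profile <- function(x, ...) {
  sp <- drive_span(x)
  cat(sprintf("Drive profile (%s), %d segment(s), t in [%g, %g] ms\n",
              x$units, nrow(x$segments), sp[1], sp[2]))
  invisible(x)
}

# convert an nA profile to dimensionless using physical parameters
drive_as_dimensionless <- function(d, params) {
  if (d$units == "dimensionless") return(d)
  stopifnot(inherits(params, "physical_params"))
  seg <- d$segments
  out <- drive_profile(seg$t_start, seg$t_end,
                       drive_to_dimensionless(seg$v_start, params),
                       drive_to_dimensionless(seg$v_end, params),
                       units = "dimensionless")
  for (a in c("baseline", "plateau", "slope_m"))
    if (!is.null(attr(d, a)))
      attr(out, a) <- drive_to_dimensionless(attr(d, a), params)
  if (!is.null(attr(d, "slope_m")))
    attr(out, "slope_m") <- attr(out, "slope_m")  # slope scales like values
  for (a in c("t_baseline", "t_plateau"))
    attr(out, a) <- attr(d, a)
  out
}

#' Read and write drive profiles as columnar text
#'
#' `write_drive()` stores the segment list as tab-separated columns
#' (`t_start`, `t_end`, `v_start`, `v_end`) with the units in a header
#' comment; `read_drive()` reconstructs the profile.
#'
#' @param d a `drive_profile`.
#' @param path file path.
#' @export
write_drive <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ripplenet drive profile; units = %s", d$units), con)
  write.table(d$segments, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_drive
#' @export
read_drive <- function(path) {
  hdr <- readLines(path, n = 1)
  units <- sub(".*units = ", "", hdr)
  seg <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  drive_profile(seg$t_start, seg$t_end, seg$v_start, seg$v_end, units)
}
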