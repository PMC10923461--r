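# Special functions used by the mean-field theory and stability analysis.

#' Error function
#'
#' Thin wrappers around [stats::pnorm()] used throughout the Gaussian-drift
#' theory. The scaled complement `erfcx(x) = exp(x^2) erfc(x)` needed by the
#' LIF f-I integral lives in `erfcx_safe()` (pracma's implementation with an
#' asymptotic tail where `exp(x^2)` overflows).
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' @rdname erf
#' @keywords internal
erfc <- function(x) 2 * pnorm(-x * sqrt(2))

# exp(x^2) erfc(x); pracma's implementation returns NaN for large x where
# exp(x^2) overflows, so switch to the asymptotic series there
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    xb <- x[big]
    out[big] <- (1 - 0.5 / xb^2 + 0.75 / xb^4) / (xb * sqrt(pi))
  }
  out
}

#' Lambert W function, log-argument form
#'
#' Solves \eqn{u e^u = y} given `log|y|` and the sign of `y`, so that the
#' transcendental rise-time equation of the linear-drive cycle theory can be
#' solved even where \eqn{y = A/(m\tau)\,e^{P/\tau}} overflows or underflows
#' double precision (the limit of vanishing drive slope). For negative
#' arguments both real branches are available; the linear-drive theory needs
#' the principal branch for rising drive and the lower branch for falling
#' drive.
#'
#' @param log_y log of the absolute value of the argument.
#' @param y_sign sign of the argument (+1 or -1).
#' @param branch `"0"` (principal) or `"-1"` (lower); ignored for positive
#'   arguments, where only the principal branch is real.
#' @return the real solution `u`, or `NA_real_` when the argument lies below
#'   the branch point \eqn{-1/e} and no real solution exists.
#' @examples
#' lambert_w_log(log(2), 1)               # W0(2)
#' lambert_w_log(log(0.2), -1, "-1")      # W-1(-0.2)
#' @export
lambert_w_log <- function(log_y, y_sign, branch = c("0", "-1")) {
  branch <- match.arg(branch)
  stopifnot(is.finite(log_y) || log_y == -Inf)
  if (y_sign > 0) {
    if (log_y < -36) return(exp(log_y))     # W0(y) ~ y for tiny y
    w <- if (log_y > 1) log_y - log(log_y) else 0.5
    for (i in 1:80) {                        # Newton on w + log w = log y
      f <- w + log(w) - log_y
      w <- w - f / (1 + 1 / w)
      if (!is.finite(w) || w <= 0) w <- 1e-8
      if (abs(f) < 1e-13) break
    }
    return(w)
  }
  # negative argument: real solutions only for |y| <= 1/e
  if (log_y > -1) {
    if (log_y < -1 + 1e-9) return(-1)
    return(NA_real_)
  }
  if (branch == "0") {
    u <- -exp(log_y)                         # u in (-1, 0), seed at y
    for (i in 1:80) {
      f <- u * exp(u) + exp(log_y)
      u <- u - f / (exp(u) * (1 + u))
      if (u <= -1) u <- -1 + 1e-10
      if (u >= 0) u <- -1e-10
      if (abs(f) < 1e-16) break
    }
    u
  } else {
    # u < -1: w = -u solves w - log w = -log y; robust for log_y -> -Inf
    w <- max(-log_y + log(max(-log_y, 2)), 1.5)
    for (i in 1:80) {
      f <- w - log(w) + log_y
      w <- w - f / (1 - 1 / w)
      if (w <= 1) w <- 1 + 1e-10
      if (abs(f) < 1e-13) break
    }
    -w
  }
}

# complex log-gamma, Lanczos approximation (g = 7, 9 coefficients);
# accurate to ~1e-14 on the half-plane Re(z) > 0.5, reflected otherwise
complex_lgamma <- function(z) {
  g <- 7
  cg <- c(0.99999999999980993, 676.5203681218851, -1259.1392167224028,
          771.32342877765313, -176.61502916214059, 12.507343278686905,
          -0.13857109526572012, 9.9843695780195716e-6, 1.5056327351493116e-7)
  z <- as.complex(z)
  refl <- Re(z) < 0.5
  zz <- ifelse(refl, 1 - z, z)
  x <- cg[1] + 0i
  for (i in 1:(g + 1)) x <- x + cg[i + 1] / (zz - 1 + i)
  t <- zz + g - 0.5
  out <- 0.5 * log(2 * pi) + (zz - 0.5) * log(t) - t + log(x)
  ifelse(refl, log(pi) - log(sin(pi * z)) - out, out)
}

complex_gamma <- function(z) exp(complex_lgamma(z))

# Kummer confluent hypergeometric M(a, b, x) by Taylor series; used with
# complex order a and small-to-moderate real x >= 0 (x = z^2/2 with z the
# standardised distance of the operating point from threshold/reset).
kummer_m <- function(a, b, x, tol = 1e-15, maxit = 1000L) {
  term <- 1 + 0i
  s <- 1 + 0i
  for (n in 0:maxit) {
    term <- term * (a + n) / (b + n) * x / (n + 1)
    s <- s + term
    if (abs(term) < tol * abs(s)) break
  }
  s
}

#' Parabolic cylinder function of complex order
#'
#' Evaluates \eqn{D_\nu(z)} for complex order \eqn{\nu} and real argument `z`
#' through its confluent hypergeometric representation. The complex order
#' arises in the linear response (susceptibility) of an LIF neuron driven by
#' Gaussian white noise, where \eqn{\nu = -i\omega\tau_m} at modulation
#' frequency \eqn{\omega}. Standard double-precision libraries only provide
#' real orders, hence this implementation.
#'
#' @param nu complex (or real) order.
#' @param z real argument.
#' @return complex scalar \eqn{D_\nu(z)}.
#' @examples
#' pcf_d(0, 1.3)   # equals exp(-1.3^2/4)
#' @export
pcf_d <- function(nu, z) {
  h <- z * z / 2
  2^(nu / 2) * exp(-h / 2) *
    (sqrt(pi) / complex_gamma((1 - nu) / 2) * kummer_m(-nu / 2, 0.5, h) -
     sqrt(2 * pi) * z / complex_gamma(-nu / 2) * kummer_m((1 - nu) / 2, 1.5, h))
}
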