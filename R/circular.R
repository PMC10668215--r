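# Circular helpers on the 180-degree orientation space.
#
# Bar orientation is axial: 0 and 180 degrees are the same stimulus. All
# circular computation therefore uses the doubled-angle convention: multiply
# orientations by 2, work in radians on the full circle, divide by 2 at the
# end. An orientation difference of x degrees maps to 2x * pi/180 radians.

#' Wrap orientations into [0, 180)
#'
#' @param x Numeric vector of orientations in degrees.
#' @return Orientations wrapped to the half-open interval `[0, 180)`.
#' @export
wrap_orientation <- function(x) {
  x %% 180
}

#' Circular distance between orientations
#'
#' Absolute distance on the 180-degree-periodic orientation circle, always in
#' `[0, 90]`.
#'
#' @param a,b Orientations in degrees.
#' @return Absolute circular distances in degrees.
#' @export
circ_dist_orientation <- function(a, b) {
  abs(((a - b + 90) %% 180) - 90)
}

# Degrees of orientation -> radians on the doubled circle.
deg_to_double_rad <- function(x) x * pi / 90

# Radians on the doubled circle -> degrees of orientation.
double_rad_to_deg <- function(x) x * 90 / pi

# Mean resultant length ratio A1(kappa) = I1(kappa) / I0(kappa), computed with
# exponentially scaled Bessel functions so large kappa does not overflow.
vm_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Inverse of vm_a1: a standard piecewise approximation (Fisher 1993) polished
# by Newton steps, using A1'(k) = 1 - A1/k - A1^2. R close to 0 or 1 is
# clamped to keep the result finite. Hot path of the EM concentration update.
vm_a1_inv <- function(r, lower = 1e-6, upper = 1e4) {
  if (r <= vm_a1(lower)) return(lower)
  if (r >= vm_a1(upper)) return(upper)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  k <- min(max(k, lower), upper)
  for (i in 1:25) {
    a <- vm_a1(k)
    step <- (a - r) / (1 - a / k - a^2)
    k_new <- min(max(k - step, lower), upper)
    if (abs(k_new - k) < 1e-12 * (1 + k)) {
      k <- k_new
      break
    }
    k <- k_new
  }
  k
}

#' Convert between circular SD in orientation degrees and concentration
#'
#' The report-noise dispersion is parameterized either as a von Mises
#' concentration `kappa` on the doubled circle or as the equivalent circular
#' standard deviation expressed in orientation degrees. The two are linked by
#' `sd_rad = sqrt(-2 log A1(kappa))` on the doubled circle, with
#' `sd_deg = sd_rad * 90 / pi`.
#'
#' @param sd_deg Circular SD in orientation degrees (> 0).
#' @param kappa von Mises concentration on the doubled circle (> 0).
#' @return The corresponding concentration, or circular SD in degrees.
#' @export
sd_deg_to_kappa <- function(sd_deg) {
  stopifnot(is.numeric(sd_deg), sd_deg > 0)
  r <- exp(-deg_to_double_rad(sd_deg)^2 / 2)
  vapply(r, vm_a1_inv, numeric(1))
}

#' @rdname sd_deg_to_kappa
#' @export
kappa_to_sd_deg <- function(kappa) {
  stopifnot(is.numeric(kappa), kappa > 0)
  double_rad_to_deg(sqrt(-2 * log(vm_a1(kappa))))
}

# von Mises log density at angle x (radians, doubled circle) centred on 0.
# Exponentially scaled Bessel keeps kappa up to several hundred stable:
# log f = kappa * (cos x - 1) - log(2 pi I0e(kappa)).
vm_log_density <- function(x, kappa) {
  kappa * (cos(x) - 1) - log(2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

vm_density <- function(x, kappa) exp(vm_log_density(x, kappa))

# Best & Fisher (1979) rejection sampler for the von Mises distribution on the
# full circle (radians). kappa near zero falls back to the uniform limit.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    return((stats::runif(n, -pi, pi) + mu + pi) %% (2 * pi) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1L
    }
  }
  (out + mu + pi) %% (2 * pi) - pi
}

# Deterministic per-subject seed streams derived from one master seed, so a
# multi-subject simulation is reproducible subject by subject.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
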