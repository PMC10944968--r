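#' Wrap angles to [-pi, pi)
#'
#' All circular arithmetic in the package goes through this helper so that
#' report errors, target separations and meridian distances are always
#' expressed on the principal branch.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector wrapped to `[-pi, pi)`.
#' @export
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Signed circular difference a - b, wrapped to [-pi, pi)
#' @param a,b angles in radians.
#' @return wrapped difference in radians.
#' @export
circ_diff <- function(a, b) wrap_angle(a - b)

#' @rdname deg_rad
#' @export
deg2rad <- function(deg) deg * pi / 180

#' Degree/radian conversion
#'
#' @param deg,rad angles in degrees / radians.
#' @name deg_rad
#' @return converted angles.
#' @export
rad2deg <- function(rad) rad * 180 / pi

# Mean resultant length of a Von Mises distribution, A1(kappa) = I1/I0.
# Computed with exponentially scaled Bessel functions for large kappa.
vm_a1 <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Convert Von Mises concentration to circular standard deviation
#'
#' Uses the standard mapping `sigma = sqrt(-2 log Rbar)` with
#' `Rbar = I1(kappa)/I0(kappa)`. The inverse [sigma_to_kappa()] is computed
#' numerically.
#'
#' @param kappa concentration parameter (>= 0).
#' @return circular SD in radians (`Inf` at `kappa = 0`).
#' @export
kappa_to_sigma <- function(kappa) {
  stopifnot(all(kappa >= 0))
  r <- vm_a1(kappa)
  ifelse(r <= 0, Inf, sqrt(-2 * log(r)))
}

#' @rdname kappa_to_sigma
#' @param sigma circular SD in radians (> 0).
#' @export
sigma_to_kappa <- function(sigma) {
  stopifnot(all(sigma > 0))
  vapply(sigma, function(s) {
    if (!is.finite(s)) return(0)
    f <- function(k) kappa_to_sigma(k) - s
    # kappa is monotone decreasing in sigma; bracket generously
    stats::uniroot(f, lower = 1e-6, upper = 1e4, tol = 1e-10)$root
  }, numeric(1))
}

# Inverse of A1 (mean resultant length -> kappa), used by the EM M-step.
# Fisher (1993) series approximation refined by a few Newton steps.
a1_inv <- function(r) {
  r <- min(max(r, 0), 1 - 1e-12)
  if (r < 0.53) {
    k <- 2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    k <- -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    k <- 1 / (r^3 - 4 * r^2 + 3 * r)
  }
  for (i in 1:4) {
    a <- vm_a1(k)
    # d A1/d kappa = 1 - A1^2 - A1/kappa
    da <- 1 - a^2 - a / max(k, 1e-12)
    if (!is.finite(da) || da <= 0) break
    k <- max(k - (a - r) / da, 1e-8)
  }
  k
}

#' Circular standard deviation of a sample
#'
#' @param x angles in radians.
#' @return `sqrt(-2 log Rbar)` where `Rbar` is the sample mean resultant
#'   length.
#' @export
circ_sd <- function(x) {
  r <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
  if (r <= 0) return(Inf)
  sqrt(-2 * log(r))
}
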