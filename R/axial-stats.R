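#' Axial angle helpers
#'
#' Collagen bundle orientations are axial: a fiber at \eqn{\theta} and one at
#' \eqn{\theta + 180^\circ} are the same axis. All orientations in this
#' package live in \eqn{[0, 180)} degrees and are compared with the axial
#' distance \eqn{\min(|\Delta|, 180 - |\Delta|)}.
#'
#' @param theta numeric vector of angles in degrees.
#' @return `fold_axial()` returns angles reduced modulo 180 into `[0, 180)`.
#' @examples
#' fold_axial(c(-10, 190, 180))
#' axial_diff(170, 0)   # 10, never 170
#' @export
fold_axial <- function(theta) {
  out <- theta %% 180
  out[out == 180] <- 0
  out
}

#' @rdname fold_axial
#' @param a,b angle vectors in degrees (recycled).
#' @return `axial_diff()` returns the axial distance in degrees, in `[0, 90]`.
#' @export
axial_diff <- function(a, b) {
  d <- abs(fold_axial(a) - fold_axial(b))
  pmin(d, 180 - d)
}

#' @rdname fold_axial
#' @return `axial_mean()` returns the mean axis direction in degrees
#'   (`[0, 180)`), computed on doubled angles.
#' @export
axial_mean <- function(theta) {
  phi <- 2 * theta * pi / 180
  fold_axial(atan2(mean(sin(phi)), mean(cos(phi))) * 180 / pi / 2)
}

# log I0(kappa), overflow-safe via the exponentially scaled Bessel function
log_bessel_i0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

# A(kappa) = I1(kappa)/I0(kappa), the von Mises mean resultant length
vm_a <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Inverse of A(kappa) by the standard piecewise approximation (Fisher 1993),
# polished with a few Newton steps. Capped to keep besselI finite.
kappa_from_rbar <- function(rbar, kappa_max = 500) {
  rbar <- min(max(rbar, 0), 0.999999)
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  k <- min(max(k, 1e-8), kappa_max)
  for (i in 1:4) {
    a <- vm_a(k)
    # dA/dk = 1 - A/k - A^2
    da <- 1 - a / k - a^2
    if (!is.finite(da) || da <= 0) break
    k <- k - (a - rbar) / da
    if (!is.finite(k)) return(kappa_max)
    k <- min(max(k, 1e-8), kappa_max)
  }
  k
}

# Von Mises sampler (Best & Fisher 1979 rejection algorithm), radians,
# vectorized in batches. Uses the current RNG stream; callers seed.
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.4) + 10
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[acc] - 0.5) * acos(pmin(pmax(f[acc], -1), 1)))
  }
  out[seq_len(n)] + mu
}

#' Sample axial angles from a von Mises component
#'
#' Draws orientations in degrees on the half-circle `[0, 180)` whose doubled
#' angles follow a von Mises distribution centred at `2 * mu_deg` with
#' concentration `kappa`. This is the standard device for axial data: fit and
#' simulate on the doubled circle, then halve.
#'
#' @param n number of draws.
#' @param mu_deg axis location in degrees, `[0, 180)`.
#' @param kappa axial concentration (> 0 for a peaked component; 0 gives a
#'   uniform axis distribution).
#' @return numeric vector of `n` angles in `[0, 180)`.
#' @export
rvm_axial <- function(n, mu_deg, kappa) {
  phi <- rvonmises(n, 2 * mu_deg * pi / 180, kappa)
  fold_axial(phi * 180 / pi / 2)
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
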