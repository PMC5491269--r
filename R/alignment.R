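#' Two-peak decomposition of an axial angle distribution
#'
#' Fits a two-component axial von Mises mixture to a sample of bundle angles
#' by expectation-maximization on doubled angles (theta -> 2 theta mod 360,
#' mapping the half-circle of axes onto the full circle). Components are
#' initialized at the two largest modes of a 5-degree histogram; additional
#' random restarts guard against local maxima and the best fit by
#' log-likelihood is kept. Components are returned sorted by weight
#' descending, so `w[1]` is the fraction of fibers in the greater of the two
#' peaks — the alignment score.
#'
#' A fit whose two peak locations end up closer than `min_separation`
#' (axially) is flagged degenerate: the sample is effectively unimodal, and
#' the score path treats all fibers as one peak (score 1).
#'
#' @param angles numeric vector of axial angles in degrees (folded to
#'   `[0, 180)`); at least 2 required, >= 10 recommended.
#' @param weights optional nonnegative per-bundle weights (default 1).
#' @param n_starts number of EM starts (1 histogram-mode start plus
#'   `n_starts - 1` random restarts).
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per start.
#' @param seed integer seed for the random restarts.
#' @param min_separation axial distance (degrees) under which the two fitted
#'   peaks are declared merged/degenerate.
#' @param kappa_max concentration cap (guards spike inputs).
#' @return an object of class `peak_decomposition`: list with `mu` (two peak
#'   locations, degrees in `[0, 180)`), `w` (two weights summing to 1,
#'   `w[1] >= w[2]`), `kappa` (two concentrations), `loglik`, `converged`,
#'   `n_iter`, `degenerate`, `n`.
#' @examples
#' a <- c(rvm_axial(790, 40, 8), rvm_axial(210, 130, 8))
#' fit_two_peaks(a, seed = 1)
#' @export
fit_two_peaks <- function(angles, weights = NULL, n_starts = 5, tol = 1e-6,
                          max_iter = 500, seed = 1, min_separation = 20,
                          kappa_max = 500) {
  angles <- fold_axial(angles)
  if (any(!is.finite(angles))) stop("angles must be finite")
  n <- length(angles)
  if (n < 2) stop("need at least 2 angles")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be nonnegative, one per angle")
  phi <- 2 * angles * pi / 180                     # doubled angles, radians
  wn <- weights / sum(weights)

  # unimodal short-circuit: (near-)zero angular spread
  rbar_all <- sqrt(sum(wn * cos(phi))^2 + sum(wn * sin(phi))^2)
  if (rbar_all > 1 - 1e-9) {
    mu0 <- fold_axial(atan2(sum(wn * sin(phi)), sum(wn * cos(phi))) * 180 / pi / 2)
    return(structure(list(mu = c(mu0, mu0), w = c(1, 0),
                          kappa = c(kappa_max, kappa_max),
                          loglik = NA_real_, converged = TRUE, n_iter = 0L,
                          degenerate = TRUE, n = n),
                     class = "peak_decomposition"))
  }

  starts <- with_seed(seed, em_starts(angles, wn, n_starts))
  best <- NULL
  for (st in starts) {
    fit <- em_axial_vm(phi, wn, st$mu2x, st$kappa, st$w, tol, max_iter, kappa_max)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$w, decreasing = TRUE)
  mu_deg <- fold_axial(best$mu2x[ord] * 180 / pi / 2)
  out <- list(mu = mu_deg, w = best$w[ord], kappa = best$kappa[ord],
              loglik = best$loglik, converged = best$converged,
              n_iter = best$n_iter,
              degenerate = axial_diff(mu_deg[1], mu_deg[2]) < min_separation,
              n = n)
  class(out) <- "peak_decomposition"
  out
}

# Starting points: histogram-mode start first, then seeded random restarts
em_starts <- function(angles, wn, n_starts) {
  br <- seq(0, 180, by = 5)
  bin <- findInterval(angles, br)
  dens <- vapply(seq_len(36), function(k) sum(wn[bin == k]), numeric(1))
  centers <- br[-length(br)] + 2.5
  top <- order(dens, decreasing = TRUE)
  m1 <- centers[top[1]]
  # second mode: highest bin at least 20 degrees (axially) from the first
  far <- top[axial_diff(centers[top], m1) >= 20]
  m2 <- if (length(far)) centers[far[1]] else fold_axial(m1 + 90)
  starts <- list(list(mu2x = 2 * c(m1, m2) * pi / 180, kappa = c(4, 4),
                      w = c(0.5, 0.5)))
  if (n_starts > 1) for (k in seq_len(n_starts - 1)) {
    mus <- sample(angles, 2)
    if (axial_diff(mus[1], mus[2]) < 5) mus[2] <- fold_axial(mus[2] + 90)
    starts[[k + 1]] <- list(mu2x = 2 * mus * pi / 180,
                            kappa = stats::runif(2, 2, 10),
                            w = c(0.5, 0.5))
  }
  starts
}

# EM for a 2-component von Mises mixture on the (doubled-angle) circle.
# phi: radians; wn: normalized observation weights summing to 1.
em_axial_vm <- function(phi, wn, mu, kappa, w, tol, max_iter, kappa_max) {
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    lg <- vapply(1:2, function(k)
      log(w[k]) + kappa[k] * cos(phi - mu[k]) - log(2 * pi) -
        log_bessel_i0(kappa[k]),
      numeric(length(phi)))
    m <- pmax(lg[, 1], lg[, 2])
    lse <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
    ll <- sum(wn * lse)
    r1 <- exp(lg[, 1] - lse)                     # responsibilities, comp 1
    resp <- cbind(r1, 1 - r1)
    for (k in 1:2) {
      rk <- wn * resp[, k]
      nk <- sum(rk)
      if (nk < 1e-12) { w[k] <- 1e-12; next }
      cs <- sum(rk * cos(phi)); sn <- sum(rk * sin(phi))
      mu[k] <- atan2(sn, cs)
      rbar <- min(sqrt(cs^2 + sn^2) / nk, 1 - 1e-12)
      kappa[k] <- kappa_from_rbar(rbar, kappa_max)
      w[k] <- nk
    }
    w <- w / sum(w)
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(mu2x = mu, kappa = kappa, w = w, loglik = ll, converged = converged,
       n_iter = it)
}

#' @export
print.peak_decomposition <- function(x, ...) {
  cat(sprintf("peak_decomposition (n = %d): mu = %.1f / %.1f deg, w = %.3f / %.3f, kappa = %.2f / %.2f%s%s\n",
              x$n, x$mu[1], x$mu[2], x$w[1], x$w[2], x$kappa[1], x$kappa[2],
              if (x$degenerate) " [degenerate: merged peaks]" else "",
              if (!x$converged) " [not converged]" else ""))
  cat("alignment score:", round(alignment_score(x), 3), "\n")
  invisible(x)
}

#' Alignment score: fraction of fibers in the greater peak
#'
#' The score of a two-peak decomposition is the weight of its dominant
#' component, in `[0.5, 1]`: 0.5 is a perfectly balanced basket-weave, 1 a
#' fully aligned (unimodal) dermis. A degenerate decomposition (merged
#' peaks) means all fibers belong to one peak and scores 1.
#'
#' @param decomp a [fit_two_peaks()] result.
#' @return numeric score in `[0.5, 1]`.
#' @export
alignment_score <- function(decomp) {
  stopifnot(inherits(decomp, "peak_decomposition"))
  if (decomp$degenerate) return(1.0)
  max(decomp$w)
}

#' Nonparametric two-mode alignment score
#'
#' Sensitivity-analysis alternative to the mixture fit: finds the two
#' dominant modes of a circular kernel density of the doubled angles, hard-
#' assigns every angle to the axially nearer mode, and scores the larger
#' assignment fraction. Returns 1 if the density has a single mode.
#'
#' @param angles axial angles in degrees.
#' @param bw kernel bandwidth in degrees (on the axial scale).
#' @param min_separation merged-mode threshold, degrees (as in
#'   [fit_two_peaks()]).
#' @return list with `score`, `modes` (degrees) and `fractions`.
#' @export
alignment_score_modes <- function(angles, bw = 8, min_separation = 20) {
  angles <- fold_axial(angles)
  grid <- seq(0, 179.75, by = 0.25)
  # circular KDE by wrapped-normal kernel on the axial (period-180) scale
  d <- vapply(grid, function(g) {
    del <- axial_diff(angles, g)
    sum(exp(-0.5 * (del / bw)^2))
  }, numeric(1))
  is_peak <- d > c(d[length(d)], d[-length(d)]) & d >= c(d[-1], d[1])
  peaks <- grid[is_peak]
  if (length(peaks) < 2) return(list(score = 1.0, modes = peaks,
                                     fractions = 1.0))
  peaks <- peaks[order(d[is_peak], decreasing = TRUE)][1:2]
  if (axial_diff(peaks[1], peaks[2]) < min_separation)
    return(list(score = 1.0, modes = peaks, fractions = 1.0))
  near1 <- axial_diff(angles, peaks[1]) <= axial_diff(angles, peaks[2])
  f <- c(mean(near1), mean(!near1))
  list(score = max(f), modes = peaks, fractions = f)
}

#' Axial angle histogram as a density
#'
#' Half-open bins `[lo, hi)` over `[0, 180)`; densities integrate to 1.
#'
#' @param angles axial angles in degrees.
#' @param bin_width bin width in degrees; must divide 180 evenly.
#' @return data.frame with `lo`, `hi`, `mid`, `count`, `density`
#'   (per degree).
#' @export
angle_histogram <- function(angles, bin_width = 5) {
  if (180 %% bin_width != 0) stop("bin_width must divide 180 evenly")
  angles <- fold_axial(angles)
  br <- seq(0, 180, by = bin_width)
  cnt <- as.vector(table(cut(angles, br, right = FALSE)))
  data.frame(lo = br[-length(br)], hi = br[-1],
             mid = br[-length(br)] + bin_width / 2,
             count = cnt,
             density = cnt / (length(angles) * bin_width))
}
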