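#' Per-pixel phasor transform of a decay image
#'
#' Maps each pixel's TCSPC histogram to its phasor coordinates
#' \deqn{g = \sum_k c_k \cos(\omega n t_k) / \sum_k c_k, \quad
#'       s = \sum_k c_k \sin(\omega n t_k) / \sum_k c_k}
#' with \eqn{t_k} the time-bin centers, \eqn{\omega = 2\pi \times} repetition
#' rate and \eqn{n} the harmonic. Single-lifetime species fall on the
#' universal semicircle (center (0.5, 0), radius 0.5); mixtures fall inside;
#' excited-state reaction products can fall outside. Pixels with fewer than
#' `min_photons` total counts are flagged invalid (noise-dominated phasors).
#'
#' No instrument calibration (reference-dye rotation/scaling) is applied by
#' default: synthetic data has a delta IRF. `calibration` accepts an optional
#' `c(phase_rad, modulation)` pair applied as a rotation+scale in phasor
#' space, defaulting to identity.
#'
#' @param decays 3-D decay array `(row, col, bin)`, a `decay_image` from
#'   [integrate_spectral()], or a single histogram vector (treated as one
#'   pixel).
#' @param meta An [acquisition_metadata()]; defaulted from a `decay_image`.
#' @param harmonic Positive integer harmonic of the repetition frequency
#'   (the fundamental, 1, is used throughout).
#' @param min_photons Minimum total counts for a pixel to be considered valid.
#' @param calibration Optional `c(phase_rad, modulation)` calibration.
#' @return A `phasor_field`: list with matrices `g`, `s`, `total_counts`,
#'   logical `valid`, plus `omega_rad_per_s` and `harmonic`.
#' @export
phasor_transform <- function(decays, meta = NULL, harmonic = 1L,
                             min_photons = 50, calibration = NULL) {
  if (inherits(decays, "decay_image")) {
    if (is.null(meta)) meta <- decays$meta
    decays <- decays$decays
  }
  stopifnot(inherits(meta, "acquisition_metadata"))
  if (is.null(dim(decays))) decays <- array(decays, c(1L, 1L, length(decays)))
  d <- dim(decays)
  if (length(d) != 3L) stop("decays must be (row, col, bin) or a vector")
  if (d[3] != meta$n_time_bins) stop("time axis does not match metadata")
  harmonic <- as.integer(harmonic)
  if (harmonic < 1L) stop("harmonic must be >= 1")
  if (min(decays) < 0) stop("decays must be non-negative")

  omega <- angular_frequency(meta)
  tk <- time_bin_centers(meta)
  cosv <- cos(omega * harmonic * tk)
  sinv <- sin(omega * harmonic * tk)
  m <- matrix(decays, nrow = d[1] * d[2], ncol = d[3])
  tot <- as.vector(m %*% rep(1, d[3]))
  g <- as.vector(m %*% cosv)
  s <- as.vector(m %*% sinv)
  valid <- tot >= min_photons & tot > 0
  g <- ifelse(valid, g / tot, NA_real_)
  s <- ifelse(valid, s / tot, NA_real_)
  if (!any(valid)) {
    warning("phasor field has no valid pixels (all below min_photons)")
  }
  if (!is.null(calibration)) {
    stopifnot(length(calibration) == 2L)
    rot <- complex(modulus = calibration[2], argument = calibration[1])
    z <- complex(real = g, imaginary = s) * rot
    g <- Re(z); s <- Im(z)
  }
  structure(
    list(g = matrix(g, d[1], d[2]), s = matrix(s, d[1], d[2]),
         total_counts = matrix(tot, d[1], d[2]),
         valid = matrix(valid, d[1], d[2]),
         omega_rad_per_s = omega, harmonic = harmonic),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("phasor_field: %d x %d px, harmonic %d, %d valid pixels\n",
              nrow(x$g), ncol(x$g), x$harmonic, sum(x$valid)))
  invisible(x)
}

#' Phasor of a single decay histogram
#'
#' Convenience wrapper around [phasor_transform()] for one histogram.
#'
#' @inheritParams phasor_transform
#' @param counts Numeric histogram vector.
#' @return Named numeric `c(g, s)`.
#' @export
decay_phasor <- function(counts, meta, harmonic = 1L) {
  f <- phasor_transform(counts, meta, harmonic = harmonic, min_photons = 0)
  c(g = f$g[1, 1], s = f$s[1, 1])
}

#' Analytic phasor of a mono-exponential decay
#'
#' Closed form `g = 1/(1 + (omega*tau)^2)`, `s = omega*tau/(1 + (omega*tau)^2)`;
#' the point lies exactly on the universal semicircle for every `tau >= 0`.
#' (For a histogram window spanning exactly one laser period this closed form
#' is also the exact phasor of the truncated exponential, since the Fourier
#' kernel is periodic over the window.)
#'
#' @param tau_s Lifetime(s) in seconds, `>= 0` (vectorized).
#' @param omega Angular frequency in rad/s.
#' @return For one lifetime, named `c(g, s)`; for several, a 2-column matrix.
#' @export
monoexp_phasor <- function(tau_s, omega) {
  if (any(tau_s < 0)) stop("lifetime must be >= 0")
  wt <- omega * tau_s
  g <- 1 / (1 + wt^2)
  s <- wt / (1 + wt^2)
  if (length(tau_s) == 1L) c(g = g, s = s) else cbind(g = g, s = s)
}

#' Phase lifetime map from a phasor field
#'
#' `tau_phi = s / (g * omega * harmonic)`, in picoseconds. Invalid pixels and
#' pixels with `g <= 0` (where the phase angle no longer maps to a lifetime)
#' are `NA`.
#'
#' @param field A `phasor_field`.
#' @return Matrix of phase lifetimes (ps).
#' @export
phase_lifetime <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  w <- field$omega_rad_per_s * field$harmonic
  tau <- ifelse(field$valid & !is.na(field$g) & field$g > 0,
                field$s / (field$g * w), NA_real_)
  tau * 1e12
}

#' Modulation lifetime map from a phasor field
#'
#' `tau_m = (1/omega) * sqrt(1/(g^2 + s^2) - 1)`, in picoseconds. Equals the
#' phase lifetime exactly on the universal circle and exceeds it for interior
#' (multi-component) points. Points with `g^2 + s^2 >= 1` get 0 ps and are
#' flagged in the `"saturated"` attribute.
#'
#' @param field A `phasor_field`.
#' @return Matrix of modulation lifetimes (ps) with logical attribute
#'   `"saturated"`.
#' @export
modulation_lifetime <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  w <- field$omega_rad_per_s * field$harmonic
  m2 <- field$g^2 + field$s^2
  sat <- !is.na(m2) & m2 >= 1
  tau <- ifelse(field$valid & !is.na(m2),
                ifelse(m2 >= 1, 0, sqrt(1 / m2 - 1) / w), NA_real_)
  structure(tau * 1e12, saturated = sat)
}

#' Signed distance from the universal semicircle
#'
#' `d = sqrt((g - 0.5)^2 + s^2) - 0.5`: negative inside (multi-exponential
#' mixtures), zero on (single-lifetime species), positive outside
#' (excited-state reaction products such as solvent-relaxation emission).
#'
#' @param g A `phasor_field`, or a numeric vector/matrix of g coordinates.
#' @param s s coordinates when `g` is numeric.
#' @return Signed distances, same shape as the input coordinates.
#' @export
circle_residual <- function(g, s = NULL) {
  if (inherits(g, "phasor_field")) {
    s <- g$s
    g <- g$g
  }
  if (is.null(s)) stop("s coordinates required")
  sqrt((g - 0.5)^2 + s^2) - 0.5
}

#' 2-D histogram of a phasor field (the phasor-plot density)
#'
#' @param field A `phasor_field`.
#' @param n_bins Number of bins per axis (>= 2).
#' @param g_range,s_range Plot ranges; defaults cover the universal semicircle
#'   with margin, `[-0.1, 1.1] x [-0.1, 0.7]`.
#' @return A `phasor_histogram`: `counts` matrix (g along rows), `g_edges`,
#'   `s_edges`. Total counts equal the number of valid in-range pixels.
#' @export
phasor_histogram <- function(field, n_bins = 128L,
                             g_range = c(-0.1, 1.1), s_range = c(-0.1, 0.7)) {
  stopifnot(inherits(field, "phasor_field"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  g <- field$g[field$valid]
  s <- field$s[field$valid]
  keep <- g >= g_range[1] & g <= g_range[2] & s >= s_range[1] & s <= s_range[2]
  g <- g[keep]; s <- s[keep]
  g_edges <- seq(g_range[1], g_range[2], length.out = n_bins + 1L)
  s_edges <- seq(s_range[1], s_range[2], length.out = n_bins + 1L)
  gi <- pmin(findInterval(g, g_edges, rightmost.closed = TRUE), n_bins)
  si <- pmin(findInterval(s, s_edges, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  if (length(gi) > 0L) {
    tab <- table(factor(gi, levels = seq_len(n_bins)),
                 factor(si, levels = seq_len(n_bins)))
    counts <- matrix(as.integer(tab), n_bins, n_bins)
  }
  structure(list(counts = counts, g_edges = g_edges, s_edges = s_edges),
            class = "phasor_histogram")
}
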