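#' Angular modulation frequency of a pulsed laser
#'
#' Converts a repetition rate in MHz to the angular frequency used by the
#' phasor transform, in rad/ns, optionally at a higher harmonic.
#'
#' @param rep_rate Laser repetition rate in MHz (80 for the instrument
#'   emulated here).
#' @param harmonic Positive integer harmonic of the repetition rate.
#' @return Angular frequency in rad/ns.
#' @examples
#' phasor_omega(80) # 2*pi*0.08
#' @export
phasor_omega <- function(rep_rate, harmonic = 1L) {
  stopifnot(rep_rate > 0, harmonic >= 1)
  2 * pi * harmonic * rep_rate / 1000
}

#' Closed-form phasor of a mono-exponential decay
#'
#' A decay with a single lifetime maps onto the universal semicircle:
#' g = 1/(1 + (omega*tau)^2), s = omega*tau/(1 + (omega*tau)^2), so that
#' (g - 1/2)^2 + s^2 = 1/4. A zero lifetime (coherent SHG-like signal)
#' maps to (1, 0); the long-lifetime limit approaches the origin.
#'
#' @param tau Lifetime in ns, `tau >= 0`. Vectorized.
#' @param omega Angular frequency in rad/ns (see [phasor_omega()]).
#' @return List with numeric components `g` and `s`.
#' @examples
#' mono_exp_phasor(0, phasor_omega(80))    # (1, 0)
#' mono_exp_phasor(2.23, phasor_omega(80)) # ~(0.443, 0.497)
#' @export
mono_exp_phasor <- function(tau, omega) {
  stopifnot(all(tau >= 0), omega > 0)
  wt <- omega * tau
  d <- 1 + wt^2
  list(g = 1 / d, s = wt / d)
}

new_phasor_field <- function(g, s, intensity, valid, omega, harmonic,
                             calibrated, pixel_size = NA_real_,
                             channel = NA_character_) {
  structure(
    list(g = g, s = s, intensity = intensity, valid = valid,
         omega = omega, harmonic = as.integer(harmonic),
         calibrated = isTRUE(calibrated), pixel_size = pixel_size,
         channel = channel),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf(
    "<phasor_field> %d x %d px, omega = %.4f rad/ns (harmonic %d), %s\n",
    nrow(x$g), ncol(x$g), x$omega, x$harmonic,
    if (x$calibrated) "calibrated" else "uncalibrated"))
  cat(sprintf("  valid pixels: %d / %d\n", sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Transform a decay stack into phasor space
#'
#' Maps each pixel's photon-count decay histogram to its first-harmonic
#' (or higher) Fourier coordinates: for a pixel with counts c(t) over bin
#' centers t and total N > 0,
#' `g = sum(c * cos(omega*t))/N`, `s = sum(c * sin(omega*t))/N`.
#' Pixels with no photons are marked invalid and carry NA coordinates.
#' The result is uncalibrated: instrument response and electronics delay
#' still rotate and demodulate it (see [calibration_from_reference()]).
#'
#' @param stack A [decay_stack()].
#' @param harmonic Positive integer; harmonics above 1 are accepted but
#'   experimental (all defaults elsewhere assume harmonic 1).
#' @return A `phasor_field` with per-pixel `g`, `s`, `intensity` (photon
#'   totals), a validity mask, and the angular frequency `omega`.
#' @export
phasor_transform <- function(stack, harmonic = 1L) {
  stopifnot(inherits(stack, "decay_stack"))
  if (harmonic < 1) stop("harmonic must be a positive integer", call. = FALSE)
  dims <- dim(stack$counts)
  nb <- dims[3]
  t_centers <- (seq_len(nb) - 0.5) * stack$bin_width
  omega <- phasor_omega(stack$rep_rate, harmonic)
  cm <- matrix(stack$counts, nrow = dims[1] * dims[2], ncol = nb)
  n <- rowSums(cm)
  g <- as.vector(cm %*% cos(omega * t_centers)) / n
  s <- as.vector(cm %*% sin(omega * t_centers)) / n
  valid <- n > 0
  g[!valid] <- NA_real_
  s[!valid] <- NA_real_
  shape <- dims[1:2]
  new_phasor_field(
    g = matrix(g, shape[1], shape[2]),
    s = matrix(s, shape[1], shape[2]),
    intensity = matrix(n, shape[1], shape[2]),
    valid = matrix(valid, shape[1], shape[2]),
    omega = omega, harmonic = harmonic, calibrated = FALSE,
    pixel_size = stack$pixel_size, channel = stack$channel
  )
}

#' Intensity-weighted aggregate phasor of a field
#'
#' @param field A `phasor_field`.
#' @return List with `g`, `s`, and `intensity` (total photons aggregated).
#' @export
aggregate_phasor <- function(field, weighted = TRUE) {
  stopifnot(inherits(field, "phasor_field"))
  v <- field$valid
  if (!any(v)) stop("no valid pixels to aggregate", call. = FALSE)
  w <- if (weighted) field$intensity[v] else rep(1, sum(v))
  list(g = stats::weighted.mean(field$g[v], w),
       s = stats::weighted.mean(field$s[v], w),
       intensity = sum(field$intensity[v]))
}

#' Phase lifetime from phasor coordinates
#'
#' `tau_phi = s / (g * omega)`: the lifetime a mono-exponential decay with
#' the same phasor angle would have. For points on the universal semicircle
#' it equals the true lifetime; for mixtures it is an apparent (phase)
#' lifetime. Pixels with `g <= 0` have no finite non-negative phase
#' lifetime and are flagged `NA`, never silently zeroed.
#'
#' @param g,s Phasor coordinates (vectorized).
#' @param omega Angular frequency in rad/ns.
#' @return Phase lifetime(s) in ns, `NA` where undefined.
#' @export
phase_lifetime <- function(g, s, omega) {
  stopifnot(omega > 0)
  out <- s / (g * omega)
  out[!is.na(g) & g <= 0] <- NA_real_
  out
}

#' Modulation lifetime from phasor coordinates
#'
#' `tau_m = (1/omega) * sqrt(1/(g^2 + s^2) - 1)`. On the universal
#' semicircle it equals the phase lifetime; interior points (mixtures)
#' have `tau_m > tau_phi`. Points with modulus > 1 after calibration are
#' unphysical and flagged `NA`.
#'
#' @inheritParams phase_lifetime
#' @return Modulation lifetime(s) in ns, `NA` where undefined.
#' @export
modulation_lifetime <- function(g, s, omega) {
  stopifnot(omega > 0)
  m2 <- g^2 + s^2
  out <- sqrt(pmax(1 / m2 - 1, 0)) / omega
  out[!is.na(m2) & (m2 > 1 + 1e-9 | m2 == 0)] <- NA_real_
  out
}

#' Two-component linear unmixing along a phasor segment
#'
#' The phasor of a mixture of two species lies on the segment joining
#' their individual phasors, at a position set by their intensity
#' fractions (law of linear combination). The point is orthogonally
#' projected onto the segment; the returned fraction is the normalized
#' distance from `end_b`, clipped to \[0, 1\]. The perpendicular residual
#' is returned rather than raised as an error: noisy real mixtures fall
#' slightly off the segment.
#'
#' @param point,end_a,end_b Phasor points: numeric `c(g, s)` or a list
#'   with `g` and `s`.
#' @return List with `fraction` (intensity fraction of `end_a`) and
#'   `residual` (perpendicular distance from the segment line).
#' @export
linear_unmix_two <- function(point, end_a, end_b) {
  as_gs <- function(p) {
    if (is.list(p)) c(p$g, p$s) else as.numeric(p)
  }
  p <- as_gs(point); a <- as_gs(end_a); b <- as_gs(end_b)
  ab <- a - b
  len2 <- sum(ab^2)
  if (len2 < 1e-24) {
    stop("unmixing endpoints are degenerate (coincident)", call. = FALSE)
  }
  t <- sum((p - b) * ab) / len2
  proj <- b + t * ab
  list(fraction = min(max(t, 0), 1),
       residual = sqrt(sum((p - proj)^2)))
}

#' Median-filter the phasor coordinates of a field
#'
#' Reduces per-pixel Poisson phasor noise before cursor selection by
#' median-filtering g and s independently over each pixel's square
#' neighborhood, using valid neighbors only. Intensity and validity are
#' untouched; the filter is off by default throughout the package.
#'
#' @param field A `phasor_field`.
#' @param window Odd window width in pixels; 1 is the identity.
#' @return The filtered `phasor_field`.
#' @export
median_filter_phasor <- function(field, window = 3L) {
  stopifnot(inherits(field, "phasor_field"), window >= 1)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window == 1) return(field)
  h <- (window - 1L) %/% 2L
  nx <- nrow(field$g); ny <- ncol(field$g)
  offs <- expand.grid(dx = -h:h, dy = -h:h)
  shift_one <- function(m, dx, dy) {
    out <- matrix(NA_real_, nx, ny)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
  }
  filt <- function(m) {
    m[!field$valid] <- NA_real_
    neigh <- vapply(seq_len(nrow(offs)),
                    function(i) as.vector(shift_one(m, offs$dx[i], offs$dy[i])),
                    numeric(nx * ny))
    res <- apply(neigh, 1, stats::median, na.rm = TRUE)
    res[is.nan(res)] <- NA_real_
    matrix(res, nx, ny)
  }
  field$g <- filt(field$g)
  field$s <- filt(field$s)
  field$g[!field$valid] <- NA_real_
  field$s[!field$valid] <- NA_real_
  field
}
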