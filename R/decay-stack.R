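#' Time-resolved photon-count image stack
#'
#' The raw FLIM object: a per-pixel histogram of photon arrival times over
#' one laser period, plus the acquisition metadata every downstream stage
#' needs. The period is fixed by the repetition rate, `1000/rep_rate` ns,
#' and must equal `n_bins * bin_width` (relative tolerance 1e-6).
#'
#' @param counts 3D numeric array `(x, y, time bin)` of non-negative
#'   photon counts (numeric expectations are allowed in noise-free mode).
#' @param rep_rate Laser repetition rate in MHz.
#' @param bin_width Width of one time bin in ns. Defaults to
#'   `1000 / (rep_rate * n_bins)`.
#' @param pixel_size Linear pixel size in micrometers.
#' @param channel Emission-channel label (free text, e.g. "shg", "fiber").
#' @return A `decay_stack` object.
#' @export
decay_stack <- function(counts, rep_rate, bin_width = NULL,
                        pixel_size = 0.195, channel = "unknown") {
  stopifnot(is.array(counts), length(dim(counts)) == 3)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (rep_rate <= 0) stop("rep_rate must be positive", call. = FALSE)
  n_bins <- dim(counts)[3]
  period <- 1000 / rep_rate
  if (is.null(bin_width)) bin_width <- period / n_bins
  if (abs(n_bins * bin_width - period) > 1e-6 * period) {
    stop(sprintf(
      "time axis inconsistent: n_bins * bin_width = %.9g ns but period = %.9g ns",
      n_bins * bin_width, period), call. = FALSE)
  }
  structure(
    list(counts = counts, rep_rate = rep_rate, n_bins = as.integer(n_bins),
         bin_width = bin_width, pixel_size = pixel_size, channel = channel),
    class = "decay_stack"
  )
}

#' @export
print.decay_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<decay_stack> %d x %d px, %d bins of %.4g ns (%.4g MHz), channel '%s'\n",
    d[1], d[2], d[3], x$bin_width, x$rep_rate, x$channel))
  cat(sprintf("  total photons: %.4g\n", sum(x$counts)))
  invisible(x)
}

#' Total-intensity image of a decay stack
#'
#' @param stack A [decay_stack()].
#' @return Matrix of per-pixel photon totals.
#' @export
stack_intensity <- function(stack) {
  stopifnot(inherits(stack, "decay_stack"))
  apply(stack$counts, c(1, 2), sum)
}

# Scaled complementary error function exp(z^2) * erfc(z), finite for all
# z >= 0: asymptotic expansion where exp(z^2) itself would overflow.
erfcx_safe <- function(z) {
  out <- numeric(length(z))
  big <- z > 25
  if (any(!big)) out[!big] <- pracma::erfcx(z[!big])
  if (any(big)) {
    zb <- z[big]
    out[big] <- (1 - 0.5 / zb^2 + 0.75 / zb^4) / (zb * sqrt(pi))
  }
  out
}

# Exponentially modified Gaussian: (1/tau) exp(-t/tau) for t>0, convolved
# with a zero-mean Gaussian of sd sigma. Evaluated in two branches to stay
# finite when exp(sigma^2/(2 tau^2)) would overflow (short lifetimes).
emg_density <- function(x, tau, sigma) {
  z <- (sigma / tau - x / sigma) / sqrt(2)
  out <- numeric(length(x))
  pos <- z >= 0
  if (any(pos)) {
    out[pos] <- (0.5 / tau) * exp(-x[pos]^2 / (2 * sigma^2)) *
      erfcx_safe(z[pos])
  }
  if (any(!pos)) {
    out[!pos] <- (0.5 / tau) * exp(sigma^2 / (2 * tau^2) - x[!pos] / tau) *
      pracma::erfc(z[!pos])
  }
  out
}

#' Expected (noise-free) decay histogram of an exponential mixture
#'
#' Computes the expected photon count per time bin for a periodic
#' excitation train: the periodic convolution of a Gaussian instrument
#' response (sd `irf_sigma`, centered at t = 0) with
#' `sum_i a_i (1/tau_i) exp(-t/tau_i)`. A lifetime of exactly 0 denotes an
#' instantaneous, SHG-like component and contributes the (wrapped) IRF
#' shape itself. Amplitudes are intensity fractions: component i
#' contributes a fraction `a_i / sum(a)` of the photons.
#'
#' Bins are evaluated by oversampled midpoint quadrature on a uniform
#' grid over one period and the histogram is normalized so that it sums
#' exactly to `total_counts`.
#'
#' @param components Two-column matrix or list of `(amplitude, lifetime)`
#'   pairs; lifetimes in ns, `>= 0`.
#' @param total_counts Expected total photons (non-negative).
#' @param n_bins Number of time bins (>= 16).
#' @param period Laser period in ns (`1000/rep_rate`).
#' @param irf_sigma Gaussian IRF standard deviation in ns; 0 gives an
#'   ideal delta response at t = 0 (assigned to the first bin).
#' @param oversample Sub-bins per bin for the quadrature.
#' @return Numeric vector of `n_bins` expected counts.
#' @export
expected_decay_histogram <- function(components, total_counts, n_bins,
                                     period, irf_sigma = 0.1,
                                     oversample = 8L) {
  comp <- as_components(components)
  if (n_bins < 16) stop("n_bins must be at least 16", call. = FALSE)
  stopifnot(period > 0, irf_sigma >= 0, total_counts >= 0)
  amps <- comp[, 1]; taus <- comp[, 2]
  if (total_counts > 0 && sum(amps) <= 0) {
    stop("all amplitudes are zero but total_counts > 0", call. = FALSE)
  }
  m <- n_bins * oversample
  tf <- (seq_len(m) - 0.5) * period / m
  mix <- numeric(m)
  for (i in seq_along(amps)) {
    if (amps[i] == 0) next
    tau <- taus[i]
    if (tau == 0) {
      if (irf_sigma <= 0) {
        shape <- numeric(m); shape[1] <- 1
      } else {
        shape <- stats::dnorm(tf, 0, irf_sigma) +
          stats::dnorm(tf - period, 0, irf_sigma) +
          stats::dnorm(tf + period, 0, irf_sigma)
      }
    } else if (irf_sigma <= 0) {
      shape <- exp(-tf / tau)  # wrapped tail is a constant factor
    } else {
      kmax <- min(200L, ceiling(40 * tau / period) + 1L)
      shape <- numeric(m)
      for (k in -1:kmax) shape <- shape + emg_density(tf + k * period, tau, irf_sigma)
    }
    mix <- mix + amps[i] * shape / sum(shape)
  }
  hist <- colSums(matrix(mix, oversample, n_bins))
  tot <- sum(hist)
  if (tot > 0) hist <- hist * (total_counts / tot)
  hist
}

as_components <- function(components) {
  if (is.list(components) && !is.data.frame(components)) {
    components <- do.call(rbind, lapply(components, function(p) as.numeric(p)[1:2]))
  }
  comp <- as.matrix(components)
  if (ncol(comp) != 2) {
    stop("components must be (amplitude, lifetime) pairs", call. = FALSE)
  }
  if (any(comp[, 1] < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (any(comp[, 2] < 0)) stop("lifetimes must be non-negative", call. = FALSE)
  comp
}

#' Simulate one photon-count decay histogram
#'
#' Draws Poisson counts around the expected histogram of
#' [expected_decay_histogram()], or returns the expectation itself in
#' noise-free mode. Deterministic for a fixed seed.
#'
#' @inheritParams expected_decay_histogram
#' @param seed Integer seed; required when `noise = TRUE`.
#' @param noise Logical; `FALSE` returns the noise-free expectation.
#' @return Numeric vector of `n_bins` counts.
#' @examples
#' h <- simulate_decay_histogram(list(c(1, 2.23)), 1e4, 256, 12.5, seed = 1)
#' sum(h)
#' @export
simulate_decay_histogram <- function(components, total_counts, n_bins,
                                     period, irf_sigma = 0.1, seed = NULL,
                                     noise = TRUE, oversample = 8L) {
  expect <- expected_decay_histogram(components, total_counts, n_bins,
                                     period, irf_sigma, oversample)
  if (!noise) return(expect)
  if (is.null(seed)) stop("seed is required for Poisson sampling", call. = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  stats::rpois(n_bins, expect)
}

#' Simulate a spatially uniform mono-exponential reference stack
#'
#' Emulates the calibration measurement: a uniform field of a reference
#' fluorophore of known mono-exponential lifetime (e.g. a coumarin
#' solution), acquired with the same laser and time axis as the samples.
#' The reference lifetime is always a parameter, never a constant.
#'
#' @param tau_ref Reference lifetime in ns; must be positive (an SHG-like
#'   zero-lifetime signal cannot serve as a fluorescent reference).
#' @param total_counts Expected photons aggregated over the whole field.
#' @param image_size `c(nx, ny)` in pixels; small fields suffice.
#' @param rep_rate Repetition rate in MHz.
#' @param n_bins Time bins per period.
#' @param irf_sigma Gaussian IRF sd in ns.
#' @param pixel_size Micrometers per pixel.
#' @param seed Integer seed (required with noise).
#' @param noise Poisson noise on/off.
#' @return A [decay_stack()] with channel `"reference"`.
#' @export
simulate_reference <- function(tau_ref, total_counts = 1e6,
                               image_size = c(32, 32), rep_rate = 80,
                               n_bins = 256, irf_sigma = 0.1,
                               pixel_size = 0.195, seed = NULL,
                               noise = TRUE) {
  if (tau_ref <= 0) {
    stop("tau_ref must be positive: the calibration reference must fluoresce",
         call. = FALSE)
  }
  period <- 1000 / rep_rate
  npx <- prod(image_size)
  expect <- expected_decay_histogram(list(c(1, tau_ref)),
                                     total_counts / npx, n_bins, period,
                                     irf_sigma)
  if (noise) {
    if (is.null(seed)) stop("seed is required for Poisson sampling", call. = FALSE)
    set.seed(as.integer(seed %% .Machine$integer.max))
    counts <- stats::rpois(npx * n_bins, rep(expect, each = npx))
  } else {
    counts <- rep(expect, each = npx)
  }
  decay_stack(array(counts, c(image_size[1], image_size[2], n_bins)),
              rep_rate = rep_rate, pixel_size = pixel_size,
              channel = "reference")
}
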