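# Shared fixtures, built in code at test time.

PERIOD_80MHZ <- 12.5 # ns
OMEGA_80MHZ <- phasor_omega(80)

# Single-pixel decay stack for a mono-exponential (or mixture) decay.
mono_stack <- function(tau, total = 1e6, n_bins = 256, irf_sigma = 0.1,
                       noise = FALSE, seed = 1, rep_rate = 80) {
  comps <- if (is.list(tau)) tau else list(c(1, tau))
  h <- simulate_decay_histogram(comps, total, n_bins, 1000 / rep_rate,
                                irf_sigma, seed = seed, noise = noise)
  decay_stack(array(h, c(1, 1, n_bins)), rep_rate = rep_rate)
}

# Calibration derived from a noise-free reference under the same IRF.
test_calibration <- function(tau_ref = 2.5, irf_sigma = 0.1, n_bins = 256,
                             rep_rate = 80) {
  ref <- simulate_reference(tau_ref, 1e6, image_size = c(4, 4),
                            rep_rate = rep_rate, n_bins = n_bins,
                            irf_sigma = irf_sigma, noise = FALSE)
  calibration_from_reference(phasor_transform(ref), tau_ref)
}

# Calibrated phasor point of a single decay histogram.
calibrated_point <- function(tau, total = 1e6, irf_sigma = 0.1,
                             noise = FALSE, seed = 1, cal = NULL) {
  st <- mono_stack(tau, total, irf_sigma = irf_sigma, noise = noise,
                   seed = seed)
  if (is.null(cal)) cal <- test_calibration(irf_sigma = irf_sigma)
  f <- apply_calibration(phasor_transform(st), cal)
  list(g = f$g[1, 1], s = f$s[1, 1])
}

# Hand-built phasor field from explicit g/s/intensity matrices.
make_field <- function(g, s, intensity = NULL, omega = OMEGA_80MHZ,
                       calibrated = TRUE) {
  if (is.null(intensity)) intensity <- matrix(1, nrow(g), ncol(g))
  valid <- intensity > 0 & !is.na(g)
  phasorFLIM:::new_phasor_field(g, s, intensity, valid, omega, 1L, calibrated)
}

# Brute-force Wilcoxon signed-rank two-sided p by enumerating all 2^n
# sign assignments; the independent oracle for the exact test.
brute_force_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  list(statistic = w_obs, p.value = min(1, 2 * min(lower, upper)))
}
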