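test_that("mono_exp_phasor matches the closed form and the semicircle law", {
  p0 <- mono_exp_phasor(0, OMEGA_80MHZ)
  expect_equal(c(p0$g, p0$s), c(1, 0))
  pinf <- mono_exp_phasor(1e9, OMEGA_80MHZ)
  expect_lt(abs(pinf$g), 1e-10)
  expect_lt(abs(pinf$s), 1e-6)
  p <- mono_exp_phasor(2.23, OMEGA_80MHZ)
  expect_equal(p$g, 0.4431716, tolerance = 1e-6)
  expect_equal(p$s, 0.4967600, tolerance = 1e-6)
  taus <- c(0.1, 0.5, 1, 2.23, 5, 10)
  sc <- mono_exp_phasor(taus, OMEGA_80MHZ)
  expect_equal((sc$g - 0.5)^2 + sc$s^2, rep(0.25, length(taus)),
               tolerance = 1e-12)
})

test_that("phasor_transform reproduces limiting histograms", {
  # everything in the first bin (t ~ 0) -> (1, 0)
  h <- numeric(256); h[1] <- 1e4
  f <- phasor_transform(decay_stack(array(h, c(1, 1, 256)), 80))
  expect_lt(abs(f$g[1, 1] - 1), 1e-3)
  expect_lt(abs(f$s[1, 1]), 0.02)
  # uniform histogram over the period -> (0, 0), full-period sums vanish
  fu <- phasor_transform(decay_stack(array(rep(1, 256), c(1, 1, 256)), 80))
  expect_lt(abs(fu$g[1, 1]), 1e-12)
  expect_lt(abs(fu$s[1, 1]), 1e-12)
})

test_that("phasor of a sampled 1.5 ns decay matches the closed form within discretization error", {
  st <- mono_stack(1.5, irf_sigma = 0, noise = FALSE)
  f <- phasor_transform(st)
  expect_equal(f$g[1, 1], 0.6375562, tolerance = 1e-3)
  expect_equal(f$s[1, 1], 0.4807060, tolerance = 1e-3)
})

test_that("phasor linearity: summed stacks give the intensity-weighted mean phasor", {
  a <- mono_stack(0.8, total = 3e5, noise = FALSE)
  b <- mono_stack(3.1, total = 7e5, noise = FALSE)
  ab <- decay_stack(a$counts + b$counts, rep_rate = 80)
  fa <- phasor_transform(a); fb <- phasor_transform(b)
  fab <- phasor_transform(ab)
  wa <- sum(a$counts); wb <- sum(b$counts)
  expect_equal(fab$g[1, 1],
               (wa * fa$g[1, 1] + wb * fb$g[1, 1]) / (wa + wb),
               tolerance = 1e-12)
  expect_equal(fab$s[1, 1],
               (wa * fa$s[1, 1] + wb * fb$s[1, 1]) / (wa + wb),
               tolerance = 1e-12)
})

test_that("zero-count pixels are invalid and harmonics are validated", {
  counts <- array(0, c(2, 1, 64))
  counts[1, 1, ] <- 1
  f <- phasor_transform(decay_stack(counts, 80))
  expect_true(f$valid[1, 1])
  expect_false(f$valid[2, 1])
  expect_true(is.na(f$g[2, 1]))
  expect_error(phasor_transform(decay_stack(counts, 80), harmonic = 0),
               "harmonic")
})

test_that("phase and modulation lifetimes invert the closed form", {
  expect_equal(phase_lifetime(1, 0, OMEGA_80MHZ), 0)
  expect_equal(phase_lifetime(0.4431716, 0.4967600, OMEGA_80MHZ), 2.23,
               tolerance = 1e-6)
  expect_equal(phase_lifetime(0.6375562, 0.4807060, OMEGA_80MHZ), 1.5,
               tolerance = 1e-6)
  expect_true(is.na(phase_lifetime(-0.1, 0.3, OMEGA_80MHZ)))
  expect_equal(modulation_lifetime(1, 0, OMEGA_80MHZ), 0)
  p <- mono_exp_phasor(1.5, OMEGA_80MHZ)
  expect_equal(modulation_lifetime(p$g, p$s, OMEGA_80MHZ), 1.5,
               tolerance = 1e-9)
  # interior point: tau_m > tau_phi
  expect_gt(modulation_lifetime(0.5, 0.25, OMEGA_80MHZ),
            phase_lifetime(0.5, 0.25, OMEGA_80MHZ))
  expect_true(is.na(modulation_lifetime(1.2, 0.3, OMEGA_80MHZ)))
})

test_that("two-component unmixing follows the law of linear combination", {
  a <- mono_exp_phasor(0, OMEGA_80MHZ)
  b <- mono_exp_phasor(2.23, OMEGA_80MHZ)
  expect_equal(linear_unmix_two(a, a, b)$fraction, 1)
  mid <- c((a$g + b$g) / 2, (a$s + b$s) / 2)
  expect_equal(linear_unmix_two(mid, a, b)$fraction, 0.5, tolerance = 1e-12)
  expect_error(linear_unmix_two(mid, a, a), "degenerate")
  # off-segment points report the perpendicular residual
  ab <- c(a$g - b$g, a$s - b$s)
  perp <- c(ab[2], -ab[1]) / sqrt(sum(ab^2))
  off <- linear_unmix_two(mid + 0.1 * perp, a, b)
  expect_equal(off$fraction, 0.5, tolerance = 1e-12)
  expect_equal(off$residual, 0.1, tolerance = 1e-9)
  # and clip fractions beyond the endpoints
  beyond <- linear_unmix_two(c(a$g + ab[1], a$s + ab[2]), a, b)
  expect_equal(beyond$fraction, 1)
})

test_that("a simulated 70:30 SHG/elastin mixture unmixes to its intensity fraction", {
  cal <- test_calibration()
  pt <- calibrated_point(list(c(0.7, 0), c(0.3, 2.23)), cal = cal)
  fr <- linear_unmix_two(pt, mono_exp_phasor(0, OMEGA_80MHZ),
                         mono_exp_phasor(2.23, OMEGA_80MHZ))
  expect_lt(abs(fr$fraction - 0.70), 0.02)
})

test_that("median filtering phasors is the identity at window 1 and removes outliers", {
  g <- matrix(0.5, 5, 5); s <- matrix(0.3, 5, 5)
  f <- make_field(g, s)
  expect_identical(median_filter_phasor(f, 1), f)
  fc <- median_filter_phasor(f, 3)
  expect_equal(fc$g, g)
  expect_equal(fc$s, s)
  g2 <- g; g2[3, 3] <- 0.9
  f2 <- median_filter_phasor(make_field(g2, s), 3)
  expect_equal(f2$g[3, 3], 0.5)
  expect_error(median_filter_phasor(f, 2), "odd")
})
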