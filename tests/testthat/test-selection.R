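test_that("cursor masks select by distance on valid pixels", {
  g <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  s <- matrix(c(0, 0.3, 0.1, 0.02), 2, 2)
  f <- make_field(g, s)
  cur <- phasor_cursor(c(1, 0), radius = 0.05)
  m <- cursor_mask(f, cur)
  expect_identical(m, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  # a cursor covering the whole plane selects exactly the valid mask
  big <- phasor_cursor(c(0, 0), radius = 10)
  expect_identical(cursor_mask(f, big), f$valid)
  # tiny cursor away from any phasor selects nothing
  none <- phasor_cursor(c(-1, -1), radius = 1e-6)
  expect_false(any(cursor_mask(f, none)))
  expect_error(phasor_cursor(c(1, 0), radius = 0), "radius")
})

test_that("cursor selection recovers the SHG ground-truth mask", {
  cfg <- scene_config(list(
    component_spec("collagen_shg", list(c(1, 0)), 800, c(shg = 1),
                   pattern = "curved_fiber", coverage = 0.2)),
    image_size = c(64, 64), seed = 8)
  sim <- simulate_scene(cfg)
  f <- apply_calibration(phasor_transform(sim$stacks$shg),
                         test_calibration())
  m <- cursor_mask(f, phasor_cursor(c(1, 0), radius = 0.05))
  gtm <- sim$ground_truth$component_masks$collagen_shg
  jac <- sum(m & gtm) / sum(m | gtm)
  expect_gte(jac, 0.9)
})

test_that("cursor label assignment partitions the union of cursor masks", {
  g <- matrix(runif(400, -0.1, 1.1), 20, 20)
  s <- matrix(runif(400, 0, 0.6), 20, 20)
  f <- make_field(g, s)
  cursors <- list(phasor_cursor(c(1, 0), 0.3, "shg"),
                  phasor_cursor(c(0.45, 0.5), 0.3, "elastin"),
                  phasor_cursor(c(0.2, 0.2), 0.25, "cells"))
  lab <- assign_cursors(f, cursors)
  masks <- lapply(cursors, function(cur) cursor_mask(f, cur))
  union <- Reduce(`|`, masks)
  expect_identical(lab > 0, union)
  for (i in seq_along(cursors)) {
    sel <- lab == i
    expect_true(all(masks[[i]][sel]))          # labeled => inside own cursor
    d_own <- (g - cursors[[i]]$center[1])^2 + (s - cursors[[i]]$center[2])^2
    for (j in seq_along(cursors)) {            # and no strictly nearer cursor
      if (j == i) next
      d_other <- (g - cursors[[j]]$center[1])^2 + (s - cursors[[j]]$center[2])^2
      expect_true(all(d_own[sel & masks[[j]]] <= d_other[sel & masks[[j]]] + 1e-12))
    }
  }
  # single cursor degenerates to its mask
  lab1 <- assign_cursors(f, cursors[1])
  expect_identical(lab1 > 0, masks[[1]])
  expect_error(assign_cursors(f, list(cursors[[1]], cursors[[1]])), "unique")
})

test_that("exact distance ties go to the first-listed cursor", {
  f <- make_field(matrix(0.5, 1, 1), matrix(0, 1, 1))
  cursors <- list(phasor_cursor(c(0.4, 0), 0.2, "a"),
                  phasor_cursor(c(0.6, 0), 0.2, "b"))
  expect_equal(as.integer(assign_cursors(f, cursors)), 1L)
})

test_that("backmapping tints labeled pixels and grays the rest", {
  int <- matrix(c(1, 2, 3, 4), 2, 2)
  lab <- matrix(c(0L, 0L, 0L, 0L), 2, 2)
  cur <- list(phasor_cursor(c(1, 0), 0.1, "x", color = c(1, 0, 0)))
  rgb0 <- backmap_colormap(int, lab, cur)
  expect_equal(rgb0[, , 1], rgb0[, , 2])
  expect_equal(rgb0[, , 2], rgb0[, , 3])
  lab2 <- matrix(1L, 2, 2)
  rgb1 <- backmap_colormap(matrix(4, 2, 2), lab2, cur)
  expect_true(all(rgb1[, , 1] == 1) && all(rgb1[, , 2] == 0))
})

test_that("region centroids are intensity-weighted means with a phase lifetime", {
  g <- matrix(c(1, 0), 1, 2); s <- matrix(0, 1, 2)
  f <- make_field(g, s)
  fp <- region_centroid(f, matrix(TRUE, 1, 2))
  expect_equal(unname(fp$centroid), c(0.5, 0))
  one <- region_centroid(f, matrix(c(TRUE, FALSE), 1, 2))
  expect_equal(unname(one$centroid), c(1, 0))
  expect_equal(one$n_pixels, 1L)
  expect_error(region_centroid(f, matrix(FALSE, 1, 2)), "no valid pixels")
  # weighting follows intensity
  fw <- make_field(g, s, intensity = matrix(c(3, 1), 1, 2))
  expect_equal(unname(region_centroid(fw, matrix(TRUE, 1, 2))$centroid[1]),
               0.75)
  # centroid of any region stays inside the convex hull of its phasors
  set.seed(4)
  gr <- matrix(runif(64, 0.2, 0.8), 8, 8)
  sr <- matrix(runif(64, 0.1, 0.5), 8, 8)
  fr <- make_field(gr, sr, intensity = matrix(rpois(64, 50), 8, 8))
  fp2 <- region_centroid(fr, matrix(TRUE, 8, 8))
  expect_true(fp2$centroid[["g"]] >= min(gr) && fp2$centroid[["g"]] <= max(gr))
  expect_true(fp2$centroid[["s"]] >= min(sr) && fp2$centroid[["s"]] <= max(sr))
})

test_that("cumulative phasor histograms are intensity-weighted and additive", {
  f <- make_field(matrix(0.5, 1, 1), matrix(0.2, 1, 1),
                  intensity = matrix(7, 1, 1))
  h1 <- cumulative_phasor(f, bins = 50)
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(sum(h1$counts), 7)
  h2 <- cumulative_phasor(list(f, f), bins = 50)
  expect_equal(h2$counts, 2 * h1$counts)
  f2 <- make_field(matrix(0.5, 1, 1), matrix(0.2, 1, 1))
  f2$omega <- phasor_omega(40)
  expect_error(cumulative_phasor(list(f, f2)), "omega")
  fu <- make_field(matrix(0.5, 1, 1), matrix(0.2, 1, 1), calibrated = FALSE)
  expect_error(cumulative_phasor(list(f, fu)), "calibrated")
})
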