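bg_only <- function(seed = 1, size = c(32, 32)) {
  scene_config(list(
    component_spec("background", list(c(1, 1)), 5,
                   c(fiber = 1), pattern = "uniform")),
    image_size = size, seed = seed)
}

test_that("a background-only scene is uniformly labeled", {
  gt <- make_label_map(bg_only())
  expect_true(all(gt$label_map == 1L))
  expect_true(all(gt$component_masks$background))
  expect_equal(unname(gt$true_areas["background"]), 32 * 32 * 0.195^2)
})

test_that("label maps and stacks are deterministic in (config, seed)", {
  cfg <- healthy_scene_config(seed = 99, image_size = c(48, 48))
  expect_identical(make_label_map(cfg)$label_map,
                   make_label_map(cfg)$label_map)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$stacks$shg$counts, s2$stacks$shg$counts)
  expect_identical(s1$stacks$fiber$counts, s2$stacks$fiber$counts)
})

test_that("curved-fiber coverage hits its target and ground truth is consistent", {
  cfg <- scene_config(list(
    component_spec("elastin", list(c(1, 2.2)), 50, c(fiber = 1),
                   pattern = "curved_fiber", coverage = 0.2)),
    image_size = c(256, 256), seed = 3)
  gt <- make_label_map(cfg)
  frac <- sum(gt$component_masks$elastin) / (256 * 256)
  expect_lt(abs(frac - 0.2), 0.05)
  # masks disjoint, areas = pixel count * pixel_size^2 exactly
  expect_equal(unname(gt$true_areas["elastin"]),
               sum(gt$component_masks$elastin) * cfg$pixel_size^2)
  overlap <- Reduce(`+`, lapply(gt$component_masks, function(m) m * 1))
  expect_true(all(overlap <= 1))
})

test_that("patterns that cannot fit raise an error naming the component", {
  cfg <- scene_config(list(
    component_spec("rbc", list(c(1, 0.2)), 10, c(nadph = 1),
                   pattern = "disc", coverage = 0.2)),
    image_size = c(4, 4), seed = 1)
  expect_error(make_label_map(cfg), "rbc")
})

test_that("an SHG-only scene sits at (1, 0) after calibration", {
  cfg <- scene_config(list(
    component_spec("collagen_shg", list(c(1, 0)), 500, c(shg = 1),
                   pattern = "curved_fiber", coverage = 0.25)),
    image_size = c(48, 48), seed = 12)
  sim <- simulate_scene(cfg)
  cal <- test_calibration()
  f <- apply_calibration(phasor_transform(sim$stacks$shg), cal)
  fib <- sim$ground_truth$component_masks$collagen_shg & f$valid
  d <- sqrt((f$g[fib] - 1)^2 + f$s[fib]^2)
  expect_gt(mean(d <= 0.05), 0.9)
  agg <- region_centroid(f, sim$ground_truth$component_masks$collagen_shg)
  expect_lt(abs(agg$centroid[["g"]] - 1), 0.01)
  expect_lt(abs(agg$centroid[["s"]]), 0.01)
})

test_that("a zero-count scene yields an all-invalid phasor field", {
  cfg <- scene_config(list(
    component_spec("background", list(c(1, 1)), 0, c(fiber = 1),
                   pattern = "uniform")),
    image_size = c(8, 8), seed = 1)
  sim <- simulate_scene(cfg)
  expect_true(all(sim$stacks$fiber$counts == 0))
  f <- phasor_transform(sim$stacks$fiber)
  expect_false(any(f$valid))
})

test_that("an elastin-only scene recovers its 2.23 ns lifetime", {
  cfg <- scene_config(list(
    component_spec("elastin", list(c(1, 2.23)), 400, c(fiber = 1),
                   pattern = "curved_fiber", coverage = 0.25)),
    image_size = c(48, 48), seed = 21)
  sim <- simulate_scene(cfg)
  f <- apply_calibration(phasor_transform(sim$stacks$fiber),
                         test_calibration())
  fp <- region_centroid(f, sim$ground_truth$component_masks$elastin)
  expect_lt(abs(fp$mean_tau_phi - 2.23), 0.05)
})

test_that("component specs validate their invariants", {
  expect_error(component_spec("elastin", list(c(0.5, 1), c(0.4, 2)), 10,
                              c(fiber = 1)), "sum to 1")
  expect_error(component_spec("elastin", list(c(1, 2)), -1, c(fiber = 1)),
               "mean_counts")
  expect_error(component_spec("elastin", list(c(1, 2)), 1, c(2)),
               "named")
  expect_error(component_spec("nonsense", list(c(1, 2)), 1, c(fiber = 1)))
  expect_error(scene_config(list(), seed = 1), "non-empty")
  cfg <- bg_only()
  expect_error(scene_config(cfg$components, n_bins = 8, seed = 1))
})
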