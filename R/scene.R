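component_labels <- c("elastin", "collagen_shg", "collagen_fluo",
                      "nadph_cells", "rbc", "lipopigment", "background")

#' Specify one tissue component of a synthetic scene
#'
#' A component couples a spatial pattern with a fluorescence decay model
#' and per-channel brightness. Lifetimes are `(amplitude, lifetime)`
#' pairs whose amplitude (intensity) fractions sum to 1; a lifetime of 0
#' denotes an instantaneous SHG-like signal.
#'
#' @param label One of `r paste(component_labels, collapse = " | ")`.
#' @param lifetimes List of `(amplitude fraction, lifetime ns)` pairs or a
#'   two-column matrix.
#' @param mean_counts Expected photons per pixel of the component in its
#'   brightest channel (weight 1).
#' @param channel_weights Named numeric vector in \[0, 1\]: relative
#'   intensity of this component in each emission channel.
#' @param pattern One of `curved_fiber`, `blob`, `disc`, `uniform`.
#' @param coverage Target fraction of the image covered (ignored for
#'   `uniform`).
#' @return A `component_spec`.
#' @export
component_spec <- function(label, lifetimes, mean_counts, channel_weights,
                           pattern = c("curved_fiber", "blob", "disc", "uniform"),
                           coverage = 0.1) {
  pattern <- match.arg(pattern)
  label <- match.arg(label, component_labels)
  lt <- as_components(lifetimes)
  if (abs(sum(lt[, 1]) - 1) > 1e-9) {
    stop(sprintf("amplitude fractions of '%s' must sum to 1", label),
         call. = FALSE)
  }
  if (mean_counts < 0) stop("mean_counts must be non-negative", call. = FALSE)
  if (is.null(names(channel_weights)) || any(!nzchar(names(channel_weights)))) {
    stop("channel_weights must be a named vector", call. = FALSE)
  }
  if (any(channel_weights < 0 | channel_weights > 1)) {
    stop("channel_weights must lie in [0, 1]", call. = FALSE)
  }
  if (pattern != "uniform" && (coverage <= 0 || coverage > 1)) {
    stop("coverage must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(label = label, lifetimes = lt, mean_counts = mean_counts,
         channel_weights = channel_weights, pattern = pattern,
         coverage = coverage),
    class = "component_spec"
  )
}

#' Configure a synthetic tissue scene
#'
#' @param components List of [component_spec()]s; later components
#'   overwrite earlier ones where patterns overlap (draw order layering).
#' @param image_size `c(nx, ny)` pixels.
#' @param pixel_size Micrometers per pixel (0.195 emulates a 100 um field
#'   of view at 512 px).
#' @param rep_rate Laser repetition rate in MHz.
#' @param n_bins Time bins per period (>= 16).
#' @param irf_sigma Gaussian IRF sd in ns.
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return A `scene_config`.
#' @export
scene_config <- function(components, image_size = c(128, 128),
                         pixel_size = 0.195, rep_rate = 80, n_bins = 256,
                         irf_sigma = 0.1, seed) {
  if (missing(seed)) stop("scene_config requires an explicit seed", call. = FALSE)
  stopifnot(n_bins >= 16, rep_rate > 0, pixel_size > 0, irf_sigma >= 0,
            length(image_size) == 2, all(image_size >= 1))
  if (!length(components) || !all(vapply(components, inherits, TRUE, "component_spec"))) {
    stop("components must be a non-empty list of component_spec objects",
         call. = FALSE)
  }
  structure(
    list(components = components, image_size = as.integer(image_size),
         pixel_size = pixel_size, rep_rate = rep_rate,
         n_bins = as.integer(n_bins), irf_sigma = irf_sigma,
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

# --- spatial pattern generators (RNG state set by the caller) ----------

pattern_curved_fiber <- function(dims, coverage) {
  nx <- dims[1]; ny <- dims[2]
  mask <- matrix(FALSE, nx, ny)
  width <- max(1L, round(min(dims) / 100))
  wo <- as.matrix(expand.grid(dx = -width:width, dy = -width:width))
  wo <- wo[wo[, 1]^2 + wo[, 2]^2 <= width^2 + 0.5, , drop = FALSE]
  target <- coverage * nx * ny
  for (f in seq_len(500)) {
    if (sum(mask) >= target) break
    x <- stats::runif(1, 1, nx); y <- stats::runif(1, 1, ny)
    ang <- stats::runif(1, 0, 2 * pi)
    nsteps <- round(stats::runif(1, 0.5, 1.5) * min(dims))
    for (i in seq_len(nsteps)) {
      ang <- ang + stats::rnorm(1, 0, 0.15)
      x <- x + cos(ang); y <- y + sin(ang)
      if (x < 1 || x > nx || y < 1 || y > ny) break
      px <- pmin(pmax(round(x) + wo[, 1], 1L), nx)
      py <- pmin(pmax(round(y) + wo[, 2], 1L), ny)
      mask[cbind(px, py)] <- TRUE
    }
  }
  mask
}

pattern_blob <- function(dims, coverage) {
  noise <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
  sm <- as.matrix(EBImage::gblur(EBImage::Image(noise),
                                 sigma = max(2, min(dims) / 32)))
  sm >= stats::quantile(sm, 1 - coverage)
}

pattern_disc <- function(dims, coverage) {
  nx <- dims[1]; ny <- dims[2]
  mask <- matrix(FALSE, nx, ny)
  r0 <- max(2, min(dims) / 24)
  target <- coverage * nx * ny
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (i in seq_len(500)) {
    if (sum(mask) >= target) break
    cx <- stats::runif(1, 1, nx); cy <- stats::runif(1, 1, ny)
    r <- stats::runif(1, 0.5 * r0, 1.5 * r0)
    mask <- mask | ((xg - cx)^2 + (yg - cy)^2 <= r^2)
  }
  mask
}

#' Build the component label map and ground truth of a scene
#'
#' Places each component's spatial pattern in list order; where patterns
#' overlap, the later component overwrites the earlier one (last wins).
#' Curved fibers are dilated correlated random walks, blobs are smoothed
#' thresholded noise, discs are random circles, and `uniform` covers the
#' whole frame (used for background). Deterministic for a fixed seed.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `ground_truth` object: integer `label_map` (0 = none of the
#'   listed components), per-label logical `component_masks` (mutually
#'   disjoint), `true_areas` in um^2 (pixel count times `pixel_size^2`),
#'   and `true_lifetimes` (each component's amplitude/lifetime table).
#' @export
make_label_map <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scene_config"))
  dims <- config$image_size
  labels <- vapply(config$components, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("component labels must be unique within a scene", call. = FALSE)
  }
  label_map <- matrix(0L, dims[1], dims[2])
  for (i in seq_along(config$components)) {
    comp <- config$components[[i]]
    if (comp$pattern != "uniform" && min(dims) < 8) {
      stop(sprintf("image %dx%d too small to place pattern for component '%s'",
                   dims[1], dims[2], comp$label), call. = FALSE)
    }
    set.seed(derive_seed(seed, paste0("labelmap/", comp$label)))
    mask <- switch(comp$pattern,
      uniform = matrix(TRUE, dims[1], dims[2]),
      curved_fiber = pattern_curved_fiber(dims, comp$coverage),
      blob = pattern_blob(dims, comp$coverage),
      disc = pattern_disc(dims, comp$coverage)
    )
    label_map[mask] <- i
  }
  masks <- lapply(seq_along(labels), function(i) label_map == i)
  names(masks) <- labels
  areas <- vapply(masks, sum, 0) * config$pixel_size^2
  structure(
    list(label_map = label_map, labels = labels, component_masks = masks,
         true_areas = areas,
         true_lifetimes = lapply(config$components, `[[`, "lifetimes"),
         pixel_size = config$pixel_size),
    class = "ground_truth"
  )
}

#' Simulate a tissue scene into per-channel decay stacks
#'
#' Composes the label map with per-component decay histograms: every
#' pixel of component i in channel c has expected histogram
#' `mean_counts_i * weight_ic * shape_i`, with Poisson photon noise
#' (or the expectation itself in noise-free mode). Channels are the union
#' of all components' channel-weight names.
#'
#' @param config A [scene_config()].
#' @param noise Poisson noise on/off.
#' @param ground_truth Optionally reuse an existing [make_label_map()]
#'   result for this config.
#' @return List with `stacks` (named list of [decay_stack()], one per
#'   channel) and `ground_truth`.
#' @export
simulate_scene <- function(config, noise = TRUE, ground_truth = NULL) {
  stopifnot(inherits(config, "scene_config"))
  gt <- if (is.null(ground_truth)) make_label_map(config) else ground_truth
  dims <- config$image_size
  n_bins <- config$n_bins
  period <- 1000 / config$rep_rate
  channels <- unique(unlist(lapply(config$components,
                                   function(cp) names(cp$channel_weights))))
  shapes <- lapply(config$components, function(cp) {
    expected_decay_histogram(cp$lifetimes, 1, n_bins, period, config$irf_sigma)
  })
  stacks <- list()
  for (ch in channels) {
    counts <- array(0, c(dims[1], dims[2], n_bins))
    for (i in seq_along(config$components)) {
      cp <- config$components[[i]]
      w <- cp$channel_weights[ch]
      if (is.na(w)) w <- 0
      idx <- which(gt$label_map == i)
      expect_tot <- cp$mean_counts * w
      if (!length(idx) || expect_tot == 0) next
      expect <- shapes[[i]] * expect_tot
      if (noise) {
        set.seed(derive_seed(config$seed, paste0("scene/", ch, "/", cp$label)))
        vals <- stats::rpois(length(idx) * n_bins, rep(expect, each = length(idx)))
      } else {
        vals <- rep(expect, each = length(idx))
      }
      lin <- rep(idx, times = n_bins) +
        (rep(seq_len(n_bins), each = length(idx)) - 1L) * prod(dims)
      counts[lin] <- vals
    }
    stacks[[ch]] <- decay_stack(counts, rep_rate = config$rep_rate,
                                pixel_size = config$pixel_size, channel = ch)
  }
  list(stacks = stacks, ground_truth = gt)
}

#' Default component palettes for healthy-like and tumor-like scenes
#'
#' `healthy_scene_config()` emulates a balanced fiber network: collagen
#' (strong SHG, zero lifetime) and elastin fibers in comparable amounts,
#' NAD(P)H-rich cells, red blood cells and lipopigments.
#' `tumor_scene_config()` emulates elastosis: abundant elastin with a
#' slightly longer lifetime, sparse collagen, no red blood cells.
#' Elastin's strong fluorescence leaks into the SHG-filter channel
#' (channel weight 0.3), reproducing the long-lifetime contamination of
#' the SHG channel that distinguishes tumor frames.
#'
#' Channels: `"shg"` (405/10-like), `"fiber"` (505/90-like fiber
#' fluorescence), `"nadph"` (450/50-like).
#'
#' @param seed Integer seed.
#' @param image_size `c(nx, ny)` pixels.
#' @param elastin_tau Elastin mono-exponential lifetime in ns.
#' @param elastin_coverage,collagen_coverage Target area fractions.
#' @param rbc_coverage Red-blood-cell coverage (0 in tumor scenes).
#' @param ... Passed on to [scene_config()].
#' @return A [scene_config()].
#' @export
healthy_scene_config <- function(seed, image_size = c(128, 128),
                                 elastin_tau = 2.23,
                                 elastin_coverage = 0.12,
                                 collagen_coverage = 0.12,
                                 rbc_coverage = 0.04, ...) {
  comps <- list(
    component_spec("background", list(c(1, 1.0)), mean_counts = 1,
                   channel_weights = c(shg = 1, fiber = 1, nadph = 1),
                   pattern = "uniform"),
    component_spec("nadph_cells", list(c(0.7, 0.4), c(0.3, 3.2)),
                   mean_counts = 40,
                   channel_weights = c(nadph = 1, fiber = 0.12, shg = 0.02),
                   pattern = "blob", coverage = 0.2),
    component_spec("lipopigment", list(c(1, 0.6)), mean_counts = 60,
                   channel_weights = c(nadph = 0.8, fiber = 0.2),
                   pattern = "blob", coverage = 0.02),
    component_spec("elastin", list(c(1, elastin_tau)), mean_counts = 90,
                   channel_weights = c(fiber = 1, shg = 0.3, nadph = 0.3),
                   pattern = "curved_fiber", coverage = elastin_coverage),
    component_spec("collagen_shg", list(c(1, 0)), mean_counts = 130,
                   channel_weights = c(shg = 1, fiber = 0.04),
                   pattern = "curved_fiber", coverage = collagen_coverage)
  )
  if (rbc_coverage > 0) {
    comps <- c(comps, list(
      component_spec("rbc", list(c(1, 0.2)), mean_counts = 50,
                     channel_weights = c(nadph = 1),
                     pattern = "disc", coverage = rbc_coverage)))
  }
  scene_config(comps, image_size = image_size, seed = seed, ...)
}

#' @rdname healthy_scene_config
#' @export
tumor_scene_config <- function(seed, image_size = c(128, 128),
                               elastin_tau = 2.31,
                               elastin_coverage = 0.20,
                               collagen_coverage = 0.03, ...) {
  healthy_scene_config(seed = seed, image_size = image_size,
                       elastin_tau = elastin_tau,
                       elastin_coverage = elastin_coverage,
                       collagen_coverage = collagen_coverage,
                       rbc_coverage = 0, ...)
}
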