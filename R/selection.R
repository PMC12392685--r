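#' Circular phasor cursor
#'
#' A cursor selects the lifetime population inside a circle of the phasor
#' plot; its color is used when the selection is mapped back onto the
#' intensity image.
#'
#' @param center `c(g, s)` center of the cursor.
#' @param radius Cursor radius (dimensionless, > 0).
#' @param label Population name (must be unique within a cursor set).
#' @param color RGB triple in \[0, 1\] or any R color name.
#' @return A `phasor_cursor`.
#' @export
phasor_cursor <- function(center, radius = 0.05, label = "population",
                          color = "red") {
  center <- as.numeric(center)
  stopifnot(length(center) == 2, all(is.finite(center)))
  if (!is.numeric(radius) || radius <= 0) {
    stop("cursor radius must be positive", call. = FALSE)
  }
  rgb <- if (is.character(color)) as.vector(grDevices::col2rgb(color)) / 255
         else as.numeric(color)
  stopifnot(length(rgb) == 3, all(rgb >= 0 & rgb <= 1))
  structure(list(center = center, radius = radius, label = label,
                 color = rgb),
            class = "phasor_cursor")
}

#' Pixels of a field selected by one cursor
#'
#' @param field A calibrated `phasor_field`.
#' @param cursor A [phasor_cursor()].
#' @return Logical matrix: valid pixels whose phasor lies inside the
#'   cursor circle (boundary included).
#' @export
cursor_mask <- function(field, cursor) {
  stopifnot(inherits(field, "phasor_field"), inherits(cursor, "phasor_cursor"))
  if (!field$calibrated) {
    warning("selecting on an uncalibrated phasor field", call. = FALSE)
  }
  d2 <- (field$g - cursor$center[1])^2 + (field$s - cursor$center[2])^2
  m <- field$valid & !is.na(d2) & d2 <= cursor$radius^2
  m[is.na(m)] <- FALSE
  m
}

#' Label image from a set of cursors
#'
#' Every valid pixel falling inside at least one cursor receives the
#' label of the nearest cursor center (exact ties go to the earlier
#' cursor in the list); pixels inside no cursor stay unlabeled (0).
#'
#' @param field A calibrated `phasor_field`.
#' @param cursors List of [phasor_cursor()]s with unique labels.
#' @return Integer matrix of cursor indices (0 = unlabeled) with the
#'   cursor labels attached as attribute `"labels"`.
#' @export
assign_cursors <- function(field, cursors) {
  stopifnot(inherits(field, "phasor_field"), length(cursors) >= 1)
  labels <- vapply(cursors, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("cursor labels must be unique", call. = FALSE)
  }
  npx <- length(field$g)
  d2 <- vapply(cursors, function(cur) {
    as.vector((field$g - cur$center[1])^2 + (field$s - cur$center[2])^2)
  }, numeric(npx))
  d2 <- matrix(d2, nrow = npx)
  inside <- sweep(d2, 2, vapply(cursors, function(cur) cur$radius^2, 0), "<=")
  d2[!inside | is.na(inside)] <- Inf
  lab <- max.col(-d2, ties.method = "first")
  lab[!as.vector(field$valid) | !is.finite(d2[cbind(seq_len(npx), lab)])] <- 0L
  out <- matrix(as.integer(lab), nrow(field$g), ncol(field$g))
  attr(out, "labels") <- labels
  out
}

#' Color-code an intensity image by cursor labels
#'
#' Labeled pixels are tinted with their cursor's color, scaled by the
#' max-normalized intensity; unlabeled pixels are rendered in grayscale.
#'
#' @param intensity Non-negative intensity matrix.
#' @param labels Integer label matrix from [assign_cursors()] (same shape).
#' @param cursors The cursor list that produced `labels`.
#' @return Numeric array `(x, y, 3)` of RGB values in \[0, 1\].
#' @export
backmap_colormap <- function(intensity, labels, cursors) {
  stopifnot(all(dim(intensity) == dim(labels)))
  mx <- max(intensity)
  v <- if (mx > 0) intensity / mx else intensity
  out <- array(rep(v, 3), c(dim(v), 3))
  for (i in seq_along(cursors)) {
    sel <- labels == i
    if (!any(sel)) next
    for (k in 1:3) {
      plane <- out[, , k]
      plane[sel] <- v[sel] * cursors[[i]]$color[k]
      out[, , k] <- plane
    }
  }
  out
}

#' Phasor fingerprint of a segmented region
#'
#' The centroid (intensity-weighted mean phasor) of the region's valid
#' pixels, the phase lifetime at that centroid, and the pixel count:
#' the region's optical signature.
#'
#' @param field A `phasor_field`.
#' @param mask Logical matrix selecting the region.
#' @param label Name carried into the result.
#' @param weighted Intensity-weighted centroid (default) or unweighted.
#' @return A `phasor_fingerprint`: `label`, `centroid` (`c(g, s)`),
#'   `mean_tau_phi` (ns), `n_pixels`.
#' @export
region_centroid <- function(field, mask, label = "region", weighted = TRUE) {
  stopifnot(inherits(field, "phasor_field"), all(dim(mask) == dim(field$g)))
  sel <- mask & field$valid
  if (!any(sel)) {
    stop(sprintf("region '%s' has no valid pixels", label), call. = FALSE)
  }
  w <- if (weighted) field$intensity[sel] else rep(1, sum(sel))
  cg <- stats::weighted.mean(field$g[sel], w)
  cs <- stats::weighted.mean(field$s[sel], w)
  structure(
    list(label = label, centroid = c(g = cg, s = cs),
         mean_tau_phi = phase_lifetime(cg, cs, field$omega),
         n_pixels = sum(sel)),
    class = "phasor_fingerprint"
  )
}

#' @export
print.phasor_fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> '%s': (g, s) = (%.4f, %.4f), tau_phi = %.3f ns, n = %d\n",
              x$label, x$centroid[1], x$centroid[2], x$mean_tau_phi, x$n_pixels))
  invisible(x)
}

#' Cumulative intensity-weighted phasor histogram
#'
#' Accumulates the phasors of one or more fields (e.g. all frames of a
#' patient region) into a 2D histogram over the phasor plane. The total
#' histogram weight equals the summed intensity of all valid pixels;
#' phasors outside the plot window are clamped into the edge bins so no
#' photons are dropped. Additive under list concatenation.
#'
#' @param fields A `phasor_field` or list of them, sharing `omega` and
#'   calibration state.
#' @param bins Number of bins per axis.
#' @param g_range,s_range Plot window; defaults frame the universal
#'   semicircle.
#' @return A `phasor_histogram`: `counts` matrix (g by s), bin `g_mid`
#'   and `s_mid` centers, `omega`.
#' @export
cumulative_phasor <- function(fields, bins = 200,
                              g_range = c(-0.1, 1.1), s_range = c(-0.1, 0.7)) {
  if (inherits(fields, "phasor_field")) fields <- list(fields)
  stopifnot(length(fields) >= 1,
            all(vapply(fields, inherits, TRUE, "phasor_field")))
  omega <- fields[[1]]$omega
  calib <- fields[[1]]$calibrated
  for (f in fields) {
    if (abs(f$omega - omega) > 1e-9 * omega) {
      stop("cumulative phasor over mixed omega is not meaningful", call. = FALSE)
    }
    if (!identical(f$calibrated, calib)) {
      stop("fields mix calibrated and uncalibrated phasors", call. = FALSE)
    }
  }
  h <- matrix(0, bins, bins)
  for (f in fields) {
    v <- f$valid
    if (!any(v)) next
    gi <- pmin(pmax(ceiling((f$g[v] - g_range[1]) / diff(g_range) * bins), 1), bins)
    si <- pmin(pmax(ceiling((f$s[v] - s_range[1]) / diff(s_range) * bins), 1), bins)
    agg <- rowsum(f$intensity[v], (si - 1L) * bins + gi)
    lin <- as.integer(rownames(agg))
    h[lin] <- h[lin] + agg[, 1]
  }
  structure(
    list(counts = h,
         g_mid = g_range[1] + (seq_len(bins) - 0.5) * diff(g_range) / bins,
         s_mid = s_range[1] + (seq_len(bins) - 0.5) * diff(s_range) / bins,
         omega = omega),
    class = "phasor_histogram"
  )
}
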