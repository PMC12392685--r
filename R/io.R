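#' Write a decay stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float page per time bin. TIFF pages store values scaled
#' into \[0, 1\] by `counts_scale` (the maximum count), recorded in the
#' sidecar together with the acquisition metadata; integer count stacks
#' round-trip bit-identically.
#'
#' @param stack A [decay_stack()].
#' @param path Output TIFF path.
#' @param sidecar Output JSON path (default `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_decay_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "decay_stack"))
  scale <- max(stack$counts, 1)
  pages <- lapply(seq_len(stack$n_bins),
                  function(k) stack$counts[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    rep_rate_mhz = stack$rep_rate, n_bins = stack$n_bins,
    bin_width_ns = stack$bin_width, pixel_size_um = stack$pixel_size,
    channel = stack$channel, counts_scale = scale,
    integer_counts = all(stack$counts == round(stack$counts))
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decay stack written by [write_decay_stack()]
#'
#' @param path Multi-page TIFF path.
#' @param sidecar JSON sidecar path; the metadata is mandatory.
#' @return A [decay_stack()].
#' @export
read_decay_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) {
    stop(sprintf(
      "sidecar '%s' not found: decay stacks need rep_rate/bin metadata",
      sidecar), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_bins) {
    stop(sprintf("TIFF has %d pages but sidecar declares n_bins = %d",
                 length(pages), meta$n_bins), call. = FALSE)
  }
  counts <- array(unlist(pages), c(dim(pages[[1]]), length(pages))) *
    meta$counts_scale
  if (isTRUE(meta$integer_counts)) counts <- round(counts)
  decay_stack(counts, rep_rate = meta$rep_rate_mhz,
              bin_width = meta$bin_width_ns,
              pixel_size = meta$pixel_size_um, channel = meta$channel)
}

#' Write a ground-truth label map and area table
#'
#' The label map goes to a single-page TIFF (labels scaled by 1/255 so
#' up to 255 components round-trip exactly in 8 bits); the per-component
#' areas to CSV.
#'
#' @param gt A ground truth from [make_label_map()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(gt$label_map / 255, file.path(dir, "labels.tif"),
                  bits.per.sample = 8L)
  utils::write.csv(
    data.frame(label = gt$labels,
               area_um2 = as.numeric(gt$true_areas),
               n_pixels = as.integer(gt$true_areas / gt$pixel_size^2)),
    file.path(dir, "areas.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read and write cursor sets as YAML
#'
#' @param cursors List of [phasor_cursor()]s.
#' @param path YAML file path.
#' @return `write_cursors()` returns `path` invisibly; `read_cursors()`
#'   the cursor list.
#' @export
write_cursors <- function(cursors, path) {
  yaml::write_yaml(lapply(cursors, function(cur) {
    list(label = cur$label, g = cur$center[1], s = cur$center[2],
         radius = cur$radius, color = as.numeric(cur$color))
  }), path)
  invisible(path)
}

#' @rdname write_cursors
#' @export
read_cursors <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    phasor_cursor(c(x$g, x$s), radius = x$radius, label = x$label,
                  color = unlist(x$color))
  })
}

#' Export a phasor field as TIFF images plus JSON metadata
#'
#' Writes a two-page TIFF of the g and s coordinates (affinely mapped to
#' \[0, 1\] over \[-1.5, 1.5\]), an intensity TIFF scaled by its maximum,
#' and a JSON file with omega, harmonic, calibration state and scaling.
#'
#' @param field A `phasor_field`.
#' @param prefix Output path prefix; writes `<prefix>_gs.tif`,
#'   `<prefix>_intensity.tif`, `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_phasor_field <- function(field, prefix) {
  stopifnot(inherits(field, "phasor_field"))
  enc <- function(m) {
    m[!field$valid] <- -1.5
    pmin(pmax((m + 1.5) / 3, 0), 1)
  }
  tiff::writeTIFF(list(enc(field$g), enc(field$s)),
                  paste0(prefix, "_gs.tif"), bits.per.sample = 32L)
  imax <- max(field$intensity, 1)
  tiff::writeTIFF(field$intensity / imax, paste0(prefix, "_intensity.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(omega_rad_per_ns = field$omega, harmonic = field$harmonic,
         calibrated = field$calibrated, gs_offset = 1.5, gs_scale = 3,
         intensity_scale = imax, channel = field$channel),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
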