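#' Segment fibers from an intensity image
#'
#' Thresholds an intensity image to separate bright fibrous structures
#' from the dimmer cellular background, then drops objects smaller than
#' `min_object_px` (8-connectivity). The default threshold is Otsu's
#' method; `"fixed:<value>"` applies a fixed cutoff for regression use.
#' Deterministic.
#'
#' @param image Non-negative intensity matrix.
#' @param method `"otsu"` or `"fixed:<value>"`.
#' @param min_object_px Minimum connected-object size kept, in pixels.
#' @return Logical fiber mask.
#' @export
segment_fibers <- function(image, method = "otsu", min_object_px = 0L) {
  stopifnot(is.matrix(image))
  if (any(image < 0)) stop("intensity image must be non-negative", call. = FALSE)
  if (identical(method, "otsu")) {
    rng <- range(image)
    if (diff(rng) == 0) {
      stop("cannot Otsu-threshold a constant image: no threshold separates it",
           call. = FALSE)
    }
    norm <- (image - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > thr
  } else if (startsWith(method, "fixed:")) {
    thr <- suppressWarnings(as.numeric(sub("^fixed:", "", method)))
    if (is.na(thr)) stop("fixed threshold must be 'fixed:<value>'", call. = FALSE)
    mask <- image > thr
  } else {
    stop(sprintf("unknown segmentation method '%s'", method), call. = FALSE)
  }
  if (min_object_px > 0 && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_object_px)
    mask <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Physical area of a mask
#'
#' @param mask Logical matrix.
#' @param pixel_size Linear pixel size in micrometers (> 0).
#' @return Area in um^2: pixel count times `pixel_size^2`.
#' @export
area_um2 <- function(mask, pixel_size) {
  stopifnot(pixel_size > 0)
  sum(mask) * pixel_size^2
}

#' Elastin/Collagen Index
#'
#' `ECI = (E - C) / (E + C)` over the segmented elastin and collagen
#' areas of one field of view. The difference in the numerator captures
#' the imbalance between the two fiber types and the sum in the
#' denominator normalizes it, so the index always lies in \[-1, +1\]:
#' 0 for a balanced network, +1 for pure elastin (elastosis), -1 for
#' pure collagen. Frames where both areas are zero have no defined
#' index and return `NA` with a warning (callers exclude and count them).
#'
#' @param elastin_area,collagen_area Non-negative areas (any common
#'   unit); vectorized.
#' @return ECI in \[-1, 1\], `NA` where both areas are zero.
#' @examples
#' eci(70, 30) # 0.4
#' @export
eci <- function(elastin_area, collagen_area) {
  stopifnot(all(elastin_area >= 0), all(collagen_area >= 0))
  tot <- elastin_area + collagen_area
  out <- ifelse(tot > 0, (elastin_area - collagen_area) / tot, NA_real_)
  if (anyNA(out)) {
    warning(sprintf("%d frame(s) with no segmented fiber area: ECI undefined",
                    sum(is.na(out))), call. = FALSE)
  }
  out
}

#' Collagen percentage of a field of view
#'
#' @param collagen_area Segmented collagen area.
#' @param fov_area Total field-of-view area (> 0), same unit.
#' @return Percentage `100 * collagen_area / fov_area`.
#' @export
collagen_percentage <- function(collagen_area, fov_area) {
  stopifnot(all(fov_area > 0))
  100 * collagen_area / fov_area
}

#' Integrated density of a region of interest
#'
#' Area (pixel count) times mean gray value, i.e. the plain sum of gray
#' values inside the ROI — the standard ImageJ-style quantity.
#'
#' @param image Intensity matrix.
#' @param roi Logical ROI mask (nonempty).
#' @return Summed intensity over the ROI.
#' @export
integrated_density <- function(image, roi) {
  stopifnot(all(dim(image) == dim(roi)))
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  sum(image[roi])
}

#' Normalize values to their global maximum
#'
#' @param values Non-negative numeric vector with a positive maximum.
#' @return `values / max(values)`, in \[0, 1\].
#' @export
normalize_to_max <- function(values) {
  stopifnot(all(values >= 0))
  mx <- max(values)
  if (mx <= 0) stop("cannot normalize: all values are zero", call. = FALSE)
  values / mx
}

#' Per-frame fiber metrics from paired-channel masks
#'
#' Combines the elastin and collagen fiber masks of one field of view
#' (the two emission channels of the same frame) into the frame's area
#' metrics. Both masks must come from the same FOV; the shared
#' `frame_id` asserts that pairing.
#'
#' @param elastin_mask,collagen_mask Logical masks of the same shape.
#' @param pixel_size Linear pixel size in micrometers.
#' @param frame_id Frame identifier.
#' @return One-row data.frame: `frame_id`, `elastin_area_um2`,
#'   `collagen_area_um2`, `fov_area_um2`, `eci`, `collagen_pct`,
#'   `elastin_pct`.
#' @export
frame_metrics <- function(elastin_mask, collagen_mask, pixel_size,
                          frame_id = "frame") {
  stopifnot(all(dim(elastin_mask) == dim(collagen_mask)))
  e <- area_um2(elastin_mask, pixel_size)
  c_ <- area_um2(collagen_mask, pixel_size)
  fov <- length(elastin_mask) * pixel_size^2
  data.frame(
    frame_id = frame_id,
    elastin_area_um2 = e,
    collagen_area_um2 = c_,
    fov_area_um2 = fov,
    eci = suppressWarnings(eci(e, c_)),
    collagen_pct = collagen_percentage(c_, fov),
    elastin_pct = 100 * e / fov,
    stringsAsFactors = FALSE
  )
}
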