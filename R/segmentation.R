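#' Circular region of interest in phasor space
#'
#' @param center_g,center_s Phasor-plot center coordinates (finite).
#' @param radius Dimensionless radius (> 0).
#' @param label Free-text label (e.g. `"tau_mono_gel"`, `"ROI 1"`).
#' @return A `phasor_roi`.
#' @export
phasor_roi <- function(center_g, center_s, radius, label = "") {
  if (!is.finite(center_g) || !is.finite(center_s)) stop("ROI center must be finite")
  if (radius <= 0) stop("ROI radius must be > 0")
  structure(list(center_g = center_g, center_s = center_s,
                 radius = radius, label = label),
            class = "phasor_roi")
}

#' Remap a phasor-plot ROI to an image mask
#'
#' Pixels whose phasor falls inside the circular ROI are selected, providing
#' segmentation by decay signature: pixels with similar lifetimes cluster in
#' phasor space regardless of where they sit in the image.
#'
#' @param field A `phasor_field` from [phasor_transform()].
#' @param roi A [phasor_roi()].
#' @return A [flim_mask()] carrying the ROI label. An empty mask triggers a
#'   warning, not an error.
#' @export
remap_phasor_roi <- function(field, roi) {
  stopifnot(inherits(field, "phasor_field"), inherits(roi, "phasor_roi"))
  inside <- field$valid & !is.na(field$g) &
    (field$g - roi$center_g)^2 + (field$s - roi$center_s)^2 <= roi$radius^2
  inside[is.na(inside)] <- FALSE
  if (!any(inside)) warning("phasor ROI '", roi$label, "' selects no pixels")
  flim_mask(inside, label = roi$label)
}

#' Brightest-percentile intensity mask
#'
#' Selects the top `top_percent` percent brightest pixels: those with
#' intensity at or above the `(100 - top_percent)` percentile of the image's
#' intensity distribution. Ties at the threshold are all included. This is the
#' intensity-based background-removal threshold applied to co-stain images
#' (top 2% for lipid droplets, top 50% for acidic organelles).
#'
#' @param img An [intensity_image()] or numeric matrix.
#' @param top_percent Percentage in (0, 100].
#' @param label Label for the resulting mask.
#' @return A [flim_mask()].
#' @export
brightest_percentile_mask <- function(img, top_percent, label = "") {
  values <- if (inherits(img, "intensity_image")) img$values else img
  stopifnot(is.matrix(values))
  if (top_percent <= 0 || top_percent > 100) stop("top_percent must be in (0, 100]")
  n <- length(values)
  k <- ceiling(top_percent / 100 * n)
  thresh <- sort(as.numeric(values), decreasing = TRUE)[k]
  flags <- values >= thresh
  if (all(flags) && stats::sd(values) == 0) {
    warning("constant image: all pixels selected")
  }
  flim_mask(flags, label = label)
}

#' Binned lifetime distribution over a mask
#'
#' Histogram of the masked per-pixel lifetimes, normalized to sum 1 (the
#' normalized pixel frequency per lifetime bin).
#'
#' @param lifetime_map 2-D lifetime matrix in ps (NA pixels are dropped).
#' @param mask A [flim_mask()] of the same shape.
#' @param bin_width_ps Lifetime bin width in ps (default 50).
#' @return A `lifetime_distribution`: `bin_centers_ps`, `freq_norm`
#'   (summing to 1), `n_pixels`.
#' @export
lifetime_distribution <- function(lifetime_map, mask, bin_width_ps = 50) {
  stopifnot(is.matrix(lifetime_map), inherits(mask, "flim_mask"))
  if (!identical(dim(lifetime_map), dim(mask$flags))) stop("mask shape mismatch")
  if (bin_width_ps <= 0) stop("bin_width_ps must be > 0")
  vals <- lifetime_map[mask$flags]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("empty mask: no finite lifetimes to bin")
  lo <- floor(min(vals) / bin_width_ps) * bin_width_ps
  hi <- ceiling(max(vals) / bin_width_ps) * bin_width_ps
  if (hi <= lo) hi <- lo + bin_width_ps
  edges <- seq(lo, hi, by = bin_width_ps)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + bin_width_ps)
  idx <- pmin(findInterval(vals, edges, rightmost.closed = TRUE), length(edges) - 1L)
  freq <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_centers_ps = (edges[-length(edges)] + edges[-1]) / 2,
                 freq_norm = freq / sum(freq),
                 n_pixels = length(vals)),
            class = "lifetime_distribution")
}

#' Mean of a lifetime distribution
#'
#' `tau_mean = sum_i tau_i * f_i_norm` over the binned, normalized frequency.
#'
#' @param dist A [lifetime_distribution()].
#' @return Mean lifetime in ps, bounded by the distribution's support.
#' @export
tau_mean <- function(dist) {
  stopifnot(inherits(dist, "lifetime_distribution"))
  sum(dist$bin_centers_ps * dist$freq_norm)
}

#' Fraction of probe-labeled pixels captured by each ROI mask
#'
#' For each ROI, `100 * |probe AND roi| / |probe|` percent. Over a disjoint
#' exhaustive ROI partition the fractions sum to at most 100%.
#'
#' @param probe_mask A non-empty [flim_mask()] of probe-labeled pixels.
#' @param roi_masks A list of [flim_mask()]s of the same shape.
#' @return Named numeric vector of percentages.
#' @export
roi_pixel_fraction <- function(probe_mask, roi_masks) {
  stopifnot(inherits(probe_mask, "flim_mask"))
  n_probe <- sum(probe_mask$flags)
  if (n_probe == 0L) stop("empty probe mask")
  out <- vapply(roi_masks, function(m) {
    stopifnot(inherits(m, "flim_mask"))
    if (!identical(dim(m$flags), dim(probe_mask$flags))) stop("mask shape mismatch")
    100 * sum(probe_mask$flags & m$flags) / n_probe
  }, 0)
  names(out) <- vapply(roi_masks, function(m) m$label, "")
  out
}

#' Normalized co-stain intensity of an ROI
#'
#' Declared interpretation of "emission intensity normalized to the fraction
#' of bright pixels": the ROI's share of total co-stain intensity divided by
#' the ROI's share of bright pixels,
#' \deqn{N(ROI) = \frac{\sum_{p \in ROI} I_p / \sum_p I_p}
#'                     {|bright \cap ROI| / |bright|}.}
#' A uniform image with `ROI = image` gives 1; co-stain concentrated in an
#' ROI holding few bright pixels gives values above 1.
#'
#' @param costain An [intensity_image()] (or matrix) of co-stain intensity.
#' @param roi_mask,bright_mask [flim_mask()]s of the same shape;
#'   `bright_mask` non-empty.
#' @return Non-negative scalar; `NaN` with a warning when
#'   `bright AND roi` is empty (undefined normalization).
#' @export
normalized_roi_intensity <- function(costain, roi_mask, bright_mask) {
  values <- if (inherits(costain, "intensity_image")) costain$values else costain
  stopifnot(is.matrix(values), inherits(roi_mask, "flim_mask"),
            inherits(bright_mask, "flim_mask"))
  if (!identical(dim(values), dim(roi_mask$flags)) ||
      !identical(dim(values), dim(bright_mask$flags))) stop("mask shape mismatch")
  n_bright <- sum(bright_mask$flags)
  if (n_bright == 0L) stop("empty bright mask")
  overlap <- sum(bright_mask$flags & roi_mask$flags)
  intensity_share <- sum(values[roi_mask$flags]) / sum(values)
  if (overlap == 0L) {
    warning("bright mask does not intersect ROI '", roi_mask$label,
            "': normalized intensity undefined")
    return(NaN)
  }
  intensity_share / (overlap / n_bright)
}

#' Aggregate per-cell values as mean and standard error
#'
#' @param per_cell_values Numeric vector, length >= 2.
#' @return List with `mean`, `se` (SD / sqrt(n)), and `n`.
#' @export
aggregate_cells <- function(per_cell_values) {
  x <- as.numeric(per_cell_values)
  if (length(x) < 2L) stop("aggregation requires at least 2 cells")
  list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
}
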