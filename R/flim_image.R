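#' Spectral FLIM image cube
#'
#' Wraps a 4-D array of photon counts indexed `(row, col, spectral_channel,
#' time_bin)` together with its [acquisition_metadata()]. Counts are
#' non-negative integers; the channel and time axes must match the metadata.
#'
#' @param counts 4-D non-negative integer array `(row, col, channel, bin)`.
#' @param meta An `acquisition_metadata` object.
#' @return An object of class `flim_image`.
#' @export
flim_image <- function(counts, meta) {
  stopifnot(inherits(meta, "acquisition_metadata"))
  d <- dim(counts)
  if (length(d) != 4L) stop("counts must be a 4-D array (row, col, channel, bin)")
  if (d[3] != length(meta$channel_centers_nm)) {
    stop("counts channel axis (", d[3], ") does not match metadata (",
         length(meta$channel_centers_nm), " channels)")
  }
  if (d[4] != meta$n_time_bins) {
    stop("counts time axis (", d[4], ") does not match metadata (",
         meta$n_time_bins, " bins)")
  }
  if (anyNA(counts) || min(counts) < 0) stop("counts must be non-negative")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, meta = meta), class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("flim_image: %d x %d px, %d spectral channels, %d time bins, %.4g photons\n",
              d[1], d[2], d[3], d[4], sum(as.numeric(x$counts))))
  invisible(x)
}

#' 2-D intensity image derived from a FLIM cube
#'
#' @param values 2-D non-negative numeric matrix.
#' @param band_nm Length-2 wavelength interval that was integrated (nm).
#' @param provenance Free-text label describing the origin.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(values, band_nm = c(NA_real_, NA_real_),
                            provenance = "") {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (anyNA(values) || min(values) < 0) stop("intensity values must be non-negative")
  structure(list(values = values, band_nm = as.numeric(band_nm),
                 provenance = provenance),
            class = "intensity_image")
}

#' Binary pixel mask
#'
#' @param flags 2-D logical matrix.
#' @param label Free-text label (e.g. `"LD"`, `"ROI 1"`).
#' @return An object of class `flim_mask`.
#' @export
flim_mask <- function(flags, label = "") {
  if (!is.matrix(flags) || !is.logical(flags)) stop("flags must be a logical matrix")
  structure(list(flags = flags, label = label), class = "flim_mask")
}

#' @export
print.flim_mask <- function(x, ...) {
  cat(sprintf("flim_mask '%s': %d / %d pixels\n", x$label,
              sum(x$flags), length(x$flags)))
  invisible(x)
}

# Channel indices whose centers lie inside the closed band; errors if none.
channels_in_band <- function(meta, band_nm) {
  stopifnot(inherits(meta, "acquisition_metadata"), length(band_nm) == 2L)
  band_nm <- sort(as.numeric(band_nm))
  idx <- which(meta$channel_centers_nm >= band_nm[1] &
               meta$channel_centers_nm <= band_nm[2])
  if (length(idx) == 0L) {
    stop(sprintf("band %g-%g nm overlaps no spectral channel center", band_nm[1], band_nm[2]))
  }
  idx
}

#' Integrate a FLIM cube over a spectral band
#'
#' Sums photon counts over all spectral channels whose centers lie inside the
#' closed wavelength interval `band_nm`, preserving the time axis. This is the
#' step that produces e.g. the blue-channel (400--475 nm) or green-channel
#' (540/50 nm) decay image from a full-spectrum acquisition.
#'
#' @param img A `flim_image`.
#' @param band_nm Length-2 wavelength interval (nm).
#' @return A `decay_image`: list with `decays` (3-D array row x col x bin),
#'   `band_nm`, and `meta`. Total photons over the included channels are
#'   conserved.
#' @export
integrate_spectral <- function(img, band_nm) {
  stopifnot(inherits(img, "flim_image"))
  idx <- channels_in_band(img$meta, band_nm)
  d <- dim(img$counts)
  sub <- img$counts[, , idx, , drop = FALSE]
  decays <- apply(sub, c(1, 2, 4), sum)
  structure(list(decays = decays, band_nm = sort(as.numeric(band_nm)),
                 channels = idx, meta = img$meta),
            class = "decay_image")
}

#' Integrate a FLIM cube over a band and all time bins
#'
#' @param img A `flim_image`.
#' @param band_nm Length-2 wavelength interval (nm).
#' @return An [intensity_image()] of total photons per pixel in the band.
#' @export
integrate_time <- function(img, band_nm) {
  stopifnot(inherits(img, "flim_image"))
  idx <- channels_in_band(img$meta, band_nm)
  sub <- img$counts[, , idx, , drop = FALSE]
  values <- apply(sub, c(1, 2), sum)
  intensity_image(values + 0, band_nm = sort(as.numeric(band_nm)),
                  provenance = sprintf("integrate_time %g-%g nm",
                                       min(band_nm), max(band_nm)))
}
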