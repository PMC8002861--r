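#' Acquisition metadata for a spectral FLIM cube
#'
#' Describes the TCSPC timing and the spectral detector geometry of an
#' acquisition. The histogram time window is tied to the laser period:
#' `time_window_s * repetition_rate_hz` must equal 1 (each pulse period is
#' histogrammed in full). The default detector grid is a 16-channel
#' 400--600 nm multiwavelength detector with 12.5 nm bandwidth per channel,
#' centers at `400 + 12.5 * (k + 0.5)` nm for `k = 0..15`.
#'
#' @param repetition_rate_hz Laser pulse repetition frequency in Hz (default
#'   80 MHz, i.e. a 12.5 ns histogram window).
#' @param n_time_bins Number of TCSPC time bins (>= 16).
#' @param channel_centers_nm Strictly increasing spectral channel centers (nm).
#' @param channel_bandwidth_nm Per-channel bandwidth (nm).
#' @param pixel_size_um Lateral pixel size (micrometres); informational.
#' @param time_window_s Histogram span in seconds; defaults to
#'   `1 / repetition_rate_hz` and must match it to 1e-9 relative.
#'
#' @return An object of class `acquisition_metadata`.
#' @export
#' @examples
#' meta <- acquisition_metadata(n_time_bins = 256)
#' angular_frequency(meta) / (2 * pi)  # 80 MHz
acquisition_metadata <- function(repetition_rate_hz = 80e6,
                                 n_time_bins = 256L,
                                 channel_centers_nm = default_channel_centers(),
                                 channel_bandwidth_nm = 12.5,
                                 pixel_size_um = 0.25,
                                 time_window_s = 1 / repetition_rate_hz) {
  stopifnot(is.numeric(repetition_rate_hz), length(repetition_rate_hz) == 1L)
  if (repetition_rate_hz <= 0) stop("repetition_rate_hz must be > 0")
  n_time_bins <- as.integer(n_time_bins)
  if (n_time_bins < 16L) stop("n_time_bins must be >= 16")
  if (abs(time_window_s * repetition_rate_hz - 1) > 1e-9) {
    stop("time_window_s must equal 1/repetition_rate_hz to 1e-9 relative")
  }
  if (length(channel_centers_nm) < 1L || is.unsorted(channel_centers_nm, strictly = TRUE)) {
    stop("channel_centers_nm must be strictly increasing")
  }
  if (channel_bandwidth_nm <= 0) stop("channel_bandwidth_nm must be > 0")
  structure(
    list(
      repetition_rate_hz = as.numeric(repetition_rate_hz),
      time_window_s = as.numeric(time_window_s),
      n_time_bins = n_time_bins,
      channel_centers_nm = as.numeric(channel_centers_nm),
      channel_bandwidth_nm = as.numeric(channel_bandwidth_nm),
      pixel_size_um = as.numeric(pixel_size_um)
    ),
    class = "acquisition_metadata"
  )
}

#' Default 16-channel spectral grid (400--600 nm, 12.5 nm bandwidth)
#'
#' Channel centers at `400 + 12.5 * (k + 0.5)` nm, `k = 0..15`. The detector
#' hardware does not publish exact channel edges; this grid is the package's
#' declared convention.
#'
#' @return Numeric vector of 16 channel centers (nm).
#' @export
default_channel_centers <- function() 400 + 12.5 * (seq_len(16L) - 0.5)

#' Laser angular frequency `omega = 2 * pi * repetition rate`
#'
#' @param meta An `acquisition_metadata` object.
#' @return Angular frequency in rad/s.
#' @export
angular_frequency <- function(meta) {
  stopifnot(inherits(meta, "acquisition_metadata"))
  2 * pi * meta$repetition_rate_hz
}

#' Time-bin centers of the TCSPC histogram
#'
#' Bins are half-open intervals `[k*dt, (k+1)*dt)` with
#' `dt = time_window_s / n_time_bins`; centers sit at `(k + 1/2) * dt`.
#'
#' @param meta An `acquisition_metadata` object.
#' @return Numeric vector of `n_time_bins` bin centers in seconds.
#' @export
time_bin_centers <- function(meta) {
  stopifnot(inherits(meta, "acquisition_metadata"))
  dt <- meta$time_window_s / meta$n_time_bins
  (seq_len(meta$n_time_bins) - 0.5) * dt
}

#' @export
print.acquisition_metadata <- function(x, ...) {
  cat("Spectral FLIM acquisition metadata\n")
  cat(sprintf("  repetition rate : %.6g MHz (window %.4g ns)\n",
              x$repetition_rate_hz / 1e6, x$time_window_s * 1e9))
  cat(sprintf("  time bins       : %d\n", x$n_time_bins))
  cat(sprintf("  spectral grid   : %d channels, %.5g-%.5g nm, bandwidth %.3g nm\n",
              length(x$channel_centers_nm), min(x$channel_centers_nm),
              max(x$channel_centers_nm), x$channel_bandwidth_nm))
  invisible(x)
}
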