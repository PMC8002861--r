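#' Save a spectral FLIM cube to an HDF5 container
#'
#' One self-describing hierarchical file per field of view. Layout:
#' dataset `counts` (32-bit integer, dimensions row x col x channel x bin) and
#' group `meta` holding one dataset per metadata field
#' (`repetition_rate_hz`, `time_window_s`, `n_time_bins`,
#' `channel_centers_nm`, `channel_bandwidth_nm`, `pixel_size_um`).
#' [load_flim_cube()] round-trips counts bit-exactly and float metadata to
#' better than 1e-12 relative.
#'
#' @param img A [flim_image()].
#' @param path Output file path; overwritten if present.
#' @return `path`, invisibly.
#' @export
save_flim_cube <- function(img, path) {
  stopifnot(inherits(img, "flim_image"))
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (isFALSE(ok)) stop("cannot write FLIM cube to '", path, "'")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(img$counts, path, "counts")
  rhdf5::h5createGroup(path, "meta")
  m <- img$meta
  for (f in names(unclass(m))) {
    rhdf5::h5write(m[[f]], path, paste0("meta/", f))
  }
  invisible(path)
}

#' Load a spectral FLIM cube from an HDF5 container
#'
#' Reads a file written by [save_flim_cube()] (or any file following the
#' documented layout) and validates all invariants: presence of every
#' metadata field, non-negative counts, and shape consistency.
#'
#' @param path Path to the container file.
#' @return A [flim_image()].
#' @export
load_flim_cube <- function(path) {
  if (!file.exists(path)) stop("no such FLIM cube file: '", path, "'")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- tryCatch(rhdf5::h5ls(path)$name,
                       error = function(e) stop("malformed FLIM cube file: ", conditionMessage(e)))
  required <- c("counts", "repetition_rate_hz", "time_window_s", "n_time_bins",
                "channel_centers_nm", "channel_bandwidth_nm", "pixel_size_um")
  missing <- setdiff(required, contents)
  if (length(missing) > 0L) {
    stop("FLIM cube file is missing field(s): ", paste(missing, collapse = ", "))
  }
  rd <- function(name) rhdf5::h5read(path, name)
  meta <- acquisition_metadata(
    repetition_rate_hz = as.numeric(rd("meta/repetition_rate_hz")),
    time_window_s = as.numeric(rd("meta/time_window_s")),
    n_time_bins = as.integer(rd("meta/n_time_bins")),
    channel_centers_nm = as.numeric(rd("meta/channel_centers_nm")),
    channel_bandwidth_nm = as.numeric(rd("meta/channel_bandwidth_nm")),
    pixel_size_um = as.numeric(rd("meta/pixel_size_um"))
  )
  counts <- rd("counts")
  if (length(dim(counts)) != 4L) stop("counts dataset is not 4-D")
  if (min(counts) < 0) stop("counts dataset contains negative values")
  flim_image(counts, meta)
}

#' Write a 2-D map as tab-separated text
#'
#' Plain-text output for derived 2-D maps (intensity, lifetime in ps, phasor
#' coordinates). One row of the image per line; `NA` for invalid pixels.
#'
#' @param mat Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat))
  utils::write.table(mat, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 2-D map written by [write_map_tsv()]
#' @param path Input path.
#' @return Numeric matrix.
#' @export
read_map_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write a mask as a plain (P2) PGM image, 0/255
#'
#' @param mask A [flim_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(mask, path) {
  stopifnot(inherits(mask, "flim_mask"))
  f <- mask$flags
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("# %s", mask$label),
               sprintf("%d %d", ncol(f), nrow(f)), "255"), con)
  for (i in seq_len(nrow(f))) {
    writeLines(paste(ifelse(f[i, ], 255L, 0L), collapse = " "), con)
  }
  invisible(path)
}
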