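# Shared fixtures: small metadata objects and independent oracles.

meta_small <- function(n_bins = 64L) acquisition_metadata(n_time_bins = n_bins)
meta_fine <- function() acquisition_metadata(n_time_bins = 4096L)

OMEGA_80MHZ <- 2 * pi * 80e6

# Independent oracle: bin a continuous emission profile by direct numerical
# integration with `sub` sub-steps per time bin (midpoint rule). Never calls
# expected_decay().
oracle_bin_profile <- function(profile_fun, meta, sub = 4000L) {
  nt <- meta$n_time_bins
  dt <- meta$time_window_s / nt
  h <- dt / sub
  t_all <- (seq_len(nt * sub) - 0.5) * h
  v <- profile_fun(t_all) * h
  out <- colSums(matrix(v, nrow = sub))
  out / sum(out)
}

# Independent oracle: phasor of a histogram by direct summation over bin
# centers (same definition, separate code path from phasor_transform's
# matrix product).
oracle_phasor <- function(counts, meta, harmonic = 1) {
  tk <- (seq_along(counts) - 0.5) * meta$time_window_s / length(counts)
  w <- 2 * pi * meta$repetition_rate_hz * harmonic
  c(g = sum(counts * cos(w * tk)) / sum(counts),
    s = sum(counts * sin(w * tk)) / sum(counts))
}

# A tiny deterministic cube: one compartmentless image with given counts
# placed programmatically.
tiny_cube <- function(nr = 4L, nc = 5L, nch = 16L, nt = 64L, fill = 0L) {
  meta <- acquisition_metadata(n_time_bins = nt)
  flim_image(array(fill, c(nr, nc, nch, nt)), meta)
}

small_scene <- function(shape = c(40L, 40L), photons = 2000, seed = 11L,
                        n_bins = 128L) {
  default_scene(shape = shape, n_time_bins = n_bins,
                photons_per_pixel = photons, seed = seed)
}
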