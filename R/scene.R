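#' Compartment specification for a synthetic scene
#'
#' One cellular compartment: its geometry, the decay model emitted in the
#' blue (< 500 nm channel centers) and green (>= 500 nm) halves of the
#' spectrum, its emission spectrum over the detector channels, its relative
#' co-stain brightness in the 575--600 nm band, and its photon budget.
#'
#' @param name One of `"background"`, `"membrane_ring"`, `"cytoplasm"`,
#'   `"lipid_droplet"`, `"acidic_organelle"`.
#' @param geometry A geometry list: `list(type = "full")`,
#'   `list(type = "disc", center = c(r, c), radius = px)`,
#'   `list(type = "ring", center = c(r, c), radius = px, thickness = px)`, or
#'   `list(type = "discs", centers = matrix n x 2, radii = numeric n)`.
#' @param blue_decay,green_decay [decay_mono()]/[decay_biexp()]/[decay_esr()]
#'   models for the two spectral halves.
#' @param emission_spectrum Per-channel relative intensity weights (sum 1).
#' @param costain_intensity Relative co-stain brightness (dimensionless);
#'   multiplied by the scene's co-stain unit photon budget.
#' @param photons_per_pixel Expected total probe photons per pixel (> 0 for
#'   non-background compartments).
#' @return A `compartment_spec`.
#' @export
compartment_spec <- function(name, geometry, blue_decay, green_decay,
                             emission_spectrum, costain_intensity = 0,
                             photons_per_pixel = 0) {
  name <- match.arg(name, c("background", "membrane_ring", "cytoplasm",
                            "lipid_droplet", "acidic_organelle"))
  stopifnot(is.list(geometry), !is.null(geometry$type))
  if (photons_per_pixel > 0) {
    stopifnot(inherits(blue_decay, "decay_model"), inherits(green_decay, "decay_model"))
    if (any(emission_spectrum < 0)) stop("emission spectrum weights must be >= 0")
    if (abs(sum(emission_spectrum) - 1) > 1e-12) stop("emission spectrum must sum to 1")
  }
  if (name != "background" && photons_per_pixel <= 0) {
    stop("photons_per_pixel must be > 0 for non-background compartments")
  }
  if (costain_intensity < 0) stop("costain_intensity must be >= 0")
  structure(list(name = name, geometry = geometry, blue_decay = blue_decay,
                 green_decay = green_decay,
                 emission_spectrum = as.numeric(emission_spectrum),
                 costain_intensity = costain_intensity,
                 photons_per_pixel = photons_per_pixel),
            class = "compartment_spec")
}

#' Scene specification
#'
#' Ordered compartment list over an image grid; later compartments overwrite
#' earlier ones at overlapping pixels, so every pixel ends up with exactly one
#' label.
#'
#' @param image_shape `c(rows, cols)`, both positive.
#' @param compartments List of [compartment_spec()] in overlay order.
#' @param meta An [acquisition_metadata()].
#' @param seed Integer RNG seed for the Poisson draw.
#' @param costain_unit_photons Photon budget corresponding to
#'   `costain_intensity = 1`, emitted in the 575--600 nm channels with a
#'   3 ns mono-exponential decay (the co-stain dyes' own lifetime is not a
#'   measured quantity here; only their intensity is used downstream).
#' @return A `scene_spec`.
#' @export
scene_spec <- function(image_shape, compartments, meta, seed = 1L,
                       costain_unit_photons = NULL) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1))
  stopifnot(inherits(meta, "acquisition_metadata"), length(compartments) >= 1L)
  for (cp in compartments) stopifnot(inherits(cp, "compartment_spec"))
  if (is.null(costain_unit_photons)) {
    ppp <- vapply(compartments, function(cp) cp$photons_per_pixel, 0)
    costain_unit_photons <- max(ppp) / 10
  }
  structure(list(image_shape = as.integer(image_shape),
                 compartments = compartments, meta = meta,
                 seed = as.integer(seed),
                 costain_unit_photons = costain_unit_photons),
            class = "scene_spec")
}

# Rasterize one geometry to a logical matrix.
rasterize_geometry <- function(geom, shape) {
  nr <- shape[1]; nc <- shape[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  switch(geom$type,
    full = matrix(TRUE, nr, nc),
    disc = {
      d2 <- (rr - geom$center[1])^2 + (cc - geom$center[2])^2
      d2 <= geom$radius^2
    },
    ring = {
      d <- sqrt((rr - geom$center[1])^2 + (cc - geom$center[2])^2)
      d <= geom$radius & d > geom$radius - geom$thickness
    },
    discs = {
      m <- matrix(FALSE, nr, nc)
      for (i in seq_len(nrow(geom$centers))) {
        d2 <- (rr - geom$centers[i, 1])^2 + (cc - geom$centers[i, 2])^2
        m <- m | (d2 <= geom$radii[i]^2)
      }
      m
    },
    stop("unknown geometry type: ", geom$type)
  )
}

#' Default PC-12-like scene
#'
#' The stated synthetic world used throughout the tests: a gel-phase plasma
#' membrane ring (mono-exponential 5.0 ns, the tau_mono_gel signature), fluid
#' cytoplasm (mono 4.0 ns, tau_mono_fluid), spherical lipid droplets (mono
#' 3.0 ns ICT emission, tau_mono_low, bright in the 575--600 nm co-stain
#' band at 10:1 contrast), and acidic organelles with a biexponential
#' 0.6 ns + 3.0 ns decay at equal amplitude fractions (amplitude-weighted
#' mean 1800 ps), also co-stain bright. The viscous membrane ring emits a
#' rising excited-state-reaction profile in the green channels
#' (relaxed-state rate 1/3 per ns, LE total rate 1 per ns).
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param n_time_bins TCSPC bins (default 256).
#' @param photons_per_pixel Expected probe photons per pixel in labeled
#'   compartments (default 5000, a typical well-exposed TCSPC budget).
#' @param seed Integer seed.
#' @param n_droplets,n_acidic Number of lipid droplets / acidic organelles.
#' @return A `scene_spec`.
#' @export
default_scene <- function(shape = c(64L, 64L), n_time_bins = 256L,
                          photons_per_pixel = 5000, seed = 1L,
                          n_droplets = 4L, n_acidic = 3L) {
  meta <- acquisition_metadata(n_time_bins = n_time_bins)
  centers <- meta$channel_centers_nm
  gauss_spec <- function(peak_nm, sd_nm) {
    w <- exp(-(centers - peak_nm)^2 / (2 * sd_nm^2))
    w / sum(w)
  }
  nr <- shape[1]; nc <- shape[2]
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  cell_radius <- 0.42 * min(nr, nc)
  # deterministic organelle placement on a ring of positions inside the cell
  ang_d <- 2 * pi * (seq_len(n_droplets) - 1) / n_droplets + 0.4
  drop_centers <- cbind(ctr[1] + 0.55 * cell_radius * cos(ang_d),
                        ctr[2] + 0.55 * cell_radius * sin(ang_d))
  drop_radii <- 3 + (seq_len(n_droplets) - 1) %% 4  # 3..6 px
  ang_a <- 2 * pi * (seq_len(n_acidic) - 1) / n_acidic + 1.9
  acid_centers <- cbind(ctr[1] + 0.3 * cell_radius * cos(ang_a),
                        ctr[2] + 0.3 * cell_radius * sin(ang_a))
  acid_radii <- rep(3, n_acidic)

  esr_green <- decay_esr(rate_LE_per_ns = 0.2, rate_transfer_per_ns = 0.8,
                         rate_R_per_ns = 1 / 3)
  comps <- list(
    compartment_spec("background", list(type = "full"),
                     blue_decay = NULL, green_decay = NULL,
                     emission_spectrum = rep(0, length(centers)),
                     costain_intensity = 0, photons_per_pixel = 0),
    compartment_spec("cytoplasm",
                     list(type = "disc", center = ctr, radius = cell_radius - 3),
                     blue_decay = decay_mono(4.0), green_decay = decay_mono(4.0),
                     emission_spectrum = gauss_spec(450, 30),
                     costain_intensity = 1, photons_per_pixel = photons_per_pixel),
    compartment_spec("membrane_ring",
                     list(type = "ring", center = ctr, radius = cell_radius,
                          thickness = 3),
                     blue_decay = decay_mono(5.0), green_decay = esr_green,
                     emission_spectrum = gauss_spec(440, 25),
                     costain_intensity = 1, photons_per_pixel = photons_per_pixel),
    compartment_spec("lipid_droplet",
                     list(type = "discs", centers = drop_centers,
                          radii = drop_radii),
                     blue_decay = decay_mono(3.0), green_decay = decay_mono(3.0),
                     emission_spectrum = gauss_spec(470, 30),
                     costain_intensity = 10, photons_per_pixel = photons_per_pixel),
    compartment_spec("acidic_organelle",
                     list(type = "discs", centers = acid_centers,
                          radii = acid_radii),
                     blue_decay = decay_biexp(c(0.6, 3.0), c(0.5, 0.5)),
                     green_decay = decay_biexp(c(0.6, 3.0), c(0.5, 0.5)),
                     emission_spectrum = gauss_spec(480, 35),
                     costain_intensity = 10, photons_per_pixel = photons_per_pixel)
  )
  scene_spec(shape, comps, meta, seed = seed)
}

# Expected per-pixel (channel x bin) photon counts for one compartment,
# including its co-stain contribution in the 575-600 nm channels.
expected_pixel_spectrum <- function(spec, comp) {
  meta <- spec$meta
  nch <- length(meta$channel_centers_nm)
  E <- matrix(0, nch, meta$n_time_bins)
  if (comp$photons_per_pixel > 0) {
    blue <- meta$channel_centers_nm < 500
    for (ch in seq_len(nch)) {
      model <- if (blue[ch]) comp$blue_decay else comp$green_decay
      frac <- expected_decay(model, meta, emission = if (blue[ch]) "blue" else "green")
      E[ch, ] <- comp$photons_per_pixel * comp$emission_spectrum[ch] * frac
    }
  }
  if (comp$costain_intensity > 0 && spec$costain_unit_photons > 0) {
    co_ch <- which(meta$channel_centers_nm >= 575 & meta$channel_centers_nm <= 600)
    if (length(co_ch) > 0L) {
      co_frac <- expected_decay(decay_mono(3.0), meta)
      per_ch <- comp$costain_intensity * spec$costain_unit_photons / length(co_ch)
      for (ch in co_ch) E[ch, ] <- E[ch, ] + per_ch * co_frac
    }
  }
  E
}

# Ground-truth mean lifetime (ps) of a compartment's whole-spectrum decay.
true_mean_lifetime_ps <- function(model) {
  if (is.null(model)) return(NA_real_)
  switch(model$kind,
    mono = model$lifetimes_ns * 1000,
    biexp = sum(model$amplitude_fractions * model$lifetimes_ns) * 1000,
    excited_state_reaction = 1000 / (model$rate_LE_per_ns + model$rate_transfer_per_ns)
  )
}

#' Poisson shot-noise draw
#'
#' @param expected Non-negative numeric array of expected counts.
#' @param seed Integer seed (the draw is reproducible for a fixed seed).
#' @return Integer array of the same shape.
#' @export
poissonize <- function(expected, seed) {
  if (anyNA(expected) || min(expected) < 0) stop("expected counts must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  out <- stats::rpois(length(expected), lambda = as.numeric(expected))
  dim(out) <- dim(expected)
  out
}

#' Render a synthetic scene to a FLIM cube with ground truth
#'
#' For every pixel, expected counts are `photons_per_pixel * spectrum
#' weight(channel) * expected decay fraction(bin)`, using the compartment's
#' blue decay for channels with centers below 500 nm and its green decay
#' otherwise, plus the co-stain contribution in the 575--600 nm channels.
#' Observed counts are independent Poisson draws, reproducible for a fixed
#' scene seed.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (a [flim_image()]) and `truth` (a
#'   `ground_truth`: integer `compartment_map` with a `labels` attribute,
#'   `true_lifetime_map` in ps, and per-compartment `true_masks`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  shape <- spec$image_shape
  meta <- spec$meta
  nch <- length(meta$channel_centers_nm)
  nt <- meta$n_time_bins

  label_map <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(spec$compartments)) {
    inside <- rasterize_geometry(spec$compartments[[i]]$geometry, shape)
    label_map[inside] <- i
  }
  if (any(label_map == 0L)) stop("scene does not cover every pixel; add a background compartment first")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  counts <- array(0L, c(shape[1], shape[2], nch, nt))
  true_tau <- matrix(NA_real_, shape[1], shape[2])
  masks <- vector("list", length(spec$compartments))
  for (i in seq_along(spec$compartments)) {
    comp <- spec$compartments[[i]]
    pix <- which(label_map == i)  # column-major pixel indices
    masks[[i]] <- flim_mask(label_map == i, label = comp$name)
    if (length(pix) == 0L) next
    true_tau[pix] <- true_mean_lifetime_ps(comp$blue_decay)
    E <- expected_pixel_spectrum(spec, comp)
    if (sum(E) == 0) next
    draws <- stats::rpois(length(pix) * nch * nt, lambda = rep(as.numeric(E), each = length(pix)))
    draws <- array(draws, c(length(pix), nch, nt))
    for (ch in seq_len(nch)) counts[pix + (ch - 1L) * prod(shape) +
        rep((seq_len(nt) - 1L) * prod(shape) * nch, each = length(pix))] <-
      draws[, ch, ]
  }

  names(masks) <- vapply(spec$compartments, function(cp) cp$name, "")
  truth <- structure(
    list(compartment_map = structure(label_map,
           labels = vapply(spec$compartments, function(cp) cp$name, "")),
         true_lifetime_map = true_tau,
         true_masks = masks),
    class = "ground_truth")
  list(image = flim_image(counts, meta), truth = truth)
}
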