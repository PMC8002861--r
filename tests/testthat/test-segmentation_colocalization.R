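# segmentation_colocalization: phasor-ROI remapping against ground truth,
# percentile masks vs sort oracle, lifetime distributions, coloc statistics

noiseless_two_phase_field <- function(n_bins = 1024L) {
  # 8x8 image: left half tau = 5 ns ("ring"), right half tau = 3 ns
  meta <- acquisition_metadata(n_time_bins = n_bins)
  decays <- array(0, c(8, 8, n_bins))
  for (j in 1:8) {
    tau <- if (j <= 4) 5.0 else 3.0
    f <- expected_decay(decay_mono(tau), meta) * 1e5
    for (i in 1:8) decays[i, j, ] <- f
  }
  list(field = phasor_transform(decays, meta), meta = meta,
       left = outer(rep(TRUE, 8), (1:8) <= 4, "&"))
}

test_that("phasor ROI remapping recovers noiseless compartments exactly", {
  tp <- noiseless_two_phase_field()
  w <- angular_frequency(tp$meta)
  p5 <- monoexp_phasor(5e-9, w)
  roi <- phasor_roi(p5["g"], p5["s"], 0.05, "gel")
  mask <- remap_phasor_roi(tp$field, roi)
  expect_identical(mask$flags, tp$left)

  # whole-plot ROI captures every valid pixel; tiny ROI off-structure warns empty
  all_roi <- phasor_roi(0.5, 0.25, 10, "all")
  expect_true(all(remap_phasor_roi(tp$field, all_roi)$flags == tp$field$valid))
  expect_warning(
    m0 <- remap_phasor_roi(tp$field, phasor_roi(0.9, 0.6, 1e-6, "none")),
    "no pixels")
  expect_equal(sum(m0$flags), 0L)
})

test_that("brightest-percentile mask matches the sort oracle incl. ties", {
  set.seed(12)
  img <- matrix(sample(1e6, 100 * 100), 100, 100)  # distinct values
  m <- brightest_percentile_mask(img, 2)
  expect_equal(sum(m$flags), 200L)
  # oracle: the 200 largest values
  expect_setequal(img[m$flags], sort(as.numeric(img), decreasing = TRUE)[1:200])

  expect_true(all(brightest_percentile_mask(img, 100)$flags))

  # ties at the threshold are all included
  tie <- matrix(c(rep(5, 10), rep(1, 90)), 10, 10)
  mt <- brightest_percentile_mask(tie, 2)
  expect_equal(sum(mt$flags), 10L)

  expect_warning(brightest_percentile_mask(matrix(3, 5, 5), 10), "constant")
  expect_error(brightest_percentile_mask(img, 0), "top_percent")

  # property: cardinality >= ceil(p% of n) for random images and percents
  set.seed(34)
  for (p in c(0.5, 2, 10, 50, 97)) {
    v <- matrix(rpois(400, 50), 20, 20)
    k <- ceiling(p / 100 * 400)
    got <- sum(brightest_percentile_mask(v, p)$flags)
    expect_gte(got, k)  # ties can only add pixels
    thresh <- sort(as.numeric(v), decreasing = TRUE)[k]
    expect_equal(got, sum(v >= thresh))  # and they match the sort oracle
  }
})

test_that("percentile mask on the synthetic LD scene stays inside droplets", {
  sc <- small_scene(shape = c(40L, 40L), photons = 2000, n_bins = 64L)
  r <- render_scene(sc)
  co <- integrate_time(r$image, c(575, 600))
  ld_truth <- r$truth$true_masks[["lipid_droplet"]]$flags |
    r$truth$true_masks[["acidic_organelle"]]$flags  # both are co-stain bright
  m <- brightest_percentile_mask(co, 2)
  expect_true(all(ld_truth[m$flags]))
})

test_that("lifetime distributions normalize, bound tau_mean, and validate", {
  mask_all <- flim_mask(matrix(TRUE, 4, 4))
  d1 <- lifetime_distribution(matrix(3000, 4, 4), mask_all, 50)
  expect_equal(sum(d1$freq_norm), 1)
  expect_equal(tau_mean(d1), 3025)  # single 50-ps bin [3000, 3050) centered 3025

  two <- matrix(rep(c(2900, 3100), 8), 4, 4)
  d2 <- lifetime_distribution(two, mask_all, 50)
  expect_equal(tau_mean(d2), 3000)  # midpoint of the two bin centers (2925, 3075)
  expect_equal(sort(d2$freq_norm[d2$freq_norm > 0]), c(0.5, 0.5))

  expect_error(
    lifetime_distribution(matrix(NA_real_, 4, 4), mask_all, 50), "empty")
  expect_error(
    lifetime_distribution(two, flim_mask(matrix(FALSE, 4, 4)), 50), "empty")

  # property: support bounds for arbitrary maps and bin widths
  set.seed(56)
  for (i in 1:10) {
    vals <- matrix(runif(64, 500, 6000), 8, 8)
    bw <- sample(c(10, 50, 200), 1)
    d <- lifetime_distribution(vals, flim_mask(matrix(TRUE, 8, 8)), bw)
    tm <- tau_mean(d)
    expect_gte(tm, min(vals) - bw)
    expect_lte(tm, max(vals) + bw)
    # binned mean stays within one bin width of the exact mean
    expect_lt(abs(tm - mean(vals)), bw)
  }
})

test_that("ROI pixel fractions behave as set fractions", {
  probe <- flim_mask(matrix(c(rep(TRUE, 40), rep(FALSE, 60)), 10, 10))
  roi1 <- flim_mask(probe$flags, "ROI 1")
  roi2 <- flim_mask(!probe$flags, "ROI 2")
  fr <- roi_pixel_fraction(probe, list(roi1, roi2))
  expect_equal(unname(fr), c(100, 0))
  expect_equal(names(fr), c("ROI 1", "ROI 2"))
  # disjoint exhaustive ROIs sum to exactly 100
  expect_equal(sum(fr), 100)
  expect_error(roi_pixel_fraction(flim_mask(matrix(FALSE, 2, 2)), list(roi1)),
               "empty probe")
})

test_that("normalized co-stain intensity matches the declared formula", {
  uni <- matrix(4, 10, 10)
  whole <- flim_mask(matrix(TRUE, 10, 10))
  expect_equal(normalized_roi_intensity(uni, whole, whole), 1.0)

  # all signal inside an ROI that holds half the bright pixels -> 2.0
  img <- matrix(0, 10, 10)
  img[, 1:2] <- 7
  roi <- flim_mask(outer(rep(TRUE, 10), 1:10 <= 2, "&"))
  bright <- flim_mask(outer(rep(TRUE, 10), 1:10 <= 4, "&"))
  expect_equal(normalized_roi_intensity(img, roi, bright), 2.0)

  # ROI with zero co-stain but some bright pixels -> 0
  roi0 <- flim_mask(outer(rep(TRUE, 10), 1:10 %in% 3:4, "&"))
  expect_equal(normalized_roi_intensity(img, roi0, bright), 0)

  # undefined when the bright mask misses the ROI entirely
  roi_off <- flim_mask(outer(rep(TRUE, 10), 1:10 >= 9, "&"), "off")
  expect_warning(v <- normalized_roi_intensity(img, roi_off, bright), "undefined")
  expect_true(is.nan(v))
})

test_that("aggregate_cells computes mean and SD/sqrt(n)", {
  expect_equal(aggregate_cells(c(3, 3, 3)), list(mean = 3, se = 0, n = 3L))
  expect_equal(aggregate_cells(c(2, 4)), list(mean = 3, se = 1, n = 2L))
  expect_error(aggregate_cells(5), "at least 2")
  set.seed(9)
  draws <- rnorm(25, 2973, 130)
  agg <- aggregate_cells(draws)
  expect_lt(abs(agg$mean - 2973), 3 * 130 / sqrt(25))
})

test_that("synthetic coloc pipeline reproduces the expected orderings", {
  # probe pixels concentrate in the ROI matching the dominant compartment;
  # normalized co-stain intensity peaks in the ROI engineered to colocalize
  sc <- small_scene(shape = c(48L, 48L), photons = 4000, n_bins = 128L)
  r <- render_scene(sc)
  blue <- integrate_spectral(r$image, c(400, 475))
  field <- phasor_transform(blue)
  w <- angular_frequency(r$image$meta)
  rois <- lapply(c(gel = 5, fluid = 4, low = 3), function(tau_ns) {
    p <- monoexp_phasor(tau_ns * 1e-9, w)
    phasor_roi(p["g"], p["s"], 0.05, sprintf("tau %g ns", tau_ns))
  })
  masks <- lapply(rois, function(roi) remap_phasor_roi(field, roi))

  probe <- brightest_percentile_mask(integrate_time(r$image, c(400, 475)), 50)
  fr <- roi_pixel_fraction(probe, masks)
  # cytoplasm dominates the scene: the fluid ROI must capture the most pixels
  expect_equal(which.max(fr), 2L, ignore_attr = TRUE)

  co <- integrate_time(r$image, c(575, 600))
  bright <- brightest_percentile_mask(co, 2)
  norm_int <- vapply(masks, function(m) {
    suppressWarnings(normalized_roi_intensity(co, m, bright))
  }, 0)
  # droplets (tau_mono_low, co-stain 10:1) colocalize with the co-stain
  finite <- is.finite(norm_int)
  expect_equal(names(which.max(norm_int[finite])), "low")
})
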