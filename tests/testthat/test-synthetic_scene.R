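# synthetic_scene: decay-model profiles against integration oracles,
# Poisson noise, deterministic rendering, ground-truth consistency

test_that("decay model constructors validate their fields", {
  expect_error(decay_mono(-1), "> 0")
  expect_error(decay_biexp(c(0.6, 3.0), c(0.3, 0.3)), "sum to 1")
  expect_error(decay_biexp(c(0.6, -3), c(0.5, 0.5)), "> 0")
  expect_error(decay_esr(0.2, 0.8, -1), "rates")
})

test_that("mono expected decay is geometric with ratio exp(-dt/tau)", {
  meta <- acquisition_metadata(n_time_bins = 256L)
  f <- expected_decay(decay_mono(4.0), meta)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_true(all(diff(f) < 0))
  dt <- meta$time_window_s / meta$n_time_bins
  ratios <- f[-1] / f[-length(f)]
  expect_equal(ratios, rep(exp(-dt / 4e-9), length(ratios)), tolerance = 1e-9)
})

test_that("expected decays match the direct numerical-integration oracle", {
  meta <- meta_small(64L)
  cases <- list(
    list(model = decay_mono(5.0),
         fun = function(t) exp(-t / 5e-9)),
    list(model = decay_biexp(c(0.6, 3.0), c(0.5, 0.5)),
         fun = function(t) 0.5 * exp(-t / 0.6e-9) + 0.5 * exp(-t / 3e-9)),
    list(model = decay_biexp(c(0.6, 3.0), c(0.25, 0.75)),
         fun = function(t) 0.25 * exp(-t / 0.6e-9) + 0.75 * exp(-t / 3e-9)),
    list(model = decay_esr(0.2, 0.8, 1 / 3),
         fun = function(t) exp(-t / 3e-9) - exp(-t / 1e-9))
  )
  for (cs in cases) {
    got <- expected_decay(cs$model, meta)
    want <- oracle_bin_profile(cs$fun, meta)
    expect_equal(got, want, tolerance = 1e-7)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_true(all(got >= 0))
  }
})

test_that("biexp intensity fraction of the slow component is a*tau-weighted", {
  # closed form: f_slow = a2*tau2/(a1*tau1 + a2*tau2) = 5/6 for equal
  # amplitudes of 0.6/3.0 ns (before window truncation). Verify on the
  # un-truncated scale by integrating the component profiles over a window
  # long enough that truncation is negligible.
  meta_long <- acquisition_metadata(repetition_rate_hz = 1e6,
                                    n_time_bins = 4096L)  # 1000 ns window
  f_mix <- expected_decay(decay_biexp(c(0.6, 3.0), c(0.5, 0.5)), meta_long)
  f_slow <- expected_decay(decay_mono(3.0), meta_long)
  f_fast <- expected_decay(decay_mono(0.6), meta_long)
  # least-squares mixture weights on the component basis
  w <- coef(lm(f_mix ~ cbind(f_fast, f_slow) - 1))
  expect_equal(as.numeric(w[2] / sum(w)), 5 / 6, tolerance = 1e-6)
})

test_that("excited-state-reaction green profile rises then falls", {
  meta <- acquisition_metadata(n_time_bins = 1024L)
  f <- expected_decay(decay_esr(0.2, 0.8, 1 / 3), meta, emission = "green")
  # starts near zero, non-monotone with an interior maximum at t = ln(3)/(2/3) ns
  expect_lt(f[1], f[2])
  k_max <- which.max(f)
  expect_gt(k_max, 1L)
  t_max <- (k_max - 0.5) * meta$time_window_s / meta$n_time_bins
  expect_equal(t_max, log(3) / (2 / 3) * 1e-9, tolerance = 0.01)
  # blue emission of the same model is mono-exponential with rate 1/ns
  fb <- expected_decay(decay_esr(0.2, 0.8, 1 / 3), meta, emission = "blue")
  expect_equal(fb, expected_decay(decay_mono(1.0), meta), tolerance = 1e-12)
})

test_that("degenerate ESR (equal rates) uses the t*exp(-Gamma t) limit", {
  meta <- meta_small(128L)
  f <- expected_decay(decay_esr(0.5, 0.5, 1.0), meta, emission = "green")
  want <- oracle_bin_profile(function(t) t * exp(-t / 1e-9), meta)
  expect_equal(f, want, tolerance = 1e-7)
})

test_that("poissonize is reproducible, mean-correct, and rejects negatives", {
  expect_error(poissonize(matrix(-1, 2, 2), 1), "non-negative")
  expect_identical(poissonize(matrix(0, 3, 3), 1), matrix(0L, 3, 3))
  expect_identical(poissonize(array(7, c(2, 3, 4)), 42),
                   poissonize(array(7, c(2, 3, 4)), 42))
  draws <- poissonize(rep(1000, 1e4), seed = 9)
  expect_equal(mean(draws), 1000, tolerance = 0.01)
  # poissonize does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(poissonize(1:5, 99)); b <- runif(1)
  expect_identical(a, b)
})

test_that("render_scene is deterministic and covers every pixel exactly once", {
  sc <- small_scene(shape = c(32L, 32L), photons = 500, n_bins = 64L)
  r1 <- render_scene(sc)
  r2 <- render_scene(sc)
  expect_identical(r1$image$counts, r2$image$counts)

  truth <- r1$truth
  expect_true(all(truth$compartment_map >= 1L))
  # masks are pairwise disjoint and jointly exhaustive
  stack <- Reduce(`+`, lapply(truth$true_masks, function(m) m$flags + 0L))
  expect_true(all(stack == 1L))
  # background emits nothing (costain 0 there too)
  bg <- truth$true_masks[["background"]]$flags
  expect_equal(sum(r1$image$counts[which(bg)]), 0)
})

test_that("rendered counts converge to the expected field over seeds", {
  sc <- small_scene(shape = c(16L, 16L), photons = 300, n_bins = 64L)
  # single lipid-droplet pixel: compare mean count over seeds to expectation
  r <- render_scene(sc)
  ld <- which(r$truth$true_masks[["lipid_droplet"]]$flags)[1]
  comp <- sc$compartments[[which(vapply(sc$compartments, `[[`, "", "name") ==
                                 "lipid_droplet")]]
  E <- flimphasor:::expected_pixel_spectrum(sc, comp)
  n_seeds <- 100L
  tot <- 0
  for (s in seq_len(n_seeds)) {
    sc$seed <- s
    tot <- tot + sum(render_scene(sc)$image$counts[ld +
      (seq_len(16 * 64) - 1L) * 16 * 16])
  }
  expected_total <- sum(E)
  se <- sqrt(expected_total / n_seeds)
  expect_lt(abs(tot / n_seeds - expected_total), 3 * se)
})

test_that("co-stain band shows the configured droplet contrast", {
  sc <- small_scene(shape = c(32L, 32L), photons = 2000, n_bins = 64L)
  r <- render_scene(sc)
  co <- integrate_time(r$image, c(575, 600))
  ld <- r$truth$true_masks[["lipid_droplet"]]$flags
  cyto <- r$truth$true_masks[["cytoplasm"]]$flags
  ratio <- mean(co$values[ld]) / mean(co$values[cyto])
  expect_equal(ratio, 10, tolerance = 0.15)  # 10:1 contrast, Poisson noise
})

test_that("scene validation rejects uncovered pixels and bad compartments", {
  meta <- meta_small()
  expect_error(
    compartment_spec("cytoplasm", list(type = "disc", center = c(5, 5), radius = 3),
                     decay_mono(4), decay_mono(4),
                     emission_spectrum = rep(1 / 16, 16), photons_per_pixel = 0),
    "photons_per_pixel")
  onecomp <- compartment_spec("cytoplasm",
    list(type = "disc", center = c(8, 8), radius = 3),
    decay_mono(4), decay_mono(4), rep(1 / 16, 16), 0, 100)
  sc <- scene_spec(c(16L, 16L), list(onecomp), meta)
  expect_error(render_scene(sc), "background")
})
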