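test_that("radial profile localises known spectral content", {
  # constant image: all energy in the lowest (DC) bin
  pr <- radial_amplitude_profile(matrix(0.5, 64, 64), 16)
  expect_gt(pr$amplitudes[1], 0)
  expect_true(all(pr$amplitudes[-1] < 1e-10))
  expect_true(all(diff(pr$bin_centers) > 0))
  # pure horizontal sinusoid, 8-pixel period on a 64-wide image: 8 cycles/width
  x <- matrix(rep(sin(2 * pi * (0:63) / 8), each = 64), 64)
  pr2 <- radial_amplitude_profile(x, 16)
  peak <- which.max(pr2$amplitudes[-1]) + 1
  expect_equal(pr2$bin_centers[peak], 8, tolerance = 1)
  expect_error(radial_amplitude_profile(matrix(0, 4, 4)), "8 x 8")
  expect_error(radial_amplitude_profile(matrix(0, 64, 64), 2), "n_bins")
})

test_that("white-noise spectra are flat away from DC", {
  amps <- withr::with_seed(77, {
    vapply(1:20, function(i) {
      radial_amplitude_profile(matrix(rnorm(100 * 100), 100), 10)$amplitudes
    }, numeric(10))
  })
  m <- rowMeans(amps)[-1]
  expect_true(all(abs(m - mean(m)) / mean(m) < 0.2))
})

test_that("profiles satisfy the Parseval identity", {
  withr::with_seed(5, {
    g <- matrix(runif(48 * 48), 48)
    pr <- radial_amplitude_profile(g, 12)
    total <- sum(Mod(stats::fft(g))^2)
    expect_equal(sum(pr$amplitudes^2 * pr$counts), total,
                 tolerance = 1e-6 * total)
  })
})

test_that("sensitivity spectra reduce to the analytic gradient cases", {
  clf <- mean_pixel_classifier()
  img <- withr::with_seed(2, matrix(runif(32 * 32), 32))
  # constant gradient: DC-only profile
  pr <- sensitivity_spectrum(clf, list(img), n_bins = 8)
  expect_true(all(pr$amplitudes[-1] < 1e-10))
  # averaging over one image equals the single-image profile
  g <- input_gradient(clf, img)
  expect_equal(pr$amplitudes,
               radial_amplitude_profile(g, 8)$amplitudes)
  expect_error(sensitivity_spectrum(structure(list(), class = "thing"),
                                    list(img)),
               "input-gradient")
  expect_error(sensitivity_spectrum(clf, list()), "at least one")
})

test_that("models trained on finer textures have higher sensitivity centroids", {
  # 32x32 desk-scale check: one conv model per texture scale, centroids ordered
  mk <- function(bands, seed) {
    cfg <- synthetic_config("texture", n_per_class = 30, image_size = 32,
                            seed = seed, texture_bands = bands,
                            lesion_radius_range = c(0.28, 0.32))
    ds <- generate_dataset(cfg)
    clf <- build_classifier(classifier_spec("local_pool", input_size = 32,
                                            depth = 2, seed = seed),
                            cfg$class_names)
    clf <- train_classifier(clf, ds,
                            train_config(epochs = 8, learning_rate = 0.02,
                                         batch_size = 16, seed = seed))
    sensitivity_spectrum(clf, lapply(ds[1:20], `[[`, "image"), n_bins = 8)
  }
  lo <- mk(c(1.5, 4), seed = 9)
  hi <- mk(c(6, 14), seed = 9)
  expect_gt(spectral_centroid(hi), spectral_centroid(lo))
})
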