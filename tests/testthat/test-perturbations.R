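test_that("the registry holds 16 corruptions with monotone severity tables", {
  nms <- corruption_names()
  expect_length(nms, 16)
  expect_true(all(c("brightness", "elastic_transform", "jpeg_compression",
                    "gaussian_blur") %in% nms))
  reg <- corruption_registry()
  for (nm in nms) {
    vals <- reg$value[reg$name == nm][order(reg$severity[reg$name == nm])]
    expect_true(all(diff(vals) > 0) || all(diff(vals) < 0),
                info = paste("non-monotone parameter for", nm))
  }
  expect_error(corruption_spec("unknown_noise", 3), "unknown corruption")
  expect_error(corruption_spec("brightness", 6), "severity")
  expect_error(corruption_spec("brightness", 0), "severity")
})

test_that("every corruption maps [0,1] images to [0,1] images of same shape", {
  img <- tiny_shape_dataset(n_per_class = 1)[[1]]$image
  for (nm in corruption_names()) for (s in c(1L, 5L)) {
    out <- corrupt(img, corruption_spec(nm, s), seed = 11)
    expect_identical(dim(out), dim(img))
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
  }
})

test_that("gaussian blur drains high-frequency energy as severity grows", {
  img <- withr::with_seed(8, matrix(runif(64 * 64), 64))
  hi_energy <- function(x) {
    pr <- radial_amplitude_profile(x, 16)
    sum((pr$amplitudes^2 * pr$counts)[pr$bin_centers > 16])  # above half-Nyquist
  }
  e1 <- hi_energy(corrupt(img, corruption_spec("gaussian_blur", 1)))
  e5 <- hi_energy(corrupt(img, corruption_spec("gaussian_blur", 5)))
  expect_lt(e5, e1)
})

test_that("brightness shifts the mean strictly monotonically in severity", {
  img <- matrix(0.5, 32, 32)
  shifts <- vapply(1:5, function(s) {
    mean(corrupt(img, corruption_spec("brightness", s))) - 0.5
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("noise corruptions are reproducible under a seed", {
  img <- matrix(0.5, 32, 32)
  a <- corrupt(img, corruption_spec("gaussian_noise", 3), seed = 42)
  b <- corrupt(img, corruption_spec("gaussian_noise", 3), seed = 42)
  expect_identical(a, b)
})

test_that("translation offsets respect the exact loss-fraction bound", {
  # at 224 pixels and a 7% budget the admissible pure-horizontal shift is
  # |dx| <= 15: enumerate the exact loss fraction over dx
  loss <- function(dx, w = 224) 1 - (w - abs(dx)) / w
  expect_lte(loss(15), 0.07)
  expect_gt(loss(16), 0.07)
  img224 <- matrix(0.5, 224, 224)
  draws <- lapply(1:200, function(i) {
    sample_translation_pair(img224, 0.07, seed = i)
  })
  offs <- do.call(rbind, lapply(draws, function(p) p$offsets))
  expect_lte(max(abs(offs)), 15)
  expect_true(all(unlist(lapply(draws, `[[`, "loss_fractions")) <= 0.07))
})

test_that("zero translation is the identity and loss formula is exact", {
  img <- tiny_shape_dataset(n_per_class = 1)[[1]]$image
  expect_identical(translate_image(img, 0, 0), img)
  shifted <- translate_image(img, 3, -2)
  # surviving pixels are copied exactly, no interpolation
  expect_identical(shifted[1:(64 - 2), 4:64], img[3:64, 1:(64 - 3)])
  expect_true(all(shifted[63:64, ] == 0))
  expect_error(sample_translation_pair(img, 1.0), "max_loss_fraction")
})

test_that("occluder area, containment and edge cases match the contract", {
  img <- matrix(0.5, 64, 64)
  bbox <- c(10, 10, 50, 50)  # 40 x 40 box, area 1600
  expect_identical(occlude(img, bbox, 0, seed = 1), img)
  full <- occlude(img, bbox, 1, seed = 1)
  expect_true(all(full[11:50, 11:50] == 0))
  expect_true(all(full[1:10, ] == 0.5))
  counts <- vapply(1:100, function(i) {
    out <- occlude(img, bbox, 0.30, seed = i)
    changed <- which(out != img, arr.ind = TRUE)
    # never writes outside the box
    expect_true(all(changed[, 1] >= 11 & changed[, 1] <= 50))
    expect_true(all(changed[, 2] >= 11 & changed[, 2] <= 50))
    nrow(changed)
  }, numeric(1))
  expect_true(all(abs(counts - 480) <= 22))  # one row/column of slack
  expect_error(occlude(img, c(10, 10, 70, 50), 0.3), "bbox")
  expect_error(occlude(img, bbox, 1.2), "ratio")
})
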