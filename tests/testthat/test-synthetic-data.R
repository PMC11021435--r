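test_that("generator config rejects invalid parameter sets", {
  expect_error(synthetic_config("speckle"), "arg")
  expect_error(synthetic_config("shape", n_classes = 1), "n_classes")
  expect_error(synthetic_config("shape", image_size = 16), "image_size")
  expect_error(synthetic_config("shape", lesion_radius_range = c(0.3, 0.2)),
               "lesion_radius_range")
  expect_error(
    synthetic_config("shape",
                     shape_harmonics = list(rep(0, 5), c(0.5, 0, 0, 0, 0))),
    "self-intersecting")
  expect_error(
    synthetic_config("shape", lesion_radius_range = c(0.4, 0.45),
                     shape_harmonics = list(rep(0, 5), c(0.3, 0, 0, 0, 0))),
    "cannot fit")
})

test_that("generated datasets have valid masks, tight boxes and folds", {
  cfg <- synthetic_config("shape", n_per_class = 10, seed = 7)
  ds <- generate_dataset(cfg)
  expect_length(ds, 20)
  for (s in ds) {
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_gt(sum(s$mask), 0)
    # brute-force tightness: all foreground inside, all four edges touched
    fg <- which(s$mask != 0, arr.ind = TRUE)
    x <- fg[, 2] - 1; y <- fg[, 1] - 1
    expect_true(all(x >= s$bbox[1] & x < s$bbox[3]))
    expect_true(all(y >= s$bbox[2] & y < s$bbox[4]))
    expect_true(any(x == s$bbox[1]) && any(x == s$bbox[3] - 1))
    expect_true(any(y == s$bbox[2]) && any(y == s$bbox[4] - 1))
  }
  expect_equal(vapply(ds, function(s) s$fold, integer(1)),
               (seq_len(20) - 1L) %% 5L)
  expect_equal(colSums(do.call(rbind, lapply(ds, `[[`, "targets"))),
               c(class_1 = 10, class_2 = 10))
})

test_that("identical configurations reproduce identical datasets", {
  cfg <- synthetic_config("texture", n_per_class = 5, seed = 123)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
})

test_that("harmonic amplitudes control measurable boundary roughness", {
  cfg <- synthetic_config("shape", n_per_class = 25, seed = 99,
                          shape_harmonics = list(rep(0, 5),
                                                 c(0, 0, 0, 0.3, 0)))
  ds <- generate_dataset(cfg)
  cls <- vapply(ds, function(s) which(s$targets == 1), integer(1))
  rough <- vapply(ds, function(s) mask_roughness(s$mask), numeric(1))
  expect_gt(mean(rough[cls == 2]), mean(rough[cls == 1]))
})

test_that("bbox_from_mask is tight and rejects empty masks", {
  m <- matrix(0, 8, 8)
  expect_error(bbox_from_mask(m), "empty")
  m[4, 6] <- 1  # (y, x) = (3, 5) in 0-based coordinates
  expect_equal(unname(bbox_from_mask(m)), c(5, 3, 6, 4))
  expect_equal(unname(bbox_from_mask(matrix(1, 8, 8))), c(0, 0, 8, 8))
})

test_that("binormal prediction generator matches its contracts", {
  expect_error(generate_predictions(100, c(1), seed = 1), "strictly inside")
  expect_error(generate_predictions(100, c(0.8), seed = 1, prevalence = 1.2),
               "prevalence")
  # deterministic positive allocation
  p <- generate_predictions(100, c(0.8, 0.6), seed = 3, prevalence = 0.5)
  expect_equal(unname(colSums(p$targets)), c(50, 50))
  expect_true(all(p$scores >= 0 & p$scores <= 1))
  # chance-level target gives chance-level discrimination
  p0 <- generate_predictions(2000, c(0.5), seed = 5)
  expect_gt(auroc(p0$scores[, 1], p0$targets[, 1]), 0.47)
  expect_lt(auroc(p0$scores[, 1], p0$targets[, 1]), 0.53)
})

test_that("prediction_set validates alignment and ranges", {
  expect_error(prediction_set(matrix(1.2, 2, 1), "a", c("i1", "i2")), "0, 1")
  expect_error(prediction_set(matrix(0.5, 2, 2), "a", c("i1", "i2")),
               "class_names")
  expect_error(prediction_set(matrix(0.5, 2, 1), "a", c("i1", "i2"),
                              targets = matrix(2, 2, 1)), "0/1")
})
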