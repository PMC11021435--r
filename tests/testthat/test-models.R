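test_that("classifier specs validate geometry", {
  expect_error(classifier_spec("local_pool", input_size = 60, depth = 3),
               "divisible")
  expect_error(classifier_spec("global_attn", input_size = 60, patch_size = 8),
               "divisible")
  expect_error(classifier_spec("local_pool", depth = 0), "depth")
  s <- classifier_spec("global_attn", input_size = 64, patch_size = 8)
  clf <- build_classifier(s)
  expect_equal(nrow(clf$params$pos_E), 64)  # an 8x8 grid of patches
})

test_that("building is deterministic and prediction has the right shape", {
  spec <- classifier_spec("local_pool", input_size = 64, n_classes = 2,
                          width = 16, depth = 3, seed = 40)
  a <- build_classifier(spec)
  b <- build_classifier(spec)
  expect_identical(a$params, b$params)
  ds <- tiny_shape_dataset(n_per_class = 3)
  p <- predict(a, ds)
  expect_s3_class(p, "prediction_set")
  expect_equal(dim(p$scores), c(6L, 2L))
  expect_true(all(p$scores >= 0 & p$scores <= 1))
})

test_that("batched and one-at-a-time prediction agree", {
  ds <- tiny_shape_dataset(n_per_class = 4)
  for (fam in c("local_pool", "global_attn")) {
    clf <- build_classifier(classifier_spec(fam, seed = 3),
                            names(ds[[1]]$targets))
    batched <- predict(clf, ds, batch_size = 8)$scores
    single <- do.call(rbind, lapply(ds, function(s) {
      predict(clf, list(s), batch_size = 1)$scores
    }))
    expect_equal(unname(batched), unname(single), tolerance = 1e-5)
  }
})

test_that("backpropagated gradients match numerical differentiation", {
  ns <- asNamespace("lesionbench")
  targets <- matrix(c(1, 0), 1)
  # conv family
  spec <- classifier_spec("local_pool", input_size = 8, n_classes = 2,
                          width = 3, depth = 2, seed = 1)
  clf <- build_classifier(spec)
  X <- withr::with_seed(4, array(runif(64), c(8, 8, 1, 1)))
  lossfn <- function(p) {
    ns$bce_loss_grad(ns$forward_local(p, spec, X)$logits, targets)$loss
  }
  fwd <- ns$forward_local(clf$params, spec, X, keep_cache = TRUE)
  bwd <- ns$backward_local(clf$params, spec, fwd,
                           ns$bce_loss_grad(fwd$logits, targets)$dlogits)
  for (nm in names(clf$params)) {
    for (i in seq_len(min(length(clf$params[[nm]]), 5))) {
      p2 <- clf$params; p2[[nm]][i] <- p2[[nm]][i] + 1e-5
      p3 <- clf$params; p3[[nm]][i] <- p3[[nm]][i] - 1e-5
      expect_equal(bwd$grads[[nm]][i], (lossfn(p2) - lossfn(p3)) / 2e-5,
                   tolerance = 1e-5, info = nm)
    }
  }
  # attention family
  spec2 <- classifier_spec("global_attn", input_size = 8, n_classes = 2,
                           width = 6, depth = 2, patch_size = 4, seed = 2)
  clf2 <- build_classifier(spec2)
  img <- withr::with_seed(5, matrix(runif(64), 8, 8))
  pidx <- ns$patch_index(8L, 4L)
  lossfn2 <- function(p) {
    ns$bce_loss_grad(matrix(ns$forward_attn_single(p, spec2, img, pidx)$logits, 1),
                     targets)$loss
  }
  fwd2 <- ns$forward_attn_single(clf2$params, spec2, img, pidx, keep_cache = TRUE)
  lg2 <- ns$bce_loss_grad(matrix(fwd2$logits, 1), targets)
  bwd2 <- ns$backward_attn_single(clf2$params, spec2, fwd2,
                                  as.numeric(lg2$dlogits),
                                  ns$zero_like(clf2$params))
  for (nm in names(clf2$params)) {
    for (i in seq_len(min(length(clf2$params[[nm]]), 4))) {
      p2 <- clf2$params; p2[[nm]][i] <- p2[[nm]][i] + 1e-5
      p3 <- clf2$params; p3[[nm]][i] <- p3[[nm]][i] - 1e-5
      expect_equal(bwd2$acc[[nm]][i], (lossfn2(p2) - lossfn2(p3)) / 2e-5,
                   tolerance = 1e-5, info = nm)
    }
  }
})

test_that("input gradients match finite differences for both families", {
  ds <- tiny_shape_dataset(n_per_class = 1, image_size = 32)
  img <- ds[[1]]$image
  for (fam in c("local_pool", "global_attn")) {
    clf <- build_classifier(classifier_spec(fam, input_size = 32, depth = 2,
                                            seed = 6))
    g <- input_gradient(clf, img)
    expect_identical(dim(g), dim(img))
    score <- function(im) sum(predict(clf, list(im))$scores)
    for (px in list(c(5, 9), c(20, 17))) {
      i2 <- img; i2[px[1], px[2]] <- i2[px[1], px[2]] + 1e-5
      i3 <- img; i3[px[1], px[2]] <- i3[px[1], px[2]] - 1e-5
      expect_equal(g[px[1], px[2]], (score(i2) - score(i3)) / 2e-5,
                   tolerance = 1e-4, info = fam)
    }
  }
})

test_that("training is reproducible, reduces the loss, and validates input", {
  cfg <- synthetic_config("texture", n_per_class = 15, image_size = 32,
                          seed = 13)
  ds <- generate_dataset(cfg)
  spec <- classifier_spec("local_pool", input_size = 32, depth = 2, seed = 8)
  tc <- train_config(epochs = 6, learning_rate = 0.02, batch_size = 16,
                     seed = 8)
  a <- train_classifier(build_classifier(spec, cfg$class_names), ds, tc)
  b <- train_classifier(build_classifier(spec, cfg$class_names), ds, tc)
  expect_identical(predict(a, ds)$scores, predict(b, ds)$scores)
  expect_lt(utils::tail(a$history, 1), a$history[1])
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(epochs = 2, learning_rate = 0), "learning_rate")
  bad <- build_classifier(classifier_spec("local_pool", input_size = 32,
                                          n_classes = 3, depth = 2))
  expect_error(train_classifier(bad, ds, tc), "class count")
  expect_error(predict(a, list(matrix(0.5, 16, 16))), "input size")
})

test_that("checkpoints round-trip through a single file", {
  clf <- build_classifier(classifier_spec("global_attn", seed = 12))
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_classifier(clf, f)
  back <- load_classifier(f)
  expect_identical(back$params, clf$params)
  expect_identical(back$spec, clf$spec)
})

test_that("the class signal is recoverable by both families at benchmark scale", {
  cfg <- synthetic_config("shape", n_per_class = 200, seed = 77)
  ds <- generate_dataset(cfg)
  for (fam in c("local_pool", "global_attn")) {
    clf <- build_classifier(classifier_spec(fam, seed = 77), cfg$class_names)
    clf <- train_classifier(clf, ds, desk_train_config(fam, seed = 77))
    expect_gte(auroc_report(predict(clf, ds))$mean, 0.95)
  }
})

test_that("the pooled conv family is more translation-consistent than the attention family on location-coded data", {
  means <- vapply(1:5, function(s) {
    cfg <- synthetic_config("location", n_per_class = 50, seed = 400 + s)
    ds <- generate_dataset(cfg)
    lp <- train_classifier(
      build_classifier(classifier_spec("local_pool", seed = s), cfg$class_names),
      ds, desk_train_config("local_pool", epochs = 10, seed = s))
    ga <- train_classifier(
      build_classifier(classifier_spec("global_attn", seed = s), cfg$class_names),
      ds, desk_train_config("global_attn", epochs = 15, seed = s))
    ce <- run_consistency_experiment(ds, list(local_pool = lp,
                                              global_attn = ga), seed = s)
    c(ce$reports$local_pool$mean, ce$reports$global_attn$mean)
  }, numeric(2))
  # per-seed values logged for inspection; the assertion is on the means
  message(sprintf("consistency local_pool: %s | global_attn: %s",
                  paste(round(means[1, ], 3), collapse = " "),
                  paste(round(means[2, ], 3), collapse = " ")))
  expect_gte(mean(means[1, ]), mean(means[2, ]))
})
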