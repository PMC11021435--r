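test_that("auroc equals pairwise counting, handles ties and errors", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  # tie pair counts half: 3.5 of 4 correct pairs
  expect_equal(auroc(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "single class")
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- sample(10:60, 1)
      s <- round(runif(n), 2)  # coarse scores force ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      expect_equal(auroc(s, y), brute_auroc(s, y))
    }
  })
})

test_that("auroc is invariant under strictly monotone score transforms", {
  withr::with_seed(17, {
    s <- runif(80)
    y <- rbinom(80, 1, 0.4)
    a <- auroc(s, y)
    expect_equal(auroc(qlogis(s), y), a)
    expect_equal(auroc(s^3, y), a)
    expect_equal(auroc(rank(s), y), a)
  })
})

test_that("auroc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(53, {
    s <- runif(150)
    y <- rbinom(150, 1, 0.5)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  })
})

test_that("auprc matches a direct precision-recall sweep", {
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  # hand case: order 0.9(+), 0.8(-), 0.4(+): recall steps at prec 1 and 2/3
  expect_equal(auprc(c(0.9, 0.8, 0.4), c(1, 0, 1)), 0.5 * 1 + 0.5 * (2 / 3))
})

test_that("consistency counts agreeing decision pairs", {
  a <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(consistency(a, a), 1.0)
  expect_equal(consistency(a, 1 - a), 0.0)
  b <- a; b[1, 1] <- 0
  expect_equal(consistency(a, b), 0.75)
  expect_equal(consistency(a, b), consistency(b, a))
  # single-label reduction: plain per-image agreement rate
  expect_equal(consistency(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.75)
  expect_error(consistency(a, a[1, , drop = FALSE]), "shape")
  expect_error(consistency(a, matrix(2, 2, 2)), "0/1")
})

test_that("delta reports subtract per class and propagate fold CIs", {
  pc_clean <- c(Cd = 0.90, Ed = 0.84)
  pc_corr <- c(Cd = 0.80, Ed = 0.80)
  clean <- metric_report("auroc", pc_clean, fold_values = c(0.87, 0.88, 0.86))
  corr <- metric_report("auroc", pc_corr, fold_values = c(0.78, 0.79, 0.77))
  d <- delta_auroc(clean, corr)
  # per-class loop oracle
  for (cn in names(pc_clean)) {
    expect_equal(d$per_class[[cn]], pc_clean[[cn]] - pc_corr[[cn]])
  }
  expect_equal(d$mean, mean(pc_clean) - mean(pc_corr))
  expect_equal(d$fold_values, c(0.09, 0.09, 0.09))
  expect_equal(delta_auroc(clean, clean)$mean, 0)
  expect_true(all(delta_auroc(clean, clean)$per_class == 0))
  other <- metric_report("auroc", c(X = 0.8, Ed = 0.8))
  expect_error(delta_auroc(clean, other), "class sets")
})

test_that("degradation of the published clean/corrupted pair is recovered", {
  clean <- metric_report("auroc", mean_value = 0.87)
  corrupted <- metric_report("auroc", mean_value = 0.78)
  expect_equal(delta_auroc(clean, corrupted)$mean, 0.09)
})

test_that("micro-averaged confusion metrics match an element-wise tally", {
  cm <- confusion_metrics(c(0.9, 0.2, 0.4, 0.6), c(1, 0, 1, 0))
  for (nm in names(cm)) expect_equal(cm[[nm]]$mean, 0.5, info = nm)
  cm2 <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  for (nm in names(cm2)) expect_equal(cm2[[nm]]$mean, 1.0, info = nm)
  withr::with_seed(61, {
    s <- runif(200); y <- rbinom(200, 1, 0.5)
    got <- confusion_metrics(s, y)
    want <- brute_confusion(s, y)
    for (nm in names(want)) expect_equal(got[[nm]]$mean, want[[nm]], info = nm)
  })
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
})

test_that("fold summaries use the normal-approximation half-width", {
  expect_equal(unname(cross_val_summary(rep(0.8, 5))), c(0.8, 0))
  folds <- c(0.8, 0.9, 0.85, 0.8, 0.9)
  got <- cross_val_summary(folds)
  expect_equal(unname(got["mean"]), 0.85)
  expect_equal(unname(got["ci_half_width"]), 1.96 * 0.05 / sqrt(5),
               tolerance = 1e-10)
  expect_equal(cross_val_summary(rev(folds)), got)
  expect_error(cross_val_summary(0.8), "2 folds")
})

test_that("per-class deviation flags class-sensitive behaviour", {
  r1 <- metric_report("auroc", c(a = 0.9, b = 0.8))
  r2 <- metric_report("auroc", c(a = 0.9, b = 0.7))
  same <- per_class_deviation(list(r1, r1))
  expect_true(all(same$range == 0) && all(same$variance == 0))
  dev <- per_class_deviation(list(r1, r2))
  expect_equal(dev$range[dev$class == "a"], 0)
  expect_equal(dev$range[dev$class == "b"], 0.1)
  # loop oracle over three reports
  r3 <- metric_report("auroc", c(a = 0.85, b = 0.75))
  dev3 <- per_class_deviation(list(r1, r2, r3))
  m <- rbind(r1$per_class, r2$per_class, r3$per_class)
  for (j in 1:2) {
    expect_equal(dev3$range[j], max(m[, j]) - min(m[, j]))
    expect_equal(dev3$variance[j], var(m[, j]))
  }
})

test_that("report tables serialise classes plus a mean row", {
  r <- metric_report("auroc", c(a = 0.9, b = 0.8),
                     fold_values = c(0.84, 0.86))
  df <- report_to_table(r)
  expect_equal(df$class, c("a", "b", "mean"))
  expect_equal(df$value, c(0.9, 0.8, 0.85))
  expect_true("fold_0" %in% names(df))
})
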