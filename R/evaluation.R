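#' Area under the ROC curve (Mann-Whitney form)
#'
#' The fraction of positive-negative score pairs ranked correctly, ties
#' counting one half; computed from mid-ranks, so it is exact and invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector of the same length with at least one positive
#'   and one negative.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0))  # 0.875
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUROC undefined: labels contain a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (interpolation-free) area: precision is accumulated at each
#' distinct recall increment in decreasing-score order, with ties processed
#' as a block.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) {
    stop("AUPRC undefined: labels contain a single class")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # process tied scores as blocks
  blocks <- cumsum(!duplicated(s))
  tp_b <- tapply(y, blocks, sum)
  n_b <- tapply(y, blocks, length)
  tp <- cumsum(tp_b)
  np <- cumsum(n_b)
  prec <- tp / np
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Translation consistency of two decision sets
#'
#' The fraction of (image, class) decision pairs that agree between two
#' renderings of the same images:
#' \deqn{\mathrm{Consistency} = \frac{1}{N} \sum_i 1\{y^1_i = y^2_i\},}
#' where N counts all compared decisions. For multi-label outputs every
#' (image, class) pair contributes one decision; with a single label the
#' statistic reduces to the per-image agreement rate.
#'
#' @param labels_a,labels_b 0/1 matrices (or vectors) of identical shape.
#' @return Agreement fraction in \[0, 1\].
#' @export
consistency <- function(labels_a, labels_b) {
  a <- as.matrix(labels_a); b <- as.matrix(labels_b)
  if (!identical(dim(a), dim(b))) stop("decision matrices differ in shape")
  if (any(!a %in% c(0, 1)) || any(!b %in% c(0, 1))) {
    stop("decisions must be 0/1")
  }
  mean(a == b)
}

#' Threshold probabilities into decisions
#'
#' @param scores Numeric matrix or vector of probabilities.
#' @param threshold Decision threshold; a score >= threshold is positive.
#' @return 0/1 object of the same shape.
#' @export
decisions <- function(scores, threshold = 0.5) {
  out <- (scores >= threshold) * 1
  out
}

#' Construct a metric report
#'
#' A named bundle of per-class values, their mean, fold-wise replicate
#' values and a 95% confidence half-width.
#'
#' @param metric_name Metric label (e.g. `"auroc"`).
#' @param per_class Named numeric vector of per-class values, or `NULL` for
#'   micro-averaged metrics.
#' @param mean_value Overall value; defaults to the mean of `per_class`.
#' @param fold_values Numeric vector of per-fold overall values, or `NULL`.
#' @param ci_half_width 95% half-width; computed from `fold_values` via
#'   [cross_val_summary()] when available.
#' @return An object of class `metric_report`.
#' @export
metric_report <- function(metric_name, per_class = NULL, mean_value = NULL,
                          fold_values = NULL, ci_half_width = NULL) {
  if (is.null(mean_value)) {
    if (is.null(per_class)) stop("either `per_class` or `mean_value` is required")
    mean_value <- mean(per_class)
  }
  if (is.null(ci_half_width)) {
    ci_half_width <- if (!is.null(fold_values) && length(fold_values) >= 2) {
      cross_val_summary(fold_values)["ci_half_width"]
    } else 0
  }
  if (ci_half_width < 0) stop("ci_half_width must be >= 0")
  structure(list(metric_name = metric_name, per_class = per_class,
                 mean = unname(mean_value), fold_values = fold_values,
                 ci_half_width = unname(ci_half_width)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s: mean %.4f (95%% CI half-width %.4f)\n",
              x$metric_name, x$mean, x$ci_half_width))
  if (!is.null(x$per_class)) {
    print(round(x$per_class, 4))
  }
  invisible(x)
}

#' Per-class AUROC report for a prediction set
#'
#' Computes AUROC per class and their macro mean; when `folds` is supplied,
#' fold-wise macro values feed a 95% confidence half-width. Classes whose
#' held-out labels are single-valued are reported as `NA` and excluded from
#' the mean.
#'
#' @param pred A [prediction_set()] with targets.
#' @param folds Optional integer vector assigning each image to a fold.
#' @param metric `"auroc"` (default) or `"auprc"`.
#' @return A [metric_report()].
#' @export
auroc_report <- function(pred, folds = NULL, metric = c("auroc", "auprc")) {
  metric <- match.arg(metric)
  stopifnot(inherits(pred, "prediction_set"))
  if (is.null(pred$targets)) stop("prediction set has no targets")
  fn <- if (metric == "auroc") auroc else auprc
  per_class <- vapply(pred$class_names, function(cn) {
    y <- pred$targets[, cn]
    if (length(unique(y)) < 2) return(NA_real_)
    fn(pred$scores[, cn], y)
  }, numeric(1))
  fold_values <- NULL
  if (!is.null(folds)) {
    fold_values <- vapply(sort(unique(folds)), function(f) {
      sel <- folds == f
      vals <- vapply(pred$class_names, function(cn) {
        y <- pred$targets[sel, cn]
        if (length(unique(y)) < 2) return(NA_real_)
        fn(pred$scores[sel, cn], y)
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
  }
  metric_report(metric, per_class = per_class,
                mean_value = mean(per_class, na.rm = TRUE),
                fold_values = fold_values)
}

#' AUROC degradation between a clean and a perturbed report
#'
#' Per-class and mean differences clean minus perturbed; when both reports
#' carry fold values, fold-wise differences propagate to a fresh 95%
#' confidence half-width.
#'
#' @param clean,perturbed [metric_report()] objects over the same classes.
#' @return A [metric_report()] named `"delta_<metric>"`.
#' @export
delta_auroc <- function(clean, perturbed) {
  stopifnot(inherits(clean, "metric_report"), inherits(perturbed, "metric_report"))
  if (!identical(names(clean$per_class), names(perturbed$per_class))) {
    stop("reports cover different class sets")
  }
  per_class <- if (is.null(clean$per_class)) NULL else
    clean$per_class - perturbed$per_class
  fold_values <- NULL
  if (!is.null(clean$fold_values) && !is.null(perturbed$fold_values) &&
      length(clean$fold_values) == length(perturbed$fold_values)) {
    fold_values <- clean$fold_values - perturbed$fold_values
  }
  metric_report(paste0("delta_", clean$metric_name),
                per_class = per_class,
                mean_value = clean$mean - perturbed$mean,
                fold_values = fold_values)
}

#' Micro-averaged confusion metrics at a threshold
#'
#' Thresholds scores at `threshold` (score >= threshold is positive) and
#' tallies one confusion table over all (image, class) pairs, yielding
#' accuracy, F1, specificity, sensitivity and precision as single scalars.
#'
#' @param scores Probability matrix or vector.
#' @param targets Aligned 0/1 matrix or vector.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list of five [metric_report()] objects
#'   (`accuracy`, `f1`, `specificity`, `sensitivity`, `precision`).
#' @export
confusion_metrics <- function(scores, targets, threshold = 0.5) {
  s <- as.numeric(scores); y <- as.numeric(targets)
  if (length(s) == 0) stop("empty input")
  if (length(s) != length(y)) stop("scores/targets length mismatch")
  if (min(s) < 0 || max(s) > 1) stop("scores must lie in [0, 1]")
  if (any(!y %in% c(0, 1))) stop("targets must be 0/1")
  d <- as.numeric(s >= threshold)
  tp <- sum(d == 1 & y == 1); tn <- sum(d == 0 & y == 0)
  fp <- sum(d == 1 & y == 0); fn <- sum(d == 0 & y == 1)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  vals <- c(accuracy = (tp + tn) / length(y),
            f1 = safe(2 * tp, 2 * tp + fp + fn),
            specificity = safe(tn, tn + fp),
            sensitivity = safe(tp, tp + fn),
            precision = safe(tp, tp + fp))
  out <- lapply(names(vals), function(nm) {
    metric_report(nm, mean_value = vals[[nm]])
  })
  stats::setNames(out, names(vals))
}

#' Mean and 95% confidence half-width over cross-validation folds
#'
#' Normal-approximation interval: half-width `1.96 * sd / sqrt(k)` with the
#' sample standard deviation over the k fold values.
#'
#' @param fold_values Numeric vector of per-fold metric values (k >= 2).
#' @return Named vector `c(mean, ci_half_width)`.
#' @export
cross_val_summary <- function(fold_values) {
  fold_values <- fold_values[is.finite(fold_values)]
  if (length(fold_values) < 2) stop("need at least 2 folds")
  c(mean = mean(fold_values),
    ci_half_width = 1.96 * stats::sd(fold_values) / sqrt(length(fold_values)))
}

#' Per-class spread across a set of reports
#'
#' Flags class-sensitive behaviour: for each class, the range (max - min)
#' and variance of its value across the supplied reports.
#'
#' @param reports List of [metric_report()] objects over an identical class
#'   set.
#' @return Data frame with columns `class`, `range`, `variance`.
#' @export
per_class_deviation <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports")
  cls <- names(reports[[1]]$per_class)
  if (is.null(cls)) stop("reports carry no per-class values")
  for (r in reports) {
    if (!identical(names(r$per_class), cls)) stop("reports cover different class sets")
  }
  m <- do.call(rbind, lapply(reports, function(r) r$per_class))
  data.frame(class = cls,
             range = apply(m, 2, function(v) max(v) - min(v)),
             variance = apply(m, 2, stats::var),
             row.names = NULL)
}

#' Serialize a metric report to a data frame / CSV
#'
#' Rows are classes plus a final `"mean"` row; columns are `value`, `ci`
#' and one column per fold when fold values are present.
#'
#' @param report A [metric_report()].
#' @param path Optional CSV path; written when supplied.
#' @return The data frame, invisibly when `path` is given.
#' @export
report_to_table <- function(report, path = NULL) {
  rows <- if (is.null(report$per_class)) character(0) else names(report$per_class)
  df <- data.frame(class = c(rows, "mean"),
                   value = c(unname(report$per_class), report$mean),
                   ci = c(rep(NA_real_, length(rows)), report$ci_half_width))
  if (!is.null(report$fold_values)) {
    for (i in seq_along(report$fold_values)) {
      df[[paste0("fold_", i - 1)]] <-
        c(rep(NA_real_, length(rows)), report$fold_values[i])
    }
  }
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
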