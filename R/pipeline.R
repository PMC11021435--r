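#' Experiment drivers
#'
#' Each `run_*_experiment()` function evaluates one analysis end to end on
#' an annotated dataset and returns the report objects; when `output_dir`
#' is given it also writes the report CSVs plus a machine-readable JSON run
#' record (configuration, seed, dataset content hash, per-fold values).
#' Reruns with identical inputs and seed reproduce every report cell.
#'
#' @name experiments
NULL

folds_of <- function(samples) {
  vapply(samples, function(s) s$fold, integer(1))
}

# Content hash of a dataset: image payloads, targets and folds.
dataset_hash <- function(samples) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  payload <- lapply(samples, function(s) {
    list(id = s$id, targets = s$targets, fold = s$fold,
         img = signif(sum(s$image), 12))
  })
  writeBin(serialize(payload, NULL), tmp)
  unname(tools::md5sum(tmp))
}

write_run_record <- function(output_dir, experiment, config, results) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- list(experiment = experiment, config = config, results = results,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(rec, file.path(output_dir,
                                      paste0(experiment, "_run.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

predict_samples <- function(classifier, samples, images = NULL) {
  if (is.null(images)) return(predict(classifier, samples))
  pred <- predict(classifier, images)
  targets <- do.call(rbind, lapply(samples, function(s) s$targets))
  prediction_set(pred$scores, classifier$class_names,
                 vapply(samples, function(s) s$id, character(1)),
                 targets = targets)
}

#' Robustness experiment: AUROC degradation under corruption
#'
#' Evaluates the classifier on the clean dataset and under every requested
#' corruption at every requested severity, then summarises the mean AUROC
#' degradation per severity (per-class AUROC, averaged over classes, then
#' over corruption types) with fold-wise 95% confidence half-widths.
#'
#' @param samples Annotated dataset (list of [image_sample()]).
#' @param classifier A trained `lesion_classifier` (or a named list of
#'   them, one row per model in the report).
#' @param corruptions Corruption names to apply (default: all 16).
#' @param severities Severity subset of 1..5.
#' @param seed Integer seed driving the stochastic corruptions.
#' @param output_dir Optional report directory.
#' @return List with per-model entries: `clean` report, `delta_by_severity`
#'   (list of [metric_report()]s), a `summary` data frame shaped
#'   model x severity, and `per_class` mean degradation per class.
#' @export
run_robustness_experiment <- function(samples, classifier,
                                      corruptions = corruption_names(),
                                      severities = 1:5,
                                      seed = 1L, output_dir = NULL) {
  models <- as_model_list(classifier)
  folds <- folds_of(samples)
  out <- list()
  summary_rows <- list()
  per_class_rows <- list()
  for (mi in seq_along(models)) {
    mname <- names(models)[mi]
    model <- models[[mi]]
    clean_rep <- auroc_report(predict_samples(model, samples), folds)
    delta_by_sev <- list()
    for (s in severities) {
      reps <- lapply(seq_along(corruptions), function(ci) {
        imgs <- lapply(seq_along(samples), function(i) {
          corrupt(samples[[i]]$image,
                  corruption_spec(corruptions[ci], s),
                  seed = derive_seed(seed, ci * 1000L + s * 100000L + i))
        })
        delta_auroc(clean_rep,
                    auroc_report(predict_samples(model, samples, imgs), folds))
      })
      per_class <- rowMeans(do.call(cbind, lapply(reps, `[[`, "per_class")))
      fold_values <- rowMeans(do.call(cbind, lapply(reps, `[[`, "fold_values")))
      delta_by_sev[[paste0("I", s)]] <-
        metric_report("delta_auroc", per_class = per_class,
                      mean_value = mean(vapply(reps, `[[`, numeric(1), "mean")),
                      fold_values = fold_values)
    }
    sev_means <- vapply(delta_by_sev, `[[`, numeric(1), "mean")
    sev_cis <- vapply(delta_by_sev, `[[`, numeric(1), "ci_half_width")
    row <- c(rbind(sev_means, sev_cis))
    names(row) <- as.vector(rbind(names(delta_by_sev),
                                  paste0(names(delta_by_sev), "_ci")))
    summary_rows[[mname]] <- c(row, mean = mean(sev_means),
                               mean_ci = mean(sev_cis))
    pc <- do.call(cbind, lapply(delta_by_sev, `[[`, "per_class"))
    per_class_rows[[mname]] <- data.frame(model = mname,
                                          class = rownames(pc), pc,
                                          row.names = NULL)
    out[[mname]] <- list(clean = clean_rep, delta_by_severity = delta_by_sev)
  }
  summary <- data.frame(model = names(summary_rows),
                        do.call(rbind, summary_rows), row.names = NULL)
  per_class <- do.call(rbind, per_class_rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(output_dir, "robustness.csv"),
                     row.names = FALSE)
    utils::write.csv(per_class, file.path(output_dir, "robustness_per_class.csv"),
                     row.names = FALSE)
    write_run_record(output_dir, "robustness",
                     list(seed = seed, corruptions = corruptions,
                          severities = severities,
                          dataset_hash = dataset_hash(samples)),
                     list(summary = summary))
  }
  c(out, list(summary = summary, per_class = per_class))
}

as_model_list <- function(classifier) {
  if (inherits(classifier, "lesion_classifier")) {
    stats::setNames(list(classifier), classifier$spec$family)
  } else {
    stopifnot(is.list(classifier), length(classifier) >= 1)
    if (is.null(names(classifier))) {
      names(classifier) <- vapply(classifier,
                                  function(m) m$spec$family, character(1))
    }
    classifier
  }
}

#' Consistency experiment: agreement under random translation pairs
#'
#' Draws one translation pair per image (shared across models), thresholds
#' each model's predictions on both renderings, and reports the per-class
#' and mean decision agreement with fold-wise confidence half-widths, plus
#' the per-class spread across models.
#'
#' @inheritParams run_robustness_experiment
#' @param max_loss_fraction Translation loss budget per rendering.
#' @param threshold Decision threshold.
#' @return List with per-model [metric_report()]s (`reports`), the
#'   `summary` data frame and the across-model `deviation` table.
#' @export
run_consistency_experiment <- function(samples, classifier,
                                       max_loss_fraction = 0.07,
                                       threshold = 0.5,
                                       seed = 1L, output_dir = NULL) {
  models <- as_model_list(classifier)
  folds <- folds_of(samples)
  pairs <- lapply(seq_along(samples), function(i) {
    sample_translation_pair(samples[[i]]$image, max_loss_fraction,
                            seed = derive_seed(seed, i))
  })
  imgs_a <- lapply(pairs, `[[`, "image_a")
  imgs_b <- lapply(pairs, `[[`, "image_b")
  reports <- list()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    da <- decisions(predict_samples(model, samples, imgs_a)$scores, threshold)
    db <- decisions(predict_samples(model, samples, imgs_b)$scores, threshold)
    per_class <- vapply(seq_len(ncol(da)),
                        function(j) mean(da[, j] == db[, j]), numeric(1))
    names(per_class) <- model$class_names
    fold_values <- vapply(sort(unique(folds)), function(f) {
      consistency(da[folds == f, , drop = FALSE], db[folds == f, , drop = FALSE])
    }, numeric(1))
    reports[[names(models)[mi]]] <-
      metric_report("consistency", per_class = per_class,
                    mean_value = consistency(da, db),
                    fold_values = fold_values)
  }
  summary <- data.frame(
    model = names(reports),
    do.call(rbind, lapply(reports, function(r) {
      c(r$per_class, mean = r$mean, ci = r$ci_half_width)
    })), row.names = NULL)
  deviation <- if (length(reports) >= 2) per_class_deviation(reports) else NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(output_dir, "consistency.csv"),
                     row.names = FALSE)
    if (!is.null(deviation)) {
      utils::write.csv(deviation,
                       file.path(output_dir, "consistency_deviation.csv"),
                       row.names = FALSE)
    }
    write_run_record(output_dir, "consistency",
                     list(seed = seed, max_loss_fraction = max_loss_fraction,
                          threshold = threshold,
                          dataset_hash = dataset_hash(samples)),
                     list(summary = summary))
  }
  list(reports = reports, summary = summary, deviation = deviation)
}

#' Obstruction experiment: degradation under bounding-box occlusion
#'
#' Occludes each lesion bounding box at the requested masking ratios (one
#' random rectangle per image and ratio) and reports the AUROC degradation
#' curve relative to the clean images.
#'
#' @inheritParams run_robustness_experiment
#' @param ratios Masking ratios (defaults to 15%, 30%, 45% and 60%).
#' @param fill Occluder intensity.
#' @return List with the clean report, per-ratio delta reports and the
#'   `curve` data frame (`ratio`, `auroc`, `delta`, `ci`).
#' @export
run_obstruction_experiment <- function(samples, classifier,
                                       ratios = c(0.15, 0.30, 0.45, 0.60),
                                       fill = 0, seed = 1L,
                                       output_dir = NULL) {
  if (any(vapply(samples, function(s) is.null(s$bbox), logical(1)))) {
    stop("obstruction analysis requires a bounding box on every sample")
  }
  folds <- folds_of(samples)
  clean_rep <- auroc_report(predict_samples(classifier, samples), folds)
  deltas <- list()
  rows <- list(data.frame(ratio = 0, auroc = clean_rep$mean, delta = 0,
                          ci = clean_rep$ci_half_width))
  for (ri in seq_along(ratios)) {
    r <- ratios[ri]
    imgs <- lapply(seq_along(samples), function(i) {
      occlude(samples[[i]]$image, samples[[i]]$bbox, r,
              seed = derive_seed(seed, ri * 100000L + i), fill = fill)
    })
    rep_r <- auroc_report(predict_samples(classifier, samples, imgs), folds)
    d <- delta_auroc(clean_rep, rep_r)
    deltas[[as.character(r)]] <- d
    rows[[ri + 1L]] <- data.frame(ratio = r, auroc = rep_r$mean,
                                  delta = d$mean, ci = d$ci_half_width)
  }
  curve <- do.call(rbind, rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(curve, file.path(output_dir, "obstruction.csv"),
                     row.names = FALSE)
    write_run_record(output_dir, "obstruction",
                     list(seed = seed, ratios = ratios, fill = fill,
                          dataset_hash = dataset_hash(samples)),
                     list(curve = curve))
  }
  list(clean = clean_rep, deltas = deltas, curve = curve)
}

#' Shape/texture bias experiment
#'
#' Evaluates the classifier on the clean images and on their shape-only and
#' texture-only ablations, reporting the two degradation tables. The
#' asymmetry of the two degradations indicates which cue the model relies
#' on.
#'
#' @inheritParams run_robustness_experiment
#' @return List with the three AUROC reports and the two delta reports
#'   (`delta_shape`, `delta_texture`), plus a `summary` data frame.
#' @export
run_shape_texture_experiment <- function(samples, classifier, seed = 1L,
                                         output_dir = NULL) {
  if (any(vapply(samples, function(s) is.null(s$mask), logical(1)))) {
    stop("shape/texture analysis requires a mask on every sample")
  }
  folds <- folds_of(samples)
  clean_rep <- auroc_report(predict_samples(classifier, samples), folds)
  shape_imgs <- lapply(samples, function(s) shape_only(s$image, s$mask))
  tex_imgs <- lapply(samples, function(s) {
    texture_only(s$image, s$mask, output_size = ncol(s$image))
  })
  shape_rep <- auroc_report(predict_samples(classifier, samples, shape_imgs), folds)
  tex_rep <- auroc_report(predict_samples(classifier, samples, tex_imgs), folds)
  d_shape <- delta_auroc(clean_rep, shape_rep)
  d_tex <- delta_auroc(clean_rep, tex_rep)
  summary <- data.frame(
    variant = c("clean", "shape_only", "texture_only"),
    auroc = c(clean_rep$mean, shape_rep$mean, tex_rep$mean),
    delta = c(0, d_shape$mean, d_tex$mean),
    ci = c(clean_rep$ci_half_width, d_shape$ci_half_width, d_tex$ci_half_width))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(output_dir, "shape_texture.csv"),
                     row.names = FALSE)
    report_to_table(d_shape, file.path(output_dir, "delta_shape.csv"))
    report_to_table(d_tex, file.path(output_dir, "delta_texture.csv"))
    write_run_record(output_dir, "shape_texture",
                     list(seed = seed, dataset_hash = dataset_hash(samples)),
                     list(summary = summary))
  }
  list(clean = clean_rep, shape = shape_rep, texture = tex_rep,
       delta_shape = d_shape, delta_texture = d_tex, summary = summary)
}

#' Ensemble experiment: general vs class-conditional combination
#'
#' Combines two aligned prediction sets with the unweighted mean and with
#' the class-conditional weighting, then reports accuracy, AUROC, AUPRC,
#' F1, specificity, sensitivity and precision for both.
#'
#' @param pred_a,pred_b Aligned [prediction_set()] objects with targets
#'   (model A and model B).
#' @param insensitive_classes Classes on which model B is up-weighted;
#'   `NULL` selects them from the per-class AUROC comparison via
#'   [select_insensitive_classes()].
#' @param base_weight Weight on model B for the selected classes.
#' @param threshold Decision threshold for the confusion metrics.
#' @param output_dir Optional report directory.
#' @return List with the selected classes, both ensembled prediction sets
#'   and the metric `summary` data frame (one row per method).
#' @export
run_ensemble_experiment <- function(pred_a, pred_b,
                                    insensitive_classes = NULL,
                                    base_weight = 0.75, threshold = 0.5,
                                    output_dir = NULL) {
  check_aligned(pred_a, pred_b)
  if (is.null(pred_a$targets)) stop("prediction sets need targets")
  if (is.null(insensitive_classes)) {
    insensitive_classes <- select_insensitive_classes(
      auroc_report(pred_a)$per_class, auroc_report(pred_b)$per_class)
  }
  w <- ensemble_weights(pred_a$class_names, insensitive_classes, base_weight)
  ens <- list(general = general_ensemble(pred_a, pred_b),
              class_conditional = class_conditional_ensemble(pred_a, pred_b, w))
  summary <- do.call(rbind, lapply(names(ens), function(nm) {
    p <- ens[[nm]]
    cm <- confusion_metrics(p$scores, p$targets, threshold)
    data.frame(method = nm,
               accuracy = cm$accuracy$mean,
               auroc = auroc_report(p)$mean,
               auprc = auroc_report(p, metric = "auprc")$mean,
               f1 = cm$f1$mean,
               specificity = cm$specificity$mean,
               sensitivity = cm$sensitivity$mean,
               precision = cm$precision$mean)
  }))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(output_dir, "ensemble.csv"),
                     row.names = FALSE)
    write_run_record(output_dir, "ensemble",
                     list(insensitive_classes = insensitive_classes,
                          base_weight = base_weight, threshold = threshold),
                     list(summary = summary))
  }
  list(insensitive_classes = insensitive_classes, ensembles = ens,
       summary = summary)
}

#' Train one classifier per cross-validation fold
#'
#' Full k-fold protocol: for each fold, trains a fresh classifier on the
#' remaining folds and predicts the held-out fold; the stitched predictions
#' cover every sample exactly once.
#'
#' @param spec A [classifier_spec()].
#' @param samples Annotated dataset with fold ids.
#' @param config A [train_config()]; each fold derives its own seed.
#' @return A [prediction_set()] of held-out predictions, with the fold
#'   vector as attribute `"folds"`.
#' @export
cross_val_predict <- function(spec, samples, config) {
  folds <- folds_of(samples)
  n <- length(samples)
  scores <- NULL
  class_names <- names(samples[[1]]$targets)
  out_scores <- matrix(NA_real_, n, length(class_names))
  for (f in sort(unique(folds))) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, f)
    sp <- spec
    sp$seed <- derive_seed(spec$seed, f)
    model <- train_classifier(build_classifier(sp, class_names),
                              samples[train_idx], cfg)
    out_scores[test_idx, ] <- predict(model, samples[test_idx])$scores
  }
  ps <- prediction_set(out_scores, class_names,
                       vapply(samples, function(s) s$id, character(1)),
                       targets = do.call(rbind, lapply(samples,
                                                       function(s) s$targets)))
  attr(ps, "folds") <- folds
  ps
}
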