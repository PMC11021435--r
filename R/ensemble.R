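#' Per-class ensemble weights for a two-model ensemble
#'
#' Model B receives weight `base_weight` on the classes in
#' `insensitive_classes` (where B is the stronger or
#' translation-change-insensitive member) and `1 - base_weight` elsewhere;
#' model A always receives the complement.
#'
#' @param class_names All class names.
#' @param insensitive_classes Subset of `class_names` on which model B is
#'   up-weighted.
#' @param base_weight Weight on model B for the insensitive classes; in
#'   \[0, 1\], default 0.75 (so the other classes weight B by 0.25).
#' @return An object of class `ensemble_weights` with the per-class weight
#'   on model B.
#' @export
ensemble_weights <- function(class_names, insensitive_classes,
                             base_weight = 0.75) {
  if (base_weight < 0 || base_weight > 1) stop("`base_weight` must lie in [0, 1]")
  if (!all(insensitive_classes %in% class_names)) {
    stop("`insensitive_classes` must be a subset of `class_names`")
  }
  w <- stats::setNames(rep(1 - base_weight, length(class_names)), class_names)
  w[insensitive_classes] <- base_weight
  structure(list(per_class_weight_b = w,
                 insensitive_classes = insensitive_classes,
                 base_weight = base_weight),
            class = "ensemble_weights")
}

#' Select the classes on which model B should be up-weighted
#'
#' Data-driven rule: a class is selected when model B's per-class value
#' (e.g. AUROC or consistency) is at least model A's — ties go to B. An
#' explicit class list supplied via `override` short-circuits the rule,
#' matching the workflow of picking known location-stable disease classes
#' by inspection.
#'
#' @param per_class_a,per_class_b Named numeric vectors over an identical
#'   class set.
#' @param override Optional character vector of class names to select
#'   regardless of the values.
#' @return Character vector of selected class names.
#' @export
select_insensitive_classes <- function(per_class_a, per_class_b,
                                       override = NULL) {
  if (!is.null(override)) return(override)
  if (!identical(sort(names(per_class_a)), sort(names(per_class_b)))) {
    stop("class sets differ")
  }
  cls <- names(per_class_a)
  cls[per_class_b[cls] >= per_class_a[cls]]
}

#' Class-conditional two-model ensemble
#'
#' Per class c the ensembled probability is the convex combination
#' \deqn{p(c) = w_B(c)\, p_B(c) + (1 - w_B(c))\, p_A(c),}
#' so each output lies between the two member probabilities. With all
#' weights 0.5 this reduces exactly to [general_ensemble()].
#'
#' @param pred_a,pred_b [prediction_set()] objects with aligned image ids
#'   and class sets.
#' @param weights An [ensemble_weights()] over the same classes.
#' @return A [prediction_set()].
#' @export
class_conditional_ensemble <- function(pred_a, pred_b, weights) {
  check_aligned(pred_a, pred_b)
  stopifnot(inherits(weights, "ensemble_weights"))
  wb <- weights$per_class_weight_b[pred_a$class_names]
  if (any(is.na(wb))) stop("weights do not cover the prediction classes")
  scores <- sweep(pred_b$scores, 2, wb, `*`) +
    sweep(pred_a$scores, 2, 1 - wb, `*`)
  prediction_set(scores, pred_a$class_names, pred_a$image_ids,
                 targets = pred_a$targets)
}

#' Unweighted two-model ensemble baseline
#'
#' The plain mean of the two probability matrices.
#'
#' @inheritParams class_conditional_ensemble
#' @return A [prediction_set()].
#' @export
general_ensemble <- function(pred_a, pred_b) {
  check_aligned(pred_a, pred_b)
  prediction_set((pred_a$scores + pred_b$scores) / 2,
                 pred_a$class_names, pred_a$image_ids,
                 targets = pred_a$targets)
}

check_aligned <- function(pred_a, pred_b) {
  stopifnot(inherits(pred_a, "prediction_set"), inherits(pred_b, "prediction_set"))
  if (!identical(pred_a$class_names, pred_b$class_names)) {
    stop("prediction sets cover different classes")
  }
  if (!identical(pred_a$image_ids, pred_b$image_ids)) {
    stop("prediction sets cover different images")
  }
  if (!is.null(pred_a$targets) && !is.null(pred_b$targets) &&
      !isTRUE(all.equal(pred_a$targets, pred_b$targets))) {
    stop("prediction sets disagree on ground truth")
  }
  invisible(TRUE)
}
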