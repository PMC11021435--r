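# Stub classifiers used to isolate pipeline logic from model training.

# Always emits the same probabilities for every image.
constant_classifier <- function(class_names, value = 0.7) {
  structure(list(class_names = class_names, value = value),
            class = c("constant_classifier"))
}

predict.constant_classifier <- function(object, newdata, ...) {
  n <- length(newdata)
  targets <- NULL
  ids <- sprintf("img_%05d", seq_len(n))
  if (inherits(newdata[[1]], "image_sample")) {
    targets <- do.call(rbind, lapply(newdata, function(s) s$targets))
    ids <- vapply(newdata, function(s) s$id, character(1))
  }
  prediction_set(matrix(object$value, n, length(object$class_names)),
                 object$class_names, ids, targets = targets)
}

# Score = mean input pixel; its input gradient is exactly constant.
mean_pixel_classifier <- function() {
  structure(list(class_names = "class_1"), class = "mean_pixel_classifier")
}

input_gradient.mean_pixel_classifier <- function(classifier, image) {
  matrix(1 / length(image), nrow(image), ncol(image))
}

# make the stub methods visible to S3 dispatch from inside the package
registerS3method("predict", "constant_classifier", predict.constant_classifier)
registerS3method("input_gradient", "mean_pixel_classifier",
                 input_gradient.mean_pixel_classifier,
                 envir = asNamespace("lesionbench"))

tiny_shape_dataset <- function(n_per_class = 10, seed = 7, ...) {
  generate_dataset(synthetic_config("shape", n_per_class = n_per_class,
                                    seed = seed, ...))
}
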