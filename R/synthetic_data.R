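#' Configuration for the synthetic lesion-image generator
#'
#' Builds and validates the parameter set used by [generate_dataset()]. The
#' generator draws star-shaped lesion blobs on a noisy gradient background and
#' encodes class identity through exactly one visual channel, selected by
#' `mode`:
#'
#' * `"shape"` — classes differ in the harmonic content of the lesion
#'   boundary (smooth vs lobed outlines); texture and location are
#'   uninformative.
#' * `"texture"` — classes differ in the centre spatial frequency of the
#'   band-pass texture filling the lesion; shape and location are
#'   uninformative.
#' * `"location"` — class 1 lesions sit at a fixed centre (the middle of
#'   the frame) while every other class is placed uniformly at random, so
#'   the class signal is purely positional; shape and texture are
#'   uninformative.
#'
#' @param mode One of `"shape"`, `"texture"`, `"location"`.
#' @param n_classes Number of classes (>= 2).
#' @param n_per_class Images generated per class.
#' @param image_size Side length in pixels of the square images (>= 32).
#' @param seed Integer seed; identical configurations reproduce identical
#'   datasets byte for byte.
#' @param lesion_radius_range Length-2 numeric, fractions of `image_size` in
#'   (0, 0.5); the base lesion radius is drawn uniformly from this interval.
#'   `NULL` selects mode-specific defaults: 0.25-0.30 for `"shape"` and
#'   `"location"` (a narrow spread keeps boundary complexity, not size, the
#'   dominant cue, and keeps the fixed-location class meaningful), and
#'   0.25-0.40 for `"texture"` (large lesions dominate the frame, so
#'   interior appearance must be read without background context).
#' @param shape_harmonics List of length `n_classes`; element `j` is the
#'   vector of harmonic amplitudes (harmonics k = 2..6, each amplitude in
#'   \[0, 0.5)) shaping the class-`j` boundary. `NULL` selects mode-specific
#'   defaults (smooth circle vs a 0.35-amplitude five-lobed star for
#'   `"shape"`; a shared mild k = 3 waviness otherwise).
#' @param texture_bands Numeric vector of length `n_classes`: per-class centre
#'   spatial frequency of the lesion texture in cycles per image width.
#'   `NULL` selects defaults (a 1.5 to 24 cycles/width geometric ladder for
#'   `"texture"`, a shared 8 cycles/width band otherwise).
#' @param noise_sd Standard deviation of the additive Gaussian background
#'   noise, in intensity units on the \[0, 1\] scale.
#' @param lesion_intensity Base interior intensity of the lesion before the
#'   texture field is added; must exceed the background's upper gradient
#'   level for the boundary to stay visible.
#' @param texture_contrast Standard deviation of the band-pass texture
#'   added inside the lesion.
#' @param n_folds Number of cross-validation folds assigned round-robin.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_dataset()]
#' @export
synthetic_config <- function(mode = c("shape", "texture", "location"),
                             n_classes = 2L,
                             n_per_class = 100L,
                             image_size = 64L,
                             seed = 1L,
                             lesion_radius_range = NULL,
                             shape_harmonics = NULL,
                             texture_bands = NULL,
                             noise_sd = 0.05,
                             lesion_intensity = 0.75,
                             texture_contrast = 0.25,
                             n_folds = 5L) {
  mode <- match.arg(mode)
  if (is.null(lesion_radius_range)) {
    lesion_radius_range <- if (mode == "texture") c(0.25, 0.40) else c(0.25, 0.30)
  }
  if (!is_count(n_classes, 2L)) stop("`n_classes` must be an integer >= 2")
  if (!is_count(n_per_class, 1L)) stop("`n_per_class` must be a positive integer")
  if (!is_count(image_size, 32L)) stop("`image_size` must be an integer >= 32")
  if (!is_count(n_folds, 1L)) stop("`n_folds` must be a positive integer")
  if (length(lesion_radius_range) != 2L ||
      any(lesion_radius_range <= 0) || any(lesion_radius_range >= 0.5) ||
      diff(lesion_radius_range) < 0) {
    stop("`lesion_radius_range` must be an increasing pair of fractions in (0, 0.5)")
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (lesion_intensity <= 0 || lesion_intensity > 1) {
    stop("`lesion_intensity` must lie in (0, 1]")
  }
  if (texture_contrast < 0) stop("`texture_contrast` must be non-negative")

  if (is.null(shape_harmonics)) {
    shape_harmonics <- default_shape_harmonics(mode, n_classes)
  }
  if (!is.list(shape_harmonics) || length(shape_harmonics) != n_classes) {
    stop("`shape_harmonics` must be a list with one amplitude vector per class")
  }
  for (a in shape_harmonics) {
    if (length(a) != 5L || any(a < 0) || any(a >= 0.5)) {
      stop("harmonic amplitudes must be 5 values (k = 2..6), each in [0, 0.5); ",
           "amplitudes >= 0.5 give a self-intersecting boundary")
    }
  }
  if (is.null(texture_bands)) {
    texture_bands <- default_texture_bands(mode, n_classes)
  }
  if (length(texture_bands) != n_classes || any(texture_bands <= 0)) {
    stop("`texture_bands` must give one positive centre frequency per class")
  }

  # The lesion (base radius times the worst-case harmonic swell) must fit
  # inside the frame for every admissible draw.
  max_amp <- max(vapply(shape_harmonics, sum, numeric(1)))
  reach <- lesion_radius_range[2] * (1 + max_amp)
  if (reach >= 0.5) {
    stop("lesion cannot fit inside the image: reduce radii or harmonic amplitudes")
  }

  structure(
    list(mode = mode, n_classes = as.integer(n_classes),
         n_per_class = as.integer(n_per_class),
         image_size = as.integer(image_size), seed = as.integer(seed),
         lesion_radius_range = as.numeric(lesion_radius_range),
         shape_harmonics = shape_harmonics,
         texture_bands = as.numeric(texture_bands),
         noise_sd = noise_sd, lesion_intensity = lesion_intensity,
         texture_contrast = texture_contrast,
         n_folds = as.integer(n_folds),
         class_names = sprintf("class_%d", seq_len(n_classes))),
    class = "synthetic_config"
  )
}

default_shape_harmonics <- function(mode, n_classes) {
  if (mode == "shape") {
    lapply(seq_len(n_classes), function(j) {
      a <- numeric(5)
      # class 2 gets a five-lobed star (k = 5); later classes cycle onward
      if (j > 1L) a[((j + 1L) %% 5L) + 1L] <- 0.35
      a
    })
  } else {
    # mild shared waviness so lesions look organic but shape is uninformative
    rep(list(c(0, 0.1, 0, 0, 0)), n_classes)
  }
}

default_texture_bands <- function(mode, n_classes) {
  if (mode == "texture") {
    # from near-homogeneous (well under one cycle across a lesion) to
    # fine-grained; wide spacing keeps the smooth-vs-grainy contrast
    # recognisable even when a lesion crop is magnified to full frame
    exp(seq(log(1.5), log(24), length.out = n_classes))
  } else {
    rep(8, n_classes)
  }
}

#' A single annotated image sample
#'
#' Container for one image with its multi-label targets, optional binary
#' lesion mask, optional tight bounding box and fold assignment.
#'
#' @param image Numeric matrix with intensities in \[0, 1\]; rows are image
#'   rows (y), columns are image columns (x).
#' @param targets Named 0/1 vector, one entry per class.
#' @param mask Optional binary matrix of the same shape with at least one
#'   foreground pixel.
#' @param bbox Optional integer vector `(x0, y0, x1, y1)`: the half-open,
#'   0-based tight box of the mask foreground.
#' @param fold Integer fold id in `[0, n_folds)`.
#' @param id Character image identifier.
#'
#' @return An object of class `image_sample`.
#' @export
image_sample <- function(image, targets, mask = NULL, bbox = NULL,
                         fold = 0L, id = "img") {
  assert_image(image)
  if (any(!targets %in% c(0, 1))) stop("`targets` must be 0/1")
  if (is.null(names(targets))) stop("`targets` must be named by class")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(image))) stop("mask/image shape mismatch")
    if (sum(mask) < 1) stop("mask must contain at least one foreground pixel")
    if (is.null(bbox)) bbox <- bbox_from_mask(mask)
  }
  structure(list(image = image, targets = targets, mask = mask,
                 bbox = bbox, fold = as.integer(fold), id = id),
            class = "image_sample")
}

#' Tight bounding box of a binary mask
#'
#' @param mask Binary matrix (0/1 or logical).
#' @return Integer vector `(x0, y0, x1, y1)`: half-open, 0-based; `x` indexes
#'   columns and `y` rows, so the foreground occupies rows `y0..y1-1` and
#'   columns `x0..x1-1` in 0-based coordinates.
#' @examples
#' m <- matrix(0, 8, 8); m[4, 6] <- 1
#' bbox_from_mask(m)  # c(5, 3, 6, 4)
#' @export
bbox_from_mask <- function(mask) {
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("mask is empty: no foreground pixel")
  c(x0 = min(fg[, 2L]) - 1L, y0 = min(fg[, 1L]) - 1L,
    x1 = max(fg[, 2L]), y1 = max(fg[, 1L]))
}

#' Generate a synthetic lesion-image dataset
#'
#' Renders `n_classes * n_per_class` images under the class-coding scheme in
#' the supplied [synthetic_config()]. Each sample carries its binary lesion
#' mask, the tight bounding box of that mask, and a round-robin fold id.
#' Identical configurations (including the seed) reproduce identical
#' datasets.
#'
#' The lesion boundary follows the truncated radial-harmonic star
#' \deqn{r(\theta) = r_0 (1 + \sum_{k=2}^{6} a_k \cos(k\theta + \phi_k)),}
#' with per-image random phases; the interior is filled with band-pass
#' filtered noise centred on the class (or shared) frequency band, on top of
#' a linear-gradient background with additive Gaussian noise.
#'
#' @param config A [synthetic_config()].
#' @return List of [image_sample()] objects, ordered class-major.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n <- config$n_classes * config$n_per_class
    samples <- vector("list", n)
    i <- 0L
    for (cls in seq_len(config$n_classes)) {
      for (rep in seq_len(config$n_per_class)) {
        i <- i + 1L
        samples[[i]] <- render_sample(config, cls, i)
      }
    }
    samples
  })
}

# Render one sample; consumes the ambient (seeded) RNG stream.
render_sample <- function(config, cls, index) {
  s <- config$image_size
  r0 <- stats::runif(1, config$lesion_radius_range[1],
                     config$lesion_radius_range[2]) * s
  amps <- config$shape_harmonics[[cls]]
  phases <- stats::runif(5, 0, 2 * pi)
  reach <- r0 * (1 + sum(amps)) + 1

  if (config$mode == "location" && cls == 1L) {
    cx <- s / 2
    cy <- s / 2
  } else {
    lo <- reach + 1
    hi <- s - reach - 1
    if (hi <= lo) {
      # image too small for random placement of this draw: centre it
      cx <- s / 2
      cy <- s / 2
    } else {
      cx <- stats::runif(1, lo, hi)
      cy <- stats::runif(1, lo, hi)
    }
  }

  xs <- matrix(rep(seq_len(s) - 0.5, each = s), s, s)   # column coordinate x
  ys <- matrix(rep(seq_len(s) - 0.5, times = s), s, s)  # row coordinate y
  dx <- xs - cx
  dy <- ys - cy
  theta <- atan2(dy, dx)
  rb <- r0 * (1 + amps[1] * cos(2 * theta + phases[1]) +
                  amps[2] * cos(3 * theta + phases[2]) +
                  amps[3] * cos(4 * theta + phases[3]) +
                  amps[4] * cos(5 * theta + phases[4]) +
                  amps[5] * cos(6 * theta + phases[5]))
  mask <- (dx * dx + dy * dy) <= rb * rb
  storage.mode(mask) <- "integer"

  # Background: random-direction linear gradient in [0.2, 0.5] + noise.
  gdir <- stats::runif(1, 0, 2 * pi)
  g <- cos(gdir) * xs / s + sin(gdir) * ys / s
  g <- (g - min(g)) / max(max(g) - min(g), 1e-12)
  img <- 0.2 + 0.3 * g

  tex <- bandpass_noise(s, config$texture_bands[cls])
  img[mask == 1L] <- config$lesion_intensity +
    config$texture_contrast * tex[mask == 1L]
  img <- img + stats::rnorm(s * s, sd = config$noise_sd)
  img <- clip01(img)

  targets <- as.numeric(seq_len(config$n_classes) == cls)
  names(targets) <- config$class_names
  image_sample(image = img, targets = targets, mask = mask,
               bbox = bbox_from_mask(mask),
               fold = (index - 1L) %% config$n_folds,
               id = sprintf("%s_%04d", config$class_names[cls], index))
}

# Unit-variance band-pass Gaussian noise field; `band` is the centre
# frequency in cycles per image width. The pass band is wide (about two
# octaves) so the texture stays recognisably low- or high-frequency even
# under the magnification of a lesion-interior crop.
bandpass_noise <- function(s, band) {
  z <- matrix(stats::rnorm(s * s), s, s)
  f1 <- c(0:(s %/% 2), -((s - s %/% 2 - 1):1))  # cycles per image width
  fr <- sqrt(outer(f1^2, f1^2, `+`))
  keep <- abs(fr - band) <= band / 1.5
  zt <- stats::fft(z) * keep
  out <- Re(stats::fft(zt, inverse = TRUE)) / (s * s)
  sdv <- stats::sd(out)
  if (sdv < 1e-12) return(out * 0)
  out / sdv
}

#' Calibrated synthetic prediction sets from a binormal score model
#'
#' Draws per-class probability scores whose discrimination converges to the
#' requested AUROC as `n_images` grows. For each class, positives and
#' negatives receive unit-variance Gaussian scores separated by
#' \eqn{d' = \sqrt{2}\,\Phi^{-1}(\mathrm{AUROC})} (the binormal identity
#' \eqn{\mathrm{AUROC} = \Phi(d'/\sqrt 2)}), then a logistic squash maps the
#' scores to \[0, 1\] without changing their ranking.
#'
#' @param n_images Number of images.
#' @param class_aurocs Target AUROC per class, each strictly inside (0, 1).
#' @param seed Integer seed.
#' @param prevalence Positive fraction per class; positives are allocated
#'   deterministically as `round(prevalence * n_images)` per class.
#' @param class_names Optional class names; defaults to `class_1`, ...
#' @param targets Optional 0/1 matrix (images x classes) of ground truth to
#'   score against; supply the same matrix to generate several member
#'   models' predictions over one validation set. When `NULL`, targets are
#'   drawn with `round(prevalence * n_images)` positives per class.
#' @return A [prediction_set()].
#' @export
generate_predictions <- function(n_images, class_aurocs, seed,
                                 prevalence = 0.5, class_names = NULL,
                                 targets = NULL) {
  if (!is_count(n_images)) stop("`n_images` must be a positive integer")
  if (any(class_aurocs <= 0) || any(class_aurocs >= 1)) {
    stop("target AUROCs must lie strictly inside (0, 1): 0 and 1 imply infinite separation")
  }
  if (prevalence <= 0 || prevalence >= 1) stop("`prevalence` must be in (0, 1)")
  k <- length(class_aurocs)
  if (is.null(class_names)) class_names <- sprintf("class_%d", seq_len(k))
  n_pos <- round(prevalence * n_images)
  if (n_pos < 1 || n_pos > n_images - 1) {
    stop("prevalence leaves no positives or no negatives at this n")
  }
  if (!is.null(targets)) {
    targets <- as.matrix(targets)
    if (nrow(targets) != n_images || ncol(targets) != k) {
      stop("`targets` must be an n_images x n_classes matrix")
    }
    if (any(!targets %in% c(0, 1))) stop("`targets` must be 0/1")
  }
  draw_targets <- is.null(targets)
  withr::with_seed(seed, {
    scores <- matrix(NA_real_, n_images, k)
    if (draw_targets) targets <- matrix(0, n_images, k)
    for (j in seq_len(k)) {
      dprime <- sqrt(2) * stats::qnorm(class_aurocs[j])
      if (draw_targets) {
        pos <- sample.int(n_images, n_pos)
        targets[pos, j] <- 1
      } else {
        pos <- which(targets[, j] == 1)
      }
      z <- stats::rnorm(n_images)
      z[pos] <- z[pos] + dprime
      scores[, j] <- stats::plogis(z)
    }
    prediction_set(scores = scores, class_names = class_names,
                   image_ids = sprintf("img_%05d", seq_len(n_images)),
                   targets = targets)
  })
}

#' Per-image, per-class probability scores aligned to targets
#'
#' @param scores Numeric matrix (images x classes) of probabilities in
#'   \[0, 1\].
#' @param class_names Character vector naming the columns.
#' @param image_ids Character vector naming the rows.
#' @param targets 0/1 matrix aligned with `scores`, or `NULL` when ground
#'   truth is unknown.
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(scores, class_names, image_ids, targets = NULL) {
  scores <- as.matrix(scores)
  if (min(scores) < 0 || max(scores) > 1) stop("scores must lie in [0, 1]")
  if (ncol(scores) != length(class_names)) stop("class_names/scores mismatch")
  if (nrow(scores) != length(image_ids)) stop("image_ids/scores mismatch")
  if (!is.null(targets)) {
    targets <- as.matrix(targets)
    if (!identical(dim(targets), dim(scores))) stop("targets/scores shape mismatch")
    if (any(!targets %in% c(0, 1))) stop("targets must be 0/1")
  }
  dimnames(scores) <- list(image_ids, class_names)
  if (!is.null(targets)) dimnames(targets) <- dimnames(scores)
  structure(list(scores = scores, class_names = class_names,
                 image_ids = image_ids, targets = targets),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d images x %d classes (%s)\n",
              nrow(x$scores), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}
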