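#' The corruption registry
#'
#' Sixteen image corruptions, each with five severities whose controlling
#' parameter is strictly monotone in severity. The suite follows the common
#' corruption-benchmark convention and covers four families:
#'
#' * noise: `gaussian_noise`, `shot_noise`, `impulse_noise`, `speckle_noise`
#' * blur: `gaussian_blur`, `defocus_blur`, `motion_blur`, `zoom_blur`
#' * photometric: `brightness`, `contrast`, `gamma`
#' * digital/geometric: `jpeg_compression`, `pixelate`, `elastic_transform`,
#'   `posterize`, `gaussian_blur_local`
#'
#' @return A data frame with columns `name`, `family`, `severity`,
#'   `parameter` (the name of the controlling parameter) and `value`.
#' @export
corruption_registry <- function() {
  reg <- corruption_table()
  do.call(rbind, lapply(names(reg), function(nm) {
    e <- reg[[nm]]
    data.frame(name = nm, family = e$family, severity = 1:5,
               parameter = e$parameter, value = e$params,
               stringsAsFactors = FALSE)
  }))
}

#' Names of the registered corruptions
#' @return Character vector of length 16.
#' @export
corruption_names <- function() names(corruption_table())

corruption_table <- function() {
  list(
    gaussian_noise = list(
      family = "noise", parameter = "sd",
      params = c(0.04, 0.08, 0.12, 0.18, 0.26), stochastic = TRUE,
      fun = function(x, p) x + matrix(stats::rnorm(length(x), sd = p), nrow(x))),
    shot_noise = list(
      family = "noise", parameter = "photons_inverse",
      params = 1 / c(500, 250, 125, 60, 30), stochastic = TRUE,
      fun = function(x, p) {
        lam <- x / p
        matrix(stats::rpois(length(x), lam), nrow(x)) * p
      }),
    impulse_noise = list(
      family = "noise", parameter = "fraction",
      params = c(0.01, 0.03, 0.06, 0.10, 0.17), stochastic = TRUE,
      fun = function(x, p) {
        n <- length(x)
        idx <- sample.int(n, round(p * n))
        x[idx] <- stats::rbinom(length(idx), 1L, 0.5)
        x
      }),
    speckle_noise = list(
      family = "noise", parameter = "sd",
      params = c(0.06, 0.10, 0.15, 0.20, 0.30), stochastic = TRUE,
      fun = function(x, p) x * (1 + matrix(stats::rnorm(length(x), sd = p), nrow(x)))),
    gaussian_blur = list(
      family = "blur", parameter = "sigma",
      params = c(0.5, 1, 1.5, 2.5, 4), stochastic = FALSE,
      fun = function(x, p) EBImage::gblur(x, sigma = p)),
    defocus_blur = list(
      family = "blur", parameter = "radius",
      params = c(1, 2, 3, 5, 7), stochastic = FALSE,
      fun = function(x, p) {
        k <- EBImage::makeBrush(2 * p + 1, "disc")
        EBImage::filter2(x, k / sum(k))
      }),
    motion_blur = list(
      family = "blur", parameter = "length",
      params = c(3, 5, 7, 11, 15), stochastic = FALSE,
      fun = function(x, p) {
        k <- matrix(1 / p, nrow = p, ncol = 1)  # horizontal streak
        EBImage::filter2(x, k)
      }),
    zoom_blur = list(
      family = "blur", parameter = "max_zoom",
      params = c(1.02, 1.04, 1.08, 1.12, 1.18), stochastic = FALSE,
      fun = function(x, p) {
        acc <- x
        for (z in seq(1 + (p - 1) / 5, p, length.out = 5)) {
          acc <- acc + center_zoom(x, z)
        }
        acc / 6
      }),
    brightness = list(
      family = "photometric", parameter = "shift",
      params = c(0.05, 0.10, 0.15, 0.20, 0.30), stochastic = FALSE,
      fun = function(x, p) x + p),
    contrast = list(
      family = "photometric", parameter = "scale",
      params = c(0.75, 0.60, 0.45, 0.30, 0.20), stochastic = FALSE,
      fun = function(x, p) (x - 0.5) * p + 0.5),
    gamma = list(
      family = "photometric", parameter = "exponent",
      params = c(1.3, 1.6, 2.0, 2.5, 3.0), stochastic = FALSE,
      fun = function(x, p) x^p),
    jpeg_compression = list(
      family = "digital", parameter = "quality_inverse",
      params = 1 / c(60, 40, 25, 15, 8), stochastic = FALSE,
      fun = function(x, p) {
        f <- tempfile(fileext = ".jpg")
        on.exit(unlink(f))
        suppressWarnings({
          EBImage::writeImage(EBImage::Image(x), f, quality = round(1 / p))
          y <- EBImage::imageData(EBImage::readImage(f))
        })
        matrix(as.numeric(y), nrow(x), ncol(x))
      }),
    pixelate = list(
      family = "digital", parameter = "factor",
      params = c(2, 3, 4, 6, 8), stochastic = FALSE,
      fun = function(x, p) {
        h <- nrow(x); w <- ncol(x)
        small <- EBImage::resize(x, w = max(1, round(h / p)),
                                 h = max(1, round(w / p)), filter = "none")
        m <- EBImage::resize(small, w = h, h = w, filter = "none")
        matrix(as.numeric(m), h, w)
      }),
    elastic_transform = list(
      family = "geometric", parameter = "alpha",
      params = c(1, 2, 3, 5, 8), stochastic = FALSE,
      fun = function(x, p) elastic_warp(x, alpha = p)),
    posterize = list(
      family = "digital", parameter = "levels_inverse",
      params = 1 / c(32, 16, 8, 5, 3), stochastic = FALSE,
      fun = function(x, p) {
        L <- round(1 / p)
        round(x * (L - 1)) / (L - 1)
      }),
    gaussian_blur_local = list(
      family = "blur", parameter = "sigma",
      params = c(1, 2, 3, 4.5, 6.5), stochastic = FALSE,
      fun = function(x, p) {
        b <- EBImage::gblur(x, sigma = p)
        h <- nrow(x); w <- ncol(x)
        cy <- (h + 1) / 2; cx <- (w + 1) / 2
        d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
        inside <- d2 <= (0.35 * min(h, w))^2
        x[inside] <- b[inside]
        x
      })
  )
}

# Zoom about the image centre by factor z >= 1, bilinear, same output size.
center_zoom <- function(x, z) {
  h <- nrow(x); w <- ncol(x)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ys <- cy + (seq_len(h) - cy) / z
  xs <- cx + (seq_len(w) - cx) / z
  bilinear_sample(x, matrix(rep(ys, times = w), h),
                  matrix(rep(xs, each = h), h))
}

# Smooth random displacement field of `alpha` pixels; the field is drawn
# from a fixed internal stream so the corruption is a deterministic
# function of its input and severity.
elastic_warp <- function(x, alpha, smooth_sigma = 8) {
  h <- nrow(x); w <- ncol(x)
  d <- withr::with_seed(193L + round(alpha * 100), {
    list(u = matrix(stats::rnorm(h * w), h, w),
         v = matrix(stats::rnorm(h * w), h, w))
  })
  u <- EBImage::gblur(d$u, sigma = smooth_sigma)
  v <- EBImage::gblur(d$v, sigma = smooth_sigma)
  u <- u / max(abs(u), 1e-12) * alpha
  v <- v / max(abs(v), 1e-12) * alpha
  ys <- matrix(rep(seq_len(h), times = w), h) + u
  xs <- matrix(rep(seq_len(w), each = h), h) + v
  bilinear_sample(x, ys, xs)
}

# Bilinear interpolation at (row, col) coordinate matrices, clamped to the
# image border.
bilinear_sample <- function(x, ys, xs) {
  h <- nrow(x); w <- ncol(x)
  ys <- pmin(pmax(ys, 1), h)
  xs <- pmin(pmax(xs, 1), w)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  fy <- ys - y0; fx <- xs - x0
  idx <- function(r, c) x[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fy) * (1 - fx) * idx(y0, x0) + (1 - fy) * fx * idx(y0, x1) +
    fy * (1 - fx) * idx(y1, x0) + fy * fx * idx(y1, x1)
  matrix(v, h, w)
}

#' Specify a corruption
#'
#' @param name A registered corruption name; see [corruption_names()].
#' @param severity Integer severity in 1..5 (mild to extreme).
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(name, severity) {
  reg <- corruption_table()
  if (!name %in% names(reg)) {
    stop("unknown corruption '", name, "'; see corruption_names()")
  }
  if (!is_count(severity, 1L) || severity > 5) {
    stop("`severity` must be an integer in 1..5")
  }
  structure(list(name = name, severity = as.integer(severity)),
            class = "corruption_spec")
}

#' Apply a corruption to an image
#'
#' Applies the registered corruption at the requested severity and clamps
#' the result back to \[0, 1\]. Noise-family corruptions are stochastic:
#' pass `seed` for a reproducible draw, otherwise the global RNG stream is
#' consumed. All other corruptions are deterministic functions of the input.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param spec A [corruption_spec()].
#' @param seed Optional integer seed for stochastic corruptions.
#' @return Corrupted image, same shape, values in \[0, 1\].
#' @export
corrupt <- function(image, spec, seed = NULL) {
  assert_image(image)
  stopifnot(inherits(spec, "corruption_spec"))
  e <- corruption_table()[[spec$name]]
  p <- e$params[spec$severity]
  out <- if (e$stochastic) {
    with_seed_or_global(seed, e$fun(image, p))
  } else {
    e$fun(image, p)
  }
  clip01(matrix(as.numeric(out), nrow(image), ncol(image)))
}

#' Integer-pixel translation with zero fill
#'
#' Shifts the image content by `(dx, dy)` pixels (positive `dx` moves
#' content towards higher column indices, positive `dy` towards higher row
#' indices); vacated pixels are set to 0. Surviving pixels are copied
#' exactly, with no interpolation.
#'
#' @param image Numeric matrix.
#' @param dx,dy Signed integer offsets.
#' @return Translated matrix of identical shape.
#' @export
translate_image <- function(image, dx, dy) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h, w)
  src_rows <- max(1, 1 - dy):min(h, h - dy)
  src_cols <- max(1, 1 - dx):min(w, w - dx)
  if (length(src_rows) > 0 && length(src_cols) > 0) {
    out[src_rows + dy, src_cols + dx] <- image[src_rows, src_cols]
  }
  out
}

# Exact fraction of the source area shifted out of frame by (dx, dy).
translation_loss_fraction <- function(h, w, dx, dy) {
  1 - ((w - abs(dx)) * (h - abs(dy))) / (w * h)
}

#' Draw a random translation pair under a bounded loss budget
#'
#' Renders the same image twice under independent random integer
#' translations, each drawn uniformly from the set of offsets `(dx, dy)`
#' whose loss fraction
#' \deqn{1 - \frac{(W - |dx|)(H - |dy|)}{W\,H}}
#' does not exceed `max_loss_fraction` (default 7% of the image area, so
#' that lesion evidence is essentially preserved). Vacated pixels are
#' zero-filled.
#'
#' @param image Numeric matrix.
#' @param max_loss_fraction Maximum fraction of the source area that may be
#'   lost per rendering; in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return An object of class `translation_pair` with elements `image_a`,
#'   `image_b`, `offsets` (2 x 2 matrix of `dx`, `dy` rows per rendering)
#'   and `loss_fractions` (length 2).
#' @export
sample_translation_pair <- function(image, max_loss_fraction = 0.07,
                                    seed = NULL) {
  if (length(image) == 0L) stop("image is empty")
  if (max_loss_fraction < 0 || max_loss_fraction >= 1) {
    stop("`max_loss_fraction` must lie in [0, 1)")
  }
  adm <- admissible_offsets(nrow(image), ncol(image), max_loss_fraction)
  with_seed_or_global(seed, {
    pick <- adm[sample.int(nrow(adm), 2L, replace = TRUE), , drop = FALSE]
    structure(list(
      image_a = translate_image(image, pick[1, 1], pick[1, 2]),
      image_b = translate_image(image, pick[2, 1], pick[2, 2]),
      offsets = matrix(c(pick[1, ], pick[2, ]), 2, 2, byrow = TRUE,
                       dimnames = list(c("a", "b"), c("dx", "dy"))),
      loss_fractions = c(
        a = translation_loss_fraction(nrow(image), ncol(image),
                                      pick[1, 1], pick[1, 2]),
        b = translation_loss_fraction(nrow(image), ncol(image),
                                      pick[2, 1], pick[2, 2]))),
      class = "translation_pair")
  })
}

# Enumerate every integer offset whose exact loss fraction is within budget.
admissible_offsets <- function(h, w, max_loss_fraction) {
  dxs <- -floor(max_loss_fraction * w):floor(max_loss_fraction * w)
  dys <- -floor(max_loss_fraction * h):floor(max_loss_fraction * h)
  grid <- expand.grid(dx = dxs, dy = dys)
  loss <- translation_loss_fraction(h, w, grid$dx, grid$dy)
  as.matrix(grid[loss <= max_loss_fraction, , drop = FALSE])
}

#' Occlude part of a bounding box with a filled rectangle
#'
#' Masks `ratio` of the bounding-box area with a single axis-aligned
#' rectangle whose aspect ratio matches the box, placed uniformly at random
#' fully inside the box. Pixels outside the occluder are never touched.
#'
#' @param image Numeric matrix.
#' @param bbox Half-open 0-based box `(x0, y0, x1, y1)` within the image.
#' @param ratio Fraction of the box area to mask, in \[0, 1\].
#' @param seed Optional integer seed for the occluder position.
#' @param fill Intensity written inside the occluder (default 0).
#' @return The occluded image.
#' @export
occlude <- function(image, bbox, ratio, seed = NULL, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  bbox <- as.integer(bbox)
  if (length(bbox) != 4L || bbox[1] < 0 || bbox[2] < 0 ||
      bbox[3] > w || bbox[4] > h || bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("`bbox` must be a half-open (x0, y0, x1, y1) box inside the image")
  }
  if (ratio < 0 || ratio > 1) stop("`ratio` must lie in [0, 1]")
  if (ratio == 0) return(image)
  bw <- bbox[3] - bbox[1]
  bh <- bbox[4] - bbox[2]
  area <- round(ratio * bw * bh)
  if (area == 0) return(image)
  ow <- max(1L, min(bw, as.integer(round(sqrt(area * bw / bh)))))
  oh <- max(1L, min(bh, as.integer(round(area / ow))))
  with_seed_or_global(seed, {
    ox <- bbox[1] + sample.int(bw - ow + 1L, 1L) - 1L
    oy <- bbox[2] + sample.int(bh - oh + 1L, 1L) - 1L
    image[(oy + 1):(oy + oh), (ox + 1):(ox + ow)] <- fill
    image
  })
}
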