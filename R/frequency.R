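#' Radially averaged Fourier amplitude profile
#'
#' Computes the 2-D discrete Fourier magnitude of a grid, centres it on DC,
#' and averages it within annular bins of radial spatial frequency (cycles
#' per image width). Bin amplitudes are root-mean-square magnitudes, so the
#' profile satisfies a Parseval identity: the sum of squared amplitudes
#' weighted by bin populations equals the total squared spectral magnitude.
#'
#' @param grid Numeric matrix, at least 8 x 8.
#' @param n_bins Number of radial bins (>= 4) spanning \[0, Nyquist\].
#' @return An object of class `radial_profile`: list with `bin_centers`
#'   (cycles per image width), `amplitudes` (RMS magnitude per bin) and
#'   `counts` (spectral coefficients per bin).
#' @export
radial_amplitude_profile <- function(grid, n_bins = 16L) {
  if (!is.matrix(grid) || nrow(grid) < 8 || ncol(grid) < 8) {
    stop("`grid` must be a matrix of at least 8 x 8")
  }
  if (!is_count(n_bins, 4L)) stop("`n_bins` must be an integer >= 4")
  h <- nrow(grid); w <- ncol(grid)
  mag2 <- Mod(stats::fft(grid))^2
  # frequency of each coefficient in cycles per image width (rows rescaled
  # so that an h x w grid shares one frequency axis)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) * (w / h)
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1))
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  nyq <- w / 2
  edges <- seq(0, nyq, length.out = n_bins + 1)
  # diagonal frequencies above the axis Nyquist fold into the top bin so
  # that every spectral coefficient is counted exactly once
  bin <- pmin(findInterval(fr, edges, rightmost.closed = TRUE), n_bins)
  sums <- tapply(mag2, factor(bin, levels = seq_len(n_bins)), sum)
  counts <- tapply(rep(1, length(mag2)), factor(bin, levels = seq_len(n_bins)), sum)
  counts[is.na(counts)] <- 0
  sums[is.na(sums)] <- 0
  amp <- sqrt(ifelse(counts > 0, sums / pmax(counts, 1), 0))
  structure(list(bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 amplitudes = as.numeric(amp),
                 counts = as.numeric(counts)),
            class = "radial_profile")
}

#' Spectral centroid of a radial profile
#'
#' Amplitude-weighted mean frequency; a scalar summary of where the
#' profile's energy sits.
#'
#' @param profile A `radial_profile`.
#' @param exclude_dc Drop the lowest bin (which contains DC) before
#'   averaging; defaults to `TRUE` so gross intensity offsets do not
#'   dominate.
#' @return Centroid frequency in cycles per image width.
#' @export
spectral_centroid <- function(profile, exclude_dc = TRUE) {
  stopifnot(inherits(profile, "radial_profile"))
  a <- profile$amplitudes
  f <- profile$bin_centers
  if (exclude_dc) {
    a <- a[-1]; f <- f[-1]
  }
  sum(a * f) / max(sum(a), 1e-12)
}

#' Input-gradient sensitivity spectrum of a classifier
#'
#' For each image, computes the gradient of the summed class scores with
#' respect to the input pixels (via [input_gradient()]), takes the radial
#' amplitude profile of that gradient map, and averages the profiles over
#' images. The result describes which spatial frequencies the classifier's
#' output responds to.
#'
#' @param classifier An object with an [input_gradient()] method.
#' @param images List of numeric matrices (or [image_sample()] objects).
#' @param n_bins Number of radial bins.
#' @return A `radial_profile` with averaged amplitudes.
#' @export
sensitivity_spectrum <- function(classifier, images, n_bins = 16L) {
  if (length(images) < 1) stop("need at least one image")
  profiles <- lapply(images, function(im) {
    if (inherits(im, "image_sample")) im <- im$image
    g <- input_gradient(classifier, im)
    radial_amplitude_profile(g, n_bins)
  })
  amps <- do.call(rbind, lapply(profiles, `[[`, "amplitudes"))
  structure(list(bin_centers = profiles[[1]]$bin_centers,
                 amplitudes = colMeans(amps),
                 counts = profiles[[1]]$counts),
            class = "radial_profile")
}

#' Gradient of the summed class scores with respect to the input image
#'
#' Generic; classes without a method (no gradient capability) raise an
#' error. The package's reference classifiers implement it by
#' backpropagation.
#'
#' @param classifier A classifier object.
#' @param image Numeric matrix matching the classifier's input size.
#' @return Numeric matrix of per-pixel gradients, same shape as `image`.
#' @export
input_gradient <- function(classifier, image) {
  UseMethod("input_gradient")
}

#' @export
input_gradient.default <- function(classifier, image) {
  stop("this classifier does not expose input-gradient evaluation")
}

#' Serialize a radial profile to a data frame / CSV
#'
#' @param profile A `radial_profile`.
#' @param path Optional CSV path.
#' @return Data frame with columns `bin_center`, `amplitude`.
#' @export
profile_to_table <- function(profile, path = NULL) {
  df <- data.frame(bin_center = profile$bin_centers,
                   amplitude = profile$amplitudes)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
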