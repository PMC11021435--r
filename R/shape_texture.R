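#' Shape-only ablation: flatten the lesion interior
#'
#' Removes texture evidence while preserving the lesion outline: every pixel
#' strictly inside the mask (the mask eroded by one pixel) is set to a
#' single constant — the mean intensity of the background ring obtained by
#' dilating the mask by 5 pixels and subtracting it — so the boundary
#' contour remains visible but carries no interior appearance. Pixels
#' outside the mask are returned unchanged, and the operation is
#' idempotent.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param mask Binary matrix of the same shape, non-empty.
#' @return The ablated image.
#' @export
shape_only <- function(image, mask) {
  assert_image(image)
  if (!identical(dim(mask), dim(image))) stop("mask/image shape mismatch")
  if (sum(mask != 0) < 1) stop("mask is empty")
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  ring <- EBImage::dilate(m, EBImage::makeBrush(11, "disc")) - m
  fill <- if (sum(ring) > 0) mean(image[ring == 1]) else mean(image[m == 0])
  interior <- EBImage::erode(m, EBImage::makeBrush(3, "box"))
  image[interior == 1] <- fill
  image
}

#' Texture-only ablation: stretch the lesion interior to full frame
#'
#' Finds the largest-area axis-aligned rectangle fully inside the mask and
#' resizes its image content (bilinear) to `output_size x output_size`, so
#' the lesion outline is discarded and only interior appearance remains. No
#' pixel outside the rectangle contributes to the output.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param mask Binary matrix of the same shape, non-empty.
#' @param output_size Output side length in pixels (>= 8).
#' @return `output_size x output_size` matrix.
#' @export
texture_only <- function(image, mask, output_size = ncol(image)) {
  assert_image(image)
  if (!identical(dim(mask), dim(image))) stop("mask/image shape mismatch")
  if (sum(mask != 0) < 1) stop("mask is empty")
  if (output_size < 8) stop("`output_size` must be >= 8")
  box <- largest_inscribed_rect(mask != 0)
  if (is.null(box) || (box[3] - box[1]) < 2 || (box[4] - box[2]) < 2) {
    stop("mask too small: no interior rectangle of at least 2 x 2 pixels")
  }
  crop <- image[(box[2] + 1):box[4], (box[1] + 1):box[3], drop = FALSE]
  out <- EBImage::resize(crop, w = output_size, h = output_size,
                         filter = "bilinear", antialias = FALSE)
  matrix(as.numeric(out), output_size, output_size)
}

#' Largest axis-aligned rectangle inscribed in a binary mask
#'
#' Classic histogram-stack sweep over rows: for each row the column-wise
#' run heights form a histogram whose largest rectangle is found with a
#' monotone stack; the best over all rows is the answer.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Half-open 0-based box `(x0, y0, x1, y1)`, or `NULL` for an empty
#'   mask.
#' @export
largest_inscribed_rect <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  heights <- integer(w)
  best <- 0L
  best_box <- NULL
  for (r in seq_len(h)) {
    row <- mask[r, ] != 0
    heights <- ifelse(row, heights + 1L, 0L)
    # largest rectangle in histogram `heights`, right edge at row r
    stack_pos <- integer(w + 1L); stack_h <- integer(w + 1L); top <- 0L
    for (c in seq_len(w + 1L)) {
      cur <- if (c <= w) heights[c] else 0L
      start <- c
      while (top > 0L && stack_h[top] > cur) {
        area <- stack_h[top] * (c - stack_pos[top])
        if (area > best) {
          best <- area
          best_box <- c(x0 = stack_pos[top] - 1L, y0 = r - stack_h[top],
                        x1 = c - 1L, y1 = r)
        }
        start <- stack_pos[top]
        top <- top - 1L
      }
      if (top == 0L || stack_h[top] < cur) {
        top <- top + 1L
        stack_pos[top] <- start
        stack_h[top] <- cur
      }
    }
  }
  if (is.null(best_box)) NULL else as.integer(best_box)
}

#' Decompose one masked image into its shape-only and texture-only variants
#'
#' Convenience wrapper bundling [shape_only()] and [texture_only()].
#'
#' @inheritParams texture_only
#' @return List with `shape_image`, `texture_image`, `fill_value` (constant
#'   used inside the lesion) and `crop_box` (the inscribed rectangle used
#'   for the texture stretch).
#' @export
decompose_image <- function(image, mask, output_size = ncol(image)) {
  sh <- shape_only(image, mask)
  box <- largest_inscribed_rect(mask != 0)
  tx <- texture_only(image, mask, output_size)
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  interior <- EBImage::erode(m, EBImage::makeBrush(3, "box"))
  fill <- if (sum(interior) > 0) sh[interior == 1][1] else NA_real_
  list(shape_image = sh, texture_image = tx, fill_value = fill,
       crop_box = box)
}
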