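# Independent oracles, deliberately naive: direct pair counting and tallies
# that never share code with the package implementations they check.

brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

brute_confusion <- function(scores, targets, threshold = 0.5) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(scores)) {
    d <- scores[i] >= threshold
    if (d && targets[i] == 1) tp <- tp + 1
    if (!d && targets[i] == 0) tn <- tn + 1
    if (d && targets[i] == 0) fp <- fp + 1
    if (!d && targets[i] == 1) fn <- fn + 1
  }
  c(accuracy = (tp + tn) / length(scores),
    f1 = 2 * tp / (2 * tp + fp + fn),
    specificity = tn / (tn + fp),
    sensitivity = tp / (tp + fn),
    precision = tp / (tp + fp))
}

# Exhaustive largest axis-aligned all-ones rectangle by scanning every
# corner pair; O(n^6) but fine for tiny masks.
brute_largest_rect <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  best <- 0
  for (y0 in 1:h) for (y1 in y0:h) for (x0 in 1:w) for (x1 in x0:w) {
    if (all(mask[y0:y1, x0:x1] != 0)) {
      best <- max(best, (y1 - y0 + 1) * (x1 - x0 + 1))
    }
  }
  best
}

# Boundary roughness of a mask: sd of boundary-pixel distance to the mask
# centroid, normalised by the mean distance.
mask_roughness <- function(mask) {
  fg <- which(mask != 0, arr.ind = TRUE)
  cy <- mean(fg[, 1]); cx <- mean(fg[, 2])
  inner <- mask
  inner[-1, ] <- inner[-1, ] & mask[-nrow(mask), ]
  inner[-nrow(mask), ] <- inner[-nrow(mask), ] & mask[-1, ]
  inner[, -1] <- inner[, -1] & mask[, -ncol(mask)]
  inner[, -ncol(mask)] <- inner[, -ncol(mask)] & mask[, -1]
  boundary <- which((mask != 0) & !inner, arr.ind = TRUE)
  d <- sqrt((boundary[, 1] - cy)^2 + (boundary[, 2] - cx)^2)
  stats::sd(d) / mean(d)
}
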