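#' Specify a tiny reference classifier
#'
#' Two desk-scale families embody the architectural contrast between local
#' convolution and global attention:
#'
#' * `local_pool` — stacked 3x3 convolutions, each followed by a leaky
#'   rectifier and 2x2 max pooling, then global average pooling and a
#'   linear head. The pooling pyramid makes it largely insensitive to where
#'   evidence sits.
#' * `global_attn` — non-overlapping patch embedding with a learned
#'   positional encoding, single-head self-attention blocks with residual
#'   MLPs (no spatial pooling), a mean-token head. The positional encoding
#'   lets it exploit absolute location.
#'
#' Both emit per-class probabilities through an elementwise sigmoid
#' (multi-label head).
#'
#' @param family `"local_pool"` or `"global_attn"`.
#' @param input_size Input side length in pixels; must be divisible by
#'   `2^depth` (local_pool) or by `patch_size` (global_attn).
#' @param n_classes Number of output classes.
#' @param width Channel count (local_pool) or embedding dimension
#'   (global_attn).
#' @param depth Number of conv or attention blocks (>= 1).
#' @param patch_size Patch side length (global_attn only).
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("local_pool", "global_attn"),
                            input_size = 64L, n_classes = 2L,
                            width = NULL, depth = NULL,
                            patch_size = 8L, seed = 1L) {
  family <- match.arg(family)
  if (is.null(width)) width <- if (family == "local_pool") 8L else 16L
  if (is.null(depth)) depth <- if (family == "local_pool") 3L else 2L
  if (!is_count(depth, 1L)) stop("`depth` must be >= 1")
  if (!is_count(width, 1L)) stop("`width` must be >= 1")
  if (!is_count(input_size, 8L)) stop("`input_size` must be a positive integer")
  if (family == "local_pool" && input_size %% 2^depth != 0) {
    stop("`input_size` must be divisible by 2^depth for local_pool")
  }
  if (family == "global_attn" && input_size %% patch_size != 0) {
    stop("`input_size` must be divisible by `patch_size` for global_attn")
  }
  structure(list(family = family, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes), width = as.integer(width),
                 depth = as.integer(depth), patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Build a reference classifier from a spec
#'
#' Initialises parameters deterministically from `spec$seed` (He-scaled
#' Gaussians for conv/MLP weights, 1/sqrt(d)-scaled for attention
#' projections).
#'
#' @param spec A [classifier_spec()].
#' @param class_names Optional class names carried into predictions.
#' @return An object of class `lesion_classifier`.
#' @export
build_classifier <- function(spec, class_names = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.null(class_names)) {
    class_names <- sprintf("class_%d", seq_len(spec$n_classes))
  }
  params <- withr::with_seed(spec$seed, init_params(spec))
  structure(list(spec = spec, params = params, class_names = class_names,
                 trained = FALSE),
            class = "lesion_classifier")
}

init_params <- function(spec) {
  gauss <- function(n, sd) stats::rnorm(n, sd = sd)
  p <- list()
  if (spec$family == "local_pool") {
    c_in <- 1L
    for (l in seq_len(spec$depth)) {
      fan_in <- 9L * c_in
      p[[sprintf("conv%d_W", l)]] <-
        matrix(gauss(fan_in * spec$width, sqrt(2 / fan_in)), fan_in, spec$width)
      p[[sprintf("conv%d_b", l)]] <- numeric(spec$width)
      c_in <- spec$width
    }
    p$head_W <- matrix(gauss(spec$width * spec$n_classes, sqrt(1 / spec$width)),
                       spec$width, spec$n_classes)
    p$head_b <- numeric(spec$n_classes)
  } else {
    d <- spec$width
    ps2 <- spec$patch_size^2
    n_tok <- (spec$input_size %/% spec$patch_size)^2
    p$embed_W <- matrix(gauss(ps2 * d, sqrt(1 / ps2)), ps2, d)
    p$embed_b <- numeric(d)
    p$pos_E <- matrix(gauss(n_tok * d, 0.02), n_tok, d)
    for (l in seq_len(spec$depth)) {
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        p[[sprintf("blk%d_%s", l, nm)]] <-
          matrix(gauss(d * d, sqrt(1 / d)), d, d)
      }
      p[[sprintf("blk%d_W1", l)]] <- matrix(gauss(d * 2 * d, sqrt(2 / d)), d, 2 * d)
      p[[sprintf("blk%d_b1", l)]] <- numeric(2 * d)
      p[[sprintf("blk%d_W2", l)]] <- matrix(gauss(2 * d * d, sqrt(1 / (2 * d))), 2 * d, d)
      p[[sprintf("blk%d_b2", l)]] <- numeric(d)
    }
    p$head_W <- matrix(gauss(d * spec$n_classes, sqrt(1 / d)), d, spec$n_classes)
    p$head_b <- numeric(spec$n_classes)
  }
  p
}

# ---- shared low-level pieces -------------------------------------------------

add_row_vec <- function(M, v) M + rep(v, each = nrow(M))

# Slope of the leaky rectifier used in conv blocks and attention MLPs; a
# small negative-side slope keeps gradient flowing through units that a
# large early step would otherwise silence for good.
leaky_slope <- 0.1

sigmoid <- function(x) 1 / (1 + exp(-x))

# im2col for a 3x3 same-padded convolution. A: array (H, W, C, N).
# Returns (H*W*N) x (9*C) matrix; rows ordered (y, x, n) column-major.
im2col3 <- function(A) {
  d <- dim(A); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Apad <- array(0, c(H + 2L, W + 2L, C, N))
  Apad[2:(H + 1), 2:(W + 1), , ] <- A
  X <- matrix(0, H * W * N, 9L * C)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    S <- Apad[(1:H) + 1L + dy, (1:W) + 1L + dx, , , drop = FALSE]
    S <- aperm(S, c(1, 2, 4, 3))
    dim(S) <- c(H * W * N, C)
    X[, (seq_len(C) - 1L) * 9L + k] <- S
  }
  X
}

# Adjoint of im2col3: scatter-add column gradients back onto the input grid.
col2im3 <- function(dX, H, W, C, N) {
  dApad <- array(0, c(H + 2L, W + 2L, C, N))
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    M <- dX[, (seq_len(C) - 1L) * 9L + k, drop = FALSE]
    dim(M) <- c(H, W, N, C)
    M <- aperm(M, c(1, 2, 4, 3))
    ry <- (1:H) + 1L + dy
    rx <- (1:W) + 1L + dx
    dApad[ry, rx, , ] <- dApad[ry, rx, , , drop = FALSE] + M
  }
  dApad[2:(H + 1), 2:(W + 1), , , drop = FALSE]
}

# 2x2 max pool. A: (H, W, N, C) -> list(P, masks); ties resolved in a fixed
# scan order so gradients stay deterministic.
maxpool2 <- function(A) {
  d <- dim(A); H <- d[1]; W <- d[2]
  r1 <- seq(1L, H, 2L); r2 <- r1 + 1L
  c1 <- seq(1L, W, 2L); c2 <- c1 + 1L
  A1 <- A[r1, c1, , , drop = FALSE]; A2 <- A[r2, c1, , , drop = FALSE]
  A3 <- A[r1, c2, , , drop = FALSE]; A4 <- A[r2, c2, , , drop = FALSE]
  P <- pmax(A1, A2, A3, A4)
  m1 <- A1 == P
  m2 <- (A2 == P) & !m1
  m3 <- (A3 == P) & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(P = P, masks = list(m1, m2, m3, m4))
}

maxpool2_backward <- function(dP, masks, H, W) {
  d <- dim(dP)
  dA <- array(0, c(H, W, d[3], d[4]))
  r1 <- seq(1L, H, 2L); r2 <- r1 + 1L
  c1 <- seq(1L, W, 2L); c2 <- c1 + 1L
  dA[r1, c1, , ] <- dP * masks[[1]]
  dA[r2, c1, , ] <- dP * masks[[2]]
  dA[r1, c2, , ] <- dP * masks[[3]]
  dA[r2, c2, , ] <- dP * masks[[4]]
  dA
}

# ---- local_pool forward/backward --------------------------------------------

# X: array (H, W, 1, N). Returns logits (N x K) and caches for backprop.
forward_local <- function(params, spec, X, keep_cache = FALSE) {
  A <- X - 0.5  # centre intensities so units start half-active
  caches <- if (keep_cache) vector("list", spec$depth) else NULL
  for (l in seq_len(spec$depth)) {
    d <- dim(A); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    Xcol <- im2col3(A)
    Y <- add_row_vec(Xcol %*% params[[sprintf("conv%d_W", l)]],
                     params[[sprintf("conv%d_b", l)]])
    mask <- (Y > 0) + leaky_slope * (Y <= 0)   # leaky ReLU multiplier
    Yr <- Y * mask
    A4 <- array(Yr, c(H, W, N, spec$width))
    mp <- maxpool2(A4)                               # (H/2, W/2, N, Cout)
    if (keep_cache) {
      caches[[l]] <- list(Xcol = Xcol, mask = mask, pool_masks = mp$masks,
                          H = H, W = W, C = C, N = N)
    }
    A <- aperm(mp$P, c(1, 2, 4, 3))                  # (H/2, W/2, Cout, N)
  }
  d <- dim(A); Hd <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  Fm <- t(matrix(colMeans(matrix(A, Hd * Wd, C * N)), C, N))  # (N x C)
  logits <- add_row_vec(Fm %*% params$head_W, params$head_b)
  list(logits = logits, features = Fm, caches = caches,
       final_dims = c(Hd, Wd, C, N))
}

# dlogits: (N x K). Returns gradients for every parameter and (optionally)
# the gradient with respect to the input grid.
backward_local <- function(params, spec, fwd, dlogits, want_input_grad = FALSE) {
  g <- list()
  g$head_W <- crossprod(fwd$features, dlogits)
  g$head_b <- colSums(dlogits)
  dF <- dlogits %*% t(params$head_W)                    # (N x C)
  fd <- fwd$final_dims; Hd <- fd[1]; Wd <- fd[2]; C <- fd[3]; N <- fd[4]
  dA <- aperm(array(t(dF), c(C, N, Hd, Wd)), c(3, 4, 1, 2)) / (Hd * Wd)
  for (l in rev(seq_len(spec$depth))) {
    cache <- fwd$caches[[l]]
    H <- cache$H; W <- cache$W
    dA4 <- maxpool2_backward(aperm(dA, c(1, 2, 4, 3)),
                             cache$pool_masks, H, W)  # (H, W, N, Cout)
    dY <- dA4
    dim(dY) <- c(H * W * cache$N, spec$width)
    dY <- dY * cache$mask
    g[[sprintf("conv%d_W", l)]] <- crossprod(cache$Xcol, dY)
    g[[sprintf("conv%d_b", l)]] <- colSums(dY)
    if (l > 1L || want_input_grad) {
      dXcol <- dY %*% t(params[[sprintf("conv%d_W", l)]])
      dA <- col2im3(dXcol, H, W, cache$C, cache$N)
    }
  }
  list(grads = g, input_grad = if (want_input_grad) dA else NULL)
}

# ---- global_attn forward/backward -------------------------------------------

# Linear index matrix mapping token x within-patch position -> image pixel.
patch_index <- function(input_size, patch_size) {
  g <- input_size %/% patch_size
  M <- matrix(0L, g * g, patch_size^2)
  t <- 0L
  for (py in seq_len(g)) for (px in seq_len(g)) {
    t <- t + 1L
    rows <- (py - 1L) * patch_size + seq_len(patch_size)
    cols <- (px - 1L) * patch_size + seq_len(patch_size)
    M[t, ] <- as.integer(outer(rows, (cols - 1L) * input_size, `+`))
  }
  M
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# img: matrix (input_size x input_size). Returns logits (1 x K) + cache.
forward_attn_single <- function(params, spec, img, pidx, keep_cache = FALSE) {
  d <- spec$width
  P <- matrix(img[pidx], nrow(pidx), ncol(pidx)) - 0.5
  X <- add_row_vec(P %*% params$embed_W, params$embed_b) + params$pos_E
  cache <- if (keep_cache) list(P = P, blocks = vector("list", spec$depth)) else NULL
  for (l in seq_len(spec$depth)) {
    Wq <- params[[sprintf("blk%d_Wq", l)]]
    Wk <- params[[sprintf("blk%d_Wk", l)]]
    Wv <- params[[sprintf("blk%d_Wv", l)]]
    Wo <- params[[sprintf("blk%d_Wo", l)]]
    Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
    A <- softmax_rows(tcrossprod(Q, K) / sqrt(d))
    O <- A %*% V
    X1 <- X + O %*% Wo
    Z <- add_row_vec(X1 %*% params[[sprintf("blk%d_W1", l)]],
                     params[[sprintf("blk%d_b1", l)]])
    Zr <- Z * ((Z > 0) + leaky_slope * (Z <= 0))
    X2 <- X1 + add_row_vec(Zr %*% params[[sprintf("blk%d_W2", l)]],
                           params[[sprintf("blk%d_b2", l)]])
    if (keep_cache) {
      cache$blocks[[l]] <- list(X = X, Q = Q, K = K, V = V, A = A, O = O,
                                X1 = X1, Z = Z, Zr = Zr)
    }
    X <- X2
  }
  m <- colMeans(X)
  logits <- as.numeric(m %*% params$head_W + params$head_b)
  list(logits = logits, tokens = X, mean_token = m, cache = cache)
}

# Accumulate parameter gradients for one image into `acc` (same shapes as
# params); returns the updated accumulator and optionally the input grad.
backward_attn_single <- function(params, spec, fwd, dlogits, acc,
                                 want_input_grad = FALSE, pidx = NULL) {
  d <- spec$width
  n_tok <- nrow(params$pos_E)
  acc$head_W <- acc$head_W + outer(fwd$mean_token, dlogits)
  acc$head_b <- acc$head_b + dlogits
  dm <- as.numeric(params$head_W %*% dlogits)
  dX <- matrix(rep(dm / n_tok, each = n_tok), n_tok, d)
  for (l in rev(seq_len(spec$depth))) {
    cb <- fwd$cache$blocks[[l]]
    W1 <- params[[sprintf("blk%d_W1", l)]]
    W2 <- params[[sprintf("blk%d_W2", l)]]
    # MLP residual
    dZr <- dX %*% t(W2)
    dZ <- dZr * ((cb$Z > 0) + leaky_slope * (cb$Z <= 0))
    acc[[sprintf("blk%d_W2", l)]] <- acc[[sprintf("blk%d_W2", l)]] +
      crossprod(cb$Zr, dX)
    acc[[sprintf("blk%d_b2", l)]] <- acc[[sprintf("blk%d_b2", l)]] + colSums(dX)
    acc[[sprintf("blk%d_W1", l)]] <- acc[[sprintf("blk%d_W1", l)]] +
      crossprod(cb$X1, dZ)
    acc[[sprintf("blk%d_b1", l)]] <- acc[[sprintf("blk%d_b1", l)]] + colSums(dZ)
    dX1 <- dX + dZ %*% t(W1)
    # attention residual
    Wo <- params[[sprintf("blk%d_Wo", l)]]
    acc[[sprintf("blk%d_Wo", l)]] <- acc[[sprintf("blk%d_Wo", l)]] +
      crossprod(cb$O, dX1)
    dO <- dX1 %*% t(Wo)
    dA <- tcrossprod(dO, cb$V)
    dV <- crossprod(cb$A, dO)
    dS <- cb$A * (dA - rowSums(dA * cb$A))
    dQ <- (dS %*% cb$K) / sqrt(d)
    dK <- (crossprod(dS, cb$Q)) / sqrt(d)
    for (nm in c("Wq", "Wk", "Wv")) {
      dmat <- switch(nm, Wq = dQ, Wk = dK, Wv = dV)
      acc[[sprintf("blk%d_%s", l, nm)]] <- acc[[sprintf("blk%d_%s", l, nm)]] +
        crossprod(cb$X, dmat)
    }
    dX <- dX1 + dQ %*% t(params[[sprintf("blk%d_Wq", l)]]) +
      dK %*% t(params[[sprintf("blk%d_Wk", l)]]) +
      dV %*% t(params[[sprintf("blk%d_Wv", l)]])
  }
  acc$embed_W <- acc$embed_W + crossprod(fwd$cache$P, dX)
  acc$embed_b <- acc$embed_b + colSums(dX)
  acc$pos_E <- acc$pos_E + dX
  input_grad <- NULL
  if (want_input_grad) {
    dP <- dX %*% t(params$embed_W)
    g <- matrix(0, spec$input_size, spec$input_size)
    g[as.vector(pidx)] <- as.vector(dP)
    input_grad <- g
  }
  list(acc = acc, input_grad = input_grad)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# ---- training ---------------------------------------------------------------

#' Training configuration for reference classifiers
#'
#' AdamW with a cosine-annealed learning rate and a per-class binary
#' cross-entropy loss.
#'
#' @param epochs Number of passes over the data (>= 1).
#' @param learning_rate Initial AdamW step size (default 1e-4).
#' @param batch_size Minibatch size.
#' @param weight_decay Decoupled weight decay applied to weight matrices.
#' @param seed Integer seed controlling shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs, learning_rate = 1e-4, batch_size = 32L,
                         weight_decay = 1e-4, seed = 1L) {
  if (!is_count(epochs, 1L)) stop("`epochs` must be an integer >= 1")
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (!is_count(batch_size, 1L)) stop("`batch_size` must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, seed = as.integer(seed),
                 loss = "binary_cross_entropy", schedule = "cosine"),
            class = "train_config")
}

#' Desk-scale training defaults per model family
#'
#' Convenience settings sized for minute-scale CPU training at 64x64: the
#' conv family takes larger steps over fewer epochs, the attention family
#' (cheaper per epoch) trains longer at a smaller rate.
#'
#' @param family `"local_pool"` or `"global_attn"`.
#' @param epochs Override the per-family default (20 / 30).
#' @param seed Integer seed.
#' @return A [train_config()].
#' @export
desk_train_config <- function(family = c("local_pool", "global_attn"),
                              epochs = NULL, seed = 1L) {
  family <- match.arg(family)
  if (family == "local_pool") {
    train_config(epochs = if (is.null(epochs)) 20L else epochs,
                 learning_rate = 0.02, batch_size = 16L, seed = seed)
  } else {
    train_config(epochs = if (is.null(epochs)) 30L else epochs,
                 learning_rate = 0.01, batch_size = 16L, seed = seed)
  }
}

samples_to_arrays <- function(dataset, input_size) {
  imgs <- lapply(dataset, function(s) if (inherits(s, "image_sample")) s$image else s)
  if (any(vapply(imgs, function(m) !all(dim(m) == input_size), logical(1)))) {
    stop("image sizes do not match the classifier input size")
  }
  X <- array(unlist(imgs, use.names = FALSE),
             c(input_size, input_size, length(imgs)))
  targets <- NULL
  if (inherits(dataset[[1]], "image_sample")) {
    targets <- do.call(rbind, lapply(dataset, function(s) s$targets))
  }
  ids <- if (inherits(dataset[[1]], "image_sample")) {
    vapply(dataset, function(s) s$id, character(1))
  } else sprintf("img_%05d", seq_along(imgs))
  list(X = X, targets = targets, ids = ids)
}

bce_loss_grad <- function(logits, targets) {
  p <- sigmoid(logits)
  eps <- 1e-12
  loss <- -mean(targets * log(p + eps) + (1 - targets) * log(1 - p + eps))
  dlogits <- (p - targets) / length(p)
  list(loss = loss, dlogits = dlogits, probs = p)
}

#' Train a reference classifier
#'
#' Minimises per-class binary cross-entropy with AdamW and a cosine
#' annealing schedule over epochs. Runs are reproducible up to
#' floating-point associativity given identical seeds.
#'
#' @param classifier A [build_classifier()] result.
#' @param dataset List of [image_sample()] objects (targets required).
#' @param config A [train_config()].
#' @return The trained classifier, with the per-epoch mean loss in
#'   `$history`.
#' @export
train_classifier <- function(classifier, dataset, config) {
  stopifnot(inherits(classifier, "lesion_classifier"),
            inherits(config, "train_config"))
  if (length(dataset) == 0) stop("dataset is empty")
  arr <- samples_to_arrays(dataset, classifier$spec$input_size)
  if (is.null(arr$targets)) stop("training requires image_sample targets")
  if (ncol(arr$targets) != classifier$spec$n_classes) {
    stop("dataset class count does not match the classifier spec")
  }
  spec <- classifier$spec
  params <- classifier$params
  n <- dim(arr$X)[3]
  state <- list(m = zero_like(params), v = zero_like(params), t = 0L)
  pidx <- if (spec$family == "global_attn") {
    patch_index(spec$input_size, spec$patch_size)
  } else NULL
  history <- numeric(config$epochs)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        tb <- arr$targets[idx, , drop = FALSE]
        if (spec$family == "local_pool") {
          Xb <- array(arr$X[, , idx, drop = FALSE],
                      c(spec$input_size, spec$input_size, 1L, length(idx)))
          fwd <- forward_local(params, spec, Xb, keep_cache = TRUE)
          lg <- bce_loss_grad(fwd$logits, tb)
          grads <- backward_local(params, spec, fwd, lg$dlogits)$grads
        } else {
          acc <- zero_like(params)
          loss_sum <- 0
          for (j in seq_along(idx)) {
            fwd <- forward_attn_single(params, spec, arr$X[, , idx[j]],
                                       pidx, keep_cache = TRUE)
            lgj <- bce_loss_grad(matrix(fwd$logits, 1L), tb[j, , drop = FALSE])
            loss_sum <- loss_sum + lgj$loss
            acc <- backward_attn_single(params, spec, fwd,
                                        as.numeric(lgj$dlogits) / length(idx),
                                        acc)$acc
          }
          grads <- acc
          lg <- list(loss = loss_sum / length(idx))
        }
        upd <- adamw_step(params, grads, state, lr, config$weight_decay)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, lg$loss)
      }
      history[epoch] <- mean(losses)
    }
  })
  classifier$params <- params
  classifier$history <- history
  classifier$trained <- TRUE
  classifier
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (grepl("_W", nm, fixed = TRUE)) {
      step <- step + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# ---- prediction and gradients -----------------------------------------------

#' Predict class probabilities
#'
#' @param object A trained (or freshly built) `lesion_classifier`.
#' @param newdata List of [image_sample()] objects or plain matrices, or a
#'   3-d array (H x W x N).
#' @param batch_size Images per forward batch (local_pool only).
#' @param ... Unused.
#' @return A [prediction_set()]; targets are carried over when `newdata`
#'   consists of annotated samples.
#' @export
predict.lesion_classifier <- function(object, newdata, batch_size = 64L, ...) {
  spec <- object$spec
  if (is.array(newdata) && length(dim(newdata)) == 3L) {
    newdata <- lapply(seq_len(dim(newdata)[3]), function(i) newdata[, , i])
  }
  arr <- samples_to_arrays(newdata, spec$input_size)
  n <- dim(arr$X)[3]
  probs <- matrix(NA_real_, n, spec$n_classes)
  if (spec$family == "local_pool") {
    for (start in seq(1L, n, by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, n)
      Xb <- array(arr$X[, , idx, drop = FALSE],
                  c(spec$input_size, spec$input_size, 1L, length(idx)))
      probs[idx, ] <- sigmoid(forward_local(object$params, spec, Xb)$logits)
    }
  } else {
    pidx <- patch_index(spec$input_size, spec$patch_size)
    for (i in seq_len(n)) {
      fwd <- forward_attn_single(object$params, spec, arr$X[, , i], pidx)
      probs[i, ] <- sigmoid(fwd$logits)
    }
  }
  prediction_set(probs, object$class_names, arr$ids, targets = arr$targets)
}

#' @rdname input_gradient
#' @export
input_gradient.lesion_classifier <- function(classifier, image) {
  spec <- classifier$spec
  if (!all(dim(image) == spec$input_size)) {
    stop("image size does not match the classifier input size")
  }
  if (spec$family == "local_pool") {
    Xb <- array(image, c(spec$input_size, spec$input_size, 1L, 1L))
    fwd <- forward_local(classifier$params, spec, Xb, keep_cache = TRUE)
    p <- sigmoid(fwd$logits)
    dlogits <- p * (1 - p)  # d/dlogit of the summed sigmoid scores
    bwd <- backward_local(classifier$params, spec, fwd, dlogits,
                          want_input_grad = TRUE)
    matrix(bwd$input_grad, spec$input_size, spec$input_size)
  } else {
    pidx <- patch_index(spec$input_size, spec$patch_size)
    fwd <- forward_attn_single(classifier$params, spec, image, pidx,
                               keep_cache = TRUE)
    p <- sigmoid(fwd$logits)
    acc <- zero_like(classifier$params)
    bwd <- backward_attn_single(classifier$params, spec, fwd, p * (1 - p),
                                acc, want_input_grad = TRUE, pidx = pidx)
    bwd$input_grad
  }
}

#' Save / load a classifier checkpoint
#'
#' Single-file RDS checkpoint embedding the spec, parameters, class names
#' and training history.
#'
#' @param classifier A `lesion_classifier`.
#' @param path Checkpoint path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the classifier.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "lesion_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "lesion_classifier")) stop("not a classifier checkpoint")
  obj
}
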