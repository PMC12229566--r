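#' Model configuration
#'
#' Describes a compact convolutional classifier: one inspectable
#' convolutional first layer (the "receptive fields" under study) followed
#' by ReLU, average pooling, one hidden fully-connected ReLU layer and a
#' softmax output. The `3d` variant gives the first layer a temporal extent
#' of `n_time` frames (valid convolution in time, activations averaged over
#' output frames before pooling).
#'
#' @param variant `"2d"` or `"3d"`.
#' @param n_filters number of first-layer filters.
#' @param filter_size spatial side length of first-layer filters (pixels).
#' @param n_classes number of output classes.
#' @param image_size input side length the model consumes; larger training
#'   images are randomly cropped to this size, evaluation images
#'   centre-cropped.
#' @param stride first-layer stride.
#' @param pool average-pooling width after the first layer.
#' @param n_hidden units in the hidden fully-connected layer.
#' @param n_time temporal extent of the 3d first layer (frames).
#' @return list of class `pm_model_config`.
#' @export
model_config <- function(variant = c("2d", "3d"), n_filters = 16,
                         filter_size = 9, n_classes = 10, image_size = 64,
                         stride = 2, pool = 2, n_hidden = 48, n_time = 5) {
  variant <- match.arg(variant)
  if (filter_size > image_size)
    stop_config("`filter_size` cannot exceed `image_size`")
  out_conv <- floor((image_size - filter_size) / stride) + 1
  if (out_conv < pool)
    stop_config("conv output smaller than the pooling width")
  structure(list(variant = variant, n_filters = n_filters,
                 filter_size = filter_size, n_classes = n_classes,
                 image_size = image_size, stride = stride, pool = pool,
                 n_hidden = n_hidden,
                 n_time = if (variant == "3d") n_time else 1L),
            class = "pm_model_config")
}

#' Model configuration from a setting preset
#'
#' @param setting a `pm_setting` from [setting_preset()].
#' @param n_classes,image_size overrides for the classification problem.
#' @param ... further arguments to [model_config()].
#' @return a `pm_model_config`.
#' @export
config_from_setting <- function(setting, n_classes = 10,
                                image_size = setting$image_size, ...) {
  model_config(n_filters = setting$n_filters,
               filter_size = setting$filter_size,
               n_classes = n_classes, image_size = image_size, ...)
}

conv_geometry <- function(config) {
  k <- config$filter_size
  n <- config$image_size
  oh <- floor((n - k) / config$stride) + 1
  p <- config$pool
  ph <- floor(oh / p)
  list(oh = oh, ow = oh, ph = ph, pw = ph, n_patch = oh * oh,
       n_pool = ph * ph, npix = k * k * 3,
       n_features = ph * ph * config$n_filters)
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

#' Build an untrained model
#'
#' Parameters are initialised Glorot-uniform from the given seed; identical
#' `(config, seed)` pairs yield bit-identical initial parameters.
#'
#' @param config a `pm_model_config`.
#' @param seed integer seed.
#' @return object of class `pm_model`.
#' @export
build_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "pm_model_config"))
  g <- conv_geometry(config)
  k <- config$filter_size
  K <- config$n_filters
  with_seed(seed, {
    if (config$variant == "2d") {
      W1 <- glorot(g$npix, k * k * K, c(k, k, 3, K))
    } else {
      W1 <- glorot(g$npix * config$n_time, config$n_time * k * k * K,
                   c(config$n_time, k, k, 3, K))
    }
    W2 <- glorot(g$n_features, config$n_hidden, c(g$n_features, config$n_hidden))
    W3 <- glorot(config$n_hidden, config$n_classes,
                 c(config$n_hidden, config$n_classes))
    model <- list(config = config, seed = seed,
                  W1 = W1, b1 = numeric(K),
                  W2 = W2, b2 = numeric(config$n_hidden),
                  W3 = W3, b3 = numeric(config$n_classes),
                  history = NULL, regimen = NULL)
  })
  structure(model, class = "pm_model")
}

#' @export
print.pm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pm_model %s> %d filters %dx%d%s, %d classes, input %d px%s\n",
              cfg$variant, cfg$n_filters, cfg$filter_size, cfg$filter_size,
              if (cfg$variant == "3d") sprintf("x%dt", cfg$n_time) else "",
              cfg$n_classes, cfg$image_size,
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

# Linear indices of all first-layer patches: n_patch x (k*k*3), patch order
# column-major over the (oh x ow) output grid, pixel order matching the
# column-major flattening of a (k, k, 3) weight slice.
conv_indices <- function(config) {
  n <- config$image_size
  k <- config$filter_size
  s <- config$stride
  o <- seq(1, n - k + 1, by = s)
  starts <- as.vector(outer(o, (o - 1) * n, "+"))
  off <- as.vector(outer(outer(0:(k - 1), (0:(k - 1)) * n, "+"),
                         (0:2) * n * n, "+"))
  outer(starts, off, "+")
}

# Pool-cell assignment of each conv patch (NA where the cell would be
# truncated at the border).
pool_groups <- function(config) {
  g <- conv_geometry(config)
  p <- config$pool
  a <- rep(seq_len(g$oh), times = g$ow)
  b <- rep(seq_len(g$ow), each = g$oh)
  ci <- ceiling(a / p)
  cj <- ceiling(b / p)
  ok <- ci <= g$ph & cj <= g$pw
  grp <- ifelse(ok, ci + (cj - 1) * g$ph, NA_integer_)
  list(group = grp, valid = ok)
}

# Stack a list of H x W x 3 arrays into a (H*W*3) x B matrix.
images_to_matrix <- function(pixels) {
  vapply(pixels, as.vector, numeric(length(pixels[[1]])))
}

# Extract patches for a batch: ((n_patch*B) x npix), patch index fastest.
batch_patches <- function(Xv, IDX, B) {
  n_patch <- nrow(IDX)
  P <- nrow(Xv)
  big <- IDX[rep(seq_len(n_patch), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * P, each = n_patch)
  out <- Xv[big]
  dim(out) <- dim(big)
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass on a batch (Xv: (H*W*3) x B for 2d, or a list of
# per-frame matrices for 3d). Returns intermediates needed for backprop
# and for activation extraction.
model_forward <- function(model, Xv, keep = FALSE) {
  cfg <- model$config
  g <- conv_geometry(cfg)
  IDX <- conv_indices(cfg)
  pg <- pool_groups(cfg)
  K <- cfg$n_filters
  p2 <- cfg$pool^2
  if (cfg$variant == "2d") {
    B <- ncol(Xv)
    Pall <- batch_patches(Xv, IDX, B)
    Wm <- matrix(model$W1, g$npix, K)
    Z1 <- Pall %*% Wm
    Z1 <- sweep(Z1, 2, model$b1, "+")
    A1 <- relu(Z1)
    Zlist <- list(Z1); Alist <- list(A1); Plist <- list(Pall)
  } else {
    Tn <- cfg$n_time
    B <- ncol(Xv[[1]])
    nfr <- length(Xv)
    To <- nfr - Tn + 1
    if (To < 1) stop_config("clip shorter than the first-layer temporal extent")
    Plist <- lapply(Xv, batch_patches, IDX = IDX, B = B)
    Wms <- lapply(seq_len(Tn), function(dt)
      matrix(model$W1[dt, , , , ], g$npix, K))
    Zlist <- vector("list", To)
    for (tau in seq_len(To)) {
      Z <- Plist[[tau]] %*% Wms[[1]]
      for (dt in 2:Tn) Z <- Z + Plist[[tau + dt - 1]] %*% Wms[[dt]]
      Zlist[[tau]] <- sweep(Z, 2, model$b1, "+")
    }
    Alist <- lapply(Zlist, relu)
  }
  # pool each activation map, average over output frames (To = 1 for 2d)
  grp_b <- pg$group[pg$valid]
  grp_all <- rep(grp_b, B) + rep((seq_len(B) - 1L) * g$n_pool,
                                 each = length(grp_b))
  vrows <- rep(pg$valid, B)
  pool_one <- function(A) rowsum(A[vrows, , drop = FALSE], grp_all) / p2
  A1p <- Reduce(`+`, lapply(Alist, pool_one)) / length(Alist)
  arr <- array(A1p, c(g$n_pool, B, K))
  Fm <- t(matrix(aperm(arr, c(1, 3, 2)), g$n_pool * K, B))
  Z2 <- sweep(Fm %*% model$W2, 2, model$b2, "+")
  H1 <- relu(Z2)
  O <- sweep(H1 %*% model$W3, 2, model$b3, "+")
  probs <- softmax_rows(O)
  out <- list(probs = probs, logits = O, H1 = H1, Z2 = Z2, Fm = Fm,
              A1p = A1p, B = B, n_out_frames = length(Alist))
  if (keep) {
    out$Zlist <- Zlist
    out$Plist <- Plist
    out$Alist <- Alist
    out$grp_all <- grp_all
    out$vrows <- vrows
  }
  out
}

# Gradients of mean cross-entropy wrt all parameters. `fw` must come from
# model_forward(..., keep = TRUE); Y is a B x n_classes one-hot matrix.
model_backward <- function(model, fw, Y) {
  cfg <- model$config
  g <- conv_geometry(cfg)
  K <- cfg$n_filters
  B <- fw$B
  p2 <- cfg$pool^2
  dO <- (fw$probs - Y) / B
  dW3 <- crossprod(fw$H1, dO)
  db3 <- colSums(dO)
  dH1 <- dO %*% t(model$W3)
  dH1[fw$Z2 <= 0] <- 0
  dW2 <- crossprod(fw$Fm, dH1)
  db2 <- colSums(dH1)
  dF <- dH1 %*% t(model$W2)
  m <- array(t(dF), c(g$n_pool, K, B))
  dA1p <- matrix(aperm(m, c(1, 3, 2)), g$n_pool * B, K)
  To <- fw$n_out_frames
  dA_valid <- dA1p[fw$grp_all, , drop = FALSE] / (p2 * To)
  n_patch <- g$n_patch
  if (cfg$variant == "2d") {
    dZ1 <- matrix(0, n_patch * B, K)
    dZ1[fw$vrows, ] <- dA_valid
    dZ1[fw$Zlist[[1]] <= 0] <- 0
    dW1 <- crossprod(fw$Plist[[1]], dZ1)
    db1 <- colSums(dZ1)
    dW1 <- array(dW1, dim(model$W1))
  } else {
    Tn <- cfg$n_time
    dW1 <- array(0, dim(model$W1))
    db1 <- numeric(K)
    for (tau in seq_len(To)) {
      dZ <- matrix(0, n_patch * B, K)
      dZ[fw$vrows, ] <- dA_valid
      dZ[fw$Zlist[[tau]] <= 0] <- 0
      db1 <- db1 + colSums(dZ)
      for (dt in seq_len(Tn)) {
        dW1[dt, , , , ] <- dW1[dt, , , , ] +
          array(crossprod(fw$Plist[[tau + dt - 1]], dZ),
                c(cfg$filter_size, cfg$filter_size, 3, K))
      }
    }
  }
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

# Crop pixels to the model input size: random offset when `random`, centre
# otherwise. Works on images and clips.
crop_to <- function(px, size, random = FALSE) {
  d <- dim(px)
  sp <- if (length(d) == 3) d[1:2] else d[2:3]
  if (all(sp == size)) return(px)
  mx <- sp - size
  off <- if (random) c(sample.int(mx[1] + 1L, 1L), sample.int(mx[2] + 1L, 1L)) - 1L
         else floor(mx / 2)
  if (length(d) == 3) {
    px[off[1] + seq_len(size), off[2] + seq_len(size), , drop = FALSE]
  } else {
    px[, off[1] + seq_len(size), off[2] + seq_len(size), , drop = FALSE]
  }
}

flip_h <- function(px) {
  d <- dim(px)
  if (length(d) == 3) px[, rev(seq_len(d[2])), , drop = FALSE]
  else px[, , rev(seq_len(d[3])), , drop = FALSE]
}

# Turn a dataset tibble (or list of arrays) into forward-pass input.
prepare_input <- function(model, pixels, degradation = NULL) {
  cfg <- model$config
  px <- lapply(pixels, function(p) {
    p <- crop_to(p, cfg$image_size)
    if (!is.null(degradation)) p <- apply_degradation(p, degradation)
    p
  })
  if (cfg$variant == "2d") {
    images_to_matrix(px)
  } else {
    nfr <- dim(px[[1]])[1]
    lapply(seq_len(nfr), function(t)
      images_to_matrix(lapply(px, function(p) p[t, , , ])))
  }
}

#' Class probabilities for a dataset
#'
#' Generic over classifiers: `pm_model` objects run the network forward
#' pass; a plain function is treated as an oracle classifier and called as
#' `f(dataset)`, expected to return an `n x n_classes` probability matrix.
#'
#' @param model a `pm_model` or a function.
#' @param dataset a dataset tibble with a `pixels` list-column.
#' @param degradation optional [degradation_spec()] applied to each input.
#' @param ... unused.
#' @return numeric matrix, one row per image, one column per class.
#' @export
predict_proba <- function(model, dataset, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.pm_model <- function(model, dataset, degradation = NULL,
                                   batch_size = 64, ...) {
  pixels <- if (is.data.frame(dataset)) dataset$pixels else dataset
  n <- length(pixels)
  out <- matrix(0, n, model$config$n_classes)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    Xv <- prepare_input(model, pixels[s:e], degradation)
    out[s:e, ] <- model_forward(model, Xv)$probs
  }
  out
}

#' @rdname predict_proba
#' @export
predict_proba.function <- function(model, dataset, ...) {
  model(dataset)
}

#' @param batch_size forward-pass batch size.
#' @rdname predict_proba
#' @export
predict.pm_model <- function(object, dataset, degradation = NULL, ...) {
  predict_proba(object, dataset, degradation = degradation, ...)
}
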