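#' Training hyperparameters
#'
#' Reference defaults mirror the optimisation used for the full-scale
#' settings: SGD with Nesterov momentum 0.9, batch size 128, constant
#' learning rate 0.001 and categorical cross-entropy. Desk-scale presets
#' shrink the batch and raise the rate; pass an `lr_schedule` from a
#' [setting_preset()] to use its schedule (constant or reduce-on-plateau).
#'
#' @param batch_size minibatch size.
#' @param lr_schedule `list(kind = "constant", rate = )` or
#'   `list(kind = "plateau", initial = , factor = , patience = ,
#'   min_delta = , cooldown = , min_rate = )` (plateau monitors the
#'   validation loss).
#' @param momentum Nesterov momentum coefficient.
#' @param n_epochs total epochs; must equal the regimen's total.
#' @param seed integer seed controlling shuffling, augmentation and the
#'   validation split.
#' @param flip apply random horizontal flips.
#' @param validation_fraction seeded fraction of the dataset held out to
#'   monitor validation loss/accuracy.
#' @return list of class `pm_hyperparams`.
#' @export
training_hyperparams <- function(batch_size = 128,
                                 lr_schedule = list(kind = "constant",
                                                    rate = 0.001),
                                 momentum = 0.9, n_epochs = 200, seed = 1,
                                 flip = TRUE, validation_fraction = 0.1) {
  structure(list(batch_size = batch_size, lr_schedule = lr_schedule,
                 momentum = momentum, n_epochs = n_epochs, seed = seed,
                 flip = flip, validation_fraction = validation_fraction),
            class = "pm_hyperparams")
}

frozen_unit_ids <- function(model, fraction) {
  if (fraction <= 0) return(integer(0))
  seq_len(ceiling(fraction * model$config$n_filters))
}

# Zero the first-layer gradient of frozen units. W1 last dim indexes units.
mask_frozen <- function(grads, frozen) {
  if (length(frozen) == 0) return(grads)
  nd <- length(dim(grads$W1))
  if (nd == 4) grads$W1[, , , frozen] <- 0 else grads$W1[, , , , frozen] <- 0
  grads$b1[frozen] <- 0
  grads
}

#' Train a model under a regimen
#'
#' Runs minibatch SGD with Nesterov momentum. At every epoch the regimen's
#' phase determines the input degradation (Gaussian blur and/or grayscale)
#' applied to each training example after crop/flip augmentation, and the
#' fraction of first-layer units whose parameters are frozen (their
#' gradients are zeroed; the frozen subset is the units with the lowest
#' indices in the seeded initialisation order). Training is deterministic
#' for a fixed seed in single-threaded BLAS mode.
#'
#' @param model an untrained (or previously trained) `pm_model`.
#' @param dataset dataset tibble from [generate_classification_dataset()] or
#'   [generate_video_dataset()].
#' @param regimen a `pm_regimen`; its total epochs must equal
#'   `hyperparams$n_epochs`.
#' @param hyperparams a `pm_hyperparams`.
#' @return the trained `pm_model`, with `$history` (per-epoch tibble:
#'   `epoch`, `phase`, `loss`, `accuracy`, `val_loss`, `val_accuracy`,
#'   `learning_rate`) and `$regimen` recorded.
#' @export
train_with_regimen <- function(model, dataset, regimen, hyperparams) {
  stopifnot(inherits(model, "pm_model"), inherits(regimen, "pm_regimen"),
            inherits(hyperparams, "pm_hyperparams"))
  hp <- hyperparams
  if (regimen$total_epochs != hp$n_epochs)
    stop_config("`hyperparams$n_epochs` must equal the regimen's total epochs")
  if (max(dataset$label) > model$config$n_classes)
    stop_config("dataset labels exceed the model's `n_classes`")
  cfg <- model$config
  C <- cfg$n_classes
  with_seed(hp$seed, {
    n <- nrow(dataset)
    n_val <- floor(hp$validation_fraction * n)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr <- dataset[setdiff(seq_len(n), val_idx), ]
    va <- dataset[val_idx, ]
    vel <- list(W1 = model$W1 * 0, b1 = model$b1 * 0, W2 = model$W2 * 0,
                b2 = model$b2 * 0, W3 = model$W3 * 0, b3 = model$b3 * 0)
    sched <- hp$lr_schedule
    lr <- if (sched$kind == "constant") sched$rate else sched$initial
    best_val <- Inf; wait <- 0
    hist <- vector("list", hp$n_epochs)
    for (ep in seq_len(hp$n_epochs)) {
      phase <- transform_for_epoch(regimen, ep - 1L)
      deg <- degradation_spec(phase$blur_sigma, !phase$chromatic)
      frozen <- frozen_unit_ids(model, phase$frozen_fraction)
      ord <- sample.int(nrow(tr))
      tot_loss <- 0; tot_correct <- 0
      for (s in seq(1, nrow(tr), by = hp$batch_size)) {
        e <- min(nrow(tr), s + hp$batch_size - 1)
        rows <- ord[s:e]
        px <- lapply(tr$pixels[rows], function(p) {
          p <- crop_to(p, cfg$image_size, random = TRUE)
          if (hp$flip && runif(1) < 0.5) p <- flip_h(p)
          apply_degradation(p, deg)
        })
        Xv <- if (cfg$variant == "2d") images_to_matrix(px) else {
          nfr <- dim(px[[1]])[1]
          lapply(seq_len(nfr), function(t)
            images_to_matrix(lapply(px, function(p) p[t, , , ])))
        }
        Y <- matrix(0, length(rows), C)
        Y[cbind(seq_along(rows), tr$label[rows])] <- 1
        fw <- model_forward(model, Xv, keep = TRUE)
        eps <- 1e-12
        loss <- -mean(log(pmax(fw$probs[Y == 1], eps)))
        if (!is.finite(loss))
          abort(sprintf("non-finite training loss at epoch %d (exploding gradients; lower the learning rate)", ep),
                class = "pm_error_training")
        gr <- mask_frozen(model_backward(model, fw, Y), frozen)
        for (nm in names(vel)) {
          vel[[nm]] <- hp$momentum * vel[[nm]] - lr * gr[[nm]]
          model[[nm]] <- model[[nm]] + hp$momentum * vel[[nm]] - lr * gr[[nm]]
        }
        tot_loss <- tot_loss + loss * length(rows)
        tot_correct <- tot_correct +
          sum(max.col(fw$probs, ties.method = "first") == tr$label[rows])
      }
      val <- c(NA_real_, NA_real_)
      if (nrow(va) > 0) {
        pv <- predict_proba(model, va, degradation = deg)
        val[1] <- -mean(log(pmax(pv[cbind(seq_len(nrow(va)), va$label)], 1e-12)))
        val[2] <- mean(max.col(pv, ties.method = "first") == va$label)
        if (sched$kind == "plateau") {
          if (val[1] < best_val - sched$min_delta) {
            best_val <- val[1]; wait <- 0
          } else {
            wait <- wait + 1
            if (wait > sched$patience) {
              lr <- max(sched$min_rate, lr * sched$factor)
              wait <- 0
            }
          }
        }
      }
      hist[[ep]] <- tibble(epoch = ep, phase = phase$phase,
                           loss = tot_loss / nrow(tr),
                           accuracy = tot_correct / nrow(tr),
                           val_loss = val[1], val_accuracy = val[2],
                           learning_rate = lr)
    }
    model$history <- dplyr::bind_rows(hist)
    model$regimen <- regimen
  })
  model
}

#' Extract first-layer receptive fields
#'
#' Returns the raw (unnormalised) first-layer weight tensors, one per unit,
#' in stable unit order: `h x w x 3` arrays for 2d models, `t x h x w x 3`
#' for 3d models.
#'
#' @param model a `pm_model` (trained or freshly initialised).
#' @return tibble with `unit_id` and the list-column `weights`.
#' @export
extract_first_layer_rfs <- function(model) {
  stopifnot(inherits(model, "pm_model"))
  K <- model$config$n_filters
  w <- if (model$config$variant == "2d") {
    lapply(seq_len(K), function(k) model$W1[, , , k])
  } else {
    lapply(seq_len(K), function(k) model$W1[, , , , k])
  }
  tibble(unit_id = seq_len(K), weights = w)
}

#' Top-1 accuracy on a dataset
#'
#' @param model a `pm_model` or oracle function (see [predict_proba()]).
#' @param dataset held-out dataset tibble.
#' @param degradation optional [degradation_spec()] applied to every test
#'   input (`NULL` = undegraded).
#' @return accuracy fraction in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, dataset, degradation = NULL) {
  if (nrow(dataset) == 0) stop_config("empty evaluation dataset")
  probs <- predict_proba(model, dataset, degradation = degradation)
  mean(max.col(probs, ties.method = "first") == dataset$label)
}

#' @export
tidy.pm_model <- function(x, ...) {
  if (is.null(x$history)) tibble() else x$history
}

#' @export
glance.pm_model <- function(x, ...) {
  h <- x$history
  tibble(
    variant = x$config$variant,
    n_filters = x$config$n_filters,
    filter_size = x$config$filter_size,
    n_classes = x$config$n_classes,
    regimen = if (is.null(x$regimen)) NA_character_ else x$regimen$name,
    n_epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_accuracy = if (is.null(h)) NA_real_ else h$accuracy[nrow(h)]
  )
}
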