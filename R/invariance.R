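# Layer-wise activation invariance to input degradations.

# Per-unit activation vectors for every layer, concatenated across the
# supplied images: conv1 (one vector per filter, all spatial positions x
# images, post-ReLU), fc_hidden (post-ReLU), output (raw class scores).
layer_activations <- function(model, pixels, degradation = NULL) {
  Xv <- prepare_input(model, pixels, degradation)
  fw <- model_forward(model, Xv, keep = TRUE)
  conv1 <- do.call(rbind, fw$Alist)
  list(conv1 = conv1, fc_hidden = fw$H1, output = fw$logits)
}

#' Activation invariance to input degradation
#'
#' Subsamples `per_class_n` images per class, presents each image
#' undegraded and under each degraded variant, and - for every unit of
#' every convolutional and fully-connected layer - computes the Pearson
#' correlation between the unit's undegraded activation vector and its
#' degraded-variant vector (activations concatenated across all images,
#' and across all spatial positions for convolutional units). Units with a
#' zero-variance activation vector have an undefined correlation; they are
#' excluded and counted rather than imputed.
#'
#' @param model a `pm_model`.
#' @param dataset a labelled dataset tibble (balanced test set).
#' @param per_class_n images sampled per class.
#' @param variants named list of [degradation_spec()] objects, e.g.
#'   `list(grayscale = degradation_spec(to_grayscale = TRUE),
#'   blur = degradation_spec(blur_sigma = 4))`.
#' @param seed integer seed for the subsample.
#' @return object of class `pm_invariance`: tibble with `variant`, `layer`,
#'   `unit_id`, `correlation`; attribute `n_excluded` is a tibble counting
#'   zero-variance units per variant and layer.
#' @export
activation_invariance <- function(model, dataset, per_class_n = 3,
                                  variants = list(
                                    grayscale = degradation_spec(to_grayscale = TRUE)),
                                  seed = 1) {
  stopifnot(inherits(model, "pm_model"))
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(dataset)), dataset$label), function(i)
      sample(i, min(per_class_n, length(i)))))
  })
  pixels <- dataset$pixels[idx]
  base <- layer_activations(model, pixels)
  rows <- list()
  excluded <- list()
  for (vn in names(variants)) {
    degraded <- layer_activations(model, pixels, variants[[vn]])
    for (ly in names(base)) {
      a <- base[[ly]]; b <- degraded[[ly]]
      sda <- apply(a, 2, sd); sdb <- apply(b, 2, sd)
      ok <- sda > 0 & sdb > 0
      cors <- rep(NA_real_, ncol(a))
      if (any(ok)) {
        cors[ok] <- vapply(which(ok), function(u) cor(a[, u], b[, u]),
                           numeric(1))
      }
      rows[[length(rows) + 1]] <- tibble(
        variant = vn, layer = ly, unit_id = which(ok),
        correlation = cors[ok])
      excluded[[length(excluded) + 1]] <- tibble(
        variant = vn, layer = ly, n_excluded = sum(!ok))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_excluded") <- dplyr::bind_rows(excluded)
  class(out) <- c("pm_invariance", class(out))
  out
}
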