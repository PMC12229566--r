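# Desk-scale comparison of the standard and biomimetic regimens: the
# package's end-to-end experiment, reproducing the qualitative pattern of
# the full-scale study at a size that runs on one CPU in minutes.

#' Run the desk-scale standard-vs-biomimetic comparison
#'
#' For each seed and each regimen, trains a fresh mini model on the same
#' synthetic corpus and measures: mean first-layer colour metric and
#' weighted average frequency; shape bias on a cue-conflict grid; ablation
#' curves of shape bias when removing least- vs most-colour-sensitive units
#' first; median activation-invariance correlations under grayscale and
#' blur; and test accuracy on colour and grayscale images. All randomness
#' is controlled by `seeds` (model initialisation, shuffling, augmentation)
#' and `data_seed` (the shared corpus).
#'
#' @param seeds integer vector; one independently initialised training run
#'   per seed and regimen.
#' @param regimens regimen names to compare (the first is treated as the
#'   control in [compare_regimens()]).
#' @param n_classes,n_per_class,image_size corpus parameters.
#' @param scale regimen epoch-count multiplier (0.05 scales the reference
#'   200-epoch schedules to 10 epochs).
#' @param conflict_k exemplars per (shape, texture) pairing in the conflict
#'   grid.
#' @param ablation_fractions ablated-unit fractions for the ablation curves.
#' @param invariance_per_class_n images per class for the invariance
#'   analysis.
#' @param upsample_factor spatial upsampling for the RF metrics.
#' @param batch_size,learning_rate optimisation of the mini model.
#' @param data_seed seed of the shared corpus, conflict grid and test set.
#' @param n_test_per_class held-out images per class.
#' @param verbose print one line per run.
#' @return object of class `pm_regimen_comparison`: list with `per_seed`
#'   (one row per seed x regimen), `curves` (all ablation curves, long
#'   format), `invariance` (all per-unit correlations) and the call
#'   parameters.
#' @export
run_regimen_comparison <- function(seeds = 1:5,
                                   regimens = c("standard", "biomimetic"),
                                   n_classes = 10, n_per_class = 48,
                                   image_size = 64, scale = 0.05,
                                   conflict_k = 2,
                                   ablation_fractions = c(0, 0.125, 0.25,
                                                          0.375, 0.5),
                                   invariance_per_class_n = 3,
                                   upsample_factor = 10,
                                   batch_size = 32, learning_rate = 0.02,
                                   data_seed = 99, n_test_per_class = 12,
                                   verbose = FALSE) {
  train_set <- generate_classification_dataset(n_classes, n_per_class,
                                               image_size, seed = data_seed)
  test_set <- generate_classification_dataset(n_classes, n_test_per_class,
                                              image_size, seed = data_seed,
                                              exemplar_seed = data_seed + 7001L)
  conflict <- generate_cue_conflict_set(n_classes, n_classes, conflict_k,
                                        image_size, seed = data_seed,
                                        exemplar_seed = data_seed + 7002L)
  sigma <- 4 * image_size / 227
  cfg <- model_config(n_filters = 16, filter_size = 9, n_classes = n_classes,
                      image_size = image_size)
  variants <- list(grayscale = degradation_spec(to_grayscale = TRUE),
                   blur = degradation_spec(blur_sigma = sigma))
  rows <- list(); curves <- list(); invs <- list()
  for (seed in seeds) {
    for (reg_name in regimens) {
      reg <- make_regimen(reg_name, scale = scale, image_size = image_size)
      hp <- training_hyperparams(batch_size = batch_size,
                                 lr_schedule = list(kind = "constant",
                                                    rate = learning_rate),
                                 n_epochs = reg$total_epochs, seed = seed)
      model <- build_model(cfg, seed = seed)
      model <- train_with_regimen(model, train_set, reg, hp)
      records <- rf_metrics(extract_first_layer_rfs(model),
                            upsample_factor = upsample_factor)
      bias <- classify_conflict_set(model, conflict)
      ev <- shape_bias_evaluator(conflict, type = "total")
      aucs <- vapply(c("least_first", "most_first"), function(dir) {
        rk <- rank_units_by_metric(records, "color_rgb", dir)
        cv <- ablation_curve(model, rk, ablation_fractions, ev)
        curves[[length(curves) + 1]] <<- dplyr::mutate(
          as_tibble(cv), seed = seed, regimen = reg_name, direction = dir)
        curve_auc(cv)
      }, numeric(1))
      inv <- activation_invariance(model, test_set,
                                   per_class_n = invariance_per_class_n,
                                   variants = variants, seed = seed)
      invs[[length(invs) + 1]] <- dplyr::mutate(as_tibble(inv), seed = seed,
                                                regimen = reg_name)
      inv_med <- tapply(inv$correlation, inv$variant, median)
      rows[[length(rows) + 1]] <- tibble(
        seed = seed, regimen = reg_name,
        train_accuracy = model$history$accuracy[nrow(model$history)],
        test_accuracy_color = evaluate_accuracy(model, test_set),
        test_accuracy_gray = evaluate_accuracy(
          model, test_set, degradation_spec(to_grayscale = TRUE)),
        mean_color_rgb = mean(records$color_rgb),
        mean_waf = mean(records$waf),
        fraction_shape = bias$fraction_shape,
        shape_bias = bias$shape_bias,
        auc_least_first = aucs[["least_first"]],
        auc_most_first = aucs[["most_first"]],
        invariance_grayscale = unname(inv_med["grayscale"]),
        invariance_blur = unname(inv_med["blur"])
      )
      if (verbose)
        message(sprintf("seed %d %-11s train acc %.2f shape frac %.2f",
                        seed, reg_name, rows[[length(rows)]]$train_accuracy,
                        rows[[length(rows)]]$fraction_shape))
    }
  }
  structure(list(per_seed = dplyr::bind_rows(rows),
                 curves = dplyr::bind_rows(curves),
                 invariance = dplyr::bind_rows(invs),
                 params = list(seeds = seeds, regimens = regimens,
                               n_classes = n_classes, scale = scale,
                               image_size = image_size, sigma = sigma)),
            class = "pm_regimen_comparison")
}

#' One-sided sign tests across seeds between two regimens
#'
#' For every directional effect expected of developmentally staged
#' training, counts the seeds for which the effect holds between the
#' treatment regimen (default `biomimetic`) and the control (`standard`),
#' and reports the exact one-sided sign-test p-value. Effects:
#' lower mean first-layer colour metric and weighted average frequency,
#' higher shape-consistent classification fraction, faster loss of shape
#' bias when ablating least-colour-sensitive units first (AUC of the
#' least-first curve below the most-first curve, within the treatment
#' model), and higher grayscale and blur invariance correlations.
#'
#' @param comparison a `pm_regimen_comparison`.
#' @param treatment,control regimen names.
#' @return tibble with `measure`, `direction`, `n_seeds`, `n_consistent`,
#'   `p_value`.
#' @export
compare_regimens <- function(comparison, treatment = "biomimetic",
                             control = "standard") {
  ps <- comparison$per_seed
  a <- ps[ps$regimen == treatment, ]
  b <- ps[ps$regimen == control, ]
  a <- a[order(a$seed), ]; b <- b[order(b$seed), ]
  stopifnot(nrow(a) == nrow(b), all(a$seed == b$seed))
  eff <- list(
    list("mean_color_rgb", "treatment lower", a$mean_color_rgb < b$mean_color_rgb),
    list("mean_waf", "treatment lower", a$mean_waf < b$mean_waf),
    list("fraction_shape", "treatment higher", a$fraction_shape > b$fraction_shape),
    list("ablation_auc", "least-first lower (treatment model)",
         a$auc_least_first < a$auc_most_first),
    list("invariance_grayscale", "treatment higher",
         a$invariance_grayscale > b$invariance_grayscale),
    list("invariance_blur", "treatment higher",
         a$invariance_blur > b$invariance_blur)
  )
  dplyr::bind_rows(lapply(eff, function(e) {
    s <- sum(e[[3]]); n <- length(e[[3]])
    tibble(measure = e[[1]], direction = e[[2]], n_seeds = n,
           n_consistent = s,
           p_value = stats::binom.test(s, n, alternative = "greater")$p.value)
  }))
}

#' @export
print.pm_regimen_comparison <- function(x, ...) {
  cat(sprintf("<pm_regimen_comparison> %d seeds x {%s}\n",
              length(x$params$seeds), paste(x$params$regimens, collapse = ", ")))
  print(dplyr::summarise(
    dplyr::group_by(x$per_seed, .data$regimen),
    dplyr::across(c("train_accuracy", "mean_color_rgb", "mean_waf",
                    "fraction_shape", "invariance_grayscale"),
                  ~ mean(.x, na.rm = TRUE))))
  invisible(x)
}

#' @export
tidy.pm_regimen_comparison <- function(x, ...) x$per_seed
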