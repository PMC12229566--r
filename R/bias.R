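# Shape/texture cue-conflict bias evaluation.

#' Identity fine-class to category mapping
#'
#' In the synthetic setting each class is its own broad category. The
#' mapping abstraction is kept so a many-to-one mapping (e.g. 1000 fine
#' classes onto 16 super-categories) can be plugged in as a two-column data
#' frame.
#'
#' @param n_classes number of fine classes.
#' @return tibble with `fine_class` and `category`.
#' @export
identity_mapping <- function(n_classes) {
  tibble(fine_class = seq_len(n_classes), category = seq_len(n_classes))
}

#' Read / write a class-category mapping as CSV
#'
#' Two-column CSV (`fine_class`, `category`).
#'
#' @param path file path.
#' @param mapping mapping tibble (for writing).
#' @return the mapping tibble (reading); the path, invisibly (writing).
#' @export
read_mapping_csv <- function(path) {
  as_tibble(utils::read.csv(path))
}

#' @rdname read_mapping_csv
#' @export
write_mapping_csv <- function(mapping, path) {
  utils::write.csv(mapping, path, row.names = FALSE)
  invisible(path)
}

#' Evaluate shape/texture bias on a cue-conflict set
#'
#' Congruent stimuli (shape class == texture class) are excluded first. For
#' every remaining image, the classifier's output probabilities are
#' restricted to the fine classes covered by the mapping, the argmax is
#' taken (ties broken by lowest class index and counted), and the chosen
#' fine class is mapped to its broad category. The decision is
#' shape-consistent if that category matches the image's shape category,
#' texture-consistent if it matches its texture category, and "neither"
#' otherwise. Shape bias is reported both as a fraction of all incongruent
#' stimuli and as a fraction of the cue-consistent decisions only.
#'
#' @param model a `pm_model` or an oracle classifier function (see
#'   [predict_proba()]).
#' @param conflict_set tibble from [generate_cue_conflict_set()].
#' @param mapping fine-class to category tibble; `NULL` uses the identity
#'   mapping over the model's classes.
#' @param degradation optional [degradation_spec()].
#' @return object of class `pm_bias_result`: list with counts (`n_shape`,
#'   `n_texture`, `n_neither`, `n_ties`), `shape_bias` (fraction of
#'   consistent decisions; `NA` with `shape_bias_defined = FALSE` when no
#'   decision was cue-consistent), `fraction_shape` / `fraction_texture` /
#'   `fraction_neither` (of all incongruent stimuli), the per-image
#'   `decisions` log and the `per_category` breakdown.
#' @export
classify_conflict_set <- function(model, conflict_set, mapping = NULL,
                                  degradation = NULL) {
  stim <- conflict_set[!conflict_set$congruent, ]
  if (nrow(stim) == 0) stop_config("no incongruent stimuli to evaluate")
  if (is.null(mapping)) {
    nc <- if (inherits(model, "pm_model")) model$config$n_classes
          else max(conflict_set$shape_class, conflict_set$texture_class)
    mapping <- identity_mapping(nc)
  }
  mapping <- as_tibble(mapping)
  if (nrow(mapping) == 0) stop_config("the class mapping covers zero classes")
  if (anyDuplicated(mapping$fine_class))
    stop_config("every mapped fine class must map to exactly one category")
  probs <- predict_proba(model, stim, degradation = degradation)
  if (ncol(probs) < max(mapping$fine_class))
    stop_config("model output dimension does not cover all mapped fine classes")
  sub <- probs[, mapping$fine_class, drop = FALSE]
  best <- max.col(sub, ties.method = "first")
  n_ties <- sum(apply(sub, 1, function(p) sum(p == max(p)) > 1))
  pred_cat <- mapping$category[best]
  decisions <- tibble(
    image_id = stim$image_id,
    shape_class = stim$shape_class,
    texture_class = stim$texture_class,
    predicted_fine = mapping$fine_class[best],
    predicted_category = pred_cat,
    outcome = dplyr::case_when(
      pred_cat == stim$shape_class ~ "shape",
      pred_cat == stim$texture_class ~ "texture",
      TRUE ~ "neither"
    )
  )
  n_shape <- sum(decisions$outcome == "shape")
  n_texture <- sum(decisions$outcome == "texture")
  n_neither <- sum(decisions$outcome == "neither")
  defined <- (n_shape + n_texture) > 0
  structure(list(
    decisions = decisions,
    n_shape = n_shape, n_texture = n_texture, n_neither = n_neither,
    n_ties = n_ties,
    shape_bias = if (defined) n_shape / (n_shape + n_texture) else NA_real_,
    shape_bias_defined = defined,
    fraction_shape = n_shape / nrow(decisions),
    fraction_texture = n_texture / nrow(decisions),
    fraction_neither = n_neither / nrow(decisions),
    per_category = per_category_breakdown(decisions)
  ), class = "pm_bias_result")
}

#' Per-shape-category shape-based fractions
#'
#' For each shape category, the fraction of cue-consistent decisions that
#' were shape-based, `n_shape / (n_shape + n_texture)`, over that
#' category's incongruent images. Categories with no cue-consistent
#' decision are flagged undefined rather than NaN-propagated.
#'
#' @param decisions a decision log (tibble from a `pm_bias_result`) or a
#'   `pm_bias_result`.
#' @return tibble with `shape_category`, `n_images`, `n_shape`, `n_texture`,
#'   `fraction_shape_based`, `defined`.
#' @export
per_category_breakdown <- function(decisions) {
  if (inherits(decisions, "pm_bias_result")) decisions <- decisions$decisions
  decisions |>
    dplyr::group_by(shape_category = .data$shape_class) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      n_shape = sum(.data$outcome == "shape"),
      n_texture = sum(.data$outcome == "texture"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      defined = (.data$n_shape + .data$n_texture) > 0,
      fraction_shape_based = ifelse(.data$defined,
                                    .data$n_shape /
                                      (.data$n_shape + .data$n_texture),
                                    NA_real_)
    )
}

#' Chance-level outcome fractions for a random classifier
#'
#' On incongruent stimuli, a classifier choosing uniformly among
#' `n_categories` is shape-consistent with probability `1/n_categories`,
#' texture-consistent with the same probability, and otherwise consistent
#' with neither.
#'
#' @param n_categories number of broad categories (>= 2).
#' @return tibble with `outcome` and `expected_fraction`.
#' @export
random_baseline <- function(n_categories) {
  if (n_categories < 2) stop_config("`n_categories` must be >= 2")
  tibble(outcome = c("shape", "texture", "neither"),
         expected_fraction = c(1 / n_categories, 1 / n_categories,
                               1 - 2 / n_categories))
}

#' @export
print.pm_bias_result <- function(x, ...) {
  cat(sprintf("<pm_bias_result> %d incongruent stimuli\n",
              x$n_shape + x$n_texture + x$n_neither))
  cat(sprintf("  shape %d (%.1f%%) | texture %d (%.1f%%) | neither %d (%.1f%%)\n",
              x$n_shape, 100 * x$fraction_shape,
              x$n_texture, 100 * x$fraction_texture,
              x$n_neither, 100 * x$fraction_neither))
  if (x$shape_bias_defined)
    cat(sprintf("  shape bias (of consistent decisions): %.3f\n", x$shape_bias))
  else cat("  shape bias undefined: no cue-consistent decisions\n")
  invisible(x)
}

#' @export
tidy.pm_bias_result <- function(x, ...) x$decisions

#' @export
glance.pm_bias_result <- function(x, ...) {
  tibble(n_shape = x$n_shape, n_texture = x$n_texture,
         n_neither = x$n_neither, n_ties = x$n_ties,
         shape_bias = x$shape_bias,
         fraction_shape = x$fraction_shape,
         fraction_texture = x$fraction_texture,
         fraction_neither = x$fraction_neither)
}
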