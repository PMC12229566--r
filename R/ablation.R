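# Rank-based first-layer unit ablation.

#' Rank first-layer units by a receptive-field metric
#'
#' Stable sort of the units by the named metric, ties broken by `unit_id`.
#'
#' @param records metric tibble from [rf_metrics()].
#' @param metric column name, e.g. `"color_rgb"` or `"waf"`.
#' @param direction `"least_first"` (ascending) or `"most_first"`.
#' @return object of class `pm_unit_ranking`: tibble with `rank`, `unit_id`,
#'   `value`; attributes `metric` and `direction`.
#' @export
rank_units_by_metric <- function(records, metric,
                                 direction = c("least_first", "most_first")) {
  direction <- match.arg(direction)
  if (!metric %in% names(records)) stop_config(paste0("unknown metric: ", metric))
  v <- records[[metric]]
  if (anyNA(v)) stop_config("metric records contain missing values")
  ord <- order(v, records$unit_id, decreasing = c(direction == "most_first", FALSE),
               method = "radix")
  out <- tibble(rank = seq_along(ord), unit_id = records$unit_id[ord],
                value = v[ord])
  attr(out, "metric") <- metric
  attr(out, "direction") <- direction
  class(out) <- c("pm_unit_ranking", class(out))
  out
}

#' Ablate first-layer units
#'
#' Returns a copy of the model in which each named unit's entire first-layer
#' weight tensor is set to zero (its bias is retained; ablation removes the
#' unit's input weighting, i.e. all `h x w x 3` - or `t x h x w x 3` -
#' values). All other parameters are bit-identical; the input model is
#' untouched.
#'
#' @param model a `pm_model`.
#' @param unit_ids first-layer unit indices, no duplicates.
#' @return the ablated `pm_model` copy.
#' @export
ablate_units <- function(model, unit_ids) {
  stopifnot(inherits(model, "pm_model"))
  K <- model$config$n_filters
  if (anyDuplicated(unit_ids) || any(unit_ids < 1) || any(unit_ids > K))
    stop_config("`unit_ids` must be distinct first-layer indices")
  if (length(unit_ids) == 0) return(model)
  if (length(dim(model$W1)) == 4) model$W1[, , , unit_ids] <- 0
  else model$W1[, , , , unit_ids] <- 0
  model
}

#' Evaluation as a function of the ablated unit fraction
#'
#' At each fraction `p`, the first `ceiling(p * n_units)` units of the
#' ranking are ablated and the evaluator applied; fraction 0 reproduces the
#' unablated baseline, and the ablated sets are nested (prefixes of the
#' ranking).
#'
#' @param model a `pm_model`.
#' @param ranking a `pm_unit_ranking`.
#' @param fractions ascending fractions in `[0, 1]`.
#' @param evaluator a function `model -> scalar`, e.g. from
#'   [shape_bias_evaluator()] or [accuracy_evaluator()].
#' @return tibble of class `pm_ablation_curve`: `fraction`, `n_ablated`,
#'   `value`; attributes `metric` and `direction` from the ranking.
#' @export
ablation_curve <- function(model, ranking, fractions, evaluator) {
  if (is.unsorted(fractions) || any(fractions < 0) || any(fractions > 1))
    stop_config("`fractions` must be ascending within [0, 1]")
  K <- model$config$n_filters
  vals <- vapply(fractions, function(p) {
    ids <- ranking$unit_id[seq_len(ceiling(p * K))]
    evaluator(ablate_units(model, ids))
  }, numeric(1))
  out <- tibble(fraction = fractions,
                n_ablated = ceiling(fractions * K), value = vals)
  attr(out, "metric") <- attr(ranking, "metric")
  attr(out, "direction") <- attr(ranking, "direction")
  class(out) <- c("pm_ablation_curve", class(out))
  out
}

#' Evaluators for ablation curves
#'
#' `shape_bias_evaluator` evaluates shape bias on a cue-conflict set
#' (either definition); `accuracy_evaluator` evaluates top-1 accuracy on a
#' held-out set under an optional degradation.
#'
#' @param conflict_set tibble from [generate_cue_conflict_set()].
#' @param mapping optional class-category mapping.
#' @param type `"consistent"`: shape / (shape + texture);
#'   `"total"`: shape / all incongruent stimuli.
#' @return a function `pm_model -> scalar`.
#' @export
shape_bias_evaluator <- function(conflict_set, mapping = NULL,
                                 type = c("consistent", "total")) {
  type <- match.arg(type)
  function(model) {
    res <- classify_conflict_set(model, conflict_set, mapping)
    if (type == "consistent") {
      if (!res$shape_bias_defined) return(NA_real_)
      res$shape_bias
    } else {
      res$fraction_shape
    }
  }
}

#' @rdname shape_bias_evaluator
#' @param dataset held-out dataset tibble.
#' @param degradation optional [degradation_spec()].
#' @export
accuracy_evaluator <- function(dataset, degradation = NULL) {
  function(model) evaluate_accuracy(model, dataset, degradation)
}

#' Trapezoidal area under an ablation curve
#'
#' @param curve a `pm_ablation_curve`.
#' @return scalar area over the curve's fraction range.
#' @export
curve_auc <- function(curve) {
  x <- curve$fraction; y <- curve$value
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
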