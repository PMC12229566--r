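#' Construct a training regimen
#'
#' A regimen is an ordered list of phases, each mapping a block of epochs to
#' an input degradation (Gaussian blur sigma, chromatic on/off) and a
#' frozen-unit fraction for the first layer. At `scale = 1` the epoch counts
#' are the reference schedules:
#'
#' * `standard`: 200 epochs, sharp, chromatic.
#' * `biomimetic`: 100 epochs blurred + achromatic, then 100 sharp + chromatic.
#' * `biomimetic_v2`: 50 blurred + achromatic, 50 blurred + chromatic,
#'   100 sharp + chromatic (colour sensitivity matures before acuity).
#' * `biomimetic_v3`: 100 blurred + achromatic, then 200 sharp + chromatic.
#' * `biomimetic_v4`: as `biomimetic`, but 50% of first-layer units are
#'   frozen (receive no updates) during phase 1.
#'
#' The blur sigma is 4 pixels at the reference input size of 227 pixels and
#' is scaled proportionally (`4 * image_size / 227`) so the blur removes the
#' same relative frequency band at any input size. Scaled epoch counts are
#' rounded half-up with a minimum of 1 epoch per phase. Phase boundaries are
#' half-open on 0-based epoch indices: the degradation switches at the first
#' epoch of the new phase.
#'
#' @param name one of `standard`, `biomimetic`, `biomimetic_v2`,
#'   `biomimetic_v3`, `biomimetic_v4`.
#' @param scale positive multiplier on phase epoch counts.
#' @param image_size input side length in pixels used to scale the blur
#'   sigma (default 227, the reference crop size).
#' @param base_sigma blur sigma in pixels at the reference size.
#' @return an object of class `pm_regimen`: list with `name`, `scale`,
#'   `total_epochs` and a `phases` tibble (`phase`, `n_epochs`, `blur_sigma`,
#'   `chromatic`, `frozen_fraction`).
#' @export
make_regimen <- function(name = c("standard", "biomimetic", "biomimetic_v2",
                                  "biomimetic_v3", "biomimetic_v4"),
                         scale = 1, image_size = 227, base_sigma = 4) {
  name <- match.arg(name)
  if (scale <= 0) stop_config("`scale` must be > 0")
  sig <- base_sigma * image_size / 227
  ph <- switch(name,
    standard = tibble(n_epochs = 200, blur_sigma = 0, chromatic = TRUE,
                      frozen_fraction = 0),
    biomimetic = tibble(n_epochs = c(100, 100), blur_sigma = c(sig, 0),
                        chromatic = c(FALSE, TRUE), frozen_fraction = c(0, 0)),
    biomimetic_v2 = tibble(n_epochs = c(50, 50, 100),
                           blur_sigma = c(sig, sig, 0),
                           chromatic = c(FALSE, TRUE, TRUE),
                           frozen_fraction = c(0, 0, 0)),
    biomimetic_v3 = tibble(n_epochs = c(100, 200), blur_sigma = c(sig, 0),
                           chromatic = c(FALSE, TRUE),
                           frozen_fraction = c(0, 0)),
    biomimetic_v4 = tibble(n_epochs = c(100, 100), blur_sigma = c(sig, 0),
                           chromatic = c(FALSE, TRUE),
                           frozen_fraction = c(0.5, 0))
  )
  ph$n_epochs <- pmax(1L, as.integer(floor(ph$n_epochs * scale + 0.5)))
  ph <- dplyr::mutate(ph, phase = dplyr::row_number(), .before = 1)
  structure(list(name = name, scale = scale, image_size = image_size,
                 base_sigma = base_sigma, phases = ph,
                 total_epochs = sum(ph$n_epochs)),
            class = "pm_regimen")
}

#' Input transformation and freezing for a given epoch
#'
#' Returns the phase whose half-open epoch interval contains the (0-based)
#' epoch index.
#'
#' @param regimen a `pm_regimen`.
#' @param epoch 0-based epoch index, `0 <= epoch < total_epochs`.
#' @return one-row tibble: `phase`, `n_epochs`, `blur_sigma`, `chromatic`,
#'   `frozen_fraction`.
#' @export
transform_for_epoch <- function(regimen, epoch) {
  stopifnot(inherits(regimen, "pm_regimen"))
  if (epoch < 0 || epoch >= regimen$total_epochs)
    stop_config(sprintf("`epoch` must be in [0, %d)", regimen$total_epochs))
  ends <- cumsum(regimen$phases$n_epochs)
  regimen$phases[which(epoch < ends)[1], ]
}

#' @export
print.pm_regimen <- function(x, ...) {
  cat(sprintf("<pm_regimen '%s'> scale %g, %d epochs\n", x$name, x$scale,
              x$total_epochs))
  print(x$phases)
  invisible(x)
}

#' @export
tidy.pm_regimen <- function(x, ...) x$phases

#' Serialize / restore a regimen as YAML
#'
#' @param regimen a `pm_regimen`.
#' @param path file path; if `NULL`, the YAML string is returned (for
#'   `regimen_to_yaml`) or parsed (for `regimen_from_yaml`, where `text`
#'   may be given instead of a path).
#' @return `regimen_to_yaml` returns the path (or YAML string) invisibly;
#'   `regimen_from_yaml` returns a `pm_regimen` identical to the one
#'   serialized.
#' @export
regimen_to_yaml <- function(regimen, path = NULL) {
  stopifnot(inherits(regimen, "pm_regimen"))
  obj <- list(name = regimen$name, scale = regimen$scale,
              image_size = regimen$image_size, base_sigma = regimen$base_sigma,
              phases = lapply(seq_len(nrow(regimen$phases)), function(i)
                as.list(regimen$phases[i, ])))
  if (is.null(path)) return(yaml::as.yaml(obj))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname regimen_to_yaml
#' @param text YAML string (alternative to `path`).
#' @export
regimen_from_yaml <- function(path = NULL, text = NULL) {
  obj <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  ph <- dplyr::bind_rows(lapply(obj$phases, as_tibble))
  structure(list(name = obj$name, scale = obj$scale,
                 image_size = obj$image_size, base_sigma = obj$base_sigma,
                 phases = ph, total_epochs = sum(ph$n_epochs)),
            class = "pm_regimen")
}

#' Architecture and optimisation presets
#'
#' Named presets for the first convolutional layer and learning-rate
#' schedule. `setting1` (the reference): 48 filters of 22 x 22 pixels,
#' 200 epochs, constant learning rate 0.001. `setting2`: 96 filters of
#' 22 x 22. `setting3`: 96 filters of 11 x 11. `setting4`: as `setting1`
#' with half the epochs. `setting5`: as `setting1` with a
#' reduce-on-plateau schedule (initial 0.02, factor 0.5, patience 10,
#' min_delta 1e-4, cooldown 0, min rate 1e-4). `mini` is the desk-scale
#' preset used throughout the package's tests and examples: 16 filters of
#' 9 x 9 pixels on 64-pixel inputs.
#'
#' @param name preset name.
#' @return list of class `pm_setting` with `n_filters`, `filter_size`,
#'   `total_epochs`, `image_size` and `lr_schedule`.
#' @export
setting_preset <- function(name = c("setting1", "setting2", "setting3",
                                    "setting4", "setting5", "mini")) {
  name <- match.arg(name)
  constant <- function(rate) list(kind = "constant", rate = rate)
  base <- list(name = name, n_filters = 48, filter_size = 22,
               total_epochs = 200, image_size = 227,
               lr_schedule = constant(0.001))
  out <- switch(name,
    setting1 = base,
    setting2 = utils::modifyList(base, list(n_filters = 96)),
    setting3 = utils::modifyList(base, list(n_filters = 96, filter_size = 11)),
    setting4 = utils::modifyList(base, list(total_epochs = 100)),
    setting5 = utils::modifyList(base, list(lr_schedule = list(
      kind = "plateau", initial = 0.02, factor = 0.5, patience = 10,
      min_delta = 1e-4, cooldown = 0, min_rate = 1e-4))),
    mini = utils::modifyList(base, list(n_filters = 16, filter_size = 9,
                                        image_size = 64, total_epochs = 10,
                                        lr_schedule = constant(0.02)))
  )
  structure(out, class = "pm_setting")
}
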