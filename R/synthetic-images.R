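#' Class specifications for the synthetic image corpus
#'
#' Each synthetic class is defined jointly by a global, low-spatial-frequency
#' silhouette (the "shape" cue) and a local, high-spatial-frequency chromatic
#' pattern (the "texture" cue). The silhouette is a smooth star-shaped
#' contour low-passed below `shape_cutoff_freq`, so essentially all of its
#' non-DC spectral power lies below that cutoff; the texture is a sum of two
#' gratings whose frequencies lie inside `texture_band`, carrying the class
#' hue. Shape and texture cues are therefore separable in the frequency
#' domain, which is what makes cue-conflict stimuli and blur-based input
#' degradation meaningful.
#'
#' @param n_classes number of classes (>= 2).
#' @param shape_cutoff_freq upper frequency bound of the shape cue, in
#'   cycles/pixel.
#' @param texture_band length-2 numeric, frequency band (cycles/pixel) of the
#'   texture gratings; must lie strictly above `shape_cutoff_freq` and below
#'   the Nyquist frequency 0.5.
#' @param seed integer seed; class parameters are a deterministic function of
#'   the seed.
#' @return a tibble with one row per class: `class_id`, `base_hue` (radians),
#'   silhouette contour parameters and texture grating parameters
#'   (list-columns).
#' @export
class_specs <- function(n_classes, shape_cutoff_freq = 0.08,
                        texture_band = c(0.2, 0.4), seed = 1) {
  if (n_classes < 2) stop_config("`n_classes` must be >= 2")
  if (length(texture_band) != 2 || texture_band[1] >= texture_band[2])
    stop_config("`texture_band` must be an increasing length-2 vector")
  if (texture_band[1] <= shape_cutoff_freq)
    stop_config("`texture_band` must lie strictly above `shape_cutoff_freq`: shape and texture cues must be spectrally separable")
  if (texture_band[2] > 0.5)
    stop_config("`texture_band` exceeds the Nyquist frequency (0.5 cycles/pixel)")
  with_seed(seed, {
    tibble(
      class_id = seq_len(n_classes),
      base_hue = (seq_len(n_classes) - 1) * 2 * pi / n_classes +
        runif(n_classes, -0.1, 0.1),
      shape_cutoff_freq = shape_cutoff_freq,
      contour = purrr::map(seq_len(n_classes), function(i) {
        list(
          harmonics = 2:5,
          amp = runif(4, 0.05, 0.22),
          phase = runif(4, 0, 2 * pi)
        )
      }),
      texture = purrr::map(seq_len(n_classes), function(i) {
        list(
          freq = runif(2, texture_band[1], texture_band[2]),
          theta = runif(2, 0, pi)
        )
      })
    )
  })
}

# Soft silhouette field in [0, 1]: star-shaped binary mask, hard low-passed
# below the class shape cutoff. `shift` translates the contour centre.
render_silhouette <- function(spec_row, image_size, shift = c(0, 0)) {
  n <- image_size
  ct <- spec_row$contour[[1]]
  cx <- n / 2 + 0.5 + shift[1]
  cy <- n / 2 + 0.5 + shift[2]
  x <- outer(seq_len(n) - cx, rep(1, n))
  y <- t(outer(seq_len(n) - cy, rep(1, n)))
  phi <- atan2(y, x)
  r0 <- 0.3 * n
  rad <- r0 * (1 + Reduce(`+`, Map(function(h, a, p) a * cos(h * phi + p),
                                   ct$harmonics, ct$amp, ct$phase)))
  mask <- (sqrt(x^2 + y^2) < rad) * 1
  s <- lowpass_field(mask, spec_row$shape_cutoff_freq)
  clamp(s, 0, 1)
}

# Texture field in roughly [-1, 1]: sum of two class gratings, per-image
# random phases supplied by the caller.
render_texture <- function(spec_row, image_size, phases = c(0, 0)) {
  n <- image_size
  tx <- spec_row$texture[[1]]
  x <- outer(0:(n - 1), rep(1, n))
  y <- t(x)
  g <- Reduce(`+`, Map(function(f, th, ph) {
    sin(2 * pi * f * (cos(th) * x + sin(th) * y) + ph)
  }, tx$freq, tx$theta, phases))
  g / max(abs(g))
}

# Zero-sum RGB direction for a hue angle: channels placed 120 degrees apart.
hue_direction <- function(hue) {
  c(cos(hue), cos(hue - 2 * pi / 3), cos(hue + 2 * pi / 3))
}

# Compose one H x W x 3 image in [-1, 1]: silhouette of `shape_row` filled
# with the (chromatic) texture of `texture_row`, plus achromatic noise.
render_image <- function(shape_row, texture_row, image_size, chroma_strength,
                         noise_sd, shift = c(0, 0), phases = c(0, 0),
                         noise = NULL) {
  s <- render_silhouette(shape_row, image_size, shift)
  tx <- render_texture(texture_row, image_size, phases)
  u <- hue_direction(texture_row$base_hue)
  base <- -0.4 + s * (0.8 + 0.3 * tx)
  img <- array(0, c(image_size, image_size, 3))
  for (c in 1:3) {
    img[, , c] <- base + chroma_strength * 0.3 * s * tx * u[c]
  }
  if (noise_sd > 0) {
    if (is.null(noise)) noise <- matrix(rnorm(image_size^2, 0, noise_sd),
                                        image_size, image_size)
    for (c in 1:3) img[, , c] <- img[, , c] + noise
  }
  clamp(img)
}

#' Generate a labelled synthetic classification corpus
#'
#' Produces a balanced, seeded-deterministic set of images in which each
#' class is identified jointly by its global silhouette and its local
#' chromatic texture (both cues predict the label, as in natural image
#' corpora where object shape and surface texture co-vary). Images are
#' `image_size` x `image_size` x 3 arrays with values in `[-1, 1]`.
#' Within-class variability comes from random silhouette translations,
#' texture phases, and additive achromatic Gaussian noise.
#'
#' @inheritParams class_specs
#' @param n_per_class images per class.
#' @param image_size side length in pixels (>= 32).
#' @param chroma_strength in `[0, 1]`; 0 yields exactly achromatic images
#'   (R == G == B everywhere).
#' @param noise_sd standard deviation of the additive achromatic noise.
#' @param seed integer seed controlling the class definitions; identical
#'   arguments and seeds reproduce bit-identical pixels.
#' @param exemplar_seed integer seed controlling the per-image variability
#'   (translations, phases, noise). Keep `seed` fixed and vary
#'   `exemplar_seed` to draw disjoint train/test sets over the *same*
#'   classes.
#' @return tibble with columns `image_id`, `label`, `shape_class`,
#'   `texture_class` and the list-column `pixels`.
#' @export
generate_classification_dataset <- function(n_classes, n_per_class,
                                            image_size = 64,
                                            shape_cutoff_freq = 0.08,
                                            texture_band = c(0.2, 0.4),
                                            chroma_strength = 0.8,
                                            noise_sd = 0.05, seed = 1,
                                            exemplar_seed = seed + 1L) {
  if (image_size < 32) stop_config("`image_size` must be >= 32")
  specs <- class_specs(n_classes, shape_cutoff_freq, texture_band, seed)
  with_seed(exemplar_seed, {
    grid <- tidyr::expand_grid(label = seq_len(n_classes),
                               rep = seq_len(n_per_class))
    pixels <- purrr::map(grid$label, function(cl) {
      row <- specs[cl, ]
      render_image(row, row, image_size, chroma_strength, noise_sd,
                   shift = round(runif(2, -image_size / 8, image_size / 8)),
                   phases = runif(2, 0, 2 * pi))
    })
    tibble(
      image_id = seq_len(nrow(grid)),
      label = grid$label,
      shape_class = grid$label,
      texture_class = grid$label,
      pixels = pixels
    )
  })
}

#' Generate a shape/texture cue-conflict stimulus grid
#'
#' Builds the full `S x T x k` grid of stimuli in which the silhouette of
#' shape class `i` is filled with the texture (and hue) of texture class
#' `j`, with `k` exemplars per pairing. Cells with `i == j` carry congruent
#' cues and are flagged (they are generated, so the grid combinatorics are
#' checkable, and excluded downstream as in the standard cue-conflict
#' protocol).
#'
#' @param S,T number of shape and texture classes (both drawn from the same
#'   class specification set of `max(S, T)` classes).
#' @param k exemplars per (shape, texture) pairing (> 0).
#' @inheritParams generate_classification_dataset
#' @return tibble with `image_id`, `shape_class`, `texture_class`,
#'   `congruent`, `pixels`.
#' @export
generate_cue_conflict_set <- function(S, T, k, image_size = 64,
                                      shape_cutoff_freq = 0.08,
                                      texture_band = c(0.2, 0.4),
                                      chroma_strength = 0.8,
                                      noise_sd = 0.05, seed = 1,
                                      exemplar_seed = seed + 2L) {
  if (S < 2 || T < 2) stop_config("`S` and `T` must be >= 2")
  if (k <= 0) stop_config("`k` must be a positive integer")
  specs <- class_specs(max(S, T), shape_cutoff_freq, texture_band, seed)
  with_seed(exemplar_seed, {
    grid <- tidyr::expand_grid(shape_class = seq_len(S),
                               texture_class = seq_len(T),
                               exemplar = seq_len(k))
    pixels <- purrr::map2(grid$shape_class, grid$texture_class, function(i, j) {
      render_image(specs[i, ], specs[j, ], image_size, chroma_strength,
                   noise_sd,
                   shift = round(runif(2, -image_size / 8, image_size / 8)),
                   phases = runif(2, 0, 2 * pi))
    })
    tibble(
      image_id = seq_len(nrow(grid)),
      shape_class = grid$shape_class,
      texture_class = grid$texture_class,
      congruent = grid$shape_class == grid$texture_class,
      pixels = pixels
    )
  })
}

#' Degrade an image, video clip, or dataset
#'
#' Applies a per-channel Gaussian blur (reflect padding) of the given sigma
#' (pixels) and/or converts to grayscale by replacing all three channels
#' with their per-pixel unweighted mean. Works on a single `H x W x 3`
#' image, a `T x H x W x 3` clip, or a dataset tibble with a `pixels`
#' list-column. Output values are clamped back to `[-1, 1]`.
#'
#' @param x image array, clip array, or dataset tibble.
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0; 0 = no blur).
#' @param to_grayscale logical.
#' @return same type as `x`.
#' @export
degrade <- function(x, blur_sigma = 0, to_grayscale = FALSE) {
  if (blur_sigma < 0) stop_config("`blur_sigma` must be >= 0")
  if (is.data.frame(x)) {
    x$pixels <- purrr::map(x$pixels, degrade, blur_sigma = blur_sigma,
                           to_grayscale = to_grayscale)
    return(x)
  }
  if (is_clip(x)) {
    for (t in seq_len(dim(x)[1])) {
      x[t, , , ] <- degrade(x[t, , , ], blur_sigma, to_grayscale)
    }
    return(x)
  }
  if (!is_image(x)) stop_config("`x` must be an H x W x 3 image, a T x H x W x 3 clip, or a dataset tibble")
  if (blur_sigma > 0) {
    for (c in 1:3) x[, , c] <- blur_matrix(x[, , c], blur_sigma)
  }
  if (to_grayscale) {
    g <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
    for (c in 1:3) x[, , c] <- g
  }
  clamp(x)
}

#' Degradation specification
#'
#' A small record naming an input degradation, used by evaluation and
#' invariance functions.
#'
#' @inheritParams degrade
#' @return a list of class `pm_degradation`.
#' @export
degradation_spec <- function(blur_sigma = 0, to_grayscale = FALSE) {
  if (blur_sigma < 0) stop_config("`blur_sigma` must be >= 0")
  structure(list(blur_sigma = blur_sigma, to_grayscale = to_grayscale),
            class = "pm_degradation")
}

apply_degradation <- function(x, spec) {
  if (is.null(spec)) return(x)
  degrade(x, blur_sigma = spec$blur_sigma, to_grayscale = spec$to_grayscale)
}
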