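#' Generate a labelled synthetic video corpus
#'
#' Short clips in which each class is defined by its shape/texture signature
#' AND by a class-specific rigid motion (direction and speed, pixels/frame),
#' so temporal structure is informative for classification. Frames are the
#' class image translated by the per-class displacement (toroidal shift),
#' with one achromatic noise field per clip that moves rigidly with the
#' scene (so a zero-speed class yields clips with exactly identical frames).
#'
#' @inheritParams generate_classification_dataset
#' @param frames frames per clip; must be at least twice the temporal extent
#'   of the first-layer 3D filter (5), i.e. >= 10.
#' @param motion_speed_range length-2 numeric, pixels/frame; per-class speeds
#'   are drawn uniformly from this range; the per-frame displacement must be
#'   smaller than `image_size`.
#' @return tibble with `clip_id`, `label`, `direction` (radians), `speed`
#'   (pixels/frame) and the list-column `pixels` of `frames x H x W x 3`
#'   arrays in `[-1, 1]`.
#' @export
generate_video_dataset <- function(n_classes, n_per_class, frames = 12,
                                   image_size = 32,
                                   motion_speed_range = c(1, 3),
                                   shape_cutoff_freq = 0.08,
                                   texture_band = c(0.2, 0.4),
                                   chroma_strength = 0.8,
                                   noise_sd = 0.03, seed = 1) {
  if (frames < 10)
    stop_config("`frames` must be >= 10 (twice the 5-frame first-layer temporal extent)")
  if (max(motion_speed_range) >= image_size)
    stop_config("per-frame motion displacement must be smaller than `image_size`")
  specs <- class_specs(n_classes, shape_cutoff_freq, texture_band, seed)
  with_seed(seed + 3L, {
    direction <- runif(n_classes, 0, 2 * pi)
    speed <- runif(n_classes, motion_speed_range[1], motion_speed_range[2])
    grid <- tidyr::expand_grid(label = seq_len(n_classes),
                               rep = seq_len(n_per_class))
    pixels <- purrr::map(grid$label, function(cl) {
      base <- render_image(specs[cl, ], specs[cl, ], image_size,
                           chroma_strength, noise_sd = noise_sd,
                           shift = round(runif(2, -image_size / 8, image_size / 8)),
                           phases = runif(2, 0, 2 * pi))
      clip <- array(0, c(frames, image_size, image_size, 3))
      for (t in seq_len(frames)) {
        dx <- round(speed[cl] * (t - 1) * cos(direction[cl])) %% image_size
        dy <- round(speed[cl] * (t - 1) * sin(direction[cl])) %% image_size
        ix <- ((seq_len(image_size) - 1 - dx) %% image_size) + 1
        iy <- ((seq_len(image_size) - 1 - dy) %% image_size) + 1
        clip[t, , , ] <- base[ix, iy, , drop = FALSE]
      }
      clip
    })
    tibble(clip_id = seq_len(nrow(grid)), label = grid$label,
           direction = direction[grid$label], speed = speed[grid$label],
           pixels = pixels)
  })
}
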