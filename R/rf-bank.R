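#' Generate an analytic receptive-field bank
#'
#' Builds a set of filters with known ground-truth properties, used as
#' oracles for the receptive-field metrics: oriented gratings (known
#' frequency and orientation), isotropic Gaussian blobs, centre-surround
#' difference-of-Gaussians, colour-opponent blobs, achromatic random noise,
#' and two temporal kinds - `static_temporal` (identical frames) and
#' `biphasic_temporal` (a frame pair that are exact negatives, the model
#' analogue of a biphasic cell's sign-reversing impulse response).
#'
#' @param kinds a character vector of kinds, or a list whose elements are
#'   either kind names or lists like `list(kind = "grating", freq = 0.2,
#'   theta = pi / 4)`. Recognised kinds: `grating`, `isotropic_blob`,
#'   `center_surround`, `color_opponent`, `gray_random`,
#'   `biphasic_temporal`, `static_temporal`.
#' @param size spatial side length of each filter, in pixels.
#' @param n_time number of frames for temporal kinds.
#' @param seed integer seed.
#' @return tibble with `unit_id`, `kind`, `weights` (list of `h x w x 3` or
#'   `t x h x w x 3` arrays) and ground-truth columns `freq`, `theta`
#'   (NA where not applicable).
#' @export
generate_rf_bank <- function(kinds, size = 9, n_time = 5, seed = 1) {
  kinds <- lapply(kinds, function(k) if (is.character(k)) list(kind = k) else k)
  with_seed(seed, {
    rows <- purrr::imap(kinds, function(spec, i) {
      w <- switch(spec$kind,
        grating = rf_grating(size, spec$freq %||% 0.2, spec$theta %||% pi / 4,
                             spec$phase %||% 0),
        isotropic_blob = rf_blob(size),
        center_surround = rf_center_surround(size),
        color_opponent = rf_color_opponent(size),
        gray_random = rf_gray_random(size),
        biphasic_temporal = rf_biphasic(size, n_time),
        static_temporal = rf_static(size, n_time),
        stop_config(paste0("unknown RF kind: ", spec$kind))
      )
      tibble(unit_id = i, kind = spec$kind, weights = list(w),
             freq = spec$freq %||% NA_real_, theta = spec$theta %||% NA_real_)
    })
    dplyr::bind_rows(rows)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gray3 <- function(m) {
  a <- array(0, c(dim(m), 3))
  for (c in 1:3) a[, , c] <- m
  a
}

rf_grating <- function(size, freq, theta, phase = 0) {
  if (freq > 0.5)
    stop_config("grating frequency exceeds the Nyquist frequency (0.5 cycles/pixel) at this size")
  x <- outer(0:(size - 1), rep(1, size))
  y <- t(x)
  gray3(cos(2 * pi * freq * (cos(theta) * x + sin(theta) * y) + phase))
}

rf_blob <- function(size, sigma = size / 6) {
  c0 <- (size + 1) / 2
  d2 <- outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, "+")
  gray3(exp(-d2 / (2 * sigma^2)))
}

rf_center_surround <- function(size) {
  c0 <- (size + 1) / 2
  d2 <- outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, "+")
  s1 <- size / 8; s2 <- size / 3.5
  gray3(exp(-d2 / (2 * s1^2)) - (s1 / s2)^2 * exp(-d2 / (2 * s2^2)))
}

rf_color_opponent <- function(size) {
  b <- rf_blob(size)[, , 1]
  pair <- sample(1:3, 2)
  a <- array(0, c(size, size, 3))
  # unequal opponent gains keep a nonzero luminance component, so the
  # spatial-frequency metric (defined on the channel mean) stays defined
  a[, , pair[1]] <- b
  a[, , pair[2]] <- -0.5 * b
  a
}

rf_gray_random <- function(size) {
  gray3(matrix(rnorm(size^2), size, size))
}

rf_static <- function(size, n_time) {
  frame <- rf_center_surround(size)
  a <- array(0, c(n_time, size, size, 3))
  for (t in seq_len(n_time)) a[t, , , ] <- frame
  a
}

rf_biphasic <- function(size, n_time) {
  frame <- rf_center_surround(size)
  env <- seq(1, -1, length.out = n_time)
  env[env == 0] <- 0.1  # keep every frame non-constant
  a <- array(0, c(n_time, size, size, 3))
  for (t in seq_len(n_time)) a[t, , , ] <- env[t] * frame
  a
}
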