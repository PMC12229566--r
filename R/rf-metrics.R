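# Receptive-field characterisation metrics: amplitude-weighted mean spatial
# frequency, orientation mean resultant length, colour-channel discrepancy
# (RGB / HSV saturation / CIELAB chroma variants), and temporal variation.

rf_to_gray <- function(rf) {
  stopifnot(length(dim(rf)) == 3, dim(rf)[3] == 3)
  (rf[, , 1] + rf[, , 2] + rf[, , 3]) / 3
}

# Keys cubic-convolution kernel (a = -0.5).
cubic_kernel <- function(s) {
  s <- abs(s)
  a <- -0.5
  ifelse(s < 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
         ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
}

# Dense 1D cubic-interpolation operator from n samples to n*factor samples
# (replicate padding at the borders). Output samples sit at pixel centres
# (the fine grid covers the same extent as the coarse one, symmetrically),
# so the operator commutes with axis flips and 90-degree rotations.
cubic_operator <- function(n, factor) {
  N <- n * factor
  u <- (seq_len(N) - 0.5) / factor + 0.5
  i0 <- floor(u)
  S <- matrix(0, N, n)
  for (o in -1:2) {
    tap <- pmin(pmax(i0 + o, 1L), n)
    w <- cubic_kernel(u - (i0 + o))
    S[cbind(seq_len(N), tap)] <- S[cbind(seq_len(N), tap)] + w
  }
  S
}

# Spatially upsample a matrix by an integer factor, either by separable
# cubic interpolation (default) or by Fourier zero-padding (sinc
# interpolation, exact for band-limited content).
upsample_matrix <- function(m, factor, method = c("interpolate", "zeropad")) {
  method <- match.arg(method)
  if (factor == 1) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  if (method == "interpolate") {
    S1 <- cubic_operator(n1, factor)
    S2 <- cubic_operator(n2, factor)
    return(S1 %*% m %*% t(S2))
  }
  N1 <- n1 * factor; N2 <- n2 * factor
  G <- fft(m)
  big <- matrix(0 + 0i, N1, N2)
  h1 <- floor(n1 / 2); h2 <- floor(n2 / 2)
  r1 <- c(seq_len(h1 + 1), (N1 - (n1 - h1 - 1) + 1):N1)
  r2 <- c(seq_len(h2 + 1), (N2 - (n2 - h2 - 1) + 1):N2)
  big[r1, r2] <- G
  Re(fft(big, inverse = TRUE)) / (n1 * n2)
}

# FFT magnitude of the grayscale, upsampled RF, with signed integer
# frequency indices. Shared by the frequency and orientation metrics.
rf_spectrum2d <- function(rf, upsample_factor, method = "interpolate") {
  g <- if (length(dim(rf)) == 3) rf_to_gray(rf) else rf
  if (sd(as.vector(g)) == 0)
    stop_undefined_metric("constant receptive field: all spectral amplitude is at DC, the metric is undefined")
  up <- upsample_matrix(g, upsample_factor, method)
  N <- nrow(up)
  M <- Mod(fft(up))
  k <- 0:(N - 1)
  ks <- ifelse(k > N / 2, k - N, k)
  list(M = M, kx = matrix(ks, N, N), ky = matrix(ks, N, N, byrow = TRUE),
       N = N, factor = upsample_factor, n_orig = nrow(g))
}

#' Radial spectral profile of a receptive field
#'
#' Grayscale conversion (unweighted channel mean), spatial upsampling, 2D
#' FFT magnitude, then radial averaging: magnitudes are grouped by the
#' rounded Euclidean radius on the frequency grid and averaged within each
#' annulus. The DC term is excluded, and the profile is restricted to
#' frequencies the original RF can represent (at most `max_freq`
#' cycles/pixel, the original Nyquist by default): the upsampled grid's
#' spectrum above that bound contains only interpolation artifacts, not RF
#' content. Frequencies are reported in cycles per original-RF pixel, so
#' the upsampling factor does not change the scale.
#'
#' @param rf an `h x w x 3` array (or `h x w` matrix, already grayscale).
#' @param upsample_factor integer spatial upsampling factor.
#' @param method `"interpolate"` (cubic) or `"zeropad"` (Fourier).
#' @param max_freq upper radial frequency bound (cycles/original pixel).
#' @return tibble with ascending `freq` (cycles/pixel, DC excluded) and
#'   nonnegative `amp`.
#' @export
radial_spectrum <- function(rf, upsample_factor = 100,
                            method = c("interpolate", "zeropad"),
                            max_freq = 0.5) {
  method <- match.arg(method)
  sp <- rf_spectrum2d(rf, upsample_factor, method)
  r <- round(sqrt(sp$kx^2 + sp$ky^2))
  keep <- r > 0 & r <= max_freq * sp$N / sp$factor
  amp <- as.vector(rowsum(sp$M[keep], r[keep])) /
    as.vector(rowsum(rep(1, sum(keep)), r[keep]))
  ri <- sort(unique(as.vector(r[keep])))
  tibble(freq = ri * sp$factor / sp$N, amp = amp)
}

#' Amplitude-weighted mean spatial frequency of a receptive field
#'
#' The radial spectral profile's amplitude-weighted mean,
#' `sum(amp(f) * f) / sum(amp(f))`, in cycles per original-RF pixel. The
#' ratio makes the metric invariant to rescaling the RF by any nonzero
#' scalar. A constant RF (all spectral amplitude at DC) raises an
#' undefined-metric error.
#'
#' @inheritParams radial_spectrum
#' @return a single nonnegative number (cycles/pixel).
#' @export
weighted_average_frequency <- function(rf, upsample_factor = 100,
                                       method = c("interpolate", "zeropad"),
                                       max_freq = 0.5) {
  prof <- radial_spectrum(rf, upsample_factor, method, max_freq)
  sum(prof$amp * prof$freq) / sum(prof$amp)
}

#' Orientation-intensity profile of a receptive field
#'
#' Azimuthal averaging of the FFT magnitude: grid points (DC excluded) with
#' radial frequency at most `freq_cutoff_fraction` of the spectrum the
#' original RF can theoretically represent (its Nyquist frequency, 0.5
#' cycles/pixel - so 0.125 cycles/pixel at the default quarter) are binned
#' by orientation `theta = atan2(fy, fx) mod pi` into `n_theta_bins`
#' uniform bins on `[0, pi)`, and magnitudes are averaged per bin. The
#' radial restriction discards high-frequency pixel and interpolation
#' noise while retaining the RF's effective low-frequency structure. Under
#' the default quarter cutoff the retained band is non-empty only for RFs
#' of side length >= 8 pixels; smaller RFs raise an undefined-metric
#' error.
#'
#' @inheritParams radial_spectrum
#' @param n_theta_bins number of orientation bins on `[0, pi)`.
#' @param freq_cutoff_fraction kept fraction of the original RF's
#'   representable radial frequency range.
#' @return tibble with bin-centre `theta` and mean `intensity` (empty bins
#'   dropped).
#' @export
orientation_profile <- function(rf, upsample_factor = 100, n_theta_bins = 36,
                                freq_cutoff_fraction = 0.25,
                                method = c("interpolate", "zeropad")) {
  method <- match.arg(method)
  sp <- rf_spectrum2d(rf, upsample_factor, method)
  r <- sqrt(sp$kx^2 + sp$ky^2)
  keep <- r > 0 & r <= freq_cutoff_fraction * 0.5 * sp$N / sp$factor
  th <- atan2(sp$ky[keep], sp$kx[keep]) %% pi
  bin <- pmin(floor(th / pi * n_theta_bins) + 1L, n_theta_bins)
  mags <- sp$M[keep]
  I <- as.vector(rowsum(mags, bin)) /
    as.vector(rowsum(rep(1, length(bin)), bin))
  bins <- sort(unique(bin))
  tibble(theta = (bins - 0.5) * pi / n_theta_bins, intensity = I)
}

#' Orientation selectivity (mean resultant length)
#'
#' The circular-statistics mean resultant length of the orientation-
#' intensity profile, `R = |sum(f(theta) e^(2 i theta))| / sum(f(theta))`,
#' on the axial (period-pi) orientation circle: 0 for an isotropic RF, 1
#' for energy concentrated at a single orientation.
#'
#' @inheritParams orientation_profile
#' @return `R` in `[0, 1]`.
#' @export
orientation_selectivity <- function(rf, upsample_factor = 100,
                                    n_theta_bins = 36,
                                    freq_cutoff_fraction = 0.25,
                                    method = c("interpolate", "zeropad")) {
  prof <- orientation_profile(rf, upsample_factor, n_theta_bins,
                              freq_cutoff_fraction, method)
  tot <- sum(prof$intensity)
  if (tot == 0)
    stop_undefined_metric("all-zero orientation profile: the resultant is undefined")
  Mod(sum(prof$intensity * exp(2i * prof$theta))) / tot
}

# Per-pixel colour-channel discrepancy: magnitude of the (R, G, B) vector
# sum with the channels placed 120 degrees apart. Zero wherever R == G == B.
color_discrepancy_map <- function(rf) {
  stopifnot(length(dim(rf)) == 3, dim(rf)[3] == 3)
  R <- rf[, , 1]; G <- rf[, , 2]; B <- rf[, , 3]
  x <- R * cos(0) + G * cos(2 * pi / 3) + B * cos(-2 * pi / 3)
  y <- R * sin(0) + G * sin(2 * pi / 3) + B * sin(-2 * pi / 3)
  sqrt(x^2 + y^2)
}

top_fraction_mean <- function(m, top_fraction) {
  v <- as.vector(m)
  k <- ceiling(top_fraction * length(v))
  mean(v[order(v, decreasing = TRUE, method = "radix")[seq_len(k)]])
}

#' Colour metrics of a receptive field
#'
#' `color_metric_rgb` measures per-pixel colour-channel discrepancy (the
#' deviation of (R, G, B) from the gray axis, channels placed 120 degrees
#' apart) and returns the mean of the top `ceiling(top_fraction * h * w)`
#' most colourful pixels (48 pixels for a 22 x 22 RF at the default 10%,
#' 12 for 11 x 11), so spatially extended RFs are not estimated as more
#' colourful merely for being extended. `color_metric_hsv` and
#' `color_metric_lab` apply the same top-fraction aggregation to per-pixel
#' HSV saturation and CIELAB chroma `sqrt(a^2 + b^2)` respectively, after
#' min-max rescaling the RF weights to the `[0, 1]` display range the
#' conversions are defined on.
#'
#' @param rf an `h x w x 3` array of filter weights.
#' @param top_fraction fraction of most-colourful pixels averaged.
#' @return a nonnegative scalar; exactly 0 when R == G == B everywhere.
#' @export
color_metric_rgb <- function(rf, top_fraction = 0.10) {
  top_fraction_mean(color_discrepancy_map(rf), top_fraction)
}

rescale01 <- function(rf) {
  lo <- min(rf); hi <- max(rf)
  if (hi == lo) return(rf * 0)
  (rf - lo) / (hi - lo)
}

#' @rdname color_metric_rgb
#' @export
color_metric_hsv <- function(rf, top_fraction = 0.10) {
  z <- rescale01(rf)
  rgbm <- rbind(as.vector(z[, , 1]), as.vector(z[, , 2]), as.vector(z[, , 3]))
  s <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)["s", ]
  top_fraction_mean(s, top_fraction)
}

#' @rdname color_metric_rgb
#' @export
color_metric_lab <- function(rf, top_fraction = 0.10) {
  z <- rescale01(rf)
  lab <- grDevices::convertColor(cbind(as.vector(z[, , 1]),
                                       as.vector(z[, , 2]),
                                       as.vector(z[, , 3])),
                                 from = "sRGB", to = "Lab")
  top_fraction_mean(sqrt(lab[, 2]^2 + lab[, 3]^2), top_fraction)
}

#' Pairwise temporal frame correlations of a 3D receptive field
#'
#' Pearson correlations between the flattened (space x channels) weight
#' tensors of every pair of time frames.
#'
#' @param rf3d a `t x h x w x 3` array, `t >= 2`; every frame must be
#'   non-constant.
#' @return tibble with `frame_a`, `frame_b`, `correlation`
#'   (`t * (t - 1) / 2` rows).
#' @export
temporal_correlations <- function(rf3d) {
  stopifnot(length(dim(rf3d)) == 4)
  tn <- dim(rf3d)[1]
  if (tn < 2) stop_undefined_metric("at least 2 frames required")
  fr <- vapply(seq_len(tn), function(t) as.vector(rf3d[t, , , ]),
               numeric(prod(dim(rf3d)[-1])))
  if (any(apply(fr, 2, sd) == 0))
    stop_undefined_metric("constant frame: its correlation with other frames is undefined")
  cm <- cor(fr)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  tibble(frame_a = pairs[, 1], frame_b = pairs[, 2],
         correlation = cm[pairs])
}

#' Temporal variation metric
#'
#' `(1 - min(correlation)) / 2` over all pairwise frame correlations: 0 for
#' a temporally static RF (minimum correlation +1), 1 for a biphasic RF
#' containing a sign-reversed frame pair (minimum correlation -1).
#'
#' @inheritParams temporal_correlations
#' @return value in `[0, 1]`.
#' @export
temporal_variation <- function(rf3d) {
  (1 - min(temporal_correlations(rf3d)$correlation)) / 2
}

#' Frame-averaged spatial metrics of a 3D receptive field
#'
#' The 2D frequency and colour metrics computed separately on each time
#' frame, then arithmetically averaged across frames.
#'
#' @inheritParams temporal_correlations
#' @inheritParams weighted_average_frequency
#' @inheritParams color_metric_rgb
#' @return list with `frequency` and `color`.
#' @export
spatial_metrics_3d <- function(rf3d, upsample_factor = 100,
                               top_fraction = 0.10,
                               method = c("interpolate", "zeropad")) {
  method <- match.arg(method)
  tn <- dim(rf3d)[1]
  waf <- vapply(seq_len(tn), function(t)
    weighted_average_frequency(rf3d[t, , , ], upsample_factor, method),
    numeric(1))
  col <- vapply(seq_len(tn), function(t)
    color_metric_rgb(rf3d[t, , , ], top_fraction), numeric(1))
  list(frequency = mean(waf), color = mean(col))
}

#' Per-unit receptive-field metric records
#'
#' Computes the full metric record for every receptive field: weighted
#' average frequency (cycles/pixel), orientation mean resultant length,
#' colour metrics (RGB discrepancy, HSV saturation, CIELAB chroma) and -
#' for 3D RFs - the temporal variation metric, with the spatial metrics
#' frame-averaged. The default upsampling factor of 10 is the desk-scale
#' choice; because frequencies are reported per original pixel, the factor
#' changes only the residual discretisation noise, not the scale.
#'
#' @param rfs tibble from [extract_first_layer_rfs()] or
#'   [generate_rf_bank()], or a plain list of weight arrays.
#' @inheritParams weighted_average_frequency
#' @inheritParams color_metric_rgb
#' @inheritParams orientation_profile
#' @return tibble with one row per unit: `unit_id`, `waf`, `orient_R`,
#'   `color_rgb`, `color_hsv`, `color_lab`, `temporal_variation` (NA for 2D
#'   RFs; `orient_R` is NA for 3D RFs).
#' @export
rf_metrics <- function(rfs, upsample_factor = 10, top_fraction = 0.10,
                       n_theta_bins = 36, freq_cutoff_fraction = 0.25,
                       method = c("interpolate", "zeropad")) {
  method <- match.arg(method)
  if (is.data.frame(rfs)) {
    ids <- rfs$unit_id
    ws <- rfs$weights
  } else {
    ids <- seq_along(rfs)
    ws <- rfs
  }
  rows <- purrr::map2(ws, ids, function(w, id) {
    if (length(dim(w)) == 4) {
      sm <- spatial_metrics_3d(w, upsample_factor, top_fraction, method)
      tn <- dim(w)[1]
      hsv <- mean(vapply(seq_len(tn), function(t)
        color_metric_hsv(w[t, , , ], top_fraction), numeric(1)))
      lab <- mean(vapply(seq_len(tn), function(t)
        color_metric_lab(w[t, , , ], top_fraction), numeric(1)))
      tibble(unit_id = id, waf = sm$frequency, orient_R = NA_real_,
             color_rgb = sm$color, color_hsv = hsv, color_lab = lab,
             temporal_variation = temporal_variation(w))
    } else {
      tibble(unit_id = id,
             waf = weighted_average_frequency(w, upsample_factor, method),
             orient_R = orientation_selectivity(w, upsample_factor,
                                                n_theta_bins,
                                                freq_cutoff_fraction, method),
             color_rgb = color_metric_rgb(w, top_fraction),
             color_hsv = color_metric_hsv(w, top_fraction),
             color_lab = color_metric_lab(w, top_fraction),
             temporal_variation = NA_real_)
    }
  })
  dplyr::bind_rows(rows)
}
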