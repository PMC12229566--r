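# Independent brute-force oracles. These deliberately avoid the package's
# vectorised implementations: plain loops, explicit formulas, no shared
# helper code beyond the upsampled grayscale input where the claim under
# test is the spectral tally itself (not the resampling).

# Unweighted grayscale of an h x w x 3 array.
oracle_gray <- function(rf) {
  if (length(dim(rf)) == 2) return(rf)
  (rf[, , 1] + rf[, , 2] + rf[, , 3]) / 3
}

# Weighted average frequency by enumerating every FFT bin of a (already
# upsampled) grayscale matrix: round each bin's Euclidean radius, tally
# amplitude sums and counts per integer radius with a loop, average per
# annulus, and take the amplitude-weighted mean frequency in cycles per
# ORIGINAL pixel (original size n_orig).
oracle_waf_from_matrix <- function(g, n_orig, max_freq = 0.5) {
  N <- nrow(g)
  A <- Mod(stats::fft(g))
  kx <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1))
  sums <- numeric(0); counts <- numeric(0)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      r <- round(sqrt(kx[i]^2 + kx[j]^2))
      if (r == 0) next
      key <- as.character(r)
      sums[key] <- (if (is.na(sums[key])) 0 else sums[key]) + A[i, j]
      counts[key] <- (if (is.na(counts[key])) 0 else counts[key]) + 1
    }
  }
  r_int <- as.numeric(names(sums))
  f <- r_int * (N / n_orig) / N
  keep <- f <= max_freq
  amp <- (sums / counts)[keep]
  sum(amp * f[keep]) / sum(amp)
}

# Mean resultant length recomputed from an orientation profile by explicit
# complex summation.
oracle_resultant <- function(theta, intensity) {
  z <- 0 + 0i
  for (i in seq_along(theta)) z <- z + intensity[i] * exp(2i * theta[i])
  Mod(z) / sum(intensity)
}

# Colour metric: per-pixel m via the stated trig sums, full sort, top-k
# mean.
oracle_color_rgb <- function(rf, top_fraction = 0.10) {
  h <- dim(rf)[1]; w <- dim(rf)[2]
  m <- numeric(h * w)
  ang <- c(0, 2 * pi / 3, -2 * pi / 3)
  idx <- 0
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      idx <- idx + 1
      x <- sum(rf[i, j, ] * cos(ang))
      y <- sum(rf[i, j, ] * sin(ang))
      m[idx] <- sqrt(x^2 + y^2)
    }
  }
  k <- ceiling(top_fraction * h * w)
  mean(sort(m, decreasing = TRUE)[seq_len(k)])
}

# HSV-saturation variant: per-pixel conversion of the min-max rescaled RF
# through grDevices, then sort + top-k.
oracle_color_hsv <- function(rf, top_fraction = 0.10) {
  z <- rf - min(rf)
  if (max(z) > 0) z <- z / max(z)
  h <- dim(rf)[1]; w <- dim(rf)[2]
  s <- numeric(h * w)
  idx <- 0
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      idx <- idx + 1
      s[idx] <- grDevices::rgb2hsv(z[i, j, 1], z[i, j, 2], z[i, j, 3],
                                   maxColorValue = 1)[2, 1]
    }
  }
  k <- ceiling(top_fraction * h * w)
  mean(sort(s, decreasing = TRUE)[seq_len(k)])
}

# CIELAB-chroma variant: per-pixel sRGB -> Lab conversion, chroma
# sqrt(a^2 + b^2), sort + top-k.
oracle_color_lab <- function(rf, top_fraction = 0.10) {
  z <- rf - min(rf)
  if (max(z) > 0) z <- z / max(z)
  h <- dim(rf)[1]; w <- dim(rf)[2]
  ch <- numeric(h * w)
  idx <- 0
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      idx <- idx + 1
      lab <- grDevices::convertColor(matrix(z[i, j, ], 1), from = "sRGB",
                                     to = "Lab")
      ch[idx] <- sqrt(lab[2]^2 + lab[3]^2)
    }
  }
  k <- ceiling(top_fraction * h * w)
  mean(sort(ch, decreasing = TRUE)[seq_len(k)])
}

# Temporal variation: all-pairs Pearson correlation with explicit loops.
oracle_temporal_variation <- function(rf3d) {
  t_n <- dim(rf3d)[1]
  cors <- c()
  for (a in seq_len(t_n - 1)) {
    for (b in (a + 1):t_n) {
      cors <- c(cors, stats::cor(as.vector(rf3d[a, , , ]),
                                 as.vector(rf3d[b, , , ])))
    }
  }
  (1 - min(cors)) / 2
}

# Radial power tally of a grayscale matrix (no upsampling): total non-DC
# power and power above a frequency threshold (cycles/pixel). Used for
# cue-separability and blur transfer-function checks.
oracle_radial_power <- function(g, threshold) {
  n <- nrow(g)
  P <- Mod(stats::fft(g))^2
  kx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  tot <- 0; above <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      f <- sqrt(kx[i]^2 + kx[j]^2)
      if (f == 0) next
      tot <- tot + P[i, j]
      if (f > threshold) above <- above + P[i, j]
    }
  }
  c(total = tot, above = above)
}

# Per-bin power of a grayscale matrix together with each bin's radial
# frequency (cycles/pixel), for transfer-function comparisons.
oracle_power_bins <- function(g) {
  n <- nrow(g)
  P <- Mod(stats::fft(g))^2
  kx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  f <- sqrt(outer(kx^2, kx^2, `+`))
  list(power = P, freq = f)
}

# Dominant rigid displacement between two grayscale frames by
# cross-correlation (phase-free, circular): the argmax of the circular
# cross-correlation surface computed by FFT.
oracle_displacement <- function(g1, g2) {
  n <- nrow(g1)
  cc <- Re(stats::fft(stats::fft(g1) * Conj(stats::fft(g2)), inverse = TRUE))
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  d <- ij - 1
  d <- ifelse(d > n / 2, d - n, d)
  unname(d)
}

# Least-squares linear classifier on raw pixels: attainability oracle for
# the separability of a 2-class synthetic set.
oracle_linear_separability <- function(dataset) {
  X <- t(vapply(dataset$pixels, as.vector,
                numeric(length(dataset$pixels[[1]]))))
  y <- ifelse(dataset$label == 1, 1, -1)
  Xc <- cbind(1, X)
  beta <- qr.coef(qr(Xc), y)
  beta[is.na(beta)] <- 0
  mean(sign(Xc %*% beta) == y)
}
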