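# Shared internal helpers: seeded evaluation, blur, clamping, error classes.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_config <- function(msg) {
  abort(msg, class = "pm_error_config")
}

stop_undefined_metric <- function(msg) {
  abort(msg, class = "pm_error_undefined_metric")
}

clamp <- function(x, lo = -1, hi = 1) {
  pmin(pmax(x, lo), hi)
}

# Reflect an out-of-range index into 1..n (mirror about the edges,
# edge sample not repeated: 0 -> 2, n+1 -> n-1).
reflect_map <- function(q, n) {
  q <- ifelse(q < 1, 2 - q, q)
  q <- ifelse(q > n, 2 * n - q, q)
  pmin(pmax(q, 1L), n)
}

gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense 1D Gaussian blur operator with reflect padding: blurred vector of
# length n is B %*% v. Cached per (n, sigma) in the session.
blur_operator_cache <- new.env(parent = emptyenv())
blur_operator <- function(n, sigma) {
  key <- paste(n, signif(sigma, 10))
  hit <- blur_operator_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- gaussian_kernel(sigma)
  half <- (length(k) - 1L) / 2L
  B <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -half:half) {
    j <- reflect_map(i + o, n)
    B[cbind(i, j)] <- B[cbind(i, j)] + k[o + half + 1L]
  }
  blur_operator_cache[[key]] <- B
  B
}

# Separable Gaussian blur of a single-channel matrix, reflect padding.
blur_matrix <- function(m, sigma) {
  if (sigma == 0) return(m)
  Br <- blur_operator(nrow(m), sigma)
  Bc <- blur_operator(ncol(m), sigma)
  Br %*% m %*% t(Bc)
}

# Hard low-pass of a matrix: zero all FFT coefficients whose radial
# frequency (cycles/pixel) exceeds `cutoff`.
lowpass_field <- function(m, cutoff) {
  n1 <- nrow(m); n2 <- ncol(m)
  f1 <- fft_freqs(n1); f2 <- fft_freqs(n2)
  rad <- sqrt(outer(f1^2, f2^2, "+"))
  G <- fft(m)
  G[rad > cutoff] <- 0 + 0i
  Re(fft(G, inverse = TRUE)) / (n1 * n2)
}

# Signed DFT frequencies in cycles/sample for an n-point transform.
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k > n / 2, k - n, k) / n
}

is_image <- function(x) is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3
is_clip <- function(x) is.array(x) && length(dim(x)) == 4 && dim(x)[4] == 3
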