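# Shared fixtures, memoised so expensive objects (trained models, the
# regimen-comparison study) are computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A grid-aligned grating RF: integer cycles along each axis, so its energy
# sits exactly on FFT bins (no spectral leakage) and its true frequency is
# sqrt(cx^2 + cy^2) / n cycles/pixel.
grating_rf <- function(n = 20, cycles_x = 3, cycles_y = 0, phase = 0.2) {
  x <- matrix(rep(seq_len(n), each = n), n)
  y <- matrix(rep(seq_len(n), n), n)
  g <- cos(2 * pi * (cycles_x * x + cycles_y * y) / n + phase)
  array(rep(g, 3), c(n, n, 3))
}

random_rf2d <- function(size = 9, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(size * size * 3), c(size, size, 3))
}

random_rf3d <- function(size = 7, n_time = 5, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(n_time * size * size * 3), c(n_time, size, size, 3))
}

# Small 4-class corpus and a briefly trained model over it, shared by the
# bias / ablation / invariance tests.
tiny_dataset <- function() {
  memo("tiny_dataset",
       generate_classification_dataset(4, 12, image_size = 32, seed = 42))
}

tiny_test_set <- function() {
  memo("tiny_test_set",
       generate_classification_dataset(4, 6, image_size = 32, seed = 42,
                                       exemplar_seed = 4242))
}

tiny_conflict <- function() {
  memo("tiny_conflict",
       generate_cue_conflict_set(4, 4, 2, image_size = 32, seed = 42))
}

tiny_config <- function() {
  # filter_size >= 8 so that the orientation metric is defined on the
  # trained first layer (see ?orientation_profile)
  model_config(n_filters = 8, filter_size = 9, n_classes = 4,
               image_size = 32, n_hidden = 24)
}

tiny_trained_model <- function() {
  memo("tiny_trained_model", {
    reg <- make_regimen("standard", scale = 0.02, image_size = 32)
    hp <- training_hyperparams(batch_size = 16,
                               lr_schedule = list(kind = "constant",
                                                  rate = 0.02),
                               n_epochs = reg$total_epochs, seed = 7)
    train_with_regimen(build_model(tiny_config(), seed = 7),
                       tiny_dataset(), reg, hp)
  })
}

# Oracle classifiers for the cue-conflict protocol: probability 1 on the
# image's shape (or texture) class.
shape_oracle <- function(dataset) {
  n <- max(dataset$shape_class, dataset$texture_class)
  p <- matrix(0, nrow(dataset), n)
  p[cbind(seq_len(nrow(dataset)), dataset$shape_class)] <- 1
  p
}

texture_oracle <- function(dataset) {
  n <- max(dataset$shape_class, dataset$texture_class)
  p <- matrix(0, nrow(dataset), n)
  p[cbind(seq_len(nrow(dataset)), dataset$texture_class)] <- 1
  p
}

# The full desk-scale regimen comparison (the expensive stochastic study);
# computed once and reused by every directional assertion.
desk_study <- function() {
  memo("desk_study", run_regimen_comparison())
}

desk_study_tests <- function() {
  memo("desk_study_tests", compare_regimens(desk_study()))
}
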