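test_that("model building is seeded-deterministic with the configured shape", {
  cfg <- tiny_config()
  a <- build_model(cfg, seed = 3)
  b <- build_model(cfg, seed = 3)
  expect_identical(a$W1, b$W1)
  expect_identical(a$W2, b$W2)
  expect_identical(a$W3, b$W3)
  c <- build_model(cfg, seed = 4)
  expect_false(identical(a$W1, c$W1))
  expect_equal(dim(a$W1), c(9, 9, 3, 8))
})

test_that("setting1 preset yields 48 filters of 22 x 22 x 3", {
  cfg <- config_from_setting(setting_preset("setting1"))
  m <- build_model(cfg, seed = 1)
  expect_equal(dim(m$W1), c(22, 22, 3, 48))
})

test_that("a filter larger than the image is rejected", {
  expect_error(model_config(n_filters = 4, filter_size = 40, n_classes = 2,
                            image_size = 32),
               class = "pm_error_config")
})

test_that("the mini preset builds and produces a valid forward pass", {
  cfg <- config_from_setting(setting_preset("mini"))
  m <- build_model(cfg, seed = 1)
  d <- generate_classification_dataset(2, 3, image_size = 64, seed = 1)
  p <- predict_proba(m, d)
  expect_equal(dim(p), c(6, cfg$n_classes))
  expect_equal(rowSums(p), rep(1, 6))
  expect_true(all(p >= 0))
})

test_that("first-layer extraction returns the raw seeded weights", {
  m <- build_model(tiny_config(), seed = 5)
  rfs <- extract_first_layer_rfs(m)
  expect_equal(nrow(rfs), 8)
  expect_identical(rfs$weights[[3]], m$W1[, , , 3])
  cfg3 <- model_config(variant = "3d", n_filters = 4, filter_size = 7,
                       n_classes = 2, image_size = 32, n_time = 5)
  m3 <- build_model(cfg3, seed = 5)
  rfs3 <- extract_first_layer_rfs(m3)
  expect_equal(dim(rfs3$weights[[1]]), c(5, 7, 7, 3))
})

test_that("training is deterministic for a fixed seed", {
  d <- generate_classification_dataset(2, 8, image_size = 32, seed = 31)
  reg <- make_regimen("standard", scale = 0.01, image_size = 32)
  cfg <- model_config(n_filters = 4, filter_size = 7, n_classes = 2,
                      image_size = 32, n_hidden = 16)
  hp <- training_hyperparams(batch_size = 8,
                             lr_schedule = list(kind = "constant", rate = 0.02),
                             n_epochs = reg$total_epochs, seed = 11)
  m1 <- train_with_regimen(build_model(cfg, seed = 11), d, reg, hp)
  m2 <- train_with_regimen(build_model(cfg, seed = 11), d, reg, hp)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W3, m2$W3)
  expect_identical(m1$history, m2$history)
})

test_that("frozen units are bit-identical across their frozen phase", {
  # a single-phase regimen with half the units frozen, built by truncating
  # the staged regimen to its first phase
  reg <- make_regimen("biomimetic_v4", scale = 0.02, image_size = 32)
  reg$phases <- reg$phases[1, ]
  reg$total_epochs <- reg$phases$n_epochs
  cfg <- tiny_config()
  hp <- training_hyperparams(batch_size = 16,
                             lr_schedule = list(kind = "constant", rate = 0.02),
                             n_epochs = reg$total_epochs, seed = 13)
  init <- build_model(cfg, seed = 13)
  trained <- train_with_regimen(init, tiny_dataset(), reg, hp)
  frozen <- seq_len(ceiling(0.5 * cfg$n_filters))
  free <- setdiff(seq_len(cfg$n_filters), frozen)
  expect_identical(trained$W1[, , , frozen], init$W1[, , , frozen])
  expect_identical(trained$b1[frozen], init$b1[frozen])
  for (u in free) {
    expect_false(identical(trained$W1[, , , u], init$W1[, , , u]))
  }
  # deeper layers keep learning during the frozen phase
  expect_false(identical(trained$W3, init$W3))
})

test_that("the full v4 regimen unfreezes in phase 2", {
  reg <- make_regimen("biomimetic_v4", scale = 0.02, image_size = 32)
  cfg <- tiny_config()
  hp <- training_hyperparams(batch_size = 16,
                             lr_schedule = list(kind = "constant", rate = 0.02),
                             n_epochs = reg$total_epochs, seed = 13)
  init <- build_model(cfg, seed = 13)
  trained <- train_with_regimen(init, tiny_dataset(), reg, hp)
  for (u in seq_len(cfg$n_filters)) {
    expect_false(identical(trained$W1[, , , u], init$W1[, , , u]))
  }
})

test_that("a separable 2-class set is learned above 90% accuracy", {
  d <- generate_classification_dataset(2, 16, image_size = 32, seed = 77)
  # attainability: a least-squares linear read-out on raw pixels separates
  # the training set before we ask the network to
  expect_gte(oracle_linear_separability(d), 0.95)
  reg <- make_regimen("standard", scale = 0.025, image_size = 32)  # 5 epochs
  cfg <- model_config(n_filters = 8, filter_size = 7, n_classes = 2,
                      image_size = 32, n_hidden = 16)
  hp <- training_hyperparams(batch_size = 8,
                             lr_schedule = list(kind = "constant", rate = 0.02),
                             n_epochs = reg$total_epochs, seed = 21,
                             validation_fraction = 0)
  m <- train_with_regimen(build_model(cfg, seed = 21), d, reg, hp)
  expect_gt(evaluate_accuracy(m, d), 0.9)
})

test_that("training history covers every epoch with its phase", {
  m <- tiny_trained_model()
  reg <- m$regimen
  expect_equal(nrow(m$history), reg$total_epochs)
  expect_equal(m$history$epoch, seq_len(reg$total_epochs))
  expect_true(all(is.finite(m$history$loss)))
  g <- glance(m)
  expect_equal(g$n_epochs, reg$total_epochs)
  expect_equal(g$regimen, "standard")
  expect_identical(tidy(m), m$history)
})

test_that("mismatched epochs and out-of-range labels are errors", {
  d <- tiny_dataset()
  reg <- make_regimen("standard", scale = 0.02, image_size = 32)
  hp <- training_hyperparams(n_epochs = reg$total_epochs + 1, seed = 1)
  m <- build_model(tiny_config(), seed = 1)
  expect_error(train_with_regimen(m, d, reg, hp), class = "pm_error_config")
  hp2 <- training_hyperparams(n_epochs = reg$total_epochs, seed = 1)
  bad <- d
  bad$label[1] <- 99
  expect_error(train_with_regimen(m, bad, reg, hp2),
               class = "pm_error_config")
})

test_that("a non-finite loss aborts with a diagnostic training error", {
  d <- generate_classification_dataset(2, 8, image_size = 32, seed = 55)
  reg <- make_regimen("standard", scale = 0.01, image_size = 32)
  hp <- training_hyperparams(batch_size = 8,
                             lr_schedule = list(kind = "constant", rate = 0.02),
                             n_epochs = reg$total_epochs, seed = 55)
  m <- build_model(model_config(n_filters = 4, filter_size = 7, n_classes = 2,
                                image_size = 32, n_hidden = 16), seed = 55)
  m$W1[1] <- NaN  # corrupt parameter state, as after a numerical blow-up
  expect_error(train_with_regimen(m, d, reg, hp), class = "pm_error_training")
})

test_that("accuracy evaluation matches oracles and rejects empty data", {
  d <- tiny_test_set()
  perfect <- function(dataset) {
    p <- matrix(0, nrow(dataset), 4)
    p[cbind(seq_len(nrow(dataset)), dataset$label)] <- 1
    p
  }
  expect_equal(evaluate_accuracy(perfect, d), 1)
  expect_error(evaluate_accuracy(perfect, d[0, ]), class = "pm_error_config")
  # a uniform-random classifier scores 1/C in expectation on balanced data
  set.seed(99)
  fake <- tibble::tibble(label = rep(1:4, each = 250),
                         pixels = replicate(1000, NA, simplify = FALSE))
  random_clf <- function(dataset) {
    p <- matrix(stats::runif(nrow(dataset) * 4), nrow(dataset), 4)
    p / rowSums(p)
  }
  acc <- evaluate_accuracy(random_clf, fake)
  se <- sqrt(0.25 * 0.75 / 1000)
  expect_lt(abs(acc - 0.25), 3 * se)
})

test_that("equal-channel filters respond identically to colour and grayscale", {
  m <- build_model(tiny_config(), seed = 17)
  # force every first-layer filter to satisfy R == G == B
  mch <- (m$W1[, , 1, ] + m$W1[, , 2, ] + m$W1[, , 3, ]) / 3
  for (c in 1:3) m$W1[, , c, ] <- mch
  img <- tiny_dataset()$pixels[[1]]
  a_color <- parvomagno:::layer_activations(m, list(img))
  a_gray <- parvomagno:::layer_activations(m, list(img),
                                           degradation_spec(to_grayscale = TRUE))
  expect_equal(a_color$conv1, a_gray$conv1, tolerance = 1e-12)
})

test_that("a 3D model trains on video and exposes temporal receptive fields", {
  d <- generate_video_dataset(2, 4, frames = 10, image_size = 32, seed = 61)
  cfg <- model_config(variant = "3d", n_filters = 4, filter_size = 7,
                      n_classes = 2, image_size = 32, n_hidden = 16,
                      n_time = 5)
  reg <- make_regimen("standard", scale = 0.01, image_size = 32)
  hp <- training_hyperparams(batch_size = 4,
                             lr_schedule = list(kind = "constant", rate = 0.01),
                             n_epochs = reg$total_epochs, seed = 61,
                             validation_fraction = 0, flip = FALSE)
  m <- train_with_regimen(build_model(cfg, seed = 61), d, reg, hp)
  expect_equal(nrow(m$history), reg$total_epochs)
  rfs <- extract_first_layer_rfs(m)
  rec <- rf_metrics(rfs, upsample_factor = 4)
  expect_true(all(!is.na(rec$temporal_variation)))
  expect_true(all(rec$temporal_variation >= 0 & rec$temporal_variation <= 1))
})
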