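test_that("classification dataset generation is seeded-deterministic", {
  a <- generate_classification_dataset(2, 3, image_size = 32, seed = 0)
  b <- generate_classification_dataset(2, 3, image_size = 32, seed = 0)
  expect_identical(a, b)
  c <- generate_classification_dataset(2, 3, image_size = 32, seed = 1)
  expect_false(identical(a$pixels[[1]], c$pixels[[1]]))
})

test_that("dataset is balanced, labelled and in range", {
  d <- generate_classification_dataset(3, 5, image_size = 32, seed = 2)
  expect_equal(nrow(d), 15)
  expect_equal(as.vector(table(d$label)), rep(5, 3))
  expect_identical(d$shape_class, d$label)
  expect_identical(d$texture_class, d$label)
  for (p in d$pixels) {
    expect_equal(dim(p), c(32, 32, 3))
    expect_true(all(p >= -1 & p <= 1))
  }
})

test_that("chroma_strength 0 yields exactly achromatic images", {
  d <- generate_classification_dataset(2, 2, image_size = 32,
                                       chroma_strength = 0, seed = 3)
  for (p in d$pixels) {
    expect_identical(p[, , 1], p[, , 2])
    expect_identical(p[, , 2], p[, , 3])
  }
})

test_that("same seed, different exemplar seeds share classes, not pixels", {
  a <- generate_classification_dataset(2, 2, image_size = 32, seed = 5)
  b <- generate_classification_dataset(2, 2, image_size = 32, seed = 5,
                                       exemplar_seed = 99)
  expect_false(identical(a$pixels[[1]], b$pixels[[1]]))
  # same class definitions: the texture parameters are seed-determined
  expect_identical(class_specs(2, seed = 5), class_specs(2, seed = 5))
})

test_that("overlapping texture band and shape cutoff is a config error", {
  expect_error(class_specs(2, shape_cutoff_freq = 0.25,
                           texture_band = c(0.2, 0.4)),
               class = "pm_error_config")
  expect_error(generate_classification_dataset(2, 1, texture_band = c(0.6, 0.7)),
               class = "pm_error_config")
  expect_error(generate_classification_dataset(1, 3),
               class = "pm_error_config")
  expect_error(generate_classification_dataset(2, 3, image_size = 16),
               class = "pm_error_config")
})

test_that("shape and texture cues are spectrally separable (FFT oracle)", {
  specs <- class_specs(10, seed = 11)
  for (i in seq_len(nrow(specs))) {
    sil <- parvomagno:::render_silhouette(specs[i, ], 64)
    pw <- oracle_radial_power(sil, threshold = 0.2)
    # silhouette power above the texture band start is < 5% of non-DC power
    expect_lt(pw["above"] / pw["total"], 0.05)
    tx <- parvomagno:::render_texture(specs[i, ], 64,
                                      phases = c(0.3, 1.1))
    # band widened by one FFT bin (1/64): the finite 64-pixel window
    # spreads each grating over adjacent bins (spectral leakage)
    inband <- oracle_radial_power(tx, threshold = 0.2 - 1 / 64)["above"] -
      oracle_radial_power(tx, threshold = 0.4 + 1 / 64)["above"]
    expect_gt(inband / oracle_radial_power(tx, threshold = 0)["total"], 0.95)
  }
})

test_that("cue-conflict grid combinatorics hold for small grids", {
  cs <- generate_cue_conflict_set(2, 2, 1, image_size = 32, seed = 1)
  expect_equal(nrow(cs), 4)
  expect_equal(sum(cs$congruent), 2)
  cs2 <- generate_cue_conflict_set(5, 3, 2, image_size = 32, seed = 1)
  expect_equal(nrow(cs2), 5 * 3 * 2)
  expect_equal(sum(cs2$congruent), min(5, 3) * 2)
  tab <- table(cs2$shape_class, cs2$texture_class)
  expect_true(all(tab == 2))
  expect_error(generate_cue_conflict_set(2, 2, 0, image_size = 32),
               class = "pm_error_config")
  expect_error(generate_cue_conflict_set(1, 2, 1, image_size = 32),
               class = "pm_error_config")
})

test_that("conflict image (i, j) carries shape i and texture j", {
  # with chroma riding the texture, the dominant hue of an incongruent
  # image must match the texture class's hue, not the shape class's
  specs <- class_specs(4, seed = 42)
  cs <- tiny_conflict()
  one <- cs[!cs$congruent, ][1, ]
  img <- one$pixels[[1]]
  hue_t <- parvomagno:::hue_direction(specs$base_hue[one$texture_class])
  hue_s <- parvomagno:::hue_direction(specs$base_hue[one$shape_class])
  dev <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  dev <- dev - rowMeans(dev)  # chromatic component only
  expect_gt(sum(dev^2), 0)
  expect_gt(sum((dev %*% hue_t)^2), sum((dev %*% hue_s)^2))
})

test_that("degrade with sigma 0 and no grayscale is the identity", {
  img <- tiny_dataset()$pixels[[1]]
  expect_identical(degrade(img, 0, FALSE), img)
})

test_that("grayscale degradation equalises channels and zeroes colour", {
  img <- tiny_dataset()$pixels[[1]]
  g <- degrade(img, 0, TRUE)
  expect_identical(g[, , 1], g[, , 2])
  expect_identical(g[, , 2], g[, , 3])
  expect_equal(color_metric_rgb(g), 0)
  # idempotence
  expect_identical(degrade(g, 0, TRUE), g)
})

test_that("negative sigma is an error", {
  img <- tiny_dataset()$pixels[[1]]
  expect_error(degrade(img, -1), class = "pm_error_config")
  expect_error(degradation_spec(-0.5), class = "pm_error_config")
})

test_that("blur attenuates high frequencies like the Gaussian MTF", {
  set.seed(8)
  n <- 64
  noise <- matrix(rnorm(n * n), n)
  img <- array(rep(noise, 3), c(n, n, 3)) * 0.3
  sigma <- 4
  blurred <- degrade(img, blur_sigma = sigma)
  pb <- oracle_power_bins(blurred[, , 1])
  p0 <- oracle_power_bins(img[, , 1])
  # theoretical squared transfer function of a Gaussian blur
  mtf2 <- exp(-(2 * pi * pb$freq * sigma)^2)
  sel <- pb$freq > 0.25
  expect_equal(sum(pb$power[sel]) / sum(p0$power[sel]),
               sum(p0$power[sel] * mtf2[sel]) / sum(p0$power[sel]),
               tolerance = 0.05)
  # and the high band is strongly attenuated in absolute terms (the
  # kernel truncation at 4 sigma leaves a small residual)
  expect_lt(sum(pb$power[sel]) / sum(p0$power[sel]), 1e-3)
})

test_that("sigma composition is approximately Pythagorean on smooth images", {
  img <- tiny_dataset()$pixels[[1]]
  once <- degrade(img, blur_sigma = sqrt(1.5^2 + 2^2))
  twice <- degrade(degrade(img, blur_sigma = 1.5), blur_sigma = 2)
  rms <- sqrt(mean((once - twice)^2)) / sqrt(mean(once^2))
  expect_lt(rms, 0.02)
})

test_that("rf bank annotates filters with generating parameters", {
  bank <- generate_rf_bank(list(list(kind = "grating", freq = 0.2,
                                     theta = pi / 4)),
                           size = 11, seed = 1)
  expect_equal(bank$freq[1], 0.2)
  expect_equal(bank$theta[1], pi / 4)
  expect_equal(dim(bank$weights[[1]]), c(11, 11, 3))
  expect_error(generate_rf_bank(list(list(kind = "grating", freq = 0.7))),
               class = "pm_error_config")
})

test_that("static and biphasic temporal filters have the stated frame structure", {
  bank <- generate_rf_bank(c("static_temporal", "biphasic_temporal"),
                           size = 9, n_time = 5, seed = 2)
  st <- bank$weights[[1]]
  cors <- as.vector(combn(5, 2, function(p)
    cor(as.vector(st[p[1], , , ]), as.vector(st[p[2], , , ]))))
  expect_equal(cors, rep(1, 10))
  bi <- bank$weights[[2]]
  cors_bi <- as.vector(combn(5, 2, function(p)
    cor(as.vector(bi[p[1], , , ]), as.vector(bi[p[2], , , ]))))
  expect_equal(min(cors_bi), -1)
  expect_equal(bi[1, , , ], -bi[5, , , ])
})

test_that("video dataset is deterministic with class-specific motion", {
  a <- generate_video_dataset(2, 2, frames = 12, image_size = 32, seed = 4)
  b <- generate_video_dataset(2, 2, frames = 12, image_size = 32, seed = 4)
  expect_identical(a, b)
  expect_true(all(vapply(a$pixels, function(p) all(p >= -1 & p <= 1),
                         logical(1))))
})

test_that("zero motion speed gives identical frames", {
  d <- generate_video_dataset(2, 1, frames = 10, image_size = 32,
                              motion_speed_range = c(0, 0), seed = 5)
  clip <- d$pixels[[1]]
  for (t in 2:dim(clip)[1]) expect_identical(clip[t, , , ], clip[1, , , ])
})

test_that("per-class motion matches a cross-correlation displacement oracle", {
  d <- generate_video_dataset(3, 2, frames = 10, image_size = 32,
                              motion_speed_range = c(1, 3), seed = 6)
  shift_mat <- function(m, dx, dy) {
    n <- nrow(m)
    m[((seq_len(n) - 1 - dx) %% n) + 1, ((seq_len(n) - 1 - dy) %% n) + 1]
  }
  for (i in seq_len(nrow(d))) {
    clip <- d$pixels[[i]]
    g1 <- oracle_gray(clip[1, , , ])
    g2 <- oracle_gray(clip[2, , , ])
    disp <- oracle_displacement(g1, g2)
    # the estimated rigid shift (up to cross-correlation sign convention)
    # must reproduce frame 2 from frame 1 exactly ...
    moved <- identical(shift_mat(g1, disp[1], disp[2]), g2) ||
      identical(shift_mat(g1, -disp[1], -disp[2]), g2)
    expect_true(moved)
    # ... and its magnitude must match the class's declared motion vector
    expected <- round(d$speed[i] * c(cos(d$direction[i]),
                                     sin(d$direction[i])))
    expect_equal(sort(abs(disp)), sort(abs(expected)))
  }
  # same class -> same estimated displacement across exemplars
  steps <- vapply(d$pixels[d$label == 1], function(clip) {
    oracle_displacement(oracle_gray(clip[1, , , ]), oracle_gray(clip[2, , , ]))
  }, numeric(2))
  expect_true(all(steps[, 1] == steps[, 2]))
})

test_that("video generator rejects invalid configurations", {
  expect_error(generate_video_dataset(2, 1, frames = 4, image_size = 32),
               class = "pm_error_config")
  expect_error(generate_video_dataset(2, 1, frames = 12, image_size = 32,
                                      motion_speed_range = c(40, 40)),
               class = "pm_error_config")
})

test_that("image datasets round-trip through PNG within quantisation", {
  d <- generate_classification_dataset(2, 2, image_size = 32, seed = 12)
  dir <- withr::local_tempdir()
  write_image_dataset(d, dir)
  back <- read_image_dataset(dir)
  expect_equal(back$label, d$label)
  for (i in seq_len(nrow(d))) {
    # 8-bit quantisation error is at most half a level, i.e. 1/255 on [-1, 1]
    expect_lt(max(abs(back$pixels[[i]] - d$pixels[[i]])), 1 / 255 + 1e-12)
  }
})
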