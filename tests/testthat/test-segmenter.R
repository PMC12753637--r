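reduced_cfg <- function(epochs = 2L, ...) {
  training_config(learning_rate = 2e-3, epochs = epochs, batch_size = 4L,
                  seed = 11L, ...)
}

test_that("the model maps RGB rasters to per-pixel class probabilities", {
  m <- build_model(reduced_cfg(), "reduced")
  img <- array(runif(64 * 64 * 3), c(64L, 64L, 3L))
  probs <- predict_probs(m, img)
  expect_identical(dim(probs), c(64L, 64L, 3L))
  expect_lt(max(abs(probs[, , 1] + probs[, , 2] + probs[, , 3] - 1)), 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("the full variant honours the encoder contract", {
  m <- build_model(reduced_cfg(), "full")
  # 7x7 stem producing 64 maps; bottleneck emitting 1024 maps
  expect_identical(dim(m$params$stem$W), c(7L * 7L * 3L, 64L))
  expect_identical(ncol(m$params$bottleneck$W), 1024L)
  img <- array(runif(64 * 64 * 3), c(64L, 64L, 3L))
  probs <- predict_probs(m, img)
  expect_identical(dim(probs), c(64L, 64L, 3L))
})

test_that("inputs not divisible by 32 are rejected", {
  m <- build_model(reduced_cfg(), "reduced")
  expect_error(predict_probs(m, array(0.5, c(100L, 100L, 3L))),
               "divisible by 32")
  expect_error(predict_probs(m, array(0.5, c(64L, 64L))), "RGB")
})

test_that("weighted cross-entropy matches its closed form", {
  # single pixel, target class 1, p = (0.25, 0.5, 0.25), w = (0.4, 0.9, 0.9)
  probs <- array(c(0.25, 0.5, 0.25), c(1L, 1L, 3L))
  target <- matrix(1L, 1L, 1L)
  expect_equal(wce_loss(probs, target), 0.9 * (-log(0.5)), tolerance = 1e-6)
  # a perfect one-hot prediction has (near-)zero loss
  hot <- array(0, c(2L, 2L, 3L)); hot[, , 1] <- 1
  expect_lt(wce_loss(hot, matrix(0L, 2L, 2L)), 1e-9)
})

test_that("unit weights reduce the loss to plain cross-entropy", {
  set.seed(5)
  for (i in 1:10) {
    z <- array(runif(16 * 16 * 3), c(16L, 16L, 3L))
    s <- z[, , 1] + z[, , 2] + z[, , 3]
    probs <- z / array(rep(s, 3L), dim(z))
    target <- matrix(sample(0:2, 256L, replace = TRUE), 16L, 16L)
    plain <- -mean(log(vapply(seq_len(256L), function(k) {
      probs[((target[k]) * 256L) + k]
    }, 0)))
    expect_equal(wce_loss(probs, target, c(1, 1, 1)), plain,
                 tolerance = 1e-9)
  }
})

test_that("degenerate zero probabilities stay finite via the epsilon clamp", {
  probs <- array(0, c(1L, 1L, 3L)); probs[1, 1, 1] <- 1
  target <- matrix(1L, 1L, 1L)    # target class has probability 0
  v <- wce_loss(probs, target)
  expect_true(is.finite(v))
})

test_that("augmentation with null settings is the identity", {
  p <- generate_patch(small_spec(n_positive = 2L, n_negative = 2L), 3L)
  cfg <- training_config(rotation_max_deg = 0, flip_probability = 0)
  a <- augment(p$image, p$mask, cfg, seed = 1L)
  expect_identical(a$image, p$image)
  expect_identical(a$mask, p$mask)
})

test_that("certain flips are involutions and masks keep legal labels", {
  p <- generate_patch(small_spec(n_positive = 2L, n_negative = 2L), 4L)
  cfg <- training_config(rotation_max_deg = 0, flip_probability = 1)
  once <- augment(p$image, p$mask, cfg, seed = 1L)
  expect_false(identical(once$mask, p$mask))
  twice <- augment(once$image, once$mask, cfg, seed = 2L)
  expect_identical(twice$image, p$image)
  expect_identical(twice$mask, p$mask)

  cfg_rot <- training_config(rotation_max_deg = 30, flip_probability = 0.5)
  for (seed in 1:5) {
    a <- augment(p$image, p$mask, cfg_rot, seed = seed)
    expect_true(all(a$mask %in% c(0L, 1L, 2L)))
    expect_identical(dim(a$image), dim(p$image))
  }
})

test_that("rotation keeps image and mask geometrically aligned", {
  p <- generate_patch(small_spec(n_positive = 2L, n_negative = 2L), 11L)
  cfg <- training_config(rotation_max_deg = 30, flip_probability = 0.5)
  a <- augment(p$image, p$mask, cfg, seed = 9L)
  rb <- a$image[, , 1] - a$image[, , 3]    # brown: R >> B; blue: B >> R
  expect_gt(mean(rb[a$mask == 1L]), 0.1)
  expect_lt(mean(rb[a$mask == 2L]), -0.1)
})

test_that("zero epochs leave the parameters untouched", {
  cfg <- reduced_cfg(epochs = 0L)
  m <- build_model(cfg, "reduced")
  ds <- sample_training_patches(4L, 2L)
  fit <- train(m, ds, cfg)
  expect_identical(fit$model$params, m$params)
  expect_identical(nrow(fit$history), 0L)
  expect_error(train(m, list(), cfg), "empty")
})

test_that("a short seeded run strictly decreases the training loss", {
  cfg <- training_config(learning_rate = 2e-3, epochs = 3L, batch_size = 4L,
                         seed = 7L)
  m <- build_model(cfg, "reduced")
  ds <- sample_training_patches(32L, 7L)
  fit <- train(m, ds, cfg)
  expect_identical(nrow(fit$history), 3L)
  expect_lt(fit$history$train_loss[3], fit$history$train_loss[1])
})

test_that("training is deterministic for a fixed seed", {
  cfg <- reduced_cfg(epochs = 1L)
  ds <- sample_training_patches(8L, 3L)
  f1 <- train(build_model(cfg, "reduced"), ds, cfg)
  f2 <- train(build_model(cfg, "reduced"), ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("mask prediction follows the threshold-and-argmax rule", {
  mk <- function(p) array(rep(p, each = 1), c(1L, 1L, 3L))
  expect_identical(mask_from_probs(mk(c(0.1, 0.7, 0.2)))[1, 1], 1L)
  expect_identical(mask_from_probs(mk(c(0.34, 0.33, 0.33)))[1, 1], 0L)
  # tie between foreground classes breaks toward positive
  expect_identical(mask_from_probs(mk(c(0.0, 0.5, 0.5)))[1, 1], 1L)
  # prediction emits only legal labels at any size
  set.seed(1)
  probs <- array(runif(32 * 32 * 3), c(32L, 32L, 3L))
  s <- probs[, , 1] + probs[, , 2] + probs[, , 3]
  probs <- probs / array(rep(s, 3L), dim(probs))
  expect_true(all(mask_from_probs(probs) %in% c(0L, 1L, 2L)))
})

test_that("checkpoints round-trip the model", {
  cfg <- reduced_cfg()
  m <- build_model(cfg, "reduced")
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_identical(back$variant, "reduced")
  img <- array(runif(64 * 64 * 3), c(64L, 64L, 3L))
  expect_identical(predict_mask(back, img), predict_mask(m, img))
  bogus <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(foo = 1), bogus)
  expect_error(load_checkpoint(bogus), "checkpoint")
})

test_that("the pretrained-encoder hook points at checkpoints", {
  expect_error(build_model(training_config(pretrained_encoder = TRUE)),
               "checkpoint")
})
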