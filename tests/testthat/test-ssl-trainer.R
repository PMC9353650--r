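# Data splitting, augmentation, and the consistency-training loop.

test_that("stratified split reproduces the 7:1:2 and 8:2 arithmetic", {
  labels <- rep(c("benign", "malignant", "normal"), c(437, 210, 133))
  sp <- split_ssl(labels, seed = 3)
  n_train <- length(sp$train_labeled) + length(sp$train_unlabeled)
  expect_equal(n_train, 546)
  expect_equal(length(sp$val), 78)
  expect_equal(length(sp$test), 156)
  # labeled fraction of the training split is 80% within stratification rounding
  expect_lte(abs(length(sp$train_labeled) - 0.8 * 546), length(unique(labels)))
  # disjoint and exhaustive
  all_idx <- c(sp$train_labeled, sp$train_unlabeled, sp$val, sp$test)
  expect_equal(sort(all_idx), seq_along(labels))
  # hidden labels retained for audit
  expect_equal(sp$hidden_labels, labels[sp$train_unlabeled])
})

test_that("split is seed-reproducible and stratified within one sample", {
  labels <- rep(1:3, c(50, 30, 20))
  a <- split_ssl(labels, seed = 11)
  b <- split_ssl(labels, seed = 11)
  expect_identical(a[names(a) != "hidden_labels"], b[names(b) != "hidden_labels"])
  for (part in list(a$test, a$val)) {
    frac <- prop.table(table(factor(labels[part], levels = 1:3)))
    full <- prop.table(table(factor(labels, levels = 1:3)))
    expect_true(all(abs(frac * length(part) - full * length(part)) <= 1))
  }
  expect_error(split_ssl(c(1, 1, 1, 2), seed = 1), "fewer than")
})

test_that("flips are involutions and the identity transform is exact", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(apply_transform(apply_transform(img, "hflip"), "hflip"), img)
  expect_equal(apply_transform(apply_transform(img, "vflip"), "vflip"), img)
  expect_equal(apply_transform(img, "identity"), img)
  aug <- augmentation_set(transforms = "identity", seed = 1)
  z <- apply_augmentation(img, aug)
  expect_equal(z$image, img)
  expect_identical(z$index, 1L)
  expect_error(augmentation_set(transforms = character(0)), "must not be empty")
  expect_error(augmentation_set(transforms = "warp"), "unknown transform")
})

test_that("augmentation draws are seeded and shape-preserving", {
  img <- array(runif(32 * 32), c(32, 32, 1))
  a1 <- augmentation_set(seed = 5)
  a2 <- augmentation_set(seed = 5)
  for (i in 1:8) {
    z1 <- apply_augmentation(img, a1)
    z2 <- apply_augmentation(img, a2)
    expect_identical(z1$transform, z2$transform)
    expect_equal(z1$image, z2$image)
    expect_equal(dim(z1$image), dim(img))
    expect_true(all(z1$image >= 0 & z1$image <= 1))
  }
})

test_that("a supervised smoke run logs the expected step count and additivity", {
  m <- tiny_model(seed = 2)
  x <- tiny_images(8, seed = 3)
  y <- rep(1:2, 4)
  expect_warning(
    fit <- train_atsvit(m, x, y,
                        config = train_config(learning_rate = 1e-3,
                                              batch_size = 4, epochs = 1,
                                              seed = 1)),
    "supervised-only")
  expect_equal(nrow(fit$step_log), 2)  # 8 images / batch 4
  expect_equal(fit$step_log$L,
               with(fit$step_log, L_CE + L_MSE + L_EM), tolerance = 1e-6)
  expect_equal(fit$step_log$L_MSE, rep(0, 2))
})

test_that("consistency losses are live and the objective stays additive", {
  m <- tiny_model(seed = 4)
  x <- tiny_images(6, seed = 5)
  y <- rep(1:2, 3)
  xu <- tiny_images(4, seed = 6)
  fit <- train_atsvit(m, x, y, x_u = xu,
                      config = train_config(learning_rate = 1e-3,
                                            batch_size = 3, epochs = 2,
                                            seed = 1))
  expect_equal(nrow(fit$step_log), 4)
  expect_equal(fit$step_log$L,
               with(fit$step_log, L_CE + L_MSE + L_EM), tolerance = 1e-6)
  expect_true(all(fit$step_log$L_MSE >= 0))
  expect_true(all(is.finite(fit$step_log$L)))
})

test_that("identity augmentation makes the pseudo-label loss vanish", {
  m <- tiny_model(seed = 7)
  x <- tiny_images(4, seed = 8)
  y <- rep(1:2, 2)
  xu <- tiny_images(4, seed = 9)
  fit <- train_atsvit(m, x, y, x_u = xu,
                      config = train_config(
                        learning_rate = 1e-4, batch_size = 4, epochs = 1,
                        seed = 1,
                        augmentations = augmentation_set(transforms = "identity",
                                                         seed = 2)))
  expect_equal(fit$step_log$L_MSE, 0, tolerance = 1e-12)
  expect_equal(fit$step_log$L_EM, 0, tolerance = 1e-12)
})

test_that("pseudo-label loss shrinks as augmentation strength shrinks", {
  # smooth regime: sampling off (fixed token set) and intensities kept inside
  # [0.3, 0.7] so the contrast family stays linear (no clipping)
  m <- vit_init(vit_config(image_size = 16, channels = 1, patch = 4, dim = 16,
                           depth = 2, heads = 2, mlp_ratio = 2, n_classes = 2,
                           seed = 10))
  rng <- make_rng(11)
  imgs <- rng_eval(rng, replicate(6, array(0.3 + 0.4 * runif(256), c(16, 16, 1)),
                                  simplify = FALSE))
  strengths <- c(0.4, 0.3, 0.2, 0.1, 0)
  losses <- vapply(strengths, function(s) {
    clean <- vit_forward(m, imgs, mode = "off")
    zu <- lapply(imgs, function(im) 0.5 + (im - 0.5) * (1 + s))
    aug <- vit_forward(m, zu, mode = "off")
    as.numeric(pseudo_label_mse(clean$probs, aug$probs))
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-15))
  expect_equal(losses[length(losses)], 0, tolerance = 1e-15)
})

test_that("consistency branch updates the shared parameter set", {
  x <- tiny_images(4, seed = 13)
  y <- rep(1:2, 2)
  xu <- tiny_images(4, seed = 14)
  cfgt <- function() train_config(learning_rate = 1e-3, batch_size = 4,
                                  epochs = 1, seed = 21)
  sup <- suppressWarnings(train_atsvit(tiny_model(seed = 12), x, y,
                                       config = cfgt()))
  ssl <- train_atsvit(tiny_model(seed = 12), x, y, x_u = xu, config = cfgt())
  # same init, same labeled data: any difference comes from the consistency
  # gradients acting on the single shared parameter set
  expect_false(isTRUE(all.equal(atsvit:::flatten_params(sup$model$params),
                                atsvit:::flatten_params(ssl$model$params))))
})

test_that("training is reproducible given the seed", {
  x <- tiny_images(4, seed = 15)
  y <- rep(1:2, 2)
  xu <- tiny_images(2, seed = 16)
  run <- function() {
    train_atsvit(tiny_model(seed = 17), x, y, x_u = xu,
                 config = train_config(learning_rate = 1e-3, batch_size = 2,
                                       epochs = 2, seed = 33))
  }
  f1 <- run(); f2 <- run()
  expect_equal(f1$step_log, f2$step_log, tolerance = 1e-12)
  expect_equal(atsvit:::flatten_params(f1$model$params),
               atsvit:::flatten_params(f2$model$params), tolerance = 1e-12)
})

test_that("validation tracking selects the best checkpoint by F1", {
  m <- tiny_model(seed = 18)
  x <- tiny_images(6, seed = 19)
  y <- rep(1:2, 3)
  fit <- suppressWarnings(
    train_atsvit(m, x, y,
                 val = list(images = x[1:4], labels = y[1:4]),
                 config = train_config(learning_rate = 1e-3, batch_size = 3,
                                       epochs = 2, seed = 1)))
  expect_false(is.null(fit$best_model))
  expect_true(fit$best_epoch %in% 1:2)
  expect_equal(fit$best_f1, max(fit$log$val_F1))
})

test_that("the default configuration mirrors the reference training setting", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 2e-5)
  expect_equal(cfg$eps, 1e-8)
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$epochs, 300L)
})
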