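# Training protocol: mining, null updates, determinism, learnability,
# multi-bag inference and patient-grouped splits.

test_that("hard-negative selection keeps the top-loss bags", {
  expect_equal(sort(hard_negative_step(c(0.9, 0.1, 0.5, 0.2), 1)), 1:4)
  expect_equal(sort(hard_negative_step(c(0.9, 0.1, 0.5, 0.2), 0.5)),
               c(1L, 3L))
  expect_equal(hard_negative_step(c(0.3), 0.1), 1L)
  expect_error(hard_negative_step(c(0.3), 1.5), "retention fraction")
  expect_error(hard_negative_step(numeric(0), 0.5), "no bags")
})

test_that("a zero learning rate leaves parameters untouched", {
  fx <- small_cohort(n_slides = 6, grid = 4, tile_size = 32)
  m <- mil_model(backbone = backbone_config(32), seed = 1)
  cfg <- desk_config(learning_rate = 0, epochs = 1, bag_size = 8, seed = 2)
  fit <- train_mil(m, fx$store, cfg)
  m0 <- fit_feature_scaling(m, do.call(rbind, lapply(fx$store, `[[`, "X")))
  for (nm in names(m$params)) {
    expect_identical(fit$model$params[[nm]], m0$params[[nm]])
  }
})

test_that("training is deterministic given config and seed", {
  fx <- small_cohort(n_slides = 6, grid = 4, tile_size = 32)
  cfg <- desk_config(epochs = 3, bag_size = 8, seed = 5)
  f1 <- train_mil(mil_model(backbone = backbone_config(32), seed = 1),
                  fx$store, cfg)
  f2 <- train_mil(mil_model(backbone = backbone_config(32), seed = 1),
                  fx$store, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the constructed signal is learnable (loss decreases)", {
  fx <- small_cohort(n_slides = 16, witness_rate = 0.3, grid = 4,
                     tile_size = 32, seed = 7)
  cfg <- desk_config(epochs = 12, bag_size = 8, seed = 3)
  fit <- train_mil(mil_model(backbone = backbone_config(32), seed = 3),
                   fx$store, cfg)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_equal(nrow(fit$history), 12)         # history recorded every epoch
})

test_that("single-class cohorts are rejected", {
  fx <- small_cohort(n_slides = 6, grid = 4, tile_size = 32)
  neg_ids <- fx$cohort$labels$slide_id[fx$cohort$labels$label == 0]
  expect_error(
    train_mil(mil_model(backbone = backbone_config(32)), fx$store,
              desk_config(epochs = 1, bag_size = 8),
              train_ids = neg_ids),
    "both classes")
})

test_that("the augmentation training path runs end to end", {
  fx <- small_cohort(n_slides = 6, grid = 4, tile_size = 32)
  mp <- dataset_mean_pixel(fx$cohort, fx$tilesets)
  cfg <- desk_config(
    epochs = 2, bag_size = 6, seed = 4, augment = TRUE,
    aug = augment_config(cutout_length = 12, mean_pixel_prob = 0.5,
                         mean_pixel = mp))
  expect_error(
    train_mil(mil_model(backbone = backbone_config(32)), fx$store, cfg),
    "slide images")
  fit <- train_mil(mil_model(backbone = backbone_config(32), seed = 2),
                   fx$store, cfg, slides = fx$cohort$slides)
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("slide prediction aggregates bag probabilities", {
  fx <- small_cohort(n_slides = 6, grid = 4, tile_size = 32)
  m <- mil_model(backbone = backbone_config(32), seed = 1)
  m <- fit_feature_scaling(m, do.call(rbind, lapply(fx$store, `[[`, "X")))
  entry <- fx$store[[1]]
  sp <- predict_slide(m, entry, n_bags = 8, bag_size = 6, seed = 11)
  expect_equal(sp$p_slide, mean(sp$bag_probs))
  expect_length(sp$bag_probs, 8)
  sp_med <- predict_slide(m, entry, n_bags = 8, bag_size = 6,
                          agg_rule = "median", seed = 11)
  expect_equal(sp_med$p_slide, median(sp_med$bag_probs))
  expect_identical(sp$bag_probs,
                   predict_slide(m, entry, n_bags = 8, bag_size = 6,
                                 seed = 11)$bag_probs)
})

test_that("more bags reduce the variance of the slide probability", {
  fx <- small_cohort(n_slides = 6, grid = 8, tile_size = 32)
  m <- mil_model(backbone = backbone_config(32), seed = 6)
  m <- fit_feature_scaling(m, do.call(rbind, lapply(fx$store, `[[`, "X")))
  entry <- fx$store[[1]]
  p8 <- sapply(1:20, function(s) predict_slide(m, entry, 8, 10,
                                               seed = s)$p_slide)
  p32 <- sapply(1:20, function(s) predict_slide(m, entry, 32, 10,
                                                seed = 100 + s)$p_slide)
  expect_lt(var(p32), var(p8))
})

test_that("splits group patients and stratify labels", {
  labels <- data.frame(slide_id = paste0("s", 1:100),
                       patient_id = paste0("p", 1:100),
                       label = rep(c(0, 1), 50))
  plan <- make_splits(labels, k = 5, seed = 3)
  expect_equal(as.integer(table(plan$assignment)), rep(20L, 5))
  per_fold <- tapply(plan$slides$label, plan$slides$fold, mean)
  expect_true(all(abs(per_fold - 0.5) < 0.11))

  # multi-slide patient stays in one fold
  labels2 <- data.frame(slide_id = paste0("s", 1:10),
                        patient_id = paste0("p", c(1, 1, 2:9)),
                        label = rep(c(0, 1), 5))
  plan2 <- make_splits(labels2, k = 3, seed = 1)
  folds_p1 <- plan2$slides$fold[plan2$slides$patient_id == "p1"]
  expect_equal(length(unique(folds_p1)), 1L)

  expect_identical(make_splits(labels, k = 5, seed = 9)$assignment,
                   make_splits(labels, k = 5, seed = 9)$assignment)
  expect_error(make_splits(labels2, k = 20), "fewer patients")

  plan3 <- make_splits(labels, k = 4, holdout_fraction = 0.2, seed = 2)
  expect_equal(length(plan3$test_holdout), 20)
  expect_true(all(plan3$assignment[plan3$test_holdout] == 0L))
})

test_that("checkpoints round-trip the trained model", {
  fx <- small_cohort(n_slides = 6, grid = 4, tile_size = 32)
  cfg <- desk_config(epochs = 1, bag_size = 6, seed = 8)
  fit <- train_mil(mil_model(backbone = backbone_config(32), seed = 1),
                   fx$store, cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, fit$model$params)
  entry <- fx$store[[1]]
  expect_identical(predict_slide(fit$model, entry, 4, 6, seed = 1)$p_slide,
                   predict_slide(m2, entry, 4, 6, seed = 1)$p_slide)
})
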