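test_that("backbones expose the documented feature contracts", {
  bb <- build_backbone("resnet_small", seed = 1)
  img <- rand_img(64, 64, seed = 2)
  f <- extract_features(bb, img)
  expect_length(f, 128)
  expect_true(all(is.finite(f)))
  expect_identical(f, extract_features(bb, img))
  dark <- array(0, dim = c(64, 64, 3))
  light <- array(255, dim = c(64, 64, 3))
  expect_false(isTRUE(all.equal(extract_features(bb, dark),
                                extract_features(bb, light))))
  expect_error(extract_features(bb, rand_img(16, 16)),
               class = "surgiview_input_error")
  expect_error(build_backbone("resnet_small", pretrained = TRUE),
               class = "surgiview_config_error")
})

test_that("the full ResNet-50 build yields the canonical 2048-dim pooled feature", {
  bb <- build_backbone("resnet50", seed = 1)
  expect_equal(bb$feature_dim, 2048L)
  # 16 bottleneck blocks plus stem/pool/gap
  expect_equal(sum(vapply(bb$layers, function(l) l$type == "resblock",
                          TRUE)), 16)
  f <- extract_features(bb, rand_img(64, 64, seed = 3))
  expect_length(f, 2048)
  expect_true(all(is.finite(f)))
  # parameter count of the bias-carrying 50-layer plan
  expect_gt(surgiview:::n_params(surgiview:::layers_params(bb$layers)),
            2.3e7)
})

test_that("feature fusion is ordered concatenation", {
  expect_equal(fuse(c(1, 2, 3), c(4, 5, 6)), 1:6)
  expect_length(fuse(rnorm(5), rnorm(5)), 10)
  a <- c(1, 2); b <- c(3, 4)
  expect_false(identical(fuse(a, b), fuse(b, a)))
  expect_error(fuse(1:3, 1:4), class = "surgiview_input_error")
})

test_that("prediction clips at the application boundary but keeps the raw head output", {
  cfg <- regressor_config(backbone = "resnet_small", seed = 1)
  model <- surgiview:::build_regressor(cfg)
  model$head$b <- c(-0.1, 1.2, rep(0.5, 6))   # force out-of-range outputs
  img <- rand_img(64, 64, seed = 4)
  expect_warning(p <- predict_params(model, img, img), "untrained")
  expect_length(p$normalized, 8)
  expect_equal(names(p$normalized), param_names())
  expect_equal(p$normalized[[1]], 0)
  expect_equal(p$normalized[[2]], 1)
  expect_lt(p$raw_output[[1]], 0)
  expect_gt(p$raw_output[[2]], 1)
})

make_toy_regression_data <- function(n = 24, size = 64, seed = 6) {
  cfg <- scene_config(image_size = size, seed = seed)
  ds <- make_dataset(n, n / 2, cfg)
  lapply(ds$samples, function(s)
    list(raw = s$roi$roi_image, fake = s$reference_image,
         target = normalize_params(s$params)))
}

test_that("cross-validated head training learns and logs every fold", {
  data <- make_toy_regression_data()
  folds <- rep(1:2, length.out = length(data))
  cfg <- regressor_config(backbone = "resnet_small", epochs = 40,
                          batch_size = 8, lr = 5e-3,
                          freeze_backbones = TRUE, seed = 2)
  fit <- train_regressor(data, folds, cfg)
  expect_equal(sort(names(fit$models)), c("1", "2"))
  expect_equal(nrow(fit$history), 80)
  h1 <- fit$history[fit$history$fold == 1, ]
  expect_lt(h1$train_loss[40], h1$train_loss[1])
  p1 <- fit$predictions[["1"]]
  expect_equal(dim(p1$normalized), c(sum(folds == 1), 8))
  expect_true(all(p1$normalized >= 0 & p1$normalized <= 1))
  # single-fold subset and empty-fold error
  fit1 <- train_regressor(data, folds, cfg, fold_subset = 1)
  expect_equal(names(fit1$models), "1")
  expect_error(train_regressor(data, rep(1, length(data)), cfg),
               class = "surgiview_config_error")
  bad <- data
  bad[[1]]$target[1] <- 1.5
  expect_error(train_regressor(bad, folds, cfg),
               class = "surgiview_input_error")
})

test_that("joint fine-tuning trains end to end and keeps a usable model", {
  data <- make_toy_regression_data(n = 12, seed = 8)
  folds <- rep(1:2, length.out = 12)
  cfg <- regressor_config(backbone = "resnet_small", epochs = 3,
                          batch_size = 4, lr = 3e-4,
                          freeze_backbones = FALSE, seed = 3)
  fit <- train_regressor(data, folds, cfg, fold_subset = 1)
  h <- fit$history
  expect_equal(nrow(h), 3)
  expect_true(all(is.finite(h$train_loss)) && all(is.finite(h$val_loss)))
  m <- fit$models[["1"]]
  p <- predict_params(m, data[[1]]$raw, data[[1]]$fake)
  expect_length(p$normalized, 8)
  expect_true(all(is.finite(p$raw_output)))
  # the kept model is never worse than the epoch-logged validation curve
  # (best-epoch selection includes the ridge warm start)
  Y <- t(vapply(data[fit$predictions[["1"]]$index], `[[`, numeric(8),
                "target"))
  kept <- mean((fit$predictions[["1"]]$raw_output - Y)^2)
  expect_lte(kept, min(h$val_loss) + 1e-9)
})
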