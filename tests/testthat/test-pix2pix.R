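test_that("the 512 generator plan reproduces the published table row-for-row", {
  sp <- generator_spec(512)
  expect_equal(nrow(sp), 22)
  expect_equal(sp$index, 0:21)
  # the six load-bearing counts, including the skip-concatenation rows
  expect_equal(sp$params[sp$index == 1], 3136)
  expect_equal(sp$params[sp$index == 2], 131200)
  expect_equal(sp$params[sp$index == 4], 2097664)
  expect_equal(sp$params[sp$index == 11], 8389120)
  expect_equal(sp$params[sp$index == 15], 4194560)
  expect_equal(sp$params[sp$index == 21], 6147)
  # encoder halves spatial dims; decoder doubles them
  enc <- sp[sp$kind == "conv_down", ]
  expect_equal(enc$h, 512 / 2^(1:7))
  dec <- sp[sp$kind == "conv_up", ]
  expect_equal(dec$h, 4 * 2^(1:7))
  expect_equal(dec$activation, c(rep("ReLU", 6), "Tanh"))
  expect_equal(dec$channels[7], 3)
  # skip concatenation shows as doubled input channels at indices 11..21
  expect_equal(sp$cin[sp$index %in% c(11, 13, 15)], rep(1024, 3))
  expect_equal(sp$cin[sp$index == 9], 512)   # innermost: no concatenation
})

test_that("built generators audit their own realized parameter counts", {
  gen <- build_generator(64, seed = 2)
  counts <- generator_param_counts(gen)
  expect_equal(counts$params, generator_spec(64)$params)
  # a tampered expectation is rejected with the offending layer named
  bad <- generator_spec(64)
  bad$params[bad$index == 3] <- bad$params[bad$index == 3] + 1
  expect_error(build_generator(64, seed = 2, spec = bad),
               "layer index 3", class = "surgiview_architecture_error")
  expect_error(generator_spec(100), class = "surgiview_config_error")
})

test_that("generator forward produces Tanh-range images of the input size", {
  gen <- build_generator(32, seed = 5)
  x <- array(runif(32 * 32 * 3, -1, 1), dim = c(32, 32, 3))
  out <- surgiview:::generator_forward(gen, x)
  expect_equal(dim(out), c(32, 32, 3))
  expect_true(all(out >= -1 & out <= 1))
  img <- rand_img(32, 32, seed = 1)
  fake <- generate_fake(gen, img)
  expect_equal(dim(fake), dim(img))
  expect_true(all(fake >= 0 & fake <= 255))
  expect_error(generate_fake(gen, rand_img(16, 16)),
               class = "surgiview_input_error")
})

test_that("the patch discriminator emits the hand-traced logit grid", {
  d <- build_discriminator(64, seed = 3)
  x <- array(runif(64 * 64 * 6, -1, 1), dim = c(64, 64, 6))
  out <- surgiview:::disc_forward(d, x)
  # 64 ->(s2) 32 ->(s2) 16 ->(s2) 8 ->(s1,k4,p1) 7 ->(s1,k4,p1) 6
  expect_equal(dim(out), c(6, 6, 1))
  d2 <- build_discriminator(64, seed = 3)
  expect_identical(d$layers[[1]]$W, d2$layers[[1]]$W)
  expect_error(build_discriminator(72), class = "surgiview_config_error")
})

test_that("adversarial training reduces the reconstruction loss deterministically", {
  cfg <- scene_config(image_size = 32, seed = 4, ui_text = FALSE)
  ds <- make_dataset(6, 3, cfg)
  pairs <- lapply(ds$samples, function(s)
    list(input = s$roi$roi_image, target = s$reference_image))
  fit <- train_pix2pix(pairs, p2p_config(epochs = 3, batch_size = 3,
                                         seed = 11))
  expect_equal(nrow(fit$history), 3)
  expect_lt(fit$history$l1_loss[3], fit$history$l1_loss[1])
  # bitwise deterministic repeat
  fit2 <- train_pix2pix(pairs, p2p_config(epochs = 3, batch_size = 3,
                                          seed = 11))
  expect_identical(fit$history, fit2$history)
  # zero epochs returns the untrained network unchanged
  fit0 <- train_pix2pix(pairs, p2p_config(epochs = 0, seed = 11))
  ref <- build_generator(32, seed = 12)   # config seed + 1
  expect_identical(fit0$generator$enc[[1]]$W, ref$enc[[1]]$W)
  expect_equal(nrow(fit0$history), 0)
  expect_error(train_pix2pix(list(list(input = rand_img(32, 32),
                                       target = rand_img(16, 16)))),
               class = "surgiview_input_error")
})
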