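test_that("scene generation is deterministic and validates its config", {
  cfg <- scene_config(image_size = 64, seed = 7)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$pupil_mask, s2$pupil_mask)
  s3 <- generate_scene(scene_config(image_size = 64, seed = 8))
  expect_false(identical(s1$image, s3$image))
  expect_error(scene_config(image_size = 8), class = "surgiview_config_error")
  expect_error(scene_config(pupil_radius_frac = 0.5),
               class = "surgiview_config_error")
  expect_error(scene_config(distractor_count = -1),
               class = "surgiview_config_error")
})

test_that("the illuminated pupil always outshines the background", {
  for (seed in 1:6) {
    sc <- generate_scene(scene_config(image_size = 64, seed = seed,
                                      noise_sigma = 2))
    g <- to_grayscale(sc$image)
    expect_gt(mean(g[sc$pupil_mask]), mean(g[!sc$pupil_mask]))
  }
})

test_that("distractors form separate bright components that small-object removal kills", {
  cfg <- scene_config(image_size = 128, seed = 3, distractor_count = 3,
                      ui_text = FALSE, noise_sigma = 0)
  sc <- generate_scene(cfg)
  g <- to_grayscale(sc$image)
  mask <- binarize(g, compute_threshold(g))
  lab <- naive_label(mask)
  expect_equal(max(lab), 4L)   # pupil + 3 distractors
  areas <- tabulate(lab[lab > 0])
  min_size <- max(areas[areas < max(areas)]) + 1
  cleaned <- remove_small_objects(mask, min_size)
  expect_equal(max(naive_label(cleaned)), 1L)
})

test_that("uniform parameter sampling respects the native ranges", {
  p1 <- sample_parameters(5)
  p2 <- sample_parameters(5)
  expect_identical(p1$values, p2$values)
  r <- default_param_ranges()
  draws <- vapply(1:2000, function(s) sample_parameters(s)$values,
                  numeric(8))
  expect_true(all(draws >= r$min & draws <= r$max))
  bad <- r; bad$min[3] <- bad$max[3]
  expect_error(sample_parameters(1, bad), class = "surgiview_config_error")
})

test_that("datasets satisfy the ground-truth closure and even patient split", {
  cfg <- scene_config(image_size = 64, seed = 9)
  ds <- make_dataset(10, 5, cfg)
  ids <- vapply(ds$samples, `[[`, 0L, "patient_id")
  expect_equal(as.vector(table(ids)), rep(2L, 5))
  for (s in ds$samples[c(1, 4, 9)]) {
    rerender <- render_params(s$roi$roi_image, s$params)
    expect_identical(s$reference_image, rerender)
    expect_equal(ssim(s$reference_image, rerender), 1)
  }
  # byte-stable across runs
  ds2 <- make_dataset(10, 5, cfg)
  expect_identical(ds, ds2)
  expect_error(make_dataset(3, 5, cfg), class = "surgiview_config_error")
})

test_that("scene-linked mode couples parameters to scene appearance", {
  cfg <- scene_config(image_size = 64, seed = 20)
  ds <- make_dataset(40, 20, cfg, param_mode = "scene_linked")
  bright_scene <- vapply(ds$samples, function(s)
    img_brightness(s$raw_image), 0)
  bright_param <- vapply(ds$samples, function(s)
    s$params$values[["brightness"]], 0)
  # dim scenes get compensating positive brightness: strong negative
  # correlation is the designed behaviour
  expect_lt(cor(bright_scene, bright_param), -0.5)
})

test_that("datasets round-trip to disk as pixmaps and CSV", {
  dir <- withr::local_tempdir()
  cfg <- scene_config(image_size = 32, seed = 2, ui_text = FALSE)
  ds <- make_dataset(4, 2, cfg)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "params.csv")))
  nat <- read.csv(file.path(dir, "params.csv"))
  expect_equal(names(nat), c("sample_id", "patient_id", param_names()))
  nrm <- read.csv(file.path(dir, "params_norm.csv"))
  expect_true(all(nrm[param_names()] >= 0 & nrm[param_names()] <= 1))
  back <- read_ppm(file.path(dir, "raw_001.ppm"))
  expect_equal(back, ds$samples[[1]]$raw_image * 1.0)
})
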