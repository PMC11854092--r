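test_that("grayscale conversion uses the BT.601 luminance weights", {
  white <- array(255, dim = c(3, 3, 3))
  expect_equal(to_grayscale(white), matrix(255, 3, 3))
  red <- array(0, dim = c(3, 3, 3)); red[, , 1] <- 255
  expect_equal(to_grayscale(red), matrix(0.299 * 255, 3, 3))
  v <- matrix(runif(9, 0, 255), 3)
  ach <- array(c(v, v, v), dim = c(3, 3, 3))
  expect_equal(to_grayscale(ach), v)
  expect_error(to_grayscale(matrix(1, 3, 3)),
               class = "surgiview_input_error")
})

test_that("histogram threshold equals the exhaustive between-class-variance maximizer", {
  half <- matrix(c(rep(0, 32), rep(255, 32)), 8)
  t0 <- compute_threshold(half)
  expect_gt(t0, 0); expect_lt(t0, 255)
  withr::with_seed(31, {
    for (r in 1:4) {
      g <- matrix(pmin(pmax(round(c(rnorm(600, 40, 12),
                                    rnorm(600, 200, 20))), 0), 255), 40)
      expect_identical(as.integer(compute_threshold(g)),
                       as.integer(naive_otsu(g)))
    }
  })
  expect_error(compute_threshold(matrix(7, 4, 4)),
               class = "surgiview_degenerate_histogram")
})

test_that("binarization is a strict greater-than threshold", {
  g <- matrix(c(0, 255), 4, 4)
  expect_false(any(binarize(g, 255)))
  expect_true(all(binarize(g + 1, 0)))
  chk <- matrix(rep(c(0, 255), length.out = 25), 5)
  expect_identical(binarize(chk, 128), chk == 255)
})

test_that("small-object removal follows component areas under 8-connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2] <- TRUE                      # area 3
  expect_false(any(remove_small_objects(m, 4)))
  big <- matrix(FALSE, 40, 40)
  big[2:21, 2:26] <- TRUE                # area 500
  big[30:34, 30:31] <- TRUE              # area 10
  out <- remove_small_objects(big, 50)
  lab <- naive_label(out)
  expect_equal(max(lab), 1L)
  expect_equal(sum(out), 500)
  expect_identical(remove_small_objects(big, 1), big)
})

test_that("largest-component bounding boxes are tight, 0-based, half-open", {
  m <- matrix(FALSE, 20, 20)
  m[1:10, 1:10] <- TRUE
  expect_equal(largest_component_bbox(m),
               c(left = 0, top = 0, right = 10, bottom = 10))
  m[15:17, 15:18] <- TRUE          # second blob, area 12 < 100
  expect_equal(unname(largest_component_bbox(m)), c(0, 0, 10, 10))
  # tie in area: smallest (top, left) anchor wins
  tie <- matrix(FALSE, 10, 10)
  tie[7:8, 7:8] <- TRUE
  tie[2:3, 2:3] <- TRUE
  expect_equal(largest_component_bbox(tie),
               c(left = 1, top = 1, right = 3, bottom = 3))
  expect_error(largest_component_bbox(matrix(FALSE, 4, 4)),
               class = "surgiview_no_roi")
})

test_that("component labelling matches a naive flood-fill oracle on random masks", {
  withr::with_seed(77, {
    for (r in 1:40) {
      m <- matrix(runif(64) < 0.4, 8)
      lab_pkg <- surgiview:::label_components(m)
      lab_ora <- naive_label(m)
      expect_equal(max(lab_pkg), max(lab_ora))
      if (max(lab_ora) > 0) {
        a1 <- sort(tabulate(lab_pkg[lab_pkg > 0]))
        a2 <- sort(tabulate(lab_ora[lab_ora > 0]))
        expect_equal(a1, a2)
        # same largest-component pixel set (unique maximum only)
        if (sum(a2 == max(a2)) == 1) {
          big1 <- lab_pkg == which.max(tabulate(lab_pkg[lab_pkg > 0]))
          big2 <- lab_ora == which.max(tabulate(lab_ora[lab_ora > 0]))
          expect_identical(big1, big2)
        }
      }
    }
  })
})

test_that("the full ROI protocol recovers the illuminated field", {
  cfg <- scene_config(image_size = 96, seed = 12, distractor_count = 2,
                      noise_sigma = 1)
  sc <- generate_scene(cfg)
  r <- extract_roi(sc$image, out_size = 64)
  expect_equal(dim(r$roi_image), c(64, 64, 3))
  expect_true(all(r$roi_image >= 0 & r$roi_image <= 255))
  expect_s3_class(r, "roi_result")
  # bbox covers at least 95% of the true pupil pixels
  m <- sc$pupil_mask
  cov <- sum(m[(r$bbox[["top"]] + 1):r$bbox[["bottom"]],
               (r$bbox[["left"]] + 1):r$bbox[["right"]]]) / sum(m)
  expect_gte(cov, 0.95)
  # default output size honours the published protocol
  r512 <- extract_roi(sc$image)
  expect_equal(dim(r512$roi_image), c(512, 512, 3))
  # a bright square on black is recovered exactly
  sq <- array(0, dim = c(32, 32, 3))
  sq[9:24, 9:24, ] <- 200
  rs <- extract_roi(sq, min_size = 4, out_size = 16)
  expect_equal(unname(rs$bbox), c(8, 8, 24, 24))
  expect_equal(rs$roi_image, array(200, dim = c(16, 16, 3)))
})

test_that("ROI extraction is idempotent and scale-covariant", {
  # re-extracting from an ROI that the illuminated field fills returns
  # (almost) the whole frame: the ellipse touches all four bbox edges
  sc <- generate_scene(scene_config(image_size = 96, seed = 3,
                                    noise_sigma = 0, ui_text = FALSE,
                                    distractor_count = 0))
  r <- extract_roi(sc$image, out_size = 48)
  r2 <- extract_roi(r$roi_image, out_size = 48)
  expect_true(all(abs(unname(r2$bbox) - c(0, 0, 48, 48)) <= 4))
  # doubling the frame scales the bbox proportionally (within 1 pixel)
  cfg1 <- scene_config(image_size = 64, seed = 5, noise_sigma = 0,
                       distractor_count = 0, ui_text = FALSE)
  cfg2 <- scene_config(image_size = 128, seed = 5, noise_sigma = 0,
                       distractor_count = 0, ui_text = FALSE)
  b1 <- extract_roi(generate_scene(cfg1)$image, out_size = 32)$bbox
  b2 <- extract_roi(generate_scene(cfg2)$image, out_size = 32)$bbox
  expect_true(all(abs(2 * b1 - b2) <= 2))
})
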