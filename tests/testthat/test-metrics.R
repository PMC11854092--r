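test_that("identity pairs hit the metric fixed points", {
  img <- rand_img(8, 8, seed = 3)
  expect_equal(nrmse(img, img), 0)
  expect_equal(ssim(img, img, window = 8, gaussian = FALSE), 1)
  expect_identical(psnr(img, img), Inf)
})

test_that("NRMSE follows the printed formula with the sum denominator", {
  I <- array(255, dim = c(4, 4, 3)); P <- array(0, dim = c(4, 4, 3))
  expect_equal(nrmse(I, P), 255 / (255 + 255))
  # the conventional range denominator stays available
  I2 <- I; I2[1, 1, ] <- 0
  expect_equal(nrmse(I2, P, denominator = "range"),
               sqrt(mean((lum(I2) - lum(P))^2)) / 255)
  expect_error(nrmse(array(0, dim = c(4, 4, 3)), P),
               class = "surgiview_degenerate_metric")
})

test_that("all metrics agree with brute-force formula evaluation on 8x8 fixtures", {
  figs <- fixture_images(6)
  w_g <- naive_gauss_win(5, 1.5)
  for (i in seq_along(figs)) {
    for (j in seq_along(figs)) {
      if (i == j) next
      I <- figs[[i]]; P <- figs[[j]]
      expect_equal(nrmse(I, P), naive_nrmse(I, P), tolerance = 1e-9)
      expect_equal(psnr(I, P), naive_psnr(I, P), tolerance = 1e-9)
      expect_equal(ssim(I, P, window = 5, sigma = 1.5),
                   naive_ssim(I, P, w_g), tolerance = 1e-9)
      expect_equal(ssim(I, P, window = 8, gaussian = FALSE),
                   naive_ssim(I, P, matrix(1 / 64, 8, 8)),
                   tolerance = 1e-9)
    }
  }
})

test_that("PSNR pins 0 dB at MSE equal to the squared peak", {
  I <- array(255, dim = c(2, 2, 3))
  P <- array(0, dim = c(2, 2, 3))
  expect_equal(psnr(I, P), 0)
})

test_that("SSIM is symmetric and a constant offset only degrades luminance", {
  a <- rand_img(12, 12, seed = 5)
  b <- rand_img(12, 12, seed = 6)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  base <- array(100, dim = c(8, 8, 3))
  off <- array(180, dim = c(8, 8, 3))
  s <- ssim(base, off, window = 8, gaussian = FALSE)
  C1 <- (0.01 * 255)^2
  L <- (2 * 100 * 180 + C1) / (100^2 + 180^2 + C1)
  expect_equal(s, L, tolerance = 1e-9)   # C and S terms are constant-stable
  expect_lt(s, 1)
})

test_that("error metrics are monotone in additive noise", {
  withr::with_seed(8, {
    I <- rand_img(16, 16, seed = 8)
    noise <- array(rnorm(prod(dim(I))), dim = dim(I))
    eps <- c(5, 20, 60)
    n_vals <- s_vals <- p_vals <- numeric(3)
    for (k in 1:3) {
      P <- as_uint8(I + eps[k] * noise)
      n_vals[k] <- nrmse(I, P)
      s_vals[k] <- ssim(I, P)
      p_vals[k] <- psnr(I, P)
    }
    expect_true(all(diff(n_vals) > 0))
    expect_true(all(diff(s_vals) < 0))
    expect_true(all(diff(p_vals) < 0))
  })
})

test_that("visualization measures match hand enumeration", {
  expect_equal(img_brightness(array(0, dim = c(3, 3, 3))), 0)
  expect_equal(img_brightness(array(255, dim = c(3, 3, 3))), 255)
  half <- matrix(c(rep(0, 8), rep(255, 8)), 4)
  expect_equal(img_brightness(half), 127.5)
  # contrast: mean absolute difference over adjacent pairs
  expect_equal(img_contrast(matrix(7, 4, 4)), 0)
  expect_equal(img_contrast(matrix(c(0, 255), 1, 2)), 255)
  g <- matrix(c(10, 50, 20, 80, 40, 90, 30, 60, 70), 3, byrow = TRUE)
  pairs <- c(abs(g[, 1] - g[, 2]), abs(g[, 2] - g[, 3]),
             abs(g[1, ] - g[2, ]), abs(g[2, ] - g[3, ]))
  expect_equal(img_contrast(g), mean(pairs))
  expect_error(img_contrast(matrix(1, 1, 1)),
               class = "surgiview_input_error")
  # sharpness: population variance of the interior Laplacian
  expect_equal(img_sharpness(matrix(5, 5, 5)), 0)
  ramp <- matrix(rep(seq(0, 80, 20), each = 5), 5)
  expect_equal(img_sharpness(ramp), 0)
  z <- matrix(0, 5, 5); z[3, 3] <- 90
  lap <- matrix(0, 3, 3)
  for (i in 2:4) for (j in 2:4)
    lap[i - 1, j - 1] <- z[i - 1, j] + z[i + 1, j] + z[i, j - 1] +
      z[i, j + 1] - 4 * z[i, j]
  expect_equal(img_sharpness(z), mean((lap - mean(lap))^2))
  expect_error(img_sharpness(matrix(1, 2, 5)),
               class = "surgiview_input_error")
})

test_that("paired comparison reproduces the textbook paired t-test", {
  a <- c(12.1, 15.3, 9.8, 11.4, 14.0)
  b <- c(11.0, 14.1, 10.2, 10.1, 12.5)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(tstat), df = 4)
  expect_equal(paired_compare(a, b), p_hand, tolerance = 1e-12)
  expect_error(paired_compare(a, a), class = "surgiview_degenerate_test")
  expect_error(paired_compare(a, a + 3), class = "surgiview_degenerate_test")
  expect_error(paired_compare(1:3, 1:4), class = "surgiview_input_error")
})

test_that("the report aggregates quality metrics and paired tests", {
  withr::with_seed(10, {
    raw <- lapply(1:5, function(i) rand_img(12, 12, seed = i))
    ref <- lapply(raw, function(x) as_uint8(x * 0.8 + 30))
    prop <- lapply(ref, function(x) as_uint8(x + array(rnorm(prod(dim(x)), 0, 4),
                                                       dim = dim(x))))
    rep <- metrics_report(raw, ref, prop)
    expect_equal(nrow(rep$per_pair), 5)
    expect_true(all(rep$per_pair$ssim <= 1 & rep$per_pair$ssim >= -1))
    expect_equal(rownames(rep$quality), c("nrmse", "psnr", "ssim"))
    expect_equal(rep$visualization$measure,
                 c("brightness", "contrast", "sharpness"))
    expect_true(all(rep$visualization$p_raw_vs_proposed <= 1, na.rm = TRUE))
  })
})
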