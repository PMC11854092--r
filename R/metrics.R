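# Full-reference image quality metrics and the three visualization
# measures. All metrics operate on the luminance channel (RGB inputs are
# converted with the BT.601 weights); `I` is the reference image and `P`
# the comparison image.

as_luma <- function(img) {
  if (is.matrix(img)) img * 1.0 else to_grayscale(img)
}

check_pair <- function(I, P) {
  a <- as_luma(I); b <- as_luma(P)
  if (!all(dim(a) == dim(b)))
    sv_error("images must have identical dimensions", "surgiview_input_error")
  list(I = a, P = b)
}

#' Normalized root mean square error
#'
#' `sqrt(mean((I - P)^2)) / (I_max + I_min)` where `I_max` and `I_min` are
#' the brightest and darkest luminance values of the reference image. The
#' `I_max + I_min` denominator follows the source formulation; the more
#' common range normalization `I_max - I_min` is available via
#' `denominator = "range"`.
#'
#' @param I Reference image (RGB array or grayscale matrix, 0..255).
#' @param P Comparison image, same dimensions.
#' @param denominator `"sum"` (default) or `"range"`.
#' @return Non-negative scalar; 0 means identical images.
#' @export
nrmse <- function(I, P, denominator = c("sum", "range")) {
  denominator <- match.arg(denominator)
  g <- check_pair(I, P)
  den <- if (denominator == "sum") max(g$I) + min(g$I) else max(g$I) - min(g$I)
  if (den == 0)
    sv_error("NRMSE denominator is zero for this reference image",
             "surgiview_degenerate_metric")
  sqrt(mean((g$I - g$P)^2)) / den
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(I_max^2 / MSE)` with `I_max` the brightest luminance of the
#' reference. Identical images give the `Inf` sentinel.
#'
#' @inheritParams nrmse
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
psnr <- function(I, P) {
  g <- check_pair(I, P)
  mse <- mean((g$I - g$P)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(g$I)^2 / mse)
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# weighted local moments by valid-mode convolution with window w
conv_valid <- function(x, w) {
  k <- nrow(w)
  xc <- array(x, dim = c(dim(x), 1L))
  wm <- matrix(as.vector(w), nrow = 1L)   # single in/out channel
  cpp_conv2d_forward(xc, wm, 0, k, 1L, 0L, 0L, 0L, 0L)[, , 1]
}

#' Structural similarity index
#'
#' Mean over sliding windows of the product of luminance, contrast and
#' structure similarity, `(L * C * S)^alpha`, with the standard
#' stabilizing constants `C1 = (0.01*255)^2`, `C2 = (0.03*255)^2`,
#' `C3 = C2/2` (which collapses the product to the familiar two-term SSIM
#' form when `alpha = 1`). The default window is 11 x 11 Gaussian with
#' sigma 1.5; `gaussian = FALSE` gives a uniform window, which together
#' with `window = min(dim)` reproduces the single-full-window textbook
#' computation.
#'
#' @inheritParams nrmse
#' @param window Window side length; must not exceed either image dimension.
#' @param sigma Gaussian window standard deviation.
#' @param alpha Weighting exponent on the window-wise product.
#' @param gaussian Use a Gaussian (TRUE) or uniform (FALSE) window.
#' @return Scalar in `[-1, 1]`; 1 means structurally identical.
#' @export
ssim <- function(I, P, window = 11, sigma = 1.5, alpha = 1, gaussian = TRUE) {
  g <- check_pair(I, P)
  if (window > min(dim(g$I)))
    sv_error("SSIM window larger than the image", "surgiview_input_error")
  w <- if (gaussian) gaussian_kernel(window, sigma)
       else matrix(1 / window^2, window, window)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2; C3 <- C2 / 2
  muI <- conv_valid(g$I, w); muP <- conv_valid(g$P, w)
  sI2 <- conv_valid(g$I^2, w) - muI^2
  sP2 <- conv_valid(g$P^2, w) - muP^2
  sIP <- conv_valid(g$I * g$P, w) - muI * muP
  sI2[sI2 < 0] <- 0; sP2[sP2 < 0] <- 0
  sI <- sqrt(sI2); sP <- sqrt(sP2)
  L <- (2 * muI * muP + C1) / (muI^2 + muP^2 + C1)
  C <- (2 * sI * sP + C2) / (sI2 + sP2 + C2)
  S <- (sIP + C3) / (sI * sP + C3)
  mean((L * C * S)^alpha)
}

#' Visualization measures: brightness, contrast, sharpness
#'
#' `img_brightness()` is the mean luminance (0..255). `img_contrast()` is
#' the mean absolute luminance difference over all horizontally and
#' vertically adjacent pixel pairs. `img_sharpness()` is the population
#' variance of the 4-neighbour Laplacian of the luminance, evaluated on
#' interior pixels only (so a linear ramp scores exactly 0).
#'
#' @param img RGB array or grayscale matrix.
#' @return Scalar measure.
#' @export
img_brightness <- function(img) {
  mean(as_luma(img))
}

#' @rdname img_brightness
#' @export
img_contrast <- function(img) {
  g <- as_luma(img)
  h <- nrow(g); w <- ncol(g)
  if (h * w < 2L)
    sv_error("contrast needs at least one adjacent pixel pair",
             "surgiview_input_error")
  diffs <- numeric(0)
  if (w > 1) diffs <- c(diffs, abs(g[, -1] - g[, -w]))
  if (h > 1) diffs <- c(diffs, abs(g[-1, ] - g[-h, ]))
  mean(diffs)
}

#' @rdname img_brightness
#' @export
img_sharpness <- function(img) {
  g <- as_luma(img)
  h <- nrow(g); w <- ncol(g)
  if (h < 3 || w < 3)
    sv_error("sharpness needs an image of at least 3 x 3 pixels",
             "surgiview_input_error")
  core <- g[2:(h - 1), 2:(w - 1)]
  lap <- g[1:(h - 2), 2:(w - 1)] + g[3:h, 2:(w - 1)] +
         g[2:(h - 1), 1:(w - 2)] + g[2:(h - 1), 3:w] - 4 * core
  mean((lap - mean(lap))^2)
}

#' Two-sided paired t-test p-value
#'
#' Thin wrapper used for the group comparisons of the visualization
#' measures. Zero variance of the paired differences (including identical
#' inputs) is a degenerate test and raises an error.
#'
#' @param values_a,values_b Equal-length numeric vectors (n >= 2).
#' @return Two-sided p-value.
#' @export
paired_compare <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2)
    sv_error("paired test needs two equal-length vectors with n >= 2",
             "surgiview_input_error")
  d <- values_a - values_b
  if (sd(d) == 0)
    sv_error("degenerate paired test: differences have zero variance",
             "surgiview_degenerate_test")
  t.test(values_a, values_b, paired = TRUE)$p.value
}

#' Metrics report over image triplets
#'
#' Computes NRMSE/PSNR/SSIM for (reference, proposed) pairs and the three
#' visualization measures for raw, reference and proposed groups, with the
#' three paired comparisons (raw vs reference, raw vs proposed, reference
#' vs proposed). PSNR `Inf` sentinels are excluded from the group mean/SD.
#'
#' @param raw,reference,proposed Lists of images (equal length).
#' @return List with `per_pair` (data frame of per-image metrics),
#'   `quality` (mean/SD of NRMSE, PSNR, SSIM of proposed vs reference) and
#'   `visualization` (per-measure group means/SDs and paired p-values;
#'   p-values are `NA` when the paired test is degenerate).
#' @export
metrics_report <- function(raw, reference, proposed) {
  n <- length(reference)
  stopifnot(length(raw) == n, length(proposed) == n, n >= 1)
  per <- data.frame(
    nrmse = vapply(seq_len(n), function(i) nrmse(reference[[i]], proposed[[i]]), 0),
    psnr  = vapply(seq_len(n), function(i) psnr(reference[[i]], proposed[[i]]), 0),
    ssim  = vapply(seq_len(n), function(i) ssim(reference[[i]], proposed[[i]]), 0)
  )
  msd <- function(x) c(mean = mean(x[is.finite(x)]), sd = sd(x[is.finite(x)]))
  quality <- rbind(nrmse = msd(per$nrmse), psnr = msd(per$psnr),
                   ssim = msd(per$ssim))
  groups <- list(raw = raw, reference = reference, proposed = proposed)
  measures <- list(brightness = img_brightness, contrast = img_contrast,
                   sharpness = img_sharpness)
  vis <- lapply(names(measures), function(mn) {
    f <- measures[[mn]]
    vals <- lapply(groups, function(g) vapply(g, f, 0))
    safe_p <- function(a, b) tryCatch(paired_compare(a, b),
                                      surgiview_degenerate_test = function(e) NA_real_,
                                      surgiview_input_error = function(e) NA_real_)
    data.frame(
      measure = mn,
      raw_mean = mean(vals$raw), raw_sd = sd(vals$raw),
      reference_mean = mean(vals$reference), reference_sd = sd(vals$reference),
      proposed_mean = mean(vals$proposed), proposed_sd = sd(vals$proposed),
      p_raw_vs_reference = safe_p(vals$raw, vals$reference),
      p_raw_vs_proposed = safe_p(vals$raw, vals$proposed),
      p_reference_vs_proposed = safe_p(vals$reference, vals$proposed)
    )
  })
  list(per_pair = per, quality = quality,
       visualization = do.call(rbind, vis))
}
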