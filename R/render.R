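# Deterministic parameter renderer: applies a param_set to an RGB image.
# This image-formation model is the package's stand-in for the (proprietary)
# display pipeline; what matters downstream is that it is fixed,
# deterministic and parameter-identifiable. The application order is pinned:
# CMY balance -> hue rotation -> saturation -> contrast -> brightness ->
# gamma, computed in floating point with a single clip/quantize at the end
# (intermediate values are clamped, never rounded).

rgb_to_hsv_arr <- function(img) {
  px <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  grDevices::rgb2hsv(px, maxColorValue = 255)   # h, s in [0,1]; v in [0,1]
}

hsv_to_rgb_arr <- function(hsv, h_img, w_img) {
  h6 <- (hsv[1, ] %% 1) * 6
  s <- hsv[2, ]; v <- hsv[3, ] * 255
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), dim = c(h_img, w_img, 3))
}

#' Apply display parameters to an image
#'
#' Renders an RGB image through the fixed eight-parameter display model, in
#' this order:
#' 1. CMY colour balance: `cyan` is subtracted from the red channel,
#'    `magenta` from green, `yellow` from blue (gray-level offsets).
#' 2. Hue rotation in HSV space by `hue` degrees.
#' 3. Saturation scaling in HSV by `1 + saturation/100`.
#' 4. Contrast scaling about mid-gray: `127.5 + (1 + contrast/100) * (v - 127.5)`.
#' 5. Additive `brightness` offset (gray levels).
#' 6. Display gamma: `255 * (v/255)^(1/gamma)`, so gamma > 1 brightens
#'    mid-tones.
#'
#' All arithmetic is floating point; the result is clipped to 0..255 and
#' quantized once at the end. `render_params(img, identity_params())`
#' returns `img` bit-exactly.
#'
#' @param image RGB array (H x W x 3, values 0..255).
#' @param params A [param_set()].
#' @return RGB array of the same dimensions, integral values in 0..255.
#' @examples
#' img <- array(100, dim = c(4, 4, 3))
#' p <- param_set(c(brightness = 10, saturation = 0, contrast = 0, cyan = 0,
#'                  gamma = 1, magenta = 0, hue = 0, yellow = 0))
#' render_params(img, p)[1, 1, ]   # 110 110 110
#' @export
render_params <- function(image, params) {
  assert_rgb(image)
  stopifnot(inherits(params, "param_set"))
  v <- params$values
  x <- image * 1.0

  # (1) CMY balance as gray-level offsets against the complementary channel
  if (v[["cyan"]] != 0)    x[, , 1] <- x[, , 1] - v[["cyan"]]
  if (v[["magenta"]] != 0) x[, , 2] <- x[, , 2] - v[["magenta"]]
  if (v[["yellow"]] != 0)  x[, , 3] <- x[, , 3] - v[["yellow"]]
  x <- clamp(x, 0, 255)

  # (2)+(3) hue rotation and saturation scaling, skipped entirely at the
  # identity so the identity map stays bit-exact
  sat_scale <- 1 + v[["saturation"]] / 100
  if (v[["hue"]] != 0 || sat_scale != 1) {
    hsv <- rgb_to_hsv_arr(x)
    hsv[1, ] <- (hsv[1, ] + v[["hue"]] / 360) %% 1
    hsv[2, ] <- clamp(hsv[2, ] * sat_scale, 0, 1)
    x <- hsv_to_rgb_arr(hsv, dim(x)[1], dim(x)[2])
  }

  # (4) contrast about mid-gray, (5) brightness offset
  con_scale <- 1 + v[["contrast"]] / 100
  if (con_scale != 1) x <- 127.5 + con_scale * (x - 127.5)
  if (v[["brightness"]] != 0) x <- x + v[["brightness"]]

  # (6) display gamma on the clamped signal
  if (v[["gamma"]] != 1) {
    x <- clamp(x, 0, 255)
    x <- 255 * (x / 255)^(1 / v[["gamma"]])
  }
  as_uint8(x)
}
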