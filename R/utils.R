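# Shared helpers: error conditions, seeded evaluation, image containers and
# plain-text (PPM/PGM) image I/O. Images are numeric arrays dim c(H, W, 3)
# with integral values in 0..255 ("uint8 semantics"); grayscale images are
# H x W matrices on the same scale.

sv_error <- function(msg, class) {
  stop(structure(class = c(class, "surgiview_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do not
#' disturb the caller's random stream. All stochastic functions in the
#' package route their draws through this helper, which is what makes
#' identical (config, seed) pairs produce bit-identical outputs.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive n reproducible child seeds below 2^31 from a parent seed
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_rgb <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    sv_error(sprintf("`%s` must be an H x W x 3 array", arg),
             "surgiview_input_error")
  if (!is.numeric(img) || anyNA(img))
    sv_error(sprintf("`%s` must be numeric with no missing values", arg),
             "surgiview_input_error")
  invisible(img)
}

assert_gray <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    sv_error(sprintf("`%s` must be a non-empty numeric matrix", arg),
             "surgiview_input_error")
  invisible(img)
}

#' Clamp and quantize an image to 8-bit range
#'
#' @param x Numeric array or matrix.
#' @return `x` rounded and clipped to 0..255 (still stored as double).
#' @export
as_uint8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read and write plain-text portable pixmaps
#'
#' `write_ppm()` stores an RGB image (H x W x 3, 0..255) as an ASCII `P3`
#' portable pixmap; grayscale matrices are stored as `P2` portable graymaps.
#' `read_ppm()` reads either format back. These text formats stand in for
#' PNG throughout the package because the environment offers no compressed
#' image reader for R.
#'
#' @param img RGB array or grayscale matrix with values in 0..255.
#' @param path File path.
#' @return `read_ppm()` returns an RGB array (P3) or matrix (P2);
#'   `write_ppm()` returns `path` invisibly.
#' @export
write_ppm <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(img)) {
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    vals <- as.integer(t(as_uint8(img)))
  } else {
    assert_rgb(img)
    writeLines(c("P3", paste(dim(img)[2], dim(img)[1]), "255"), con)
    # interleave channels pixel-by-pixel, row-major
    q <- as_uint8(img)
    vals <- as.integer(aperm(q, c(3, 2, 1)))
  }
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1]
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (magic == "P2") {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else if (magic == "P3") {
    aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
  } else {
    sv_error("unsupported pixmap magic (expected P2 or P3)",
             "surgiview_input_error")
  }
}

#' Bilinear image resize
#'
#' Resizes with half-pixel-centre sampling (source coordinate
#' `(i + 0.5) * scale - 0.5`, edges clamped), the convention shared by the
#' common image libraries. Works on RGB arrays and grayscale matrices;
#' output is quantized back to 0..255.
#'
#' @param img RGB array or grayscale matrix.
#' @param out_h,out_w Output dimensions in pixels.
#' @return Resized image of the same kind as the input.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  gray <- is.matrix(img)
  if (gray) img <- array(img, dim = c(dim(img), 1L))
  h <- dim(img)[1]; w <- dim(img)[2]
  sy <- h / out_h; sx <- w / out_w
  yc <- clamp((seq_len(out_h) - 0.5) * sy - 0.5, 0, h - 1)
  xc <- clamp((seq_len(out_w) - 0.5) * sx - 0.5, 0, w - 1)
  y0 <- pmin(floor(yc), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(xc), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- yc - y0; fx <- xc - x0
  out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
  wy0 <- 1 - fy; wx0 <- 1 - fx
  for (c in seq_len(dim(img)[3])) {
    ch <- img[, , c]
    a <- ch[y0 + 1, x0 + 1, drop = FALSE] * outer(wy0, wx0)
    b <- ch[y0 + 1, x1 + 1, drop = FALSE] * outer(wy0, fx)
    d <- ch[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, wx0)
    e <- ch[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
    out[, , c] <- a + b + d + e
  }
  out <- as_uint8(out)
  if (gray) out[, , 1] else out
}
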