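# ROI extraction protocol for the illuminated surgical field: grayscale ->
# histogram (Otsu) threshold -> binarize -> remove small objects -> largest
# connected component -> tight bounding box -> crop the colour frame ->
# resize. Coordinates are 0-based, half-open (left, top, right, bottom).

#' Convert an RGB image to luminance
#'
#' ITU-R BT.601 weights (0.299, 0.587, 0.114), the default of the classic
#' image libraries. The result is kept in floating point on the 0..255
#' scale.
#'
#' @param image RGB array (H x W x 3).
#' @return H x W numeric matrix.
#' @export
to_grayscale <- function(image) {
  assert_rgb(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Otsu threshold from the gray-level histogram
#'
#' Implements histogram analysis as Otsu's method: the integer threshold
#' `t` in 0..254 maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the two classes `{<= t}` and `{> t}`,
#' computed over the 256-bin histogram of the rounded image. When several
#' thresholds tie (a flat plateau between two well-separated modes), the
#' midpoint of the maximizing set is returned, so a half-black/half-white
#' image thresholds at mid-scale rather than at an extreme.
#'
#' @param gray Numeric matrix, values in 0..255.
#' @return Integer threshold in 0..254.
#' @export
compute_threshold <- function(gray) {
  assert_gray(gray, "gray")
  g <- as.integer(clamp(round(gray), 0, 255))
  counts <- tabulate(g + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    sv_error("degenerate histogram: image has a single gray level",
             "surgiview_degenerate_histogram")
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)
  m <- cumsum(p * levels)
  mt <- m[256]
  # between-class variance for t = 0..254 (class split {<=t} / {>t})
  w0t <- w0[1:255]
  mut <- m[1:255]
  valid <- w0t > 0 & w0t < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mt * w0t[valid] - mut[valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  mx <- max(sigma_b)
  cands <- which(sigma_b >= mx - abs(mx) * 1e-12)
  as.integer(round(mean(cands))) - 1L
}

#' Binarize a grayscale image
#'
#' Pixels strictly above the threshold become foreground.
#'
#' @param gray Numeric matrix.
#' @param threshold Gray level in 0..255.
#' @return Logical matrix (TRUE = foreground).
#' @export
binarize <- function(gray, threshold) {
  assert_gray(gray, "gray")
  gray > threshold
}

label_components <- function(mask) {
  storage.mode(mask) <- "logical"
  cpp_label_components(mask)
}

#' Remove small connected components from a binary mask
#'
#' Foreground components (8-connectivity) with area strictly below
#' `min_size` pixels are set to background, matching the semantics of the
#' standard morphology routine.
#'
#' @param mask Logical matrix.
#' @param min_size Minimum component area to keep (>= 1).
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, min_size) {
  if (!is.matrix(mask)) sv_error("`mask` must be a matrix",
                                 "surgiview_input_error")
  if (min_size < 1) sv_error("`min_size` must be >= 1",
                             "surgiview_config_error")
  if (min_size == 1) return(mask & TRUE)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_size)
  matrix(lab %in% keep, nrow = nrow(mask))
}

#' Bounding box of the largest foreground component
#'
#' Returns the tight bounding box of the largest-area 8-connected
#' component as `(left, top, right, bottom)`, 0-based and half-open. Equal
#' areas are broken by the lexicographically smallest (top, left) anchor so
#' the choice is deterministic.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return Named integer vector `c(left, top, right, bottom)`.
#' @export
largest_component_bbox <- function(mask) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L)
    sv_error("no foreground component: cannot locate an ROI",
             "surgiview_no_roi")
  areas <- tabulate(lab[lab > 0L], nbins = n)
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    anchors <- t(vapply(best, function(id) {
      idx <- which(lab == id, arr.ind = TRUE)
      c(min(idx[, 1]), min(idx[, 2]))
    }, numeric(2)))
    best <- best[order(anchors[, 1], anchors[, 2])][1]
  } else {
    best <- best[1]
  }
  idx <- which(lab == best, arr.ind = TRUE)
  c(left = min(idx[, 2]) - 1L, top = min(idx[, 1]) - 1L,
    right = max(idx[, 2]), bottom = max(idx[, 1]))
}

#' Extract the illuminated surgical field from a frame
#'
#' Runs the full ROI protocol: luminance conversion, Otsu threshold,
#' binarization, small-object removal, selection of the largest component,
#' tight bounding box, crop of the colour frame, and bilinear resize to
#' `out_size` x `out_size` (default 512).
#'
#' @param image RGB array.
#' @param min_size Minimum component area in pixels; default 1% of the
#'   frame area.
#' @param out_size Output side length in pixels.
#' @return An object of class `roi_result`: list with `roi_image`
#'   (`out_size` x `out_size` x 3, 0..255), `bbox` (0-based half-open),
#'   `threshold`, `n_components_before`, `n_components_after`. After the
#'   largest-component step exactly one object is retained; the stored
#'   `n_components_after` counts the components that survived small-object
#'   removal.
#' @export
extract_roi <- function(image, min_size = NULL, out_size = 512) {
  assert_rgb(image)
  if (is.null(min_size))
    min_size <- max(1, floor(0.01 * prod(dim(image)[1:2])))
  gray <- to_grayscale(image)
  thr <- compute_threshold(gray)
  mask <- binarize(gray, thr)
  n_before <- max(label_components(mask))
  mask2 <- remove_small_objects(mask, min_size)
  n_after <- max(label_components(mask2))
  bbox <- largest_component_bbox(mask2)
  crop <- image[(bbox[["top"]] + 1):bbox[["bottom"]],
                (bbox[["left"]] + 1):bbox[["right"]], , drop = FALSE]
  roi <- resize_bilinear(crop, out_size, out_size)
  structure(list(roi_image = roi, bbox = bbox, threshold = thr,
                 n_components_before = n_before,
                 n_components_after = n_after),
            class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  cat("<roi_result> ", dim(x$roi_image)[1], "x", dim(x$roi_image)[2],
      " threshold=", x$threshold,
      " bbox=(", paste(x$bbox, collapse = ","), ")",
      " components ", x$n_components_before, "->", x$n_components_after,
      "\n", sep = "")
  invisible(x)
}
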