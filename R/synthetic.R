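# Seeded synthetic ocular-microscope scenes. Each frame contains one bright
# roughly elliptical illuminated pupil (with red-reflex-like colouring and
# radial falloff), a dimmer scleral ellipse around it, a dark periphery,
# optional white UI glyphs near the borders, optional small bright
# instrument-like distractor blobs, and Gaussian pixel noise. The generator
# also emits the true pupil mask so segmentation accuracy can be scored,
# and (in make_dataset) the ground-truth parameter set plus the reference
# image rendered from it.

#' Synthetic scene configuration
#'
#' @param image_size Pixels per side (default 512; 64 is typical for fast
#'   tests).
#' @param pupil_radius_frac Pupil semi-major axis as a fraction of the
#'   image width, in (0.1, 0.45).
#' @param background_level Peripheral gray level, 0..255.
#' @param pupil_base_color RGB triple of the illuminated pupil centre.
#' @param ui_text Overlay small white UI glyphs near the borders.
#' @param distractor_count Number of small bright distractor blobs.
#' @param noise_sigma Gaussian pixel-noise standard deviation (gray levels).
#' @param seed Integer RNG seed; identical configs produce bit-identical
#'   scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = 512, pupil_radius_frac = 0.28,
                         background_level = 25,
                         pupil_base_color = c(205, 125, 70),
                         ui_text = TRUE, distractor_count = 2,
                         noise_sigma = 2, seed = 1) {
  if (image_size < 16)
    sv_error("`image_size` must be at least 16 pixels",
             "surgiview_config_error")
  if (pupil_radius_frac <= 0.1 || pupil_radius_frac >= 0.45)
    sv_error("`pupil_radius_frac` must lie in (0.1, 0.45)",
             "surgiview_config_error")
  if (background_level < 0 || background_level > 255)
    sv_error("`background_level` must be a gray level in 0..255",
             "surgiview_config_error")
  if (distractor_count < 0)
    sv_error("`distractor_count` must be non-negative",
             "surgiview_config_error")
  if (noise_sigma < 0)
    sv_error("`noise_sigma` must be non-negative", "surgiview_config_error")
  structure(list(image_size = as.integer(image_size),
                 pupil_radius_frac = pupil_radius_frac,
                 background_level = background_level,
                 pupil_base_color = pupil_base_color,
                 ui_text = isTRUE(ui_text),
                 distractor_count = as.integer(distractor_count),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# squared elliptical radius (1 on the boundary) for a rotated ellipse
ellipse_r2 <- function(xg, yg, cx, cy, a, b, theta) {
  dx <- xg - cx; dy <- yg - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2
}

#' Generate a synthetic ocular scene
#'
#' Deterministic given the config (including its seed). The pupil is an
#' ellipse with mild eccentricity and quadratic radial intensity falloff;
#' the surrounding sclera is a dimmer concentric ellipse; UI glyphs are
#' small white rectangles near the borders; distractors are small bright
#' blobs in the periphery, clear of the sclera and of each other.
#'
#' The optional `degrade` list (used by [make_dataset()] to couple scene
#' appearance to the ground-truth parameters) applies global factors to the
#' clean scene: `bright` multiplies all intensities, `contrast` scales
#' deviations from the frame mean, `cast` multiplies the three channels,
#' `sat` scales pupil chroma and `hue_shift` rotates pupil hue (degrees).
#'
#' @param config A [scene_config()].
#' @param degrade Optional named list of degradation factors (see Details).
#' @return A `scene` object: list with `image` (H x W x 3, uint8 values),
#'   `pupil_mask` (logical matrix), and `meta` (ellipse geometry).
#' @export
generate_scene <- function(config, degrade = NULL) {
  stopifnot(inherits(config, "scene_config"))
  s <- config$image_size
  with_seed(config$seed, {
    cx <- s / 2 + runif(1, -0.04, 0.04) * s
    cy <- s / 2 + runif(1, -0.04, 0.04) * s
    a <- config$pupil_radius_frac * s
    b <- a * runif(1, 0.78, 0.95)
    theta <- runif(1, 0, pi)
    xg <- matrix(rep(seq_len(s), each = s), nrow = s)   # column index
    yg <- matrix(rep(seq_len(s), times = s), nrow = s)  # row index
    r2p <- ellipse_r2(xg, yg, cx, cy, a, b, theta)
    r2s <- ellipse_r2(xg, yg, cx, cy, a * 1.35, b * 1.4, theta)
    pupil <- r2p <= 1
    sclera <- r2s <= 1 & !pupil

    col <- config$pupil_base_color
    if (!is.null(degrade)) {
      gray <- mean(col)
      sat <- if (is.null(degrade$sat)) 1 else degrade$sat
      col <- gray + sat * (col - gray)
      if (!is.null(degrade$hue_shift) && degrade$hue_shift != 0) {
        hsv <- grDevices::rgb2hsv(matrix(clamp(col, 0, 255), ncol = 1),
                                  maxColorValue = 255)
        hsv[1, 1] <- (hsv[1, 1] + degrade$hue_shift / 360) %% 1
        col <- grDevices::hsv(hsv[1, 1], hsv[2, 1], hsv[3, 1])
        col <- as.numeric(grDevices::col2rgb(col))
      }
      # channel cast is applied globally after composition, not here
    }

    img <- array(config$background_level, dim = c(s, s, 3))
    falloff <- 1 - 0.35 * clamp(r2p, 0, 1)
    scl_level <- config$background_level + 0.16 * (mean(col) -
                                                   config$background_level)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[sclera] <- scl_level
      ch[pupil] <- col[c] * falloff[pupil]
      img[, , c] <- ch
    }

    # distractors: bright blobs in the periphery, away from the sclera,
    # the borders and each other
    if (config$distractor_count > 0) {
      rad <- max(2, round(s / 40))
      placed <- 0; tries <- 0
      centers <- matrix(numeric(0), ncol = 2)
      while (placed < config$distractor_count && tries < 500) {
        tries <- tries + 1
        px <- runif(1, 3 * rad, s - 3 * rad)
        py <- runif(1, 3 * rad, s - 3 * rad)
        if (ellipse_r2(px, py, cx, cy, a * 1.35, b * 1.4, theta) < 1.6)
          next
        if (nrow(centers) > 0 &&
            min((centers[, 1] - px)^2 + (centers[, 2] - py)^2) <
              (5 * rad)^2)
          next
        centers <- rbind(centers, c(px, py))
        blob <- (xg - px)^2 + (yg - py)^2 <= rad^2
        for (c in 1:3) {
          ch <- img[, , c]
          ch[blob] <- 225
          img[, , c] <- ch
        }
        placed <- placed + 1
      }
    }

    # UI glyphs: small white rectangles hugging the top and bottom borders
    if (config$ui_text) {
      gh <- max(2, round(s / 64)); gw <- max(4, round(s / 24))
      xs <- round(seq(0.06 * s, 0.6 * s, length.out = 3))
      for (x0 in xs) {
        img[2:(1 + gh), x0:(x0 + gw), ] <- 255
        img[(s - gh):(s - 1), (s - x0 - gw):(s - x0), ] <- 255
      }
    }

    if (!is.null(degrade)) {
      if (!is.null(degrade$cast))
        for (c in 1:3) img[, , c] <- img[, , c] * degrade$cast[c]
      if (!is.null(degrade$bright)) img <- img * degrade$bright
      if (!is.null(degrade$contrast))
        img <- mean(img) + degrade$contrast * (img - mean(img))
    }

    if (config$noise_sigma > 0)
      img <- img + rnorm(length(img), 0, config$noise_sigma)
    structure(list(image = as_uint8(img), pupil_mask = pupil,
                   meta = list(center = c(cx, cy), axes = c(a, b),
                               theta = theta)),
              class = "scene")
  })
}

#' Sample a parameter set uniformly within the native ranges
#'
#' Each of the eight parameters is drawn independently and uniformly within
#' its native `(min, max)` range; the normalized view therefore lies in
#' `[0,1]^8`. Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param ranges Native range table (see [default_param_ranges()]).
#' @return A [param_set()].
#' @export
sample_parameters <- function(seed, ranges = default_param_ranges()) {
  ranges <- check_ranges(ranges)
  with_seed(seed, {
    v <- runif(8, ranges$min, ranges$max)
    names(v) <- param_names()
    param_set(v, ranges)
  })
}

# Scene-linked ground truth. A patient draws latent degradation factors
# (how dim / flat / colour-cast / desaturated / hue-shifted their imaging
# condition is); each frame jitters those latents slightly, and the
# "surgeon" parameters compensate the frame's own latents plus tuning
# noise. Parameters are clamped into the central 90% of each native range.
draw_patient_latents <- function() {
  list(bright = runif(1, 0.55, 1.05),
       contrast = runif(1, 0.65, 1.15),
       cast = runif(3, c(0.82, 0.9, 0.82), c(1.18, 1.1, 1.18)),
       sat = runif(1, 0.55, 1.2),
       hue_shift = runif(1, -25, 25))
}

jitter_latents <- function(z) {
  z$bright <- clamp(z$bright * runif(1, 0.96, 1.04), 0.5, 1.1)
  z$contrast <- clamp(z$contrast * runif(1, 0.96, 1.04), 0.6, 1.2)
  z$cast <- clamp(z$cast + runif(3, -0.02, 0.02), 0.8, 1.2)
  z$sat <- clamp(z$sat + runif(1, -0.03, 0.03), 0.5, 1.25)
  z$hue_shift <- clamp(z$hue_shift + runif(1, -2, 2), -28, 28)
  z
}

latents_to_params <- function(z, ranges) {
  p <- c(brightness = 80 * (0.8 - z$bright) + rnorm(1, 0, 3),
         saturation = 70 * (0.9 - z$sat) + rnorm(1, 0, 3),
         contrast = 70 * (0.9 - z$contrast) + rnorm(1, 0, 3),
         cyan = 120 * (z$cast[1] - 1) + rnorm(1, 0, 3),
         gamma = 1 + 0.9 * (0.8 - z$bright) + rnorm(1, 0, 0.04),
         magenta = 120 * (z$cast[2] - 1) + rnorm(1, 0, 3),
         hue = -z$hue_shift + rnorm(1, 0, 2),
         yellow = 120 * (z$cast[3] - 1) + rnorm(1, 0, 3))
  lo <- ranges$min + 0.05 * (ranges$max - ranges$min)
  hi <- ranges$max - 0.05 * (ranges$max - ranges$min)
  param_set(clamp(p, lo, hi), ranges)
}

#' Build a synthetic dataset with ground-truth parameters
#'
#' Generates `n` scenes assigned as evenly as possible to `patients` group
#' labels. For every sample the ROI is extracted with [extract_roi()] and
#' the reference image is rendered from the sample's own ground-truth
#' parameters, so `reference == render_params(roi(raw), params)` holds by
#' construction.
#'
#' In the default `"scene_linked"` mode, each patient draws latent
#' degradation factors (dim, low-contrast, colour-cast, desaturated,
#' hue-shifted scenes) with small per-frame jitter, and the ground-truth
#' parameters are compensating functions of those latents plus noise —
#' emulating a surgeon tuning the display against the visible condition of
#' the eye, and making the parameters statistically identifiable from the
#' images. `"uniform"` draws parameters independently of the scene via
#' [sample_parameters()].
#'
#' @param n Number of samples.
#' @param patients Number of synthetic patients (1 <= patients <= n).
#' @param config A [scene_config()]; its `image_size` is also the ROI
#'   output size, and its `seed` drives all randomness.
#' @param param_mode `"scene_linked"` (default) or `"uniform"`.
#' @param ranges Native parameter range table.
#' @param roi_min_size Passed to [extract_roi()]; default 1% of frame area.
#' @return A `scene_dataset`: list of samples, each with `raw_image`,
#'   `roi` (an `roi_result`), `reference_image`, `params`, `patient_id`,
#'   `seed` and `pupil_mask`.
#' @export
make_dataset <- function(n, patients, config = scene_config(),
                         param_mode = c("scene_linked", "uniform"),
                         ranges = default_param_ranges(),
                         roi_min_size = NULL) {
  param_mode <- match.arg(param_mode)
  if (patients < 1 || n < patients)
    sv_error("need n >= patients >= 1", "surgiview_config_error")
  ranges <- check_ranges(ranges)
  patient_id <- rep(seq_len(patients), length.out = n)
  seeds <- child_seeds(config$seed, 2L * n + patients)
  scene_seeds <- seeds[seq_len(n)]
  draw_seeds <- seeds[n + seq_len(n)]
  patient_seeds <- seeds[2L * n + seq_len(patients)]

  samples <- vector("list", n)
  for (i in seq_len(n)) {
    if (param_mode == "scene_linked") {
      # patient-level latent draw, then per-frame jitter; the frame's own
      # latents determine both its appearance and its ground-truth params
      zbase <- with_seed(patient_seeds[patient_id[i]],
                         draw_patient_latents())
      drawn <- with_seed(draw_seeds[i], {
        z <- jitter_latents(zbase)
        list(degrade = z, params = latents_to_params(z, ranges))
      })
    } else {
      drawn <- list(degrade = NULL,
                    params = sample_parameters(draw_seeds[i], ranges))
    }
    cfg_i <- config
    cfg_i$seed <- scene_seeds[i]
    scene <- generate_scene(cfg_i, degrade = drawn$degrade)
    roi <- extract_roi(scene$image, min_size = roi_min_size,
                       out_size = config$image_size)
    reference <- render_params(roi$roi_image, drawn$params)
    samples[[i]] <- list(raw_image = scene$image, roi = roi,
                         reference_image = reference,
                         params = drawn$params,
                         patient_id = patient_id[i],
                         seed = scene_seeds[i],
                         pupil_mask = scene$pupil_mask)
  }
  structure(list(samples = samples, config = config, ranges = ranges,
                 param_mode = param_mode),
            class = "scene_dataset")
}

#' @export
print.scene_dataset <- function(x, ...) {
  cat("<scene_dataset> n=", length(x$samples),
      " patients=", length(unique(vapply(x$samples, `[[`, 0L, "patient_id"))),
      " size=", x$config$image_size, " mode=", x$param_mode, "\n", sep = "")
  invisible(x)
}

#' Write a dataset to disk as pixmaps and CSV tables
#'
#' Writes `raw_NNN.ppm`, `roi_NNN.ppm`, `ref_NNN.ppm` per sample plus
#' `params.csv` (native units, header `sample_id,patient_id,` followed by
#' the eight canonical parameter columns) and `params_norm.csv` (the
#' normalized view).
#'
#' @param dataset A `scene_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "scene_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nat <- list(); nrm <- list()
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    tag <- sprintf("%03d", i)
    write_ppm(s$raw_image, file.path(dir, paste0("raw_", tag, ".ppm")))
    write_ppm(s$roi$roi_image, file.path(dir, paste0("roi_", tag, ".ppm")))
    write_ppm(s$reference_image, file.path(dir, paste0("ref_", tag, ".ppm")))
    nat[[i]] <- data.frame(sample_id = i, patient_id = s$patient_id,
                           t(s$params$values))
    nrm[[i]] <- data.frame(sample_id = i, patient_id = s$patient_id,
                           t(normalize_params(s$params)))
  }
  write.csv(do.call(rbind, nat), file.path(dir, "params.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, nrm), file.path(dir, "params_norm.csv"),
            row.names = FALSE)
  invisible(dir)
}
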