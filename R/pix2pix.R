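# Conditional image-to-image model mapping a raw ROI frame to a
# pseudo-optimal ("fake") frame. The generator is a U-Net built to match
# the published architecture table exactly at 512x512: seven stride-2 4x4
# encoder convolutions (LeakyReLU), then seven (2x nearest upsample + 4x4
# stride-1 "same" convolution) decoder steps (ReLU, Tanh on the 3-channel
# output). Tracing the table's per-layer trainable parameter counts pins
# the skip topology unambiguously: each decoder convolution's OUTPUT is
# concatenated with the encoder activation at the same resolution, and the
# concatenated tensor is what gets upsampled into the next decoder
# convolution. That gives the doubled input channel counts at layer
# indices 11, 13, 15, 17, 19 and 21 (e.g. 4*4*1024*512 + 512 = 8,389,120
# at index 11). Smaller image sizes reuse the same channel logic
# (64 * 2^(depth-1), capped at 512, bottleneck at 4x4).

#' Generator layer plan
#'
#' Builds the ordered layer table of the U-Net generator for a given input
#' size: one input row, `log2(size) - 2` encoder convolutions and the
#' matching upsample/convolution decoder pairs, with output shapes,
#' activations and the expected trainable parameter count of every layer
#' (kernel 4x4; convolution parameters are `k*k*Cin*Cout + Cout`, where
#' `Cin` includes skip-concatenated channels where the topology demands
#' them).
#'
#' @param image_size Input side length; a power of two, at least 16.
#' @return Data frame with columns `index`, `kind`, `h`, `w`, `channels`,
#'   `activation`, `cin`, `params`. At `image_size = 512` there are 22
#'   rows (indices 0-21).
#' @export
generator_spec <- function(image_size = 512) {
  n <- log2(image_size) - 2
  if (image_size < 16 || n != round(n))
    sv_error("`image_size` must be a power of two >= 16",
             "surgiview_config_error")
  n <- as.integer(n)
  enc_ch <- pmin(64 * 2^(seq_len(n) - 1), 512)
  rows <- list(data.frame(index = 0L, kind = "input", h = image_size,
                          w = image_size, channels = 3L, activation = "-",
                          cin = NA_integer_, params = 0))
  idx <- 1L
  cin <- 3L
  for (i in seq_len(n)) {
    res <- image_size / 2^i
    rows[[length(rows) + 1]] <-
      data.frame(index = idx, kind = "conv_down", h = res, w = res,
                 channels = enc_ch[i], activation = "LeakyReLU", cin = cin,
                 params = 16 * cin * enc_ch[i] + enc_ch[i])
    cin <- enc_ch[i]
    idx <- idx + 1L
  }
  for (j in seq_len(n)) {
    res <- 4 * 2^j
    # the upsample row lists the main decoder branch (as published; the
    # concatenate step is implicit); the conv row's cin additionally
    # carries the skip channels from the encoder activation one level up
    up_ch <- if (j == 1) enc_ch[n] else cout_prev
    cin_j <- if (j == 1) enc_ch[n] else cout_prev + enc_ch[n - j + 1]
    cout <- if (j < n) enc_ch[n - j] else 3L
    actv <- if (j < n) "ReLU" else "Tanh"
    rows[[length(rows) + 1]] <-
      data.frame(index = idx, kind = "upsample", h = res, w = res,
                 channels = up_ch, activation = "-", cin = NA_integer_,
                 params = 0)
    rows[[length(rows) + 1]] <-
      data.frame(index = idx + 1L, kind = "conv_up", h = res, w = res,
                 channels = cout, activation = actv, cin = cin_j,
                 params = 16 * cin_j * cout + cout)
    cout_prev <- cout
    idx <- idx + 2L
  }
  do.call(rbind, rows)
}

#' Build the U-Net generator
#'
#' Realizes weight arrays for every convolution of the plan in
#' [generator_spec()] and audits each layer's actual trainable parameter
#' count against the plan, raising an architecture-mismatch error naming
#' the first offending layer if a custom `spec` disagrees with the
#' realized build.
#'
#' @param image_size Input side length (power of two, >= 16; 512 matches
#'   the published table).
#' @param seed Seed for the weight initialization (normal, sd 0.02).
#' @param spec Layer plan to audit against; defaults to
#'   `generator_spec(image_size)`.
#' @return An object of class `p2p_generator`.
#' @export
build_generator <- function(image_size = 512, seed = 1,
                            spec = generator_spec(image_size)) {
  plan <- generator_spec(image_size)
  n <- sum(plan$kind == "conv_down")
  gen <- with_seed(seed, {
    enc <- lapply(which(plan$kind == "conv_down"), function(r) {
      conv_make(plan$cin[r], plan$channels[r], 4L, stride = 2L, pad = 1L,
                act = "lrelu", init = "gan")
    })
    dec <- lapply(which(plan$kind == "conv_up"), function(r) {
      conv_make(plan$cin[r], plan$channels[r], 4L, stride = 1L,
                pad = "same",
                act = if (plan$activation[r] == "Tanh") "tanh" else "relu",
                init = "gan")
    })
    list(enc = enc, dec = dec)
  })
  model <- structure(list(image_size = as.integer(image_size),
                          n_levels = n, enc = gen$enc, dec = gen$dec,
                          spec = plan),
                     class = "p2p_generator")
  counts <- generator_param_counts(model)
  if (!all(dim(spec)[1] == dim(plan)[1]) ||
      any(counts$params != spec$params)) {
    bad <- counts$index[which(counts$params != spec$params)[1]]
    sv_error(sprintf(
      "architecture mismatch at layer index %d: realized %d parameters, spec expects %d",
      bad, counts$params[counts$index == bad],
      spec$params[spec$index == bad]),
      "surgiview_architecture_error")
  }
  model
}

#' Per-layer trainable parameter counts of a built generator
#'
#' Counts the actual lengths of the realized weight and bias arrays, layer
#' by layer, in the order of the layer plan (input and upsample rows count
#' zero).
#'
#' @param generator A `p2p_generator`.
#' @return Data frame with columns `index`, `kind`, `params`.
#' @export
generator_param_counts <- function(generator) {
  stopifnot(inherits(generator, "p2p_generator"))
  plan <- generator$spec
  counts <- integer(nrow(plan))
  e <- d <- 0L
  for (r in seq_len(nrow(plan))) {
    if (plan$kind[r] == "conv_down") {
      e <- e + 1L
      ly <- generator$enc[[e]]
      counts[r] <- length(ly$W) + length(ly$b)
    } else if (plan$kind[r] == "conv_up") {
      d <- d + 1L
      ly <- generator$dec[[d]]
      counts[r] <- length(ly$W) + length(ly$b)
    }
  }
  data.frame(index = plan$index, kind = plan$kind, params = counts)
}

#' @export
print.p2p_generator <- function(x, ...) {
  cat("<p2p_generator> input ", x$image_size, "x", x$image_size,
      "x3, levels=", x$n_levels, ", trainable parameters=",
      format(sum(generator_param_counts(x)$params), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

# forward pass on a [-1,1]-scaled H x W x 3 array
generator_forward <- function(gen, x, keep = FALSE) {
  n <- gen$n_levels
  e <- vector("list", n)
  ez <- if (keep) vector("list", n)
  h <- x
  for (i in seq_len(n)) {
    cc <- conv_fwd(gen$enc[[i]], h, keep)
    if (keep) ez[[i]] <- cc
    e[[i]] <- cc$a
    h <- cc$a
  }
  d <- e[[n]]
  dz <- if (keep) vector("list", n)
  ups <- if (keep) vector("list", n)
  out <- NULL
  for (j in seq_len(n)) {
    u <- upsample2x(d)
    cc <- conv_fwd(gen$dec[[j]], u, keep)
    if (keep) { dz[[j]] <- cc; ups[[j]] <- dim(u) }
    if (j < n) d <- concat_ch(cc$a, e[[n - j]]) else out <- cc$a
  }
  if (keep) list(out = out, enc = ez, dec = dz, e = e) else out
}

# backward pass; dout is the gradient wrt the Tanh output
generator_backward <- function(gen, cache, dout) {
  n <- gen$n_levels
  enc_g <- vector("list", n)
  dec_g <- vector("list", n)
  skip_g <- vector("list", n)   # gradient flowing into e[[i]] via skips
  g_a <- dout
  for (j in rev(seq_len(n))) {
    g <- conv_bwd(gen$dec[[j]], cache$dec[[j]], g_a)
    dec_g[[j]] <- list(W = g$dW, b = g$db)
    gd <- upsample2x_bwd(g$dx)    # grad wrt the tensor that was upsampled
    if (j == 1) {
      skip_g[[n]] <- gd           # d_0 == e[[n]]
    } else {
      cprev <- dim(cache$dec[[j - 1]]$a)[3]
      g_a <- gd[, , seq_len(cprev), drop = FALSE]
      sk <- gd[, , (cprev + 1):dim(gd)[3], drop = FALSE]
      i <- n - (j - 1)
      skip_g[[i]] <- if (is.null(skip_g[[i]])) sk else skip_g[[i]] + sk
    }
  }
  g <- NULL
  for (i in rev(seq_len(n))) {
    gi <- skip_g[[i]] %||% 0
    if (!is.null(g)) gi <- gi + g
    bb <- conv_bwd(gen$enc[[i]], cache$enc[[i]], gi)
    enc_g[[i]] <- list(W = bb$dW, b = bb$db)
    g <- bb$dx
  }
  list(enc = enc_g, dec = dec_g, dx = g)
}

gen_params <- function(gen) {
  list(enc = lapply(gen$enc, function(l) list(W = l$W, b = l$b)),
       dec = lapply(gen$dec, function(l) list(W = l$W, b = l$b)))
}

gen_set_params <- function(gen, p) {
  for (i in seq_along(gen$enc)) {
    gen$enc[[i]]$W <- p$enc[[i]]$W; gen$enc[[i]]$b <- p$enc[[i]]$b
  }
  for (j in seq_along(gen$dec)) {
    gen$dec[[j]]$W <- p$dec[[j]]$W; gen$dec[[j]]$b <- p$dec[[j]]$b
  }
  gen
}

#' Build the conditional patch discriminator
#'
#' The canonical patch-based conditional discriminator: the input frame
#' and the candidate frame are concatenated channel-wise (6 channels) and
#' passed through 4x4 convolutions (64, 128, 256 at stride 2, then 512 and
#' 1 at stride 1 with symmetric padding 1), LeakyReLU throughout, linear
#' patch-logit output. The output is a spatial grid of real/fake logits,
#' not a scalar.
#'
#' @param image_size Input side length; must be divisible by 16.
#' @param seed Weight-init seed.
#' @return Object of class `p2p_discriminator`.
#' @export
build_discriminator <- function(image_size, seed = 1) {
  if (image_size %% 16 != 0)
    sv_error("`image_size` must be divisible by 16",
             "surgiview_config_error")
  layers <- with_seed(seed, list(
    conv_make(6, 64, 4L, stride = 2L, pad = 1L, act = "lrelu", init = "gan"),
    conv_make(64, 128, 4L, stride = 2L, pad = 1L, act = "lrelu", init = "gan"),
    conv_make(128, 256, 4L, stride = 2L, pad = 1L, act = "lrelu", init = "gan"),
    conv_make(256, 512, 4L, stride = 1L, pad = 1L, act = "lrelu", init = "gan"),
    conv_make(512, 1, 4L, stride = 1L, pad = 1L, act = "linear", init = "gan")
  ))
  structure(list(image_size = as.integer(image_size), layers = layers),
            class = "p2p_discriminator")
}

disc_forward <- function(disc, xpair, keep = FALSE) {
  r <- seq_forward(disc$layers, xpair, keep)
  if (keep) r else r
}

#' Pix2Pix training configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Samples per optimizer step.
#' @param lr Adam learning rate (the canonical recipe: 2e-4, beta1 0.5).
#' @param beta1 Adam first-moment decay.
#' @param lambda_l1 Weight of the L1 reconstruction loss against the
#'   adversarial loss (canonical 100).
#' @param seed Seed fixing initialization and batch order.
#' @param verbose Print per-epoch losses.
#' @return A `p2p_config` list.
#' @export
p2p_config <- function(epochs = 20, batch_size = 1, lr = 2e-4,
                       beta1 = 0.5, lambda_l1 = 100, seed = 1,
                       verbose = FALSE) {
  if (epochs < 0 || batch_size < 1 || lr <= 0 || lambda_l1 < 0)
    sv_error("invalid training configuration", "surgiview_config_error")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, lambda_l1 = lambda_l1,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "p2p_config")
}

to_signed <- function(img) img / 127.5 - 1
from_signed <- function(x) as_uint8((x + 1) * 127.5)

#' Train the conditional image-to-image model
#'
#' Alternating optimization of the patch discriminator (binary
#' cross-entropy with logits on real/fake pairs) and the generator
#' (adversarial loss plus `lambda_l1` times the mean absolute
#' reconstruction error against the reference), with Adam. Deterministic
#' given the config seed.
#'
#' @param pairs List of `list(input =, target =)` RGB images (uint8 scale,
#'   all the same size).
#' @param config A [p2p_config()].
#' @return List with `generator` (trained `p2p_generator`),
#'   `discriminator`, and `history` (data frame `epoch`, `d_loss`,
#'   `g_loss`, `l1_loss`; L1 is on the internal [-1,1] scale).
#' @export
train_pix2pix <- function(pairs, config = p2p_config()) {
  if (length(pairs) < 1)
    sv_error("need at least one training pair", "surgiview_input_error")
  sz <- dim(pairs[[1]]$input)
  for (p in pairs) {
    if (!all(dim(p$input) == sz) || !all(dim(p$target) == sz))
      sv_error("all images must share the same size",
               "surgiview_input_error")
  }
  gen <- build_generator(sz[1], seed = config$seed + 1L)
  disc <- build_discriminator(sz[1], seed = config$seed + 2L)
  gp <- gen_params(gen); dp <- layers_params(disc$layers)
  g_state <- adam_init(gp); d_state <- adam_init(dp)
  xs <- lapply(pairs, function(p) to_signed(p$input))
  ys <- lapply(pairs, function(p) to_signed(p$target))
  hist <- vector("list", config$epochs)
  order_seeds <- child_seeds(config$seed, max(config$epochs, 1))

  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(order_seeds[ep], sample(length(pairs)))
    ep_d <- ep_g <- ep_l1 <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      fakes <- vector("list", length(bt))
      gcaches <- vector("list", length(bt))
      d_acc <- tree_zero(dp)
      # --- discriminator step (generator frozen) ---
      for (s in seq_along(bt)) {
        i <- bt[s]
        fc <- generator_forward(gen, xs[[i]], keep = TRUE)
        fakes[[s]] <- fc$out
        gcaches[[s]] <- fc
        real <- concat_ch(xs[[i]], ys[[i]])
        fake <- concat_ch(xs[[i]], fc$out)
        rr <- seq_forward(disc$layers, real, keep = TRUE)
        ep_d <- ep_d + bce_logits(rr$out, 1)
        br <- seq_backward(disc$layers, rr$caches,
                           bce_logits_grad(rr$out, 1),
                           input_grad = FALSE)
        d_acc <- tree_map2(d_acc, grads_as_params(br$grads), `+`)
        ff <- seq_forward(disc$layers, fake, keep = TRUE)
        ep_d <- ep_d + bce_logits(ff$out, 0)
        bf <- seq_backward(disc$layers, ff$caches,
                           bce_logits_grad(ff$out, 0),
                           input_grad = FALSE)
        d_acc <- tree_map2(d_acc, grads_as_params(bf$grads), `+`)
      }
      d_acc <- tree_map2(d_acc, d_acc, function(a, b) a / (2 * length(bt)))
      st <- adam_step(dp, d_acc, d_state, config$lr, config$beta1)
      dp <- st$params; d_state <- st$state
      disc$layers <- layers_set_params(disc$layers, dp)
      # --- generator step (against the updated discriminator) ---
      g_acc <- tree_zero(gp)
      for (s in seq_along(bt)) {
        i <- bt[s]
        fake_pair <- concat_ch(xs[[i]], fakes[[s]])
        ff <- seq_forward(disc$layers, fake_pair, keep = TRUE)
        adv <- bce_logits(ff$out, 1)
        bf <- seq_backward(disc$layers, ff$caches,
                           bce_logits_grad(ff$out, 1),
                           param_grads = FALSE)
        d_fake <- bf$dx[, , 4:6, drop = FALSE]
        resid <- fakes[[s]] - ys[[i]]
        l1 <- mean(abs(resid))
        d_fake <- d_fake + config$lambda_l1 * sign(resid) / length(resid)
        gb <- generator_backward(gen, gcaches[[s]], d_fake)
        g_acc <- tree_map2(g_acc, list(enc = gb$enc, dec = gb$dec), `+`)
        ep_g <- ep_g + adv + config$lambda_l1 * l1
        ep_l1 <- ep_l1 + l1
      }
      g_acc <- tree_map2(g_acc, g_acc, function(a, b) a / length(bt))
      st <- adam_step(gp, g_acc, g_state, config$lr, config$beta1)
      gp <- st$params; g_state <- st$state
      gen <- gen_set_params(gen, gp)
    }
    hist[[ep]] <- data.frame(epoch = ep,
                             d_loss = ep_d / (2 * length(pairs)),
                             g_loss = ep_g / length(pairs),
                             l1_loss = ep_l1 / length(pairs))
    if (config$verbose)
      message(sprintf("epoch %d: d=%.4f g=%.4f l1=%.4f", ep,
                      hist[[ep]]$d_loss, hist[[ep]]$g_loss,
                      hist[[ep]]$l1_loss))
  }
  list(generator = gen, discriminator = disc,
       history = if (config$epochs > 0) do.call(rbind, hist)
                 else data.frame(epoch = integer(), d_loss = numeric(),
                                 g_loss = numeric(), l1_loss = numeric()))
}

#' Generate a pseudo-optimal image from a raw ROI frame
#'
#' Runs the generator and maps the Tanh output back to the 0..255 scale.
#'
#' @param generator A `p2p_generator`.
#' @param image RGB array matching the generator's input size.
#' @return RGB array of identical dimensions, integral values 0..255.
#' @export
generate_fake <- function(generator, image) {
  stopifnot(inherits(generator, "p2p_generator"))
  assert_rgb(image)
  if (dim(image)[1] != generator$image_size ||
      dim(image)[2] != generator$image_size)
    sv_error("image size does not match the generator input size",
             "surgiview_input_error")
  from_signed(generator_forward(generator, to_signed(image)))
}
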