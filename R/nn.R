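# Minimal convolutional-network engine. The environment provides no deep
# learning framework for R, so convolution layers (im2col + BLAS, analytic
# gradients), activations, nearest-neighbour upsampling, max pooling,
# residual blocks, global average pooling and Adam are implemented here.
# Feature maps are numeric arrays dim c(H, W, C); a conv layer's weights
# are a (Cout x k*k*Cin) matrix in the kernel order fixed by the C++
# kernels, plus a bias vector.

# -- padding ----------------------------------------------------------------

# TF-style "same" padding totals k - stride (even kernels pad more on the
# bottom/right); symmetric integer padding is also accepted.
pad_spec <- function(pad, k, stride) {
  if (identical(pad, "same")) {
    total <- max(k - stride, 0)
    pt <- floor(total / 2)
    c(pt, total - pt, pt, total - pt)
  } else if (length(pad) == 1L) {
    rep(as.integer(pad), 4)
  } else {
    as.integer(pad)
  }
}

# -- layers -----------------------------------------------------------------

conv_make <- function(cin, cout, k, stride = 1L, pad = "same",
                      act = "linear", init = c("he", "gan")) {
  init <- match.arg(init)
  sdv <- if (init == "gan") 0.02 else sqrt(2 / (k * k * cin))
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = pad_spec(pad, k, stride),
       act = act,
       W = matrix(rnorm(cout * k * k * cin, 0, sdv), nrow = cout),
       b = numeric(cout))
}

act_apply <- function(z, act) {
  switch(act,
         linear = z,
         relu = pmax(z, 0),
         lrelu = pmax(z, 0) + 0.2 * pmin(z, 0),
         tanh = tanh(z),
         stop("unknown activation"))
}

# multiply upstream gradient by the activation derivative at z (a = act(z))
act_grad <- function(dout, z, a, act) {
  switch(act,
         linear = dout,
         relu = dout * (z > 0),
         lrelu = dout * (0.2 + 0.8 * (z > 0)),
         tanh = dout * (1 - a^2),
         stop("unknown activation"))
}

# NN layers run the single-precision kernel path; exact-arithmetic callers
# (e.g. the SSIM moments) call cpp_conv2d_forward directly with the
# double-precision default.
conv_fwd <- function(layer, x, keep = FALSE) {
  z <- cpp_conv2d_forward(x, layer$W, layer$b, layer$k, layer$stride,
                          layer$pad[1], layer$pad[2], layer$pad[3],
                          layer$pad[4], single = TRUE)
  a <- act_apply(z, layer$act)
  if (keep) list(a = a, z = z, x = x) else list(a = a)
}

conv_bwd <- function(layer, cache, dout, want_dx = TRUE, want_dw = TRUE) {
  dz <- act_grad(dout, cache$z, act_apply(cache$z, layer$act), layer$act)
  g <- cpp_conv2d_backward(cache$x, layer$W, dz, layer$k, layer$stride,
                           layer$pad[1], layer$pad[2], layer$pad[3],
                           layer$pad[4], want_dx, want_dw, single = TRUE)
  list(dx = g$dx, dW = g$dW,
       db = if (want_dw) as.numeric(g$db) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

upsample2x <- function(x) cpp_upsample2x(x)
upsample2x_bwd <- function(d) cpp_upsample2x_backward(d)

concat_ch <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

# -- sequential / residual networks ----------------------------------------

block_make <- function(convs, proj = NULL) {
  list(type = "resblock", convs = convs, proj = proj)
}

seq_forward <- function(layers, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      cc <- conv_fwd(ly, x, keep)
      if (keep) caches[[i]] <- cc
      x <- cc$a
    } else if (ly$type == "maxpool") {
      mp <- cpp_maxpool_forward(x, ly$k, ly$stride, ly$pad[1], ly$pad[2],
                                ly$pad[3], ly$pad[4])
      if (keep) caches[[i]] <- list(arg = mp$arg, dims = dim(x))
      x <- mp$out
    } else if (ly$type == "resblock") {
      xin <- x
      sub <- if (keep) vector("list", length(ly$convs)) else NULL
      h <- xin
      for (j in seq_along(ly$convs)) {
        cc <- conv_fwd(ly$convs[[j]], h, keep)
        if (keep) sub[[j]] <- cc
        h <- cc$a
      }
      if (!is.null(ly$proj)) {
        pc <- conv_fwd(ly$proj, xin, keep)
        s <- pc$a
      } else {
        pc <- NULL
        s <- xin
      }
      pre <- h + s
      x <- pmax(pre, 0)   # ReLU after the residual add
      if (keep) caches[[i]] <- list(sub = sub, proj = pc, pre = pre)
    } else if (ly$type == "gap") {
      if (keep) caches[[i]] <- list(dims = dim(x))
      x <- apply(x, 3, mean)
    } else stop("unknown layer type")
  }
  if (keep) list(out = x, caches = caches) else x
}

# `input_grad = FALSE` skips the gradient wrt the network input (the
# first layer's dx); `param_grads = FALSE` skips all dW/db (used when only
# dx is needed, e.g. the adversarial gradient through the discriminator)
seq_backward <- function(layers, caches, dout, input_grad = TRUE,
                         param_grads = TRUE) {
  grads <- vector("list", length(layers))
  d <- dout
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "conv") {
      g <- conv_bwd(ly, cc, d, want_dx = input_grad || i > 1L,
                    want_dw = param_grads)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      d <- g$dx
    } else if (ly$type == "maxpool") {
      d <- cpp_maxpool_backward(d, cc$arg, cc$dims[1], cc$dims[2],
                                cc$dims[3])
    } else if (ly$type == "resblock") {
      dpre <- d * (cc$pre > 0)
      # shortcut branch
      if (!is.null(ly$proj)) {
        gp <- conv_bwd(ly$proj, cc$proj, dpre, want_dw = param_grads)
        dskip <- gp$dx
        proj_g <- list(dW = gp$dW, db = gp$db)
      } else {
        dskip <- dpre
        proj_g <- NULL
      }
      # main branch
      dh <- dpre
      sub_g <- vector("list", length(ly$convs))
      for (j in rev(seq_along(ly$convs))) {
        g <- conv_bwd(ly$convs[[j]], cc$sub[[j]], dh,
                      want_dw = param_grads)
        sub_g[[j]] <- list(dW = g$dW, db = g$db)
        dh <- g$dx
      }
      grads[[i]] <- list(convs = sub_g, proj = proj_g)
      d <- dh + dskip
    } else if (ly$type == "gap") {
      hw <- cc$dims[1] * cc$dims[2]
      d <- array(rep(d / hw, each = hw), dim = cc$dims)
    }
  }
  list(dx = d, grads = grads)
}

# -- parameter plumbing -----------------------------------------------------

# extract/replace the trainable arrays of a layer list as a nested list
layers_params <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type == "conv") list(W = ly$W, b = ly$b)
    else if (ly$type == "resblock")
      list(convs = lapply(ly$convs, function(c) list(W = c$W, b = c$b)),
           proj = if (!is.null(ly$proj)) list(W = ly$proj$W, b = ly$proj$b))
    else NULL
  })
}

layers_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    p <- params[[i]]
    if (is.null(p)) next
    if (layers[[i]]$type == "conv") {
      layers[[i]]$W <- p$W; layers[[i]]$b <- p$b
    } else {
      for (j in seq_along(layers[[i]]$convs)) {
        layers[[i]]$convs[[j]]$W <- p$convs[[j]]$W
        layers[[i]]$convs[[j]]$b <- p$convs[[j]]$b
      }
      if (!is.null(layers[[i]]$proj)) {
        layers[[i]]$proj$W <- p$proj$W
        layers[[i]]$proj$b <- p$proj$b
      }
    }
  }
  layers
}

# seq_backward grads -> same nesting as layers_params
grads_as_params <- function(grads) {
  lapply(grads, function(g) {
    if (is.null(g)) return(NULL)
    if (!is.null(g$dW)) list(W = g$dW, b = g$db)
    else list(convs = lapply(g$convs, function(c) list(W = c$dW, b = c$db)),
              proj = if (!is.null(g$proj)) list(W = g$proj$dW,
                                                b = g$proj$db))
  })
}

n_params <- function(p) {
  if (is.null(p)) 0
  else if (is.numeric(p)) length(p)
  else sum(vapply(p, n_params, 0))
}

# -- generic tree arithmetic + Adam ----------------------------------------

tree_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next       # assigning NULL would drop the slot
    out[[i]] <- tree_map2(a[[i]], b[[i]], f)
  }
  out
}

tree_zero <- function(a) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(a * 0)
  lapply(a, tree_zero)
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m +
                         (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v +
                         (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  params <- tree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# binary cross-entropy with logits, element mean; grad wrt logits
bce_logits <- function(z, target) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}

bce_logits_grad <- function(z, target) {
  (stats::plogis(z) - target) / length(z)
}
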