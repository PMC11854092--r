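# Dual-branch ensemble regressor: two residual-network feature extractors
# (one fed the raw ROI frame, one the pseudo-optimal fake) whose
# concatenated features feed a fully connected affine head that predicts
# the eight normalized display parameters by least squares.

#' Regressor configuration
#'
#' @param backbone `"resnet_small"` (feature dim 128, CPU-friendly) or
#'   `"resnet50"` (feature dim 2048).
#' @param pretrained Pretrained backbone init; must be FALSE in this build.
#' @param epochs,batch_size,lr Adam training schedule for the mean squared
#'   error objective on the normalized parameters.
#' @param loss Only `"mse"` is supported.
#' @param weight_decay L2 penalty on the head weights (not the bias);
#'   regularizes the high-dimensional feature-to-parameter map.
#' @param freeze_backbones If TRUE only the affine head is trained on
#'   fixed backbone features (features are computed once, so training is
#'   much faster); if FALSE (default) both branches are fine-tuned jointly
#'   with the head, end to end.
#' @param branches `"both"` (default), `"raw_only"` or `"fake_only"`;
#'   the single-branch variants exist for ensemble-benefit comparisons.
#' @param seed Seed fixing initialization and batch order.
#' @return A `regressor_config` list.
#' @export
regressor_config <- function(backbone = c("resnet_small", "resnet50"),
                             pretrained = FALSE, epochs = 30,
                             batch_size = 16, lr = 1e-3, loss = "mse",
                             weight_decay = 1e-3,
                             freeze_backbones = FALSE,
                             branches = c("both", "raw_only", "fake_only"),
                             seed = 1) {
  backbone <- match.arg(backbone)
  branches <- match.arg(branches)
  if (!identical(loss, "mse"))
    sv_error("only the mse loss is supported", "surgiview_config_error")
  if (epochs < 1 || batch_size < 1 || lr <= 0 || weight_decay < 0)
    sv_error("hyperparameters must be positive", "surgiview_config_error")
  structure(list(backbone = backbone, pretrained = isTRUE(pretrained),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, loss = loss,
                 weight_decay = weight_decay,
                 freeze_backbones = isTRUE(freeze_backbones),
                 branches = branches, seed = as.integer(seed)),
            class = "regressor_config")
}

build_regressor <- function(config) {
  bb_raw <- build_backbone(config$backbone, seed = config$seed + 11L,
                           pretrained = config$pretrained)
  bb_fake <- if (config$branches == "both")
    build_backbone(config$backbone, seed = config$seed + 12L,
                   pretrained = config$pretrained)
  d <- bb_raw$feature_dim * (if (config$branches == "both") 2L else 1L)
  structure(list(backbone_raw = bb_raw, backbone_fake = bb_fake,
                 head = list(W = matrix(0, nrow = 8, ncol = d),
                             b = rep(0.5, 8)),
                 scaler = NULL, config = config, trained = FALSE),
            class = "sv_regressor")
}

regressor_features <- function(model, raw, fake) {
  switch(model$config$branches,
         both = fuse(extract_features(model$backbone_raw, raw),
                     extract_features(model$backbone_fake, fake)),
         raw_only = extract_features(model$backbone_raw, raw),
         fake_only = extract_features(model$backbone_raw, fake))
}

#' Predict the eight normalized display parameters
#'
#' Runs both feature branches, fuses them (raw branch first) and applies
#' the affine regression head. The head output is unconstrained ("linear
#' regression"); values are clipped to [0, 1] only at the application
#' boundary, and the raw head output stays retrievable.
#'
#' @param model A trained `sv_regressor` (predicting with an untrained
#'   model warns but proceeds).
#' @param raw RGB ROI frame at the model input size.
#' @param fake The corresponding pseudo-optimal frame.
#' @return List with `normalized` (clipped to `[0,1]^8`, canonical order)
#'   and `raw_output` (the unclipped affine head output).
#' @export
predict_params <- function(model, raw, fake) {
  stopifnot(inherits(model, "sv_regressor"))
  if (!isTRUE(model$trained))
    warning("predicting with an untrained regressor")
  f <- regressor_features(model, raw, fake)
  if (!is.null(model$scaler))
    f <- (f - model$scaler$center) / model$scaler$scale
  y <- as.numeric(model$head$W %*% f + model$head$b)
  names(y) <- param_names()
  list(normalized = clamp(y, 0, 1), raw_output = y)
}

#' Train the ensemble regressor with cross-validation folds
#'
#' Minimizes the mean squared error between the affine head output and the
#' reference normalized parameters, per fold: for every requested fold the
#' samples assigned to it form the validation set and all others the
#' training set. With `freeze_backbones = TRUE` the backbone features are
#' computed once and only the head is fitted; otherwise the two branches
#' and the head are optimized jointly end to end.
#'
#' @param dataset List of samples `list(raw =, fake =, target =)` where
#'   `target` is the normalized 8-vector in `[0,1]^8`.
#' @param folds Integer fold label per sample (a partition).
#' @param config A [regressor_config()].
#' @param fold_subset Folds to actually train (default: all labels).
#' @return List with `models` (one `sv_regressor` per trained fold,
#'   named by fold), `history` (data frame `fold`, `epoch`, `train_loss`,
#'   `val_loss`) and `predictions` (per-fold validation predictions,
#'   rows = samples, plus sample indices).
#' @export
train_regressor <- function(dataset, folds, config = regressor_config(),
                            fold_subset = NULL) {
  n <- length(dataset)
  if (length(folds) != n)
    sv_error("`folds` must label every sample", "surgiview_input_error")
  for (s in dataset)
    if (length(s$target) != 8 || any(s$target < 0 | s$target > 1))
      sv_error("targets must be normalized 8-vectors in [0,1]",
               "surgiview_input_error")
  labels <- sort(unique(folds))
  fold_subset <- fold_subset %||% labels
  Y <- t(vapply(dataset, function(s) as.numeric(s$target), numeric(8)))

  proto <- build_regressor(config)
  feats <- NULL
  if (config$freeze_backbones) {
    feats <- t(vapply(dataset, function(s)
      regressor_features(proto, s$raw, s$fake),
      numeric(nrow(t(proto$head$W)))))
  }

  models <- list(); hist <- list(); preds <- list()
  for (k in fold_subset) {
    val <- which(folds == k); tr <- which(folds != k)
    if (length(val) == 0 || length(tr) == 0)
      sv_error(sprintf("fold %s has an empty train or validation set", k),
               "surgiview_config_error")
    if (config$freeze_backbones) {
      fit <- train_head(feats, Y, tr, val, config)
      model <- proto
      model$head <- fit$head
      model$scaler <- fit$scaler
    } else {
      fit <- train_joint(dataset, Y, tr, val, config)
      model <- fit$model
    }
    model$trained <- TRUE
    models[[as.character(k)]] <- model
    hist[[as.character(k)]] <- cbind(fold = k, fit$history)
    pv <- t(vapply(val, function(i) {
      if (config$freeze_backbones) {
        f <- (feats[i, ] - model$scaler$center) / model$scaler$scale
        as.numeric(model$head$W %*% f + model$head$b)
      } else {
        predict_params(model, dataset[[i]]$raw,
                       dataset[[i]]$fake)$raw_output
      }
    }, numeric(8)))
    preds[[as.character(k)]] <- list(index = val, raw_output = pv,
                                     normalized = clamp(pv, 0, 1))
  }
  list(models = models, history = do.call(rbind, hist), predictions = preds)
}

# head-only fit on fixed features, standardized on the training fold:
# closed-form ridge warm start, then Adam refinement (which also yields
# the per-epoch loss history)
train_head <- function(feats, Y, tr, val, config) {
  center <- colMeans(feats[tr, , drop = FALSE])
  scale <- apply(feats[tr, , drop = FALSE], 2, sd)
  scale[scale < 1e-8] <- 1
  Z <- sweep(sweep(feats, 2, center), 2, scale, "/")
  head <- ridge_head(Z, Y, tr, config)
  st <- adam_init(head)
  ord_seeds <- child_seeds(config$seed + 101L, config$epochs)
  history <- vector("list", config$epochs)
  mse_of <- function(h, idx) {
    P <- Z[idx, , drop = FALSE] %*% t(h$W) +
      matrix(h$b, length(idx), 8, byrow = TRUE)
    mean((P - Y[idx, , drop = FALSE])^2)
  }
  best <- list(head = head, val = mse_of(head, val))   # warm start = epoch 0
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(ord_seeds[ep], sample(tr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      X <- Z[bt, , drop = FALSE]
      P <- X %*% t(head$W) + matrix(head$b, length(bt), 8, byrow = TRUE)
      E <- 2 * (P - Y[bt, , drop = FALSE]) / (8 * length(bt))
      g <- list(W = t(E) %*% X + 2 * config$weight_decay * head$W,
                b = colSums(E))
      up <- adam_step(head, g, st, config$lr)
      head <- up$params; st <- up$state
    }
    vl <- mse_of(head, val)
    history[[ep]] <- data.frame(epoch = ep, train_loss = mse_of(head, tr),
                                val_loss = vl)
    if (vl < best$val) best <- list(head = head, val = vl)
  }
  list(head = best$head, scaler = list(center = center, scale = scale),
       history = do.call(rbind, history))
}

# closed-form ridge fit of the affine head on given features; lambda is
# expressed through the config weight decay on the per-output objective
ridge_head <- function(feats, Y, tr, config) {
  lam <- config$weight_decay * 8 * length(tr)
  X <- feats[tr, , drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ym <- colMeans(Y[tr, , drop = FALSE])
  Yc <- sweep(Y[tr, , drop = FALSE], 2, ym)
  W <- solve(crossprod(Xc) + lam * diag(ncol(X)), crossprod(Xc, Yc))
  list(W = t(W), b = as.numeric(ym - t(W) %*% mu))
}

# joint end-to-end fit (backbones + head). The initial backbone features
# define a fixed standardization (absorbed into the model's scaler), the
# head is warm-started by a ridge fit on them, and fine-tuning keeps the
# parameters of the best-validation epoch (the warm start counts as
# epoch 0), so fine-tuning can only improve on the linear readout.
train_joint <- function(dataset, Y, tr, val, config) {
  model <- build_regressor(config)
  feats0 <- t(vapply(seq_along(dataset), function(i)
    regressor_features(model, dataset[[i]]$raw, dataset[[i]]$fake),
    numeric(ncol(model$head$W))))
  center <- colMeans(feats0[tr, , drop = FALSE])
  scale <- apply(feats0[tr, , drop = FALSE], 2, sd)
  scale[scale < 1e-8] <- 1
  Z0 <- sweep(sweep(feats0, 2, center), 2, scale, "/")
  model$scaler <- list(center = center, scale = scale)
  model$head <- ridge_head(Z0, Y, tr, config)
  params <- list(raw = layers_params(model$backbone_raw$layers),
                 fake = if (!is.null(model$backbone_fake))
                   layers_params(model$backbone_fake$layers),
                 head = model$head)
  st <- adam_init(params)
  ord_seeds <- child_seeds(config$seed + 101L, config$epochs)
  history <- vector("list", config$epochs)
  d1 <- model$backbone_raw$feature_dim

  fwd_sample <- function(i, keep = FALSE) {
    s <- dataset[[i]]
    if (model$config$branches == "both") {
      fr <- seq_forward(model$backbone_raw$layers, to_signed(s$raw), keep)
      ff <- seq_forward(model$backbone_fake$layers, to_signed(s$fake), keep)
      if (keep) list(f = c(fr$out, ff$out), r = fr, k = ff)
      else c(fr, ff)
    } else {
      img <- if (model$config$branches == "raw_only") s$raw else s$fake
      fr <- seq_forward(model$backbone_raw$layers, to_signed(img), keep)
      if (keep) list(f = fr$out, r = fr, k = NULL) else fr
    }
  }
  predict_scaled <- function(f)
    as.numeric(model$head$W %*% ((f - center) / scale) + model$head$b)
  mse_of <- function(idx) {
    P <- t(vapply(idx, function(i) predict_scaled(fwd_sample(i)),
                  numeric(8)))
    mean((P - Y[idx, , drop = FALSE])^2)
  }

  best <- list(params = params, val = mse_of(val))     # epoch 0
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(ord_seeds[ep], sample(tr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (bt in batches) {
      acc <- tree_zero(params)
      for (i in bt) {
        fw <- fwd_sample(i, keep = TRUE)
        pred <- predict_scaled(fw$f)
        err <- pred - Y[i, ]
        tr_loss <- tr_loss + mean(err^2)
        dy <- 2 * err / (8 * length(bt))
        gh <- list(W = outer(dy, (fw$f - center) / scale), b = dy)
        dfeat <- as.numeric(t(model$head$W) %*% dy) / scale
        gr <- seq_backward(model$backbone_raw$layers, fw$r$caches,
                           dfeat[seq_len(d1)], input_grad = FALSE)
        gk <- if (!is.null(fw$k))
          seq_backward(model$backbone_fake$layers, fw$k$caches,
                       dfeat[d1 + seq_len(d1)], input_grad = FALSE)
        acc <- tree_map2(acc, list(raw = grads_as_params(gr$grads),
                                   fake = if (!is.null(gk))
                                     grads_as_params(gk$grads),
                                   head = gh), `+`)
      }
      acc <- tree_map2(acc, acc, function(a, b) a / length(bt))
      acc$head$W <- acc$head$W + 2 * config$weight_decay * params$head$W
      up <- adam_step(params, acc, st, config$lr)
      params <- up$params; st <- up$state
      model$backbone_raw$layers <-
        layers_set_params(model$backbone_raw$layers, params$raw)
      if (!is.null(model$backbone_fake))
        model$backbone_fake$layers <-
          layers_set_params(model$backbone_fake$layers, params$fake)
      model$head <- params$head
    }
    vl <- mse_of(val)
    history[[ep]] <- data.frame(epoch = ep,
                                train_loss = tr_loss / length(tr),
                                val_loss = vl)
    if (vl < best$val) best <- list(params = params, val = vl)
  }
  params <- best$params
  model$backbone_raw$layers <-
    layers_set_params(model$backbone_raw$layers, params$raw)
  if (!is.null(model$backbone_fake))
    model$backbone_fake$layers <-
      layers_set_params(model$backbone_fake$layers, params$fake)
  model$head <- params$head
  list(model = model, history = do.call(rbind, history))
}
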