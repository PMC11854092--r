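# Residual-network feature extractors. `resnet50` is the standard 50-layer
# plan (7x7/2 stem, 3x3/2 max pool, bottleneck stages of 3/4/6/3 blocks
# with widths 64/128/256/512 and expansion 4, global average pooling to a
# 2048-dimensional feature). `resnet_small` is a reduced backbone for
# desk-scale training: a stride-2 stem and three stages of one basic
# residual block each (widths 32/64/128), feature dimension 128.
# Batch normalization is omitted (convolutions carry biases instead): the
# backbones here are feature extractors trained from scratch at desk
# scale, where the feature-tap contract (global average pooled final
# stage) is what matters, not ImageNet parity.

bottleneck_block <- function(cin, w, stride) {
  convs <- list(
    conv_make(cin, w, 1L, stride = 1L, pad = 0L, act = "relu"),
    conv_make(w, w, 3L, stride = stride, pad = 1L, act = "relu"),
    conv_make(w, 4L * w, 1L, stride = 1L, pad = 0L, act = "linear")
  )
  proj <- if (stride != 1L || cin != 4L * w)
    conv_make(cin, 4L * w, 1L, stride = stride, pad = 0L, act = "linear")
  block_make(convs, proj)
}

basic_block <- function(w) {
  block_make(list(
    conv_make(w, w, 3L, stride = 1L, pad = 1L, act = "relu"),
    conv_make(w, w, 3L, stride = 1L, pad = 1L, act = "linear")
  ))
}

#' Build a residual-network feature extractor
#'
#' @param type `"resnet50"` (feature dimension 2048) or `"resnet_small"`
#'   (feature dimension 128, cheap enough to fine-tune on a CPU).
#' @param seed Weight-initialization seed (He initialization).
#' @param pretrained Must be `FALSE`: pretrained weights cannot be bundled
#'   with this package; requesting them raises an error.
#' @return Object of class `sv_backbone` with fields `layers`,
#'   `feature_dim`, `type`.
#' @export
build_backbone <- function(type = c("resnet_small", "resnet50"), seed = 1,
                           pretrained = FALSE) {
  type <- match.arg(type)
  if (isTRUE(pretrained))
    sv_error(paste0("pretrained weights are not available in this build; ",
                    "backbones train from scratch"),
             "surgiview_config_error")
  layers <- with_seed(seed, {
    if (type == "resnet50") {
      ls <- list(conv_make(3, 64, 7L, stride = 2L, pad = 3L, act = "relu"),
                 list(type = "maxpool", k = 3L, stride = 2L,
                      pad = c(1L, 1L, 1L, 1L)))
      widths <- c(64, 128, 256, 512)
      blocks <- c(3, 4, 6, 3)
      cin <- 64
      for (s in 1:4) {
        for (b in seq_len(blocks[s])) {
          stride <- if (b == 1L && s > 1L) 2L else 1L
          ls[[length(ls) + 1]] <- bottleneck_block(cin, widths[s], stride)
          cin <- 4L * widths[s]
        }
      }
      ls[[length(ls) + 1]] <- list(type = "gap")
      ls
    } else {
      # shallow-and-wide: three residual stages keep the pooled feature
      # close to first-order image statistics (channel means, local
      # contrast), which the display parameters act on most directly
      ls <- list(conv_make(3, 32, 3L, stride = 2L, pad = 1L, act = "relu"),
                 basic_block(32))
      cin <- 32
      for (w in c(64, 128)) {
        ls[[length(ls) + 1]] <- conv_make(cin, w, 3L, stride = 2L,
                                          pad = 1L, act = "relu")
        ls[[length(ls) + 1]] <- basic_block(w)
        cin <- w
      }
      ls[[length(ls) + 1]] <- list(type = "gap")
      ls
    }
  })
  structure(list(type = type, layers = layers,
                 feature_dim = if (type == "resnet50") 2048L else 128L),
            class = "sv_backbone")
}

#' @export
print.sv_backbone <- function(x, ...) {
  cat("<sv_backbone> ", x$type, ", feature_dim=", x$feature_dim,
      ", trainable parameters=",
      format(n_params(layers_params(x$layers)), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Extract a global feature vector from an image
#'
#' Scales the image to the internal [-1, 1] range and runs the backbone;
#' the feature is the global average pooled final convolutional stage.
#' Any square input of at least 32 pixels works (global pooling absorbs
#' the spatial size).
#'
#' @param backbone An `sv_backbone`.
#' @param image RGB array (uint8 scale).
#' @return Numeric vector of length `backbone$feature_dim`.
#' @export
extract_features <- function(backbone, image) {
  stopifnot(inherits(backbone, "sv_backbone"))
  assert_rgb(image)
  if (min(dim(image)[1:2]) < 32)
    sv_error("backbone input must be at least 32 x 32 pixels",
             "surgiview_input_error")
  seq_forward(backbone$layers, to_signed(image))
}

#' Concatenate the two branch features into the fused vector
#'
#' Raw-branch features come first, fake-branch features second; the order
#' is fixed and meaningful (reordering the inputs changes the output).
#'
#' @param raw_features,fake_features Equal-length numeric vectors.
#' @return Numeric vector of length `2 * length(raw_features)`.
#' @export
fuse <- function(raw_features, fake_features) {
  if (length(raw_features) != length(fake_features))
    sv_error("branch feature lengths differ", "surgiview_input_error")
  c(raw_features, fake_features)
}
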