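# A width-1.0 MobileNetV2-style feature extractor, defined explicitly so the
# package can build, count, and run it without a deep-learning framework.
# Structure: 3x3 stride-2 stem to 32 channels, seventeen inverted-residual
# bottleneck blocks with expansion/channels/repeats/stride settings
# (1,16,1,1) (6,24,2,2) (6,32,3,2) (6,64,4,2) (6,96,3,1) (6,160,3,2)
# (6,320,1,1), and a final 1x1 expansion to 1280 channels; every convolution
# is bias-free and followed by batch normalization, with ReLU6 activations
# except after the linear bottleneck projections.  Output spatial size is
# input_size / 32.

.relu6 <- function(x) pmin(pmax(x, 0), 6)

# layer constructors: weights are stored pre-flattened for the C++ kernels
.new_conv <- function(cin, cout, k, stride, gain = 2) {
  sd <- sqrt(gain / (k * k * cin))
  w <- matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout)
  list(type = "conv", w = w, k = k, stride = stride, pad = (k - 1L) %/% 2L,
       cin = cin, cout = cout)
}

.new_dwconv <- function(c, k, stride, gain = 2) {
  sd <- sqrt(gain / (k * k))
  w <- matrix(rnorm(k * k * c, 0, sd), k * k, c)
  list(type = "dwconv", w = w, k = k, stride = stride, pad = (k - 1L) %/% 2L,
       cin = c, cout = c)
}

.new_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = rep(0, c),
       mean = rep(0, c), var = rep(1, c))
}

.bn_apply <- function(x, bn, eps = 1e-5) {
  hw <- dim(x)[1] * dim(x)[2]
  scale <- bn$gamma / sqrt(bn$var + eps)
  shift <- bn$beta - bn$mean * scale
  x * rep(scale, each = hw) + rep(shift, each = hw)
}

.mobilenet_v2_setting <- list(
  c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
  c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))

#' Build the randomly initialized backbone feature extractor
#'
#' Convolutions that feed a ReLU6 use He-normal initialization; the linear
#' bottleneck projections use Xavier-style gain 1 so activations neither
#' explode nor die through the deep stack at random initialization (relevant
#' because the package trains with a frozen backbone).
#'
#' @param in_channels 1 for grayscale energy images, 3 when replicating to
#'   RGB for externally trained weights.
#' @param seed RNG seed for the initialization.
#' @return A `gait_backbone` list of blocks, each a list of layers.
#' @export
build_backbone <- function(in_channels = 1L, seed = 1L) {
  with_private_seed(seed, {
    blocks <- list()
    blocks[[1]] <- list(kind = "stem",
                        layers = list(.new_conv(in_channels, 32L, 3L, 2L),
                                      .new_bn(32L)))
    cin <- 32L
    for (set in .mobilenet_v2_setting) {
      t <- set[1]; cout <- set[2]; n <- set[3]; s <- set[4]
      for (i in seq_len(n)) {
        stride <- if (i == 1L) s else 1L
        hidden <- as.integer(cin * t)
        layers <- list()
        if (t != 1L) {
          layers <- c(layers, list(.new_conv(cin, hidden, 1L, 1L), .new_bn(hidden)))
        }
        layers <- c(layers, list(.new_dwconv(hidden, 3L, stride), .new_bn(hidden),
                                 .new_conv(hidden, cout, 1L, 1L, gain = 1),
                                 .new_bn(cout)))
        blocks[[length(blocks) + 1L]] <- list(
          kind = "bottleneck", expand = (t != 1L),
          residual = (stride == 1L && cin == cout), layers = layers)
        cin <- cout
      }
    }
    blocks[[length(blocks) + 1L]] <- list(
      kind = "final", layers = list(.new_conv(cin, 1280L, 1L, 1L), .new_bn(1280L)))
    structure(list(blocks = blocks, in_channels = as.integer(in_channels),
                   out_channels = 1280L, stride = 32L, seed = as.integer(seed)),
              class = "gait_backbone")
  })
}

.conv_apply <- function(x, ly) {
  if (ly$type == "conv") {
    conv2d_fwd_cpp(x, ly$w, ly$k, ly$k, ly$stride, ly$pad)
  } else {
    dwconv2d_fwd_cpp(x, ly$w, ly$k, ly$k, ly$stride, ly$pad)
  }
}

#' Run the backbone on one image
#'
#' @param backbone a [build_backbone()] object.
#' @param x `(H, W, C)` array on \[0, 1\], or an `(H, W)` matrix for a
#'   single channel.
#' @return Feature array `(H/32, W/32, 1280)`.
#' @export
backbone_forward <- function(backbone, x) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (dim(x)[3] != backbone$in_channels) {
    if (dim(x)[3] == 1L && backbone$in_channels == 3L) {
      x <- array(rep(x, 3L), c(dim(x)[1], dim(x)[2], 3L))
    } else {
      stop("input has ", dim(x)[3], " channels; backbone expects ",
           backbone$in_channels)
    }
  }
  for (blk in backbone$blocks) {
    if (blk$kind == "bottleneck") {
      inp <- x
      ls <- blk$layers
      i <- 1L
      if (blk$expand) {
        x <- .relu6(.bn_apply(.conv_apply(x, ls[[1]]), ls[[2]])); i <- 3L
      }
      x <- .relu6(.bn_apply(.conv_apply(x, ls[[i]]), ls[[i + 1L]]))
      x <- .bn_apply(.conv_apply(x, ls[[i + 2L]]), ls[[i + 3L]])  # linear
      if (blk$residual) x <- x + inp
    } else {
      x <- .relu6(.bn_apply(.conv_apply(x, blk$layers[[1]]), blk$layers[[2]]))
    }
  }
  x
}

# trainable parameter count of a layer list (BN counts gamma + beta)
.layers_param_count <- function(layers) {
  sum(vapply(layers, function(ly) {
    switch(ly$type,
           conv = , dwconv = length(ly$w) + length(ly$bias %||% numeric(0)),
           bn = length(ly$gamma) + length(ly$beta),
           dense = length(ly$w) + length(ly$b),
           stop("unknown layer type"))
  }, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gait_backbone <- function(x, ...) {
  n <- sum(vapply(x$blocks, function(b) .layers_param_count(b$layers), numeric(1)))
  cat(sprintf("<gait_backbone: %d blocks, %d-channel input, %s trainable parameters>\n",
              length(x$blocks), x$in_channels, format(n, big.mark = ",")))
  invisible(x)
}
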