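# Improved convolutional block attention (parallel CBAM variant).
#
# Channel attention: a shared two-layer MLP applied to the global average-
# and max-pooled channel descriptors, summed, sigmoid.  Spatial attention:
# per-pixel mean and max over channels stacked into a 2-channel map, a 7x7
# depthwise convolution over that stack, a 1x1 pointwise convolution to one
# channel, sigmoid.  Both maps are computed from the ORIGINAL input and
# combined multiplicatively (parallel topology) - unlike serial CBAM, where
# spatial attention sees the channel-reweighted features.
#
# Feature maps here are (C, H, W) arrays (channels first).

#' Attention block configuration
#'
#' @param channels number of feature channels the block sees.
#' @param reduction bottleneck ratio of the shared MLP (hidden size
#'   `channels / reduction`).
#' @param spatial_kernel depthwise kernel size of the spatial branch.
#' @return An `icbam_config` list.
#' @export
icbam_config <- function(channels = 1280L, reduction = 16L, spatial_kernel = 7L) {
  channels <- as.integer(channels); reduction <- as.integer(reduction)
  if (channels %/% reduction < 1L) stop("channels/reduction must be >= 1")
  structure(list(channels = channels, reduction = reduction,
                 hidden = channels %/% reduction,
                 spatial_kernel = as.integer(spatial_kernel)),
            class = "icbam_config")
}

#' Initialize attention block parameters
#'
#' MLP and convolution weights are He-normal; all biases start at zero.
#'
#' @param config an [icbam_config()].
#' @param seed RNG seed.
#' @return An `icbam_params` list (`W0`, `b0`, `W1`, `b1` for the MLP;
#'   `dw`, `b_dw`, `pw`, `b_pw` for the spatial branch).
#' @export
icbam_init <- function(config, seed = 1L) {
  C <- config$channels; Ch <- config$hidden; k <- config$spatial_kernel
  with_private_seed(seed, {
    structure(list(
      W0 = matrix(rnorm(Ch * C, 0, sqrt(2 / C)), Ch, C), b0 = rep(0, Ch),
      W1 = matrix(rnorm(C * Ch, 0, sqrt(2 / Ch)), C, Ch), b1 = rep(0, C),
      dw = matrix(rnorm(k * k * 2, 0, sqrt(2 / (k * k))), k * k, 2),
      b_dw = rep(0, 2),
      pw = rnorm(2, 0, 1), b_pw = 0,
      config = config), class = "icbam_params")
  })
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.as_chw <- function(F) {
  if (length(dim(F)) != 3L) stop("feature map must be a (C, H, W) array")
  F
}

#' Channel attention weights
#'
#' `M_c = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` with one shared MLP
#' (`W0`: C -> C/r, rectifier, `W1`: C/r -> C); pooling is global over the
#' spatial grid.
#'
#' @param F `(C, H, W)` feature array.
#' @param params an [icbam_init()] parameter set.
#' @return `(C, 1, 1)` array of weights in (0, 1).
#' @export
channel_attention <- function(F, params) {
  F <- .as_chw(F)
  C <- dim(F)[1]
  if (C != params$config$channels) stop("channel mismatch")
  m <- matrix(F, C, dim(F)[2] * dim(F)[3])
  mlp <- function(v) {
    as.numeric(params$W1 %*% pmax(params$W0 %*% v + params$b0, 0) + params$b1)
  }
  s <- mlp(rowMeans(m)) + mlp(apply(m, 1, max))
  array(.sigmoid(s), c(C, 1L, 1L))
}

#' Spatial attention weights
#'
#' Per-pixel mean and max over channels are stacked into a 2-channel map;
#' a depthwise `k x k` convolution (padding `(k-1)/2`) runs over the stack,
#' a pointwise 1x1 convolution reduces to one channel, and a sigmoid maps to
#' (0, 1).
#'
#' @param F `(C, H, W)` feature array.
#' @param params an [icbam_init()] parameter set.
#' @return `(1, H, W)` array of weights in (0, 1).
#' @export
spatial_attention <- function(F, params) {
  F <- .as_chw(F)
  C <- dim(F)[1]; H <- dim(F)[2]; W <- dim(F)[3]
  m <- matrix(F, C, H * W)
  stack <- array(0, c(H, W, 2L))
  stack[, , 1] <- matrix(colMeans(m), H, W)
  stack[, , 2] <- matrix(apply(m, 2, max), H, W)
  k <- params$config$spatial_kernel
  U <- dwconv2d_fwd_cpp(stack, params$dw, k, k, 1L, (k - 1L) %/% 2L)
  U[, , 1] <- U[, , 1] + params$b_dw[1]
  U[, , 2] <- U[, , 2] + params$b_dw[2]
  v <- params$pw[1] * U[, , 1] + params$pw[2] * U[, , 2] + params$b_pw
  array(.sigmoid(v), c(1L, H, W))
}

#' Apply the parallel attention block
#'
#' `F2 = M_c(F) * M_s(F) * F` with broadcasting (`M_c` over space, `M_s`
#' over channels); both maps are computed from the original `F`, so the
#' result does not depend on the order in which they are evaluated.
#'
#' @param F `(C, H, W)` feature array.
#' @param params an [icbam_init()] parameter set.
#' @return Re-weighted `(C, H, W)` feature array.
#' @export
apply_icbam <- function(F, params) {
  F <- .as_chw(F)
  C <- dim(F)[1]; H <- dim(F)[2]; W <- dim(F)[3]
  Mc <- as.numeric(channel_attention(F, params))
  Ms <- as.numeric(spatial_attention(F, params))
  F * Mc * rep(Ms, each = C)
}

#' Serial CBAM reference using the same parameters
#'
#' Channel attention first, then spatial attention computed on the already
#' re-weighted features - the serial topology this block's parallel design
#' departs from.  Used to demonstrate the two differ.
#'
#' @inheritParams apply_icbam
#' @return Re-weighted `(C, H, W)` feature array.
#' @export
apply_cbam_serial <- function(F, params) {
  F <- .as_chw(F)
  C <- dim(F)[1]
  F1 <- F * as.numeric(channel_attention(F, params))
  F1 * rep(as.numeric(spatial_attention(F1, params)), each = C)
}

#' Trainable parameter count of the attention variants
#'
#' Counts the parameters each attention flavour adds at a given channel
#' width: the parallel block (`icbam`), serial `cbam` (ordinary 7x7 spatial
#' convolution), `se` (channel MLP only), `eca` (a k-tap 1-D convolution
#' across channels, `k = 5` at 1280 channels), or `none`.
#'
#' @param type attention flavour.
#' @param channels feature channels.
#' @param reduction MLP bottleneck ratio.
#' @param spatial_kernel spatial kernel size.
#' @return Integer parameter count.
#' @export
attention_param_count <- function(type = c("icbam", "cbam", "se", "eca", "none"),
                                  channels = 1280L, reduction = 16L,
                                  spatial_kernel = 7L) {
  type <- match.arg(type)
  C <- channels; Ch <- channels %/% reduction; k <- spatial_kernel
  mlp <- Ch * C + Ch + C * Ch + C
  switch(type,
         icbam = mlp + (k * k * 2 + 2) + (2 + 1),
         cbam  = mlp + (k * k * 2 + 1),
         se    = mlp,
         eca   = {  # adaptive odd kernel ~ log2(C)/2 + 1/2
           kk <- max(3L, as.integer(round((log2(C) + 1) / 2)))
           if (kk %% 2L == 0L) kk <- kk + 1L
           kk
         },
         none  = 0L)
}
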