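# The dual-branch classifier: one shared backbone feeds (A) its raw
# convolutional features and (B) the same features re-weighted by the
# parallel attention block; the branches are fused elementwise and classified
# by a depthwise-separable head (depthwise 3x3 + pointwise bottleneck,
# flatten, dense, batch-norm, rectifier, dropout, dense, softmax).
#
# The branches share one backbone: two independent stacks would exceed the
# model's parameter budget (~3 M at 256 input) by a full backbone.

#' Classifier model configuration
#'
#' @param input_size input side length in pixels; must be divisible by 32.
#' @param in_channels 1 for grayscale energy images.
#' @param n_classes number of gait classes.
#' @param attention attention flavour of branch B: `"icbam"` (default),
#'   `"cbam"`, `"se"`, `"eca"`, or `"none"`.
#' @param reduction MLP bottleneck ratio of the attention block.
#' @param head_pointwise_channels output channels of the head's pointwise
#'   convolution.
#' @param head_dense_units width of the head's first dense layer.
#' @param dropout dropout rate before the final dense layer, in \[0, 1).
#' @param fusion branch fusion operator, `"sum"` (default, keeps 1280
#'   channels) or `"concat"`.
#' @param pretrained load externally trained backbone weights (requires a
#'   weight file; see [apply_transfer_learning()]).
#' @param freeze_backbone exclude backbone parameters from training.
#' @param seed RNG seed for all weight initialization.
#' @return A `gait_model_config` list.
#' @export
model_config <- function(input_size = 256L, in_channels = 1L, n_classes = 5L,
                         attention = "icbam", reduction = 16L,
                         head_pointwise_channels = 32L,
                         head_dense_units = 256L, dropout = 0.2,
                         fusion = c("sum", "concat"), pretrained = FALSE,
                         freeze_backbone = FALSE, seed = 1L) {
  fusion <- match.arg(fusion)
  attention <- match.arg(attention, c("icbam", "cbam", "se", "eca", "none"))
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 attention = attention, reduction = as.integer(reduction),
                 head_pointwise_channels = as.integer(head_pointwise_channels),
                 head_dense_units = as.integer(head_dense_units),
                 dropout = dropout, fusion = fusion,
                 pretrained = isTRUE(pretrained),
                 freeze_backbone = isTRUE(freeze_backbone),
                 seed = as.integer(seed)),
            class = "gait_model_config")
}

.head_init <- function(feat_channels, spatial, pointwise, units, n_classes) {
  nin <- pointwise * spatial * spatial
  list(dw = matrix(rnorm(9L * feat_channels, 0, sqrt(2 / 9)), 9L, feat_channels),
       b_dw = rep(0, feat_channels),
       pw = matrix(rnorm(feat_channels * pointwise, 0, sqrt(2 / feat_channels)),
                   feat_channels, pointwise),
       b_pw = rep(0, pointwise),
       W1 = matrix(rnorm(units * nin, 0, sqrt(2 / nin)), units, nin),
       b1 = rep(0, units),
       bn_gamma = rep(1, units), bn_beta = rep(0, units),
       bn_mean = rep(0, units), bn_var = rep(1, units),
       W2 = matrix(rnorm(n_classes * units, 0, sqrt(1 / units)), n_classes, units),
       b2 = rep(0, n_classes))
}

#' Build the dual-branch gait classifier
#'
#' @param config a [model_config()].
#' @return A `gait_model` list: `config`, `backbone`, `attention` parameters,
#'   `head` parameters, and bookkeeping (`feat_channels`, `feat_spatial`).
#' @export
build_model <- function(config = model_config()) {
  if (config$pretrained) {
    stop("no pretrained backbone weights are bundled (offline build); ",
         "build with pretrained = FALSE and optionally load weights via ",
         "apply_transfer_learning()")
  }
  backbone <- build_backbone(config$in_channels, seed = config$seed)
  att_cfg <- icbam_config(1280L, config$reduction)
  attention <- if (config$attention %in% c("icbam", "cbam")) {
    p <- icbam_init(att_cfg, seed = config$seed + 1L)
    p$type <- config$attention
    if (config$attention == "cbam") {
      # serial CBAM uses an ordinary 7x7 spatial convolution (2 -> 1)
      p$dw <- NULL; p$b_dw <- NULL
      p$conv7 <- with_private_seed(config$seed + 1L,
                                   matrix(rnorm(98, 0, sqrt(2 / 98)), 98, 1))
      p$b_conv7 <- 0
    }
    p
  } else {
    structure(list(type = config$attention,
                   n_params = attention_param_count(config$attention, 1280L,
                                                    config$reduction)),
              class = "attention_stub")
  }
  feat_channels <- if (config$fusion == "concat" &&
                       !(config$attention %in% c("none"))) 2560L else 1280L
  spatial <- config$input_size %/% 32L
  head <- with_private_seed(config$seed + 2L,
    .head_init(feat_channels, spatial, config$head_pointwise_channels,
               config$head_dense_units, config$n_classes))
  structure(list(config = config, backbone = backbone, attention = attention,
                 head = head, feat_channels = feat_channels,
                 feat_spatial = spatial, class_names = NULL),
            class = "gait_model")
}

.attention_n_params <- function(att) {
  if (inherits(att, "attention_stub")) return(att$n_params)
  n <- length(att$W0) + length(att$b0) + length(att$W1) + length(att$b1)
  if (identical(att$type, "cbam")) {
    n + length(att$conv7) + 1L
  } else {
    n + length(att$dw) + length(att$b_dw) + length(att$pw) + length(att$b_pw)
  }
}

.head_n_params <- function(h) {
  length(h$dw) + length(h$b_dw) + length(h$pw) + length(h$b_pw) +
    length(h$W1) + length(h$b1) + length(h$bn_gamma) + length(h$bn_beta) +
    length(h$W2) + length(h$b2)
}

#' Count trainable model parameters
#'
#' Convolution weights, dense weights and biases, and batch-norm scale/shift
#' count; batch-norm running statistics do not.
#'
#' @param model a `gait_model`, `gait_backbone`, or attention/head parameter
#'   list.
#' @param trainable_only when `TRUE` (default), parameters of a frozen
#'   backbone are excluded.
#' @return Integer count of scalar parameters.
#' @export
count_parameters <- function(model, trainable_only = TRUE) {
  if (inherits(model, "gait_backbone")) {
    return(sum(vapply(model$blocks,
                      function(b) .layers_param_count(b$layers), numeric(1))))
  }
  stopifnot(inherits(model, "gait_model"))
  n_bb <- count_parameters(model$backbone)
  if (trainable_only && model$config$freeze_backbone) n_bb <- 0
  n_bb + .attention_n_params(model$attention) + .head_n_params(model$head)
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model: %dx%d/%d-ch input, %d classes, attention=%s, fusion=%s>\n",
              x$config$input_size, x$config$input_size, x$config$in_channels,
              x$config$n_classes, x$config$attention, x$config$fusion))
  cat(sprintf("  trainable parameters: %s (%.2f M)%s\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6,
              if (x$config$freeze_backbone) " [backbone frozen]" else ""))
  invisible(x)
}

#' Extract backbone features of one energy image
#'
#' @param model a `gait_model`.
#' @param img `(H, W)` matrix on \[0, 255\] (an FEI) or `(H, W, C)` array.
#' @return Feature array `(C=1280, H/32, W/32)`, channels first.
#' @export
model_features <- function(model, img) {
  x <- unclass(img) / 255
  f <- backbone_forward(model$backbone, x)   # (h, w, C)
  aperm(f, c(3, 1, 2))
}

#' Forward pass of the full classifier
#'
#' Runs the backbone, both branches, fusion, and the head in evaluation mode
#' (batch-norm running statistics, no dropout).
#'
#' @param model a `gait_model`.
#' @param img `(H, W)` matrix on \[0, 255\].
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
model_forward <- function(model, img) {
  Fc <- model_features(model, img)                  # (C, h, w)
  d <- dim(Fc)
  F4 <- array(Fc, c(d, 1L))
  out <- trainable_forward(model, F4, training = FALSE)
  p <- as.numeric(out$probs)
  names(p) <- model$class_names %||% paste0("class", seq_along(p))
  p
}

#' Load and freeze externally trained backbone weights
#'
#' Replaces the model's backbone parameters with those serialized in
#' `weights_source` (an RDS file holding a `gait_backbone`, e.g. from a
#' previous [build_model()] run), freezes the backbone, and leaves the
#' attention block and head trainable at their fresh initialization.
#'
#' @param model a `gait_model`.
#' @param weights_source path to an RDS file, or a `gait_backbone` object.
#' @return The model with loaded, frozen backbone.
#' @export
apply_transfer_learning <- function(model, weights_source) {
  bb <- if (inherits(weights_source, "gait_backbone")) weights_source
        else readRDS(weights_source)
  if (!inherits(bb, "gait_backbone")) stop("weights_source is not a gait_backbone")
  mism <- character(0)
  for (i in seq_along(model$backbone$blocks)) {
    old <- model$backbone$blocks[[i]]$layers
    new <- bb$blocks[[i]]$layers
    for (j in seq_along(old)) {
      if (old[[j]]$type != new[[j]]$type ||
          !identical(dim(old[[j]]$w %||% matrix(0)), dim(new[[j]]$w %||% matrix(0)))) {
        mism <- c(mism, sprintf("block %d layer %d (%s)", i, j, old[[j]]$type))
      }
    }
  }
  if (length(mism) > 0) {
    stop("backbone weight shape mismatch in: ", paste(mism, collapse = ", "))
  }
  model$backbone <- bb
  model$config$freeze_backbone <- TRUE
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file with a JSON sidecar describing the
#' configuration.
#'
#' @param model a `gait_model`.
#' @param path checkpoint path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model$config[setdiff(names(model$config), "")],
                       paste0(sub("\\.rds$", "", path), "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "gait_model")) stop("not a gait_model checkpoint")
  m
}
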