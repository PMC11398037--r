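# Training loop (Adam, cross-entropy, stratified 80/20 split) and the
# evaluation metrics: overall accuracy plus macro-averaged per-class
# precision, sensitivity, specificity, and F1, all reported in percent.

#' Training configuration
#'
#' Defaults follow the standard recipe for this model family: Adam,
#' cross-entropy loss, learning rate 1e-4, batch size 32, 100 epochs,
#' stratified 80/20 train/test split, dropout handled by the model config.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (>= 1).
#' @param epochs training epochs.
#' @param train_frac fraction of samples used for training (rest for test).
#' @param seed RNG seed for the split, shuffling, and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         epochs = 100L, train_frac = 0.8, seed = 1L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must lie in (0, 1)")
  structure(list(optimizer = "adam", loss = "cross-entropy",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), train_frac = train_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/test split
#'
#' Splits per class so proportions are preserved; the two parts are disjoint
#' and their union is the input.
#'
#' @param samples list of samples, each with a `label` element.
#' @param config a [train_config()] (uses `train_frac` and `seed`), or a
#'   numeric train fraction.
#' @param seed RNG seed when `config` is a plain fraction.
#' @return List with `train` and `test` sample lists.
#' @export
split_dataset <- function(samples, config = train_config(), seed = NULL) {
  if (is.numeric(config)) config <- train_config(train_frac = config,
                                                 seed = seed %||% 1L)
  labels <- vapply(samples, function(s) as.character(s$label), character(1))
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("every class needs at least 2 samples; got: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  idx_train <- with_private_seed(config$seed, {
    unlist(lapply(split(seq_along(samples), labels), function(ix) {
      n_tr <- round(config$train_frac * length(ix))
      n_tr <- max(1L, min(length(ix) - 1L, n_tr))
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  list(train = samples[sort(idx_train)],
       test = samples[sort(setdiff(seq_along(samples), idx_train))])
}

.one_hot <- function(labels, class_names) {
  Y <- matrix(0, length(class_names), length(labels),
              dimnames = list(class_names, NULL))
  Y[cbind(match(labels, class_names), seq_along(labels))] <- 1
  Y
}

# backbone features of a sample list, cached as a list of (C, h, w) arrays
.feature_cache <- function(model, samples, verbose = FALSE) {
  lapply(seq_along(samples), function(i) {
    if (verbose && i %% 25L == 0L) message("  features ", i, "/", length(samples))
    model_features(model, samples[[i]]$fei)
  })
}

#' Train the classifier on labeled energy images
#'
#' Trains the attention block and head with Adam on cross-entropy loss; the
#' backbone is frozen (its features are computed once and cached), following
#' the transfer-learning regime.  All randomness (shuffling, dropout) is
#' seeded.
#'
#' @param model a [build_model()] model.
#' @param train_set list of samples, each `list(fei = <256x256 matrix on
#'   [0,255]>, label = <class>)`.
#' @param config a [train_config()].
#' @param features optional precomputed feature cache (list of `(C, h, w)`
#'   arrays aligned with `train_set`), e.g. to reuse across runs.
#' @param verbose print per-epoch progress.
#' @return List with the trained `model` and `history` (data frame of
#'   per-epoch loss and training accuracy).
#' @export
train_model <- function(model, train_set, config = train_config(),
                        features = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "gait_model"))
  labels <- vapply(train_set, function(s) as.character(s$label), character(1))
  class_names <- model$class_names %||% sort(unique(labels))
  if (length(class_names) != model$config$n_classes) {
    stop("model expects ", model$config$n_classes, " classes; training data has ",
         length(class_names))
  }
  model$class_names <- class_names
  if (is.null(features)) features <- .feature_cache(model, train_set, verbose)
  n <- length(train_set)
  fd <- dim(features[[1]])
  params <- .trainable_params(model)
  state <- list(t = 0L, m = list(), v = list())
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  momentum <- 0.1

  with_private_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0; n_batches <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1L, n)]
        B <- length(ix)
        F4 <- array(0, c(fd, B))
        for (b in seq_len(B)) F4[, , , b] <- features[[ix[b]]]
        model <- .set_trainable_params(model, params)
        fw <- trainable_forward(model, F4, training = TRUE)
        Y <- .one_hot(labels[ix], class_names)
        pt <- fw$probs[cbind(match(labels[ix], class_names), seq_len(B))]
        loss <- -mean(log(pmax(pt, 1e-12)))
        if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep)
        grads <- trainable_backward(model, fw$cache, Y)
        upd <- .adam_step(params, grads, state, config$learning_rate)
        params <- upd$params; state <- upd$state
        if (!is.null(fw$batch_mu)) {
          model$head$bn_mean <- (1 - momentum) * model$head$bn_mean +
            momentum * fw$batch_mu
          model$head$bn_var <- (1 - momentum) * model$head$bn_var +
            momentum * fw$batch_va * B / max(1L, B - 1L)
        }
        ep_loss <- ep_loss + loss
        ep_hits <- ep_hits + sum(max.col(t(fw$probs)) == match(labels[ix], class_names))
        n_batches <- n_batches + 1L
      }
      history <- rbind(history, data.frame(
        epoch = ep, loss = ep_loss / n_batches, accuracy = ep_hits / n))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                        ep_loss / n_batches, ep_hits / n))
      }
    }
  })
  model <- .set_trainable_params(model, params)
  list(model = model, history = history)
}

#' Predict class labels for energy-image samples
#'
#' @param model a trained `gait_model`.
#' @param samples list of samples with `fei` elements (labels optional).
#' @param features optional precomputed feature cache.
#' @param batch_size evaluation batch size.
#' @return Character vector of predicted class labels.
#' @export
predict_classes <- function(model, samples, features = NULL, batch_size = 32L) {
  if (is.null(model$class_names)) stop("model has no class names; train it first")
  if (is.null(features)) features <- .feature_cache(model, samples)
  fd <- dim(features[[1]])
  out <- character(length(samples))
  for (start in seq(1L, length(samples), by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, length(samples))
    F4 <- array(0, c(fd, length(ix)))
    for (b in seq_along(ix)) F4[, , , b] <- features[[ix[b]]]
    fw <- trainable_forward(model, F4, training = FALSE)
    out[ix] <- model$class_names[max.col(t(fw$probs))]
  }
  out
}

#' Confusion matrix of predictions against truth
#'
#' @param truth character vector of true labels, or a trained model (then
#'   `predicted` is the test sample list and predictions are computed).
#' @param predicted character vector of predicted labels, or the test set.
#' @param class_names class ordering; defaults to the sorted union.
#' @return A `confusion_matrix`: integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, class_names = NULL) {
  if (inherits(truth, "gait_model")) {
    model <- truth
    test_set <- predicted
    predicted <- predict_classes(model, test_set)
    truth <- vapply(test_set, function(s) as.character(s$label), character(1))
    class_names <- class_names %||% model$class_names
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  class_names <- class_names %||% sort(unique(c(truth, predicted)))
  k <- length(class_names)
  cm <- matrix(0L, k, k, dimnames = list(true = class_names,
                                         predicted = class_names))
  for (i in seq_along(truth)) {
    cm[match(truth[i], class_names), match(predicted[i], class_names)] <-
      cm[match(truth[i], class_names), match(predicted[i], class_names)] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is the diagonal sum over the total count.  Per class
#' *i*: precision `TP/(TP+FP)`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, and F1 `2PR/(P+R)`; macro metrics are their
#' unweighted means.  A class whose denominator is zero contributes 0 with a
#' warning.  All values are percentages.
#'
#' @param cm a [confusion_matrix()].
#' @return A `metrics_report` list: `accuracy`, `macro_precision`,
#'   `macro_sensitivity`, `macro_specificity`, `macro_f1`, and a `per_class`
#'   data frame.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix")
  k <- nrow(cm)
  TP <- diag(cm)
  FP <- colSums(cm) - TP
  FN <- rowSums(cm) - TP
  TN <- N - TP - FP - FN
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning("zero denominator for ", what, " in class(es): ",
              paste(rownames(cm)[bad], collapse = ", "), "; contributing 0")
    }
    ifelse(bad, 0, num / den)
  }
  prec <- safe_div(TP, TP + FP, "precision")
  sens <- safe_div(TP, TP + FN, "sensitivity")
  spec <- safe_div(TN, TN + FP, "specificity")
  f1 <- safe_div(2 * prec * sens, prec + sens, "F1")
  per_class <- data.frame(class = rownames(cm) %||% paste0("class", seq_len(k)),
                          precision = 100 * prec, sensitivity = 100 * sens,
                          specificity = 100 * spec, f1 = 100 * f1,
                          row.names = NULL)
  structure(list(accuracy = 100 * sum(TP) / N,
                 macro_precision = 100 * mean(prec),
                 macro_sensitivity = 100 * mean(sens),
                 macro_specificity = 100 * mean(spec),
                 macro_f1 = 100 * mean(f1),
                 per_class = per_class, n = N),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report (n=%d): accuracy %.2f%%, macro ",
                     "precision %.2f%%, sensitivity %.2f%%, specificity ",
                     "%.2f%%, F1 %.2f%%>\n"),
              x$n, x$accuracy, x$macro_precision, x$macro_sensitivity,
              x$macro_specificity, x$macro_f1))
  invisible(x)
}

#' Evaluate a trained model on a test set
#'
#' @param model a trained `gait_model`.
#' @param test_set list of samples with `fei` and `label`.
#' @return List with `confusion`, `metrics`, and `predictions`.
#' @export
evaluate_model <- function(model, test_set) {
  pred <- predict_classes(model, test_set)
  truth <- vapply(test_set, function(s) as.character(s$label), character(1))
  cm <- confusion_matrix(truth, pred, model$class_names)
  list(confusion = cm, metrics = metrics_from_confusion(cm),
       predictions = pred)
}
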