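# Shared fixtures, memoised so expensive objects are built once per session.

.fixture_env <- new.env(parent = emptyenv())

# silhouette frames are stored as integer matrices; coerce expectations
int_mat <- function(m) {
  storage.mode(m) <- "integer"
  m
}

# strip class/kind/flag attributes, keeping only dim, for value comparisons
plain <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a clean normal-gait walker with known period
walker_fixture <- function() {
  fixture("walker20", function() {
    generate_walker_sequence(walker_params("normal", cycle_frames = 20L,
                                           n_cycles = 3L, seed = 1L))
  })
}

# random binary toy cycles for template oracles
toy_cycle <- function(n_frames = 8L, size = 16L, seed = 1L, p = 0.4) {
  set.seed(seed)
  lapply(seq_len(n_frames), function(i) {
    matrix(255 * rbinom(size * size, 1, p), size, size)
  })
}

# templates of one real walker cycle (for fusion tests)
walker_templates_fixture <- function() {
  fixture("walker_tpl", function() {
    s <- walker_fixture()
    cyc <- segment_cycles(s, detect_troughs(aspect_ratio_series(s)))[[1]]
    compute_templates(cyc)
  })
}

# exact constrained least squares on the simplex by active-set enumeration:
# minimize ||X w - t||^2 s.t. w >= 0, sum w = 1 (independent oracle)
simplex_cls_oracle <- function(X, t) {
  p <- ncol(X)
  best <- NULL
  for (mask in 1:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    XS <- X[, S, drop = FALSE]
    G <- crossprod(XS); b <- crossprod(XS, t)
    A <- rbind(cbind(2 * G, rep(1, length(S))), c(rep(1, length(S)), 0))
    sol <- tryCatch(solve(A, c(2 * b, 1)), error = function(e) NULL)
    if (is.null(sol)) next
    wS <- sol[seq_along(S)]
    if (any(wS < -1e-9)) next
    w <- numeric(p); w[S] <- pmax(wS, 0); w <- w / sum(w)
    cost <- sum((X %*% w - t)^2)
    if (is.null(best) || cost < best$cost) best <- list(weights = w, cost = cost)
  }
  best
}

# tiny fabricated model exposing only the trainable part (attention + head)
tiny_trainable_model <- function(C = 8L, spatial = 4L, pointwise = 3L,
                                 units = 10L, n_classes = 3L, seed = 3L,
                                 attention = "icbam", dropout = 0) {
  att <- if (attention == "icbam") {
    icbam_init(icbam_config(C, 2L), seed = seed)
  } else {
    structure(list(type = "none", n_params = 0L), class = "attention_stub")
  }
  head <- withr::with_seed(seed + 1L,
    pathogait:::.head_init(C, spatial, pointwise, units, n_classes))
  structure(list(config = list(attention = attention, dropout = dropout,
                               n_classes = n_classes),
                 attention = att, head = head),
            class = "gait_model")
}

# brute-force per-sample metric oracle: tally TP/TN/FP/FN by looping over
# samples, then apply the macro formulas directly
.metrics_oracle <- function(truth, pred, classes) {
  n <- length(classes)
  prec <- sens <- spec <- f1 <- numeric(n)
  for (k in seq_len(n)) {
    tp <- tn <- fp <- fn <- 0
    for (i in seq_along(truth)) {
      is_k <- truth[i] == classes[k]; said_k <- pred[i] == classes[k]
      if (is_k && said_k) tp <- tp + 1
      if (!is_k && !said_k) tn <- tn + 1
      if (!is_k && said_k) fp <- fp + 1
      if (is_k && !said_k) fn <- fn + 1
    }
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[k] <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1[k] <- if (prec[k] + sens[k] > 0) 2 * prec[k] * sens[k] / (prec[k] + sens[k]) else 0
  }
  list(accuracy = 100 * mean(truth == pred), precision = 100 * mean(prec),
       sensitivity = 100 * mean(sens), specificity = 100 * mean(spec),
       f1 = 100 * mean(f1))
}
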