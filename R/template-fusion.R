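# Fusion of {GEI, GEnI, AEI} into the FEI.
#
# The fusion weights minimize the squared reconstruction error between the
# weighted template combination and a target image, by full-batch gradient
# descent on the probability simplex: after each descent step negative
# components are clipped to zero and the vector renormalized to sum 1.  The
# cost is quadratic, so the 3x3 Gram matrix is precomputed once and each
# iteration costs O(1) regardless of image size.  Multiple seeded restarts
# (uniform init first, then random simplex points) guard against the
# projection trapping a run on a simplex face; the lowest-cost run wins.

.proj_simplexish <- function(w) {
  w[w < 0] <- 0
  s <- sum(w)
  if (s <= 0) rep(1 / length(w), length(w)) else w / s
}

#' Set up a template-fusion problem
#'
#' @param image_matrix n_pixels x n_images matrix of template pixel values.
#' @param target_pixels numeric vector of length n_pixels.
#' @param learning_rate step size; `NULL` (default) picks
#'   `0.9 * n_pixels / lambda_max(2 Gram)` automatically from the Gram
#'   spectrum, the largest step that keeps the quadratic descent stable.
#' @param max_iter maximum descent iterations per restart.
#' @param cost_tol stop when the cost change between iterations falls below
#'   this.
#' @param n_restarts number of descents (first from the uniform weights
#'   `1/n_images`, the rest from seeded random simplex points).
#' @param seed RNG seed for the random restarts.
#' @return A `fusion_problem` list.
#' @export
fusion_problem <- function(image_matrix, target_pixels, learning_rate = NULL,
                           max_iter = 20000L, cost_tol = 1e-8,
                           n_restarts = 5L, seed = 1L) {
  image_matrix <- as.matrix(image_matrix)
  stopifnot(length(target_pixels) == nrow(image_matrix))
  structure(list(image_matrix = image_matrix,
                 target_pixels = as.numeric(target_pixels),
                 learning_rate = learning_rate,
                 max_iter = as.integer(max_iter),
                 cost_tol = cost_tol,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "fusion_problem")
}

.auto_lr <- function(G, n_pixels) {
  lam <- max(eigen(2 * G, symmetric = TRUE, only.values = TRUE)$values)
  if (lam <= 0) return(0.01)
  0.9 * n_pixels / lam
}

#' One batch-gradient-descent step on the fusion weights
#'
#' Computes `estimated = X w`, `error = target - estimated`,
#' `cost = sum(error^2)`, the gradient `-2 X' error`, takes a descent step of
#' `learning_rate / n_pixels` along the negative gradient, then clips
#' negative components to zero and renormalizes to sum 1.
#'
#' @param weights current weight vector.
#' @param problem a [fusion_problem()].
#' @return List `(weights, cost)`: the updated weights and the cost at the
#'   *input* weights.
#' @export
bgd_step <- function(weights, problem) {
  X <- problem$image_matrix
  e <- problem$target_pixels - as.numeric(X %*% weights)
  cost <- sum(e^2)
  if (!is.finite(cost)) stop("diverged; reduce learning_rate")
  grad <- -2 * as.numeric(crossprod(X, e))
  lr <- problem$learning_rate
  if (is.null(lr)) lr <- .auto_lr(crossprod(X), nrow(X))
  w_new <- .proj_simplexish(weights - lr * grad / nrow(X))
  list(weights = w_new, cost = cost)
}

# one full descent from a given start, using the precomputed quadratic form
# cost(w) = tt - 2 w.b + w' G w  (identical to sum((target - X w)^2))
.bgd_descend <- function(w, G, b, tt, lr, max_iter, cost_tol, n_pixels) {
  cost <- tt - 2 * sum(w * b) + as.numeric(t(w) %*% G %*% w)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    trace[it] <- cost
    grad <- 2 * (as.numeric(G %*% w) - b)
    w <- .proj_simplexish(w - lr * grad / n_pixels)
    new_cost <- tt - 2 * sum(w * b) + as.numeric(t(w) %*% G %*% w)
    if (!is.finite(new_cost)) stop("diverged; reduce learning_rate")
    done <- abs(cost - new_cost) < cost_tol
    cost <- new_cost
    if (done) break
  }
  list(weights = w, cost = cost, n_iter = it, trace = c(trace, cost))
}

#' Optimize fusion weights for the three gait templates
#'
#' Runs `n_restarts` batch-gradient descents of the squared reconstruction
#' error between `w1*GEI + w2*GEnI + w3*AEI` and the target image, keeping
#' the restart with the smallest final cost.  Pixels are rescaled to
#' \[0, 1\] internally; the first restart starts from uniform weights
#' `1/3`, the others from seeded random points on the simplex.
#'
#' @param gei,geni,aei [energy_image()]s (or matrices) on \[0, 255\].
#' @param target target image: an [energy_image()]/matrix, or one of
#'   `"max"` (per-pixel maximum of the three templates, the pipeline
#'   default) or `"mean"`.
#' @param learning_rate,max_iter,cost_tol,n_restarts,seed see
#'   [fusion_problem()].
#' @return A `fusion_weights` list: `weights` (length 3, nonnegative, sum 1),
#'   `cost`, `n_iter`, `restart_index`, `cost_trace` of the winning run.
#' @export
optimize_fusion_weights <- function(gei, geni, aei, target = "max",
                                    learning_rate = NULL, max_iter = 20000L,
                                    cost_tol = 1e-8, n_restarts = 5L,
                                    seed = 1L) {
  X <- cbind(as.numeric(unclass(gei)), as.numeric(unclass(geni)),
             as.numeric(unclass(aei))) / 255
  if (all(abs(X) < .Machine$double.eps)) {
    stop("degenerate fusion problem: all templates are zero")
  }
  tvec <- if (is.character(target)) {
    switch(match.arg(target, c("max", "mean")),
           max = pmax(X[, 1], X[, 2], X[, 3]),
           mean = rowMeans(X))
  } else {
    as.numeric(unclass(target)) / 255
  }
  stopifnot(length(tvec) == nrow(X))
  n_pixels <- nrow(X)
  G <- crossprod(X)
  b <- as.numeric(crossprod(X, tvec))
  tt <- sum(tvec^2)
  lr <- if (is.null(learning_rate)) .auto_lr(G, n_pixels) else learning_rate
  starts <- with_private_seed(seed, {
    c(list(rep(1 / 3, 3)),
      lapply(seq_len(max(0L, n_restarts - 1L)), function(i) {
        e <- -log(runif(3)); e / sum(e)
      }))
  })
  best <- NULL
  for (i in seq_along(starts)) {
    run <- .bgd_descend(starts[[i]], G, b, tt, lr, max_iter, cost_tol, n_pixels)
    if (is.null(best) || run$cost < best$cost) {
      best <- run
      best$restart_index <- i
    }
  }
  structure(list(weights = best$weights, cost = best$cost,
                 n_iter = best$n_iter, restart_index = best$restart_index,
                 cost_trace = best$trace, learning_rate = lr),
            class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("<fusion_weights: (%.4f, %.4f, %.4f), cost %.6g, %d iters (restart %d)>\n",
              x$weights[1], x$weights[2], x$weights[3], x$cost, x$n_iter,
              x$restart_index))
  invisible(x)
}

#' Fuse the three templates into the FEI
#'
#' `FEI = w1*GEI + w2*GEnI + w3*AEI`, clipped to \[0, 255\].
#'
#' @param gei,geni,aei [energy_image()]s (or matrices) on \[0, 255\].
#' @param weights a `fusion_weights` object or a numeric vector of length 3
#'   summing to 1.
#' @return An [energy_image()] of kind `"FEI"`.
#' @export
fuse_templates <- function(gei, geni, aei, weights) {
  w <- if (inherits(weights, "fusion_weights")) weights$weights else as.numeric(weights)
  if (length(w) != 3L) stop("weights must have length 3")
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1")
  fei <- w[1] * unclass(gei) + w[2] * unclass(geni) + w[3] * unclass(aei)
  energy_image(pmin(pmax(fei, 0), 255), kind = "FEI")
}

#' Compute the FEI of one gait cycle
#'
#' Convenience wrapper: templates, weight optimization, fusion.
#'
#' @param cycle a `gait_cycle` or list of binary frames.
#' @param target,seed,... passed to [optimize_fusion_weights()].
#' @return List with `fei`, `weights`, and the three `templates`.
#' @export
cycle_fei <- function(cycle, target = "max", seed = 1L, ...) {
  tpl <- compute_templates(cycle)
  w <- optimize_fusion_weights(tpl$gei, tpl$geni, tpl$aei, target = target,
                               seed = seed, ...)
  list(fei = fuse_templates(tpl$gei, tpl$geni, tpl$aei, w),
       weights = w, templates = tpl)
}
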