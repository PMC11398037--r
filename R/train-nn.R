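# Forward and backward passes of the trainable part of the classifier: the
# attention block, branch fusion, and the depthwise-separable head, operating
# on backbone features.  The backbone is frozen during training (the
# transfer-learning regime), so gradients are only needed for attention and
# head parameters, never for the input features.
#
# Batched tensors are (C, H, W, B) arrays; depthwise convolutions are
# evaluated by shift-and-add over kernel offsets, pointwise convolutions and
# dense layers as matrix products.

.bn_eps <- 1e-5

# depthwise conv on (C, H, W, B) with per-channel (k*k, C) weights, pad (k-1)/2
.dw_shift_fwd <- function(x, w, k) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(C, H + 2L * p, W + 2L * p, B))
  xp[, (1:H) + p, (1:W) + p, ] <- x
  out <- array(0, d)
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      wv <- w[di + dj * k + 1L, ]          # length C, recycles over H, W, B
      out <- out + xp[, (1:H) + di, (1:W) + dj, , drop = FALSE] * wv
    }
  }
  list(out = out, xp = xp)
}

# gradients of .dw_shift_fwd: returns d(weights); input gradient omitted
# (inputs are frozen features or recomputed upstream activations)
.dw_shift_bwd_w <- function(dout, xp, k, C, H, W, B) {
  dw <- matrix(0, k * k, C)
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      prod <- dout * xp[, (1:H) + di, (1:W) + dj, , drop = FALSE]
      dw[di + dj * k + 1L, ] <- rowSums(matrix(prod, C, H * W * B))
    }
  }
  dw
}

# forward pass of attention + fusion + head on a feature batch F4 (C,H,W,B).
# Returns probs (n_classes x B) and, when training, every cache needed by
# trainable_backward.
trainable_forward <- function(model, F4, training = FALSE, rng_dropout = TRUE) {
  cfg <- model$config
  att <- model$attention
  head <- model$head
  d <- dim(F4); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  HW <- H * W
  cache <- list(F4 = F4, dims = d)

  if (cfg$attention == "icbam") {
    # -- channel attention ------------------------------------------------
    Pm <- aperm(array(F4, c(C, HW, B)), c(2, 1, 3))   # (HW, C, B)
    dim(Pm) <- c(HW, C * B)
    Aav <- matrix(colMeans(Pm), C, B)
    tPm <- t(Pm)                                       # (C*B, HW)
    idx_cmax <- max.col(tPm, ties.method = "first")
    Amax <- matrix(tPm[cbind(seq_len(C * B), idx_cmax)], C, B)
    Ha <- pmax(att$W0 %*% Aav + att$b0, 0)
    Sa <- att$W1 %*% Ha + att$b1
    Hm <- pmax(att$W0 %*% Amax + att$b0, 0)
    Sm <- att$W1 %*% Hm + att$b1
    Mc <- .sigmoid(Sa + Sm)                            # (C, B)

    # -- spatial attention ------------------------------------------------
    Fm <- matrix(F4, C, HW * B)
    Sav <- array(colMeans(Fm), c(H, W, B))
    tF <- t(Fm)                                        # (HW*B, C)
    idx_smax <- max.col(tF, ties.method = "first")
    Smax <- array(tF[cbind(seq_len(HW * B), idx_smax)], c(H, W, B))
    St <- array(0, c(2L, H, W, B))
    St[1, , , ] <- Sav
    St[2, , , ] <- Smax
    k <- att$config$spatial_kernel
    dwres <- .dw_shift_fwd(St, att$dw, k)
    U <- dwres$out + att$b_dw                          # b_dw recycles over dim 1
    v <- U[1, , , ] * att$pw[1] + U[2, , , ] * att$pw[2] + att$b_pw
    Ms <- .sigmoid(array(v, c(H, W, B)))               # (H, W, B)

    # -- parallel re-weighting + sum fusion -------------------------------
    G <- array(0, d)
    for (b in seq_len(B)) {
      F2b <- F4[, , , b] * Mc[, b] * rep(Ms[, , b], each = C)
      G[, , , b] <- F4[, , , b] + F2b
    }
    if (training) {
      cache[c("Aav", "Amax", "Ha", "Hm", "Mc", "Ms", "U", "St_xp")] <-
        list(Aav, Amax, Ha, Hm, Mc, Ms, U, dwres$xp)
    }
  } else if (cfg$attention == "none") {
    G <- F4
  } else {
    stop("forward pass implemented for attention 'icbam' and 'none' only")
  }

  # -- depthwise-separable head ------------------------------------------
  dwh <- .dw_shift_fwd(G, head$dw, 3L)
  D <- dwh$out + head$b_dw                             # b recycles over dim 1
  Dm <- matrix(D, C, HW * B)
  P <- crossprod(head$pw, Dm) + head$b_pw              # (Pch, HW*B)
  Pch <- ncol(head$pw)
  z <- P; dim(z) <- c(Pch * HW, B)                     # flatten (p fastest)
  u <- head$W1 %*% z + head$b1                         # (units, B)
  if (training && B > 1L) {
    mu <- rowMeans(u)
    va <- rowMeans((u - mu)^2)
    uhat <- (u - mu) / sqrt(va + .bn_eps)
  } else {
    mu <- head$bn_mean; va <- head$bn_var
    uhat <- (u - mu) / sqrt(va + .bn_eps)
  }
  y <- uhat * head$bn_gamma + head$bn_beta
  r <- pmax(y, 0)
  if (training && cfg$dropout > 0) {
    mask <- matrix((runif(length(r)) >= cfg$dropout) / (1 - cfg$dropout),
                   nrow(r), ncol(r))
    dd <- r * mask
  } else {
    mask <- NULL
    dd <- r
  }
  o <- head$W2 %*% dd + head$b2                        # (n_classes, B)
  om <- apply(o, 2, max)
  eo <- exp(sweep(o, 2, om))
  probs <- sweep(eo, 2, colSums(eo), "/")
  if (training) {
    cache[c("G_xp", "D", "z", "u", "mu", "va", "uhat", "y", "mask", "dd",
            "probs")] <- list(dwh$xp, D, z, u, mu, va, uhat, y, mask, dd, probs)
  }
  list(probs = probs, cache = if (training) cache else NULL,
       batch_mu = if (training && B > 1L) mu else NULL,
       batch_va = if (training && B > 1L) va else NULL)
}

# cross-entropy gradients for every trainable parameter given the forward
# cache and one-hot labels Y (n_classes x B); returns a nested list mirroring
# model$attention / model$head
trainable_backward <- function(model, cache, Y) {
  cfg <- model$config
  att <- model$attention
  head <- model$head
  d <- cache$dims; C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  HW <- H * W
  g <- list(att = list(), head = list())

  dO <- (cache$probs - Y) / B                          # softmax + CE
  g$head$W2 <- dO %*% t(cache$dd)
  g$head$b2 <- rowSums(dO)
  ddd <- crossprod(head$W2, dO)
  dr <- if (is.null(cache$mask)) ddd else ddd * cache$mask
  dy <- dr * (cache$y > 0)
  g$head$bn_gamma <- rowSums(dy * cache$uhat)
  g$head$bn_beta <- rowSums(dy)
  duh <- dy * head$bn_gamma
  inv <- 1 / sqrt(cache$va + .bn_eps)
  du <- (inv / B) * (B * duh - rowSums(duh) - cache$uhat * rowSums(duh * cache$uhat))
  g$head$W1 <- du %*% t(cache$z)
  g$head$b1 <- rowSums(du)
  dz <- crossprod(head$W1, du)
  Pch <- ncol(head$pw)
  dP <- dz; dim(dP) <- c(Pch, HW * B)
  Dm <- matrix(cache$D, C, HW * B)
  g$head$pw <- Dm %*% t(dP)
  g$head$b_pw <- rowSums(dP)
  dD <- head$pw %*% dP
  dim(dD) <- c(C, H, W, B)
  g$head$dw <- .dw_shift_bwd_w(dD, cache$G_xp, 3L, C, H, W, B)
  g$head$b_dw <- rowSums(matrix(dD, C, HW * B))

  if (cfg$attention == "none") return(g)

  # dG: backprop through the head's depthwise conv to the fused features
  k3 <- 3L
  dGp <- array(0, c(C, H + 2L, W + 2L, B))
  for (dj in 0:2) {
    for (di in 0:2) {
      wv <- head$dw[di + dj * k3 + 1L, ]
      dGp[, (1:H) + di, (1:W) + dj, ] <-
        dGp[, (1:H) + di, (1:W) + dj, , drop = FALSE] + dD * wv
    }
  }
  dG <- dGp[, 2:(H + 1L), 2:(W + 1L), , drop = FALSE]
  dim(dG) <- c(C, H, W, B)
  # G = F4 + F2, so dF2 = dG; F2 = F4 * Mc * Ms
  dMc <- matrix(0, C, B)
  dMs <- array(0, c(H, W, B))
  for (b in seq_len(B)) {
    T1 <- dG[, , , b] * cache$F4[, , , b]              # (C, H, W)
    dMc[, b] <- rowSums(matrix(T1 * rep(cache$Ms[, , b], each = C), C, HW))
    dMs[, , b] <- colSums(matrix(T1 * cache$Mc[, b], C, HW))
  }

  # channel branch: Mc = sigmoid(W1 relu(W0 a) + W1 relu(W0 m) + ...)
  dS <- dMc * cache$Mc * (1 - cache$Mc)
  dHa <- crossprod(att$W1, dS) * (cache$Ha > 0)
  dHm <- crossprod(att$W1, dS) * (cache$Hm > 0)
  g$att$W1 <- dS %*% t(cache$Ha) + dS %*% t(cache$Hm)
  g$att$b1 <- 2 * rowSums(dS)
  g$att$W0 <- dHa %*% t(cache$Aav) + dHm %*% t(cache$Amax)
  g$att$b0 <- rowSums(dHa) + rowSums(dHm)

  # spatial branch: Ms = sigmoid(pw . (dw7(St) + b_dw) + b_pw)
  dv <- dMs * cache$Ms * (1 - cache$Ms)                # (H, W, B)
  U <- cache$U
  g$att$pw <- c(sum(dv * U[1, , , ]), sum(dv * U[2, , , ]))
  g$att$b_pw <- sum(dv)
  dU <- array(0, c(2L, H, W, B))
  dU[1, , , ] <- dv * att$pw[1]
  dU[2, , , ] <- dv * att$pw[2]
  g$att$b_dw <- rowSums(matrix(dU, 2L, HW * B))
  k <- att$config$spatial_kernel
  g$att$dw <- .dw_shift_bwd_w(dU, cache$St_xp, k, 2L, H, W, B)
  g
}

# flatten/unflatten nested param lists for the optimizer
.trainable_params <- function(model) {
  p <- list(head = model$head[c("dw", "b_dw", "pw", "b_pw", "W1", "b1",
                                "bn_gamma", "bn_beta", "W2", "b2")])
  if (model$config$attention == "icbam") {
    p$att <- model$attention[c("W0", "b0", "W1", "b1", "dw", "b_dw",
                               "pw", "b_pw")]
  }
  p
}

.set_trainable_params <- function(model, p) {
  for (nm in names(p$head)) model$head[[nm]] <- p$head[[nm]]
  if (!is.null(p$att)) {
    for (nm in names(p$att)) model$attention[[nm]] <- p$att[[nm]]
  }
  model
}

# one Adam update; state holds first/second moments and the step counter
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (grp in names(grads)) {
    for (nm in names(grads[[grp]])) {
      key <- paste(grp, nm, sep = ".")
      gmat <- grads[[grp]][[nm]]
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- gmat * 0
        state$v[[key]] <- gmat * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * gmat
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * gmat^2
      step <- lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
      params[[grp]][[nm]] <- params[[grp]][[nm]] - step
    }
  }
  list(params = params, state = state)
}
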