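# loop oracle for the channel attention formula at C = 4, r = 2
.channel_oracle <- function(F, p) {
  C <- dim(F)[1]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(F[c, , ]); mx[c] <- max(F[c, , ])
  }
  mlp <- function(v) {
    h <- as.numeric(p$W0 %*% v + p$b0); h[h < 0] <- 0
    as.numeric(p$W1 %*% h + p$b1)
  }
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

# direct convolution oracle for the spatial attention on small maps
.spatial_oracle <- function(F, p) {
  C <- dim(F)[1]; H <- dim(F)[2]; W <- dim(F)[3]
  k <- p$config$spatial_kernel; half <- (k - 1) %/% 2
  avg <- matrix(0, H, W); mx <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    avg[i, j] <- mean(F[, i, j]); mx[i, j] <- max(F[, i, j])
  }
  stack <- list(avg, mx)
  U <- list(matrix(0, H, W), matrix(0, H, W))
  for (ch in 1:2) for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
      ii <- i + di - half; jj <- j + dj - half
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        acc <- acc + p$dw[di + dj * k + 1, ch] * stack[[ch]][ii, jj]
      }
    }
    U[[ch]][i, j] <- acc + p$b_dw[ch]
  }
  1 / (1 + exp(-(p$pw[1] * U[[1]] + p$pw[2] * U[[2]] + p$b_pw)))
}

.zeroed <- function(p) {
  for (nm in c("W0", "b0", "W1", "b1", "dw", "b_dw", "pw")) p[[nm]][] <- 0
  p$b_pw <- 0
  p
}

test_that("zero parameters force both attention maps to 0.5 and F2 = F/4", {
  p <- .zeroed(icbam_init(icbam_config(8L, 2L), seed = 1))
  set.seed(1)
  F <- array(rnorm(8 * 6 * 5), c(8, 6, 5))
  expect_equal(as.numeric(channel_attention(F, p)), rep(0.5, 8))
  expect_equal(as.numeric(spatial_attention(F, p)), rep(0.5, 30))
  expect_equal(apply_icbam(F, p), 0.25 * F)
  expect_equal(apply_icbam(array(0, c(8, 6, 5)), p), array(0, c(8, 6, 5)))
})

test_that("constant-per-channel maps make avg and max pooling coincide", {
  p <- icbam_init(icbam_config(4L, 2L), seed = 2)
  v <- c(0.3, -1.2, 2.0, 0.7)
  F <- array(rep(v, 6 * 6), c(4, 6, 6))
  mlp <- function(x) {
    as.numeric(p$W1 %*% pmax(p$W0 %*% x + p$b0, 0) + p$b1)
  }
  expect_equal(as.numeric(channel_attention(F, p)),
               1 / (1 + exp(-2 * mlp(v))))
})

test_that("channel and spatial attention match elementwise loop oracles", {
  for (seed in 1:3) {
    p <- icbam_init(icbam_config(4L, 2L), seed = seed)
    set.seed(seed + 10)
    F <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
    expect_equal(as.numeric(channel_attention(F, p)), .channel_oracle(F, p),
                 tolerance = 1e-12)
    expect_equal(as.numeric(spatial_attention(F, p))[seq_len(64)],
                 as.numeric(.spatial_oracle(F, p)), tolerance = 1e-12)
  }
  # single-channel map: spatial attention peaks at a lone bright pixel when
  # the pointwise weights pass the depthwise response through positively
  p1 <- icbam_init(icbam_config(1L, 1L), seed = 4)
  p1$dw[] <- 0; p1$dw[(49 + 1) / 2, ] <- 1  # identity-like center tap
  p1$b_dw[] <- 0; p1$pw <- c(1, 1); p1$b_pw <- 0
  F1 <- array(0, c(1, 8, 8)); F1[1, 3, 6] <- 5
  Ms <- spatial_attention(F1, p1)
  expect_equal(which.max(Ms), which.max(array(F1, c(1, 8, 8))))
})

test_that("the block preserves shape and attenuates magnitudes", {
  for (dims in list(c(4L, 8L, 8L), c(8L, 3L, 7L), c(2L, 1L, 1L))) {
    p <- icbam_init(icbam_config(dims[1], min(2L, dims[1])), seed = 5)
    set.seed(6)
    F <- array(rnorm(prod(dims)), dims)
    F2 <- apply_icbam(F, p)
    expect_identical(dim(F2), dims)
    expect_true(all(abs(F2) <= abs(F) + 1e-12))
  }
})

test_that("parallel topology differs from the serial reference but is
           order-independent internally", {
  p <- icbam_init(icbam_config(4L, 2L), seed = 7)
  set.seed(8)
  F <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  # recomposition: the block equals the product of its two published maps
  Mc <- as.numeric(channel_attention(F, p))
  Ms <- as.numeric(spatial_attention(F, p))
  expect_equal(apply_icbam(F, p), F * Mc * rep(Ms, each = 4))
  # computing Ms before Mc changes nothing (both read the original F)
  expect_equal(F * rep(Ms, each = 4) * Mc, apply_icbam(F, p))
  # the serial CBAM reference disagrees on generic inputs
  expect_gt(max(abs(apply_icbam(F, p) - apply_cbam_serial(F, p))), 1e-6)
})

test_that("attention parameter accounting matches the architecture arithmetic", {
  p <- icbam_init(icbam_config(1280L, 16L), seed = 1)
  n <- length(p$W0) + length(p$b0) + length(p$W1) + length(p$b1) +
    length(p$dw) + length(p$b_dw) + length(p$pw) + length(p$b_pw)
  expect_identical(n, 80L * 1280L + 80L + 1280L * 80L + 1280L + 98L + 2L + 2L + 1L)
  expect_equal(attention_param_count("icbam", 1280L, 16L), n)
  expect_error(channel_attention(array(0, c(4, 2, 2)), p), "channel mismatch")
})
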