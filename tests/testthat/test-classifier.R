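# R-side loop oracle for the C++ convolution kernels
.conv_oracle <- function(x, warr, stride, pad) {
  kh <- dim(warr)[1]; kw <- dim(warr)[2]; C <- dim(warr)[3]; K <- dim(warr)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  out <- array(0, c(Ho, Wo, K))
  for (k in 1:K) for (io in 1:Ho) for (jo in 1:Wo) {
    acc <- 0
    for (c in 1:C) for (di in 1:kh) for (dj in 1:kw) {
      i <- (io - 1) * stride - pad + di
      j <- (jo - 1) * stride - pad + dj
      if (i >= 1 && i <= H && j >= 1 && j <= W) {
        acc <- acc + warr[di, dj, c, k] * x[i, j, c]
      }
    }
    out[io, jo, k] <- acc
  }
  out
}

test_that("the convolution kernels match a direct loop oracle", {
  set.seed(12)
  x <- array(rnorm(9 * 8 * 3), c(9, 8, 3))
  warr <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  wm <- warr; dim(wm) <- c(27, 4)
  for (cfg in list(c(1, 1), c(2, 1), c(1, 0), c(2, 0))) {
    got <- pathogait:::conv2d_fwd_cpp(x, wm, 3L, 3L, cfg[1], cfg[2])
    expect_equal(got, .conv_oracle(x, warr, cfg[1], cfg[2]), tolerance = 1e-12)
  }
  # depthwise = grouped convolution with one filter per channel
  wd <- matrix(rnorm(9 * 3), 9, 3)
  got <- pathogait:::dwconv2d_fwd_cpp(x, wd, 3L, 3L, 1L, 1L)
  for (c in 1:3) {
    wfull <- array(0, c(3, 3, 3, 1)); wfull[, , c, 1] <- wd[, c]
    expect_equal(got[, , c], .conv_oracle(x, wfull, 1, 1)[, , 1],
                 tolerance = 1e-12)
  }
})

test_that("model configuration is validated", {
  expect_error(model_config(input_size = 250), "divisible by 32")
  expect_error(model_config(n_classes = 1), "n_classes")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(build_model(model_config(pretrained = TRUE)), "pretrained")
})

test_that("parameter counts reproduce the architecture arithmetic", {
  # the canonical width-1.0 feature extractor has 2,223,872 parameters with
  # a 3-channel stem; a 1-channel stem drops 2*32*9 - 32*9 = 576
  expect_equal(count_parameters(build_backbone(3L)), 2223872)
  expect_equal(count_parameters(build_backbone(1L)), 2223296)
  m256 <- build_model(model_config(input_size = 256L))
  m224 <- build_model(model_config(input_size = 224L))
  # head at 256: dw 1280*9+1280, pw 1280*32+32, dense 2048*256+256, bn 512,
  # out 256*5+5; attention block 206,263
  head256 <- (1280 * 9 + 1280) + (1280 * 32 + 32) + (2048 * 256 + 256) +
    512 + (256 * 5 + 5)
  expect_equal(count_parameters(m256), 2223296 + 206263 + head256)
  # 224 vs 256 differ only in the flatten -> dense weights: 32*(64-49)*256
  expect_equal(count_parameters(m256) - count_parameters(m224),
                   32L * 15L * 256L)
  # frozen backbone drops out of the trainable count
  mf <- build_model(model_config(freeze_backbone = TRUE))
  expect_equal(count_parameters(mf, trainable_only = TRUE),
                   count_parameters(m256) - 2223296)
  expect_equal(count_parameters(mf, trainable_only = FALSE),
                   count_parameters(m256))
})

test_that("backbone output obeys the stride-32 contract", {
  m <- build_model(model_config(input_size = 256L, seed = 2L))
  img <- matrix(runif(256 * 256) * 255, 256, 256)
  f <- model_features(m, img)
  expect_identical(dim(f), c(1280L, 8L, 8L))
  f2 <- model_features(m, img)
  expect_identical(f, f2)  # deterministic forward
})

test_that("the full forward pass emits a probability simplex", {
  m <- build_model(model_config(input_size = 256L, seed = 3L))
  set.seed(3)
  img <- matrix(runif(256 * 256) * 255, 256, 256)
  p <- model_forward(m, img)
  expect_length(p, 5L)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("zeroed attention makes the fused branch 1.25x the plain branch", {
  # same head weights, one model with a zeroed attention block and one with
  # no attention: sum fusion means probs(icbam0, F) == probs(none, 1.25 F)
  mi <- tiny_trainable_model(attention = "icbam")
  for (nm in c("W0", "b0", "W1", "b1", "dw", "b_dw", "pw")) {
    mi$attention[[nm]][] <- 0
  }
  mi$attention$b_pw <- 0
  mn <- tiny_trainable_model(attention = "none")
  set.seed(5)
  F4 <- array(rnorm(8 * 4 * 4 * 2), c(8, 4, 4, 2))
  pi_ <- pathogait:::trainable_forward(mi, F4, training = FALSE)$probs
  pn <- pathogait:::trainable_forward(mn, 1.25 * F4, training = FALSE)$probs
  expect_equal(pi_, pn, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on the trainable part", {
  model <- tiny_trainable_model()
  set.seed(7)
  F4 <- array(rnorm(8 * 4 * 4 * 3), c(8, 4, 4, 3))
  Y <- pathogait:::.one_hot(c("a", "c", "b"), c("a", "b", "c"))
  lossfun <- function(m) {
    fw <- pathogait:::trainable_forward(m, F4, training = TRUE)
    -mean(log(colSums(fw$probs * Y)))
  }
  fw <- pathogait:::trainable_forward(model, F4, training = TRUE)
  g <- pathogait:::trainable_backward(model, fw$cache, Y)
  eps <- 1e-6
  for (grp in names(g)) {
    slot <- if (grp == "att") "attention" else "head"
    for (nm in names(g[[grp]])) {
      theta <- model[[slot]][[nm]]
      set.seed(nchar(nm))
      for (ii in sample(length(theta), min(length(theta), 4))) {
        m2 <- model
        m2[[slot]][[nm]][ii] <- theta[ii] + eps
        lp <- lossfun(m2)
        m2[[slot]][[nm]][ii] <- theta[ii] - eps
        lm <- lossfun(m2)
        fd <- (lp - lm) / (2 * eps)
        an <- g[[grp]][[nm]][ii]
        expect_lt(abs(fd - an), 1e-5 + 1e-3 * (abs(fd) + abs(an)))
      }
    }
  }
})

test_that("transfer learning loads and freezes a compatible backbone", {
  m <- build_model(model_config(seed = 4L))
  donor <- build_backbone(1L, seed = 99L)
  m2 <- apply_transfer_learning(m, donor)
  expect_true(m2$config$freeze_backbone)
  expect_identical(m2$backbone$blocks[[1]]$layers[[1]]$w,
                   donor$blocks[[1]]$layers[[1]]$w)
  expect_equal(count_parameters(m2), count_parameters(m) - 2223296)
  wrong <- build_backbone(3L, seed = 1L)
  expect_error(apply_transfer_learning(m, wrong), "mismatch")
})
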