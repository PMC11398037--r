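test_that("a single BGD step matches finite differences of the cost", {
  X <- matrix(c(1, 0, 2, 1,
                0, 1, 1, 3), 4, 2)
  t <- c(0.5, 0.25, 1.5, 2)
  pr <- fusion_problem(X, t, learning_rate = 0.05)
  w0 <- c(0.6, 0.4)
  step <- bgd_step(w0, pr)
  expect_equal(step$cost, sum((t - X %*% w0)^2))
  # finite-difference gradient of sum((t - X w)^2)
  eps <- 1e-7
  fd <- vapply(1:2, function(k) {
    wp <- w0; wp[k] <- wp[k] + eps
    wm <- w0; wm[k] <- wm[k] - eps
    (sum((t - X %*% wp)^2) - sum((t - X %*% wm)^2)) / (2 * eps)
  }, numeric(1))
  raw <- w0 - 0.05 * fd / nrow(X)
  raw[raw < 0] <- 0
  expect_equal(step$weights, raw / sum(raw), tolerance = 1e-6)
})

test_that("an optimal point is a fixed point of the step with zero cost", {
  X <- matrix(c(1, 2, 0, 3), 4, 1)
  pr <- fusion_problem(X, as.numeric(X), learning_rate = 0.1)
  step <- bgd_step(1, pr)
  expect_equal(step$weights, 1)
  expect_equal(step$cost, 0)
})

test_that("planted convex combinations are recovered within 1e-3", {
  tpl <- walker_templates_fixture()
  for (plant in list(c(1, 0, 0), c(0.2, 0.3, 0.5), c(0.6, 0.1, 0.3))) {
    target <- plant[1] * unclass(tpl$gei) + plant[2] * unclass(tpl$geni) +
      plant[3] * unclass(tpl$aei)
    w <- optimize_fusion_weights(tpl$gei, tpl$geni, tpl$aei, target = target,
                                 seed = 5)
    expect_lt(max(abs(w$weights - plant)), 1e-3)
    X <- cbind(as.numeric(tpl$gei), as.numeric(tpl$geni),
               as.numeric(tpl$aei)) / 255
    oracle <- simplex_cls_oracle(X, as.numeric(target) / 255)
    expect_lt(max(abs(w$weights - oracle$weights)), 1e-3)
  }
})

test_that("the zero-image target matches a brute-force simplex grid search", {
  tpl <- walker_templates_fixture()
  zero <- matrix(0, 256, 256)
  w <- optimize_fusion_weights(tpl$gei, tpl$geni, tpl$aei, target = zero,
                               seed = 2)
  X <- cbind(as.numeric(tpl$gei), as.numeric(tpl$geni), as.numeric(tpl$aei)) / 255
  # grid over the simplex at 0.01 resolution
  gr <- seq(0, 1, by = 0.01)
  best_cost <- Inf; best_w <- NULL
  G <- crossprod(X)
  for (a in gr) for (b in gr[gr <= 1 - a + 1e-12]) {
    wv <- c(a, b, 1 - a - b)
    cost <- as.numeric(t(wv) %*% G %*% wv)
    if (cost < best_cost) { best_cost <- cost; best_w <- wv }
  }
  expect_lt(max(abs(w$weights - best_w)), 0.011)
  expect_lte(w$cost, best_cost + 1e-6)
})

test_that("cost is non-increasing along the winning descent", {
  tpl <- walker_templates_fixture()
  w <- optimize_fusion_weights(tpl$gei, tpl$geni, tpl$aei, target = "max",
                               seed = 9)
  expect_true(all(diff(w$cost_trace) <= 1e-9))
  expect_true(all(w$weights >= 0))
  expect_equal(sum(w$weights), 1)
})

test_that("weights stay on the simplex over random problems", {
  set.seed(31)
  for (i in 1:5) {
    X <- matrix(runif(64 * 3) * 255, 64, 3)
    t <- runif(64) * 255
    w <- optimize_fusion_weights(matrix(X[, 1], 8, 8), matrix(X[, 2], 8, 8),
                                 matrix(X[, 3], 8, 8),
                                 target = matrix(t, 8, 8), seed = i)
    expect_true(all(w$weights >= -1e-12))
    expect_equal(sum(w$weights), 1, tolerance = 1e-9)
  }
})

test_that("fusion is a convex per-pixel combination", {
  tpl <- walker_templates_fixture()
  expect_equal(plain(fuse_templates(tpl$gei, tpl$geni, tpl$aei, c(1, 0, 0))),
               plain(tpl$gei))
  mean3 <- (plain(tpl$gei) + plain(tpl$geni) + plain(tpl$aei)) / 3
  expect_equal(plain(fuse_templates(tpl$gei, tpl$geni, tpl$aei,
                                      rep(1 / 3, 3))), mean3)
  set.seed(6)
  e <- -log(runif(3)); wv <- e / sum(e)
  fei <- plain(fuse_templates(tpl$gei, tpl$geni, tpl$aei, wv))
  lo <- pmin(unclass(tpl$gei), unclass(tpl$geni), unclass(tpl$aei))
  hi <- pmax(unclass(tpl$gei), unclass(tpl$geni), unclass(tpl$aei))
  expect_true(all(fei >= lo - 1e-9 & fei <= hi + 1e-9))
  expect_error(fuse_templates(tpl$gei, tpl$geni, tpl$aei, c(0.5, 0.5)),
               "length 3")
  expect_error(fuse_templates(tpl$gei, tpl$geni, tpl$aei, c(0.5, 0.4, 0.3)),
               "sum to 1")
})

test_that("degenerate all-zero templates are rejected", {
  z <- matrix(0, 8, 8)
  expect_error(optimize_fusion_weights(z, z, z, target = z), "degenerate")
})
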