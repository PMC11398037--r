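# independent morphology oracle: plain min/max filter under a 0/1 element
.morph_oracle <- function(m, brush, op = c("erode", "dilate")) {
  op <- match.arg(op)
  kh <- nrow(brush); kw <- ncol(brush)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(if (op == "erode") 1 else 0, H + 2 * ph, W + 2 * pw)
  pad[(1:H) + ph, (1:W) + pw] <- m
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    patch <- pad[i:(i + kh - 1), j:(j + kw - 1)][brush > 0]
    out[i, j] <- if (op == "erode") min(patch) else max(patch)
  }
  out
}

test_that("binarization handles empty and clean inputs", {
  expect_warning(f <- binarize_and_clean(matrix(0, 20, 20)), "empty foreground")
  expect_true(attr(f, "empty_foreground"))
  expect_true(all(f == 0))

  img <- matrix(0, 120, 80)
  img[11:110, 21:70] <- 255
  f <- binarize_and_clean(img, threshold = 127, open_radius = 1, close_radius = 1)
  expect_true(all(f %in% c(0, 255)))
  expect_identical(plain(f), int_mat(img))  # idempotent on a clean rectangle
  expect_error(binarize_and_clean(img, threshold = 0), "threshold")
})

test_that("cleaning removes speckles like the brute-force morphology oracle", {
  set.seed(4)
  img <- matrix(0, 64, 64)
  img[20:45, 25:40] <- 255
  speckles <- cbind(sample(c(2:15, 50:63), 10, TRUE), sample(2:63, 10, TRUE))
  img[speckles] <- 255
  f <- binarize_and_clean(img, open_radius = 1, close_radius = 0)
  brush <- as.matrix(EBImage::makeBrush(3, "disc"))
  opened <- .morph_oracle(.morph_oracle(img / 255, brush, "erode"),
                          brush, "dilate") * 255
  expect_identical(plain(f), int_mat(opened))
  expect_true(all(f[speckles] == 0))          # isolated pixels removed
  expect_true(all(f[21:44, 26:39] == 255))    # rectangle interior intact
})

test_that("binarize_and_clean is idempotent on random blobs", {
  set.seed(9)
  for (i in 1:3) {
    img <- matrix(255 * rbinom(40 * 40, 1, 0.3), 40, 40)
    img[15:30, 15:30] <- 255
    once <- binarize_and_clean(img)
    twice <- binarize_and_clean(unclass(once))
    expect_identical(plain(once), plain(twice))
  }
})

test_that("crop_to_person keeps the largest component only", {
  m <- matrix(0, 100, 100)
  m[11:50, 21:40] <- 255      # area 800
  m[80:83, 80:84] <- 255      # area 20
  crop <- crop_to_person(silhouette_frame(m), margin = 0)
  expect_identical(dim(unclass(crop)), c(40L, 20L))
  expect_true(all(crop == 255))

  single <- matrix(0, 60, 60); single[11:50, 11:30] <- 255
  crop1 <- crop_to_person(silhouette_frame(single), margin = 0)
  expect_identical(dim(unclass(crop1)), c(40L, 20L))
  expect_error(crop_to_person(silhouette_frame(matrix(0, 5, 5))), "no person")
})

test_that("normalization scales the bounding box height to out_size exactly", {
  rect <- matrix(0, 140, 80)
  rect[7:134, 9:72] <- 255    # 128 x 64
  out <- normalize_silhouette(crop_to_person(silhouette_frame(rect)), 256)
  expect_identical(dim(unclass(out)), c(256L, 256L))
  bb <- pathogait:::fg_bbox(unclass(out))
  expect_identical(bb$r1 - bb$r0 + 1L, 256L)
  expect_identical(bb$c1 - bb$c0 + 1L, 128L)  # aspect preserved (scale 2)

  # irregular but connected blob: output tight bounding box height is exactly
  # out_size and the width-to-height ratio is preserved up to quantization
  blob <- matrix(0, 90, 90)
  blob[25:75, 42:55] <- 255       # torso core (taller than wide)
  blob[30:36, 55:62] <- 255       # attached arm
  blob[66:75, 36:42] <- 255       # attached foot
  bbin <- pathogait:::fg_bbox(blob)
  out2 <- normalize_silhouette(crop_to_person(silhouette_frame(blob)), 256)
  bb2 <- pathogait:::fg_bbox(unclass(out2))
  expect_identical(bb2$r1 - bb2$r0 + 1L, 256L)
  ratio_in <- (bbin$c1 - bbin$c0 + 1) / (bbin$r1 - bbin$r0 + 1)
  ratio_out <- (bb2$c1 - bb2$c0 + 1) / 256
  expect_lt(abs(ratio_in - ratio_out), 1 / (bbin$r1 - bbin$r0 + 1))
  expect_error(normalize_silhouette(silhouette_frame(matrix(0, 4, 4))), "empty")
})
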