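test_that("binarization recovers an analytic ellipse under both polarities", {
  n <- 200L
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  inside <- ((xy$x - 100) / 60)^2 + ((xy$y - 100) / 35)^2 <= 1
  img <- matrix(0, n, n)
  img[cbind(xy$x, xy$y)] <- as.numeric(inside)
  mask <- binarizeImage(img, polarity = "auto")
  truth <- matrix(inside, n, n)
  # disagreement only allowed within a 1-px boundary band
  expect_lt(sum(mask != truth) / sum(truth), 0.02)
  maskInv <- binarizeImage(1 - img, polarity = "auto")
  expect_identical(mask, maskInv)
  expect_error(binarizeImage(matrix(0, 100, 100)), "foreground")
})

test_that("outline extraction keeps the largest component and fills holes", {
  n <- 300L
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  disk <- (xy$x - 150)^2 + (xy$y - 150)^2 <= 100^2
  m <- matrix(FALSE, n, n)
  m[cbind(xy$x, xy$y)] <- disk
  out <- extractOutline(m)
  d <- sqrt((out[, 1] - 150)^2 + (out[, 2] - 150)^2)
  expect_lt(max(abs(d - 100)), 1.6)  # boundary digitization error
  expect_gt(nrow(out), 64L)
  # speck + hole must not change the traced boundary
  m2 <- m
  m2[10:14, 10:14] <- TRUE                             # 5x5 speck
  hole <- (xy$x - 150)^2 + (xy$y - 150)^2 <= 20^2
  m2[cbind(xy$x, xy$y)[hole, ]] <- FALSE               # interior hole
  expect_identical(extractOutline(m2), out)
})

test_that("outline orientation is counter-clockwise", {
  n <- 200L
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  disk <- (xy$x - 100)^2 + (xy$y - 100)^2 <= 50^2
  m <- matrix(FALSE, n, n)
  m[cbind(xy$x, xy$y)] <- disk
  out <- extractOutline(m)
  expect_gt(otoshape:::.signedArea(out), 0)
})

test_that("polygon centroid is the area centroid, not the vertex mean", {
  expect_equal(outlineCentroid(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))),
               c(x = 0.5, y = 0.5))
  expect_equal(outlineCentroid(circleOutline(2, c(3, 7))),
               c(x = 3, y = 7), tolerance = 1e-6)
  # L-shape vs dense Monte-Carlo oracle
  L <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 3, 3))
  set.seed(1)
  pts <- cbind(runif(4e5, 0, 2), runif(4e5, 0, 3))
  inL <- pts[, 2] <= 1 | pts[, 1] <= 1
  mc <- colMeans(pts[inL, ])
  expect_equal(unname(outlineCentroid(L)), mc, tolerance = 5e-3)
})

test_that("radial profile matches analytic shapes", {
  rp <- radialProfile(circleOutline(1, n = 1024L), 256L)
  expect_lt(max(abs(profileRadii(rp) - 1)), 1e-3)
  th <- 2 * pi * (0:1023) / 1024
  ell <- cbind(2 * cos(th), sin(th))
  r <- profileRadii(radialProfile(ell, 256L))
  expect_equal(r[1], 2, tolerance = 1e-4)
  expect_equal(r[65], 1, tolerance = 1e-4)
  sq <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  r <- profileRadii(radialProfile(sq, 64L))
  expect_equal(r[9], sqrt(2), tolerance = 1e-9)   # 45 degrees
  expect_equal(r[1], 1, tolerance = 1e-9)
  expect_error(radialProfile(sq, 60L), "power of two")
})

test_that("radial profile is rotation-equivariant and scales exactly", {
  set.seed(3)
  r0 <- 1 + 0.1 * sin(3 * 2 * pi * (0:255) / 256) +
    0.05 * cos(5 * 2 * pi * (0:255) / 256)
  out <- profileToOutline(r0)
  base <- profileRadii(radialProfile(out, 256L))
  k <- 16L
  phi <- 2 * pi * k / 256
  rot <- cbind(out[, 1] * cos(phi) - out[, 2] * sin(phi),
               out[, 1] * sin(phi) + out[, 2] * cos(phi))
  rotr <- profileRadii(radialProfile(rot, 256L))
  shifted <- c(base[(256 - k + 1):256], base[1:(256 - k)])
  expect_equal(rotr, shifted, tolerance = 1e-6)
  scl <- profileRadii(radialProfile(out * 3.5, 256L))
  expect_equal(scl, base * 3.5, tolerance = 1e-9)
})

test_that("grayscale image reading preserves geometry through the stack", {
  # render a disk, write as PNG via EBImage, read back and extract
  img <- rasterizeOutline(circleOutline(1, n = 512L), size_px = 256L)
  tf <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(img), tf)
  rp <- imageToProfile(tf, nAngles = 128L)
  r <- profileRadii(rp)
  expect_lt(sd(r) / mean(r), 0.01)  # still a circle
})
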