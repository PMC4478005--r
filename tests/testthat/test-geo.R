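test_that("along-coast distances follow the haversine closed form", {
  coast <- data.frame(lat = c(0, 0), lon = c(0, 1))
  pops <- data.frame(population_id = c("A", "B"),
                     latitude = c(0, 0), longitude = c(0, 1))
  D <- coastlineDistances(coast, pops)
  # one degree of longitude on the equator: 6371 * pi / 180 km
  expect_equal(D["A", "B"], 6371 * pi / 180, tolerance = 0.1)
  # same waypoint -> zero
  pops0 <- data.frame(population_id = c("A", "B"),
                      latitude = 0, longitude = 0)
  expect_equal(coastlineDistances(coast, pops0)["A", "B"], 0)
})

test_that("along-coast distances are additive along the path", {
  coast <- data.frame(lat = seq(58, 64, by = 0.25), lon = 5)
  pops <- data.frame(population_id = c("A", "B", "C"),
                     latitude = c(58, 60, 63.5), longitude = 5)
  D <- coastlineDistances(coast, pops)
  expect_equal(D["A", "C"], D["A", "B"] + D["B", "C"], tolerance = 1e-9)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("shape distances are plain Euclidean on the first two axes", {
  cent <- rbind(A = c(0, 0, 9), B = c(3, 4, -9), C = c(1, 1, 0))
  D <- shapeDistances(cent)
  expect_equal(D["A", "B"], 5)              # 3-4-5, third axis ignored
  expect_equal(D["A", "A"], 0)
  set.seed(30)
  cent4 <- matrix(rnorm(8), 4, dimnames = list(LETTERS[1:4], NULL))
  D4 <- shapeDistances(cent4)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(D4[i, j], sqrt(sum((cent4[i, ] - cent4[j, ])^2)))
  expect_error(shapeDistances(cent[, 1, drop = FALSE]), "axes")
})

test_that("Mantel r is 1 for proportional matrices, symmetric in arguments", {
  set.seed(31)
  D1 <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(D1) <- list(LETTERS[1:5], LETTERS[1:5])
  D2 <- 2 * D1
  got <- mantelTest(D1, D2, nPermutations = 200)
  expect_equal(got$statistic, 1)
  a <- mantelTest(D1, D2 + as.matrix(dist(matrix(rnorm(10), 5))),
                  nPermutations = 200)
  D3 <- D2 + as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(D3) <- dimnames(D1)
  ab <- mantelTest(D1, D3, nPermutations = 200)
  ba <- mantelTest(D3, D1, nPermutations = 200)
  expect_equal(ab$statistic, ba$statistic)
  expect_true(ab$exhaustive)          # 5! = 120 <= 200
  expect_equal(ab$pValue, ba$pValue)  # exhaustive mode: identical
})

test_that("exhaustive Mantel p equals enumeration over all relabelings", {
  set.seed(32)
  D1 <- as.matrix(dist(matrix(rnorm(10), 5)))
  D2 <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(D1) <- dimnames(D2) <- list(LETTERS[1:5], LETTERS[1:5])
  got <- mantelTest(D1, D2, nPermutations = 1000)
  expect_true(got$exhaustive)
  # oracle: independent enumeration with explicit permutation matrices
  perms <- otoshape:::allPermutations(5L)
  v1 <- D1[upper.tri(D1)]
  rs <- apply(perms, 1, function(p) {
    Pm <- diag(5)[p, ]
    Dp <- Pm %*% D2 %*% t(Pm)
    cor(v1, Dp[upper.tri(Dp)])
  })
  rObs <- cor(v1, D2[upper.tri(D2)])
  expect_equal(got$statistic, rObs)
  expect_equal(got$pValue, mean(rs >= rObs - 1e-12))
})

test_that("Mantel r is invariant to affine rescaling of either matrix", {
  set.seed(33)
  D1 <- as.matrix(dist(matrix(rnorm(12), 6)))
  D2 <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(D1) <- dimnames(D2) <- list(LETTERS[1:6], LETTERS[1:6])
  r0 <- mantelTest(D1, D2, nPermutations = 100, exhaustive = FALSE,
                   seed = 1)$statistic
  D2b <- 3.7 * D2; diag(D2b) <- 0
  D2c <- D2b + 5; diag(D2c) <- 0  # affine on off-diagonals
  D2c[upper.tri(D2c) | lower.tri(D2c)] <-
    3.7 * D2[upper.tri(D2) | lower.tri(D2)] + 5
  r1 <- mantelTest(D1, D2c, nPermutations = 100, exhaustive = FALSE,
                   seed = 1)$statistic
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("label mismatches and degenerate inputs are rejected", {
  D1 <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(D1) <- list(LETTERS[1:5], LETTERS[1:5])
  D2 <- D1
  dimnames(D2) <- list(letters[1:5], letters[1:5])
  expect_error(mantelTest(D1, D2, 200), "mismatch|labels")
  D3 <- as.matrix(dist(matrix(rnorm(6), 3)))
  dimnames(D3) <- list(LETTERS[1:3], LETTERS[1:3])
  expect_error(mantelTest(D3, D3, 200), "at least 4")
})

test_that("isolation-by-distance report flags only constructed outliers", {
  set.seed(34)
  pos <- c(A = 0, B = 300, C = 800, D = 1500, E = 2100)
  dGeo <- abs(outer(pos, pos, "-"))
  dShape <- 0.002 * dGeo
  dimnames(dShape) <- dimnames(dGeo)
  rep0 <- ibdReport(dShape, dGeo)
  expect_false(any(rep0$outlier))       # perfectly linear: no outliers
  dShape2 <- dShape
  dShape2["A", "E"] <- dShape2["E", "A"] <- dShape["A", "E"] + 3
  rep1 <- ibdReport(dShape2, dGeo)
  flagged <- rep1[rep1$outlier, c("pop1", "pop2")]
  expect_equal(nrow(flagged), 1L)
  expect_setequal(unlist(flagged), c("A", "E"))
  # oracle: explicit OLS + 2 SD screen
  fit <- lm(shape_dist ~ geo_km, data = rep1)
  resid <- rep1$shape_dist - fitted(fit)
  expect_equal(rep1$outlier, unname(abs(resid) > 2 * sd(resid)))
})
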