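test_that("ANCOVA filter drops constructed interactions, keeps null columns", {
  set.seed(10)
  n <- 90
  g <- factor(rep(c("a", "b", "c"), each = 30))
  len <- runif(n, 20, 35)
  slopes <- c(a = -1, b = 0, c = 1)
  m <- cbind(inter = slopes[g] * len,            # exact interaction
             flat = rep(1, n),                   # constant
             noise = rnorm(n))                   # pure noise
  rep <- suppressWarnings(ancovaFilter(m, len, g, alpha = 0.05))
  expect_true(1 %in% rep$dropped$index)
  expect_true(all(c(2, 3) %in% rep$kept))
  expect_true(all(sort(c(rep$kept, rep$dropped$index)) == 1:3))
})

test_that("ANCOVA interaction p-values equal the nested-model F oracle", {
  set.seed(11)
  n <- 90
  g <- factor(rep(c("a", "b", "c"), each = 30))
  len <- runif(n, 20, 35)
  m <- sapply(1:6, function(j)
    rnorm(n) + 0.02 * j * as.integer(g) * len)
  rep <- ancovaFilter(m, len, g)
  for (j in 1:6) {
    full <- lm(m[, j] ~ len * g)
    red <- lm(m[, j] ~ len + g)
    pOracle <- anova(red, full)$`Pr(>F)`[2]
    expect_equal(unname(rep$pValues[j]), pOracle, tolerance = 1e-8)
  }
})

test_that("ANCOVA drop rate is near alpha under the null", {
  set.seed(12)
  n <- 60
  g <- factor(rep(c("a", "b", "c"), each = 20))
  len <- runif(n, 20, 35)
  m <- matrix(rnorm(n * 1000), n)
  rep <- ancovaFilter(m, len, g, alpha = 0.05)
  rate <- nrow(rep$dropped) / 1000
  expect_gt(rate, qbinom(0.005, 1000, 0.05) / 1000)
  expect_lt(rate, qbinom(0.995, 1000, 0.05) / 1000)
})

test_that("CAP separates two clouds on a single constrained axis", {
  set.seed(13)
  Y <- rbind(matrix(rnorm(20 * 5), 20), matrix(rnorm(20 * 5, 4), 20))
  g <- factor(rep(c("L", "R"), each = 20))
  cap <- capOrdination(Y, g)
  expect_equal(length(capEigenvalues(cap)), 1L)
  cent <- capCentroids(cap)
  expect_lt(cent["L", 1] * cent["R", 1], 0)   # opposite signs
  spread <- max(tapply(capScores(cap)[, 1], g, sd))
  expect_gt(abs(diff(cent[, 1])), spread)
})

test_that("CAP pseudo-F and eigenvalues match the vegan RDA oracle", {
  skip_if_not_installed("vegan")
  suppressMessages(library(vegan))  # Condition() must be visible in formulas
  set.seed(14)
  n <- 40
  Y <- matrix(rnorm(n * 8), n)
  g <- factor(rep(letters[1:4], each = 10))
  Y[, 1] <- Y[, 1] + 2 * as.integer(g)
  z <- rnorm(n)
  cap <- capOrdination(Y, g)
  m <- vegan::rda(Y ~ g)
  expect_equal(pseudoF(cap),
               unname(vegan::anova.cca(m, permutations = 99)$F[1]),
               tolerance = 1e-8)
  expect_equal(capEigenvalues(cap) / sum(capEigenvalues(cap)),
               unname(m$CCA$eig / sum(m$CCA$eig)), tolerance = 1e-8)
  capz <- capOrdination(Y, g, covariate = z)
  mz <- vegan::rda(Y ~ g + Condition(z))
  expect_equal(pseudoF(capz),
               unname(vegan::anova.cca(mz, permutations = 99)$F[1]),
               tolerance = 1e-8)
})

test_that("covariate equal to the first principal direction absorbs its inertia", {
  set.seed(15)
  Y <- matrix(rnorm(30 * 5), 30) %*% diag(c(5, 2, 1, 0.5, 0.2))
  g <- factor(rep(c("a", "b", "c"), 10))
  pc <- prcomp(Y, center = TRUE)
  cov <- pc$x[, 1]
  cap <- capOrdination(Y, g, covariate = cov)
  expect_equal(cap@conditionalInertia,
               sum(pc$x[, 1]^2), tolerance = 1e-8)
})

test_that("inertia partition is exact on random datasets", {
  set.seed(16)
  for (i in 1:25) {
    n <- sample(12:30, 1)
    Y <- matrix(rnorm(n * 4), n)
    g <- factor(sample(letters[1:3], n, replace = TRUE))
    if (min(table(g)) < 2) next
    z <- if (i %% 2) rnorm(n) else NULL
    cap <- capOrdination(Y, g, covariate = z)
    ine <- capInertia(cap)
    expect_equal(unname(ine["total"]),
                 unname(sum(ine[c("conditional", "constrained", "residual")])),
                 tolerance = 1e-9)
  }
})

test_that("exhaustive permutation ANOVA equals exact enumeration", {
  set.seed(17)
  Y <- matrix(rnorm(6 * 3), 6)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  Y[g == "b", 1] <- Y[g == "b", 1] + 1
  got <- permutationAnova(Y, g, nPermutations = 2000)
  expect_true(got$exhaustive)
  expect_equal(got$nPermutations, 720L)
  # oracle: enumerate all orderings, recompute F through lm on the
  # centered response each time
  perms <- otoshape:::allPermutations(6L)
  fOf <- function(idx) {
    Yp <- scale(Y[idx, ], center = TRUE, scale = FALSE)
    fit <- lm(Yp ~ g)
    ssFit <- sum(fitted(fit)^2); ssRes <- sum(resid(fit)^2)
    (ssFit / 1) / (ssRes / 4)
  }
  fAll <- apply(perms, 1, fOf)
  fObs <- fOf(1:6)
  expect_equal(got$pseudoF, fObs, tolerance = 1e-8)
  expect_equal(got$pValue, mean(fAll >= fObs - 1e-10), tolerance = 1e-12)
})

test_that("duplicated groups give no signal; separated groups the minimum p", {
  set.seed(18)
  block <- matrix(rnorm(5 * 4), 5)
  Y <- rbind(block, block)
  g <- factor(rep(c("a", "b"), each = 5))
  got <- suppressWarnings(permutationAnova(Y, g, nPermutations = 500,
                                           exhaustive = FALSE, seed = 1))
  expect_gt(got$pValue, 0.5)
  Y2 <- rbind(matrix(rnorm(15 * 4), 15), matrix(rnorm(15 * 4, 10), 15))
  g2 <- factor(rep(c("a", "b"), each = 15))
  got2 <- permutationAnova(Y2, g2, nPermutations = 199, seed = 2)
  expect_equal(got2$pValue, 1 / 200)
})

test_that("a-priori contrasts pool populations and subset specimens", {
  set.seed(19)
  Y <- matrix(rnorm(40 * 3), 40)
  g <- factor(rep(c("P1", "P2", "P3", "P4"), each = 10))
  Y[g == "P1", ] <- Y[g == "P1", ] + 3
  ct <- list(focal = "P1", pooled = c("P2", "P3"))
  got <- permutationAnova(Y, g, contrast = ct, nPermutations = 199, seed = 3)
  expect_equal(got$df[1], 1)
  expect_equal(got$df[2], 30 - 1 - 1)  # P4 dropped
  expect_equal(got$pValue, 1 / 200)
  expect_error(permutationAnova(Y, g, contrast = list(only = "P1"),
                                nPermutations = 199), "2 groups")
})

test_that("within-cell variance matches hand values and the trace identity", {
  m <- matrix(c(0, 2), 2, 1)
  g <- factor(c("a", "a"))
  vt <- withinVariance(m, g)
  expect_equal(vt$variance, 2)       # d^2 = 4, n(n-1) = 2
  m2 <- rbind(m, m[1, , drop = FALSE] * 0)
  vtIdent <- withinVariance(rbind(c(1, 5), c(1, 5)), factor(c("a", "a")))
  expect_equal(vtIdent$variance, 0)
  set.seed(20)
  cell <- matrix(rnorm(20 * 5), 20)
  vt2 <- withinVariance(cell, factor(rep("a", 20)))
  expect_equal(vt2$variance, sum(apply(cell, 2, var)), tolerance = 1e-10)
  # cells with n < 2 are omitted
  g3 <- factor(c(rep("a", 19), "b"))
  vt3 <- withinVariance(cell, g3)
  expect_equal(vt3$population_id, "a")
})

test_that("dispersion-age regression recovers a noiseless slope", {
  ages <- rep(3:8, each = 4)
  g <- factor(rep("P1", length(ages)))
  # one coordinate per specimen whose cell variance is exactly 2 - 0.25*age:
  # place pairs at +/- sqrt(v/2)... use specimen mode on distances instead
  set.seed(21)
  vTarget <- 2 - 0.25 * (3:8)
  m <- matrix(0, length(ages), 1)
  for (i in seq_along(3:8)) {
    idx <- which(ages == (3:8)[i])
    h <- sqrt(3 * vTarget[i] / 4)   # var of (-h, h, -h, h) is 4h^2/3
    m[idx, 1] <- c(-h, h, -h, h)
  }
  got <- suppressWarnings(varianceAgeRegression(m, g, ages, mode = "cell"))
  expect_equal(got$slope, -0.25, tolerance = 1e-10)
  expect_lt(got$p_value, 1e-10)
  # two cells -> exact interpolating slope
  ages2 <- c(3, 3, 6, 6)
  m2 <- matrix(c(0, 2, 0, 4), 4, 1)
  g2 <- factor(rep("P1", 4))
  got2 <- varianceAgeRegression(m2, g2, ages2, mode = "cell")
  expect_equal(got2$slope, (8 - 2) / 3, tolerance = 1e-10)
  expect_error(varianceAgeRegression(m2, g2, rep(3, 4)), "constant")
})

test_that("dispersion-age regression has uniform p under the null", {
  set.seed(22)
  ps <- replicate(300, {
    ages <- sample(3:6, 40, replace = TRUE)
    g <- factor(rep(c("P1", "P2"), each = 20))
    m <- matrix(rnorm(40 * 3), 40)
    out <- try(varianceAgeRegression(m, g, ages, mode = "cell"),
               silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out$p_value
  })
  ps <- ps[!is.na(ps)]
  rate <- mean(ps < 0.05)
  expect_gt(length(ps), 250)
  expect_lt(rate, qbinom(0.9995, length(ps), 0.05) / length(ps))
})
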