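# Statistical core: ANCOVA coefficient filtering, CAP ordination with
# covariate adjustment, ANOVA-like permutation tests, within-population
# variance and the dispersion-on-age regression.

# Accept either a WaveletDescriptors object or a plain specimens x
# variables matrix, resolving group/covariate columns from colData when
# available.
.coefInput <- function(x, group = NULL, covariate = NULL) {
  if (is(x, "WaveletDescriptors")) {
    sd <- specimenData(x)
    if (is.null(group) && "population_id" %in% colnames(sd))
      group <- sd$population_id
    m <- coefMatrix(x)
  } else {
    m <- as.matrix(x)
  }
  if (is.null(group)) stop("group labels are required")
  group <- factor(group)
  stopifnot(length(group) == nrow(m))
  list(m = m, group = group, covariate = covariate)
}

#' Filter coefficients with a length-by-population ANCOVA
#'
#' Otolith size scales with fish length, and if the length--shape
#' relationship differs among populations a coefficient confounds shape
#' with growth. For each wavelet coefficient this fits
#' \code{coefficient ~ length * population} and tests the interaction term
#' with the nested-model F-test; coefficients with interaction p < alpha
#' are excluded from all downstream analyses. P-values are per coefficient
#' with no multiple-testing correction, so under the no-interaction null
#' about alpha of the coefficients are dropped by chance — a deliberately
#' conservative screen.
#'
#' @param x a [WaveletDescriptors-class] object or specimens x
#'   coefficients matrix.
#' @param length_cm per-specimen fish length (taken from the metadata when
#'   \code{x} carries it).
#' @param group population labels (ditto).
#' @param alpha interaction-test significance threshold (default 0.05).
#' @return an object of class \code{"FilterReport"}: list with
#'   \code{kept} (column indices), \code{dropped} (data.frame of index and
#'   interaction p-value), \code{pValues} (all coefficients) and
#'   \code{alpha}.
#' @export
ancovaFilter <- function(x, length_cm = NULL, group = NULL, alpha = 0.05) {
  inp <- .coefInput(x, group)
  if (is.null(length_cm) && is(x, "WaveletDescriptors"))
    length_cm <- specimenData(x)$length_cm
  stopifnot(!is.null(length_cm), length(length_cm) == nrow(inp$m),
            alpha > 0, alpha < 1)
  if (any(length_cm <= 0, na.rm = TRUE)) stop("lengths must be positive")
  keep <- !is.na(length_cm) & !is.na(inp$group)
  m <- inp$m[keep, , drop = FALSE]
  g <- droplevels(inp$group[keep])
  len <- length_cm[keep]
  small <- names(table(g))[table(g) < 3L]
  if (length(small)) {
    warning("excluding population(s) with < 3 specimens from the ANCOVA: ",
            paste(small, collapse = ", "))
    ok <- !g %in% small
    m <- m[ok, , drop = FALSE]; g <- droplevels(g[ok]); len <- len[ok]
  }
  k <- nlevels(g); n <- nrow(m)
  if (k < 2L) stop("ancovaFilter needs >= 2 populations")
  qrFull <- qr(model.matrix(~ len * g))
  qrRed <- qr(model.matrix(~ len + g))
  df1 <- qrFull$rank - qrRed$rank
  df2 <- n - qrFull$rank
  if (df1 < 1L || df2 < 1L) stop("not enough residual degrees of freedom")
  rssF <- colSums(qr.resid(qrFull, m)^2)
  rssR <- colSums(qr.resid(qrRed, m)^2)
  f <- ((rssR - rssF) / df1) / (rssF / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  dropped <- which(p < alpha)
  out <- list(kept = setdiff(seq_len(ncol(m)), dropped),
              dropped = data.frame(index = dropped,
                                   p_value = p[dropped], row.names = NULL),
              pValues = p, alpha = alpha, df = c(df1, df2))
  class(out) <- "FilterReport"
  out
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("ANCOVA length-by-population filter (alpha =", x$alpha, "):",
      length(x$kept), "coefficients kept,", nrow(x$dropped), "dropped\n")
  invisible(x)
}

#' Subset a descriptor object to the coefficients kept by a filter
#'
#' @param x a [WaveletDescriptors-class] object.
#' @param report a \code{FilterReport} from [ancovaFilter()].
#' @return \code{x} restricted to the kept coefficients.
#' @export
applyFilter <- function(x, report) {
  stopifnot(is(x, "WaveletDescriptors"), inherits(report, "FilterReport"))
  x[report$kept, ]
}

# Principal-coordinate scores of the Euclidean distance matrix among rows
# of m. All axes with eigenvalue > tol * max are retained. For Euclidean
# input this is an exact rigid re-embedding of the centered data.
.pcoaScores <- function(m, tol = 1e-10) {
  d2 <- as.matrix(dist(m))^2
  n <- nrow(d2)
  A <- -0.5 * d2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J  # Gower double centering
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) stop("distance matrix has no positive principal axes")
  Q <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                sum(keep))
  rownames(Q) <- rownames(m)
  Q
}

# Shared CAP machinery: principal coordinates, optional covariate
# residualization, orthonormal constraint basis. Returns everything the
# ordination and the permutation test need.
.capCore <- function(m, group, covariate = NULL, tol = 1e-10) {
  n <- nrow(m)
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  Q <- .pcoaScores(m, tol)
  total <- sum(Q^2)
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == n)
    Z <- cbind(1, as.numeric(covariate))
    qrZ <- qr(Z)
    conditional <- sum(qr.fitted(qrZ, Q)^2)
    Qr <- qr.resid(qrZ, Q)
    p0 <- qrZ$rank
  } else {
    qrZ <- qr(matrix(1, n, 1))
    conditional <- 0
    Qr <- Q  # PCoA scores are already centered
    p0 <- 1L
  }
  X <- model.matrix(~ group)[, -1L, drop = FALSE]  # intercept lives in Z
  Xr <- qr.resid(qrZ, X)
  qrX <- qr(Xr)
  dfC <- qrX$rank
  P <- qr.Q(qrX)[, seq_len(dfC), drop = FALSE]
  constrained <- sum(crossprod(P, Qr)^2)
  residual <- total - conditional - constrained
  dfR <- n - p0 - dfC
  list(Q = Q, Qr = Qr, P = P, group = group, total = total,
       conditional = conditional, constrained = constrained,
       residual = residual, dfC = dfC, dfR = dfR)
}

# Permutation distribution of the pseudo-F under row permutation of the
# (residualized) principal coordinates; reduced-model permutation when a
# covariate is present.
.permuteF <- function(core, nPermutations, seed, exhaustive) {
  n <- nrow(core$Qr)
  fStat <- function(idx) {
    cI <- sum(crossprod(core$P, core$Qr[idx, , drop = FALSE])^2)
    (cI / core$dfC) / (((core$total - core$conditional) - cI) / core$dfR)
  }
  fObs <- (core$constrained / core$dfC) / (core$residual / core$dfR)
  nAll <- if (n <= 8L) factorial(n) else Inf
  if (is.null(exhaustive)) exhaustive <- nAll <= nPermutations
  tolF <- 1e-8 * (1 + abs(fObs))
  if (exhaustive) {
    if (n > 8L) stop("exhaustive mode supports at most 8 specimens")
    perms <- allPermutations(n)
    fAll <- apply(perms, 1L, fStat)
    p <- mean(fAll >= fObs - tolF)
    list(pseudoF = fObs, pValue = p, nPermutations = nrow(perms),
         exhaustive = TRUE)
  } else {
    hits <- withSeed(seed, {
      sum(vapply(seq_len(nPermutations),
                 function(i) fStat(sample.int(n)) >= fObs - tolF,
                 logical(1)))
    })
    list(pseudoF = fObs, pValue = (1 + hits) / (1 + nPermutations),
         nPermutations = as.integer(nPermutations), exhaustive = FALSE)
  }
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' Constrained ordination of the among-specimen Euclidean distances on
#' population membership: (1) principal-coordinate decomposition of the
#' distance matrix (all axes with eigenvalue > 1e-10 of the largest are
#' kept); (2) optional adjustment for a covariate (age) by linear
#' residualization of the coordinate scores, the covariate's share of the
#' inertia reported as conditional; (3) redundancy-style analysis on
#' population indicators, yielding the constrained axes CAP1, CAP2, ...
#' With Euclidean distances on wavelet coefficients this is equivalent to
#' a (partial) redundancy analysis on the coefficients themselves — the
#' natural metric for orthonormal-transform descriptors.
#'
#' @param x a [WaveletDescriptors-class] object (typically after
#'   [applyFilter()]) or a specimens x variables matrix.
#' @param group population labels (default: metadata
#'   \code{population_id}).
#' @param covariate optional numeric covariate (e.g. age) to partial out.
#' @param nPermutations if > 0, run the ANOVA-like permutation test for
#'   the significance of the constraints (see [permutationAnova()]).
#' @param seed RNG seed for the permutation test.
#' @param exhaustive permutation mode; NULL = automatic (enumerate all
#'   n! row orders when that is no more work than \code{nPermutations}).
#' @return a [CapOrdination-class] object.
#' @export
capOrdination <- function(x, group = NULL, covariate = NULL,
                          nPermutations = 0L, seed = NULL,
                          exhaustive = NULL) {
  inp <- .coefInput(x, group)
  cov <- covariate
  if (!is.null(cov) && length(cov) != nrow(inp$m))
    stop("covariate must be NULL or one value per specimen")
  n <- nrow(inp$m)
  if (n < nlevels(droplevels(inp$group)) + 2L)
    stop("need at least #populations + 2 specimens")
  empty <- setdiff(levels(inp$group), as.character(unique(inp$group)))
  if (length(empty))
    warning("dropping empty population level(s): ",
            paste(empty, collapse = ", "))
  core <- .capCore(inp$m, inp$group, cov)
  sv <- svd(core$P %*% crossprod(core$P, core$Qr))
  keep <- which(sv$d^2 > 1e-10 * max(sv$d^2))
  keep <- head(keep, core$dfC)
  eig <- sv$d[keep]^2
  scores <- core$Qr %*% sv$v[, keep, drop = FALSE]
  colnames(scores) <- paste0("CAP", seq_along(keep))
  rownames(scores) <- rownames(inp$m)
  cent <- rowsum(scores, core$group) / as.numeric(table(core$group))
  fObs <- (core$constrained / core$dfC) / (core$residual / core$dfR)
  pv <- NA_real_
  nPerm <- 0L
  if (nPermutations > 0L) {
    pt <- .permuteF(core, nPermutations, seed, exhaustive)
    pv <- pt$pValue
    nPerm <- pt$nPermutations
  }
  new("CapOrdination", scores = scores, centroids = cent,
      eigenvalues = eig, totalInertia = core$total,
      constrainedInertia = core$constrained,
      conditionalInertia = core$conditional,
      residualInertia = core$residual, pseudoF = fObs, pValue = pv,
      df = c(core$dfC, core$dfR), group = core$group,
      nPermutations = as.integer(nPerm))
}

#' ANOVA-like permutation test for population differences in shape
#'
#' Tests the significance of the CAP constraints with a pseudo-F statistic
#' — (constrained inertia / df1) / (residual inertia / df2) — against a
#' null distribution obtained by permuting specimen rows. With a
#' covariate, rows of the covariate-residualized coordinates are permuted
#' (reduced-model permutation). The sampled p-value uses the add-one
#' convention p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm), so the
#' smallest attainable p is 1/(n_perm + 1); ties count as extreme. When
#' enumerating every row order costs no more than \code{nPermutations}
#' draws (n! <= n_perm) the test switches to exact exhaustive mode, where
#' p is the fraction of all n! orderings (identity included) with
#' F >= F_obs. An a-priori \code{contrast} pools populations into named
#' super-groups and tests that coarser constraint on the corresponding
#' specimen subset (e.g. one fjord population against all others pooled).
#'
#' @param x a [WaveletDescriptors-class] object or specimens x variables
#'   matrix.
#' @param group population labels.
#' @param covariate optional numeric covariate (age) to condition on.
#' @param contrast optional named list mapping contrast levels to
#'   character vectors of population ids; specimens from unlisted
#'   populations are dropped.
#' @param nPermutations number of random permutations (>= 99; default
#'   2000).
#' @param seed RNG seed for reproducibility.
#' @param exhaustive TRUE/FALSE to force the mode; NULL = automatic.
#' @return list of class \code{"permAnova"}: \code{pseudoF},
#'   \code{pValue}, \code{df}, \code{inertia} (named components),
#'   \code{nPermutations}, \code{exhaustive}.
#' @export
permutationAnova <- function(x, group = NULL, covariate = NULL,
                             contrast = NULL, nPermutations = 2000L,
                             seed = NULL, exhaustive = NULL) {
  stopifnot(nPermutations >= 99L)
  inp <- .coefInput(x, group)
  m <- inp$m; g <- inp$group; cov <- covariate
  if (!is.null(contrast)) {
    stopifnot(is.list(contrast), !is.null(names(contrast)))
    map <- rep(NA_character_, length(g))
    for (lev in names(contrast))
      map[as.character(g) %in% contrast[[lev]]] <- lev
    keep <- !is.na(map)
    if (!any(keep)) stop("contrast matches no specimens")
    m <- m[keep, , drop = FALSE]
    if (!is.null(cov)) cov <- cov[keep]
    g <- factor(map[keep], levels = names(contrast))
  }
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("permutation test needs >= 2 groups")
  core <- .capCore(m, g, cov)
  pt <- .permuteF(core, nPermutations, seed, exhaustive)
  out <- c(pt, list(df = c(core$dfC, core$dfR),
                    inertia = c(total = core$total,
                                conditional = core$conditional,
                                constrained = core$constrained,
                                residual = core$residual)))
  class(out) <- "permAnova"
  out
}

#' @export
print.permAnova <- function(x, ...) {
  cat("ANOVA-like permutation test:",
      if (x$exhaustive) "exhaustive," else "sampled,",
      x$nPermutations, "permutations\n")
  cat("  pseudo-F =", format(x$pseudoF, digits = 5), "on", x$df[1], "and",
      x$df[2], "df; p =", format(x$pValue, digits = 4), "\n")
  invisible(x)
}

#' Within-population shape variance per age group
#'
#' For each population x age-group cell with at least two specimens,
#' summarises dispersion as the mean squared pairwise Euclidean distance
#' over ordered pairs, variance = sum_\{i<j\} d_ij^2 / (n (n-1)) — which
#' equals the trace of the within-cell covariance matrix (the sum of the
#' per-dimension sample variances). Cells with n < 2 are omitted.
#'
#' @param x a [WaveletDescriptors-class] object, [CapOrdination-class]
#'   scores, or a specimens x variables matrix.
#' @param group population labels.
#' @param age_group age-group labels (see [assignAgeGroups()]); specimens
#'   with NA are skipped.
#' @return data.frame with columns \code{population_id}, \code{age_group},
#'   \code{variance}, \code{n}, \code{mean_age} (NA when ages are not
#'   available).
#' @export
withinVariance <- function(x, group = NULL, age_group = NULL) {
  if (is(x, "CapOrdination")) {
    m <- capScores(x)
    if (is.null(group)) group <- x@group
  } else {
    inp <- .coefInput(x, group)
    m <- inp$m; group <- inp$group
  }
  age <- NULL
  if (is(x, "WaveletDescriptors")) {
    sd <- specimenData(x)
    if (is.null(age_group) && "age_group" %in% colnames(sd))
      age_group <- sd$age_group
    if ("age_years" %in% colnames(sd)) age <- sd$age_years
  }
  if (is.null(age_group)) age_group <- factor(rep("all", nrow(m)))
  group <- factor(group); age_group <- factor(age_group)
  out <- list()
  for (pop in levels(group)) for (ag in levels(age_group)) {
    idx <- which(group == pop & age_group == ag)
    if (length(idx) < 2L) next
    n <- length(idx)
    v <- sum(dist(m[idx, , drop = FALSE])^2) / (n * (n - 1))
    out[[length(out) + 1L]] <- data.frame(
      population_id = pop, age_group = ag, variance = v, n = n,
      mean_age = if (is.null(age)) NA_real_ else mean(age[idx]))
  }
  if (!length(out)) stop("no (population, age group) cell has >= 2 specimens")
  do.call(rbind, out)
}

#' Regression of within-population dispersion on age
#'
#' Tests whether individual shape variation shrinks with age. In
#' \code{"cell"} mode (default) the response is the within-cell variance
#' from [withinVariance()] computed per population x age cell and the
#' predictor the cell's mean age; in \code{"specimen"} mode the response
#' is each specimen's Euclidean distance to its cell centroid and the
#' predictor its own age. Either way an ordinary least-squares slope with
#' its t-test p-value is returned; a negative slope means dispersion
#' decreases with age.
#'
#' @param x coefficient matrix, [WaveletDescriptors-class] or
#'   [CapOrdination-class] (as in [withinVariance()]).
#' @param group population labels.
#' @param age per-specimen age in years.
#' @param mode \code{"cell"} or \code{"specimen"}.
#' @param cellBy how to bin ages into cells: \code{"age"} (each integer
#'   age its own cell) or a data.frame of age groups as in [ageGroups()].
#' @return list with \code{slope}, \code{p_value}, \code{n} (observations
#'   in the regression), \code{mode} and the \code{lm} fit.
#' @export
varianceAgeRegression <- function(x, group = NULL, age = NULL,
                                  mode = c("cell", "specimen"),
                                  cellBy = "age") {
  mode <- match.arg(mode)
  if (is(x, "WaveletDescriptors")) {
    sd <- specimenData(x)
    if (is.null(group)) group <- sd$population_id
    if (is.null(age)) age <- sd$age_years
    m <- coefMatrix(x)
  } else if (is(x, "CapOrdination")) {
    m <- capScores(x)
    if (is.null(group)) group <- x@group
  } else m <- as.matrix(x)
  stopifnot(!is.null(group), !is.null(age), length(age) == nrow(m))
  group <- factor(group)
  if (length(unique(age)) < 2L) stop("age is constant; no regression possible")
  if (identical(cellBy, "age")) {
    cellAge <- factor(age)
  } else {
    lab <- assignAgeGroups(data.frame(age_years = age), cellBy)$age_group
    cellAge <- lab
  }
  if (mode == "cell") {
    vt <- withinVariance(m, group = group, age_group = cellAge)
    ageNum <- vapply(seq_len(nrow(vt)), function(i)
      mean(age[group == vt$population_id[i] & cellAge == vt$age_group[i]]),
      numeric(1))
    fit <- lm(vt$variance ~ ageNum)
    nObs <- nrow(vt)
  } else {
    cell <- interaction(group, cellAge, drop = TRUE)
    ok <- cell %in% names(table(cell))[table(cell) >= 2L]
    d <- numeric(0); aa <- numeric(0)
    for (cl in levels(droplevels(cell[ok]))) {
      idx <- which(cell == cl)
      ctr <- colMeans(m[idx, , drop = FALSE])
      d <- c(d, sqrt(rowSums(sweep(m[idx, , drop = FALSE], 2L, ctr)^2)))
      aa <- c(aa, age[idx])
    }
    fit <- lm(d ~ aa)
    nObs <- length(d)
  }
  sm <- summary(fit)$coefficients
  pv <- if (nrow(sm) >= 2L && ncol(sm) >= 4L) sm[2L, 4L] else NA_real_
  list(slope = unname(coef(fit)[2L]), p_value = pv, n = nObs,
       mode = mode, fit = fit)
}
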