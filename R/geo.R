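# Along-coast geographic distances, shape distances on CAP centroids, the
# Mantel test and the isolation-by-distance report.

.EARTH_RADIUS_KM <- 6371.0  # mean Earth radius; spherical model

.haversineKm <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM * 1000) / 1000
}

#' Along-coast distances between populations
#'
#' Distances in km measured along an ordered coastline path rather than as
#' the crow flies: each population is anchored to its nearest waypoint
#' (great-circle distance) and the distance between two populations is the
#' absolute difference of their cumulative along-path positions. Segments
#' are great-circle arcs (haversine, mean Earth radius 6371 km); a
#' geodesic ellipsoid model would change hand-traced coastal paths by far
#' less than the tracing error.
#'
#' @param coastline data.frame with ordered waypoint columns \code{lat},
#'   \code{lon} (southern anchor first), at least 2 rows.
#' @param populations data.frame with columns \code{population_id},
#'   \code{latitude}, \code{longitude} (one row per population), or a
#'   specimen table (unique populations are extracted).
#' @return symmetric distance matrix (km) with population ids as dimnames.
#' @export
coastlineDistances <- function(coastline, populations) {
  stopifnot(all(c("lat", "lon") %in% colnames(coastline)),
            nrow(coastline) >= 2L)
  pops <- unique(populations[, c("population_id", "latitude", "longitude")])
  if (anyNA(pops))
    stop("population(s) without coordinates: ",
         paste(pops$population_id[!complete.cases(pops)], collapse = ", "))
  wp <- cbind(coastline$lon, coastline$lat)
  seg <- .haversineKm(wp[-nrow(wp), , drop = FALSE], wp[-1L, , drop = FALSE])
  cum <- c(0, cumsum(seg))
  anchor <- vapply(seq_len(nrow(pops)), function(i) {
    d <- .haversineKm(cbind(pops$longitude[i], pops$latitude[i]), wp)
    which.min(d)
  }, integer(1))
  pos <- cum[anchor]
  D <- abs(outer(pos, pos, "-"))
  dimnames(D) <- list(pops$population_id, pops$population_id)
  diag(D) <- 0
  D
}

#' Shape distances between population centroids
#'
#' Pairwise Euclidean distances between population mean scores on the
#' first two constrained axes (CAP1, CAP2) of a CAP ordination — the
#' morphological distance matrix entering the isolation-by-distance test.
#'
#' @param x a [CapOrdination-class] object, or a populations x axes
#'   matrix of centroid scores (row names = population ids).
#' @return symmetric distance matrix with population ids as dimnames.
#' @export
shapeDistances <- function(x) {
  cent <- if (is(x, "CapOrdination")) capCentroids(x) else as.matrix(x)
  if (ncol(cent) < 2L)
    stop("need at least 2 constrained axes (CAP1, CAP2); ",
         "with only 2 populations CAP yields a single axis — ",
         "include more populations or use the single-axis scores directly")
  if (nrow(cent) < 3L) stop("need at least 3 populations")
  D <- as.matrix(dist(cent[, 1:2, drop = FALSE]))
  dimnames(D) <- list(rownames(cent), rownames(cent))
  D
}

.checkDistanceMatrix <- function(D, name) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop(name, " must have population labels")
  if (max(abs(D - t(D))) > 1e-9) stop(name, " is not symmetric")
  if (any(abs(diag(D)) > 0)) stop(name, " must have a zero diagonal")
  D
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation r over the n(n-1)/2 off-diagonal upper-triangle
#' pairs, tested by simultaneously permuting the rows and columns of the
#' second matrix. Default is one-sided against positive association (the
#' isolation-by-distance alternative); sampled p uses the add-one
#' convention. When enumerating all n! relabelings costs no more than
#' \code{nPermutations} draws the test is exact (exhaustive mode, identity
#' permutation included in the count).
#'
#' @param d1,d2 symmetric distance matrices with identical population
#'   labels in identical order (at least 4 populations).
#' @param nPermutations number of permutations (default 10000).
#' @param seed RNG seed.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @param exhaustive TRUE/FALSE to force the mode; NULL = automatic.
#' @return list of class \code{"mantelTest"}: \code{statistic} (r),
#'   \code{pValue}, \code{nPermutations}, \code{exhaustive},
#'   \code{alternative}, \code{n}.
#' @export
mantelTest <- function(d1, d2, nPermutations = 10000L, seed = NULL,
                       alternative = c("greater", "two.sided"),
                       exhaustive = NULL) {
  alternative <- match.arg(alternative)
  d1 <- .checkDistanceMatrix(d1, "d1")
  d2 <- .checkDistanceMatrix(d2, "d2")
  if (!identical(rownames(d1), rownames(d2))) {
    diff <- c(setdiff(rownames(d1), rownames(d2)),
              setdiff(rownames(d2), rownames(d1)))
    stop("distance matrices must share labels in the same order; ",
         "mismatch: ", paste(unique(c(diff, "ordering")), collapse = ", "))
  }
  n <- nrow(d1)
  if (n < 4L) stop("Mantel test needs at least 4 populations")
  stopifnot(nPermutations >= 99L)
  v1 <- upperTri(d1)
  rObs <- cor(v1, upperTri(d2))
  stat <- function(idx) cor(v1, upperTri(d2[idx, idx]))
  extreme <- function(r) {
    if (alternative == "greater") r >= rObs - 1e-12 else
      abs(r) >= abs(rObs) - 1e-12
  }
  nAll <- if (n <= 8L) factorial(n) else Inf
  if (is.null(exhaustive)) exhaustive <- nAll <= nPermutations
  if (exhaustive) {
    if (n > 8L) stop("exhaustive mode supports at most 8 populations")
    perms <- allPermutations(n)
    rAll <- apply(perms, 1L, stat)
    p <- mean(extreme(rAll))
    nP <- nrow(perms)
  } else {
    hits <- withSeed(seed, {
      sum(vapply(seq_len(nPermutations),
                 function(i) extreme(stat(sample.int(n))), logical(1)))
    })
    p <- (1 + hits) / (1 + nPermutations)
    nP <- as.integer(nPermutations)
  }
  out <- list(statistic = rObs, pValue = p, nPermutations = nP,
              exhaustive = exhaustive, alternative = alternative, n = n)
  class(out) <- "mantelTest"
  out
}

#' @export
print.mantelTest <- function(x, ...) {
  cat("Mantel test (", x$alternative, ", ",
      if (x$exhaustive) "exhaustive" else "sampled", "): r = ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$pValue, digits = 4), " (", x$nPermutations,
      " permutations, n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Isolation-by-distance pair report
#'
#' Regresses shape distance on along-coast geographic distance over all
#' population pairs and flags pairs whose residual exceeds two standard
#' deviations of the residuals — pairs more (or less) different in shape
#' than their geographic separation predicts.
#'
#' @param d_shape,d_geo aligned distance matrices (shape, km).
#' @return data.frame with one row per unordered pair: \code{pop1},
#'   \code{pop2}, \code{geo_km}, \code{shape_dist}, \code{residual},
#'   \code{outlier} (logical, |residual| > 2 SD).
#' @export
ibdReport <- function(d_shape, d_geo) {
  d_shape <- .checkDistanceMatrix(d_shape, "d_shape")
  d_geo <- .checkDistanceMatrix(d_geo, "d_geo")
  if (!identical(rownames(d_shape), rownames(d_geo)))
    stop("distance matrices must share labels in the same order")
  n <- nrow(d_shape)
  ut <- which(upper.tri(d_shape), arr.ind = TRUE)
  if (nrow(ut) < 3L) stop("need at least 3 population pairs")
  df <- data.frame(pop1 = rownames(d_shape)[ut[, 1]],
                   pop2 = rownames(d_shape)[ut[, 2]],
                   geo_km = d_geo[ut], shape_dist = d_shape[ut])
  fit <- lm(shape_dist ~ geo_km, data = df)
  df$residual <- unname(fit$residuals)
  s <- sd(df$residual)
  # guard against an (near-)exact linear fit, where 2 SD of pure rounding
  # noise would flag arbitrary pairs
  degenerate <- s <= 1e-10 * (max(abs(df$shape_dist)) + 1)
  df$outlier <- if (degenerate) rep(FALSE, nrow(df)) else
    abs(df$residual) > 2 * s
  attr(df, "fit") <- fit
  attr(df, "residual_sd") <- s
  df
}
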