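# Periodized orthonormal discrete wavelet transform of circular radius
# functions. The radius-vs-angle function is periodic, so circular
# convolution is the natural boundary rule and the analysis matrix (even
# circular shifts of the scaling/wavelet filter pair) is exactly
# orthogonal: energy is conserved and the inverse is the transpose.

# Scaling (low-pass) filter taps. "haar" and "db4" are the classical
# Daubechies extremal-phase filters with 1 and 4 vanishing moments;
# "sym10" is the least-asymmetric Daubechies filter with 10 vanishing
# moments (20 taps), the default shape-descriptor filter here.
.WAVELET_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  sym10 = c(0.0007701598091144901, 9.563267072289475e-05,
            -0.008641299277022422, -0.0014653825813050513,
            0.0459272392310922, 0.011609893903711381,
            -0.15949427888491757, -0.07088053578324385,
            0.47169066693843925, 0.7695100370211071,
            0.38382676106708546, -0.03553674047381755,
            -0.0319900568824278, 0.04999497207737669,
            0.005764912033581909, -0.02035493981231129,
            -0.0008043589320165449, 0.004593173585311828,
            5.7036083618494284e-05, -0.0004593294210046588)
)

#' Quadrature mirror filter pair for a wavelet family
#'
#' @param family \code{"sym10"} (default downstream), \code{"db4"} or
#'   \code{"haar"}.
#' @return list with low-pass taps \code{h} and high-pass taps \code{g}
#'   (\code{g[l] = (-1)^(l-1) h[L - l + 1]}).
#' @export
waveletFilter <- function(family = c("sym10", "db4", "haar")) {
  family <- match.arg(family)
  h <- .WAVELET_FILTERS[[family]]
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * h[L - seq_len(L) + 1L]
  list(h = h, g = g, length = L, family = family)
}

#' Maximum usable decomposition depth
#'
#' Decomposition stops before the signal at the current level becomes
#' shorter than the filter, so every level's analysis matrix stays exactly
#' orthogonal (no filter wrap-around past a full period).
#'
#' @param n signal length (power of two).
#' @param family wavelet family name.
#' @return integer number of levels.
#' @export
maxDwtLevels <- function(n, family = "sym10") {
  L <- waveletFilter(family)$length
  lev <- 0L
  len <- as.integer(n)
  while (len >= max(L, 2L) && len %% 2L == 0L) {
    lev <- lev + 1L
    len <- len %/% 2L
  }
  if (lev < 1L) stop("signal too short for family ", family)
  lev
}

# One analysis step: x (length n, even) -> list(a, d) of length n/2.
# a[k] = sum_l h[l] x[(2(k-1) + l - 1) mod n + 1].
.dwtStep <- function(x, h, g) {
  n <- length(x)
  half <- n %/% 2L
  idx <- (outer(2L * (seq_len(half) - 1L), seq_along(h) - 1L, "+") %% n) + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% h), d = drop(xm %*% g))
}

# One synthesis step (transpose of the analysis step).
.idwtStep <- function(a, d, h, g) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (l in seq_along(h)) {
    m <- ((base + l - 1L) %% n) + 1L
    x[m] <- x[m] + a * h[l] + d * g[l]
  }
  x
}

#' Discrete wavelet transform of a radial profile
#'
#' Full orthonormal dyadic decomposition of the circular radius function.
#' The output has the same length as the input and is ordered coarse to
#' fine: scaling (approximation) coefficients at the deepest level first,
#' then detail bands from coarsest (level = \code{levels}) down to finest
#' (level 1). Orthonormality means the total energy (sum of squares) of
#' the coefficients equals that of the radii exactly.
#'
#' @param x numeric vector of length 2^J, or a [RadialProfile-class].
#' @param family wavelet family (see [waveletFilter()]).
#' @param levels decomposition depth; default the maximum usable depth for
#'   this length and filter.
#' @return numeric coefficient vector of length 2^J with attribute
#'   \code{"map"}: a data.frame (kind, level, position, angle) aligned with
#'   the coefficients (see [coefMap()]).
#' @export
dwtRadii <- function(x, family = "sym10", levels = NULL) {
  if (is(x, "RadialProfile")) x <- profileRadii(x)
  n <- length(x)
  if (!isPowerOfTwo(n))
    stop("input length must be a power of two, got ", n)
  if (is.null(levels)) levels <- maxDwtLevels(n, family)
  stopifnot(levels >= 1L, 2^levels <= n)
  f <- waveletFilter(family)
  details <- vector("list", levels)
  cur <- x
  for (j in seq_len(levels)) {
    st <- .dwtStep(cur, f$h, f$g)
    details[[j]] <- st$d
    cur <- st$a
  }
  out <- c(cur, unlist(rev(details)))
  attr(out, "map") <- coefMap(n, levels, family)
  out
}

#' Inverse discrete wavelet transform
#'
#' Exact inverse of [dwtRadii()] (the transform is orthogonal, so the
#' synthesis filters are the analysis filters transposed).
#'
#' @param coefs coefficient vector from [dwtRadii()] (coarse-to-fine
#'   ordering).
#' @param family wavelet family; must match the forward transform.
#' @param levels decomposition depth of the forward transform; default the
#'   maximum usable depth (the [dwtRadii()] default).
#' @return numeric vector of radii.
#' @export
idwtRadii <- function(coefs, family = "sym10", levels = NULL) {
  n <- length(coefs)
  if (!isPowerOfTwo(n))
    stop("coefficient length must be a power of two, got ", n)
  if (is.null(levels)) levels <- maxDwtLevels(n, family)
  f <- waveletFilter(family)
  nApprox <- n %/% 2L^levels
  a <- coefs[seq_len(nApprox)]
  pos <- nApprox
  for (j in rev(seq_len(levels))) {
    nd <- n %/% 2L^j
    d <- coefs[pos + seq_len(nd)]
    pos <- pos + nd
    a <- .idwtStep(a, d, f$h, f$g)
  }
  a
}

#' Coefficient annotation map for a dyadic decomposition
#'
#' Assigns each coefficient its kind (scaling \code{"s"} or detail
#' \code{"d"}), level, within-level position and centre angle on the
#' outline — the abscissa for plotting coefficient statistics (mean, SD,
#' ICC) against position along the outline. Within a band of m
#' coefficients, successive positions step 360/m degrees apart; the
#' band's offset is the circular energy centroid of its position-0 basis
#' function (the inverse transform of a unit coefficient), which accounts
#' for the phase delay of asymmetric filters. With \code{family = NULL} a
#' naive midpoint mapping 360 (k + 0.5) / m is used instead.
#'
#' @param n transform length (power of two).
#' @param levels decomposition depth.
#' @param family wavelet family used to place band centres; NULL for the
#'   naive midpoint mapping.
#' @return data.frame with columns \code{kind}, \code{level},
#'   \code{position}, \code{angle}, in coefficient order (coarse to fine).
#' @export
coefMap <- function(n, levels, family = "sym10") {
  nApprox <- n %/% 2L^levels
  bands <- list(data.frame(kind = "s", level = as.integer(levels),
                           position = seq_len(nApprox) - 1L))
  for (j in rev(seq_len(levels))) {
    nd <- n %/% 2L^j
    bands[[length(bands) + 1L]] <-
      data.frame(kind = "d", level = as.integer(j),
                 position = seq_len(nd) - 1L)
  }
  m <- do.call(rbind, bands)
  counts <- c(rep(nApprox, nApprox),
              unlist(lapply(rev(seq_len(levels)),
                            function(j) rep(n %/% 2L^j, n %/% 2L^j))))
  if (is.null(family)) {
    m$angle <- 360 * (m$position + 0.5) / counts
  } else {
    offs <- .bandOffsets(n, levels, family)
    key <- paste(m$kind, m$level)
    m$angle <- (360 * m$position / counts + offs[key]) %% 360
  }
  m
}

# Circular energy centroid (degrees) of each band's position-0 basis
# function; named by "kind level".
.bandOffsets <- function(n, levels, family) {
  nApprox <- n %/% 2L^levels
  bandLens <- c(nApprox, n %/% 2L^rev(seq_len(levels)))
  kinds <- c("s", rep("d", levels))
  levs <- c(levels, rev(seq_len(levels)))
  starts <- cumsum(c(0L, bandLens[-length(bandLens)]))
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  offs <- numeric(length(kinds))
  for (b in seq_along(kinds)) {
    e <- numeric(n)
    e[starts[b] + 1L] <- 1
    psi2 <- idwtRadii(e, family = family, levels = levels)^2
    ang <- atan2(sum(psi2 * sin(theta)), sum(psi2 * cos(theta)))
    offs[b] <- (ang * 180 / pi) %% 360
  }
  names(offs) <- paste(kinds, levs)
  offs
}

#' Build wavelet descriptors for a set of specimens
#'
#' Applies [dwtRadii()] to each specimen's radial profile and assembles
#' the [WaveletDescriptors-class] container with per-coefficient
#' annotation and the specimen metadata as \code{colData}.
#'
#' @param radii specimens x nAngles numeric matrix (rows named by
#'   specimen id), or a named list of [RadialProfile-class] objects.
#' @param specimens optional specimen metadata data.frame with a
#'   \code{specimen_id} column.
#' @param family,levels passed to [dwtRadii()].
#' @return a [WaveletDescriptors-class] object.
#' @export
buildDescriptors <- function(radii, specimens = NULL, family = "sym10",
                             levels = NULL) {
  if (is.list(radii) && !is.matrix(radii)) {
    nm <- names(radii)
    radii <- do.call(rbind, lapply(radii, function(p)
      if (is(p, "RadialProfile")) profileRadii(p) else as.numeric(p)))
    rownames(radii) <- nm
  }
  stopifnot(is.matrix(radii))
  n <- ncol(radii)
  if (is.null(levels)) levels <- maxDwtLevels(n, family)
  co <- t(apply(radii, 1L, dwtRadii, family = family, levels = levels))
  map <- coefMap(n, levels, family)
  colnames(co) <- sprintf("%s%d.%d", map$kind, map$level, map$position)
  .newDescriptors(co, specimens = specimens, rowInfo = map,
                  family = family, levels = levels, nAngles = n)
}
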