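# Image -> outline -> radial profile. Convention: a grayscale image is a
# numeric matrix indexed [x, y] with intensities in [0, 1], y increasing
# upward (EBImage's row-major, y-down frames are flipped on read so that
# outline coordinates live in ordinary mathematical axes).

#' Read a grayscale otolith image
#'
#' Reads PNG/TIFF/JPEG through EBImage, averages colour channels if
#' present, rescales to [0, 1] and flips the vertical axis so that y
#' increases upward. An optional horizontal mirror supports standardizing
#' left and right sagittae to a common orientation; which side a study
#' mirrors (if any) is a protocol choice, not something the package
#' decides.
#'
#' @param path image file path.
#' @param mirror \code{"none"} (default) or \code{"horizontal"}.
#' @return numeric matrix indexed [x, y] with values in [0, 1].
#' @export
readGrayImage <- function(path, mirror = c("none", "horizontal")) {
  mirror <- match.arg(mirror)
  img <- EBImage::readImage(path)
  d <- dim(img)
  px <- if (length(d) == 3L) apply(img, c(1L, 2L), mean) else EBImage::imageData(img)
  rng <- range(px)
  if (rng[2] > 1 || rng[1] < 0)
    px <- (px - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  px <- px[, rev(seq_len(ncol(px))), drop = FALSE]  # y now increases upward
  if (mirror == "horizontal") px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
  px
}

#' Threshold an image into an otolith mask
#'
#' Separates otolith from background by global thresholding (Otsu's method
#' by default). With \code{polarity = "auto"} the side of the threshold
#' forming the foreground is chosen automatically: of the two candidate
#' masks (bright side, dark side), the one whose largest connected
#' component has its centroid nearer the image centre wins, so images with
#' a light otolith on dark background and their inverses yield the same
#' mask.
#'
#' @param image numeric [x, y] matrix in [0, 1] (see [readGrayImage()]).
#' @param method thresholding method; only \code{"otsu"} is implemented.
#' @param polarity \code{"auto"}, \code{"light"} (foreground above the
#'   threshold) or \code{"dark"}.
#' @return logical matrix of the same dimension; TRUE = otolith.
#' @export
binarizeImage <- function(image, method = "otsu",
                          polarity = c("auto", "light", "dark")) {
  polarity <- match.arg(polarity)
  method <- match.arg(method, "otsu")
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (any(dim(image) < 64L))
    stop("image must be at least 64 x 64 pixels")
  if (diff(range(image)) < .Machine$double.eps)
    stop("no foreground: image is constant")
  th <- EBImage::otsu(EBImage::Image(image), range = range(image))
  light <- image > th
  if (polarity == "light") return(light)
  if (polarity == "dark") return(!light)
  # Score each candidate side by (border contact of its largest component,
  # centroid distance from the image centre, component area): an otolith
  # sits centrally and clear of the frame edge, the background does not.
  pick <- function(mask) {
    if (!any(mask)) return(c(Inf, Inf, Inf))
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    tab <- tabulate(as.integer(lab[lab > 0]))
    big <- which.max(tab)
    idx <- which(EBImage::imageData(lab) == big, arr.ind = TRUE)
    onBorder <- sum(idx[, 1] == 1L | idx[, 1] == nrow(mask) |
                    idx[, 2] == 1L | idx[, 2] == ncol(mask))
    ctr <- colMeans(idx)
    c(onBorder, sqrt(sum((ctr - dim(mask) / 2)^2)), tab[big])
  }
  sLight <- pick(light); sDark <- pick(!light)
  lightWins <- if (sLight[1] != sDark[1]) sLight[1] < sDark[1] else
    if (abs(sLight[2] - sDark[2]) > 0.5) sLight[2] < sDark[2] else
      sLight[3] <= sDark[3]
  if (lightWins) light else !light
}

#' Extract the closed outline of the otolith from a binary mask
#'
#' Keeps the largest connected foreground component, fills interior holes
#' and traces its boundary, returning the contour ordered
#' counter-clockwise in the y-up coordinate frame. If the component
#' touches the image border a warning flags a possibly clipped otolith.
#'
#' @param mask logical [x, y] matrix (see [binarizeImage()]).
#' @return two-column matrix of (x, y) boundary points (closed implicitly:
#'   the last point connects back to the first).
#' @export
extractOutline <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  if (!any(mask)) stop("no foreground component in mask")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  big <- which.max(tab)
  comp <- EBImage::imageData(lab) == big
  comp <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
  idx <- which(comp, arr.ind = TRUE)
  if (any(idx[, 1] == 1L | idx[, 1] == nrow(mask) |
          idx[, 2] == 1L | idx[, 2] == ncol(mask)))
    warning("largest component touches the image border; ",
            "the otolith may be clipped")
  ct <- EBImage::ocontour(EBImage::Image(comp * 1))[[1]]
  pts <- cbind(x = ct[, 1] + 1, y = ct[, 2] + 1)  # ocontour is 0-based
  if (nrow(pts) < 64L)
    warning("outline has fewer than 64 points; the component may be too small")
  if (.signedArea(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# Shoelace signed area; > 0 for counter-clockwise vertex order.
.signedArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area of a closed polygon outline
#' @param outline two-column (x, y) matrix of vertices.
#' @return positive area (shoelace formula).
#' @export
outlineArea <- function(outline) abs(.signedArea(as.matrix(outline)))

#' Area centroid of a closed polygon outline
#'
#' The centroid of the enclosed region (first area moments over the
#' shoelace area), not the vertex mean — the two differ for unevenly
#' spaced vertices. This point is the pole of the polar coordinate system
#' in which radii are measured.
#'
#' @param outline two-column (x, y) matrix of vertices (closed implicitly).
#' @return numeric length-2 (x, y).
#' @export
outlineCentroid <- function(outline) {
  p <- as.matrix(outline)
  stopifnot(ncol(p) == 2L, nrow(p) >= 3L)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12 * max(1, max(abs(p))^2))
    stop("degenerate (zero-area) polygon")
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' Sample a radial profile from an outline
#'
#' Draws \code{nAngles} equally spaced rays from the outline's area
#' centroid (angle 0 along the +x axis, counter-clockwise) and records the
#' distance to the \emph{farthest} intersection of each ray with the
#' polygon boundary. Taking the farthest crossing makes the radius a
#' single-valued function of angle even across indentations such as the
#' excisura, where the notch then shows up as a local radius minimum — the
#' representation the dyadic wavelet transform requires.
#'
#' @param outline two-column (x, y) vertex matrix.
#' @param nAngles number of rays; must be a power of two (default 512).
#' @return a [RadialProfile-class] object.
#' @export
radialProfile <- function(outline, nAngles = 512L) {
  p <- as.matrix(outline)
  stopifnot(ncol(p) == 2L, nrow(p) >= 3L)
  if (!isPowerOfTwo(nAngles))
    stop("nAngles must be a power of two, got ", nAngles)
  ctr <- outlineCentroid(p)
  a <- sweep(p, 2L, ctr)                    # edge starts, centroid at origin
  b <- a[c(seq_len(nrow(a))[-1], 1L), , drop = FALSE]  # edge ends
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  theta <- 2 * pi * (seq_len(nAngles) - 1L) / nAngles
  ct <- cos(theta); st <- sin(theta)
  radii <- numeric(nAngles)
  for (i in seq_len(nAngles)) {
    # ray: t * (ct, st), t >= 0; edge: a + s * (b - a), s in [0, 1]
    den <- ct[i] * ey - st[i] * ex
    ok <- abs(den) > 1e-12
    s <- (st[i] * a[ok, 1] - ct[i] * a[ok, 2]) / den[ok]
    t <- if (abs(ct[i]) >= abs(st[i]))
      (a[ok, 1] + s * ex[ok]) / ct[i] else (a[ok, 2] + s * ey[ok]) / st[i]
    hit <- s >= -1e-9 & s <= 1 + 1e-9 & t > 0
    if (!any(hit)) {
      radii[i] <- NA_real_
    } else {
      radii[i] <- max(t[hit])
    }
  }
  if (anyNA(radii))
    stop("centroid lies outside the polygon for some rays; ",
         "the outline is too concave for a radial representation — ",
         "review this specimen manually")
  new("RadialProfile", radii = radii, centroid = as.numeric(ctr))
}

#' Full image-to-profile convenience wrapper
#'
#' \code{readGrayImage} + \code{binarizeImage} + \code{extractOutline} +
#' \code{radialProfile} in one call.
#'
#' @param path image file path.
#' @param nAngles number of radii (power of two).
#' @param mirror,polarity passed to the respective steps.
#' @return a [RadialProfile-class] object.
#' @export
imageToProfile <- function(path, nAngles = 512L, mirror = "none",
                           polarity = "auto") {
  img <- readGrayImage(path, mirror = mirror)
  radialProfile(extractOutline(binarizeImage(img, polarity = polarity)),
                nAngles = nAngles)
}

#' Convert a radial profile back to outline coordinates
#'
#' @param radii numeric vector of radii at equally spaced angles (or a
#'   [RadialProfile-class] object).
#' @param centre (x, y) to place the centroid at (default origin).
#' @return two-column (x, y) matrix tracing the closed outline
#'   counter-clockwise from angle 0.
#' @export
profileToOutline <- function(radii, centre = c(0, 0)) {
  if (is(radii, "RadialProfile")) radii <- profileRadii(radii)
  n <- length(radii)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = centre[1] + radii * cos(theta),
        y = centre[2] + radii * sin(theta))
}
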