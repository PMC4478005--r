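#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' RadialProfile: equally angle-spaced centroid-to-outline radii
#'
#' A closed otolith outline reduced to a single-valued function of angle:
#' the distance from the outline's area centroid to the boundary, sampled at
#' \code{n} equally spaced angles (a power of two, as required by the dyadic
#' wavelet transform downstream). Angles start at 0 along the +x axis and
#' increase counter-clockwise.
#'
#' @slot radii numeric vector of length 2^J, all positive.
#' @slot centroid numeric length-2 (x, y) of the polygon area centroid.
#'
#' @seealso [radialProfile()], [dwtRadii()]
#' @exportClass RadialProfile
setClass("RadialProfile",
  representation(radii = "numeric", centroid = "numeric"),
  validity = function(object) {
    n <- length(object@radii)
    if (n < 16L || bitwAnd(n, n - 1L) != 0L)
      return("length of 'radii' must be a power of two >= 16")
    if (!all(is.finite(object@radii)) || any(object@radii <= 0))
      return("all radii must be finite and > 0")
    if (length(object@centroid) != 2L || !all(is.finite(object@centroid)))
      return("'centroid' must be finite (x, y)")
    TRUE
  }
)

#' WaveletDescriptors: wavelet shape coefficients for a set of otoliths
#'
#' Container for the complete orthonormal wavelet decomposition of each
#' specimen's radial profile. Extends
#' \linkS4class{SummarizedExperiment}: rows are coefficients (with
#' \code{rowData} columns \code{level}, \code{position} and \code{angle},
#' the centre angle in degrees of the coefficient's support on the outline),
#' columns are specimens (with \code{colData} holding the specimen metadata
#' table: population, latitude/longitude, length, age, year). The single
#' assay \code{"coefficients"} holds the coefficient values; the wavelet
#' family and number of decomposition levels sit in \code{metadata()}.
#'
#' @seealso [buildDescriptors()], [iccProfile()], [meanShape()],
#'   [ancovaFilter()], [capOrdination()]
#' @exportClass WaveletDescriptors
setClass("WaveletDescriptors",
  contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"coefficients" %in% SummarizedExperiment::assayNames(object))
      return("assay 'coefficients' is required")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("level", "position", "angle")
    if (!all(need %in% colnames(rd)))
      return(paste("rowData must contain:", paste(need, collapse = ", ")))
    a <- rd$angle
    if (any(!is.finite(a)) || any(a < 0 | a >= 360))
      return("rowData$angle must lie in [0, 360)")
    if (!all(is.finite(SummarizedExperiment::assay(object, "coefficients"))))
      return("coefficients must be finite")
    TRUE
  }
)

#' CapOrdination: constrained ordination of shape coefficients
#'
#' Result of canonical analysis of principal coordinates (CAP): a principal
#' coordinate decomposition of the among-specimen Euclidean distance matrix,
#' optionally residualized on a covariate (age), followed by a
#' redundancy-style constrained ordination on population membership. Site
#' scores on the constrained axes (CAP1, CAP2, ...) and per-population
#' centroids are stored together with the inertia partition and, when
#' permutations were run, the ANOVA-like permutation test summary.
#'
#' @slot scores matrix, specimens x constrained axes (CAP1, CAP2, ...).
#' @slot centroids matrix, populations x constrained axes.
#' @slot eigenvalues numeric, one nonnegative value per constrained axis,
#'   sorted decreasing.
#' @slot totalInertia,constrainedInertia,conditionalInertia,residualInertia
#'   numeric scalars; the partition satisfies total = conditional +
#'   constrained + residual.
#' @slot pseudoF numeric scalar: (constrained/df1) / (residual/df2).
#' @slot pValue numeric scalar in (0, 1]; NA when no permutations were run.
#' @slot df numeric length-2: constraint and residual degrees of freedom.
#' @slot group factor of population labels, one per specimen.
#' @slot nPermutations integer; 0 when no test was run.
#'
#' @seealso [capOrdination()], [permutationAnova()], [shapeDistances()]
#' @exportClass CapOrdination
setClass("CapOrdination",
  representation(
    scores = "matrix", centroids = "matrix", eigenvalues = "numeric",
    totalInertia = "numeric", constrainedInertia = "numeric",
    conditionalInertia = "numeric", residualInertia = "numeric",
    pseudoF = "numeric", pValue = "numeric", df = "numeric",
    group = "factor", nPermutations = "integer"
  ),
  validity = function(object) {
    if (any(diff(object@eigenvalues) > 1e-9))
      return("eigenvalues must be sorted in decreasing order")
    if (any(object@eigenvalues < -1e-9))
      return("constrained eigenvalues must be nonnegative")
    tot <- object@totalInertia
    parts <- object@constrainedInertia + object@conditionalInertia
    if (parts > tot + 1e-9 * max(1, tot))
      return("constrained + conditional inertia exceeds total inertia")
    TRUE
  }
)
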