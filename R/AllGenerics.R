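#' @importFrom stats anova aov coef complete.cases cor dist lm median
#'   model.matrix pf prcomp pt qnorm quantile rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv write.table
NULL

#' Radii of a radial profile
#' @param x a [RadialProfile-class] object.
#' @return numeric vector of centroid-to-outline distances.
#' @export
setGeneric("profileRadii", function(x) standardGeneric("profileRadii"))

#' @rdname profileRadii
#' @export
setMethod("profileRadii", "RadialProfile", function(x) x@radii)

#' Angle grid of a radial profile (degrees)
#' @param x a [RadialProfile-class] object.
#' @return numeric vector, 360 * i / n for i = 0 ... n-1.
#' @export
setGeneric("profileAngles", function(x) standardGeneric("profileAngles"))

#' @rdname profileAngles
#' @export
setMethod("profileAngles", "RadialProfile", function(x) {
  n <- length(x@radii)
  360 * (seq_len(n) - 1L) / n
})

setMethod("show", "RadialProfile", function(object) {
  r <- object@radii
  cat("RadialProfile:", length(r), "radii, mean",
      format(mean(r), digits = 4), "| centroid (",
      format(object@centroid[1], digits = 4), ",",
      format(object@centroid[2], digits = 4), ")\n")
})

#' Coefficient values of a WaveletDescriptors object
#'
#' Returns the specimens x coefficients matrix (the transpose of the
#' internal assay, matching the orientation used by the statistical layer).
#'
#' @param x a [WaveletDescriptors-class] object.
#' @return numeric matrix, specimens in rows, coefficients in columns.
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))

#' @rdname coefMatrix
#' @export
setMethod("coefMatrix", "WaveletDescriptors", function(x) {
  t(SummarizedExperiment::assay(x, "coefficients"))
})

#' Per-coefficient centre angles (degrees)
#' @param x a [WaveletDescriptors-class] object.
#' @return numeric vector in [0, 360).
#' @export
setGeneric("coefAngles", function(x) standardGeneric("coefAngles"))

#' @rdname coefAngles
#' @export
setMethod("coefAngles", "WaveletDescriptors", function(x) {
  SummarizedExperiment::rowData(x)$angle
})

#' Per-coefficient decomposition levels
#'
#' Level 1 is the finest detail band; the largest level labels both the
#' coarsest detail band and the scaling (approximation) coefficients, which
#' are distinguished by \code{rowData(x)$kind}.
#'
#' @param x a [WaveletDescriptors-class] object.
#' @return integer vector.
#' @export
setGeneric("coefLevels", function(x) standardGeneric("coefLevels"))

#' @rdname coefLevels
#' @export
setMethod("coefLevels", "WaveletDescriptors", function(x) {
  SummarizedExperiment::rowData(x)$level
})

#' Specimen metadata of a WaveletDescriptors object
#' @param x a [WaveletDescriptors-class] object.
#' @return a data.frame, one row per specimen.
#' @export
setGeneric("specimenData", function(x) standardGeneric("specimenData"))

#' @rdname specimenData
#' @export
setMethod("specimenData", "WaveletDescriptors", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

setMethod("show", "WaveletDescriptors", function(object) {
  cat("WaveletDescriptors:", ncol(object), "specimens x", nrow(object),
      "coefficients\n")
  md <- S4Vectors::metadata(object)
  cat("  family:", md$family, "| levels:", md$levels,
      "| n_angles:", md$n_angles, "\n")
  cd <- SummarizedExperiment::colData(object)
  if ("population_id" %in% colnames(cd))
    cat("  populations:", length(unique(cd$population_id)), "\n")
  invisible(NULL)
})

#' Site scores of a CAP ordination
#' @param x a [CapOrdination-class] object.
#' @return matrix of specimen scores on CAP1, CAP2, ...
#' @export
setGeneric("capScores", function(x) standardGeneric("capScores"))

#' @rdname capScores
#' @export
setMethod("capScores", "CapOrdination", function(x) x@scores)

#' Population centroids of a CAP ordination
#' @param x a [CapOrdination-class] object.
#' @return matrix of per-population mean scores on the constrained axes.
#' @export
setGeneric("capCentroids", function(x) standardGeneric("capCentroids"))

#' @rdname capCentroids
#' @export
setMethod("capCentroids", "CapOrdination", function(x) x@centroids)

#' Constrained eigenvalues of a CAP ordination
#' @param x a [CapOrdination-class] object.
#' @return numeric vector, decreasing.
#' @export
setGeneric("capEigenvalues", function(x) standardGeneric("capEigenvalues"))

#' @rdname capEigenvalues
#' @export
setMethod("capEigenvalues", "CapOrdination", function(x) x@eigenvalues)

#' Inertia partition of a CAP ordination
#' @param x a [CapOrdination-class] object.
#' @return named numeric: total, conditional, constrained, residual.
#' @export
setGeneric("capInertia", function(x) standardGeneric("capInertia"))

#' @rdname capInertia
#' @export
setMethod("capInertia", "CapOrdination", function(x) {
  c(total = x@totalInertia, conditional = x@conditionalInertia,
    constrained = x@constrainedInertia, residual = x@residualInertia)
})

#' Pseudo-F statistic of a CAP ordination
#' @param x a [CapOrdination-class] object.
#' @return numeric scalar.
#' @export
setGeneric("pseudoF", function(x) standardGeneric("pseudoF"))

#' @rdname pseudoF
#' @export
setMethod("pseudoF", "CapOrdination", function(x) x@pseudoF)

#' Permutation p-value of a CAP ordination
#' @param x a [CapOrdination-class] object.
#' @return numeric scalar in (0, 1], or NA if no permutation test was run.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "CapOrdination", function(x) x@pValue)

setMethod("show", "CapOrdination", function(object) {
  cat("CapOrdination:", nrow(object@scores), "specimens,",
      nlevels(object@group), "groups,", length(object@eigenvalues),
      "constrained axes\n")
  ine <- capInertia(object)
  cat("  inertia: total", format(ine["total"], digits = 5),
      "| conditional", format(ine["conditional"], digits = 5),
      "| constrained", format(ine["constrained"], digits = 5),
      "| residual", format(ine["residual"], digits = 5), "\n")
  cat("  pseudo-F =", format(object@pseudoF, digits = 5),
      "on", object@df[1], "and", object@df[2], "df")
  if (object@nPermutations > 0L)
    cat("; p =", format(object@pValue, digits = 4),
        "(", object@nPermutations, "permutations )")
  cat("\n")
  invisible(NULL)
})
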