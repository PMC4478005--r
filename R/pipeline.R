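# Run configuration and the end-to-end analysis pipeline.

#' Analysis run configuration
#'
#' Collects the tunable parameters of the full pipeline in one validated
#' list. Defaults: 512 radii (2^9; the dyadic transform needs a power of
#' two), the least-asymmetric 10-vanishing-moment wavelet, ANCOVA
#' screening at alpha = 0.05, 2000 permutations for the ANOVA-like tests
#' and 10000 for the Mantel test.
#'
#' @param n_angles radii per outline; power of two, >= 16.
#' @param wavelet_family see [waveletFilter()].
#' @param decomposition_levels DWT depth; NULL = maximum usable.
#' @param ancova_alpha interaction-test threshold in (0, 1).
#' @param n_perm_anova permutations for [permutationAnova()] (>= 99).
#' @param n_perm_mantel permutations for [mantelTest()] (>= 99).
#' @param rng_seed integer; every random step in a pipeline run derives
#'   its stream from this seed, so equal config + inputs gives identical
#'   output.
#' @param threshold_method image binarization method (\code{"otsu"}).
#' @param mirror image mirroring protocol (\code{"none"} or
#'   \code{"horizontal"}); whether a study mirrors one otolith side is a
#'   lab protocol choice surfaced here as an option.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(n_angles = 512L, wavelet_family = "sym10",
                      decomposition_levels = NULL, ancova_alpha = 0.05,
                      n_perm_anova = 2000L, n_perm_mantel = 10000L,
                      rng_seed = 1L, threshold_method = "otsu",
                      mirror = "none") {
  if (!isPowerOfTwo(n_angles) || n_angles < 16L)
    stop("n_angles must be a power of two >= 16")
  stopifnot(ancova_alpha > 0, ancova_alpha < 1,
            n_perm_anova >= 99L, n_perm_mantel >= 99L)
  cfg <- list(n_angles = as.integer(n_angles),
              wavelet_family = wavelet_family,
              decomposition_levels = decomposition_levels,
              ancova_alpha = ancova_alpha,
              n_perm_anova = as.integer(n_perm_anova),
              n_perm_mantel = as.integer(n_perm_mantel),
              rng_seed = as.integer(rng_seed),
              threshold_method = threshold_method, mirror = mirror)
  class(cfg) <- "RunConfig"
  cfg
}

#' Full otolith shape analysis pipeline
#'
#' Runs the complete analysis on a set of radial profiles: wavelet
#' decomposition, ANCOVA coefficient screen, ICC profile, CAP ordination
#' with age as covariate plus the ANOVA-like permutation test,
#' within-population variance by age group, the dispersion-on-age
#' regression, and — when a coastline is supplied — the Mantel test of
#' isolation by distance with its pair report.
#'
#' @param specimens specimen metadata data.frame (see
#'   [readSpecimenTable()] for the columns).
#' @param radii specimens x n_angles matrix of radial profiles, rows
#'   named by specimen id (e.g. from [generateDataset()] or stacked
#'   [radialProfile()] output).
#' @param coastline optional ordered waypoint data.frame (\code{lat},
#'   \code{lon}) for along-coast distances.
#' @param config a [runConfig()] list.
#' @param ageCovariate logical; adjust the ordination for age (default
#'   TRUE).
#' @return list with elements \code{descriptors}, \code{filter},
#'   \code{icc}, \code{cap}, \code{anova}, \code{varianceTable},
#'   \code{ageRegression}, and (with a coastline) \code{geoDistances},
#'   \code{shapeDistances}, \code{mantel}, \code{ibd}.
#' @export
runShapeAnalysis <- function(specimens, radii, coastline = NULL,
                             config = runConfig(), ageCovariate = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  specimens <- validateSpecimenTable(specimens)
  specimens <- assignAgeGroups(specimens)
  wd <- buildDescriptors(radii, specimens,
                         family = config$wavelet_family,
                         levels = config$decomposition_levels)
  flt <- ancovaFilter(wd, alpha = config$ancova_alpha)
  wdKept <- applyFilter(wd, flt)
  icc <- iccProfile(wd)
  age <- specimenData(wdKept)$age_years
  cov <- if (ageCovariate) age else NULL
  cap <- capOrdination(wdKept, covariate = cov,
                       nPermutations = config$n_perm_anova,
                       seed = config$rng_seed)
  pa <- permutationAnova(wdKept, covariate = cov,
                         nPermutations = config$n_perm_anova,
                         seed = config$rng_seed)
  vt <- withinVariance(wdKept)
  vr <- varianceAgeRegression(wdKept)
  out <- list(descriptors = wd, filter = flt, icc = icc, cap = cap,
              anova = pa, varianceTable = vt, ageRegression = vr,
              config = config)
  if (!is.null(coastline)) {
    dGeo <- coastlineDistances(coastline, specimens)
    dShape <- shapeDistances(cap)
    ord <- rownames(dShape)
    dGeo <- dGeo[ord, ord]
    out$geoDistances <- dGeo
    out$shapeDistances <- dShape
    out$mantel <- mantelTest(dShape, dGeo,
                             nPermutations = config$n_perm_mantel,
                             seed = config$rng_seed + 1L)
    out$ibd <- ibdReport(dShape, dGeo)
  }
  out
}
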