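# Population-level summaries of the wavelet shape coefficients: mean
# shapes (coefficient means inverse-transformed back to outlines) and the
# intraclass-correlation profile along the outline.

#' Mean otolith shape per population
#'
#' Averages each wavelet coefficient within a population and
#' inverse-transforms the mean coefficient vector back to radii, giving
#' the population's mean outline about the origin. Because the transform
#' is linear, this equals the mean of the individual radius functions.
#'
#' @param x a [WaveletDescriptors-class] object.
#' @param group population labels, one per specimen; default the
#'   \code{population_id} column of the specimen metadata.
#' @param normalize if TRUE, rescale each mean outline to unit mean radius
#'   (display aid when populations differ in size).
#' @return named list of two-column (x, y) outline matrices, one per
#'   population (empty populations are skipped with a warning).
#' @export
meanShape <- function(x, group = NULL, normalize = FALSE) {
  stopifnot(is(x, "WaveletDescriptors"))
  if (is.null(group)) group <- specimenData(x)$population_id
  group <- factor(group)
  stopifnot(length(group) == ncol(x))
  m <- coefMatrix(x)
  md <- S4Vectors::metadata(x)
  empty <- levels(group)[!levels(group) %in% group]
  if (length(empty))
    warning("skipping empty population(s): ", paste(empty, collapse = ", "))
  out <- list()
  for (g in levels(droplevels(group))) {
    mu <- colMeans(m[group == g, , drop = FALSE])
    radii <- idwtRadii(mu, family = md$family, levels = md$levels)
    if (normalize) radii <- radii / mean(radii)
    out[[g]] <- profileToOutline(radii)
  }
  out
}

#' Intraclass-correlation profile along the outline
#'
#' For each wavelet coefficient, partitions variance between and within
#' populations with the one-way random-effects ANOVA estimator and
#' reports the intraclass correlation ICC = s2_between / (s2_between +
#' s2_within) — the proportion of variation among groups. Variance
#' components come from the mean squares, s2_between = (MSB - MSW) / n0
#' with the standard unbalanced-design coefficient n0 = (N - sum(n_i^2)/N)
#' / (k - 1); a negative between-group component is truncated to zero, so
#' the reported ICC lies in [0, 1]. Rows are ordered by the coefficient's
#' centre angle, ready for plotting ICC (and the coefficient mean/SD
#' envelope) against position on the outline.
#'
#' @param x a [WaveletDescriptors-class] object, or a specimens x
#'   coefficients matrix.
#' @param group population labels, one per specimen; populations with a
#'   single specimen are dropped with a warning.
#' @return data.frame with columns \code{coefficient}, \code{kind},
#'   \code{level}, \code{angle}, \code{icc}, \code{mean_coef},
#'   \code{sd_coef}, ordered by \code{angle}.
#' @export
iccProfile <- function(x, group = NULL) {
  if (is(x, "WaveletDescriptors")) {
    if (is.null(group)) group <- specimenData(x)$population_id
    m <- coefMatrix(x)
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    ann <- data.frame(coefficient = rownames(rd), kind = rd$kind,
                      level = rd$level, angle = rd$angle,
                      stringsAsFactors = FALSE)
  } else {
    m <- as.matrix(x)
    if (is.null(colnames(m))) colnames(m) <- sprintf("C%d", seq_len(ncol(m)))
    ann <- data.frame(coefficient = colnames(m), kind = NA, level = NA,
                      angle = seq_len(ncol(m)), stringsAsFactors = FALSE)
  }
  group <- factor(group)
  stopifnot(length(group) == nrow(m))
  nPer <- table(group)
  drop <- names(nPer)[nPer < 2L]
  if (length(drop)) {
    warning("dropping population(s) with a single specimen: ",
            paste(drop, collapse = ", "))
    keep <- !group %in% drop
    m <- m[keep, , drop = FALSE]
    group <- droplevels(group[keep])
    nPer <- table(group)
  }
  k <- nlevels(group)
  if (k < 2L) stop("iccProfile needs at least 2 populations with >= 2 specimens")
  icc <- iccComponents(m, group)$icc
  out <- data.frame(ann, icc = icc,
                    mean_coef = colMeans(m),
                    sd_coef = apply(m, 2L, sd), row.names = NULL)
  out[order(out$angle), ]
}

#' One-way random-effects variance components per column
#'
#' Vectorized ANOVA mean-square computation behind [iccProfile()],
#' exposed for reuse and testing.
#'
#' @param m numeric matrix, observations x variables.
#' @param group factor of group labels (every level with n >= 2).
#' @return list with vectors \code{msb}, \code{msw}, \code{sigma2Between}
#'   (truncated at 0), \code{sigma2Within}, \code{icc}, and scalar
#'   \code{n0}.
#' @export
iccComponents <- function(m, group) {
  group <- droplevels(factor(group))
  nPer <- as.numeric(table(group))
  stopifnot(all(nPer >= 2L), nlevels(group) >= 2L)
  N <- nrow(m); k <- nlevels(group)
  gm <- rowsum(m, group) / nPer           # k x p group means
  grand <- colMeans(m)
  ssb <- colSums(nPer * sweep(gm, 2L, grand)^2)
  ssw <- colSums((m - gm[as.integer(group), , drop = FALSE])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(nPer^2) / N) / (k - 1)
  s2b <- pmax((msb - msw) / n0, 0)
  denom <- s2b + msw
  icc <- ifelse(denom > 0, s2b / denom, 0)
  list(msb = msb, msw = msw, sigma2Between = s2b, sigma2Within = msw,
       icc = icc, n0 = n0)
}
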