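# Specimen metadata and coefficient-table I/O. CSV (comma, UTF-8, header
# row) is the interchange format throughout.

.SPECIMEN_COLS <- c("specimen_id", "population_id", "latitude", "longitude",
                    "length_cm", "age_years", "year")

#' Read and validate a specimen metadata table
#'
#' Reads the per-fish metadata CSV: one row per specimen with columns
#' \code{specimen_id}, \code{population_id}, \code{latitude},
#' \code{longitude} (decimal degrees), \code{length_cm}, \code{age_years},
#' \code{year} and optionally \code{image_path}. Rows with missing length
#' or age are kept in the table but flagged (attribute
#' \code{"incomplete"}) and are excluded from group statistics downstream;
#' Table-style survey data normally have complete records, so these are
#' reported rather than errored.
#'
#' @param path path to a CSV file with a header row.
#' @return a \code{data.frame} with typed columns; specimen ids are
#'   guaranteed unique.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(specimen_id = c("F1", "F2"),
#'                      population_id = "A", latitude = 60, longitude = 5,
#'                      length_cm = c(28.5, 31), age_years = c(4L, 6L),
#'                      year = 2012), tf, row.names = FALSE)
#' readSpecimenTable(tf)
#' @export
readSpecimenTable <- function(path) {
  if (!file.exists(path)) stop("specimen table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validateSpecimenTable(df)
}

#' Validate an in-memory specimen table
#'
#' Applies the same contract as [readSpecimenTable()]: required columns
#' present, unique specimen ids, positive lengths, integer ages >= 1.
#'
#' @param df a data.frame of specimen metadata.
#' @return the validated (typed) data.frame.
#' @export
validateSpecimenTable <- function(df) {
  missing <- setdiff(.SPECIMEN_COLS, colnames(df))
  if (length(missing))
    stop("specimen table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$specimen_id <- as.character(df$specimen_id)
  df$population_id <- as.character(df$population_id)
  dup <- unique(df$specimen_id[duplicated(df$specimen_id)])
  if (length(dup))
    stop("duplicate specimen_id value(s): ", paste(dup, collapse = ", "))
  for (col in c("latitude", "longitude", "length_cm"))
    df[[col]] <- as.numeric(df[[col]])
  df$age_years <- as.integer(df$age_years)
  df$year <- as.integer(df$year)
  bad <- which(!is.na(df$length_cm) & df$length_cm <= 0)
  if (length(bad))
    stop("non-positive length_cm in row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.na(df$age_years) & df$age_years < 1L)
  if (length(bad))
    stop("age_years < 1 in row(s): ", paste(bad, collapse = ", "))
  incomplete <- which(is.na(df$length_cm) | is.na(df$age_years))
  if (length(incomplete))
    message(length(incomplete), " specimen(s) with missing length or age ",
            "will be excluded from statistics (rows: ",
            paste(incomplete, collapse = ", "), ")")
  attr(df, "incomplete") <- incomplete
  df
}

#' Default age-group definitions
#'
#' Three inclusive integer age bins used to stratify the shape analysis:
#' 3--5, 6--8 and 9--12 years. Age has a strong confounding effect on
#' otolith shape, so comparisons among populations are run within these
#' strata.
#'
#' @return a data.frame with columns \code{label}, \code{lo}, \code{hi}.
#' @export
ageGroups <- function() {
  data.frame(label = c("3-5", "6-8", "9-12"),
             lo = c(3L, 6L, 9L), hi = c(5L, 8L, 12L),
             stringsAsFactors = FALSE)
}

#' Assign specimens to age groups
#'
#' Labels each specimen with the (unique) age group whose inclusive
#' \code{[lo, hi]} range contains its age; specimens whose age falls
#' outside all groups get \code{NA} and are excluded from stratified
#' statistics.
#'
#' @param table a specimen data.frame (see [readSpecimenTable()]).
#' @param groups a data.frame of age-group definitions
#'   (default [ageGroups()]); ranges must not overlap.
#' @return \code{table} with an added \code{age_group} factor column.
#' @export
assignAgeGroups <- function(table, groups = ageGroups()) {
  stopifnot(all(c("label", "lo", "hi") %in% colnames(groups)))
  if (any(groups$lo > groups$hi))
    stop("age group with lo > hi: ", paste(groups$label[groups$lo > groups$hi],
                                           collapse = ", "))
  g <- groups[order(groups$lo), ]
  if (nrow(g) > 1L && any(g$lo[-1L] <= g$hi[-nrow(g)]))
    stop("overlapping age group definitions")
  lab <- rep(NA_character_, nrow(table))
  for (i in seq_len(nrow(g))) {
    inG <- !is.na(table$age_years) &
      table$age_years >= g$lo[i] & table$age_years <= g$hi[i]
    lab[inG] <- g$label[i]
  }
  table$age_group <- factor(lab, levels = groups$label)
  table
}

#' Write a coefficient table to CSV
#'
#' Writes the specimens x coefficients matrix of a
#' [WaveletDescriptors-class] object as a CSV (key column
#' \code{specimen_id}, one column per coefficient) plus a sidecar file
#' \code{<path>.coefinfo.csv} carrying the per-coefficient annotation
#' (kind, level, position, centre angle) and the transform parameters, so
#' that [readCoefficientTable()] can reconstruct the object exactly.
#' Values are written with 17 significant digits; the round trip is exact
#' at double precision.
#'
#' @param x a [WaveletDescriptors-class] object.
#' @param path output CSV path.
#' @return invisibly, the two paths written.
#' @export
writeCoefficientTable <- function(x, path) {
  stopifnot(is(x, "WaveletDescriptors"))
  m <- coefMatrix(x)
  if (!all(is.finite(m))) stop("coefficient matrix contains non-finite values")
  fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  out <- data.frame(specimen_id = colnames(x), fm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("specimen_id", rownames(x))
  write.table(out, path, sep = ",", row.names = FALSE, qmethod = "double",
              fileEncoding = "UTF-8")
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  md <- S4Vectors::metadata(x)
  info <- data.frame(coefficient = rownames(x), rd,
                     family = md$family, levels = md$levels,
                     n_angles = md$n_angles, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".coefinfo.csv")
  write.csv(info, sidecar, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(path, sidecar))
}

#' Read a coefficient table written by [writeCoefficientTable()]
#'
#' @param path the CSV path given to [writeCoefficientTable()]; the sidecar
#'   \code{<path>.coefinfo.csv} must sit beside it.
#' @param specimens optional specimen metadata data.frame to attach as
#'   \code{colData} (matched on \code{specimen_id}).
#' @return a [WaveletDescriptors-class] object.
#' @export
readCoefficientTable <- function(path, specimens = NULL) {
  sidecar <- paste0(path, ".coefinfo.csv")
  if (!file.exists(path)) stop("coefficient table not found: ", path)
  if (!file.exists(sidecar)) stop("coefficient sidecar not found: ", sidecar)
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  info <- read.csv(sidecar, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$specimen_id
  if (!identical(colnames(m), as.character(info$coefficient)))
    stop("sidecar coefficient names do not match the table")
  .newDescriptors(m, specimens = specimens,
                  rowInfo = info[, c("kind", "level", "position", "angle")],
                  family = info$family[1], levels = info$levels[1],
                  nAngles = info$n_angles[1])
}

# Assemble a WaveletDescriptors object from a specimens x coefficients
# matrix plus annotation; shared by buildDescriptors() and the reader.
.newDescriptors <- function(m, specimens, rowInfo, family, levels, nAngles) {
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  cd <- S4Vectors::DataFrame(row.names = rownames(m))
  if (!is.null(specimens)) {
    idx <- match(rownames(m), specimens$specimen_id)
    if (anyNA(idx))
      stop("specimens table is missing id(s): ",
           paste(rownames(m)[is.na(idx)], collapse = ", "))
    cd <- S4Vectors::DataFrame(specimens[idx, , drop = FALSE],
                               row.names = rownames(m))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(coefficients = t(m)),
    rowData = S4Vectors::DataFrame(rowInfo, row.names = colnames(m)),
    colData = cd
  )
  S4Vectors::metadata(se) <- list(family = family, levels = levels,
                                  n_angles = nAngles)
  new("WaveletDescriptors", se)
}
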