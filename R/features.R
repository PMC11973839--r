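#' @importFrom stats quantile sd
NULL

.STATS <- c("MEAN", "SD", "MIN", "MAX", paste0("P", seq(10, 90, by = 10)))
.KINDS <- c("REST", "STRESS", "RESERVE")

#' Canonical feature names
#'
#' The 663 feature names in canonical order: map kind (REST, STRESS,
#' RESERVE), then segment 1-17, then statistic (MEAN, SD, MIN, MAX,
#' P10...P90), e.g. `"STRESS_S14_MIN"`. 3 maps x 17 segments x 13
#' statistics = 663.
#'
#' @return character vector of length 663.
#' @examples
#' head(canonicalFeatureNames())
#' @export
canonicalFeatureNames <- function() {
  as.vector(vapply(.KINDS, function(k)
    as.vector(vapply(1:17, function(s)
      paste0(k, "_S", s, "_", .STATS), character(13))), character(17 * 13)))
}

# 13 statistics of one segment's pixel values, canonical order.
# percentiles use linear interpolation between closest order statistics
# (quantile type 7)
.segStats <- function(v) {
  c(mean(v), if (length(v) > 1L) sd(v) else 0,
    min(v), max(v),
    quantile(v, probs = seq(0.1, 0.9, by = 0.1), names = FALSE, type = 7))
}

#' Per-segment statistics of a polar map
#'
#' Computes, for each of the 17 AHA segments, the 13 statistics mean,
#' standard deviation, minimum, maximum and the 9 deciles (10th-90th
#' percentile, linear interpolation).
#'
#' @param map a [PolarMap-class].
#' @param geometry a [SegmentGeometry-class]; default AHA layout.
#' @return 17 x 13 numeric matrix, rows `S1..S17`, columns the statistic
#'   names.
#' @export
setMethod("segmentStatistics", signature("PolarMap", "SegmentGeometry"),
  function(map, geometry) {
    inside <- map@grid[map@mask]
    if (any(is.nan(inside))) {
      bad <- which(map@mask & is.nan(map@grid), arr.ind = TRUE)
      stop("NaN perfusion values inside the disc at pixels: ",
           paste(utils::head(apply(bad, 1, paste, collapse = ","), 5),
                 collapse = "; "))
    }
    lab <- .segmentLabels(geometry, map@mask, map@center, map@radius)
    .statsFromLabels(map@grid, lab)
  })

# shared worker: stats per segment given a label grid
.statsFromLabels <- function(grid, lab) {
  out <- matrix(NA_real_, 17L, 13L,
                dimnames = list(paste0("S", 1:17), .STATS))
  keep <- !is.na(lab)
  groups <- split(grid[keep], lab[keep])
  present <- as.integer(names(groups))
  if (length(present) != 17L)
    stop("segment ", paste(setdiff(1:17, present), collapse = ", "),
         " contains no pixels at this resolution")
  for (s in 1:17) out[s, ] <- .segStats(groups[[as.character(s)]])
  out
}

#' Build the 663-entry feature vector of one patient
#'
#' Applies [segmentStatistics()] to the rest, stress and reserve maps and
#' flattens the result in canonical order (map kind, then segment, then
#' statistic).
#'
#' @param rest,stress,reserve [PolarMap-class] objects of the matching
#'   kinds, sharing raster dimensions, centre and radius.
#' @param geometry a [SegmentGeometry-class].
#' @return named numeric vector of length 663.
#' @export
buildFeatureVector <- function(rest, stress, reserve,
                               geometry = segmentGeometry()) {
  maps <- list(REST = rest, STRESS = stress, RESERVE = reserve)
  for (k in .KINDS)
    if (maps[[k]]@kind != k)
      stop("map supplied as ", tolower(k), " has kind ", maps[[k]]@kind)
  ref <- maps[[1]]
  for (m in maps[-1])
    if (!identical(dim(m@grid), dim(ref@grid)) ||
        !isTRUE(all.equal(m@center, ref@center)) ||
        !isTRUE(all.equal(m@radius, ref@radius)))
      stop("the three maps must share raster dimensions, centre and radius")
  vals <- unlist(lapply(maps, function(m)
    as.vector(t(segmentStatistics(m, geometry)))), use.names = FALSE)
  names(vals) <- canonicalFeatureNames()
  vals
}

#' Assemble a feature table as a SummarizedExperiment
#'
#' Feature tables are stored Bioconductor-style: one assay `features` with
#' the 663 features as rows and patients as columns, and `colData` columns
#' `patient_id` and (optionally) `MACE`.
#'
#' @param values numeric matrix, patients x 663 (rows will be transposed
#'   into assay columns); column names must be the canonical feature names.
#' @param patientId character/integer patient identifiers.
#' @param mace optional binary outcome vector (1 = event within follow-up).
#' @return a [SummarizedExperiment::SummarizedExperiment-class].
#' @export
makeFeatureTable <- function(values, patientId = NULL, mace = NULL) {
  stopifnot(is.matrix(values))
  canon <- canonicalFeatureNames()
  if (is.null(colnames(values)) || !identical(colnames(values), canon))
    stop("feature columns must be the 663 canonical names in order")
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature values must be finite with no missing entries")
  if (is.null(patientId)) patientId <- paste0("P", seq_len(nrow(values)))
  cd <- S4Vectors::DataFrame(patient_id = as.character(patientId))
  if (!is.null(mace)) {
    .assertBinary(mace, "MACE")
    cd$MACE <- as.integer(mace)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)), colData = cd)
}

# patients x features matrix from a feature table
.featureMatrix <- function(se) {
  t(SummarizedExperiment::assay(se, "features"))
}

.outcomes <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!"MACE" %in% names(cd))
    stop("feature table carries no MACE outcome column")
  as.integer(cd$MACE)
}

#' Read/write feature tables as CSV
#'
#' The CSV layout is one row per patient with columns `patient_id`,
#' `MACE` (0/1; omitted when unknown) and then the 663 canonical features.
#' The header is byte-stable across runs.
#'
#' @param se a feature table from [makeFeatureTable()].
#' @param path CSV file path.
#' @return `readFeatureTable` returns a SummarizedExperiment;
#'   `writeFeatureTable` returns `path` invisibly.
#' @export
writeFeatureTable <- function(se, path) {
  m <- .featureMatrix(se)
  cd <- SummarizedExperiment::colData(se)
  df <- data.frame(patient_id = cd$patient_id, check.names = FALSE)
  if ("MACE" %in% names(cd)) df$MACE <- cd$MACE
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  keep <- setdiff(names(df), c("patient_id", "MACE"))
  m <- as.matrix(df[, keep, drop = FALSE])
  if (anyNA(m) || any(!is.finite(m)))
    stop("feature values must be finite with no missing entries")
  if (identical(colnames(m), canonicalFeatureNames()))
    return(makeFeatureTable(m, patientId = df$patient_id,
                            mace = df$MACE))
  # reduced tables (e.g. simulation presets) keep whatever features exist
  cd <- S4Vectors::DataFrame(patient_id = as.character(df$patient_id))
  if ("MACE" %in% names(df)) {
    .assertBinary(df$MACE, "MACE")
    cd$MACE <- as.integer(df$MACE)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(m)), colData = cd)
}
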