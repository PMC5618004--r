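#' @include AllGenerics.R
NULL

#' BandMatrix: binary community fingerprints with sample metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass for binary
#' presence/absence band patterns from gel fingerprinting (DGGE for
#' bacterial 16S communities, PFGE for viral genome-size spectra).  Bands
#' are rows, samples are columns; the single assay `"occurrence"` holds 0/1
#' values.  Per-sample metadata (`day`, `glucose_x`, `silicate`,
#' `nitrogen_source`) live in `colData`.
#'
#' Every sample must carry at least one band: Jaccard dissimilarity is
#' undefined for empty fingerprints, so empty samples are rejected at
#' construction.
#'
#' @seealso [bandMatrix()], [readBandMatrix()], [jaccardDistances()]
#' @export
#' @import SummarizedExperiment
#' @import S4Vectors
setClass("BandMatrix", contains = "SummarizedExperiment")

setValidity("BandMatrix", function(object) {
  msg <- character()
  if (!("occurrence" %in% SummarizedExperiment::assayNames(object)))
    return("BandMatrix must carry an assay named 'occurrence'")
  v <- SummarizedExperiment::assay(object, "occurrence")
  if (!all(v %in% c(0, 1)))
    msg <- c(msg, "assay values must be binary (0/1)")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "band ids must be present and unique")
  if (ncol(v) && any(colSums(v) == 0))
    msg <- c(msg, sprintf("sample(s) with no band present: %s",
                          paste(colnames(object)[colSums(v) == 0],
                                collapse = ", ")))
  if (length(msg)) msg else TRUE
})

metadataColumns <- c("day", "glucose_x", "silicate", "nitrogen_source")

#' Construct a BandMatrix from a samples-by-bands binary matrix
#'
#' @param values binary matrix, samples in rows, bands in columns (the
#'   orientation of a fingerprint table on disk).  Row and column names are
#'   used as sample/band ids; defaults are generated when absent.
#' @param sampleData `data.frame` or `DataFrame` of per-sample metadata, one
#'   row per sample.  Missing standard columns (`day`, `glucose_x`,
#'   `silicate`, `nitrogen_source`) are filled with `NA`.
#' @return a validated [BandMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 1, 0, 1, 0, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("b1", "b2", "b3")))
#' bandMatrix(m)
#' @export
bandMatrix <- function(values, sampleData = NULL) {
  values <- as.matrix(values)
  if (all(values %in% c(0, 1))) storage.mode(values) <- "integer"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("band%03d", seq_len(ncol(values)))
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = rownames(values))
  sampleData <- as(sampleData, "DataFrame")
  for (col in setdiff(metadataColumns, names(sampleData)))
    sampleData[[col]] <- NA
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(occurrence = t(values)), colData = sampleData)
  new("BandMatrix", se)
}

#' @describeIn BandMatrix-class the samples-by-bands binary matrix.
#' @param object a `BandMatrix`.
#' @export
setMethod("bandValues", "BandMatrix",
          function(object) t(SummarizedExperiment::assay(object, "occurrence")))
#' @describeIn BandMatrix-class sample identifiers, in order.
#' @export
setMethod("sampleIds", "BandMatrix", function(object) colnames(object))
#' @describeIn BandMatrix-class band identifiers, in order.
#' @export
setMethod("bandIds", "BandMatrix", function(object) rownames(object))
#' @describeIn BandMatrix-class per-sample metadata (`DataFrame`).
#' @export
setMethod("sampleData", "BandMatrix",
          function(object) SummarizedExperiment::colData(object))

setMethod("show", "BandMatrix", function(object) {
  v <- SummarizedExperiment::assay(object, "occurrence")
  cat(sprintf("BandMatrix: %d samples x %d bands (%.0f%% presence)\n",
              ncol(v), nrow(v), 100 * mean(v)))
  md <- SummarizedExperiment::colData(object)
  filled <- names(md)[vapply(md, function(x) !all(is.na(x)), logical(1))]
  if (length(filled))
    cat("  metadata: ", paste(filled, collapse = ", "), "\n", sep = "")
  cat("  samples: ", paste(utils::head(colnames(v), 6), collapse = ", "),
      if (ncol(v) > 6) ", ..." else "", "\n", sep = "")
  invisible(NULL)
})

#' Read a band matrix from a tab-separated fingerprint table
#'
#' The expected dialect has a `sample_id` first column, optional metadata
#' columns (`day`, `glucose_x`, `silicate`, `nitrogen_source`) and then one
#' 0/1 column per band.  Missing metadata columns are filled with `NA`
#' under a warning; any non-binary cell is a parse error naming its
#' location.  [writeBandMatrix()] followed by `readBandMatrix()`
#' round-trips exactly.
#'
#' @param path path to a TSV file.
#' @return a validated [BandMatrix-class] object.
#' @export
readBandMatrix <- function(path) {
  if (!file.exists(path)) stop("band matrix file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!nrow(tab) || names(tab)[1] != "sample_id")
    stop("malformed band matrix: first column must be 'sample_id'")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  present <- intersect(metadataColumns, names(tab))
  missing <- setdiff(metadataColumns, names(tab))
  if (length(missing))
    warning("metadata column(s) absent, filled with NA: ",
            paste(missing, collapse = ", "))
  bandCols <- setdiff(names(tab), c("sample_id", metadataColumns))
  if (!length(bandCols)) stop("no band columns found in ", path)
  if (anyDuplicated(bandCols))
    stop("duplicate band id(s): ",
         paste(unique(bandCols[duplicated(bandCols)]), collapse = ", "))
  vals <- as.matrix(tab[bandCols])
  bad <- which(matrix(!(vals %in% c(0, 1)), nrow(vals)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-binary value %s at sample '%s', band '%s'",
                 format(vals[bad[1, 1], bad[1, 2]]),
                 tab$sample_id[bad[1, 1]], bandCols[bad[1, 2]]))
  storage.mode(vals) <- "integer"
  rownames(vals) <- tab$sample_id
  md <- S4Vectors::DataFrame(tab[present], row.names = tab$sample_id)
  bandMatrix(vals, md)
}

#' Write a band matrix as a tab-separated fingerprint table
#'
#' @param x a [BandMatrix-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBandMatrix <- function(x, path) {
  stopifnot(is(x, "BandMatrix"))
  md <- as.data.frame(sampleData(x))[, metadataColumns, drop = FALSE]
  out <- cbind(sample_id = sampleIds(x), md, as.data.frame(bandValues(x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
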