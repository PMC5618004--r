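#' @include BandMatrix.R
NULL

#' Jaccard dissimilarities between binary fingerprints
#'
#' Pairwise Jaccard distance `d(i, j) = 1 - |intersection| / |union|` over
#' band presence sets.  Computed through `stats::dist(method = "binary")`,
#' which coincides with the Jaccard distance on 0/1 data.  Samples with no
#' band present are rejected (the coefficient is undefined for empty sets).
#'
#' @param x a [BandMatrix-class] or a binary samples-by-bands matrix.
#' @return a `dist` object with values in `[0, 1]`.
#' @examples
#' m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
#' jaccardDistances(m)  # 1 - 1/3
#' @export
jaccardDistances <- function(x) {
  v <- if (is(x, "BandMatrix")) bandValues(x) else as.matrix(x)
  if (!all(v %in% c(0, 1))) stop("fingerprint matrix must be binary (0/1)")
  empty <- rowSums(v) == 0
  if (any(empty))
    stop("Jaccard distance undefined for sample(s) with no band present: ",
         paste(rownames(v)[empty], collapse = ", "))
  stats::dist(v, method = "binary")
}

#' Pearson correlation test between two series
#'
#' Sample Pearson correlation with the two-sided t-test
#' (`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom),
#' as used for relating ciliate abundance to the virus-to-prokaryote ratio.
#' Delegates to [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length `n >= 3`; neither may be
#'   constant.
#' @return a list with `rho`, `p` (two-sided), `statistic` (t), `df` and `n`.
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for a constant series")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(rho = unname(ct$estimate), p = ct$p.value,
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       n = length(x))
}

#' Virus-to-prokaryote ratio
#'
#' Elementwise ratio of small-virus counts (the flow-cytometric group that
#' mainly infects prokaryotes) to total prokaryote counts.
#'
#' @param virusSmallGroup virus counts (per mL), non-negative.
#' @param prokaryotes prokaryote counts (per mL), strictly positive.
#' @return dimensionless ratio series.
#' @export
vpr <- function(virusSmallGroup, prokaryotes) {
  if (length(virusSmallGroup) != length(prokaryotes))
    stop("count series must have equal length")
  if (any(!is.finite(virusSmallGroup)) || any(virusSmallGroup < 0))
    stop("virus counts must be finite and non-negative")
  bad <- which(!is.finite(prokaryotes) | prokaryotes <= 0)
  if (length(bad))
    stop("prokaryote count must be strictly positive; offending index: ",
         paste(bad, collapse = ", "))
  virusSmallGroup / prokaryotes
}
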