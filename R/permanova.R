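#' @include fingerprintBasics.R
NULL

#' PermanovaResult: distance-based permutational ANOVA summary
#'
#' @slot pseudoF the pseudo-F statistic.
#' @slot R2 between-group fraction of the total sum of squares.
#' @slot p permutation p-value (add-one convention; never 0).
#' @slot nPermutations number of label permutations performed.
#' @slot dfBetween,dfResidual degrees of freedom.
#' @export
setClass("PermanovaResult",
  representation(pseudoF = "numeric", R2 = "numeric", p = "numeric",
                 nPermutations = "integer", dfBetween = "integer",
                 dfResidual = "integer"))

setValidity("PermanovaResult", function(object) {
  msg <- character()
  if (object@R2 < -1e-12 || object@R2 > 1 + 1e-12)
    msg <- c(msg, "R2 must lie in [0, 1]")
  if (object@p <= 0 || object@p > 1)
    msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn PermanovaResult-class the pseudo-F statistic.
#' @param object a `PermanovaResult`.
#' @export
setMethod("pseudoF", "PermanovaResult", function(object) object@pseudoF)
#' @describeIn PermanovaResult-class between-group variance fraction.
#' @export
setMethod("rSquared", "PermanovaResult", function(object) object@R2)
#' @describeIn PermanovaResult-class permutation p-value.
#' @export
setMethod("pValue", "PermanovaResult", function(object) object@p)

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PERMANOVA: F(%d, %d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              object@dfBetween, object@dfResidual, object@pseudoF,
              object@R2, object@p, object@nPermutations))
  invisible(NULL)
})

## Partition of the squared-distance sums for one labelling.
## SS_total = sum_{i<j} d_ij^2 / n ; SS_within = sum_g (sum_{i<j in g} d^2)/n_g.
permanovaSS <- function(D2, grouping) {
  n <- nrow(D2)
  ssT <- sum(D2) / (2 * n)
  ssW <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    ssW <- ssW + sum(D2[idx, idx]) / (2 * length(idx))
  }
  c(total = ssT, within = ssW)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Distance-based one-factor PERMANOVA testing whether fingerprints group
#' by treatment.  The pseudo-F follows the standard partition of
#' squared interpoint distances,
#' `F = (SS_between/df_between) / (SS_within/df_within)`, equivalent to the
#' Gower-centred inner-product formulation; significance comes from
#' shuffling the group labels, with the add-one p-value convention.
#'
#' @param d a `dist` object or symmetric distance matrix (e.g. from
#'   [jaccardDistances()]).
#' @param grouping factor-like vector of group labels, one per sample; at
#'   least two groups.
#' @param nPerm number of label permutations (default 99999).
#' @param seed optional integer seed for the permutation stream.
#' @return a [PermanovaResult-class] object.
#' @examples
#' m <- rbind(matrix(rep(c(1, 0), each = 6), 2, 6, byrow = TRUE),
#'            matrix(rep(c(0, 1), each = 6), 2, 6, byrow = TRUE))
#' m <- m[rep(1:4, 2), ]
#' bandPermanova(dist(m), rep(c("a", "b"), each = 2), nPerm = 99, seed = 1)
#' @export
bandPermanova <- function(d, grouping, nPerm = 99999, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (length(grouping) != n)
    stop("'grouping' must supply one label per sample")
  if (anyNA(grouping)) stop("'grouping' contains missing labels")
  grouping <- as.character(grouping)
  a <- length(unique(grouping))
  if (a < 2) stop("PERMANOVA needs at least two groups")
  if (a >= n) stop("PERMANOVA needs residual degrees of freedom (n > groups)")
  if (nPerm < 1) stop("'nPerm' must be at least 1")
  D2 <- dm^2
  ss <- permanovaSS(D2, grouping)
  if (ss["total"] <= 0)
    stop("total sum of squares is zero; all samples are identical")
  dfB <- a - 1L
  dfW <- n - a
  fStat <- function(ssPair)
    ((ssPair["total"] - ssPair["within"]) / dfB) / (ssPair["within"] / dfW)
  fObs <- fStat(ss)
  fPerm <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i)
      fStat(permanovaSS(D2, grouping[sample.int(n)])), numeric(1))
  })
  p <- (1 + sum(fPerm >= fObs - 1e-12)) / (nPerm + 1)
  new("PermanovaResult",
      pseudoF = unname(fObs),
      R2 = unname((ss["total"] - ss["within"]) / ss["total"]),
      p = p, nPermutations = as.integer(nPerm),
      dfBetween = as.integer(dfB), dfResidual = as.integer(dfW))
}
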