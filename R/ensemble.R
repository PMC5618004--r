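#' @include procrustes.R
NULL

#' EnsembleCouplingResult: repeated NMDS + protest summary
#'
#' Summary of the ensemble procedure used to obtain stable host-virus
#' coupling evidence from stochastic ordinations: many independently
#' re-seeded NMDS fits of both fingerprint matrices, each followed by a
#' Procrustes permutation test.
#'
#' @slot medianP median protest p-value over the repetitions.
#' @slot pctSignificant percentage of repetitions with p < 0.05.
#' @slot medianCorrelation median Procrustes correlation.
#' @slot nRepeats number of repetitions.
#' @slot pValues,correlations the per-repetition values.
#' @export
setClass("EnsembleCouplingResult",
  representation(medianP = "numeric", pctSignificant = "numeric",
                 medianCorrelation = "numeric", nRepeats = "integer",
                 pValues = "numeric", correlations = "numeric"))

setValidity("EnsembleCouplingResult", function(object) {
  msg <- character()
  if (object@medianP < 0 || object@medianP > 1)
    msg <- c(msg, "medianP must lie in [0, 1]")
  if (object@pctSignificant < 0 || object@pctSignificant > 100)
    msg <- c(msg, "pctSignificant must lie in [0, 100]")
  if (object@medianCorrelation < 0 || object@medianCorrelation > 1 + 1e-12)
    msg <- c(msg, "medianCorrelation must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnsembleCouplingResult-class median protest p-value.
#' @param object an `EnsembleCouplingResult`.
#' @export
setMethod("medianP", "EnsembleCouplingResult", function(object) object@medianP)
#' @describeIn EnsembleCouplingResult-class percent of repetitions with
#'   p < 0.05.
#' @export
setMethod("pctSignificant", "EnsembleCouplingResult",
          function(object) object@pctSignificant)
#' @describeIn EnsembleCouplingResult-class median Procrustes correlation.
#' @export
setMethod("medianCorrelation", "EnsembleCouplingResult",
          function(object) object@medianCorrelation)
#' @describeIn EnsembleCouplingResult-class number of repetitions.
#' @export
setMethod("nRepeats", "EnsembleCouplingResult",
          function(object) object@nRepeats)

setMethod("show", "EnsembleCouplingResult", function(object) {
  cat(sprintf("Ensemble coupling over %d NMDS repetitions:\n", object@nRepeats))
  cat(sprintf("  median p = %.4g, %% p < 0.05 = %.1f, median Procrustes correlation = %.3f\n",
              object@medianP, object@pctSignificant,
              object@medianCorrelation))
  invisible(NULL)
})

#' Host-virus coupling by an ensemble of NMDS + protest repetitions
#'
#' A single nonmetric MDS is a stochastic optimisation, so a single protest
#' p-value inherits that noise.  This procedure repeats
#' \{fresh randomly-started NMDS of the host matrix, fresh NMDS of the virus
#' matrix, Procrustes permutation test\} `nRepeats` times and reports the
#' median p-value, the percentage of significant repetitions (p < 0.05) and
#' the median Procrustes correlation.  `mode = "fixedOrdination"` is the
#' alternative reading in which both ordinations are fitted once and only
#' the protest permutations are repeated.
#'
#' Within a repetition the two NMDS fits share one random-start stream
#' (common random numbers).  This makes the coupling statistic measure
#' differences between the two matrices rather than optimiser luck: for
#' identical inputs the two fits are identical and the correlation is
#' exactly 1, while on rugged stress landscapes with near-tied local optima
#' independently seeded fits of even the same matrix can disagree.
#'
#' @param host,virus [BandMatrix-class] objects (or `dist` objects) with
#'   identical sample sets in identical order.
#' @param nRepeats number of NMDS + protest repetitions (the reference
#'   procedure uses 1000).
#' @param nPerm protest row permutations per repetition.
#' @param k ordination dimensionality.
#' @param nRestarts starts per NMDS fit (default 20, as in
#'   [nmdsOrdination()]; rugged stress landscapes of small binary data sets
#'   need this many for two independent fits of the same matrix to agree on
#'   the global optimum).
#' @param seed root seed; per-repetition child seeds are derived
#'   deterministically from it.
#' @param mode `"refit"` (re-run NMDS each repetition; default) or
#'   `"fixedOrdination"`.
#' @return an [EnsembleCouplingResult-class] object.
#' @export
nmdsProcrustesEnsemble <- function(host, virus, nRepeats = 1000, nPerm = 999,
                                   k = 2, nRestarts = 20, seed = NULL,
                                   mode = c("refit", "fixedOrdination")) {
  mode <- match.arg(mode)
  if (nRepeats < 1) stop("'nRepeats' must be at least 1")
  toDist <- function(x, what) {
    if (is(x, "BandMatrix")) return(jaccardDistances(x))
    if (inherits(x, "dist")) return(x)
    stop("'", what, "' must be a BandMatrix or a dist object")
  }
  dh <- toDist(host, "host")
  dv <- toDist(virus, "virus")
  lh <- attr(dh, "Labels"); lv <- attr(dv, "Labels")
  if (attr(dh, "Size") != attr(dv, "Size") ||
      (!is.null(lh) && !is.null(lv) && !identical(lh, lv)))
    stop("host and virus matrices must share the same samples in the same order")

  seeds <- childSeeds(seed, 2L * nRepeats)
  ps <- numeric(nRepeats)
  corrs <- numeric(nRepeats)
  if (mode == "fixedOrdination") {
    oh <- nmdsOrdination(dh, k = k, nRestarts = nRestarts, seed = seeds[[1]])
    ov <- nmdsOrdination(dv, k = k, nRestarts = nRestarts, seed = seeds[[1]])
  }
  for (i in seq_len(nRepeats)) {
    if (mode == "refit") {
      ## common random numbers: both fits share the repetition's seed
      oh <- nmdsOrdination(dh, k = k, nRestarts = nRestarts,
                           seed = seeds[[2 * i - 1]])
      ov <- nmdsOrdination(dv, k = k, nRestarts = nRestarts,
                           seed = seeds[[2 * i - 1]])
    }
    pt <- protestTest(oh, ov, nPerm = nPerm, seed = seeds[[2 * i]])
    ps[i] <- pt$p
    corrs[i] <- pt$correlation
  }
  new("EnsembleCouplingResult",
      medianP = stats::median(ps),
      pctSignificant = 100 * mean(ps < 0.05),
      medianCorrelation = stats::median(corrs),
      nRepeats = as.integer(nRepeats),
      pValues = ps, correlations = corrs)
}
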