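#' @include fingerprintBasics.R
NULL

#' OrdinationResult: a nonmetric MDS configuration
#'
#' @slot coordinates samples-by-k matrix of ordination scores, row order
#'   matching the input distance matrix.
#' @slot stress Kruskal stress-1 of the returned configuration.
#' @slot converged whether the best run met the stress-change tolerance.
#' @slot seed RNG seed used (`NA` when none was given).
#' @export
setClass("OrdinationResult",
  representation(coordinates = "matrix", stress = "numeric",
                 converged = "logical", seed = "integer"))

setValidity("OrdinationResult", function(object) {
  if (length(object@stress) != 1L || is.na(object@stress) ||
      object@stress < 0)
    return("stress must be a single non-negative number")
  TRUE
})

#' @describeIn OrdinationResult-class ordination scores matrix.
#' @param object an `OrdinationResult`.
#' @export
setMethod("ordinationScores", "OrdinationResult",
          function(object) object@coordinates)
#' @describeIn OrdinationResult-class Kruskal stress-1.
#' @export
setMethod("stressValue", "OrdinationResult", function(object) object@stress)
#' @describeIn OrdinationResult-class convergence flag.
#' @export
setMethod("isConverged", "OrdinationResult", function(object) object@converged)

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d samples in %d dimensions, stress-1 = %.4g%s\n",
              nrow(object@coordinates), ncol(object@coordinates),
              object@stress,
              if (object@converged) "" else " (not converged)"))
  invisible(NULL)
})

## Monotone (isotonic) fit of configuration distances on the dissimilarity
## order; primary tie treatment (within tied dissimilarities the fitted
## values are unconstrained, realised by ordering ties by current distance).
monotoneFit <- function(dvec, Dvec) {
  ord <- order(dvec, Dvec)
  dhat <- numeric(length(Dvec))
  dhat[ord] <- stats::isoreg(seq_along(ord), Dvec[ord])$yf
  dhat
}

kruskalStress <- function(Dvec, dhat) {
  denom <- sum(Dvec^2)
  if (denom == 0) return(if (sum(dhat^2) == 0) 0 else 1)
  sqrt(sum((Dvec - dhat)^2) / denom)
}

## One SMACOF run (Guttman transform alternated with monotone regression)
## from a given start.  Stress-1 is tracked and the iteration stops when it
## decreases by less than `tol` or would increase.
smacofRun <- function(dvec, X, maxIter, tol) {
  n <- nrow(X)
  D <- as.vector(stats::dist(X))
  dhat <- monotoneFit(dvec, D)
  s <- kruskalStress(D, dhat)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    ratio <- ifelse(D > 1e-12, dhat / D, 0)
    Rm <- matrix(0, n, n)
    Rm[lower.tri(Rm)] <- ratio
    Rm <- Rm + t(Rm)
    Bm <- -Rm
    diag(Bm) <- rowSums(Rm)
    Xnew <- Bm %*% X / n
    Dnew <- as.vector(stats::dist(Xnew))
    dhatNew <- monotoneFit(dvec, Dnew)
    sNew <- kruskalStress(Dnew, dhatNew)
    if (sNew > s + 1e-12) break        # keep the better configuration
    improved <- s - sNew
    X <- Xnew; D <- Dnew; dhat <- dhatNew; s <- sNew
    if (improved < tol) { converged <- TRUE; break }
  }
  list(X = X, stress = s, converged = converged)
}

## Rotate a centred configuration to its principal axes with deterministic
## axis signs (largest-magnitude loading positive).
principalAxes <- function(X) {
  X <- scale(X, scale = FALSE)
  if (nrow(X) > ncol(X)) {
    sv <- svd(X)
    X <- X %*% sv$v
  }
  for (j in seq_len(ncol(X))) {
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  X
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style nonmetric MDS: SMACOF majorisation (Guttman transform)
#' alternated with monotone regression of configuration distances on the
#' dissimilarity ranks (pool-adjacent-violators via [stats::isoreg()],
#' primary tie treatment).  The best of `nRestarts` starts is returned; the
#' first start is the classical (metric) MDS solution, the rest are random.
#' Samples at zero dissimilarity from one another are collapsed to a single
#' point before embedding and share coordinates afterwards.
#'
#' @param d a `dist` object or symmetric dissimilarity matrix.
#' @param k number of ordination dimensions (default 2, the planar
#'   ordinations conventional for fingerprint data); must be < n samples.
#' @param nRestarts number of starts (first is metric MDS; rest random).
#' @param maxIter maximum SMACOF iterations per start.
#' @param tol stop when stress-1 improves by less than this.
#' @param seed optional integer seed; given the seed the result is
#'   deterministic and the caller's RNG state is untouched.
#' @return an [OrdinationResult-class] object.
#' @examples
#' m <- matrix(rbinom(60, 1, 0.5), nrow = 6)
#' m[rowSums(m) == 0, 1] <- 1
#' ord <- nmdsOrdination(jaccardDistances(m), seed = 1)
#' stressValue(ord)
#' @export
nmdsOrdination <- function(d, k = 2, nRestarts = 20, maxIter = 500,
                           tol = 1e-7, seed = NULL) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8) || any(dm < 0))
    stop("'d' must be a symmetric non-negative dissimilarity matrix")
  n <- nrow(dm)
  if (k < 1 || k >= n)
    stop("'k' must satisfy 1 <= k < number of samples")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  ## collapse zero-dissimilarity duplicates to unique representatives
  group <- integer(n)
  gid <- 0L
  for (i in seq_len(n)) {
    if (group[i] == 0L) {
      gid <- gid + 1L
      group[i] <- gid
      if (i < n) {
        j <- (i + 1L):n
        group[j][group[j] == 0L & dm[i, j] < .Machine$double.eps] <- gid
      }
    }
  }
  reps <- match(seq_len(max(group)), group)
  dmU <- dm[reps, reps, drop = FALSE]
  nU <- length(reps)
  if (k >= nU && nU > 1)
    stop("'k' must be smaller than the number of distinct samples")

  dvecFull <- dm[lower.tri(dm)]
  result <- withSeed(seed, {
    if (nU == 1) {
      list(X = matrix(0, 1, k), stress = 0, converged = TRUE)
    } else {
      dvec <- dmU[lower.tri(dmU)]
      scale0 <- max(dvec)
      best <- NULL
      for (r in seq_len(max(1L, nRestarts))) {
        X0 <- if (r == 1L) {
          cm <- suppressWarnings(stats::cmdscale(stats::as.dist(dmU), k = k))
          if (ncol(cm) < k)
            cm <- cbind(cm, matrix(stats::runif(nU * (k - ncol(cm)),
                                                -1e-4, 1e-4), nU))
          cm + matrix(stats::runif(nU * k, -1e-6, 1e-6), nU)
        } else {
          matrix(stats::runif(nU * k, -scale0, scale0), nU, k)
        }
        run <- smacofRun(dvec, X0, maxIter, tol)
        if (is.null(best) || run$stress < best$stress) best <- run
      }
      best
    }
  })

  Xfull <- result$X[group, , drop = FALSE]
  if (nU > 1) Xfull <- principalAxes(Xfull)
  ## report stress on the full problem (duplicates contribute zero)
  Dfull <- as.vector(stats::dist(Xfull))
  stressFull <- kruskalStress(Dfull, monotoneFit(dvecFull, Dfull))
  dimnames(Xfull) <- list(labels, paste0("axis", seq_len(k)))
  new("OrdinationResult", coordinates = Xfull, stress = stressFull,
      converged = result$converged,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
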