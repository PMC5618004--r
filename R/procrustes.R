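#' @include nmds.R
NULL

## Centre a configuration and scale it to unit sum of squares.
normaliseConfig <- function(X, name) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("'", name, "' contains missing values")
  X <- scale(X, scale = FALSE)
  ss <- sum(X^2)
  if (ss == 0) stop("'", name, "' is degenerate (all points coincide)")
  X / sqrt(ss)
}

## Sum of singular values of t(X) %*% Y for unit-normalised configurations:
## this is the Procrustes correlation.  Closed form in two dimensions.
procrustesTrace <- function(M) {
  if (nrow(M) == 2L && ncol(M) == 2L) {
    sqrt(sum(M^2) + 2 * abs(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]))
  } else {
    sum(svd(M)$d)
  }
}

#' Symmetric Procrustes superimposition of two configurations
#'
#' Both configurations are centred and scaled to unit total sum of squares,
#' then `Y` is rotated (and rescaled) onto `X` to minimise the residual sum
#' of squares.  With this symmetric normalisation the residual statistic is
#' `m2 = 1 - (sum of singular values of X'Y)^2`, and the Procrustes
#' correlation is `sqrt(1 - m2)`.
#'
#' @param X,Y configurations (matrices or [OrdinationResult-class]) with the
#'   same samples in the same row order and equal column count.
#' @return a list with `m2`, `correlation`, the orthogonal `rotation`
#'   applied to `Y` and the least-squares `scaling` factor.
#' @examples
#' X <- matrix(rnorm(12), 6)
#' theta <- pi / 3
#' R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
#' procrustesAnalysis(X, X %*% R)$m2  # ~0
#' @export
procrustesAnalysis <- function(X, Y) {
  if (is(X, "OrdinationResult")) X <- ordinationScores(X)
  if (is(Y, "OrdinationResult")) Y <- ordinationScores(Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y)))
    stop("configurations must have identical dimensions")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("configurations must contain the same samples in the same order")
  Xn <- normaliseConfig(X, "X")
  Yn <- normaliseConfig(Y, "Y")
  sv <- svd(crossprod(Xn, Yn))
  corr <- sum(sv$d)
  m2 <- max(0, 1 - corr^2)
  list(m2 = m2, correlation = min(1, corr),
       rotation = sv$v %*% t(sv$u), scaling = corr)
}

#' Permutation test of Procrustes concordance (protest)
#'
#' Tests whether two configurations agree more than expected by chance by
#' permuting the row order of `Y` and recomputing the Procrustes
#' correlation.  The p-value uses the add-one convention
#' `p = (1 + #permuted >= observed) / (nPerm + 1)`, so it can never be 0.
#'
#' @inheritParams procrustesAnalysis
#' @param nPerm number of row permutations (>= 1).
#' @param seed optional integer seed for the permutation stream.
#' @return a list with `p`, the observed `correlation`, `m2`, `nPerm` and
#'   the vector of `permutedCorrelations`.
#' @export
protestTest <- function(X, Y, nPerm = 999, seed = NULL) {
  if (nPerm < 1) stop("'nPerm' must be at least 1")
  if (is(X, "OrdinationResult")) X <- ordinationScores(X)
  if (is(Y, "OrdinationResult")) Y <- ordinationScores(Y)
  obs <- procrustesAnalysis(X, Y)
  Xn <- normaliseConfig(X, "X")
  Yn <- normaliseConfig(Y, "Y")
  n <- nrow(Xn)
  perms <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      idx <- sample.int(n)
      ## row-permuted Y stays centred and unit-scaled
      procrustesTrace(crossprod(Xn, Yn[idx, , drop = FALSE]))
    }, numeric(1))
  })
  p <- (1 + sum(perms >= obs$correlation - 1e-12)) / (nPerm + 1)
  list(p = p, correlation = obs$correlation, m2 = obs$m2, nPerm = nPerm,
       permutedCorrelations = perms)
}
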