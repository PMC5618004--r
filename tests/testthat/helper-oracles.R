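## Shared fixtures and independent oracles for the test suite.

## Reference rate constants with unit yield/supply, convenient for hand
## arithmetic (k = 1.1111e-3, crossover at C = 30 nmol-P/L).
unitParams <- function(yieldBC = 1, psi = 1)
  foodWebParameters(yieldBC = yieldBC, psi = psi)

shippedParams <- function()
  readFoodWebParameters(system.file("extdata", "params_pentagon.yaml",
                                    package = "pentaweb"))

## Random binary samples-by-bands matrix with no empty rows.
randomBinaryMatrix <- function(n, b, p = 0.5) {
  m <- matrix(rbinom(n * b, 1, p), n, b)
  m[rowSums(m) == 0, 1] <- 1L
  storage.mode(m) <- "integer"
  rownames(m) <- sprintf("s%02d", seq_len(n))
  colnames(m) <- sprintf("b%03d", seq_len(b))
  m
}

## All n! permutations of 1:n (n <= 7), one per row.
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

## Independent NMDS stress oracle: numerical minimisation (BFGS with
## numerical gradients) of Kruskal stress-1 over raw coordinates, with its
## own monotone-regression step.  Returns the best stress over many starts.
oracleBestStress <- function(dmat, k, nStarts = 30) {
  dv <- dmat[lower.tri(dmat)]
  n <- nrow(dmat)
  ord <- order(dv)
  stressOf <- function(x) {
    X <- matrix(x, n, k)
    D <- as.vector(dist(X))
    dhat <- numeric(length(D))
    dhat[ord] <- isoreg(seq_along(ord), D[ord])$yf
    den <- sum(D^2)
    if (den == 0) return(1)
    sqrt(sum((D - dhat)^2) / den)
  }
  best <- Inf
  for (s in seq_len(nStarts)) {
    x0 <- runif(n * k, -1, 1)
    fit <- suppressWarnings(optim(x0, stressOf, method = "BFGS",
                                  control = list(maxit = 400, reltol = 1e-12)))
    best <- min(best, fit$value)
  }
  best
}

## Independent Procrustes m2 oracle in two dimensions: explicit search over
## the rotation angle (both chiralities), scale optimised analytically.
oracleProcrustesM2 <- function(X, Y) {
  norm1 <- function(Z) {
    Z <- scale(as.matrix(Z), scale = FALSE)
    Z / sqrt(sum(Z^2))
  }
  Xn <- norm1(X); Yn <- norm1(Y)
  tr <- function(theta, refl) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    if (refl) R <- R %*% diag(c(1, -1))
    sum(diag(crossprod(Xn, Yn %*% R)))
  }
  best <- -Inf
  for (refl in c(FALSE, TRUE)) {
    ## coarse grid + local refinement
    grid <- seq(-pi, pi, length.out = 721)
    vals <- vapply(grid, tr, numeric(1), refl = refl)
    i <- which.max(vals)
    opt <- optimize(tr, interval = grid[c(max(1, i - 2), min(721, i + 2))],
                    refl = refl, maximum = TRUE, tol = 1e-12)
    best <- max(best, opt$objective)
  }
  1 - best^2
}

## Exact protest p by full enumeration of row permutations (n <= 6).
exactProtestP <- function(X, Y) {
  perms <- allPermutations(nrow(as.matrix(X)))
  obs <- procrustesAnalysis(X, Y)$correlation
  stats <- apply(perms, 1, function(idx)
    procrustesAnalysis(X, as.matrix(Y)[idx, , drop = FALSE])$correlation)
  mean(stats >= obs - 1e-12)
}

## Independent PERMANOVA oracle via Gower centring and the hat matrix.
oraclePermanovaF <- function(dmat, grouping) {
  n <- nrow(dmat)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (dmat^2) %*% J
  Xm <- model.matrix(~ factor(grouping))
  Hm <- Xm %*% solve(crossprod(Xm)) %*% t(Xm)
  ssT <- sum(diag(G))
  ssB <- sum(diag(Hm %*% G %*% Hm))
  a <- length(unique(grouping))
  list(F = (ssB / (a - 1)) / ((ssT - ssB) / (n - a)), R2 = ssB / ssT)
}

## Exact PERMANOVA p by full enumeration of label permutations (n <= 6).
exactPermanovaP <- function(dmat, grouping) {
  perms <- allPermutations(length(grouping))
  fObs <- oraclePermanovaF(dmat, grouping)$F
  fAll <- apply(perms, 1, function(idx)
    oraclePermanovaF(dmat, grouping[idx])$F)
  mean(fAll >= fObs - 1e-12)
}

## 99% binomial confidence bounds for an empirical rate.
binom99 <- function(p, n) {
  hw <- 2.576 * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - hw), upper = min(1, p + hw))
}
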