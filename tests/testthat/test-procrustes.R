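test_that("Procrustes residual is zero under similarity transforms", {
  set.seed(1)
  X <- matrix(rnorm(16), 8)
  fit <- procrustesAnalysis(X, X)
  expect_equal(fit$m2, 0, tolerance = 1e-12)
  expect_equal(fit$correlation, 1, tolerance = 1e-12)
  ## rotation by 90 degrees plus a shift and rescaling
  R <- matrix(c(0, 1, -1, 0), 2)
  Y <- 3 * X %*% R + matrix(rep(c(5, -2), each = 8), 8)
  expect_equal(procrustesAnalysis(X, Y)$m2, 0, tolerance = 1e-12)
})

test_that("m2 agrees with independent oracles", {
  set.seed(2)
  for (i in 1:5) {
    X <- matrix(rnorm(8), 4)
    Y <- matrix(rnorm(8), 4)
    fit <- procrustesAnalysis(X, Y)
    ## rotation-angle search oracle
    expect_equal(fit$m2, oracleProcrustesM2(X, Y), tolerance = 1e-10)
    ## reference implementation (symmetric scaling)
    ref <- vegan::procrustes(X, Y, symmetric = TRUE)
    expect_equal(fit$m2, ref$ss, tolerance = 1e-10)
    expect_equal(fit$correlation, sqrt(1 - fit$m2), tolerance = 1e-12)
  }
})

test_that("procrustes rejects mismatched configurations", {
  X <- matrix(rnorm(12), 6)
  expect_error(procrustesAnalysis(X, X[1:5, ]), "identical dimensions")
  Y <- X
  rownames(X) <- letters[1:6]; rownames(Y) <- letters[6:1]
  expect_error(procrustesAnalysis(X, Y), "same samples")
  expect_error(procrustesAnalysis(X, matrix(0, 6, 2)), "degenerate")
})

test_that("protest p-values honour the add-one convention", {
  set.seed(3)
  X <- matrix(rnorm(16), 8)
  ## self-comparison with distinct rows: no permutation beats identity
  pt <- protestTest(X, X, nPerm = 999, seed = 5)
  expect_equal(pt$p, 1 / 1000)
  expect_true(all(pt$permutedCorrelations <= 1))
  expect_error(protestTest(X, X, nPerm = 0), "at least 1")
  ## p can never be zero
  Y <- matrix(rnorm(16), 8)
  ps <- replicate(20, protestTest(X, Y, nPerm = 19)$p)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("Monte-Carlo protest p matches full enumeration on 3 samples", {
  set.seed(4)
  for (i in 1:3) {
    X <- matrix(rnorm(6), 3)
    Y <- matrix(rnorm(6), 3)
    exact <- exactProtestP(X, Y)
    mc <- protestTest(X, Y, nPerm = 1999, seed = i)$p
    expect_lt(abs(mc - exact), 0.05)
  }
})

test_that("protest rejects at the nominal rate under the null", {
  set.seed(6)
  rej <- mean(replicate(400, {
    X <- matrix(rnorm(20), 10)
    Y <- matrix(rnorm(20), 10)
    protestTest(X, Y, nPerm = 99)$p < 0.05
  }))
  ci <- binom99(0.05, 400)
  expect_gte(rej, ci["lower"])
  expect_lte(rej, ci["upper"])
})
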