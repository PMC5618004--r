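test_that("perfectly coupled matrices give unit correlation and full significance", {
  spec <- couplingSpec(nSamples = 12, nBandsHost = 30, nBandsVirus = 30,
                       coupling = 1, flipRate = 0)
  bm <- generateBandMatrices(spec, seed = 11)
  ens <- nmdsProcrustesEnsemble(bm$host, bm$virus, nRepeats = 20,
                                nPerm = 99, nRestarts = 5, seed = 3)
  expect_gte(medianCorrelation(ens), 0.999)
  expect_equal(pctSignificant(ens), 100)
  expect_equal(nRepeats(ens), 20L)
  expect_lte(medianP(ens), 0.05)
})

test_that("coupled-with-noise matrices beat the null coupling level", {
  te <- 0.35
  coupled <- generateBandMatrices(
    couplingSpec(nBandsVirus = 30, treatmentEffect = te, coupling = 1,
                 flipRate = 0.10), seed = 42)
  nullpair <- generateBandMatrices(
    couplingSpec(nBandsVirus = 30, treatmentEffect = te, coupling = 0),
    seed = 42)
  eC <- nmdsProcrustesEnsemble(coupled$host, coupled$virus, nRepeats = 12,
                               nPerm = 199, nRestarts = 3, seed = 9)
  eN <- nmdsProcrustesEnsemble(nullpair$host, nullpair$virus, nRepeats = 12,
                               nPerm = 199, nRestarts = 3, seed = 9)
  expect_gt(medianCorrelation(eC), medianCorrelation(eN))
  expect_lt(medianP(eC), medianP(eN))
})

test_that("power increases with coupling strength (averaged over datasets)", {
  pct <- sapply(c(0, 0.5, 1), function(cpl) {
    mean(sapply(1:4, function(i) {
      b <- generateBandMatrices(couplingSpec(coupling = cpl,
                                             flipRate = 0.05),
                                seed = 300 + i)
      pctSignificant(nmdsProcrustesEnsemble(b$host, b$virus, nRepeats = 8,
                                            nPerm = 99, nRestarts = 2,
                                            seed = i))
    }))
  })
  expect_true(all(diff(pct) >= 0))
})

test_that("the fixed-ordination mode and input contracts behave", {
  bm <- generateBandMatrices(couplingSpec(coupling = 1), seed = 5)
  ens <- nmdsProcrustesEnsemble(bm$host, bm$virus, nRepeats = 10,
                                nPerm = 99, nRestarts = 5, seed = 1,
                                mode = "fixedOrdination")
  expect_equal(length(ens@pValues), 10)
  ## with both ordinations frozen the correlation is constant across repeats
  expect_equal(length(unique(ens@correlations)), 1)
  ## mismatched samples are rejected
  other <- generateBandMatrices(couplingSpec(nSamples = 10), seed = 6)
  expect_error(nmdsProcrustesEnsemble(bm$host, other$virus, nRepeats = 2,
                                      nPerm = 9), "same samples")
  expect_error(nmdsProcrustesEnsemble(bm$host, bm$virus, nRepeats = 0,
                                      nPerm = 9), "at least 1")
})
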