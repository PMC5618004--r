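test_that("the two standard tank designs are laid out correctly", {
  d1 <- generateDesign("PAME-I")
  expect_equal(nrow(d1@tanks), 8)
  expect_equal(d1@volumeL, 700)
  ## two gradients of 0, 0.5, 1, 3; one with silicate
  for (si in c(TRUE, FALSE)) {
    g <- sort(d1@tanks$glucose_x[d1@tanks$silicate == si])
    expect_equal(g, c(0, 0.5, 1, 3))
  }
  d2 <- generateDesign("PAME-II")
  expect_equal(nrow(d2@tanks), 9)
  expect_equal(d2@volumeL, 900)
  expect_true(all(d2@tanks$silicate))
  expect_equal(sort(d2@tanks$glucose_x[d2@tanks$nitrogen_source == "NH4"]),
               c(0, 0.5, 1, 2, 3))
  expect_equal(sort(d2@tanks$glucose_x[d2@tanks$nitrogen_source == "NO3"]),
               c(0, 0.5, 1, 3))
  ## every gradient has exactly one unamended and one 3x tank
  for (d in list(d1, d2)) {
    grad <- if (identical(d, d1)) d@tanks$silicate else d@tanks$nitrogen_source
    for (g in unique(grad)) {
      expect_equal(sum(d@tanks$glucose_x[grad == g] == 0), 1)
      expect_equal(sum(d@tanks$glucose_x[grad == g] == 3), 1)
    }
  }
  expect_error(generateDesign("PAME-III"))
})

test_that("simulated experiments are deterministic and regime-faithful", {
  p <- shippedParams()
  des <- generateDesign("PAME-I")
  s1 <- simulateExperiment(des, p, "low", noiseCv = 0.1, seed = 9)
  s2 <- simulateExperiment(des, p, "low", noiseCv = 0.1, seed = 9)
  expect_identical(s1, s2)
  ## without noise, tanks differing only in silicate are identical
  s0 <- simulateExperiment(des, p, "low", noiseCv = 0, seed = 1)
  t1 <- s0[s0$tank_id == "T1", ]          # 0x glucose, -Si
  t5 <- s0[s0$tank_id == "T5", ]          # 0x glucose, +Si
  expect_equal(t1$value, t5$value)
  ## tidy output contract
  expect_identical(names(s0),
                   c("tank_id", "day", "time_h", "variable", "value", "unit"))
  expect_setequal(unique(s0$variable),
                  c("prokaryotes", "hnf", "ciliates", "virus_I", "virus_II",
                    "virus_III", "virus_IV"))
  expect_true(all(s0$value >= 0))
})

test_that("glucose response appears under high-ciliate forcing only", {
  p <- shippedParams()
  des <- generateDesign("PAME-I")
  finalB <- function(regime) {
    s <- simulateExperiment(des, p, regime, noiseCv = 0, seed = 1)
    f <- s[s$variable == "prokaryotes" & s$day == 12, ]
    sapply(c(0, 3), function(g) {
      ids <- des@tanks$tank_id[des@tanks$glucose_x == g]
      mean(f$value[f$tank_id %in% ids])
    })
  }
  lo <- finalB("low")
  hi <- finalB("high")
  expect_lt(abs(lo[2] / lo[1] - 1), 0.05)   # MNL: no glucose response
  expect_gt(abs(hi[2] / hi[1] - 1), 0.20)   # OCL: strong response
})

test_that("band-matrix generation honours coupling, noise and feasibility", {
  spec <- couplingSpec(nSamples = 12, nBandsHost = 30, nBandsVirus = 30,
                       coupling = 1, flipRate = 0)
  bm <- generateBandMatrices(spec, seed = 11)
  ## perfect coupling with matched band count: identical matrices
  expect_identical(unname(bandValues(bm$host)), unname(bandValues(bm$virus)))
  expect_identical(sampleIds(bm$host), sampleIds(bm$virus))
  ## metadata carries the fingerprinted treatments
  expect_true(all(sampleData(bm$host)$glucose_x %in% c(0, 3)))
  ## deterministic given a seed
  bm2 <- generateBandMatrices(spec, seed = 11)
  expect_identical(bandValues(bm2$host), bandValues(bm$host))
  expect_identical(bandValues(bm2$virus), bandValues(bm$virus))
  ## no empty fingerprints even under heavy noise
  noisy <- generateBandMatrices(couplingSpec(flipRate = 0.4), seed = 12)
  expect_true(all(rowSums(bandValues(noisy$virus)) > 0))
  ## infeasible spec: mirrored all-ones rows flipped to all-zero
  expect_error(
    generateBandMatrices(couplingSpec(nBandsHost = 4, nBandsVirus = 4,
                                      baseProb = 1, coupling = 1,
                                      flipRate = 1), seed = 1),
    "infeasible")
  ## treatment effect shifts presence in responding bands
  eff <- generateBandMatrices(couplingSpec(nSamples = 40,
                                           treatmentEffect = 0.4),
                              seed = 13)
  v <- bandValues(eff$host)
  treated <- sampleData(eff$host)$glucose_x > 0
  respond <- seq_len(ncol(v)) <= ncol(v) / 2
  expect_gt(mean(v[treated, respond]) - mean(v[!treated, respond]), 0.2)
})

test_that("the piecewise carbon-demand fit recovers and flags parameters", {
  k <- 1.1111e-3; psi <- 1
  C <- seq(1, 60, length.out = 20)
  ## noiseless identifiability
  fit <- fitBcdCurve(C, pmin(k * C^2, psi))
  expect_lt(abs(fit$k / k - 1), 1e-6)
  expect_lt(abs(fit$psi / psi - 1), 1e-6)
  expect_true(all(fit$identifiable))
  expect_equal(fit$crossover, sqrt(psi / k), tolerance = 1e-5)
  ## censoring below the crossover: plateau unidentifiable
  Clow <- seq(1, 20, length.out = 10)
  expect_warning(fitLow <- fitBcdCurve(Clow, k * Clow^2), "psi")
  expect_false(fitLow$identifiable[["psi"]])
  expect_true(is.na(fitLow$psi))
  expect_lt(abs(fitLow$k / k - 1), 1e-4)
  ## all observations on the plateau: curvature unidentifiable
  Chigh <- seq(40, 90, length.out = 10)
  expect_warning(fitHigh <- fitBcdCurve(Chigh, rep(psi, 10)), "k")
  expect_false(fitHigh$identifiable[["k"]])
  ## contracts
  expect_error(fitBcdCurve(1:3, 1:3), "at least 4")
  expect_error(fitBcdCurve(1:4, c(1, 2, 3, -1)), "non-negative")
})
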