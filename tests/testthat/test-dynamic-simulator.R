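test_that("derivative balances vanish at the closed-form roots", {
  p <- shippedParams()
  Cc <- 4
  ## nanoflagellate balance at B = alphaC*C/(yieldH*alphaH)
  st <- foodWebState(P = 0.2, D = 500, A = 5,
                     B = prokaryoteBiomass(Cc, p), H = 2, C = Cc)
  d <- foodWebDerivatives(st, p)
  expect_equal(unname(d["H"]), 0, tolerance = 1e-15)
  ## autotroph balance at P = (alphaC/alphaA)*C
  st2 <- foodWebState(P = freePhosphate(Cc, p), D = 500, A = 5, B = 1,
                      H = 2, C = Cc)
  d2 <- foodWebDerivatives(st2, p)
  expect_equal(unname(d2["A"]), 0, tolerance = 1e-15)
  ## a fully empty closed system stays empty
  d0 <- foodWebDerivatives(foodWebState(), p,
                           forcingSchedule(phosphateDose = 0, psi = 0))
  expect_true(all(d0 == 0))
  ## negative states are domain errors
  expect_error(foodWebDerivatives(c(P = -1, B = 2), p), "non-negative")
})

test_that("total phosphorus is conserved in a closed run", {
  p <- shippedParams()
  y0 <- foodWebState(P = 5, D = 100, A = 3, B = 4, H = 1, C = 2)
  tr <- simulateFoodWeb(y0, p, forcingSchedule(durationDays = 30),
                        closed = TRUE, tGrid = seq(0, 720, by = 2))
  total <- rowSums(tr[, c("P", "A", "B", "H", "C", "S")])
  expect_lt(max(abs(total / total[1] - 1)), 1e-6)
  expect_true(all(as.matrix(tr[, c("P", "D", "A", "B", "H", "C", "S")]) >= 0))
})

test_that("a clamped-ciliate run relaxes onto the closed-form steady state", {
  p <- shippedParams()
  Cc <- 5
  rp <- equilibriumPhosphateSupply(Cc, p)
  y0 <- equilibriumState(Cc, p)
  y0["B"] <- 2 * y0["B"]        # start prokaryotes at twice the equilibrium
  tr <- simulateFoodWeb(y0, p,
                        forcingSchedule(durationDays = 1000,
                                        phosphateDose = rp,
                                        dosing = "continuous"),
                        tGrid = seq(0, 24000, by = 100),
                        clampCiliates = TRUE)
  fin <- tr[nrow(tr), ]
  expect_lt(abs(fin$B / prokaryoteBiomass(Cc, p) - 1), 1e-3)
  expect_lt(abs(fin$P / freePhosphate(Cc, p) - 1), 1e-3)
  chk <- steadyStateCheck(tr, p, tol = 1e-3)
  expect_true(all(chk$pass))
  ## the transient-only window is flagged
  early <- tr[tr$time_h <= 2400, ]
  chkEarly <- steadyStateCheck(early, p, tol = 1e-3)
  expect_false(all(chkEarly$pass))
})

test_that("non-negativity holds from random initial conditions", {
  p <- shippedParams()
  set.seed(3)
  for (i in 1:5) {
    y0 <- foodWebState(P = runif(1, 0, 50), D = runif(1, 0, 5000),
                       A = runif(1, 0, 30), B = runif(1, 0, 30),
                       H = runif(1, 0, 10), C = runif(1, 0, 20))
    tr <- simulateFoodWeb(y0, p, forcingSchedule(durationDays = 12),
                          tGrid = seq(0, 288, by = 4))
    expect_true(all(as.matrix(tr[, c("P", "D", "A", "B", "H", "C")]) >= 0))
  }
})

test_that("simulator input contracts are enforced", {
  p <- shippedParams()
  expect_error(simulateFoodWeb(foodWebState(B = 1), p,
                               tGrid = c(0, 0, 1)), "strictly increasing")
  expect_error(simulateFoodWeb(c(B = 1, X = 2), p), "unknown state")
  expect_error(forcingSchedule(glucoseMultiplier = 1.7), "0, 0.5, 1, 2, 3")
  tr <- simulateFoodWeb(foodWebState(B = 1), p,
                        forcingSchedule(durationDays = 1),
                        tGrid = seq(0, 24, by = 12))
  expect_error(steadyStateCheck(tr[1:2, ], p), "too short")
  ## degenerate all-zero trajectory has residuals defined as zero
  trz <- simulateFoodWeb(foodWebState(), p,
                         forcingSchedule(phosphateDose = 0, psi = 0),
                         tGrid = seq(0, 24, by = 1))
  chk <- steadyStateCheck(trz, p)
  expect_true(all(chk$maxRelResidual == 0))
})
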