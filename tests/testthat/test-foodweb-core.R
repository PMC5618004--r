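test_that("closed-form steady states match hand-derived values", {
  p <- unitParams()
  ## prokaryote biomass: B = alphaC*C/(yieldH*alphaH)
  expect_identical(prokaryoteBiomass(0, p), 0)
  expect_equal(prokaryoteBiomass(9, p), 10)
  expect_equal(prokaryoteBiomass(1, p), 10 / 9)
  ## free phosphate: P = (alphaC/alphaA)*C
  expect_identical(freePhosphate(0, p), 0)
  expect_equal(freePhosphate(8, p), 0.1)
  expect_equal(freePhosphate(1, p), 0.0125)
  ## growth rate: mu = alphaB*P, composition exact
  expect_identical(prokaryoteGrowthRate(0, p), 0)
  expect_equal(prokaryoteGrowthRate(100, p), 0.1)
  expect_equal(prokaryoteGrowthRate(10, p), 0.01)
  expect_identical(prokaryoteGrowthRate(7.3, p),
                   alphaB(p) * freePhosphate(7.3, p))
  ## negative abundances are domain errors
  expect_error(prokaryoteBiomass(-1, p), "non-negative")
  expect_error(freePhosphate(-0.1, p), "non-negative")
  expect_error(prokaryoteGrowthRate(-2, p), "non-negative")
})

test_that("carbon demand is quadratic below the supply ceiling and capped above", {
  p <- unitParams()          # k = 1.1111e-3, psi = 1, crossover C* = 30
  expect_identical(bcdMineralLimited(0, p), 0)
  expect_equal(bcdMineralLimited(10, p), 2e-8 / 1.8e-5 * 100)
  expect_equal(bcdMineralLimited(20, p) / bcdMineralLimited(10, p), 4)
  ## demand equals production over yield
  C <- c(0.5, 3, 17, 42)
  expect_equal(bcdMineralLimited(C, p),
               prokaryoteGrowthRate(C, p) * prokaryoteBiomass(C, p) /
                 yieldBC(p), tolerance = 1e-12)
  ## ceiling
  expect_equal(bcd(30, p), 1)              # exactly at the crossover
  expect_equal(bcd(1000, p), 1)            # saturated
  expect_identical(bcd(0, p), 0)
  ## non-decreasing over an increasing grid
  grid <- seq(0, 120, length.out = 400)
  expect_true(all(diff(bcd(grid, p)) >= 0))
})

test_that("regime classification switches at the crossover with an OCL tie", {
  p <- unitParams()
  expect_identical(as.character(classifyRegime(0, p)), "MNL")
  expect_identical(as.character(classifyRegime(29.9, p)), "MNL")
  expect_identical(as.character(classifyRegime(30.1, p)), "OCL")
  expect_identical(as.character(classifyRegime(30, p)), "OCL")  # tie rule
  ## OCL <=> demand capped at psi
  C <- seq(0, 80, by = 0.7)
  expect_identical(classifyRegime(C, p) == "OCL",
                   bcd(C, p) == docSupply(p))
  ## crossover closed form and continuity there
  expect_equal(crossoverCiliateDensity(p), 30)
  Cstar <- crossoverCiliateDensity(p)
  expect_lt(abs(bcd(Cstar, p) - docSupply(p)) / docSupply(p), 1e-10)
  expect_lt(abs(bcdMineralLimited(Cstar, p) - docSupply(p)) /
              docSupply(p), 1e-12)
  ## sqrt scaling in psi and k
  p4 <- unitParams(psi = 4)
  expect_equal(crossoverCiliateDensity(p4), 60)
  pk <- foodWebParameters(alphaC = 2 * alphaC(p), yieldBC = 1, psi = 1)
  expect_equal(crossoverCiliateDensity(pk), 15)  # k x4 halves C*
})

test_that("closed-form identities hold over random parameter sets", {
  set.seed(1)
  for (i in 1:1000) {
    p <- foodWebParameters(alphaB = runif(1, 1e-3, 1),
                           alphaA = runif(1, 1e-3, 1),
                           alphaH = runif(1, 1e-4, 0.1),
                           alphaC = runif(1, 1e-4, 0.1),
                           yieldH = runif(1, 0.05, 1),
                           yieldBC = runif(1, 1e-3, 1),
                           psi = runif(1, 0.1, 10))
    C <- runif(3, 0, 50)
    ## composition identity
    expect_equal(bcdMineralLimited(C, p),
                 prokaryoteGrowthRate(C, p) * prokaryoteBiomass(C, p) /
                   yieldBC(p), tolerance = 1e-12)
    ## crossover continuity and regime equivalence
    Cstar <- crossoverCiliateDensity(p)
    expect_lt(abs(bcd(Cstar, p) - docSupply(p)) / docSupply(p), 1e-10)
    expect_identical(as.character(classifyRegime(0.999 * Cstar, p)), "MNL")
    expect_identical(as.character(classifyRegime(1.001 * Cstar, p)), "OCL")
    ## scaling laws in alphaC: B, P linear; BCD_P quadratic
    s <- runif(1, 1.1, 5)
    ps <- foodWebParameters(alphaB = alphaB(p), alphaA = alphaA(p),
                            alphaH = alphaH(p), alphaC = s * alphaC(p),
                            yieldH = yieldH(p), yieldBC = yieldBC(p),
                            psi = docSupply(p))
    expect_equal(prokaryoteBiomass(C, ps), s * prokaryoteBiomass(C, p))
    expect_equal(freePhosphate(C, ps), s * freePhosphate(C, p))
    expect_equal(bcdMineralLimited(C, ps), s^2 * bcdMineralLimited(C, p))
  }
})

test_that("ciliate P content follows sphere volume and Redfield stoichiometry", {
  sigma <- ciliatePContent(20)
  expect_equal(signif(sigma, 2), 0.00043)
  expect_identical(ciliatePContent(0), 0)
  expect_equal(ciliatePContent(40) / ciliatePContent(20), 8)
  expect_error(ciliatePContent(-5), "non-negative")
  expect_error(ciliatePContent(20, carbonDensity = 0), "positive")
})

test_that("cell-count carbon demand bridges units and temperature", {
  p <- unitParams()
  expect_identical(bcdCells(0, p), 0)
  ## unit-consistency identity at the reference temperature
  x <- c(1, 7, 33, 120)
  expect_equal(bcdCells(x, p), bcd(x * sigmaCiliate(p) * 1000, p),
               tolerance = 1e-12)
  ## net Q10 factor on the quadratic coefficient
  xc <- 5   # cells/mL, below the ceiling either way
  cold <- bcdCells(xc, p, temperature = refTemperature(p) - 10)
  ref <- bcdCells(xc, p)
  expect_equal(cold, ref / q10(p), tolerance = 1e-12)
  expect_equal(cold, q10(p)^((-10) / 10) *
                 bcd(xc * sigmaCiliate(p) * 1000, p), tolerance = 1e-12)
  ## consistent with rescaling the whole parameter set
  expect_equal(bcdCells(xc, p, temperature = 12),
               bcd(xc * sigmaCiliate(p) * 1000, temperatureScale(p, 12)),
               tolerance = 1e-12)
})

test_that("temperature scaling acts on the alphas only and composes", {
  p <- unitParams()
  expect_equal(temperatureScale(p, refTemperature(p)), p)
  warm <- temperatureScale(p, refTemperature(p) + 10)
  expect_equal(alphaB(warm), 1.3 * alphaB(p))
  expect_equal(alphaC(warm), 1.3 * alphaC(p))
  expect_identical(yieldH(warm), yieldH(p))
  expect_identical(sigmaCiliate(warm), sigmaCiliate(p))
  expect_identical(docSupply(warm), docSupply(p))
  back <- temperatureScale(warm, refTemperature(p))
  expect_equal(alphaA(back), alphaA(p), tolerance = 1e-12)
})

test_that("steadyState tabulates all quantities coherently", {
  p <- shippedParams()
  st <- steadyState(c(0, 2, 5, 12.5), p)
  expect_identical(names(st), c("C", "B", "P", "mu", "bcd", "regime"))
  expect_true(all(st$B >= 0 & st$P >= 0 & st$mu >= 0 & st$bcd >= 0))
  expect_identical(as.character(st$regime), c("MNL", "MNL", "MNL", "OCL"))
  ## cell-count interface agrees with the biomass interface
  stc <- steadyState(10, p, cells = TRUE)
  expect_equal(stc$C, 10 * sigmaCiliate(p) * 1000)
  expect_equal(stc$B, prokaryoteBiomass(stc$C, p))
})

test_that("parameter validity is enforced", {
  expect_error(foodWebParameters(psi = 1), "yieldBC")
  expect_error(foodWebParameters(yieldBC = 0.006), "psi")
  expect_error(foodWebParameters(yieldBC = -1, psi = 1), "positive")
  expect_error(foodWebParameters(yieldBC = 0.1, psi = 1, yieldH = 1.4),
               "yieldH")
  expect_error(foodWebParameters(yieldBC = 0.1, psi = 1, q10 = 0.8), "q10")
})
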