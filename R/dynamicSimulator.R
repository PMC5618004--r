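#' @include foodwebCore.R
NULL

designMultipliers <- c(0, 0.5, 1, 2, 3)

#' ForcingSchedule: external inputs to a mesocosm tank
#'
#' Describes the bottom-up forcing of one experimental unit: daily mineral
#' nutrient (phosphate) doses, glucose doses expressed as a multiple of the
#' Redfield carbon equivalent of the phosphate dose (C:P = 106 molar),
#' continuous autochthonous labile-DOC supply `psi`, and copepod grazing as
#' a fixed specific loss rate on ciliates.
#'
#' @slot phosphateDose phosphate added per dosing event (nmol-P/L).
#' @slot glucoseMultiplier Redfield-C multiple of the glucose addition; one
#'   of 0, 0.5, 1, 2, 3 (the gradient levels of the enrichment design).
#' @slot psi autochthonous labile-DOC supply (nmol-C/L/h); `NA` means "use
#'   the value carried by the parameter set".
#' @slot copepodClearance specific loss rate imposed on ciliates (1/h).
#' @slot durationDays experiment duration (days).
#' @slot doseTimes times of the dosing events (hours from start).
#' @slot dosing `"impulse"` (instantaneous additions at `doseTimes`, the
#'   mesocosm protocol) or `"continuous"` (the same daily amounts spread
#'   evenly in time, the appropriate boundary condition for steady-state
#'   experiments).
#' @export
setClass("ForcingSchedule",
  representation(phosphateDose = "numeric", glucoseMultiplier = "numeric",
                 psi = "numeric", copepodClearance = "numeric",
                 durationDays = "numeric", doseTimes = "numeric",
                 dosing = "character"))

setValidity("ForcingSchedule", function(object) {
  msg <- character()
  if (!(object@glucoseMultiplier %in% designMultipliers))
    msg <- c(msg, "glucoseMultiplier must be one of 0, 0.5, 1, 2, 3")
  if (object@phosphateDose < 0 || object@copepodClearance < 0 ||
      object@durationDays < 0)
    msg <- c(msg, "rates and duration must be non-negative")
  if (!is.na(object@psi) && object@psi < 0)
    msg <- c(msg, "psi must be non-negative (or NA to defer to parameters)")
  if (any(object@doseTimes < 0))
    msg <- c(msg, "doseTimes must be non-negative")
  if (!(object@dosing %in% c("impulse", "continuous")))
    msg <- c(msg, "dosing must be 'impulse' or 'continuous'")
  if (length(msg)) msg else TRUE
})

#' Construct a ForcingSchedule
#'
#' @param glucoseMultiplier Redfield-C multiple of the glucose gradient
#'   (0, 0.5, 1, 2 or 3).
#' @param phosphateDose phosphate per dosing event (nmol-P/L); the glucose
#'   dose is `glucoseMultiplier * 106 * phosphateDose` nmol-C/L.
#' @param psi continuous labile-DOC supply (nmol-C/L/h), or `NA` to use the
#'   value in the parameter object.
#' @param copepodClearance specific ciliate loss rate (1/h).
#' @param durationDays duration in days.
#' @param doseTimes dosing times in hours; default one dose per day starting
#'   at t = 0.  Use `numeric(0)` for a closed (unforced) system.
#' @param dosing `"impulse"` (default) or `"continuous"`; in continuous mode
#'   `phosphateDose` per day is applied as a constant rate
#'   `phosphateDose/24` per hour (and likewise for glucose).
#' @return a validated [ForcingSchedule-class] object.
#' @export
forcingSchedule <- function(glucoseMultiplier = 0, phosphateDose = 100,
                            psi = NA_real_, copepodClearance = 0,
                            durationDays = 12, doseTimes = NULL,
                            dosing = c("impulse", "continuous")) {
  dosing <- match.arg(dosing)
  if (is.null(doseTimes))
    doseTimes <- if (durationDays >= 1) seq(0, (durationDays - 1) * 24, by = 24)
                 else numeric(0)
  new("ForcingSchedule", phosphateDose = phosphateDose,
      glucoseMultiplier = glucoseMultiplier, psi = as.numeric(psi),
      copepodClearance = copepodClearance, durationDays = durationDays,
      doseTimes = as.numeric(doseTimes), dosing = dosing)
}

setMethod("show", "ForcingSchedule", function(object) {
  cat(sprintf("ForcingSchedule: %g x Redfield glucose, %g nmol-P/L per dose (%d doses), psi=%s, copepod clearance %g/h, %g days\n",
              object@glucoseMultiplier, object@phosphateDose,
              length(object@doseTimes),
              ifelse(is.na(object@psi), "from params", format(object@psi)),
              object@copepodClearance, object@durationDays))
  invisible(NULL)
})

stateVars <- c("P", "D", "A", "B", "H", "C", "S")

#' Assemble and validate a food-web state vector
#'
#' State components, all in nmol-P/L except the labile-DOC pool `D`
#' (nmol-C/L): free phosphate `P`, DOC `D`, autotrophic flagellates `A`,
#' heterotrophic prokaryotes `B`, heterotrophic nanoflagellates `H`,
#' ciliates `C`, and a sink pool `S` that accumulates yield losses and
#' copepod harvest so that total phosphorus is conserved in a closed run.
#'
#' @param P,D,A,B,H,C,S non-negative pool sizes.
#' @return a named numeric vector.
#' @export
foodWebState <- function(P = 0, D = 0, A = 0, B = 0, H = 0, C = 0, S = 0) {
  y <- c(P = P, D = D, A = A, B = B, H = H, C = C, S = S)
  if (any(!is.finite(y)) || any(y < 0))
    stop("all state components must be finite and non-negative")
  y
}

## The one place where every invented closure term lives (bilinear type-I
## grazing, Liebig minimum of P- and C-limited prokaryote growth, copepods
## as fixed specific loss, yield losses routed to the sink pool S).
pentagonRates <- function(y, params, psi, copepodClearance, alphaD, yieldC,
                          clampCiliates, pSupply = 0, dSupply = 0,
                          muMax = 0.06) {
  y <- pmax(y, 0)
  P <- y[["P"]]; D <- y[["D"]]; A <- y[["A"]]
  B <- y[["B"]]; H <- y[["H"]]; C <- y[["C"]]
  aB <- alphaB(params); aA <- alphaA(params)
  aH <- alphaH(params); aC <- alphaC(params)
  yH <- yieldH(params); yBC <- yieldBC(params)
  mu <- min(aB * P, yBC * alphaD * D, muMax)   # Liebig minimum, 1/h
  bcdRate <- mu * B / yBC                # realized carbon consumption
  dP <- pSupply - aA * P * A - mu * B
  dD <- psi + dSupply - bcdRate
  dA <- aA * P * A - aC * A * C
  dB <- mu * B - aH * B * H
  dH <- yH * aH * B * H - aC * H * C
  dC <- if (clampCiliates) 0 else yieldC * aC * (A + H) * C - copepodClearance * C
  dS <- (1 - yH) * aH * B * H + (1 - yieldC) * aC * (A + H) * C +
    (if (clampCiliates) 0 else copepodClearance * C)
  list(deriv = c(P = dP, D = dD, A = dA, B = dB, H = dH, C = dC, S = dS),
       mu = mu, bcdRate = bcdRate)
}

#' Instantaneous rates of change of the pentagon food web
#'
#' The Lotka-Volterra reconstruction uses bilinear (type-I) functional
#' responses throughout, so that the nanoflagellate and autotroph balances
#' vanish exactly at the closed-form steady states: `dH/dt = 0` when
#' `B = alphaC*C/(yieldH*alphaH)` and `dA/dt = 0` when
#' `P = (alphaC/alphaA)*C`.  Prokaryote growth is the Liebig minimum of the
#' phosphate-limited rate `alphaB*P` and the carbon-limited rate
#' `yieldBC*alphaD*D`.  Dosing is impulsive and therefore does not appear
#' here; only the continuous DOC supply `psi` does.
#'
#' @param state named state vector from [foodWebState()].
#' @param params a [FoodWebParameters-class] object.
#' @param forcing a [ForcingSchedule-class] object (only `psi` and
#'   `copepodClearance` act on the continuous dynamics).
#' @param t time (hours); unused by the autonomous closure but kept in the
#'   signature for solver compatibility.
#' @param alphaD prokaryote clearance rate for labile DOC
#'   (L/nmol-P-biomass/h per nmol-C/L).
#' @param yieldC ciliate yield on flagellate prey; defaults to `yieldH`.
#' @param muMax maximum prokaryote growth rate (1/h); the third entry of
#'   the Liebig minimum, relevant only during nutrient-pulse transients.
#' @param clampCiliates hold ciliate biomass fixed (boundary condition for
#'   steady-state experiments).
#' @return named vector of derivatives with attributes `mu` (realised
#'   prokaryote growth rate, 1/h) and `bcdRate` (realised carbon
#'   consumption, nmol-C/L/h).
#' @export
foodWebDerivatives <- function(state, params, forcing = forcingSchedule(),
                               t = 0, alphaD = 2e-4, yieldC = NULL,
                               muMax = 0.06, clampCiliates = FALSE) {
  stopifnot(is(params, "FoodWebParameters"), is(forcing, "ForcingSchedule"))
  if (any(!is.finite(state)) || any(state < 0))
    stop("state components must be finite and non-negative")
  state <- state[stateVars[stateVars %in% names(state)]]
  y <- foodWebState()
  y[names(state)] <- state
  psi <- if (is.na(forcing@psi)) docSupply(params) else forcing@psi
  if (is.null(yieldC)) yieldC <- yieldH(params)
  cont <- forcing@dosing == "continuous"
  r <- pentagonRates(y, params, psi, forcing@copepodClearance, alphaD,
                     yieldC, clampCiliates,
                     pSupply = if (cont) forcing@phosphateDose / 24 else 0,
                     dSupply = if (cont) forcing@glucoseMultiplier * 106 *
                       forcing@phosphateDose / 24 else 0,
                     muMax = muMax)
  structure(r$deriv, mu = r$mu, bcdRate = r$bcdRate)
}

#' Integrate the pentagon food web through time
#'
#' Wraps a stiff-capable solver (deSolve) around [foodWebDerivatives()],
#' applying the forcing schedule's phosphate and glucose additions as
#' impulsive events (glucose dose per event =
#' `glucoseMultiplier * 106 * phosphateDose` nmol-C/L).  Tiny negative
#' excursions (below `1e-8` of the state scale) are clipped to zero;
#' anything larger is reported as a solver failure.
#'
#' @param initial named state vector from [foodWebState()].
#' @param params a [FoodWebParameters-class] object.
#' @param forcing a [ForcingSchedule-class] object.
#' @param tGrid strictly increasing vector of output times (hours); default
#'   hourly over the forcing duration.
#' @param closed if `TRUE`, ignore the dosing events and the continuous DOC
#'   supply (conservation experiments).
#' @param method solver passed to [deSolve::ode()].
#' @inheritParams foodWebDerivatives
#' @param ... further solver options for [deSolve::ode()].
#' @return a `data.frame` with columns `time_h`, the seven state pools, and
#'   the realised `mu` (1/h) and `bcdRate` (nmol-C/L/h).
#' @examples
#' p <- foodWebParameters(yieldBC = 0.006, psi = 4.63)
#' y0 <- equilibriumState(5, p)
#' tr <- simulateFoodWeb(y0, p, forcingSchedule(durationDays = 2),
#'                       clampCiliates = TRUE)
#' head(tr)
#' @export
simulateFoodWeb <- function(initial, params, forcing = forcingSchedule(),
                            tGrid = NULL, alphaD = 2e-4, yieldC = NULL,
                            muMax = 0.06, clampCiliates = FALSE,
                            closed = FALSE, method = "lsoda", ...) {
  stopifnot(is(params, "FoodWebParameters"), is(forcing, "ForcingSchedule"))
  y0 <- foodWebState()
  bad <- setdiff(names(initial), stateVars)
  if (length(bad)) stop("unknown state component(s): ", paste(bad, collapse = ", "))
  y0[names(initial)] <- initial
  if (any(!is.finite(y0)) || any(y0 < 0))
    stop("initial state must be finite and non-negative")
  if (is.null(tGrid)) tGrid <- seq(0, forcing@durationDays * 24, by = 1)
  if (length(tGrid) < 2 || any(diff(tGrid) <= 0))
    stop("'tGrid' must be strictly increasing with at least two points")
  psi <- if (closed) 0 else if (is.na(forcing@psi)) docSupply(params) else forcing@psi
  if (is.null(yieldC)) yieldC <- yieldH(params)
  cont <- !closed && forcing@dosing == "continuous"
  pSupply <- if (cont) forcing@phosphateDose / 24 else 0
  dSupply <- if (cont) forcing@glucoseMultiplier * 106 *
    forcing@phosphateDose / 24 else 0

  rhs <- function(t, y, parms) {
    list(pentagonRates(y, params, psi, forcing@copepodClearance, alphaD,
                       yieldC, clampCiliates, pSupply, dSupply, muMax)$deriv)
  }

  events <- NULL
  doseTimes <- forcing@doseTimes
  doseTimes <- doseTimes[doseTimes > min(tGrid) & doseTimes <= max(tGrid)]
  if (!closed && !cont && length(doseTimes) && forcing@phosphateDose > 0) {
    glucoseDose <- forcing@glucoseMultiplier * 106 * forcing@phosphateDose
    ev <- rbind(
      data.frame(var = "P", time = doseTimes, value = forcing@phosphateDose,
                 method = "add"),
      if (glucoseDose > 0)
        data.frame(var = "D", time = doseTimes, value = glucoseDose,
                   method = "add"))
    events <- list(data = ev[order(ev$time), ])
    tGrid <- sort(unique(c(tGrid, doseTimes)))
  }

  sol <- try(deSolve::ode(y = y0, times = tGrid, func = rhs, parms = NULL,
                          method = method, events = events, ...),
             silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("ODE integration failed: ", attr(sol, "condition")$message)
  diag <- attr(sol, "istate")
  sol <- as.data.frame(unclass(sol))
  names(sol)[1] <- "time_h"
  scale <- max(abs(as.matrix(sol[stateVars])), 1)
  if (any(as.matrix(sol[stateVars]) < -1e-8 * scale))
    stop("ODE integration produced substantially negative states; ",
         "try a smaller hmax or a stiff method (diagnostics: istate = ",
         diag[1], ")")
  sol[stateVars] <- pmax(as.matrix(sol[stateVars]), 0)
  extra <- t(vapply(seq_len(nrow(sol)), function(i) {
    r <- pentagonRates(unlist(sol[i, stateVars]), params, psi,
                       forcing@copepodClearance, alphaD, yieldC,
                       clampCiliates, muMax = muMax)
    c(mu = r$mu, bcdRate = r$bcdRate)
  }, numeric(2)))
  cbind(sol, extra)
}

#' Closed-form equilibrium state for a clamped ciliate biomass
#'
#' Convenience constructor of an initial condition consistent with the
#' steady-state relations: `B` and `P` from the closed forms, `H` from the
#' prokaryote balance (`H = mu/alphaH`), and `A` a standing autotroph stock.
#' The labile-DOC pool depends on the regime: under organic-carbon
#' limitation it sits at the level where supply balances capped consumption
#' (`psi/(alphaD*B)`); under mineral-nutrient limitation DOC has no finite
#' equilibrium (supply exceeds demand, the pool accumulates), so it is set
#' to an organic-C-replete level at which the carbon branch of the Liebig
#' minimum is comfortably above `muMax`.
#'
#' @param C ciliate biomass (nmol-P/L).
#' @param params a [FoodWebParameters-class] object.
#' @param alphaD DOC clearance rate used by the simulator.
#' @param muMax maximum prokaryote growth rate used by the simulator (1/h).
#' @param A autotroph biomass; defaults to a standing stock of 10 nmol-P/L.
#' @return a named state vector (see [foodWebState()]).
#' @export
equilibriumState <- function(C, params, alphaD = 2e-4, muMax = 0.06, A = 10) {
  stopifnot(is(params, "FoodWebParameters"))
  checkCiliate(C)
  B <- prokaryoteBiomass(C, params)
  P <- freePhosphate(C, params)
  demand <- bcd(C, params)               # realised consumption at steady state
  D <- if (B == 0) {
    0
  } else if (classifyRegime(C, params) == "OCL") {
    demand / (alphaD * B)                # dD/dt = 0 under carbon limitation
  } else {
    1.5 * muMax / (yieldBC(params) * alphaD)  # accumulated, organic-C replete
  }
  muRealised <- if (B > 0) demand * yieldBC(params) / B else 0
  H <- muRealised / alphaH(params)
  foodWebState(P = P, D = D, A = A, B = B, H = H, C = C)
}

#' Continuous phosphate supply that sustains a clamped steady state
#'
#' At the clamped-ciliate equilibrium the phosphate pool is drained by
#' autotroph uptake (`alphaA * P* * A`) and prokaryote growth
#' (`mu* * B*`); this returns the matching continuous supply in
#' nmol-P/L/day for use as `phosphateDose` with `dosing = "continuous"`.
#'
#' @inheritParams equilibriumState
#' @return phosphate supply rate (nmol-P/L/day).
#' @export
equilibriumPhosphateSupply <- function(C, params, alphaD = 2e-4, A = 10) {
  stopifnot(is(params, "FoodWebParameters"))
  checkCiliate(C)
  B <- prokaryoteBiomass(C, params)
  P <- freePhosphate(C, params)
  muRealised <- if (B > 0) bcd(C, params) * yieldBC(params) / B else 0
  24 * (alphaA(params) * P * A + muRealised * B)
}

#' Residuals of the closed-form steady states along a trajectory
#'
#' Evaluates, over the late-time window of a simulated trajectory, how far
#' the prokaryote biomass, free phosphate and phosphate-limited growth rate
#' are from their closed-form values at the concurrent ciliate biomass.
#' Residuals are relative; a state that is exactly zero on both sides
#' counts as residual zero (degenerate equilibrium).
#'
#' @param trajectory output of [simulateFoodWeb()].
#' @param params a [FoodWebParameters-class] object.
#' @param tol pass/fail threshold on the maximum relative residual.
#' @param window fraction of the trajectory (from the end) to evaluate.
#' @return a `data.frame` with one row per relation (`B`, `P`, `mu`) giving
#'   maximum and mean relative residuals and a `pass` flag.
#' @export
steadyStateCheck <- function(trajectory, params, tol = 1e-3, window = 0.1) {
  stopifnot(is(params, "FoodWebParameters"))
  need <- c("time_h", "P", "B", "C", "mu")
  if (!all(need %in% names(trajectory)))
    stop("trajectory must contain columns: ", paste(need, collapse = ", "))
  n <- nrow(trajectory)
  idx <- which(trajectory$time_h >=
                 max(trajectory$time_h) - window * diff(range(trajectory$time_h)))
  if (n < 3 || length(idx) < 2)
    stop("trajectory too short to evaluate a late-time window")
  w <- trajectory[idx, ]
  relres <- function(obs, ref) {
    r <- abs(obs - ref) / pmax(abs(ref), .Machine$double.xmin)
    r[obs == 0 & ref == 0] <- 0
    r
  }
  ## The growth-rate closed form mu = alphaB*P applies under MNL; where
  ## carbon limitation binds, the regime-consistent expectation is
  ## bcd * yieldBC / B (production over standing stock at capped demand).
  muRef <- ifelse(classifyRegime(w$C, params) == "MNL",
                  prokaryoteGrowthRate(w$C, params),
                  ifelse(w$B > 0,
                         bcd(w$C, params) * yieldBC(params) /
                           prokaryoteBiomass(w$C, params), 0))
  res <- rbind(
    B = relres(w$B, prokaryoteBiomass(w$C, params)),
    P = relres(w$P, freePhosphate(w$C, params)),
    mu = relres(w$mu, muRef))
  out <- data.frame(equation = rownames(res),
                    maxRelResidual = apply(res, 1, max),
                    meanRelResidual = rowMeans(res))
  out$pass <- out$maxRelResidual < tol
  rownames(out) <- NULL
  out
}
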