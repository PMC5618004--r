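#' @include dynamicSimulator.R
#' @include BandMatrix.R
NULL

#' ExperimentDesign: layout of a glucose-gradient mesocosm experiment
#'
#' @slot tanks `data.frame` with columns `tank_id`, `glucose_x` (Redfield-C
#'   multiple), `silicate` (logical), `nitrogen_source` ("NH4" or "NO3").
#' @slot volumeL tank volume (L).
#' @slot durationDays experiment duration (days).
#' @slot samplingDays days on which samples are taken.
#' @export
setClass("ExperimentDesign",
  representation(tanks = "data.frame", volumeL = "numeric",
                 durationDays = "numeric", samplingDays = "numeric"))

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  need <- c("tank_id", "glucose_x", "silicate", "nitrogen_source")
  if (!all(need %in% names(object@tanks)))
    return(paste("tanks must have columns:", paste(need, collapse = ", ")))
  if (!all(object@tanks$glucose_x %in% designMultipliers))
    msg <- c(msg, "glucose_x must be drawn from 0, 0.5, 1, 2, 3")
  if (anyDuplicated(object@tanks$tank_id))
    msg <- c(msg, "tank ids must be unique")
  if (!all(object@tanks$nitrogen_source %in% c("NH4", "NO3")))
    msg <- c(msg, "nitrogen_source must be 'NH4' or 'NO3'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf("ExperimentDesign: %d tanks of %g L, %g days, %d sampling days\n",
              nrow(object@tanks), object@volumeL, object@durationDays,
              length(object@samplingDays)))
  print(object@tanks, row.names = FALSE)
  invisible(NULL)
})

#' Tank layout of the two standard enrichment experiments
#'
#' `"PAME-I"`: eight 700-L units forming two four-point glucose gradients
#' (0, 0.5, 1, 3 x Redfield-C), one gradient with silicate addition, ammonium
#' as nitrogen source throughout.  `"PAME-II"`: nine 900-L units, a
#' five-point gradient (0, 0.5, 1, 2, 3) on ammonium and a four-point
#' gradient (0, 0.5, 1, 3) on nitrate, all silicate-replete.  Sampling days
#' 0 through 12.
#'
#' @param experiment `"PAME-I"` or `"PAME-II"`.
#' @return an [ExperimentDesign-class] object.
#' @examples
#' generateDesign("PAME-I")
#' @export
generateDesign <- function(experiment = c("PAME-I", "PAME-II")) {
  experiment <- match.arg(experiment)
  if (experiment == "PAME-I") {
    tanks <- data.frame(
      tank_id = sprintf("T%d", 1:8),
      glucose_x = rep(c(0, 0.5, 1, 3), 2),
      silicate = rep(c(FALSE, TRUE), each = 4),
      nitrogen_source = "NH4")
    vol <- 700
  } else {
    tanks <- data.frame(
      tank_id = sprintf("T%d", 1:9),
      glucose_x = c(0, 0.5, 1, 2, 3, 0, 0.5, 1, 3),
      silicate = TRUE,
      nitrogen_source = rep(c("NH4", "NO3"), c(5, 4)))
    vol <- 900
  }
  new("ExperimentDesign", tanks = tanks, volumeL = vol, durationDays = 12,
      samplingDays = 0:12)
}

## cells/mL <-> nmol-P/L conversion factors for the counted populations.
## Prokaryote: ~10 fg C/cell over molar C:P ~50; HNF: 3-um flagellate at the
## same volumetric carbon density as ciliates.
cellConversions <- function(params) {
  pgC2nmolP <- function(pgC, cp) pgC * 1e-12 / 12.011 / cp * 1e9
  c(prokaryotes = pgC2nmolP(0.010, 50),            # nmol-P per cell
    hnf = pgC2nmolP(pi / 6 * 3^3 * 0.13, 106),
    ciliates = sigmaCiliate(params))
}

#' Simulate FCM-like abundance time series for a tank design
#'
#' Runs the pentagon food-web simulator for every tank of a design under a
#' clamped low- or high-ciliate boundary condition (the trophic-cascade
#' states that put prokaryotes under mineral-nutrient vs organic-carbon
#' limitation), converts biomasses to cell counts, attaches flow-cytometry
#' style virus group counts (I-IV) and applies multiplicative lognormal
#' observation noise.
#'
#' Virus counts are a documented synthetic stand-in (the dynamic model has
#' no lysis term): group I tracks prokaryote counts through a
#' virus-to-prokaryote ratio that rises linearly with ciliate abundance
#' from a baseline of 10, and groups II-IV are fixed fractions of group I.
#'
#' @param design an [ExperimentDesign-class] object.
#' @param params a [FoodWebParameters-class] object.
#' @param ciliateRegime `"low"` (MNL side of the crossover) or `"high"`
#'   (OCL side).  The clamped biomass is 0.4 x or 2.5 x the crossover
#'   ciliate biomass respectively.
#' @param noiseCv coefficient of variation of the lognormal observation
#'   noise (0 for noise-free output).
#' @param seed optional integer seed; output is bit-reproducible given the
#'   seed.
#' @param alphaD DOC clearance rate passed to the simulator.
#' @param muMax maximum prokaryote growth rate passed to the simulator.
#' @param vprCiliateSlope increase of the virus-to-prokaryote ratio per
#'   ciliate cell/mL above the initial abundance.
#' @return a tidy `data.frame` with columns `tank_id`, `day`, `time_h`,
#'   `variable`, `value`, `unit`.
#' @export
simulateExperiment <- function(design, params,
                               ciliateRegime = c("low", "high"),
                               noiseCv = 0.1, seed = NULL, alphaD = 2e-4,
                               muMax = 0.06, vprCiliateSlope = 2) {
  stopifnot(is(design, "ExperimentDesign"), is(params, "FoodWebParameters"))
  ciliateRegime <- match.arg(ciliateRegime)
  if (noiseCv < 0) stop("'noiseCv' must be non-negative")
  Cstar <- crossoverCiliateDensity(params)
  Cclamp <- if (ciliateRegime == "low") 0.4 * Cstar else 2.5 * Cstar
  conv <- cellConversions(params)
  sdlog <- sqrt(log(1 + noiseCv^2))

  withSeed(seed, {
    rows <- lapply(seq_len(nrow(design@tanks)), function(i) {
      tank <- design@tanks[i, ]
      forcing <- forcingSchedule(glucoseMultiplier = tank$glucose_x,
                                 durationDays = design@durationDays)
      y0 <- equilibriumState(Cclamp, params, alphaD = alphaD, muMax = muMax)
      tr <- simulateFoodWeb(y0, params, forcing,
                            tGrid = seq(0, design@durationDays * 24, by = 2),
                            alphaD = alphaD, muMax = muMax,
                            clampCiliates = TRUE)
      keep <- tr[tr$time_h %in% (design@samplingDays * 24), ]
      counts <- data.frame(
        prokaryotes = keep$B / conv[["prokaryotes"]] / 1000,   # cells/mL
        hnf = keep$H / conv[["hnf"]] / 1000,
        ciliates = keep$C / conv[["ciliates"]] / 1000)
      vprSeries <- 10 + vprCiliateSlope *
        (counts$ciliates - counts$ciliates[1])
      counts$virus_I <- vprSeries * counts$prokaryotes
      counts$virus_II <- 0.30 * counts$virus_I
      counts$virus_III <- 0.10 * counts$virus_I
      counts$virus_IV <- 0.02 * counts$virus_I
      if (noiseCv > 0) {
        noise <- matrix(stats::rlnorm(nrow(counts) * ncol(counts),
                                      -sdlog^2 / 2, sdlog),
                        nrow(counts))
        counts <- counts * noise
      }
      data.frame(tank_id = tank$tank_id,
                 day = rep(keep$time_h / 24, ncol(counts)),
                 time_h = rep(keep$time_h, ncol(counts)),
                 variable = rep(names(counts), each = nrow(counts)),
                 value = unlist(counts, use.names = FALSE),
                 unit = "cells/mL")
    })
    do.call(rbind, rows)
  })
}

#' CouplingSpec: parameters of the synthetic fingerprint generator
#'
#' @slot nSamples number of samples (gel lanes).
#' @slot nBandsHost,nBandsVirus numbers of host (DGGE) and virus (PFGE)
#'   bands.
#' @slot baseProb baseline band presence probability.
#' @slot treatmentEffect additive shift of the presence probability of the
#'   responding half of the host bands in glucose-amended samples.
#' @slot coupling probability that a virus band mirrors its mapped host
#'   band rather than varying independently, in [0, 1].
#' @slot flipRate per-cell bit-flip noise applied to the virus matrix.
#' @slot seed default seed carried by the object (NA for none).
#' @export
setClass("CouplingSpec",
  representation(nSamples = "integer", nBandsHost = "integer",
                 nBandsVirus = "integer", baseProb = "numeric",
                 treatmentEffect = "numeric", coupling = "numeric",
                 flipRate = "numeric", seed = "integer"))

setValidity("CouplingSpec", function(object) {
  msg <- character()
  if (object@nSamples < 2) msg <- c(msg, "need at least 2 samples")
  if (object@nBandsHost < 1 || object@nBandsVirus < 1)
    msg <- c(msg, "need at least one band per matrix")
  probs <- c(object@baseProb, object@coupling, object@flipRate)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "baseProb, coupling and flipRate must lie in [0, 1]")
  if (object@baseProb + abs(object@treatmentEffect) > 1 ||
      object@baseProb - abs(object@treatmentEffect) < 0)
    msg <- c(msg, "treatmentEffect must keep probabilities in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a CouplingSpec
#'
#' Defaults mirror the observed scale of the gel data: ~30 host bands,
#' ~20 virus bands, base presence probability 0.5.
#'
#' @param nSamples number of samples.
#' @param nBandsHost,nBandsVirus band counts.
#' @param baseProb baseline presence probability.
#' @param treatmentEffect probability shift for responding bands in treated
#'   samples.
#' @param coupling host-to-virus dependence strength in [0, 1].
#' @param flipRate bit-flip noise on the virus matrix.
#' @param seed optional default seed.
#' @return a validated [CouplingSpec-class] object.
#' @export
couplingSpec <- function(nSamples = 12, nBandsHost = 30, nBandsVirus = 20,
                         baseProb = 0.5, treatmentEffect = 0,
                         coupling = 0, flipRate = 0, seed = NA) {
  new("CouplingSpec", nSamples = as.integer(nSamples),
      nBandsHost = as.integer(nBandsHost),
      nBandsVirus = as.integer(nBandsVirus), baseProb = baseProb,
      treatmentEffect = treatmentEffect, coupling = coupling,
      flipRate = flipRate, seed = as.integer(seed))
}

resampleCap <- 100L

#' Generate paired host and virus fingerprint matrices
#'
#' Synthetic stand-in for DGGE (host) and PFGE (virus) band patterns.
#' Host bands are independent Bernoulli draws; in samples from
#' glucose-amended tanks (`glucose_x > 0`) the presence probability of the
#' first half of the bands is shifted by `treatmentEffect`.  Each virus
#' band either mirrors its mapped host band (with probability `coupling`;
#' the map is identity modulo the host band count) or is an independent
#' draw, after which `flipRate` bit-flip noise is applied.  Samples that
#' would come out empty are redrawn up to 100 times.
#'
#' Samples are (tank, day) combinations of the fingerprinted treatment
#' levels (glucose 0x and 3x), days spread evenly over the design's
#' sampling days.
#'
#' @param spec a [CouplingSpec-class] object.
#' @param design an [ExperimentDesign-class] object.
#' @param seed optional integer seed (overrides the one in `spec`).
#' @return a list with elements `host` and `virus`, both
#'   [BandMatrix-class] objects on identical samples.
#' @export
generateBandMatrices <- function(spec, design = generateDesign("PAME-I"),
                                 seed = NULL) {
  stopifnot(is(spec, "CouplingSpec"), is(design, "ExperimentDesign"))
  if (is.null(seed) && !is.na(spec@seed)) seed <- spec@seed
  tanks <- design@tanks[design@tanks$glucose_x %in% c(0, 3), ]
  if (!nrow(tanks)) tanks <- design@tanks
  nPerTank <- ceiling(spec@nSamples / nrow(tanks))
  days <- design@samplingDays[
    round(seq(1, length(design@samplingDays), length.out = nPerTank))]
  grid <- expand.grid(day = days, tank = seq_len(nrow(tanks)))[
    seq_len(spec@nSamples), ]
  meta <- S4Vectors::DataFrame(
    day = as.integer(grid$day),
    glucose_x = tanks$glucose_x[grid$tank],
    silicate = tanks$silicate[grid$tank],
    nitrogen_source = tanks$nitrogen_source[grid$tank],
    row.names = sprintf("%s_d%02d", tanks$tank_id[grid$tank], grid$day))

  n <- spec@nSamples
  treated <- meta$glucose_x > 0
  respond <- seq_len(spec@nBandsHost) <= spec@nBandsHost / 2
  pHost <- matrix(spec@baseProb, n, spec@nBandsHost)
  pHost[treated, respond] <- pmin(pmax(
    spec@baseProb + spec@treatmentEffect, 0), 1)

  withSeed(seed, {
    drawRow <- function(p) stats::rbinom(length(p), 1, p)
    drawNonEmpty <- function(p, what, i) {
      for (try in seq_len(resampleCap)) {
        row <- drawRow(p)
        if (sum(row) > 0) return(row)
      }
      stop("could not draw a non-empty ", what, " fingerprint for sample ",
           i, " within ", resampleCap, " attempts; the generator settings are infeasible")
    }
    host <- t(vapply(seq_len(n),
                     function(i) drawNonEmpty(pHost[i, ], "host", i),
                     integer(spec@nBandsHost)))
    bandMap <- ((seq_len(spec@nBandsVirus) - 1L) %% spec@nBandsHost) + 1L
    mirrored <- stats::runif(spec@nBandsVirus) < spec@coupling
    virusFor <- function(i) {
      for (try in seq_len(resampleCap)) {
        row <- ifelse(mirrored, host[i, bandMap],
                      drawRow(rep(spec@baseProb, spec@nBandsVirus)))
        if (spec@flipRate > 0) {
          flips <- drawRow(rep(spec@flipRate, spec@nBandsVirus))
          row <- as.integer(xor(row, flips))
        }
        if (sum(row) > 0) return(row)
      }
      stop("could not draw a non-empty virus fingerprint for sample ", i,
           " within ", resampleCap, " attempts; the generator settings are infeasible ",
           "(flipRate/coupling force empty rows)")
    }
    virus <- t(vapply(seq_len(n), virusFor, integer(spec@nBandsVirus)))
    rownames(host) <- rownames(virus) <- rownames(meta)
    colnames(host) <- sprintf("hband%03d", seq_len(spec@nBandsHost))
    colnames(virus) <- sprintf("vband%03d", seq_len(spec@nBandsVirus))
    list(host = bandMatrix(host, meta), virus = bandMatrix(virus, meta))
  })
}
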