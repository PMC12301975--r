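#' @import methods
#' @importFrom stats setNames
NULL

GENOTYPES <- c("WT", "SIRT2KO", "SOD1KO", "DKO")

#' Simulation configuration
#'
#' Holds every parameter of the synthetic cohort / expression generator.
#' Lesion onset follows a constant (exponential) hazard per genotype; the
#' double-knockout hazard is \code{interactionMultiplier} times the
#' Bliss-independent baseline \code{lambda_SIRT2KO + lambda_SOD1KO}, so a
#' multiplier of 1 encodes exact Bliss independence at every horizon.
#' Censoring is independent exponential plus administrative censoring at
#' \code{followupDays}.
#'
#' @slot nPerGenotype named integer vector (WT, SIRT2KO, SOD1KO, DKO),
#'   subjects per genotype.
#' @slot lesionHazard named numeric vector of per-day lesion-onset hazards
#'   for WT, SIRT2KO and SOD1KO (the DKO hazard is derived).
#' @slot interactionMultiplier nonnegative scalar scaling the DKO hazard
#'   relative to the Bliss-independent baseline (1 = no interaction).
#' @slot followupDays administrative censoring horizon in days.
#' @slot censorHazard per-day hazard of independent loss to follow-up.
#' @slot nGenes number of genes in simulated expression data.
#' @slot fracUp,fracDown fractions of genes planted up-/down-regulated.
#' @slot effectLog2fc planted absolute log2 fold change (> 0).
#' @slot lengthShift log-scale shortening of planted up-regulated
#'   transcript lengths (positive = up genes shorter).
#' @slot noiseSd standard error scale of the simulated log2FC estimates.
#' @slot nPerGroup samples per group for count simulation.
#' @slot dispersion negative-binomial dispersion (1/size) for counts.
#' @slot seed integer master seed; all operations split deterministic
#'   sub-streams from it.
#' @export
setClass("SimulationConfig",
  representation(
    nPerGenotype = "integer",
    lesionHazard = "numeric",
    interactionMultiplier = "numeric",
    followupDays = "integer",
    censorHazard = "numeric",
    nGenes = "integer",
    fracUp = "numeric",
    fracDown = "numeric",
    effectLog2fc = "numeric",
    lengthShift = "numeric",
    noiseSd = "numeric",
    nPerGroup = "integer",
    dispersion = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!identical(sort(names(object@nPerGenotype)), sort(GENOTYPES)))
    msg <- c(msg, "nPerGenotype must be named WT, SIRT2KO, SOD1KO, DKO")
  if (any(object@nPerGenotype < 1L))
    msg <- c(msg, "cohort sizes must be positive")
  if (!all(c("WT", "SIRT2KO", "SOD1KO") %in% names(object@lesionHazard)))
    msg <- c(msg, "lesionHazard must name WT, SIRT2KO and SOD1KO")
  if (any(object@lesionHazard < 0))
    msg <- c(msg, "hazards must be nonnegative")
  if (object@interactionMultiplier < 0)
    msg <- c(msg, "interactionMultiplier must be nonnegative")
  if (object@followupDays < 1L)
    msg <- c(msg, "followupDays must be positive")
  if (object@censorHazard < 0)
    msg <- c(msg, "censorHazard must be nonnegative")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@fracUp < 0 || object@fracDown < 0 ||
      object@fracUp + object@fracDown > 1)
    msg <- c(msg, "fracUp and fracDown must be in [0,1] with sum <= 1")
  if (object@effectLog2fc <= 0)
    msg <- c(msg, "effectLog2fc must be > 0")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (object@nPerGroup < 2L)
    msg <- c(msg, "nPerGroup must be at least 2")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (length(msg)) msg else TRUE
})

#' Kaplan-Meier curve
#'
#' Product-limit estimate of a survival function: event times, survival
#' probability after each time, the size of the risk set and event /
#' censoring counts at each time.
#'
#' @slot time ordered unique observed times (days).
#' @slot surv survival probability just after each time; nonincreasing.
#' @slot nRisk number at risk just before each time.
#' @slot nEvent events at each time.
#' @slot nCensor censorings at each time.
#' @slot n total subjects.
#' @export
setClass("KMCurve",
  representation(time = "numeric", surv = "numeric", nRisk = "numeric",
                 nEvent = "numeric", nCensor = "numeric", n = "integer")
)

setValidity("KMCurve", function(object) {
  k <- length(object@time)
  msg <- character()
  if (any(lengths(list(object@surv, object@nRisk, object@nEvent,
                       object@nCensor)) != k))
    msg <- c(msg, "all slots must have one entry per time point")
  if (k && is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (k && any(diff(object@surv) > 1e-12))
    msg <- c(msg, "survival must be nonincreasing")
  if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12))
    msg <- c(msg, "survival probabilities must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Bliss synergy result at one horizon
#'
#' @slot horizon horizon in days.
#' @slot pAB observed double-knockout incidence.
#' @slot pA,pB single-knockout incidences.
#' @slot expected Bliss-expected incidence pA + pB - pA*pB.
#' @slot score synergy score pAB - expected.
#' @slot ciLow,ciHigh 95 percent percentile-bootstrap interval (NA when
#'   not requested).
#' @slot pPerm one-sided resampling p-value toward synergy (NA when not
#'   requested).
#' @slot nBoot,nPerm resample counts used.
#' @slot method incidence estimator used ("crude" or "km").
#' @slot seed seed used for the resampling streams.
#' @export
setClass("SynergyResult",
  representation(horizon = "numeric", pAB = "numeric", pA = "numeric",
                 pB = "numeric", expected = "numeric", score = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pPerm = "numeric",
                 nBoot = "integer", nPerm = "integer", method = "character",
                 seed = "integer")
)

setValidity("SynergyResult", function(object) {
  msg <- character()
  probs <- c(object@pAB, object@pA, object@pB, object@expected)
  if (any(probs < -1e-12 | probs > 1 + 1e-12))
    msg <- c(msg, "incidences must lie in [0,1]")
  if (abs(object@expected -
          (object@pA + object@pB - object@pA * object@pB)) > 1e-12)
    msg <- c(msg, "expected must equal pA + pB - pA*pB")
  if (abs(object@score - (object@pAB - object@expected)) > 1e-12)
    msg <- c(msg, "score must equal pAB - expected")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh + 1e-12)
    msg <- c(msg, "ciLow must not exceed ciHigh")
  if (length(msg)) msg else TRUE
})

#' @describeIn SynergyResult-class compact display
#' @param object a \code{SynergyResult}
#' @export
setMethod("show", "SynergyResult", function(object) {
  cat(sprintf(
    "Bliss synergy at %g days: score %.3f (obs %.1f%%, expected %.1f%%)\n",
    object@horizon, object@score, 100 * object@pAB, 100 * object@expected))
  if (!is.na(object@ciLow))
    cat(sprintf("  95%% bootstrap CI [%.3f, %.3f] (n_boot = %d)\n",
                object@ciLow, object@ciHigh, object@nBoot))
  if (!is.na(object@pPerm))
    cat(sprintf("  one-sided resampling p = %.4g (n_perm = %d)\n",
                object@pPerm, object@nPerm))
  invisible(object)
})

#' @describeIn KMCurve-class compact display
#' @param object a \code{KMCurve}
#' @export
setMethod("show", "KMCurve", function(object) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event times, S(max) = %.3f\n",
              object@n, sum(object@nEvent > 0), min(c(1, object@surv))))
  invisible(object)
})

#' @describeIn SimulationConfig-class compact display
#' @param object a \code{SimulationConfig}
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  cohort: n =", paste(sprintf("%s:%d", names(object@nPerGenotype),
                                     object@nPerGenotype), collapse = ", "),
      "\n")
  cat(sprintf("  hazards/day: %s; interaction x%.3g; follow-up %d d; censor %.2g/d\n",
              paste(sprintf("%s %.3g", names(object@lesionHazard),
                            object@lesionHazard), collapse = ", "),
              object@interactionMultiplier, object@followupDays,
              object@censorHazard))
  cat(sprintf("  expression: %d genes (up %.2g, down %.2g, |log2FC| %.2g, length shift %.2g)\n",
              object@nGenes, object@fracUp, object@fracDown,
              object@effectLog2fc, object@lengthShift))
  cat(sprintf("  seed %d\n", object@seed))
  invisible(object)
})
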