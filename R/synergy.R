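#' Bliss-expected combined incidence
#'
#' Under Bliss independence two perturbations with individual incidences
#' \eqn{p_A} and \eqn{p_B} combine to \eqn{E = p_A + p_B - p_A p_B}: the
#' probability that at least one of two independent events occurs.
#'
#' @param pA,pB incidences in [0, 1] (vectorised).
#' @return expected combined incidence in [0, 1].
#' @examples
#' blissExpected(0.350, 0.045)  # 0.37925, the 38.0 % expected rate
#' @export
blissExpected <- function(pA, pB) {
  checkProb(pA, "pA"); checkProb(pB, "pB")
  pA + pB - pA * pB
}

#' Bliss synergy score
#'
#' Observed double-perturbation incidence minus the Bliss-expected
#' incidence. Positive values indicate synergy, negative antagonism.
#'
#' @param pAB observed double-knockout incidence in [0, 1].
#' @param pA,pB single-knockout incidences in [0, 1].
#' @return score in [-1, 1].
#' @examples
#' synergyScore(0.854, 0.350, 0.045)  # 0.47475, printed as 0.474
#' @export
synergyScore <- function(pAB, pA, pB) {
  checkProb(pAB, "pAB")
  pAB - blissExpected(pA, pB)
}

# Per-genotype 0/1 outcome vectors at horizon t for crude incidence
# bootstrap/permutation machinery: events by t among status-known
# subjects.
.armOutcomes <- function(cohort, genotype, t) {
  sub <- cohort[cohort$genotype == genotype, , drop = FALSE]
  if (nrow(sub) < 2L)
    stop("need at least 2 subjects of genotype ", genotype, call. = FALSE)
  evt <- sub$lesion_event == 1 & sub$lesion_time <= t
  known <- evt | sub$lesion_time >= t
  out <- as.integer(evt[known])
  if (length(out) < 2L)
    stop("fewer than 2 informative subjects of genotype ", genotype,
         " at day ", t, call. = FALSE)
  out
}

#' Point synergy estimate from a cohort
#'
#' Estimates the three incidences at horizon \code{t} with
#' \code{\link{incidenceAt}} and forms the Bliss synergy score
#' (DKO observed minus Bliss-expected from SIRT2KO and SOD1KO).
#'
#' @param cohort cohort \code{data.frame}.
#' @param t horizon in days.
#' @param method incidence estimator, \code{"crude"} or \code{"km"}.
#' @return a \code{\linkS4class{SynergyResult}} without CI / p-value.
#' @export
synergyEstimate <- function(cohort, t, method = c("crude", "km")) {
  method <- match.arg(method)
  inc <- lapply(c("DKO", "SIRT2KO", "SOD1KO"), function(g)
    incidenceAt(cohort, g, t, method))
  pAB <- inc[[1]]$incidence; pA <- inc[[2]]$incidence; pB <- inc[[3]]$incidence
  if (anyNA(c(pAB, pA, pB)))
    stop("incidence undefined for at least one genotype at day ", t,
         call. = FALSE)
  new("SynergyResult", horizon = as.numeric(t), pAB = pAB, pA = pA, pB = pB,
      expected = blissExpected(pA, pB), score = synergyScore(pAB, pA, pB),
      ciLow = NA_real_, ciHigh = NA_real_, pPerm = NA_real_,
      nBoot = 0L, nPerm = 0L, method = method, seed = NA_integer_)
}

#' Percentile bootstrap CI for the synergy score
#'
#' Resamples subjects with replacement within each of the three knockout
#' genotypes, recomputes the synergy score for each resample, and returns
#' the 2.5 / 97.5 percentiles. Deterministic under \code{seed}.
#'
#' @param cohort cohort \code{data.frame}; DKO, SIRT2KO and SOD1KO must
#'   each contribute at least two status-known subjects at \code{t}.
#' @param t horizon in days.
#' @param nBoot number of bootstrap resamples (default 1000; fewer than
#'   100 triggers a warning).
#' @param seed integer seed for the resampling stream.
#' @param level confidence level (default 0.95).
#' @return named numeric \code{c(ciLow, ciHigh)}.
#' @importFrom stats quantile
#' @export
synergyCI <- function(cohort, t, nBoot = 1000L, seed = 1L, level = 0.95) {
  validateCohort(cohort)
  if (nBoot < 100L) warning("nBoot < 100 gives unstable percentiles")
  ab <- .armOutcomes(cohort, "DKO", t)
  a <- .armOutcomes(cohort, "SIRT2KO", t)
  b <- .armOutcomes(cohort, "SOD1KO", t)
  scores <- withSeed(streamSeed(seed, "synergy_boot"), {
    resampMean <- function(x) {
      idx <- sample.int(length(x), length(x) * nBoot, replace = TRUE)
      colMeans(matrix(x[idx], nrow = length(x)))
    }
    synergyScore(resampMean(ab), resampMean(a), resampMean(b))
  })
  q <- unname(quantile(scores, c((1 - level) / 2, 1 - (1 - level) / 2),
                       type = 7))
  c(ciLow = q[1], ciHigh = q[2])
}

#' Resampling p-value for synergy under the Bliss-independence null
#'
#' The null model Bliss independence states is that the DKO incidence
#' equals the expected \eqn{E(p_A, p_B)} of the single knockouts. Each
#' null replicate resamples the two single-KO arms with replacement,
#' forms the resampled expected rate \eqn{E^*}, simulates the DKO arm as
#' independent Bernoulli draws at \eqn{E^*}, and scores the replicate
#' against the observed expected incidence. The p-value is the add-one
#' estimator \eqn{(1 + \#\{S^* \ge S_{obs}\}) / (n_{perm} + 1)},
#' one-sided toward synergy.
#'
#' @param cohort cohort \code{data.frame}.
#' @param t horizon in days.
#' @param nPerm number of null replicates (at least 100).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @importFrom stats rbinom
#' @export
synergyPermutationP <- function(cohort, t, nPerm = 1000L, seed = 1L) {
  validateCohort(cohort)
  if (nPerm < 100L) stop("nPerm must be at least 100", call. = FALSE)
  ab <- .armOutcomes(cohort, "DKO", t)
  a <- .armOutcomes(cohort, "SIRT2KO", t)
  b <- .armOutcomes(cohort, "SOD1KO", t)
  obsE <- blissExpected(mean(a), mean(b))
  obsS <- mean(ab) - obsE
  nullS <- withSeed(streamSeed(seed, "synergy_perm"), {
    pa <- rbinom(nPerm, length(a), mean(a)) / length(a)
    pb <- rbinom(nPerm, length(b), mean(b)) / length(b)
    eStar <- blissExpected(pa, pb)
    pabStar <- rbinom(nPerm, length(ab), eStar) / length(ab)
    pabStar - obsE
  })
  (1 + sum(nullS >= obsS - 1e-12)) / (nPerm + 1)
}

#' Synergy score time-course
#'
#' Runs the full Bliss analysis (point score, bootstrap CI, resampling
#' p-value) at each horizon on the same cohort.
#'
#' @param cohort cohort \code{data.frame}.
#' @param horizons ascending horizons in days, e.g.
#'   \code{c(100, 200, 300, 400)}.
#' @param nBoot,nPerm resample counts; set to 0 to skip the CI or the
#'   p-value.
#' @param seed integer seed (horizon-specific streams are split from it).
#' @param method incidence estimator passed to \code{\link{incidenceAt}}.
#' @return a \code{\link[S4Vectors]{DataFrame}} with one row per horizon:
#'   \code{horizon}, \code{pAB}, \code{pA}, \code{pB}, \code{expected},
#'   \code{score}, \code{ciLow}, \code{ciHigh}, \code{pPerm}.
#' @importFrom S4Vectors DataFrame metadata<-
#' @export
synergyTimecourse <- function(cohort, horizons, nBoot = 1000L,
                              nPerm = 1000L, seed = 1L,
                              method = c("crude", "km")) {
  method <- match.arg(method)
  if (is.unsorted(horizons))
    stop("horizons must be sorted ascending", call. = FALSE)
  rows <- lapply(horizons, function(t) {
    est <- synergyEstimate(cohort, t, method)
    ci <- c(ciLow = NA_real_, ciHigh = NA_real_)
    if (nBoot > 0)
      ci <- synergyCI(cohort, t, nBoot, seed = streamSeed(seed,
                      paste0("h", t)))
    pp <- NA_real_
    if (nPerm > 0)
      pp <- synergyPermutationP(cohort, t, nPerm,
                                seed = streamSeed(seed, paste0("hp", t)))
    DataFrame(horizon = est@horizon, pAB = est@pAB, pA = est@pA,
              pB = est@pB, expected = est@expected, score = est@score,
              ciLow = unname(ci["ciLow"]), ciHigh = unname(ci["ciHigh"]),
              pPerm = pp)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    DataFrame(horizon = numeric(), pAB = numeric(), pA = numeric(),
              pB = numeric(), expected = numeric(), score = numeric(),
              ciLow = numeric(), ciHigh = numeric(), pPerm = numeric())
  metadata(out) <- list(method = method, nBoot = as.integer(nBoot),
                        nPerm = as.integer(nPerm), seed = as.integer(seed))
  out
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-tailed p-value sums all tables with
#' the observed margins whose point probability does not exceed that of
#' the observed table (the probability-mass rule). The odds ratio is the
#' conditional maximum-likelihood estimate, with 0/Inf on zero cells.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#'   (group x outcome).
#' @return list with \code{oddsRatio} and \code{p}.
#' @examples
#' fisherExact2x2(matrix(c(0, 10, 10, 0), 2))  # p = 2 / choose(20, 10)
#' @importFrom stats fisher.test
#' @export
fisherExact2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == 2L))
    stop("table must be a 2x2 matrix", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be nonnegative integers", call. = FALSE)
  if (sum(table) == 0)
    stop("table has all-zero margins", call. = FALSE)
  ft <- fisher.test(table)
  list(oddsRatio = unname(ft$estimate), p = ft$p.value)
}
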