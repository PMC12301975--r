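test_that("Bliss expectation and synergy score reproduce worked values", {
  # printed single-KO incidences give the printed expected rate
  expect_equal(blissExpected(0.350, 0.045), 0.37925, tolerance = 1e-12)
  expect_equal(blissExpected(0, 0), 0)
  expect_equal(blissExpected(1, 0.3), 1)
  expect_equal(blissExpected(1, 0), 1)
  # the 400-day score from the printed incidences
  expect_equal(synergyScore(0.854, 0.350, 0.045), 0.47475,
               tolerance = 1e-12)
  expect_equal(synergyScore(blissExpected(0.2, 0.3), 0.2, 0.3), 0)
  expect_equal(synergyScore(0.5, 0.5, 0.5), -0.25)
  expect_error(blissExpected(1.2, 0.1), "probability")
  expect_error(synergyScore(-0.1, 0.2, 0.2), "probability")
})

test_that("Bliss expectation is symmetric, monotone and maps into [0,1]", {
  grid <- seq(0, 1, by = 0.1)
  for (a in grid) for (b in grid) {
    e <- blissExpected(a, b)
    expect_equal(e, blissExpected(b, a))
    expect_gte(e, max(a, b) - 1e-12)
    expect_lte(e, 1)
  }
  # monotone in each argument
  expect_true(all(diff(blissExpected(grid, 0.3)) >= 0))
})

test_that("degenerate cohorts give a zero-width CI at the point score", {
  cohort <- degenerateCohort()
  est <- synergyEstimate(cohort, 100)
  expect_equal(est@score, 1)  # DKO all lesioned, singles lesion-free
  ci <- synergyCI(cohort, 100, nBoot = 200, seed = 5)
  expect_equal(unname(ci["ciLow"]), est@score)
  expect_equal(unname(ci["ciHigh"]), est@score)
})

test_that("percentile CI contains the point estimate on simulated cohorts", {
  for (i in 1:30) {
    cohort <- simulateCohort(simConfig(nPerGenotype = 30L, seed = 100 + i))
    est <- synergyEstimate(cohort, 400)
    ci <- synergyCI(cohort, 400, nBoot = 400, seed = i)
    expect_lte(ci[["ciLow"]], est@score + 1e-9)
    expect_gte(ci[["ciHigh"]], est@score - 1e-9)
  }
})

test_that("resampling p-value obeys the add-one lower bound", {
  cohort <- simulateCohort(simConfig(seed = 8))
  p <- synergyPermutationP(cohort, 400, nPerm = 500, seed = 1)
  expect_gte(p, 1 / 501)
  expect_lte(p, 1)
  # deterministic under the seed
  expect_identical(p, synergyPermutationP(cohort, 400, nPerm = 500, seed = 1))
  expect_error(synergyPermutationP(cohort, 400, nPerm = 50), "at least 100")
})

test_that("strong planted synergy is detected with high power", {
  # true score ~0.45 at 400 d, n = 45 per genotype
  lam <- c(WT = 2e-5, SIRT2KO = 1.077e-3, SOD1KO = 1.151e-4)
  theta <- thetaForSynergy(lam["SIRT2KO"], lam["SOD1KO"], 400, 0.45)
  hits <- vapply(1:60, function(i) {
    cohort <- simulateCohort(simConfig(
      nPerGenotype = 45L, lesionHazard = lam,
      interactionMultiplier = theta, censorHazard = 0, seed = 7000 + i))
    synergyPermutationP(cohort, 400, nPerm = 300, seed = i) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("time-course output matches per-horizon computation", {
  cohort <- simulateCohort(simConfig(seed = 17))
  tc <- synergyTimecourse(cohort, c(200, 400), nBoot = 150, nPerm = 150,
                          seed = 9)
  expect_equal(nrow(tc), 2L)
  expect_equal(tc$score[2], synergyEstimate(cohort, 400)@score)
  expect_equal(tc$expected, tc$pA + tc$pB - tc$pA * tc$pB)
  # singleton equals direct computation; empty list gives empty output
  single <- synergyTimecourse(cohort, 400, nBoot = 0, nPerm = 0)
  expect_equal(single$score, synergyEstimate(cohort, 400)@score)
  expect_equal(nrow(synergyTimecourse(cohort, numeric(0),
                                      nBoot = 0, nPerm = 0)), 0L)
  expect_error(synergyTimecourse(cohort, c(400, 100), 0, 0), "ascending")
})

test_that("a late-acting interaction yields a rising score time-course", {
  # hand-built cohort: all onsets after day 250, with final incidences
  # near the published ones -> scores ~0 at 100/200 d, large at 400 d
  n <- 48
  onset <- function(k) seq(251, 399, length.out = k)
  arm <- function(prefix, genotype, k) rbind(
    cohortRow(sprintf("%s%02d", prefix, 1:k), genotype, onset(k), 1),
    cohortRow(sprintf("%sc%02d", prefix, seq_len(n - k)), genotype, 400, 0))
  cohort <- rbind(cohortRow(sprintf("W%02d", 1:n), "WT", 400, 0),
                  arm("A", "SIRT2KO", 17),  # 35 %
                  arm("B", "SOD1KO", 2),    # ~4 %
                  arm("D", "DKO", 41))      # ~85 %
  tc <- synergyTimecourse(cohort, c(100, 200, 300, 400),
                          nBoot = 0, nPerm = 0)
  expect_equal(tc$score[1], 0)
  expect_equal(tc$score[2], 0)
  expect_gt(tc$score[4], 0.4)
  expect_true(all(diff(tc$score) >= 0))
})

test_that("Fisher's exact test matches enumeration and conventions", {
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  # fully discordant table: only two equally extreme tables exist
  res <- fisherExact2x2(matrix(c(0, 10, 10, 0), 2))
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$oddsRatio, 0)
  tab <- matrix(c(2, 8, 8, 2), 2)
  expect_equal(fisherExact2x2(tab)$p, oracleFisherP(tab),
               tolerance = 1e-12)
  expect_error(fisherExact2x2(matrix(0L, 2, 2)), "all-zero")
  expect_error(fisherExact2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})
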