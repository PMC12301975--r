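test_that("expression filter applies the strict >10-in-3 rule", {
  counts <- rbind(
    pass_boundary = c(11, 11, 11, 0, 0, 0),   # strictly >10 in exactly 3
    fail_at10     = c(10, 10, 10, 10, 10, 10),# never exceeds 10
    pass_all      = c(100, 90, 80, 70, 60, 50),
    fail_two      = c(50, 50, 0, 0, 0, 0),
    fail_zero     = c(0, 0, 0, 0, 0, 0))
  expect_setequal(filterExpressed(counts), c("pass_boundary", "pass_all"))
  expect_identical(filterExpressed(matrix(0, 4, 6)), character(0))
  expect_warning(few <- filterExpressed(matrix(100, 5, 2)), "fewer than")
  expect_identical(few, character(0))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(5)
  p <- runif(50)^2
  adj <- bhAdjust(p)
  expect_equal(adj, oracleBH(p))
  expect_true(all(adj >= p))
  # invariant under permutation of the input order
  perm <- sample(50)
  expect_equal(bhAdjust(p[perm]), adj[perm])
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calling uses strict thresholds", {
  tab <- degTable(c("a", "b", "c", "d", "e"),
                  log2fc = c(1.0, 2, -1.5, -1.5, 0.2),
                  padj = c(0.01, 0.04, 0.06, 0.001, 0.001))
  degs <- callDegs(tab)
  expect_identical(degs$up, "b")      # "a" sits exactly at the cutoff
  expect_identical(degs$down, "d")    # "c" misses the padj cutoff
})

test_that("ranking metric is the signed -log10 padj", {
  expect_equal(rankMetric(0.01, 3), 2)
  expect_equal(rankMetric(0.05, -2), -log10(0.05) * -1, tolerance = 1e-9)
  expect_equal(rankMetric(0.05, -2), -1.30103, tolerance = 1e-5)
  expect_warning(z <- rankMetric(1.0, 2), NA)
  expect_equal(z, 0)
  expect_warning(clamped <- rankMetric(0, 2), "clamped")
  expect_equal(clamped, 300)
  expect_warning(nosign <- rankMetric(0.01, 0), "no sign")
  expect_equal(nosign, 0)
  # antisymmetric in fold-change sign, monotone decreasing in padj
  p <- c(0.5, 0.1, 0.01)
  expect_equal(rankMetric(p, 1), -rankMetric(p, -1))
  expect_true(all(diff(rankMetric(p, 1)) > 0))
})

test_that("ranked lists are ordered with deterministic tie-breaking", {
  tab <- degTable(c("zed", "ant", "mid", "big"),
                  log2fc = c(2, 2, -2, 3),
                  padj = c(0.05, 0.05, 0.01, 0.001))
  ranked <- rankGenes(tab)
  expect_equal(names(ranked), c("big", "ant", "zed", "mid"))
  expect_true(all(diff(ranked) <= 1e-12))
})

test_that("rank-sum test: exact enumeration, ties, and the switch point", {
  rs <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(rs$p, 1 / 3, tolerance = 1e-12)
  expect_equal(rs$statistic, 3)
  expect_equal(wilcoxonRankSum(c(5, 6, 7), c(5, 6, 7))$p, 1)
  # exact p agrees with the enumeration oracle, with and without ties
  cases <- list(list(x = c(1.2, 3.4, 2.2), y = c(0.1, 5, 6, 7)),
                list(x = c(1, 1, 2, 9), y = c(1, 3, 3)),
                list(x = c(10, 12), y = c(11, 13, 9, 14, 8, 15, 7, 16, 6, 17)))
  for (cs in cases)
    expect_equal(wilcoxonRankSum(cs$x, cs$y)$p,
                 oracleRankSumP(cs$x, cs$y), tolerance = 1e-12)
  # untied exact branch agrees with wilcox.test's exact p
  x <- c(1.1, 2.3, 5.2, 7.1); y <- c(0.4, 3.3, 4.4, 8.8)
  expect_equal(wilcoxonRankSum(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  # at the m+n = 12 boundary exact and approximate p agree closely
  set.seed(9)
  x <- rnorm(6); y <- rnorm(6) + 0.5
  exact <- wilcoxonRankSum(x, y, exactLimit = 12)$p
  approx <- wilcoxonRankSum(x, y, exactLimit = 0)$p
  expect_lt(abs(exact - approx), 0.02)
  expect_error(wilcoxonRankSum(numeric(0), 1), "nonempty")
})

test_that("signed-rank test matches full sign enumeration", {
  d <- c(0.5, -0.2, 1.4, 0.3, -0.7)
  expect_equal(wilcoxonSignedRank(d)$p, oracleSignedRankP(d),
               tolerance = 1e-12)
  # agreement with wilcox.test on untied differences
  expect_equal(wilcoxonSignedRank(d)$p,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_warning(res <- wilcoxonSignedRank(c(0, 0, 1, -2)), "dropped")
  expect_equal(res$p, oracleSignedRankP(c(1, -2)), tolerance = 1e-12)
})

test_that("length imbalance reproduces the toy enumeration example", {
  tab <- degTable(c("u1", "u2", "d1", "d2", "n1"),
                  log2fc = c(2, 2, -2, -2, 0.1),
                  padj = c(0.01, 0.01, 0.01, 0.01, 0.9),
                  length = c(500, 600, 3000, 4000, 1000))
  li <- lengthImbalance(tab)
  expect_equal(li$direction, "up-shorter")
  expect_equal(li$p, 1 / 3, tolerance = 1e-12)
  expect_equal(li$medianUp, 550)
  expect_equal(li$medianDown, 3500)
  noDown <- degTable(c("u1", "n1"), log2fc = c(2, 0), padj = c(0.01, 0.9))
  expect_error(lengthImbalance(noDown), "undefined")
})

test_that("length imbalance is calibrated when no shift is planted", {
  rejections <- vapply(1:60, function(i) {
    sim <- simulateDegTable(simConfig(nGenes = 600L, lengthShift = 0,
                                      seed = 4000 + i))
    lengthImbalance(sim$table)$p < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.15)
})

test_that("core signature is the cross-tissue intersection", {
  sig <- coreSignature(list(T1 = c("A", "B", "C"), T2 = c("B", "C", "D"),
                            T3 = c("B", "C", "E")))
  expect_equal(sig$signature, c("B", "C"))
  expect_equal(sig$size, 2L)
  expect_equal(sig$pairwiseOverlap["T1", "T2"], 2L)
  expect_equal(sig$pairwiseOverlap["T1", "T1"], 3L)
  # disjoint sets
  expect_equal(coreSignature(list(a = "x", b = "y"))$size, 0L)
  # a subset of all others is the intersection; order-independent
  sets <- list(big = c("p", "q", "r", "s"), small = c("q", "r"),
               mid = c("p", "q", "r"))
  expect_equal(coreSignature(sets)$signature, c("q", "r"))
  expect_equal(coreSignature(rev(sets))$signature, c("q", "r"))
  # idempotent: intersecting the result with itself changes nothing
  expect_equal(coreSignature(list(a = c("q", "r"), b = c("q", "r")))$signature,
               c("q", "r"))
  expect_error(coreSignature(list(only = "x")), "at least 2")
})

test_that("paired fold-change comparison detects systematic shifts", {
  fc <- setNames(c(1.2, 2.5, 0.8, 3.1, 1.9), letters[1:5])
  same <- foldchangeComparison(letters[1:5], fc, fc)
  expect_equal(same$medianDiff, 0)
  expect_equal(same$p, 1)
  up <- foldchangeComparison(letters[1:5], fc + 0.5, fc)
  expect_equal(up$medianDiff, 0.5)
  expect_true(all(up$pairs$diff > 0))
  # n = 5 exact p equals the 2^5 sign enumeration
  fc2 <- setNames(c(1.0, 2.0, 1.1, 3.5, 2.2), letters[1:5])
  res <- foldchangeComparison(letters[1:5], fc, fc2)
  expect_equal(res$p, oracleSignedRankP(fc[letters[1:5]] - fc2[letters[1:5]]),
               tolerance = 1e-12)
  expect_error(foldchangeComparison(character(0), fc, fc), "empty")
  expect_error(foldchangeComparison(c("a", "zz"), fc, fc), "covered")
})

test_that("marker scores are z-scored population means", {
  expr <- matrix(5, nrow = 4, ncol = 3,
                 dimnames = list(paste0("m", 1:4), paste0("s", 1:3)))
  sets <- list(neutrophil = c("m1", "m2"), macrophage = c("m3", "m4"))
  expect_true(all(immuneScore(expr, sets) == 0))
  # doubling one sample's markers makes it the top scorer
  expr2 <- expr; expr2[c("m1", "m2"), "s2"] <- 10
  sc <- immuneScore(expr2, sets)
  expect_equal(rownames(sc)[which.max(sc[, "neutrophil"])], "s2")
  # hand computation on a 3-sample toy matrix
  expr3 <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), nrow = 4,
                  dimnames = list(paste0("m", 1:4), paste0("s", 1:3)))
  raw <- colMeans(expr3[c("m1", "m2"), ])   # 1.5, 5.5, 9.5
  hand <- (raw - mean(raw)) / sd(raw)
  expect_equal(unname(immuneScore(expr3, sets)[, "neutrophil"]),
               unname(hand))
  expect_warning(
    dropped <- immuneScore(expr, list(neutrophil = c("m1", "m2", "zz"))),
    "absent")
  expect_equal(colnames(dropped), "neutrophil")
  expect_error(suppressWarnings(
    immuneScore(expr, list(bad = c("m1", "zz")))), "no population")
})

test_that("simple DE test is antisymmetric and controls the null", {
  cfg <- simConfig(nGenes = 200L, fracUp = 0, fracDown = 0, seed = 12)
  se <- simulateCounts(cfg)
  counts <- SummarizedExperiment::assay(se)
  groups <- SummarizedExperiment::colData(se)$group
  deg <- simpleDeTest(counts, groups)
  flipped <- simpleDeTest(counts, factor(groups, levels = c("case", "control")))
  expect_equal(deg$log2fc, -flipped$log2fc, tolerance = 1e-12)
  # null simulation: essentially no BH-significant calls
  expect_lte(sum(deg$padj < 0.05), 1)
  expect_error(simpleDeTest(counts, rep("one", ncol(counts))), "2 groups")
})
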