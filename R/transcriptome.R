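#' Expression filter: detectable genes
#'
#' Keeps genes with read counts strictly greater than 10 in at least 3
#' samples — the detectability filter applied before differential
#' expression.
#'
#' @param counts gene-by-sample integer matrix or a
#'   \code{SummarizedExperiment} with a \code{"counts"} assay.
#' @param minCount count threshold (strict inequality; default 10).
#' @param minSamples minimum number of samples exceeding it (default 3).
#' @return character vector of retained gene ids.
#' @importFrom SummarizedExperiment assay
#' @export
filterExpressed <- function(counts, minCount = 10, minSamples = 3) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  if (!is.matrix(counts) || any(counts < 0))
    stop("counts must be a nonnegative matrix", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (ncol(counts) < minSamples) {
    warning("fewer than ", minSamples,
            " samples: no gene can pass the filter")
    return(character(0))
  }
  rownames(counts)[rowSums(counts > minCount) >= minSamples]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone, capped at 1) via
#' \code{\link[stats]{p.adjust}}.
#'
#' @param pvalues p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @importFrom stats p.adjust
#' @export
bhAdjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' Strict thresholds: up-regulated genes have \code{log2fc > lfc} and
#' \code{padj < alpha}; down-regulated genes \code{log2fc < -lfc} and
#' \code{padj < alpha}. A gene at exactly the fold-change cutoff is not
#' called.
#'
#' @param table DEG \code{data.frame} (columns \code{gene_id},
#'   \code{log2fc}, \code{padj}, ...).
#' @param lfc absolute log2 fold-change cutoff (default 1).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
callDegs <- function(table, lfc = 1, alpha = 0.05) {
  validateDegTable(table)
  up <- table$gene_id[!is.na(table$padj) & table$log2fc > lfc &
                        table$padj < alpha]
  down <- table$gene_id[!is.na(table$padj) & table$log2fc < -lfc &
                          table$padj < alpha]
  list(up = up, down = down)
}

#' Signed ranking metric
#'
#' \code{-log10(padj) * sign(log2fc)}: the score used to order genes for
#' pre-ranked enrichment analysis. \code{padj = 0} is clamped to 1e-300
#' (with a warning) to keep scores finite; \code{log2fc = 0} yields a
#' score of 0 with a warning since its sign is undefined.
#'
#' @param padj adjusted p-values in (0, 1].
#' @param log2fc log2 fold changes (sign carrier).
#' @return numeric scores (vectorised).
#' @export
rankMetric <- function(padj, log2fc) {
  if (any(!is.finite(padj) | padj < 0 | padj > 1))
    stop("padj must lie in [0, 1]", call. = FALSE)
  if (any(padj == 0)) {
    warning("padj = 0 clamped to 1e-300")
    padj[padj == 0] <- 1e-300
  }
  if (any(log2fc == 0))
    warning("log2fc = 0 has no sign; score set to 0")
  -log10(padj) * sign(log2fc)
}

#' Build a ranked gene list from a DEG table
#'
#' Scores each gene with \code{\link{rankMetric}} and orders decreasingly;
#' ties in score are broken by gene id (lexicographic) so the ranking is
#' deterministic across platforms.
#'
#' @param table DEG \code{data.frame}.
#' @return named numeric vector, scores nonincreasing — the ranked-list
#'   input of \code{\link{gseaPreranked}}.
#' @export
rankGenes <- function(table) {
  validateDegTable(table)
  score <- rankMetric(table$padj, table$log2fc)
  ord <- order(-score, table$gene_id)
  setNames(score[ord], table$gene_id[ord])
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Rank-sum test with average ranks for ties. For combined sample size
#' up to 12 the p-value is exact, from full enumeration of all
#' \code{choose(m+n, m)} group assignments (ties handled through average
#' ranks, which \code{wilcox.test} cannot do exactly); larger samples use
#' the normal approximation with continuity correction.
#'
#' @param x,y numeric samples (both nonempty).
#' @param exactLimit combined size at or below which enumeration is used
#'   (default 12).
#' @return list with \code{statistic} (rank sum of \code{x}),
#'   \code{p} (two-sided) and \code{method}.
#' @importFrom stats wilcox.test
#' @importFrom utils combn
#' @export
wilcoxonRankSum <- function(x, y, exactLimit = 12L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  if (m + n <= exactLimit) {
    sums <- colSums(matrix(r[combn(m + n, m)], nrow = m))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(sums <= W + eps), mean(sums >= W - eps)))
    list(statistic = W, p = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = W, p = wt$p.value, method = "normal approximation")
  }
}

#' Wilcoxon signed-rank test on paired differences (two-sided)
#'
#' Zero differences are dropped (with a warning); for up to
#' \code{exactLimit} nonzero pairs the p-value is exact over all
#' \eqn{2^n} sign assignments (average ranks for tied magnitudes),
#' otherwise the normal approximation with continuity correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exactLimit number of pairs at or below which enumeration is
#'   used (default 12).
#' @return list with \code{statistic} (positive-rank sum \code{V}),
#'   \code{p} and \code{method}.
#' @importFrom stats wilcox.test
#' @export
wilcoxonSignedRank <- function(d, exactLimit = 12L) {
  if (length(d) == 0L) stop("no differences supplied", call. = FALSE)
  if (any(d == 0)) {
    warning("zero differences dropped")
    d <- d[d != 0]
  }
  if (length(d) == 0L) return(list(statistic = 0, p = 1, method = "degenerate"))
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exactLimit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.vector(signs %*% r)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(sums <= V + eps), mean(sums >= V - eps)))
    list(statistic = V, p = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
    list(statistic = V, p = wt$p.value, method = "normal approximation")
  }
}

#' Transcript-length imbalance of up- vs down-regulated genes
#'
#' Tests whether significantly up-regulated transcripts are shorter (or
#' longer) than significantly down-regulated ones — the length imbalance
#' characteristic of aged transcriptomes — using the two-sided rank-sum
#' test of \code{\link{wilcoxonRankSum}} on transcript lengths of the DEG
#' sets from \code{\link{callDegs}}.
#'
#' @param table DEG \code{data.frame} including \code{transcript_length}.
#' @param lfc,alpha DEG thresholds (see \code{\link{callDegs}}).
#' @return list with \code{medianUp}, \code{medianDown} (bases),
#'   \code{statistic}, \code{p} and \code{direction} (one of
#'   \code{"up-shorter"}, \code{"down-shorter"}, \code{"none"}).
#' @importFrom stats median
#' @export
lengthImbalance <- function(table, lfc = 1, alpha = 0.05) {
  degs <- callDegs(table, lfc, alpha)
  if (length(degs$up) == 0L || length(degs$down) == 0L)
    stop("length imbalance undefined: need at least one up- and one ",
         "down-regulated gene", call. = FALSE)
  lenUp <- table$transcript_length[match(degs$up, table$gene_id)]
  lenDown <- table$transcript_length[match(degs$down, table$gene_id)]
  wt <- wilcoxonRankSum(lenUp, lenDown)
  mu <- median(lenUp); md <- median(lenDown)
  list(medianUp = mu, medianDown = md, statistic = wt$statistic,
       p = wt$p,
       direction = if (mu < md) "up-shorter"
                   else if (mu > md) "down-shorter" else "none",
       nUp = length(lenUp), nDown = length(lenDown))
}

#' Cross-tissue core signature
#'
#' Intersects per-tissue gene sets (typically up-regulated DEGs) to the
#' genes shared by every tissue, and reports pairwise overlap counts for
#' Venn-style summaries.
#'
#' @param perTissue named list (>= 2 tissues) of character gene sets.
#' @return list with \code{signature} (sorted intersection),
#'   \code{size}, and \code{pairwiseOverlap} (symmetric count matrix).
#' @export
coreSignature <- function(perTissue) {
  if (!is.list(perTissue) || length(perTissue) < 2L)
    stop("need gene sets for at least 2 tissues", call. = FALSE)
  if (is.null(names(perTissue)) || any(names(perTissue) == ""))
    stop("tissue sets must be named", call. = FALSE)
  sets <- lapply(perTissue, unique)
  sig <- sort(Reduce(intersect, sets))
  k <- length(sets)
  ov <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    ov[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(signature = sig, size = length(sig), pairwiseOverlap = ov)
}

#' Paired fold-change comparison on a common gene set
#'
#' For genes up-regulated in both a double and a single knockout, tests
#' whether the double-knockout fold changes are systematically larger:
#' per-gene paired differences (double minus single) with a two-sided
#' Wilcoxon signed-rank test.
#'
#' @param commonGenes character vector of shared genes.
#' @param fcDouble,fcSingle named numeric log2 fold-change mappings; both
#'   must cover \code{commonGenes}.
#' @return list with \code{medianDiff}, \code{p}, and \code{pairs}
#'   (per-gene \code{data.frame}).
#' @importFrom stats median
#' @export
foldchangeComparison <- function(commonGenes, fcDouble, fcSingle) {
  if (length(commonGenes) == 0L)
    stop("empty common gene set", call. = FALSE)
  if (!all(commonGenes %in% names(fcDouble)) ||
      !all(commonGenes %in% names(fcSingle)))
    stop("commonGenes must be covered by both fold-change mappings",
         call. = FALSE)
  d <- unname(fcDouble[commonGenes] - fcSingle[commonGenes])
  sr <- if (all(d == 0)) list(p = 1, statistic = 0)
        else wilcoxonSignedRank(d)
  list(medianDiff = median(d), p = sr$p,
       pairs = data.frame(gene_id = commonGenes,
                          fc_double = unname(fcDouble[commonGenes]),
                          fc_single = unname(fcSingle[commonGenes]),
                          diff = d, stringsAsFactors = FALSE))
}

#' Marker-based immune population scores
#'
#' A simplified marker-mean analogue of murine immune deconvolution
#' tools: each population's score in a sample is the mean log-scale
#' expression of its marker genes, z-scored across samples. Scores are
#' relative between samples, not absolute cell proportions. Markers
#' missing from the matrix are dropped with a warning; populations with
#' fewer than 2 remaining markers are skipped.
#'
#' @param expr gene-by-sample log-scale expression matrix (rownames =
#'   gene ids).
#' @param markerSets named list: population -> character marker genes.
#' @return sample-by-population score matrix.
#' @importFrom stats sd
#' @export
immuneScore <- function(expr, markerSets) {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop("expr must be a matrix with gene rownames", call. = FALSE)
  if (length(markerSets) == 0L || is.null(names(markerSets)))
    stop("markerSets must be a named list", call. = FALSE)
  scores <- list()
  for (pop in names(markerSets)) {
    mk <- unique(markerSets[[pop]])
    present <- intersect(mk, rownames(expr))
    if (length(present) < length(mk))
      warning(length(mk) - length(present), " marker(s) of ", pop,
              " absent from the matrix")
    if (length(present) < 2L) {
      warning("population ", pop, " skipped: fewer than 2 markers present")
      next
    }
    raw <- colMeans(expr[present, , drop = FALSE])
    s <- sd(raw)
    scores[[pop]] <- if (s > 0) (raw - mean(raw)) / s else raw * 0
  }
  if (length(scores) == 0L)
    stop("no population could be scored", call. = FALSE)
  do.call(cbind, scores)
}

#' Simple two-group differential-expression test
#'
#' A deliberately plain stand-in for a full negative-binomial DE model,
#' used to close the loop on synthetic data: counts are library-size
#' normalised (scaled to the mean library), log2-transformed with a
#' pseudo-count of 0.5, and compared between the two groups with a
#' per-gene Welch t-test; p-values are BH-adjusted. The log2 fold change
#' is the difference of group means on the log scale (second group minus
#' first, in order of appearance of the labels).
#'
#' @param counts gene-by-sample matrix or \code{SummarizedExperiment}
#'   with a \code{"counts"} assay (group labels then taken from
#'   \code{colData(counts)$group}).
#' @param groups two-level labels, one per sample (ignored for a
#'   \code{SummarizedExperiment}).
#' @param transcriptLength optional per-gene lengths carried into the
#'   result.
#' @return a DEG \code{data.frame} (see \code{\link{simulateDegTable}}
#'   for columns).
#' @importFrom SummarizedExperiment assay colData
#' @importFrom stats pt
#' @export
simpleDeTest <- function(counts, groups = NULL, transcriptLength = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(groups)) groups <- colData(counts)$group
    counts <- assay(counts, "counts")
  }
  if (is.null(groups) || length(groups) != ncol(counts))
    stop("groups must label every sample", call. = FALSE)
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L || any(table(groups) < 2L))
    stop("need exactly 2 groups with at least 2 samples each",
         call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  libSize <- colSums(counts)
  norm <- sweep(counts, 2, libSize / mean(libSize), "/")
  lg <- log2(norm + 0.5)
  g1 <- groups == levels(groups)[1]
  welch <- function(mat) {
    n1 <- sum(g1); n2 <- sum(!g1)
    m1 <- rowMeans(mat[, g1, drop = FALSE])
    m2 <- rowMeans(mat[, !g1, drop = FALSE])
    v1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
    v2 <- rowSums((mat[, !g1, drop = FALSE] - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m2 - m1) / sqrt(pmax(se2, 1e-16))
    df <- pmax(se2^2 / pmax(v1^2 / (n1^2 * (n1 - 1)) +
                            v2^2 / (n2^2 * (n2 - 1)), 1e-300), 1)
    p <- 2 * pt(-abs(tstat), df)
    p[se2 == 0 & m1 == m2] <- 1  # flat rows carry no evidence
    p[se2 == 0 & m1 != m2] <- 0  # constant rows at different levels
    list(lfc = m2 - m1, p = p)
  }
  w <- welch(lg)
  tab <- data.frame(
    gene_id = rownames(counts),
    log2fc = unname(w$lfc),
    pvalue = unname(w$p),
    padj = bhAdjust(unname(w$p)),
    mean_count = unname(rowMeans(norm)),
    transcript_length = if (is.null(transcriptLength)) NA_integer_
                        else as.integer(transcriptLength),
    stringsAsFactors = FALSE)
  validateDegTable(tab)
  tab
}
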