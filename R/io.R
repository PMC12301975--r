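# Readers and writers for the package's tabular contracts. All files are
# UTF-8 tab-separated with '.' decimals; gene sets use the GMT dialect.

#' Read / write a cohort table
#'
#' Cohort TSV columns: \code{subject_id}, \code{genotype} (WT, SIRT2KO,
#' SOD1KO, DKO), \code{lesion_time}, \code{lesion_event},
#' \code{followup_time}, \code{death_event}. Rows violating the contract
#' (non-positive times, unknown genotypes, events after follow-up) are
#' reported with their row numbers.
#'
#' @param path file path.
#' @return \code{readCohort}: a validated cohort \code{data.frame}.
#' @importFrom utils read.delim write.table
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validateCohort(tab)
  tab
}

#' @rdname readCohort
#' @param cohort cohort \code{data.frame} to write.
#' @export
writeCohort <- function(cohort, path) {
  validateCohort(cohort)
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a differential-expression table
#'
#' DEG TSV columns: \code{gene_id}, \code{log2fc}, \code{pvalue},
#' \code{padj}, \code{mean_count}, \code{transcript_length}.
#'
#' @param path file path.
#' @return \code{readDegTable}: a validated DEG \code{data.frame}.
#' @export
readDegTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validateDegTable(tab)
  tab
}

#' @rdname readDegTable
#' @param table DEG \code{data.frame} to write.
#' @export
writeDegTable <- function(table, path) {
  validateDegTable(table)
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-by-sample count matrix
#' @param path TSV path; first column \code{gene_id}, remaining columns
#'   samples.
#' @return \code{readCounts}: integer matrix with gene rownames.
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("negative counts in ", path, call. = FALSE)
  m
}

#' @rdname readCounts
#' @param counts matrix to write.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: \code{name TAB description TAB gene1 TAB gene2 ...}.
#' Duplicate genes within a set are removed with a warning; a line with
#' fewer than three fields is an error; an empty file yields an empty
#' collection with a warning.
#'
#' @param path GMT file path.
#' @return named list of character gene sets; descriptions in
#'   \code{attr(, "description")}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    out <- list(); attr(out, "description") <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    u <- unique(genes)
    if (length(u) < length(genes))
      warning("duplicated genes removed in set '", fields[[i]][1], "'")
    u
  })
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character gene sets.
#' @param path output path.
#' @param description per-set description strings (recycled).
#' @rdname readGmt
#' @export
writeGmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
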