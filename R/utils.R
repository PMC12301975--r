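# Internal helpers: seed streams and input checks.

# Deterministic sub-seed for a named stream of the master seed, so the
# cohort, DEG and count generators (and the resampling machinery) never
# share RNG state. Kept below 2^31 - 1.
streamSeed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

checkProb <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# Column contract shared by readers, writers and the simulator.
COHORT_COLUMNS <- c("subject_id", "genotype", "lesion_time", "lesion_event",
                    "followup_time", "death_event")

DEG_COLUMNS <- c("gene_id", "log2fc", "pvalue", "padj", "mean_count",
                 "transcript_length")

# Validate a cohort data.frame; returns it invisibly or stops with
# row-numbered messages.
validateCohort <- function(cohort) {
  if (!is.data.frame(cohort))
    stop("cohort must be a data.frame", call. = FALSE)
  missing <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- character()
  if (anyDuplicated(cohort$subject_id))
    bad <- c(bad, "duplicated subject_id values")
  unknown <- which(!cohort$genotype %in% GENOTYPES)
  if (length(unknown))
    bad <- c(bad, sprintf("row %d: unknown genotype '%s'", unknown,
                          cohort$genotype[unknown]))
  for (col in c("lesion_time", "followup_time")) {
    nn <- which(!is.finite(cohort[[col]]) | cohort[[col]] <= 0)
    if (length(nn))
      bad <- c(bad, sprintf("row %d: %s must be a positive number", nn, col))
  }
  for (col in c("lesion_event", "death_event")) {
    nn <- which(!cohort[[col]] %in% c(0, 1))
    if (length(nn))
      bad <- c(bad, sprintf("row %d: %s must be 0 or 1", nn, col))
  }
  late <- which(cohort$lesion_event == 1 &
                cohort$lesion_time > cohort$followup_time + 1e-9)
  if (length(late))
    bad <- c(bad, sprintf(
      "row %d: lesion_event = 1 but lesion_time exceeds followup_time", late))
  if (length(bad))
    stop("invalid cohort table:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(cohort)
}

validateDegTable <- function(deg) {
  if (!is.data.frame(deg)) stop("DEG table must be a data.frame", call. = FALSE)
  missing <- setdiff(DEG_COLUMNS, names(deg))
  if (length(missing))
    stop("DEG table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(deg$gene_id))
    stop("DEG table has duplicated gene_id values", call. = FALSE)
  if (any(deg$pvalue < 0 | deg$pvalue > 1, na.rm = TRUE) ||
      any(deg$padj < 0 | deg$padj > 1, na.rm = TRUE))
    stop("p-values and padj must lie in [0, 1]", call. = FALSE)
  if (any(deg$transcript_length <= 0, na.rm = TRUE))
    stop("transcript lengths must be positive", call. = FALSE)
  invisible(deg)
}
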