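#' Per-nucleotide coverage for one sequencing library
#'
#' A `coverage_set` holds, for one (assay, condition, replicate) library, a
#' named list of per-nucleotide count vectors (one per transcript) plus the
#' library size (total mapped reads). Counts are in transcript space.
#'
#' @param counts Named list of non-negative numeric vectors; names are
#'   transcript IDs.
#' @param assay One of `"m6a_ip"`, `"rna_input"`, `"rpf"`, `"parclip"`.
#' @param condition One of `"control"`, `"stress_200"`, `"stress_500"`.
#' @param replicate Integer >= 1.
#' @param library_size Total mapped reads; defaults to the sum of all counts,
#'   which is exact in transcript space.
#' @return A `coverage_set` object.
#' @export
coverage_set <- function(counts, assay, condition, replicate = 1L,
                         library_size = NULL) {
  assay <- match.arg(assay, c("m6a_ip", "rna_input", "rpf", "parclip"))
  condition <- match.arg(condition, c("control", "stress_200", "stress_500"))
  if (is.null(names(counts)) || anyNA(names(counts)))
    stop("counts must be a named list keyed by transcript_id")
  if (any(vapply(counts, function(x) any(x < 0), logical(1))))
    stop("coverage counts must be non-negative")
  if (is.null(library_size)) library_size <- sum(vapply(counts, sum, numeric(1)))
  if (library_size <= 0) stop("library_size must be positive")
  structure(list(counts = counts, assay = assay, condition = condition,
                 replicate = as.integer(replicate), library_size = library_size),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("<coverage_set> %s / %s / rep %d: %d transcripts, library size %.0f\n",
              x$assay, x$condition, x$replicate, length(x$counts), x$library_size))
  invisible(x)
}

# Per-transcript total reads of a coverage set, as a named numeric vector.
coverage_totals <- function(cov) vapply(cov$counts, sum, numeric(1))

#' Merge two replicate coverage libraries
#'
#' Replicates are merged by summing per-nucleotide counts and library sizes,
#' after a concordance gate: the Pearson r-squared of log1p per-transcript
#' totals must reach `min_r2`, otherwise the merge is refused.
#'
#' @param rep1,rep2 `coverage_set` objects over the same transcripts, same
#'   assay and condition.
#' @param min_r2 Concordance gate on r-squared (default 0.9).
#' @return A merged `coverage_set` (replicate number 0 denotes "merged").
#' @export
merge_coverage_replicates <- function(rep1, rep2, min_r2 = 0.9) {
  if (rep1$assay != rep2$assay || rep1$condition != rep2$condition)
    stop("replicates must share assay and condition")
  if (!identical(sort(names(rep1$counts)), sort(names(rep2$counts))))
    stop("replicates must cover the same transcript set")
  t1 <- coverage_totals(rep1); t2 <- coverage_totals(rep2)[names(t1)]
  r2 <- cor(log1p(t1), log1p(t2))^2
  if (is.na(r2) || r2 < min_r2)
    stop(sprintf("discordant replicates: r^2 = %.3f < %.2f, merge refused", r2, min_r2))
  merged <- lapply(names(rep1$counts), function(id) rep1$counts[[id]] + rep2$counts[[id]])
  names(merged) <- names(rep1$counts)
  coverage_set(merged, rep1$assay, rep1$condition, replicate = 0L,
               library_size = rep1$library_size + rep2$library_size)
}
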