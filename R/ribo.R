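#' Reads per million / per kilobase per million
#'
#' @param reads Non-negative read counts (vectorized).
#' @param library_size Total mapped reads of the library (> 0).
#' @param length_nt Effective transcript length in nt (> 0) for RPKM.
#' @return Numeric vector of RPM or RPKM values.
#' @export
compute_rpm <- function(reads, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  reads * 1e6 / library_size
}

#' @rdname compute_rpm
#' @export
compute_rpkm <- function(reads, library_size, length_nt) {
  if (any(length_nt <= 0)) stop("effective length must be positive")
  compute_rpm(reads, library_size) * 1e3 / length_nt
}

#' Ribosome density (RD)
#'
#' RD = RPF \[RPM\] / mRNA \[RPM\], the classical translation-efficiency
#' proxy. Undefined (NA) where the mRNA abundance is zero; such records are
#' classed "undetected" downstream.
#'
#' @param rpf_rpm,mrna_rpm RPM abundances (vectorized).
#' @return Numeric vector; NA where `mrna_rpm == 0`.
#' @export
compute_rd <- function(rpf_rpm, mrna_rpm) {
  ifelse(mrna_rpm > 0, rpf_rpm / mrna_rpm, NA_real_)
}

#' Normalize RD to the mitochondrial baseline
#'
#' Mitochondrially encoded genes escape the cytosolic stress response and
#' keep their ribosome density under stress; RD of every gene is divided by
#' the median RD of the mitochondrial genes (per condition), making RD
#' comparable across conditions despite library renormalization.
#'
#' @param records Tibble with `rd_raw` and `is_mitochondrial` columns (one
#'   condition at a time).
#' @return The tibble with an `rd_norm` column added.
#' @export
normalize_rd <- function(records) {
  base <- median(records$rd_raw[records$is_mitochondrial & !is.na(records$rd_raw)])
  if (!is.finite(base) || base <= 0)
    stop("no usable mitochondrial gene: RD baseline undefined")
  records$rd_norm <- records$rd_raw / base
  records
}

#' Translation ratio R_t of one RPF profile
#'
#' R_t measures how much of a gene's ribosome footprint signal piles up in
#' the initiation region (first `window` nt of the CDS). In `"fraction"` mode
#' (default) R_t = reads in the window / reads over the denominator region, a
#' value in \[0, 1\]; library-size factors cancel. In `"literal_rpkm"` mode
#' both numerator and denominator are length-normalized (RPKM-style), so a
#' perfectly uniform gene scores 1: the mode is provided for comparison, but
#' under it "uniform" and "stalled" coincide, which is why `"fraction"` is
#' the default.
#'
#' @param rpf_counts Per-nucleotide RPF counts over the full transcript.
#' @param utr5_len,cds_len Transcript geometry (nt).
#' @param mode `"fraction"` or `"literal_rpkm"`.
#' @param window Initiation window in nt from the first CDS base (default 100).
#' @param denominator `"cds"` (default) or `"transcript"`: region whose reads
#'   form the denominator.
#' @return R_t, or NA if the denominator region has zero reads (undetected).
#' @export
compute_rt <- function(rpf_counts, utr5_len, cds_len,
                       mode = c("fraction", "literal_rpkm"),
                       window = 100L, denominator = c("cds", "transcript")) {
  mode <- match.arg(mode); denominator <- match.arg(denominator)
  w <- min(window, cds_len)
  win_reads <- sum(rpf_counts[(utr5_len + 1L):(utr5_len + w)])
  if (denominator == "cds") {
    den_reads <- sum(rpf_counts[(utr5_len + 1L):(utr5_len + cds_len)])
    den_len <- cds_len
  } else {
    den_reads <- sum(rpf_counts)
    den_len <- length(rpf_counts)
  }
  if (den_reads == 0) return(NA_real_)
  if (mode == "fraction") win_reads / den_reads
  else (win_reads / (w / 1e3)) / (den_reads / (den_len / 1e3))
}

#' Classify transcripts as translated or stalled
#'
#' Genes with a uniform footprint distribution (R_t at or below the
#' threshold) are genuinely translated; genes whose footprints pile up at
#' initiation (R_t above it) are stalled and considered triaged for stress
#' granules. Undefined R_t gives "undetected".
#'
#' @param r_t Numeric vector of translation ratios (NA = undetected).
#' @param r_t_threshold Threshold (default 0.5, inclusive on the translated
#'   side).
#' @return Character vector: `"translated"`, `"stalled"`, `"undetected"`.
#' @export
classify_translation <- function(r_t, r_t_threshold = 0.5) {
  ifelse(is.na(r_t), "undetected",
         ifelse(r_t <= r_t_threshold, "translated", "stalled"))
}

#' Per-transcript translation table for one condition
#'
#' Combines RPF coverage and mRNA counts into RD (raw and
#' mitochondrially normalized), R_t and the translated/stalled class.
#'
#' @param rpf `coverage_set` of RPF counts (one condition, replicates merged).
#' @param mrna_counts Tibble with `transcript_id` and `reads` (mRNA library,
#'   same condition); its library size is `sum(reads)` unless a
#'   `library_size` attribute-like column `library_size` is supplied.
#' @param tx Transcriptome tibble.
#' @param r_t_threshold,rt_mode,window,denominator Passed to [compute_rt()] /
#'   [classify_translation()].
#' @return Tibble: `transcript_id`, `condition`, `is_mitochondrial`,
#'   `rpf_reads`, `rpf_rpm`, `mrna_rpm`, `rd_raw`, `rd_norm`, `r_t`, `class`.
#' @export
translation_table <- function(rpf, mrna_counts, tx, r_t_threshold = 0.5,
                              rt_mode = "fraction", window = 100L,
                              denominator = "cds") {
  ids <- intersect(names(rpf$counts), tx$transcript_id)
  i <- match(ids, tx$transcript_id)
  rpf_reads <- vapply(rpf$counts[ids], sum, numeric(1))
  mrna <- mrna_counts$reads[match(ids, mrna_counts$transcript_id)]
  mrna[is.na(mrna)] <- 0
  mlib <- sum(mrna_counts$reads)
  rec <- tibble::tibble(
    transcript_id = ids,
    condition = rpf$condition,
    is_mitochondrial = tx$is_mitochondrial[i],
    rpf_reads = rpf_reads,
    rpf_rpm = compute_rpm(rpf_reads, rpf$library_size),
    mrna_rpm = compute_rpm(mrna, mlib))
  rec$rd_raw <- compute_rd(rec$rpf_rpm, rec$mrna_rpm)
  rec <- normalize_rd(rec)
  rec$r_t <- vapply(seq_along(ids), function(k) {
    compute_rt(rpf$counts[[ids[k]]], tx$utr5_len[i[k]], tx$cds_len[i[k]],
               mode = rt_mode, window = window, denominator = denominator)
  }, numeric(1))
  rec$class <- classify_translation(rec$r_t, r_t_threshold)
  rec$class[is.na(rec$rd_raw)] <- "undetected"
  rec
}

#' Start-aligned metagene density profile
#'
#' Each expressed gene's coverage is restricted to a window around the start
#' codon (first CDS base = offset 0), normalized to sum 1, and averaged with
#' equal weight across genes; the cumulative curve is the running sum.
#'
#' @param cov A `coverage_set` (RPF or mRNA).
#' @param tx Transcriptome tibble.
#' @param window Integer length-2 window in nt relative to the CDS start
#'   (default `c(-50, 500)`, inclusive).
#' @return Tibble: `offset`, `mean_density`, `cumulative`; attribute
#'   `n_genes` gives the number of genes averaged.
#' @export
metagene_density <- function(cov, tx, window = c(-50L, 500L)) {
  offs <- seq(window[1], window[2])
  acc <- numeric(length(offs)); n_genes <- 0L
  for (id in intersect(names(cov$counts), tx$transcript_id)) {
    i <- match(id, tx$transcript_id)
    counts <- cov$counts[[id]]
    pos <- tx$utr5_len[i] + offs + 1L          # 1-based indices
    ok <- pos >= 1L & pos <= length(counts)
    v <- numeric(length(offs)); v[ok] <- counts[pos[ok]]
    s <- sum(v)
    if (s == 0) next
    acc <- acc + v / s
    n_genes <- n_genes + 1L
  }
  if (n_genes == 0L) stop("no gene with reads in the metagene window")
  mean_density <- acc / n_genes
  out <- tibble::tibble(offset = offs, mean_density = mean_density,
                        cumulative = cumsum(mean_density))
  attr(out, "n_genes") <- n_genes
  out
}

#' Global RD shift between conditions
#'
#' Median over genes detected in both conditions of
#' log2(RD_control / RD_stress), computed on mitochondrially normalized RD.
#' Positive values mean translation is reduced under stress.
#'
#' @param records_control,records_stress Translation tables from
#'   [translation_table()].
#' @return Median log2 ratio (single number).
#' @export
rd_shift <- function(records_control, records_stress) {
  m <- dplyr::inner_join(records_control, records_stress, by = "transcript_id",
                         suffix = c("_c", "_s"))
  m <- m[!is.na(m$rd_norm_c) & !is.na(m$rd_norm_s) &
           m$rd_norm_c > 0 & m$rd_norm_s > 0, , drop = FALSE]
  if (nrow(m) == 0L) stop("no gene detected in both conditions")
  median(log2(m$rd_norm_c / m$rd_norm_s))
}
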