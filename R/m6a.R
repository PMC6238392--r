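#' Mean-normalize a coverage profile
#'
#' Each per-nucleotide value is divided by the mean coverage of the transcript
#' ("internal" normalization), so profiles of differently expressed genes are
#' comparable. An all-zero profile returns all zeros.
#'
#' @param counts Numeric vector of per-nucleotide coverage.
#' @return Numeric vector of the same length.
#' @export
normalize_profile <- function(counts) {
  m <- mean(counts)
  if (m == 0) return(rep(0, length(counts)))
  counts / m
}

#' Build the adjusted m6A profile for one transcript
#'
#' The IP and input profiles are each mean-normalized, then the input is
#' subtracted from the IP, yielding per-nucleotide methylation excess.
#' Transcripts whose maximal *raw* IP coverage is below `coverage_min` are
#' excluded as too weakly covered to call (the threshold is on raw counts;
#' a normalized threshold of 15 would be dimensionless). Negative adjusted
#' values are retained, not clipped.
#'
#' @param ip,input Numeric per-nucleotide count vectors of equal length for
#'   the same transcript (m6A-IP and RNA-seq input).
#' @param coverage_min Raw IP coverage maximum required (default 15).
#' @return List with `values` (numeric, may be negative) and `excluded`
#'   (`"none"` or `"low_coverage"`).
#' @export
adjust_profile <- function(ip, input, coverage_min = 15) {
  if (length(ip) != length(input))
    stop("IP and input profile lengths differ: inconsistent annotation")
  excluded <- if (max(ip) < coverage_min) "low_coverage" else "none"
  list(values = normalize_profile(ip) - normalize_profile(input),
       excluded = excluded)
}

#' Call peaks on an adjusted profile
#'
#' Threshold-and-run calling: maximal runs of consecutive positions with
#' adjusted value strictly above `tau`, of length at least `min_width`, are
#' emitted with their maximum height. Peaks therefore require strictly
#' positive methylation excess.
#'
#' @param values Adjusted profile (numeric).
#' @param tau Peak threshold in normalized units (default 0.5).
#' @param min_width Minimum run length in nt (default 10).
#' @return Tibble with `start`, `end` (0-based half-open) and `height`.
#' @export
call_peaks <- function(values, tau = 0.5, min_width = 10L) {
  above <- values > tau
  if (!any(above))
    return(tibble::tibble(start = integer(0), end = integer(0), height = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width
  if (!any(keep))
    return(tibble::tibble(start = integer(0), end = integer(0), height = numeric(0)))
  s <- starts[keep]; e <- ends[keep]
  tibble::tibble(
    start = s - 1L,                      # 0-based
    end = e,                             # half-open
    height = vapply(seq_along(s), function(i) max(values[s[i]:e[i]]), numeric(1))
  )
}

#' Assign peaks to the DRACH motifs they cover
#'
#' Peaks covering no predicted DRACH motif are discarded. For each retained
#' peak, every motif whose 5-nt span intersects the peak interval is called
#' methylated; a motif covered by several peaks is called once.
#'
#' @param peaks Tibble with `transcript_id`, `start`, `end` (0-based
#'   half-open) and optionally `height`; typically pooled over transcripts.
#' @param motifs Motif tibble from [scan_drach()].
#' @param condition Condition label attached to the calls.
#' @return Tibble of methylation calls: `transcript_id`, `start`, `a_pos`,
#'   `region` (if present in `motifs`), `condition`, `peak_start`,
#'   `peak_end`, `peak_height`.
#' @export
assign_peaks_to_motifs <- function(peaks, motifs, condition) {
  empty <- tibble::tibble(
    transcript_id = character(0), start = integer(0), a_pos = integer(0),
    region = character(0), condition = character(0),
    peak_start = integer(0), peak_end = integer(0), peak_height = numeric(0))
  if (nrow(peaks) == 0L || nrow(motifs) == 0L) return(empty)
  ids <- union(peaks$transcript_id, motifs$transcript_id)
  pk <- GenomicRanges::GRanges(factor(peaks$transcript_id, ids),
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  mt <- GenomicRanges::GRanges(factor(motifs$transcript_id, ids),
                               IRanges::IRanges(motifs$start + 1L, motifs$start + 5L))
  ov <- GenomicRanges::findOverlaps(mt, pk)
  if (length(ov) == 0L) return(empty)
  mi <- S4Vectors::queryHits(ov); pi <- S4Vectors::subjectHits(ov)
  calls <- tibble::tibble(
    transcript_id = motifs$transcript_id[mi],
    start = motifs$start[mi],
    a_pos = motifs$a_pos[mi],
    region = if ("region" %in% names(motifs)) motifs$region[mi] else NA_character_,
    condition = condition,
    peak_start = peaks$start[pi],
    peak_end = peaks$end[pi],
    peak_height = if ("height" %in% names(peaks)) peaks$height[pi] else NA_real_)
  # one call per motif per condition: keep the highest supporting peak
  calls <- calls[order(calls$transcript_id, calls$start, -calls$peak_height), ]
  calls[!duplicated(calls[c("transcript_id", "start")]), , drop = FALSE]
}

#' Call methylated DRACH sites for one condition
#'
#' Runs the full per-transcript chain: low-coverage exclusion on raw IP
#' counts, mean normalization of IP and input, input subtraction, peak
#' calling, and assignment of peaks to predicted DRACH motifs.
#'
#' @param ip,input `coverage_set` objects (assays `m6a_ip` / `rna_input`) for
#'   the same condition and transcript universe.
#' @param motifs Motif tibble from [scan_drach()].
#' @param coverage_min,tau,min_width See [adjust_profile()] and
#'   [call_peaks()].
#' @return List with `calls` (methylation-call tibble), `peaks` (all peaks,
#'   including ones later dropped for covering no motif), and `excluded`
#'   (tibble of transcript_id / reason).
#' @export
call_methylation <- function(ip, input, motifs, coverage_min = 15,
                             tau = 0.5, min_width = 10L) {
  ids <- intersect(names(ip$counts), names(input$counts))
  if (length(ids) == 0L) stop("IP and input share no transcripts")
  peak_list <- vector("list", length(ids))
  excl <- character(0)
  for (k in seq_along(ids)) {
    id <- ids[k]
    adj <- adjust_profile(ip$counts[[id]], input$counts[[id]], coverage_min)
    if (adj$excluded != "none") { excl <- c(excl, id); next }
    pk <- call_peaks(adj$values, tau = tau, min_width = min_width)
    if (nrow(pk) > 0L) peak_list[[k]] <- tibble::tibble(transcript_id = id, pk)
  }
  peaks <- dplyr::bind_rows(peak_list)
  if (is.null(peaks) || nrow(peaks) == 0L)
    peaks <- tibble::tibble(transcript_id = character(0), start = integer(0),
                            end = integer(0), height = numeric(0))
  calls <- assign_peaks_to_motifs(peaks, motifs, condition = ip$condition)
  list(calls = calls, peaks = peaks,
       excluded = tibble::tibble(transcript_id = excl,
                                 reason = rep("low_coverage", length(excl))))
}

#' Per-transcript m6A/A summary
#'
#' The m6A/A statistic: methylated DRACH motifs over predicted DRACH motifs,
#' per transcript. Transcripts with zero predicted motifs get `ratio = NA`
#' and `flagged = TRUE`; they are omitted from ratio distributions.
#'
#' @param calls Methylation-call tibble for one condition.
#' @param motifs Motif tibble from [scan_drach()].
#' @param transcript_ids Optional character vector restricting (and ordering)
#'   the summarized transcripts; defaults to all transcripts in `motifs`.
#' @param condition Condition label; defaults to the calls' condition.
#' @return Tibble: `transcript_id`, `condition`, `n_predicted`,
#'   `n_methylated`, `ratio`, `flagged`.
#' @export
methylation_summary <- function(calls, motifs, transcript_ids = NULL,
                                condition = NULL) {
  if (is.null(transcript_ids)) transcript_ids <- unique(motifs$transcript_id)
  if (is.null(condition))
    condition <- if (nrow(calls) > 0L) calls$condition[1L] else NA_character_
  n_pred <- table(factor(motifs$transcript_id, transcript_ids))
  n_meth <- table(factor(calls$transcript_id, transcript_ids))
  out <- tibble::tibble(
    transcript_id = transcript_ids,
    condition = condition,
    n_predicted = as.integer(n_pred),
    n_methylated = as.integer(n_meth))
  out$ratio <- ifelse(out$n_predicted > 0L, out$n_methylated / out$n_predicted, NA_real_)
  out$flagged <- out$n_predicted == 0L
  out
}

#' Stress-induced methylation sites
#'
#' Motifs called methylated under stress but not under control. Sites lost
#' under stress are not reported (losses are not "induced").
#'
#' @param control_calls,stress_calls Methylation-call tibbles.
#' @return The subset of `stress_calls` absent from `control_calls`, keyed by
#'   (transcript_id, start).
#' @export
stress_induced_sites <- function(control_calls, stress_calls) {
  dplyr::anti_join(stress_calls, control_calls,
                   by = c("transcript_id", "start"))
}

#' Binned metagene methylation profile
#'
#' For each (segment, bin) across the transcript set: methylated DRACH motifs
#' whose adenosine falls in the bin over predicted DRACH motifs there, pooled
#' across transcripts. Bins with no predicted motif are reported with
#' `ratio = NA` (missing, not zero).
#'
#' @param motifs Motif tibble (with `region`) from [scan_drach()].
#' @param calls Methylation-call tibble for one condition.
#' @param tx Transcriptome tibble.
#' @param bins A [segment_bins()] scheme.
#' @return Tibble: `segment`, `bin`, `n_predicted`, `n_methylated`, `ratio`,
#'   with every configured bin present.
#' @export
metagene_methylation <- function(motifs, calls, tx, bins = segment_bins()) {
  loc <- motif_bins(motifs, tx, bins)
  key <- paste(loc$segment, loc$bin)
  called <- paste(calls$transcript_id, calls$start) %in%
    paste(motifs$transcript_id, motifs$start)
  call_key <- key[match(paste(calls$transcript_id, calls$start),
                        paste(motifs$transcript_id, motifs$start))]
  grid <- tibble::tibble(
    segment = rep(c("utr5", "cds", "utr3"), times = c(bins$utr5, bins$cds, bins$utr3)),
    bin = c(seq_len(bins$utr5), seq_len(bins$cds), seq_len(bins$utr3)) - 1L)
  gkey <- paste(grid$segment, grid$bin)
  grid$n_predicted <- as.integer(table(factor(key, gkey)))
  grid$n_methylated <- as.integer(table(factor(call_key, gkey)))
  grid$ratio <- ifelse(grid$n_predicted > 0L,
                       grid$n_methylated / grid$n_predicted, NA_real_)
  grid
}

# (segment, bin) of each motif's adenosine. Over-binned segments (shorter
# than the bin count) are tolerated here by capping the effective bin count
# at the segment length, so short UTRs still contribute to metagene pooling.
motif_bins <- function(motifs, tx, bins = segment_bins()) {
  i <- match(motifs$transcript_id, tx$transcript_id)
  if (anyNA(i))
    stop("motifs reference transcripts absent from the transcriptome")
  utr5 <- tx$utr5_len[i]; cds <- tx$cds_len[i]; utr3 <- tx$utr3_len[i]
  seg <- motifs$region %||% assign_region(motifs$a_pos, utr5, cds, utr3)
  off <- ifelse(seg == "utr5", 0L, ifelse(seg == "cds", utr5, utr5 + cds))
  L <- ifelse(seg == "utr5", utr5, ifelse(seg == "cds", cds, utr3))
  n <- unlist(bins[seg], use.names = FALSE)
  pos <- motifs$a_pos - off
  # closed form of bin_index() (bin b spans [floor(bL/n), floor((b+1)L/n))),
  # vectorized over rows
  bin <- ceiling((pos + 1) * pmin(n, L) / L) - 1L
  tibble::tibble(segment = seg, bin = as.integer(bin))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
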