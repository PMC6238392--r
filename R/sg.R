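#' Per-transcript count records with RPM/RPKM
#'
#' @param reads Tibble with `transcript_id` and `reads` columns, or a named
#'   numeric vector of read counts.
#' @param tx Transcriptome tibble supplying effective lengths (full
#'   transcript length).
#' @param assay,condition,replicate Library labels.
#' @param library_size Total mapped reads; defaults to `sum(reads)`.
#' @return Tibble: `transcript_id`, `assay`, `condition`, `replicate`,
#'   `reads`, `rpm`, `rpkm`, plus a `library_size` column (constant).
#' @export
count_records <- function(reads, tx, assay, condition, replicate = 1L,
                          library_size = NULL) {
  if (!is.data.frame(reads))
    reads <- tibble::tibble(transcript_id = names(reads), reads = as.numeric(reads))
  i <- match(reads$transcript_id, tx$transcript_id)
  if (anyNA(i))
    stop("count table references transcripts absent from the annotation: ",
         paste(head(reads$transcript_id[is.na(i)], 5L), collapse = ", "))
  if (is.null(library_size)) library_size <- sum(reads$reads)
  len <- tx_length(tx)[i]
  nreads <- reads$reads
  tibble::tibble(
    transcript_id = reads$transcript_id,
    assay = assay, condition = condition, replicate = as.integer(replicate),
    reads = nreads,
    rpm = compute_rpm(nreads, library_size),
    rpkm = compute_rpkm(nreads, library_size, len),
    library_size = library_size)
}

#' Spike-in detection threshold
#'
#' Synthetic spike-in RNAs of known concentration calibrate what "detected"
#' means in a library: the threshold is the minimum RPKM among spike-ins
#' observed with nonzero counts in every replicate; spike-ins dropping out of
#' any replicate do not qualify.
#'
#' @param replicates List of count-record tibbles (one per replicate) limited
#'   to, or containing, the spike-in transcripts.
#' @param spikein_ids Character vector of spike-in transcript IDs.
#' @return The detection floor `rpkm_min` (single number), from the merged
#'   replicates' RPKM.
#' @export
spikein_threshold <- function(replicates, spikein_ids) {
  if (length(replicates) == 0L) stop("no replicate supplied")
  nonzero_all <- Reduce(intersect, lapply(replicates, function(r)
    r$transcript_id[r$transcript_id %in% spikein_ids & r$reads > 0]))
  if (length(nonzero_all) == 0L)
    stop("no spike-in with nonzero counts in all replicates: library uncalibrated")
  merged <- if (length(replicates) > 1L)
    Reduce(merge_replicates, replicates) else replicates[[1L]]
  min(merged$rpkm[merged$transcript_id %in% nonzero_all])
}

#' Detected transcripts under a threshold
#'
#' @param records Count-record tibble.
#' @param rpkm_min Detection floor (inclusive: `rpkm >= rpkm_min` counts as
#'   detected).
#' @param exclude_spikeins Optional character vector of IDs to drop from the
#'   result (spike-ins are calibration, not biology).
#' @return Character vector of detected transcript IDs.
#' @export
detect_expressed <- function(records, rpkm_min, exclude_spikeins = NULL) {
  ids <- records$transcript_id[records$rpkm >= rpkm_min]
  setdiff(ids, exclude_spikeins)
}

#' Merge two count-record replicates
#'
#' Counts are summed per transcript and library sizes summed, but only after
#' a concordance gate: Pearson r-squared of log RPKM over co-detected
#' transcripts (nonzero in both) must reach `min_r2`, otherwise the merge is
#' refused with an error.
#'
#' @param rep1,rep2 Count-record tibbles over the same transcript universe.
#' @param min_r2 Concordance gate (default 0.9).
#' @return Merged count-record tibble (replicate 0 denotes "merged").
#' @export
merge_replicates <- function(rep1, rep2, min_r2 = 0.9) {
  if (!identical(sort(rep1$transcript_id), sort(rep2$transcript_id)))
    stop("replicates must cover the same transcript universe")
  i <- match(rep1$transcript_id, rep2$transcript_id)
  co <- rep1$reads > 0 & rep2$reads[i] > 0
  if (sum(co) < 2L) stop("too few co-detected transcripts to assess concordance")
  r2 <- cor(log(rep1$rpkm[co]), log(rep2$rpkm[i][co]))^2
  if (is.na(r2) || r2 < min_r2)
    stop(sprintf("discordant replicates: r^2 = %.3f < %.2f, merge refused", r2, min_r2))
  lib <- rep1$library_size[1L] + rep2$library_size[1L]
  reads <- tibble::tibble(transcript_id = rep1$transcript_id,
                          reads = rep1$reads + rep2$reads[i])
  out <- reads
  out$assay <- rep1$assay[1L]; out$condition <- rep1$condition[1L]
  out$replicate <- 0L
  out$rpm <- compute_rpm(out$reads, lib)
  # effective lengths back out of either replicate's rpm/rpkm ratio
  len <- ifelse(rep1$reads > 0, rep1$rpm / rep1$rpkm,
                ifelse(rep2$reads[i] > 0, rep2$rpm[i] / rep2$rpkm[i], NA_real_)) * 1e3
  out$rpkm <- ifelse(!is.na(len), out$rpm * 1e3 / len, 0)
  out$library_size <- lib
  out[, c("transcript_id", "assay", "condition", "replicate",
          "reads", "rpm", "rpkm", "library_size")]
}

#' PAR-CLIP enrichment and SG-client selection
#'
#' Transcript-level log2 enrichment of PAR-CLIP abundance under stress over
#' control, with a pseudocount to keep control-absent transcripts defined.
#' A transcript is an SG client when detected in the stress library and
#' enriched at least `log2_cutoff`.
#'
#' The default cutoff is log2 >= 1 (twofold over control). The selection has
#' also been described with a fourfold wording in the field; the cutoff is a
#' plain knob, so `log2_cutoff = 2` reproduces that stricter rule.
#'
#' When a sizeable fraction of the transcriptome shifts into stress granules,
#' per-library RPKM compresses the very enrichment being measured (the stress
#' library's total grows, deflating every stress RPKM). With the default
#' `scale = "common"` both libraries are therefore expressed on a common
#' scale (the geometric mean of the two library sizes), so the ratio reflects
#' per-transcript count ratios — the per-cell-equivalent comparison that
#' spike-in calibration would provide. `scale = "per_library"` keeps each
#' library's own RPKM.
#'
#' @param stress,control Count-record tibbles (same annotation).
#' @param epsilon Pseudocount added to both RPKM values; default half the
#'   smallest nonzero RPKM across the two libraries.
#' @param log2_cutoff Enrichment cutoff in log2 units (default 1, inclusive).
#' @param detected Optional character vector of transcripts counted as
#'   detected in stress; default: nonzero stress reads.
#' @param scale `"common"` (default) or `"per_library"`, see above.
#' @return Tibble: `transcript_id`, `rpkm_control`, `rpkm_stress`,
#'   `log2_enrichment`, `is_sg_client`.
#' @export
parclip_enrichment <- function(stress, control, epsilon = NULL,
                               log2_cutoff = 1, detected = NULL,
                               scale = c("common", "per_library")) {
  scale <- match.arg(scale)
  i <- match(stress$transcript_id, control$transcript_id)
  if (anyNA(i)) stop("stress and control libraries disagree on transcripts")
  rs <- stress$rpkm; rc <- control$rpkm[i]
  if (scale == "common") {
    g <- sqrt(stress$library_size[1L] * control$library_size[1L])
    rs <- rs * stress$library_size[1L] / g
    rc <- rc * control$library_size[1L] / g
  }
  if (is.null(epsilon)) {
    nz <- c(rs[rs > 0], rc[rc > 0])
    if (length(nz) == 0L) stop("all-zero libraries: enrichment undefined")
    epsilon <- min(nz) / 2
  }
  if (is.null(detected)) detected <- stress$transcript_id[stress$reads > 0]
  out <- tibble::tibble(
    transcript_id = stress$transcript_id,
    rpkm_control = rc,
    rpkm_stress = rs,
    log2_enrichment = log2((rs + epsilon) / (rc + epsilon)))
  out$is_sg_client <- out$transcript_id %in% detected &
    out$log2_enrichment >= log2_cutoff
  attr(out, "epsilon") <- epsilon
  attr(out, "log2_cutoff") <- log2_cutoff
  out
}

#' Merge PAR-CLIP clients and stalled transcripts into the SG metagene set
#'
#' The SG client census is the union of transcripts selected by PAR-CLIP
#' enrichment and transcripts whose footprints classify them as stalled,
#' with per-member provenance.
#'
#' @param parclip_clients,stalled Character vectors of transcript IDs.
#' @return Tibble: `transcript_id`, `provenance` in
#'   `{"parclip", "stalled", "both"}`.
#' @export
merge_sg_set <- function(parclip_clients, stalled) {
  ids <- sort(union(parclip_clients, stalled))
  tibble::tibble(
    transcript_id = ids,
    provenance = ifelse(ids %in% parclip_clients & ids %in% stalled, "both",
                        ifelse(ids %in% parclip_clients, "parclip", "stalled")))
}
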