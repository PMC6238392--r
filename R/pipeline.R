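#' Pipeline parameters
#'
#' All thresholds of the analysis chain in one object, with the defaults the
#' pipeline is validated under.
#'
#' @param coverage_min Raw IP coverage maximum required per transcript (15).
#' @param tau Peak threshold on the adjusted profile (0.5 normalized units).
#' @param min_width Minimum peak width (10 nt).
#' @param r_t_threshold Translated/stalled cutoff on R_t (0.5, inclusive on
#'   the translated side).
#' @param rt_mode `"fraction"` (default) or `"literal_rpkm"`.
#' @param rt_window Initiation window (100 nt).
#' @param log2_cutoff PAR-CLIP enrichment cutoff, log2 units (1 = twofold).
#' @param min_r2 Replicate concordance gate for coverage and RNA count
#'   libraries (0.9).
#' @param min_r2_parclip Concordance gate for PAR-CLIP replicates (0.6):
#'   transcript-level CLIP counts are intrinsically noisier than RNA-seq, and
#'   replicate r-squared near 0.7 is typical for acceptable libraries.
#' @param bins [segment_bins()] scheme for metagene profiles.
#' @param cds5_fraction "5' vicinity of the CDS" as a fraction of CDS bins
#'   (0.2).
#' @return List of class `pipeline_params`.
#' @export
pipeline_params <- function(coverage_min = 15, tau = 0.5, min_width = 10L,
                            r_t_threshold = 0.5, rt_mode = "fraction",
                            rt_window = 100L, log2_cutoff = 1, min_r2 = 0.9,
                            min_r2_parclip = 0.6, bins = segment_bins(),
                            cds5_fraction = 0.2) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full analysis chain on a dataset
#'
#' Executes, in order: DRACH scanning; spike-in detection thresholds and
#' detected-mRNA sets from the RNA libraries (replicates merged after the
#' concordance gate); m6A calling under control and harsh stress with
#' per-transcript m6A/A summaries, stress-induced sites and binned metagene
#' profiles; translation classification and the global RD shift from the RPF
#' libraries; PAR-CLIP SG-client selection and the merged SG metagene set;
#' and the cross-set statistics (rank-sum on m6A/A distributions,
#' hypergeometric SG-vs-methylated overlap).
#'
#' @param ds Dataset from [simulate_dataset()] (or assembled from readers in
#'   the same shape).
#' @param params A [pipeline_params()].
#' @return List with elements `motifs`, `detection` (thresholds + detected
#'   sets), `m6a` (per condition: calls/peaks/excluded/summary; plus
#'   `stress_induced`, `metagene`), `translation` (tables, `rd_log2_shift`,
#'   class counts), `sg` (enrichment, clients, `sg_set`), `stats`, and
#'   `summary` (flat named list of headline numbers).
#' @export
run_pipeline <- function(ds, params = pipeline_params()) {
  tx <- ds$transcriptome
  motifs <- ds$motifs %||% scan_drach(tx)
  mrna_ids <- tx$transcript_id[!tx$is_spikein]
  spike_ids <- tx$transcript_id[tx$is_spikein]

  ## detection: spike-in thresholds on the RNA libraries
  rna <- lapply(ds$rna, function(reps) Reduce(function(a, b)
    merge_replicates(a, b, params$min_r2), reps))
  thresholds <- lapply(ds$rna, function(reps) spikein_threshold(reps, spike_ids))
  detected <- lapply(names(rna), function(cond)
    detect_expressed(rna[[cond]], thresholds[[cond]], exclude_spikeins = spike_ids))
  names(detected) <- names(rna)

  ## m6A calling per condition
  m6a <- lapply(names(ds$m6a), function(cond) {
    ip <- Reduce(function(a, b) merge_coverage_replicates(a, b, params$min_r2),
                 ds$m6a[[cond]]$ip)
    input <- Reduce(function(a, b) merge_coverage_replicates(a, b, params$min_r2),
                    ds$m6a[[cond]]$input)
    res <- call_methylation(ip, input, motifs, params$coverage_min,
                            params$tau, params$min_width)
    det <- intersect(detected[[cond]] %||% mrna_ids, mrna_ids)
    res$summary <- methylation_summary(res$calls, motifs,
                                       transcript_ids = det, condition = cond)
    res$metagene <- metagene_methylation(
      motifs[motifs$transcript_id %in% mrna_ids, ],
      res$calls[res$calls$transcript_id %in% mrna_ids, ], tx, params$bins)
    res
  })
  names(m6a) <- names(ds$m6a)
  m6a$stress_induced <- stress_induced_sites(m6a$control$calls,
                                             m6a$stress_500$calls)

  ## translation
  rpf <- lapply(ds$rpf, function(reps) Reduce(function(a, b)
    merge_coverage_replicates(a, b, params$min_r2), reps))
  rna_for_rpf <- list(
    control = rna$control,
    stress_200 = rna$stress_500)  # transcription unaltered at mild stress
  trans <- lapply(names(rpf), function(cond)
    translation_table(rpf[[cond]], rna_for_rpf[[cond]], tx,
                      r_t_threshold = params$r_t_threshold,
                      rt_mode = params$rt_mode, window = params$rt_window))
  names(trans) <- names(rpf)
  rd_log2 <- rd_shift(trans$control, trans$stress_200)
  stress_classes <- trans$stress_200$class
  stalled_ids <- trans$stress_200$transcript_id[stress_classes == "stalled"]

  ## SG selection
  pc <- lapply(ds$parclip, function(reps) Reduce(function(a, b)
    merge_replicates(a, b, params$min_r2_parclip), reps))
  enrich <- parclip_enrichment(pc$stress_500, pc$control,
                               log2_cutoff = params$log2_cutoff)
  enrich <- enrich[enrich$transcript_id %in% mrna_ids, , drop = FALSE]
  clients <- enrich$transcript_id[enrich$is_sg_client]
  sg_set <- merge_sg_set(clients, stalled_ids)

  ## statistics
  ctl_ratio <- m6a$control$summary$ratio
  str_ratio <- m6a$stress_500$summary$ratio
  mw <- mann_whitney_u(ctl_ratio[!is.na(ctl_ratio)], str_ratio[!is.na(str_ratio)])
  meth_stress_ids <- unique(m6a$stress_500$calls$transcript_id)
  universe <- length(detected$control)
  ov <- hypergeometric_tail(length(intersect(sg_set$transcript_id, meth_stress_ids)),
                            length(meth_stress_ids), nrow(sg_set), universe)

  n_detected_control <- length(detected$control)
  n_detected_stress <- length(detected$stress_500)
  meth_control_ids <- unique(m6a$control$calls$transcript_id)
  summary <- list(
    n_transcripts = length(mrna_ids),
    n_detected_control = n_detected_control,
    n_detected_stress = n_detected_stress,
    pct_detected_decrease = 100 * (n_detected_control - n_detected_stress) /
      n_detected_control,
    n_peaks_control = nrow(m6a$control$peaks),
    n_peaks_stress = nrow(m6a$stress_500$peaks),
    n_methylated_control = length(intersect(meth_control_ids, detected$control)),
    pct_methylated_control = 100 *
      length(intersect(meth_control_ids, detected$control)) / n_detected_control,
    n_methylated_stress = length(intersect(meth_stress_ids, detected$stress_500)),
    n_stress_induced_sites = nrow(m6a$stress_induced),
    rd_log2_shift = rd_log2,
    n_translated = sum(stress_classes == "translated"),
    n_stalled = sum(stress_classes == "stalled"),
    n_rpf_transcripts = sum(stress_classes %in% c("translated", "stalled")),
    n_sg_clients = nrow(sg_set),
    pct_sg_methylated = 100 *
      length(intersect(sg_set$transcript_id, meth_stress_ids)) / nrow(sg_set),
    mw_p_m6a_ratio = mw$p_value,
    hypergeom_p_sg_meth = ov$p_value)

  list(motifs = motifs,
       detection = list(thresholds = thresholds, detected = detected),
       m6a = m6a,
       translation = list(tables = trans, rd_log2_shift = rd_log2,
                          stalled_ids = stalled_ids),
       sg = list(enrichment = enrich, clients = clients, sg_set = sg_set),
       stats = list(mann_whitney = mw, overlap = ov),
       summary = summary)
}

#' Write pipeline outputs to a directory
#'
#' Stage TSVs (calls, summaries, metagene, translation, enrichment, SG set)
#' plus a `summary.json` of the headline numbers.
#'
#' @param result Output of [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in c("control", "stress_500")) {
    write_tsv_strict(result$m6a[[cond]]$calls,
                     file.path(dir, sprintf("m6a_calls_%s.tsv", cond)))
    write_tsv_strict(result$m6a[[cond]]$summary,
                     file.path(dir, sprintf("m6a_summary_%s.tsv", cond)))
    write_tsv_strict(result$m6a[[cond]]$metagene,
                     file.path(dir, sprintf("metagene_%s.tsv", cond)))
  }
  for (cond in names(result$translation$tables))
    write_tsv_strict(result$translation$tables[[cond]],
                     file.path(dir, sprintf("translation_%s.tsv", cond)))
  write_tsv_strict(result$sg$enrichment, file.path(dir, "sg_enrichment.tsv"))
  write_tsv_strict(result$sg$sg_set, file.path(dir, "sg_set.tsv"))
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score methylation calls against planted truth
#'
#' A call is a true positive when its adenosine lies within `tol` nt of a
#' planted site on the same transcript (peak-resolution matching: under the
#' "every motif under a peak is methylated" rule, motifs neighbouring a true
#' site within the peak kernel are legitimate calls, not errors). Planted
#' sites on transcripts excluded for low coverage are not scored: they are
#' flagged unanalyzable by the method, not missed by the caller.
#'
#' @param calls Methylation-call tibble.
#' @param truth_sites Tibble with `transcript_id`, `a_pos` (planted sites for
#'   the matching condition).
#' @param excluded Optional character vector of excluded transcript IDs.
#' @param tol Matching tolerance in nt (default 25, the IP kernel
#'   half-width).
#' @return List: `sensitivity`, `precision`, `n_truth`, `n_calls`.
#' @export
score_m6a_calls <- function(calls, truth_sites, excluded = character(0), tol = 25L) {
  truth_sites <- truth_sites[!truth_sites$transcript_id %in% excluded, , drop = FALSE]
  near <- function(a, b) {
    # for each row of a: any site in b on the same transcript within tol?
    key <- split(b$a_pos, b$transcript_id)
    vapply(seq_len(nrow(a)), function(i) {
      p <- key[[a$transcript_id[i]]]
      !is.null(p) && any(abs(p - a$a_pos[i]) <= tol)
    }, logical(1))
  }
  tp_truth <- if (nrow(truth_sites) > 0L) near(truth_sites, calls) else logical(0)
  tp_calls <- if (nrow(calls) > 0L) near(calls, truth_sites) else logical(0)
  list(sensitivity = if (length(tp_truth)) mean(tp_truth) else NA_real_,
       precision = if (length(tp_calls)) mean(tp_calls) else NA_real_,
       n_truth = nrow(truth_sites), n_calls = nrow(calls))
}

#' Score a binary classification against planted truth
#'
#' @param predicted,truth Character vectors of positive-class IDs.
#' @param universe All IDs under consideration.
#' @return List: `precision`, `recall`, `f1`, `accuracy`, `n`.
#' @export
score_binary <- function(predicted, truth, universe) {
  predicted <- intersect(predicted, universe)
  truth <- intersect(truth, universe)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(universe) - tp - fp - fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = (tp + tn) / length(universe), n = length(universe))
}
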