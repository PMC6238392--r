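#' Simulation configuration
#'
#' Parameters of the synthetic dataset generator. Defaults reproduce the
#' study conditions the pipeline is designed for: a ~2,000-transcript
#' transcriptome with 13 mitochondrially encoded genes and ERCC-like
#' spike-ins; 3'UTR-biased baseline methylation reaching roughly 39% of
#' mRNAs; stress-induced additional sites confined to the 5'UTR and the 5'
#' fifth of the CDS of ~70% of stress-granule clients; an 8-fold IP
#' enrichment over a 50-nt triangular kernel; stalled genes with 85% of
#' footprints in the first 100 CDS nt; a global nuclear RD reduction of
#' log2 = 2.9 under stress sparing mitochondrial genes; 4-fold PAR-CLIP
#' enrichment of SG clients with 20% lognormal noise; and a 6.5% loss of
#' detected mRNAs under stress.
#'
#' @param n_transcripts Number of mRNAs (excluding spike-ins).
#' @param n_mitochondrial Mitochondrially encoded genes among them.
#' @param n_spikeins Spike-in species with known concentrations.
#' @param utr5_meanlog,utr5_sdlog,cds_meanlog,cds_sdlog,utr3_meanlog,utr3_sdlog
#'   Lognormal length parameters per segment (nt); CDS lengths are rounded to
#'   codon multiples.
#' @param min_utr5,min_cds,min_utr3 Length floors (nt).
#' @param base_depth_meanlog,base_depth_sdlog,min_depth Per-transcript
#'   expression depth (expected input coverage per nt); floored at
#'   `min_depth` so coverage-based calling is exercised, not starved.
#' @param fraction_sg_clients Fraction of mRNAs that are SG clients.
#' @param fraction_stress_methylated Fraction of SG clients gaining
#'   stress-induced sites.
#' @param fraction_stalled_stress Fraction of mRNAs stalled under mild
#'   stress.
#' @param fraction_degraded_stress Fraction of mRNAs degraded below
#'   detection under stress.
#' @param control_site_prob Named per-motif methylation probabilities under
#'   control (3'UTR-biased).
#' @param stress_site_prob Named per-motif probabilities of stress-induced
#'   additions (5'-biased; `cds5` applies to the first `cds5_fraction` of the
#'   CDS, the rest of the CDS gains nothing).
#' @param cds5_fraction 5' vicinity of the CDS as a fraction of its length.
#' @param ip_enrichment IP/input enrichment factor at a methylated site.
#' @param peak_halfwidth Triangular kernel half-width (nt).
#' @param rd_log2_shift Planted global RD reduction under stress (log2).
#' @param stall_fraction Fraction of a stalled gene's footprints inside the
#'   first 100 CDS nt.
#' @param rpf_factor,parclip_factor,rna_factor Expected reads per nt of
#'   expression depth for each assay.
#' @param parclip_fold PAR-CLIP stress/control fold for SG clients.
#' @param parclip_cv Lognormal coefficient of variation of PAR-CLIP counts.
#' @param spikein_depths Known spike-in concentrations (expected depth per
#'   nt); default 20 log-spaced values from 2^-4 to 2^6.
#' @param n_replicates Replicates per library.
#' @param seed Integer RNG seed; fixed seed gives identical output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000L,
                       n_mitochondrial = 13L,
                       n_spikeins = 20L,
                       utr5_meanlog = log(150), utr5_sdlog = 0.35,
                       cds_meanlog = log(900), cds_sdlog = 0.35,
                       utr3_meanlog = log(500), utr3_sdlog = 0.4,
                       min_utr5 = 20L, min_cds = 300L, min_utr3 = 30L,
                       base_depth_meanlog = log(60), base_depth_sdlog = 0.5,
                       min_depth = 30,
                       fraction_sg_clients = 0.55,
                       fraction_stress_methylated = 0.70,
                       fraction_stalled_stress = 0.95,
                       fraction_degraded_stress = 0.065,
                       control_site_prob = c(utr5 = 0.01, cds = 0.005, utr3 = 0.05),
                       stress_site_prob = c(utr5 = 0.15, cds5 = 0.08, utr3 = 0),
                       cds5_fraction = 0.2,
                       ip_enrichment = 8,
                       peak_halfwidth = 25L,
                       rd_log2_shift = 2.9,
                       stall_fraction = 0.85,
                       rpf_factor = 0.25, parclip_factor = 0.05, rna_factor = 0.1,
                       parclip_fold = 4,
                       parclip_cv = 0.2,
                       spikein_depths = 2^seq(-4, 6, length.out = 20L),
                       n_replicates = 2L,
                       seed = 42L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_transcripts >= 1L,
            cfg$n_mitochondrial >= 1L,
            cfg$n_mitochondrial < cfg$n_transcripts,
            length(cfg$spikein_depths) == cfg$n_spikeins,
            all(vapply(cfg[grep("^fraction", names(cfg))], function(f)
              f >= 0 && f <= 1, logical(1))))
  structure(cfg, class = "sim_config")
}

# random sequence of length n guaranteed to contain >= 1 DRACH motif when
# n >= 5 (resampled until it does; a 20-nt uniform segment misses with
# probability ~0.76 per draw, so a handful of tries suffice)
random_segment <- function(n, require_drach = n >= 5L) {
  if (n == 0L) return("")
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (!require_drach || grepl("[AGT][AG]AC[TAC]", s)) return(s)
  }
}

#' Generate a synthetic transcriptome
#'
#' Sequences have uniform base composition; every nonempty segment of length
#' >= 5 nt is resampled until it carries at least one DRACH motif, so all
#' segments are informative for methylation planting. The first
#' `n_mitochondrial` mRNAs are flagged mitochondrial; spike-ins are appended
#' as UTR-less transcripts.
#'
#' @param config A [sim_config()].
#' @return A `transcriptome` tibble.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_transcripts
  rl <- function(meanlog, sdlog, minv)
    pmax(minv, round(rlnorm(n, meanlog, sdlog)))
  utr5 <- as.integer(rl(config$utr5_meanlog, config$utr5_sdlog, config$min_utr5))
  cds <- as.integer(rl(config$cds_meanlog, config$cds_sdlog, config$min_cds))
  cds <- cds - cds %% 3L
  utr3 <- as.integer(rl(config$utr3_meanlog, config$utr3_sdlog, config$min_utr3))
  seqs <- vapply(seq_len(n), function(i)
    paste0(random_segment(utr5[i]), random_segment(cds[i]), random_segment(utr3[i])),
    character(1))
  ids <- sprintf("TX%04d", seq_len(n))
  mito <- seq_len(n) <= config$n_mitochondrial
  tx <- tibble::tibble(
    transcript_id = ids,
    gene_id = sprintf("G%04d", seq_len(n)),
    sequence = seqs, utr5_len = utr5, cds_len = cds, utr3_len = utr3,
    is_mitochondrial = mito, is_spikein = FALSE)
  if (config$n_spikeins > 0L) {
    slen <- as.integer(300L + 60L * (seq_len(config$n_spikeins) - 1L))
    slen <- slen - slen %% 3L
    sp <- tibble::tibble(
      transcript_id = sprintf("SPIKE%02d", seq_len(config$n_spikeins)),
      gene_id = sprintf("SPIKE%02d", seq_len(config$n_spikeins)),
      sequence = vapply(slen, random_segment, character(1)),
      utr5_len = 0L, cds_len = slen, utr3_len = 0L,
      is_mitochondrial = FALSE, is_spikein = TRUE)
    tx <- dplyr::bind_rows(tx, sp)
  }
  validate_transcriptome(tx)
  class(tx) <- c("transcriptome", class(tx))
  tx
}

#' Plant ground truth: expression, methylation, translation, SG membership
#'
#' Control methylation is drawn per motif with 3'UTR-biased probabilities;
#' stress adds sites with 5'UTR / 5'-CDS-biased probabilities to a subset of
#' SG clients (stress truth is a superset of control truth per transcript).
#' Translation is uniform for every gene under control; under mild stress a
#' planted fraction of mRNAs stalls. A planted fraction of mRNAs is degraded
#' below detection under stress. Mitochondrial genes never stall, are never
#' SG clients and are never degraded.
#'
#' @param tx Transcriptome from [simulate_transcriptome()].
#' @param motifs Motif tibble from [scan_drach()] on `tx`.
#' @param config A [sim_config()].
#' @return List of tibbles: `expression` (`transcript_id`, `depth_control`,
#'   `depth_stress`, `degraded`), `sg` (`transcript_id`, `is_sg_client`),
#'   `translation` (`transcript_id`, `condition`, `class`), `methylation`
#'   (`transcript_id`, `start`, `a_pos`, `region`, `condition`; stress rows
#'   include the carried-over control sites).
#' @export
plant_truth <- function(tx, motifs, config = sim_config()) {
  set.seed(config$seed + 1L)
  mrna <- tx[!tx$is_spikein, , drop = FALSE]
  n <- nrow(mrna)
  depth <- pmax(config$min_depth,
                rlnorm(n, config$base_depth_meanlog, config$base_depth_sdlog))
  degradable <- !mrna$is_mitochondrial
  degraded <- degradable &
    runif(n) < config$fraction_degraded_stress / mean(degradable)
  # degraded transcripts fall to the noise floor, below the spike-in threshold
  depth_stress <- ifelse(degraded, 0, depth)
  sg <- !mrna$is_mitochondrial & runif(n) < config$fraction_sg_clients
  stalled <- !mrna$is_mitochondrial & runif(n) < config$fraction_stalled_stress

  expression <- tibble::tibble(
    transcript_id = mrna$transcript_id,
    depth_control = depth, depth_stress = depth_stress, degraded = degraded)
  sg_tbl <- tibble::tibble(transcript_id = mrna$transcript_id, is_sg_client = sg)
  translation <- dplyr::bind_rows(
    tibble::tibble(transcript_id = mrna$transcript_id, condition = "control",
                   class = "translated"),
    tibble::tibble(transcript_id = mrna$transcript_id, condition = "stress_200",
                   class = ifelse(stalled, "stalled", "translated")))

  mo <- motifs[motifs$transcript_id %in% mrna$transcript_id, , drop = FALSE]
  i <- match(mo$transcript_id, mrna$transcript_id)
  p_ctrl <- unname(config$control_site_prob[mo$region])
  ctrl_hit <- runif(nrow(mo)) < p_ctrl
  # stress additions: UTR5 and 5' vicinity of CDS, clients only
  gains_client <- sg & runif(n) < config$fraction_stress_methylated
  cds_rel <- (mo$a_pos - mrna$utr5_len[i]) / pmax(1L, mrna$cds_len[i])
  p_str <- ifelse(mo$region == "utr5", config$stress_site_prob[["utr5"]],
           ifelse(mo$region == "cds" & cds_rel < config$cds5_fraction,
                  config$stress_site_prob[["cds5"]],
           ifelse(mo$region == "utr3", config$stress_site_prob[["utr3"]], 0)))
  str_hit <- ctrl_hit | (gains_client[i] & runif(nrow(mo)) < p_str)
  ctrl_sites <- mo[ctrl_hit, c("transcript_id", "start", "a_pos", "region")]
  ctrl_sites$condition <- "control"
  str_sites <- mo[str_hit, c("transcript_id", "start", "a_pos", "region")]
  str_sites$condition <- "stress_500"
  methylation <- dplyr::bind_rows(ctrl_sites, str_sites)
  list(expression = expression, sg = sg_tbl, translation = translation,
       methylation = methylation)
}

# triangular enrichment kernel over a transcript: 1 + (enrichment-1) * tri
ip_kernel <- function(length_nt, a_pos, enrichment, halfwidth) {
  k <- rep(1, length_nt)
  for (p in a_pos) {
    lo <- max(0L, p - halfwidth); hi <- min(length_nt - 1L, p + halfwidth)
    d <- abs(seq(lo, hi) - p)
    k[(lo:hi) + 1L] <- pmax(k[(lo:hi) + 1L], 1 + (enrichment - 1) * (1 - d / halfwidth))
  }
  k
}

#' Simulate m6A-IP or input coverage for one library
#'
#' Input coverage has a flat expectation at the transcript's expression
#' depth; IP coverage multiplies it by a triangular enrichment kernel
#' (factor `ip_enrichment` at each planted methylated adenosine, decaying to
#' 1 over `peak_halfwidth` nt). Per-base counts are Poisson (variance =
#' mean). Spike-ins are covered at their known concentrations.
#'
#' @param tx Transcriptome tibble.
#' @param truth Output of [plant_truth()].
#' @param config A [sim_config()].
#' @param assay `"m6a_ip"` or `"rna_input"`.
#' @param condition `"control"` or `"stress_500"`.
#' @param replicate Replicate number (seeds differ per library).
#' @return A `coverage_set`.
#' @export
simulate_coverage <- function(tx, truth, config = sim_config(),
                              assay = c("m6a_ip", "rna_input"),
                              condition = c("control", "stress_500"),
                              replicate = 1L) {
  assay <- match.arg(assay); condition <- match.arg(condition)
  set.seed(config$seed + 1000L * match(assay, c("m6a_ip", "rna_input")) +
             100L * match(condition, c("control", "stress_200", "stress_500")) +
             replicate)
  depth <- sim_depths(tx, truth, condition, config)
  meth <- truth$methylation[truth$methylation$condition == condition, , drop = FALSE]
  sites <- split(meth$a_pos, meth$transcript_id)
  lens <- tx_length(tx)
  counts <- lapply(seq_len(nrow(tx)), function(i) {
    lam <- rep(depth[i], lens[i])
    if (assay == "m6a_ip") {
      ap <- sites[[tx$transcript_id[i]]]
      if (!is.null(ap) && length(ap) > 0L)
        lam <- lam * ip_kernel(lens[i], ap, config$ip_enrichment,
                               config$peak_halfwidth)
    }
    rpois(lens[i], lam)
  })
  names(counts) <- tx$transcript_id
  coverage_set(counts, assay, condition, replicate)
}

# per-transcript expected depth per nt for a condition (spike-ins fixed)
sim_depths <- function(tx, truth, condition, config) {
  e <- truth$expression
  d <- if (condition == "control") e$depth_control else e$depth_stress
  depth <- d[match(tx$transcript_id, e$transcript_id)]
  depth[tx$is_spikein] <- config$spikein_depths[cumsum(tx$is_spikein)[tx$is_spikein]]
  depth
}

#' Simulate ribosome-protected-fragment coverage
#'
#' Footprints fall only in the CDS. Translated genes have a uniform CDS
#' expectation; stalled genes concentrate `stall_fraction` of it in the first
#' 100 CDS nt. Under stress the nuclear RPF expectation (relative to mRNA) is
#' scaled by `2^-rd_log2_shift`; mitochondrial genes are spared. Per-base
#' counts are Poisson.
#'
#' @param tx,truth,config As in [simulate_coverage()].
#' @param condition `"control"` or `"stress_200"`.
#' @param replicate Replicate number.
#' @return A `coverage_set` with assay `"rpf"`.
#' @export
simulate_rpf <- function(tx, truth, config = sim_config(),
                         condition = c("control", "stress_200"), replicate = 1L) {
  condition <- match.arg(condition)
  set.seed(config$seed + 3000L +
             100L * match(condition, c("control", "stress_200", "stress_500")) +
             replicate)
  depth <- sim_depths(tx, truth, condition, config)
  tr <- truth$translation[truth$translation$condition == condition, , drop = FALSE]
  cls <- tr$class[match(tx$transcript_id, tr$transcript_id)]
  lens <- tx_length(tx)
  scale <- ifelse(tx$is_mitochondrial | condition == "control",
                  1, 2^(-config$rd_log2_shift))
  counts <- lapply(seq_len(nrow(tx)), function(i) {
    lam <- numeric(lens[i])
    if (!tx$is_spikein[i] && !is.na(cls[i])) {
      cds_idx <- (tx$utr5_len[i] + 1L):(tx$utr5_len[i] + tx$cds_len[i])
      total <- depth[i] * tx$cds_len[i] * config$rpf_factor * scale[i]
      w <- rep(1, tx$cds_len[i])
      if (cls[i] == "stalled") {
        win <- min(100L, tx$cds_len[i])
        w[seq_len(win)] <- config$stall_fraction / win
        if (tx$cds_len[i] > win)
          w[(win + 1L):tx$cds_len[i]] <- (1 - config$stall_fraction) /
            (tx$cds_len[i] - win)
      } else {
        w <- w / tx$cds_len[i]
      }
      lam[cds_idx] <- total * w
    }
    rpois(lens[i], lam)
  })
  names(counts) <- tx$transcript_id
  coverage_set(counts, "rpf", condition, replicate)
}

#' Simulate PAR-CLIP (or RNA-seq) transcript-level counts
#'
#' PAR-CLIP counts are Poisson around an expectation proportional to
#' expression, multiplied for SG clients under stress by `parclip_fold`, with
#' multiplicative lognormal noise of coefficient of variation `parclip_cv`.
#' RNA-seq counts are Poisson around expression alone (spike-ins at known
#' concentrations).
#'
#' @param tx,truth,config As in [simulate_coverage()].
#' @param condition Library condition.
#' @param replicate Replicate number.
#' @return Count-record tibble (see [count_records()]).
#' @export
simulate_parclip <- function(tx, truth, config = sim_config(),
                             condition = c("control", "stress_500"),
                             replicate = 1L) {
  condition <- match.arg(condition)
  set.seed(config$seed + 5000L +
             100L * match(condition, c("control", "stress_200", "stress_500")) +
             replicate)
  depth <- sim_depths(tx, truth, "control", config)  # crosslink input is pre-stress pool
  client <- truth$sg$is_sg_client[match(tx$transcript_id, truth$sg$transcript_id)]
  fold <- ifelse(condition != "control" & !is.na(client) & client,
                 config$parclip_fold, 1)
  sdlog <- sqrt(log(1 + config$parclip_cv^2))
  noise <- rlnorm(nrow(tx), -sdlog^2 / 2, sdlog)
  lam <- depth * tx_length(tx) * config$parclip_factor * fold * noise
  lam[tx$is_spikein] <- 0
  reads <- rpois(nrow(tx), lam)
  count_records(setNames(reads, tx$transcript_id), tx,
                assay = "parclip", condition = condition, replicate = replicate)
}

#' @rdname simulate_parclip
#' @export
simulate_rnaseq <- function(tx, truth, config = sim_config(),
                            condition = c("control", "stress_500", "stress_200"),
                            replicate = 1L) {
  condition <- match.arg(condition)
  set.seed(config$seed + 7000L +
             100L * match(condition, c("control", "stress_200", "stress_500")) +
             replicate)
  depth <- sim_depths(tx, truth,
                      if (condition == "control") "control" else "stress_500",
                      config)
  lam <- depth * tx_length(tx) * config$rna_factor
  reads <- rpois(nrow(tx), lam)
  count_records(setNames(reads, tx$transcript_id), tx,
                assay = "rna_input", condition = condition, replicate = replicate)
}

#' Simulate the complete dataset
#'
#' Generates the transcriptome, plants ground truth, and simulates every
#' library the pipeline consumes: m6A-IP and input coverage (control and
#' harsh stress), RPF coverage (control and mild stress), RNA-seq counts and
#' PAR-CLIP counts, each in `n_replicates` replicates. Fully deterministic
#' under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List: `config`, `transcriptome`, `motifs`, `truth`, and nested
#'   library lists `m6a` (`[[condition]]$ip` / `$input`, lists of replicate
#'   `coverage_set`s), `rpf` (`[[condition]]`, replicate list), `rna` and
#'   `parclip` (`[[condition]]`, lists of count tibbles).
#' @export
simulate_dataset <- function(config = sim_config()) {
  tx <- simulate_transcriptome(config)
  motifs <- scan_drach(tx)
  truth <- plant_truth(tx, motifs, config)
  reps <- seq_len(config$n_replicates)
  m6a <- lapply(c(control = "control", stress_500 = "stress_500"), function(cond)
    list(ip = lapply(reps, function(r)
           simulate_coverage(tx, truth, config, "m6a_ip", cond, r)),
         input = lapply(reps, function(r)
           simulate_coverage(tx, truth, config, "rna_input", cond, r))))
  rpf <- lapply(c(control = "control", stress_200 = "stress_200"), function(cond)
    lapply(reps, function(r) simulate_rpf(tx, truth, config, cond, r)))
  rna <- lapply(c(control = "control", stress_500 = "stress_500"), function(cond)
    lapply(reps, function(r) simulate_rnaseq(tx, truth, config, cond, r)))
  parclip <- lapply(c(control = "control", stress_500 = "stress_500"), function(cond)
    lapply(reps, function(r) simulate_parclip(tx, truth, config, cond, r)))
  list(config = config, transcriptome = tx, motifs = motifs, truth = truth,
       m6a = m6a, rpf = rpf, rna = rna, parclip = parclip)
}
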