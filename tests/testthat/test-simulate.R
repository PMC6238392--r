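test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_transcripts = 30, n_mitochondrial = 2, seed = 5,
                    n_spikeins = 6, spikein_depths = 2^seq(-2, 4, length.out = 6))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$transcriptome, b$transcriptome)
  expect_identical(a$truth, b$truth)
  expect_identical(a$m6a$control$ip[[1]]$counts, b$m6a$control$ip[[1]]$counts)
  expect_identical(a$parclip$stress_500[[2]], b$parclip$stress_500[[2]])
})

test_that("generated transcripts carry a DRACH motif in every nonempty segment", {
  ds <- small_dataset()
  tx <- ds$transcriptome
  expect_equal(nrow(tx), 80L + 12L)
  expect_equal(sum(tx$is_mitochondrial), 4L)
  expect_equal(sum(tx$is_spikein), 12L)
  mrna <- tx[!tx$is_spikein, ]
  motifs <- ds$motifs
  for (i in seq_len(nrow(mrna))) {
    id <- mrna$transcript_id[i]
    regs <- motifs$region[motifs$transcript_id == id]
    expect_true("utr5" %in% regs)
    expect_true("cds" %in% regs)
    expect_true("utr3" %in% regs)
  }
  # CDS lengths are codon multiples
  expect_true(all(tx$cds_len %% 3L == 0L))
})

test_that("planted stress methylation is a superset of control, 5'-shifted", {
  ds <- small_dataset()
  meth <- ds$truth$methylation
  ctl <- meth[meth$condition == "control", ]
  str <- meth[meth$condition == "stress_500", ]
  key <- function(d) paste(d$transcript_id, d$start)
  expect_true(all(key(ctl) %in% key(str)))
  expect_gt(nrow(str), nrow(ctl))
  gained <- str[!key(str) %in% key(ctl), ]
  # additions live in the 5'UTR or the 5' fifth of the CDS, on SG clients only
  expect_true(all(gained$region %in% c("utr5", "cds")))
  clients <- ds$truth$sg$transcript_id[ds$truth$sg$is_sg_client]
  expect_true(all(gained$transcript_id %in% clients))
  i <- match(gained$transcript_id, ds$transcriptome$transcript_id)
  rel <- (gained$a_pos - ds$transcriptome$utr5_len[i]) /
    ds$transcriptome$cds_len[i]
  expect_true(all(gained$region == "utr5" | rel < 0.2))
})

test_that("IP coverage is enriched only around planted sites", {
  cfg <- small_config()
  ds <- small_dataset()
  tx <- ds$transcriptome
  meth <- ds$truth$methylation
  with_sites <- intersect(
    meth$transcript_id[meth$condition == "control"],
    tx$transcript_id[!tx$is_spikein])
  id <- with_sites[1]
  ip <- ds$m6a$control$ip[[1]]$counts[[id]]
  input <- ds$m6a$control$input[[1]]$counts[[id]]
  a_pos <- meth$a_pos[meth$condition == "control" & meth$transcript_id == id]
  near <- unique(unlist(lapply(a_pos, function(p)
    pmax(1L, p - 5L):pmin(length(ip), p + 5L))))
  ratio_near <- mean(ip[near]) / mean(input[near])
  far <- setdiff(seq_along(ip), unique(unlist(lapply(a_pos, function(p)
    pmax(1L, p - 30L):pmin(length(ip), p + 30L)))))
  ratio_far <- mean(ip[far]) / mean(input[far])
  expect_gt(ratio_near, 4)          # enrichment 8 at the apex, kernel-averaged
  expect_lt(abs(ratio_far - 1), 0.2)
})

test_that("RPF profiles place stalled mass in the first 100 CDS nt and spare mitochondria", {
  ds <- small_dataset()
  tx <- ds$transcriptome
  tr <- ds$truth$translation
  stalled <- tr$transcript_id[tr$condition == "stress_200" & tr$class == "stalled"]
  id <- stalled[1]
  i <- match(id, tx$transcript_id)
  prof <- ds$rpf$stress_200[[1]]$counts[[id]]
  cds <- prof[(tx$utr5_len[i] + 1L):(tx$utr5_len[i] + tx$cds_len[i])]
  frac <- sum(cds[1:100]) / sum(cds)
  expect_gt(frac, 0.75)             # planted 0.85 with Poisson noise
  expect_equal(sum(prof[seq_len(tx$utr5_len[i])]), 0)  # no footprints in UTRs

  res <- small_result()
  mito <- res$translation$tables$stress_200
  mito <- mito[mito$is_mitochondrial, ]
  expect_true(all(abs(log2(mito$rd_norm)) < 1))  # rd_norm ~ 1 by construction
})

test_that("PAR-CLIP counts multiply client expectation by the planted fold", {
  cfg <- sim_config(n_transcripts = 150, n_mitochondrial = 2, parclip_cv = 1e-6,
                    seed = 19, n_spikeins = 4,
                    spikein_depths = 2^seq(0, 3, length.out = 4))
  tx <- simulate_transcriptome(cfg)
  motifs <- scan_drach(tx)
  truth <- plant_truth(tx, motifs, cfg)
  ctl <- simulate_parclip(tx, truth, cfg, "control")
  str <- simulate_parclip(tx, truth, cfg, "stress_500")
  e <- parclip_enrichment(str, ctl, epsilon = 0)
  e <- e[e$transcript_id %in% truth$sg$transcript_id, ]  # mRNAs, not spike-ins
  cl <- truth$sg$is_sg_client[match(e$transcript_id, truth$sg$transcript_id)]
  # with (near) zero lognormal noise, Poisson counts put clients near log2 = 2
  expect_equal(median(e$log2_enrichment[cl]), 2, tolerance = 0.1)
  expect_equal(median(e$log2_enrichment[!cl]), 0, tolerance = 0.1)
})
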