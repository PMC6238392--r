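toy_counts <- function(reads, tx, condition = "control", replicate = 1L,
                       assay = "parclip", library_size = NULL) {
  count_records(setNames(reads, tx$transcript_id), tx, assay, condition,
                replicate, library_size = library_size)
}

test_that("spike-in threshold is the minimum RPKM among always-detected spike-ins", {
  tx <- toy_transcriptome(6)
  spikes <- tx$transcript_id[1:3]
  r1 <- toy_counts(c(5, 20, 80, 1000, 2000, 3000), tx)
  r2 <- toy_counts(c(6, 18, 85, 1100, 1900, 3100), tx, replicate = 2L)
  thr <- spikein_threshold(list(r1, r2), spikes)
  merged <- merge_replicates(r1, r2)
  expect_equal(thr, min(merged$rpkm[merged$transcript_id %in% spikes]))

  # a spike-in dropping to zero in one replicate is ignored for the min
  r2z <- toy_counts(c(0, 18, 85, 1100, 1900, 3100), tx, replicate = 2L)
  thr2 <- spikein_threshold(list(r1, r2z), spikes)
  m2 <- merge_replicates(r1, r2z)
  expect_equal(thr2, min(m2$rpkm[m2$transcript_id %in% spikes[2:3]]))

  rz <- toy_counts(c(0, 0, 0, 1000, 2000, 3000), tx)
  expect_error(spikein_threshold(list(rz), spikes), "uncalibrated")
})

test_that("detection is inclusive at the threshold and monotone in it", {
  tx <- toy_transcriptome(4)
  rec <- toy_counts(c(0, 10, 20, 40), tx)
  thr <- rec$rpkm[2]
  det <- detect_expressed(rec, thr)
  expect_true(rec$transcript_id[2] %in% det)       # rpkm == threshold detected
  expect_false(rec$transcript_id[1] %in% det)      # zero never detected
  for (f in c(1.5, 3, 10))
    expect_true(all(detect_expressed(rec, thr * f) %in% det))
})

test_that("replicate merging sums counts after the concordance gate", {
  tx <- toy_transcriptome(6)
  r1 <- toy_counts(c(10, 20, 40, 80, 160, 320), tx)
  m <- merge_replicates(r1, r1)
  expect_equal(m$reads, 2 * r1$reads)
  expect_equal(m$library_size[1], 2 * r1$library_size[1])
  expect_equal(m$rpkm, r1$rpkm)                    # doubling cancels in RPKM

  r3 <- toy_counts(3 * c(10, 20, 40, 80, 160, 320), tx, replicate = 2L)
  expect_silent(merge_replicates(r1, r3))          # scaling invariance of r^2

  set.seed(99)
  tx200 <- toy_transcriptome(200, seed = 42)
  a <- toy_counts(rpois(200, 50) + 1, tx200)
  b <- toy_counts(sample(rpois(200, 50) + 1), tx200, replicate = 2L)
  expect_error(merge_replicates(a, b), "refused")
})

test_that("PAR-CLIP enrichment scores log2 stress/control with pseudocount", {
  tx <- toy_transcriptome(3)
  ctl <- toy_counts(c(10, 10, 0), tx, "control", library_size = 1e6)
  str <- toy_counts(c(40, 10, 8), tx, "stress_500", library_size = 1e6)
  e <- parclip_enrichment(str, ctl, epsilon = 0, log2_cutoff = 2)
  expect_equal(e$log2_enrichment[1], 2)
  expect_true(e$is_sg_client[1])                   # log2 == cutoff is inclusive
  expect_equal(e$log2_enrichment[2], 0)
  expect_false(e$is_sg_client[2])

  # pseudocount arithmetic: control 0, stress 8, epsilon 0.5 in RPKM units
  len_kb <- (tx_len <- 180) / 1e3
  eps <- 0.5
  e2 <- parclip_enrichment(str, ctl, epsilon = eps, log2_cutoff = 2)
  rpkm8 <- 8 * 1e9 / (1e6 * 180)
  expect_equal(e2$log2_enrichment[3], log2((rpkm8 + eps) / eps))
  expect_true(e2$is_sg_client[3])

  # antisymmetry: swapping stress and control negates enrichment exactly
  set.seed(12)
  tx2 <- toy_transcriptome(50, seed = 3)
  a <- toy_counts(rpois(50, 40) + 1, tx2, "control")
  b <- toy_counts(rpois(50, 90) + 1, tx2, "stress_500")
  eab <- parclip_enrichment(b, a, epsilon = 0.25)
  eba <- parclip_enrichment(a, b, epsilon = 0.25)
  expect_equal(eab$log2_enrichment, -eba$log2_enrichment)
})

test_that("the SG metagene set is a provenance-tagged union", {
  sg <- merge_sg_set(c("A", "B"), c("B", "C"))
  expect_equal(nrow(sg), 3L)
  expect_equal(sg$provenance[sg$transcript_id == "B"], "both")
  expect_equal(sg$provenance[sg$transcript_id == "A"], "parclip")
  expect_equal(sg$provenance[sg$transcript_id == "C"], "stalled")
  expect_equal(merge_sg_set(c("A", "B"), character(0))$transcript_id, c("A", "B"))
  expect_equal(nrow(merge_sg_set(letters[1:10], letters[11:15])), 15L)
  # provenance tags partition the union
  expect_equal(sum(table(sg$provenance)), nrow(sg))
})
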