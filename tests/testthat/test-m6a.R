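test_that("mean normalization behaves on constant, sparse and zero profiles", {
  expect_equal(normalize_profile(rep(8, 6)), rep(1, 6))
  expect_equal(normalize_profile(c(0, 0, 30)), c(0, 0, 3))
  expect_equal(normalize_profile(rep(0, 4)), rep(0, 4))
})

test_that("adjusted profile subtracts normalized input and applies the raw-coverage filter", {
  a <- adjust_profile(c(30, 10, 20), c(5, 10, 15))
  expect_equal(a$values, c(1.0, -0.5, -0.5))
  expect_equal(a$excluded, "none")

  # identical IP and input cancel exactly
  p <- c(20, 40, 20, 60)
  expect_equal(adjust_profile(p, p)$values, rep(0, 4))

  # the <15 exclusion is on the raw IP maximum
  expect_equal(adjust_profile(rep(14, 10), rep(1, 10))$excluded, "low_coverage")
  expect_equal(adjust_profile(rep(15, 10), rep(1, 10))$excluded, "none")
  expect_error(adjust_profile(1:3, 1:4), "length")
})

test_that("peak calling finds plateaus above tau wider than min_width", {
  expect_equal(nrow(call_peaks(rep(0, 100))), 0L)

  v <- rep(0, 100); v[31:50] <- 2
  pk <- call_peaks(v, tau = 0.5, min_width = 10)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 30L)
  expect_equal(pk$end, 50L)
  expect_equal(pk$height, 2)

  v5 <- rep(0, 100); v5[11:15] <- 2   # run of 5 < min_width
  expect_equal(nrow(call_peaks(v5, min_width = 10)), 0L)

  # raising tau never increases total covered positions
  set.seed(5)
  v <- abs(rnorm(500))
  covered <- function(tau) { p <- call_peaks(v, tau, 3); sum(p$end - p$start) }
  taus <- seq(0, 2, by = 0.25)
  expect_true(all(diff(vapply(taus, covered, numeric(1))) <= 0))
})

test_that("peaks are assigned to every covered motif, deduplicated", {
  motifs <- tibble::tibble(transcript_id = "t1", start = c(10L, 20L, 50L),
                           a_pos = c(12L, 22L, 52L),
                           region = c("cds", "cds", "cds"))
  peaks <- tibble::tibble(transcript_id = "t1", start = 5L, end = 30L, height = 2)
  calls <- assign_peaks_to_motifs(peaks, motifs, "control")
  expect_equal(sort(calls$start), c(10L, 20L))  # one peak, two motifs -> two calls

  # peak covering no motif is dropped
  far <- tibble::tibble(transcript_id = "t1", start = 80L, end = 95L, height = 1)
  expect_equal(nrow(assign_peaks_to_motifs(far, motifs, "control")), 0L)

  # two overlapping peaks over the same motif give a single call
  two <- tibble::tibble(transcript_id = "t1", start = c(5L, 8L), end = c(18L, 20L),
                        height = c(1, 3))
  calls2 <- assign_peaks_to_motifs(two, motifs, "control")
  expect_equal(calls2$start, 10L)
  expect_equal(nrow(calls2), 1L)

  # boundary: pentamer span [start, start+5) must intersect the peak
  edge <- tibble::tibble(transcript_id = "t1", start = 14L, end = 16L, height = 1)
  expect_equal(assign_peaks_to_motifs(edge, motifs, "control")$start, 10L)
  after <- tibble::tibble(transcript_id = "t1", start = 15L, end = 18L, height = 1)
  expect_equal(nrow(assign_peaks_to_motifs(after, motifs, "control")), 0L)
})

test_that("m6A/A summaries divide calls by predicted motifs and flag motif-free transcripts", {
  motifs <- tibble::tibble(transcript_id = rep(c("a", "b"), c(10L, 7L)),
                           start = c(10L * (1:10), 10L * (1:7)),
                           a_pos = c(10L * (1:10), 10L * (1:7)) + 2L)
  calls <- tibble::tibble(transcript_id = c("a", "a"), start = c(10L, 20L),
                          condition = "control")
  s <- methylation_summary(calls, motifs, transcript_ids = c("a", "b", "c"))
  expect_equal(s$ratio[s$transcript_id == "a"], 0.2)
  expect_equal(s$ratio[s$transcript_id == "b"], 0)
  expect_true(is.na(s$ratio[s$transcript_id == "c"]))
  expect_true(s$flagged[s$transcript_id == "c"])
  expect_true(all(s$n_methylated <= s$n_predicted))
})

test_that("stress-induced sites are the stress-only calls", {
  ctl <- tibble::tibble(transcript_id = "t", start = 10L, condition = "control")
  str <- tibble::tibble(transcript_id = "t", start = c(10L, 30L), condition = "stress_500")
  ind <- stress_induced_sites(ctl, str)
  expect_equal(ind$start, 30L)
  expect_equal(nrow(stress_induced_sites(str, str)), 0L)
  expect_equal(nrow(stress_induced_sites(ctl, ctl[0, ])), 0L)  # losses not induced
})

test_that("metagene methylation pools per-bin ratios and reports empty bins as NA", {
  tx <- transcriptome("t1", "g1",
                      paste(rep("GGACT", 40), collapse = ""), 20L, 150L, 30L)
  motifs <- scan_drach(tx)
  bins <- segment_bins(2, 5, 2)
  # methylate exactly one of the motifs; its bin must get ratio > 0
  calls <- motifs[3, ]; calls$condition <- "control"
  mg <- metagene_methylation(motifs, calls, tx, bins)
  expect_equal(nrow(mg), 9L)
  expect_equal(sum(mg$n_predicted), nrow(motifs))  # conservation over bins
  expect_equal(sum(mg$n_methylated), 1L)
  expect_true(all(is.na(mg$ratio) | (mg$ratio >= 0 & mg$ratio <= 1)))

  # one transcript, 1 methylated of 2 predicted in the same bin -> 0.5
  tx2 <- transcriptome("t2", "g2",
                       paste0("GGACTGGACT", paste(rep("C", 120), collapse = "")),
                       10L, 120L, 0L)
  m2 <- scan_drach(tx2)
  expect_equal(nrow(m2), 2L)
  c2 <- m2[1, ]; c2$condition <- "control"
  mg2 <- metagene_methylation(m2, c2, tx2, segment_bins(1, 1, 1))
  expect_equal(mg2$ratio[mg2$segment == "utr5"], 0.5)
  expect_true(is.na(mg2$ratio[mg2$segment == "utr3"]))  # empty segment: missing, not zero
})

test_that("identical IP and input libraries yield zero calls everywhere", {
  ds <- small_dataset()
  ip <- ds$m6a$control$ip[[1]]
  same <- ip; same$assay <- "rna_input"
  res <- call_methylation(ip, same, ds$motifs)
  expect_equal(nrow(res$calls), 0L)
  expect_equal(nrow(res$peaks), 0L)
})
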