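test_that("RPM and RPKM follow their definitions", {
  expect_equal(compute_rpm(10, 1e6), 10)
  expect_equal(compute_rpkm(100, 1e6, 1000), 100)
  expect_equal(compute_rpm(0, 5e6), 0)
  expect_error(compute_rpm(1, 0), "positive")
  expect_error(compute_rpkm(1, 10, 0), "positive")
})

test_that("ribosome density divides RPF by mRNA RPM and guards zero mRNA", {
  expect_equal(compute_rd(4, 2), 2)
  expect_equal(compute_rd(0, 5), 0)
  expect_true(is.na(compute_rd(3, 0)))
})

test_that("RD normalization divides by the mitochondrial median", {
  rec <- tibble::tibble(rd_raw = c(1, 2, 3, 4),
                        is_mitochondrial = c(TRUE, TRUE, TRUE, FALSE))
  out <- normalize_rd(rec)
  expect_equal(out$rd_norm[4], 2)          # median mito RD = 2
  expect_equal(out$rd_norm[1:3], c(0.5, 1, 1.5))
  rec1 <- tibble::tibble(rd_raw = c(2, 2), is_mitochondrial = c(TRUE, FALSE))
  expect_equal(normalize_rd(rec1)$rd_norm, c(1, 1))
  expect_error(normalize_rd(tibble::tibble(rd_raw = 1, is_mitochondrial = FALSE)),
               "mitochondrial")
})

test_that("translation ratio distinguishes 5' pile-ups from uniform coverage", {
  utr5 <- 50L; cds <- 1000L
  # all reads within the first 100 CDS nt
  stalled <- c(rep(0, utr5), rep(0.5, 100), rep(0, cds - 100), rep(0, 20))
  expect_equal(compute_rt(stalled, utr5, cds), 1.0)

  uniform <- c(rep(0, utr5), rep(1, cds), rep(0, 20))
  expect_equal(compute_rt(uniform, utr5, cds), 0.1)
  expect_equal(compute_rt(uniform, utr5, cds, mode = "literal_rpkm"), 1.0)

  # literal mode equals fraction scaled by CDS length / window
  set.seed(21)
  prof <- c(rep(0, utr5), rpois(cds, 2), rep(0, 20))
  f <- compute_rt(prof, utr5, cds)
  l <- compute_rt(prof, utr5, cds, mode = "literal_rpkm")
  expect_equal(l, f * cds / 100)
  expect_true(f >= 0 && f <= 1)

  expect_true(is.na(compute_rt(rep(0, 200), 20L, 150L)))
})

test_that("classification thresholds R_t at 0.5 inclusive and survives rescaling", {
  expect_equal(classify_translation(c(0.05, 0.5, 0.51, NA)),
               c("translated", "translated", "stalled", "undetected"))
  # invariant to library-size rescaling of the profile
  utr5 <- 10L; cds <- 300L
  prof <- c(rep(0, utr5), rpois(cds, 3), rep(0, 5))
  for (sc in c(0.5, 1, 7)) {
    expect_equal(compute_rt(prof * sc, utr5, cds), compute_rt(prof, utr5, cds))
  }
})

test_that("start-aligned metagene density averages genes with equal weight", {
  tx <- dplyr::bind_rows(
    transcriptome("a", "a", paste(rep("A", 700), collapse = ""), 60L, 600L, 40L),
    transcriptome("b", "b", paste(rep("A", 700), collapse = ""), 60L, 600L, 40L))
  mk <- function(at) { v <- numeric(700); v[60L + at + 1L] <- 1; v }
  cov <- coverage_set(list(a = mk(0L), b = mk(100L)), "rpf", "control")
  mg <- metagene_density(cov, tx, window = c(-50L, 500L))
  expect_equal(mg$mean_density[mg$offset == 0], 0.5)
  expect_equal(mg$mean_density[mg$offset == 100], 0.5)
  expect_equal(sum(mg$mean_density), 1)
  expect_equal(mg$cumulative[mg$offset == 50], 0.5)   # step at 0, next at 100
  expect_equal(mg$cumulative[mg$offset == 500], 1)
  expect_true(all(diff(mg$cumulative) >= 0))

  # uniform profiles give a linear cumulative curve
  covu <- coverage_set(list(a = rep(1, 700), b = rep(1, 700)), "rpf", "control")
  mgu <- metagene_density(covu, tx, window = c(-50L, 500L))
  expect_equal(max(abs(diff(mgu$cumulative) - 1 / 551)), 0, tolerance = 1e-12)
})

test_that("rd_shift recovers exact fold changes", {
  mk <- function(rd) tibble::tibble(transcript_id = paste0("t", 1:4),
                                    rd_norm = rd)
  expect_equal(rd_shift(mk(c(1, 2, 3, 4)), mk(c(1, 2, 3, 4))), 0)
  expect_equal(rd_shift(mk(c(4, 8, 12, 16)), mk(c(1, 2, 3, 4))), 2)
  expect_error(rd_shift(mk(rep(NA_real_, 4)), mk(c(1, 2, 3, 4))), "no gene")
})
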