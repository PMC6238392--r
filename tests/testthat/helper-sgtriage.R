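# Shared fixtures and independent oracles.

# Independent DRACH oracle: explicit enumeration of the 18-pentamer alphabet
# (built here by nested combination, not from drach_pentamers()) and a plain
# window scan against it.
oracle_pentamers <- local({
  out <- character(0)
  for (d in c("A", "G", "T")) for (r in c("A", "G")) for (h in c("T", "A", "C"))
    out <- c(out, paste0(d, r, "A", "C", h))
  sort(out)
})

oracle_scan <- function(seq) {
  n <- nchar(seq)
  if (n < 5L) return(integer(0))
  win <- substring(seq, 1:(n - 4L), 5:n)
  which(win %in% oracle_pentamers) - 1L  # 0-based starts
}

# Exact Mann-Whitney oracle: full enumeration of all C(n1+n2, n1) group
# assignments of the pooled sample (tie-free inputs only).
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(u = u_obs, p_two_sided = min(1, 2 * min(p_le, p_ge)))
}

# Hypergeometric upper-tail oracle by direct combinatorial summation.
oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# A tiny hand-built transcriptome for unit tests: geometry is fixed, the
# sequence is random but seeded.
toy_transcriptome <- function(n = 5L, seed = 11L) {
  set.seed(seed)
  utr5 <- rep(20L, n); cds <- rep(120L, n); utr3 <- rep(40L, n)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), utr5[i] + cds[i] + utr3[i],
                 replace = TRUE), collapse = ""), character(1))
  transcriptome(sprintf("t%02d", seq_len(n)), sprintf("g%02d", seq_len(n)),
                seqs, utr5, cds, utr3)
}

# Cached datasets so expensive simulations run once per test session.
.sg_cache <- new.env(parent = emptyenv())

small_config <- function() sim_config(n_transcripts = 80L, n_mitochondrial = 4L,
                                      n_spikeins = 12L,
                                      spikein_depths = 2^seq(-4, 6, length.out = 12L),
                                      seed = 7L)

small_dataset <- function() {
  if (is.null(.sg_cache$small)) .sg_cache$small <- simulate_dataset(small_config())
  .sg_cache$small
}

small_result <- function() {
  if (is.null(.sg_cache$small_res))
    .sg_cache$small_res <- run_pipeline(small_dataset())
  .sg_cache$small_res
}

default_dataset <- function() {
  if (is.null(.sg_cache$default)) .sg_cache$default <- simulate_dataset(sim_config())
  .sg_cache$default
}

default_result <- function() {
  if (is.null(.sg_cache$default_res))
    .sg_cache$default_res <- run_pipeline(default_dataset())
  .sg_cache$default_res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
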