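#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples (two-sided by default). The p-value is
#' exact (full enumeration) when `n1 + n2 <= 12` and the pooled sample is
#' tie-free; otherwise the normal approximation with midrank tie correction
#' and continuity correction is used.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List: `statistic` (U for `x`), `p_value`, `method`, `n1`, `n2`,
#'   `exact` (logical).
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2 <= 12L) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "mann_whitney_u", n1 = n1, n2 = n2, exact = exact)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing at least `k` marked elements when `n` elements are
#' drawn without replacement from a universe of `N` containing `K` marked
#' ones: P(X >= k). Computed via the stable distribution-function routine
#' (log-space internally), suitable for the tiny p-values typical of gene-set
#' overlaps.
#'
#' @param k Observed overlap.
#' @param K Size of the first set (marked elements).
#' @param n Size of the second set (draws).
#' @param N Universe size.
#' @return List: `statistic` (= k), `p_value`, `method`, `k`, `K`, `n`, `N`.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent sizes: need 0 <= k <= min(K, n) <= N")
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(statistic = k, p_value = p, method = "hypergeometric_tail",
       k = k, K = K, n = n, N = N)
}

#' Pearson correlation with r-squared
#'
#' @param x,y Numeric vectors of equal length (n >= 2), each with nonzero
#'   variance.
#' @return List: `r`, `r_squared`, `n`, `method`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  r <- cor(x, y, method = "pearson")
  list(r = r, r_squared = r^2, n = length(x), method = "pearson")
}

#' Venn region counts for up to three named sets
#'
#' Exact element counts for every exclusive intersection region; the counts
#' sum to the size of the union.
#'
#' @param sets Named list of 1-3 vectors (coerced to character sets).
#' @return Tibble with one row per region: logical membership columns (one
#'   per set) and `count`.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 1L || length(sets) > 3L)
    stop("overlap_counts supports 1 to 3 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(grid) <- names(sets)
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  grid$count <- apply(grid, 1L, function(row) {
    sum(apply(member, 1L, function(m) all(m == as.logical(row[names(sets)]))))
  })
  tibble::as_tibble(grid)
}
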