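#' The DRACH consensus pentamers
#'
#' m6A is installed at the degenerate DRACH consensus (D = A/G/U, R = A/G,
#' then A-C, H = U/A/C); the methylated base is the central adenosine. In the
#' DNA alphabet used throughout this package (U read as T) the consensus is
#' `[AGT][AG]AC[TAC]`, giving 3 x 2 x 1 x 1 x 3 = 18 pentamers.
#'
#' @return Character vector of the 18 DRACH pentamers (DNA alphabet), sorted.
#' @export
#' @examples
#' length(drach_pentamers())  # 18
drach_pentamers <- function() {
  g <- expand.grid(d = c("A", "G", "T"), r = c("A", "G"),
                   a = "A", c = "C", h = c("T", "A", "C"),
                   stringsAsFactors = FALSE)
  sort(paste0(g$d, g$r, g$a, g$c, g$h))
}

#' Build a transcriptome table
#'
#' A transcriptome is a tibble with one row per transcript: its sequence and
#' 5'UTR/CDS/3'UTR geometry plus gene-class flags. Segment lengths must sum to
#' the sequence length; sequences are uppercased with U converted to T.
#'
#' @param transcript_id,gene_id Character vectors.
#' @param sequence Character vector over A/C/G/T (U accepted, read as T).
#' @param utr5_len,cds_len,utr3_len Segment lengths in nucleotides;
#'   `utr5_len + cds_len + utr3_len` must equal `nchar(sequence)` and
#'   `cds_len >= 3`.
#' @param is_mitochondrial,is_spikein Logical flags (recycled).
#' @return A tibble of class `transcriptome`.
#' @export
transcriptome <- function(transcript_id, gene_id, sequence,
                          utr5_len, cds_len, utr3_len,
                          is_mitochondrial = FALSE, is_spikein = FALSE) {
  sequence <- chartr("u", "T", chartr("U", "T", toupper(sequence)))
  tx <- tibble::tibble(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    sequence = unname(sequence),
    utr5_len = as.integer(utr5_len),
    cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    is_mitochondrial = as.logical(is_mitochondrial),
    is_spikein = as.logical(is_spikein)
  )
  validate_transcriptome(tx)
  class(tx) <- c("transcriptome", class(tx))
  tx
}

validate_transcriptome <- function(tx) {
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(tx$transcript_id[duplicated(tx$transcript_id)]), collapse = ", "))
  if (any(tx$utr5_len < 0L) || any(tx$utr3_len < 0L) || any(tx$cds_len < 3L))
    stop("segment lengths must satisfy utr5_len >= 0, cds_len >= 3, utr3_len >= 0")
  tot <- tx$utr5_len + tx$cds_len + tx$utr3_len
  bad <- tot != nchar(tx$sequence)
  if (any(bad))
    stop("segment lengths do not sum to sequence length for: ",
         paste(head(tx$transcript_id[bad], 5L), collapse = ", "))
  if (any(grepl("[^ACGT]", tx$sequence)))
    stop("sequences must contain only A/C/G/T (U is converted on input)")
  invisible(tx)
}

tx_length <- function(tx) tx$utr5_len + tx$cds_len + tx$utr3_len

#' Scan sequences for DRACH motifs
#'
#' Exhaustive consensus matching: every 5-nt window matching
#' `[AGT][AG]AC[TAC]` is reported, overlaps included. Matching is done with
#' IUPAC degenerate-base matching (`DRACH` as a DNA pattern). When a
#' transcriptome is given, each site is assigned to the 5'UTR/CDS/3'UTR by the
#' position of its methylatable adenosine (`a_pos = start + 2`): a
#' junction-spanning pentamer belongs to the segment holding the A, since the
#' methyl mark sits on that base.
#'
#' @param x A `transcriptome` tibble, or a (optionally named) character vector
#'   of sequences.
#' @return Tibble with columns `transcript_id`, `start` (0-based offset of the
#'   pentamer's first base), `a_pos` (`start + 2`), `pentamer`, and — when
#'   geometry is available — `region` (one of `"utr5"`, `"cds"`, `"utr3"`).
#'   Sorted by transcript then start. Sequences shorter than 5 nt simply yield
#'   no rows.
#' @export
#' @examples
#' scan_drach(c(tx1 = "GGACT"))  # one site, start 0, a_pos 2
scan_drach <- function(x) {
  if (inherits(x, "transcriptome") || (is.data.frame(x) && "sequence" %in% names(x))) {
    seqs <- setNames(x$sequence, x$transcript_id)
    geom <- x
  } else {
    nm <- names(x)
    seqs <- chartr("u", "T", chartr("U", "T", toupper(as.character(x))))
    names(seqs) <- if (is.null(nm)) paste0("seq", seq_along(seqs)) else nm
    geom <- NULL
  }
  subject <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vmatchPattern("DRACH", subject, fixed = FALSE)
  starts <- lapply(hits, IRanges::start)
  n <- lengths(starts)
  out <- tibble::tibble(
    transcript_id = rep(names(seqs), n),
    start = unlist(starts, use.names = FALSE) - 1L  # to 0-based
  )
  if (nrow(out) == 0L) {
    out$a_pos <- integer(0); out$pentamer <- character(0)
  } else {
    out$a_pos <- out$start + 2L
    out$pentamer <- unname(substr(seqs[out$transcript_id], out$start + 1L,
                                  out$start + 5L))
  }
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  if (!is.null(geom)) {
    i <- match(out$transcript_id, geom$transcript_id)
    out$region <- assign_region(out$a_pos, geom$utr5_len[i], geom$cds_len[i],
                                geom$utr3_len[i])
  }
  out
}

#' Assign a transcript position to its segment
#'
#' Half-open boundaries: position `p` is `"utr5"` if `p < utr5_len`, `"cds"`
#' if `utr5_len <= p < utr5_len + cds_len`, else `"utr3"`. Vectorized.
#'
#' @param position 0-based nucleotide offset(s).
#' @param utr5_len,cds_len,utr3_len Segment lengths (recycled).
#' @return Character vector of region labels.
#' @export
assign_region <- function(position, utr5_len, cds_len, utr3_len) {
  total <- utr5_len + cds_len + utr3_len
  if (any(position < 0L | position >= total))
    stop("position out of range [0, transcript length)")
  ifelse(position < utr5_len, "utr5",
         ifelse(position < utr5_len + cds_len, "cds", "utr3"))
}

#' Segment binning scheme
#'
#' Bin counts per transcript segment used for metagene profiles. Each segment
#' of length L is split into n contiguous near-equal bins; bin b (0-based)
#' covers positions `[floor(bL/n), floor((b+1)L/n))`, so bin sizes differ by
#' at most 1 nt.
#'
#' @param n_utr5,n_cds,n_utr3 Positive bin counts. Defaults 10/30/10, roughly
#'   proportional to typical human segment lengths.
#' @return List of class `segment_bins`.
#' @export
segment_bins <- function(n_utr5 = 10L, n_cds = 30L, n_utr3 = 10L) {
  stopifnot(n_utr5 >= 1L, n_cds >= 1L, n_utr3 >= 1L)
  structure(list(utr5 = as.integer(n_utr5), cds = as.integer(n_cds),
                 utr3 = as.integer(n_utr3)), class = "segment_bins")
}

# 0-based bin index of 0-based positions within a segment of length L split
# into n bins. Errors on over-binning (n > L).
bin_index <- function(position, L, n) {
  if (L <= 0L) stop("empty segment has no bins")
  if (n > L) stop("over-binning: ", n, " bins requested for a ", L, "-nt segment")
  breaks <- floor((0:n) * L / n)
  findInterval(position, breaks, rightmost.closed = FALSE) - 1L
}

#' Map every position of a transcript to its (segment, bin)
#'
#' @param tx_row One row of a transcriptome (or a list with `utr5_len`,
#'   `cds_len`, `utr3_len`).
#' @param bins A [segment_bins()] scheme.
#' @return Tibble with columns `position` (0-based), `segment`, `bin`
#'   (0-based within segment). Zero-length segments contribute no rows.
#' @export
bin_segments <- function(tx_row, bins = segment_bins()) {
  lens <- c(utr5 = tx_row$utr5_len, cds = tx_row$cds_len, utr3 = tx_row$utr3_len)
  offs <- c(0L, cumsum(lens))[1:3]
  parts <- lapply(c("utr5", "cds", "utr3"), function(seg) {
    L <- lens[[seg]]
    if (L == 0L) return(NULL)
    pos <- seq_len(L) - 1L
    tibble::tibble(position = pos + offs[[match(seg, c("utr5", "cds", "utr3"))]],
                   segment = seg, bin = bin_index(pos, L, bins[[seg]]))
  })
  dplyr::bind_rows(parts)
}

#' Pick the longest isoform per gene
#'
#' For genes with multiple mRNA isoforms the longest one is kept; ties are
#' broken by the lexicographically smallest transcript_id.
#'
#' @param tx A transcriptome tibble (possibly several isoforms per gene_id).
#' @return The filtered transcriptome, one row per gene.
#' @export
select_longest_isoform <- function(tx) {
  if (nrow(tx) == 0L) stop("empty transcriptome")
  len <- tx_length(tx)
  ord <- order(tx$gene_id, -len, tx$transcript_id)
  keep <- tx[ord, , drop = FALSE][!duplicated(tx$gene_id[ord]), , drop = FALSE]
  keep[order(keep$transcript_id), , drop = FALSE]
}
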