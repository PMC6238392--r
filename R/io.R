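#' Read transcript sequences from FASTA
#'
#' The transcript ID is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (U converted to T).
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate transcript IDs in ", path)
  chartr("U", "T", toupper(seqs))
}

#' Read the transcript annotation TSV
#'
#' Tab-delimited with header; required columns: `transcript_id`, `gene_id`,
#' `utr5_len`, `cds_len`, `utr3_len`, `is_mitochondrial` (0/1), `is_spikein`
#' (0/1).
#'
#' @param path Annotation TSV.
#' @param sequences Optional named sequence vector (e.g. from
#'   [read_transcript_fasta()]); when given, a full `transcriptome` is
#'   returned and IDs/lengths are cross-checked.
#' @return A tibble (annotation only) or a `transcriptome`.
#' @export
read_annotation <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  need <- c("transcript_id", "gene_id", "utr5_len", "cds_len", "utr3_len",
            "is_mitochondrial", "is_spikein")
  ann <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L)
    stop("annotation ", path, " lacks columns: ", paste(miss, collapse = ", "))
  ann <- tibble::as_tibble(ann[need])
  if (is.null(sequences)) return(ann)
  absent <- setdiff(names(sequences), ann$transcript_id)
  if (length(absent) > 0L)
    stop("sequences without annotation in ", path, ": ",
         paste(head(absent, 5L), collapse = ", "))
  ann <- ann[match(names(sequences), ann$transcript_id), , drop = FALSE]
  transcriptome(ann$transcript_id, ann$gene_id, sequences[ann$transcript_id],
                ann$utr5_len, ann$cds_len, ann$utr3_len,
                as.logical(ann$is_mitochondrial), as.logical(ann$is_spikein))
}

#' Read per-nucleotide coverage from bedGraph
#'
#' The "chrom" column carries transcript IDs (transcript space, 0-based
#' half-open intervals); interval values are expanded to per-nucleotide
#' vectors over the annotated transcript length, with uncovered positions 0.
#' Overlapping intervals for a transcript, IDs absent from the annotation,
#' or intervals past the annotated length are errors.
#'
#' @param path bedGraph file.
#' @param tx Transcriptome (or annotation tibble with lengths).
#' @param assay,condition,replicate,library_size Passed to [coverage_set()].
#' @return A `coverage_set` covering every annotated non-spike-in transcript
#'   mentioned or not (unmentioned transcripts get all-zero vectors).
#' @export
read_bedgraph <- function(path, tx, assay, condition, replicate = 1L,
                          library_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  ids <- as.character(GenomicRanges::seqnames(gr))
  absent <- setdiff(unique(ids), tx$transcript_id)
  if (length(absent) > 0L)
    stop("bedGraph ", path, " references transcripts absent from annotation: ",
         paste(head(absent, 5L), collapse = ", "))
  lens <- setNames(tx_length(tx), tx$transcript_id)
  starts <- GenomicRanges::start(gr)        # 1-based after import
  ends <- GenomicRanges::end(gr)
  if (any(ends > lens[ids]))
    stop("bedGraph ", path, " has intervals past the annotated length")
  counts <- lapply(tx$transcript_id, function(id) numeric(lens[[id]]))
  names(counts) <- tx$transcript_id
  sc <- GenomicRanges::score(gr)
  cov_hit <- lapply(counts, function(v) logical(length(v)))
  for (k in seq_along(gr)) {
    id <- ids[k]; span <- starts[k]:ends[k]
    if (any(cov_hit[[id]][span]))
      stop("bedGraph ", path, ": overlapping intervals for transcript ", id)
    cov_hit[[id]][span] <- TRUE
    counts[[id]][span] <- sc[k]
  }
  coverage_set(counts, assay, condition, replicate, library_size)
}

#' Write a coverage set as bedGraph
#'
#' Runs of equal coverage are collapsed into 0-based half-open intervals;
#' zero-coverage runs are omitted (bedGraph sparsity convention).
#'
#' @param cov A `coverage_set`.
#' @param path Output file (`.bedGraph`).
#' @export
write_bedgraph <- function(cov, path) {
  rows <- lapply(names(cov$counts), function(id) {
    v <- cov$counts[[id]]
    r <- rle(as.numeric(v))
    e <- cumsum(r$lengths); s <- e - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = id, start = s[keep], end = e[keep], value = r$values[keep])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), value = numeric(0))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read tab-separated tables
#'
#' Headered, tab-delimited UTF-8 with fixed column order; `read_tsv_strict`
#' refuses files missing required columns.
#'
#' @param x Data frame.
#' @param path File path.
#' @param required Character vector of required column names.
#' @return `write_tsv_strict` returns `path` invisibly; `read_tsv_strict`
#'   returns a tibble.
#' @export
write_tsv_strict <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv_strict
#' @export
read_tsv_strict <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L)
    stop(path, " lacks columns: ", paste(miss, collapse = ", "))
  tibble::as_tibble(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits the transcript FASTA, the annotation TSV, one bedGraph per coverage
#' library, count TSVs, the ground-truth tables and the resolved
#' configuration (YAML) into `dir`.
#'
#' @param ds Dataset from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tx <- ds$transcriptome
  seqs <- Biostrings::DNAStringSet(setNames(tx$sequence, tx$transcript_id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "transcripts.fasta"))
  ann <- tx[, c("transcript_id", "gene_id", "utr5_len", "cds_len", "utr3_len")]
  ann$is_mitochondrial <- as.integer(tx$is_mitochondrial)
  ann$is_spikein <- as.integer(tx$is_spikein)
  write_tsv_strict(ann, file.path(dir, "annotation.tsv"))
  for (cond in names(ds$m6a)) for (part in c("ip", "input"))
    for (cv in ds$m6a[[cond]][[part]])
      write_bedgraph(cv, file.path(dir, sprintf("m6a_%s_%s_rep%d.bedGraph",
                                                part, cond, cv$replicate)))
  for (cond in names(ds$rpf)) for (cv in ds$rpf[[cond]])
    write_bedgraph(cv, file.path(dir, sprintf("rpf_%s_rep%d.bedGraph",
                                              cond, cv$replicate)))
  for (cond in names(ds$rna)) for (ct in ds$rna[[cond]])
    write_tsv_strict(ct, file.path(dir, sprintf("rna_%s_rep%d.tsv",
                                                cond, ct$replicate[1L])))
  for (cond in names(ds$parclip)) for (ct in ds$parclip[[cond]])
    write_tsv_strict(ct, file.path(dir, sprintf("parclip_%s_rep%d.tsv",
                                                cond, ct$replicate[1L])))
  for (nm in names(ds$truth))
    write_tsv_strict(ds$truth[[nm]], file.path(dir, sprintf("truth_%s.tsv", nm)))
  cfg <- unclass(ds$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
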