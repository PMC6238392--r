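# sgtriage

Oxidative stress silences most translation and routes mRNAs into stress
granules (SGs). Part of that routing is sequence-addressed: N⁶-methyladenosine
(m⁶A) marks deposited at DRACH motifs (D = A/G/U, R = A/G, then A·C, H =
U/A/C) in the 5′UTR and 5′ vicinity of the CDS flag transcripts for SG
triage, while mRNAs that stay translated carry high, stress-invariant
methylation. `sgtriage` implements the computational side of that analysis as
a tested, reusable R pipeline for anyone working with m⁶A-IP ("MeRIP")
coverage, ribosome profiling and transcript-level CLIP counts in transcript
coordinates:

* **DRACH-anchored m⁶A calling** — per-gene mean normalization of IP and
  input coverage, input subtraction, exclusion of genes with maximal raw IP
  coverage < 15, threshold-and-run peak calling, and the rule that every
  predicted DRACH motif under a retained peak is methylated. Per-transcript
  methylation is summarized as the m⁶A/A ratio (methylated / predicted DRACH
  motifs) and as binned metagene profiles over 5′UTR/CDS/3′UTR.
* **Translation classification** — ribosome density `RD = RPF[RPM] /
  mRNA[RPM]`, normalized to the median RD of mitochondrially encoded genes
  (whose translation is stress-invariant), and the translation ratio `R_t` =
  fraction of a gene's footprints in the first 100 nt of its CDS. `R_t ≤ 0.5`
  means genuinely translated; `R_t > 0.5` means stalled at initiation and
  triaged for SGs.
* **SG client selection** — ERCC-like spike-in detection thresholds,
  replicate merging behind a concordance gate, transcript-level PAR-CLIP
  log₂ stress/control enrichment with a pseudocount, and the union of
  PAR-CLIP-selected and stalled transcripts as the SG metagene set.
* **Statistics** — Mann–Whitney rank-sum (exact for small tie-free samples),
  stable hypergeometric overlap tails, Pearson correlation, Venn counts.
* **Synthetic data with planted truth** — a generator that emulates all of
  the above (3′-biased baseline methylation, stress-induced 5′ additions on
  SG clients, stalled vs uniform footprints, a global log₂ = 2.9 RD
  reduction sparing mitochondrial genes, 4-fold PAR-CLIP client enrichment,
  spike-ins), so every stage is testable end to end with no downloads.

Coordinates are 0-based half-open throughout; bedGraph files carry transcript
IDs in the "chrom" column (transcript space, not genome space).

## Worked example

```r
library(sgtriage)

ds  <- simulate_dataset(sim_config(seed = 42))   # ~2,000 transcripts
res <- run_pipeline(ds)
str(res$summary)
```

```
List of 18
 $ n_transcripts         : int 2000
 $ n_detected_control    : int 2000
 $ n_detected_stress     : int 1867
 $ pct_detected_decrease : num 6.65
 $ n_peaks_control       : int 1181
 $ n_peaks_stress        : int 1534
 $ n_methylated_control  : int 892
 $ pct_methylated_control: num 44.6
 $ n_methylated_stress   : int 1025
 $ n_stress_induced_sites: int 766
 $ rd_log2_shift         : num 2.89
 $ n_translated          : int 102
 $ n_stalled             : int 1765
 $ n_rpf_transcripts     : int 1867
 $ n_sg_clients          : int 1885
 $ pct_sg_methylated     : num 53.4
 $ mw_p_m6a_ratio        : num 1.22e-13
 $ hypergeom_p_sg_meth   : num 3.16e-16
```

Reading the output: stress degrades 6.65% of detected mRNAs; peak counts rise
under stress (1,181 → 1,534) because SG clients gain 5′ methylation; the
mitochondrially normalized ribosome-density shift recovers the planted
log₂ = 2.9 global translation shutdown at 2.89; of the 1,867
footprint-bearing transcripts, 102 classify as genuinely translated and 1,765
as stalled; 53.4% of the 1,885-member SG set is methylated under stress, and
the rank-sum test on m⁶A/A distributions (control vs stress) and the
hypergeometric SG-vs-methylated overlap are both far below any conventional
threshold. Against the planted truth this run recovers methylated sites with
sensitivity and precision 1.00, translation classes at 100% agreement and SG
clients at F1 ≈ 0.9995 (see `score_m6a_calls()` / `score_binary()`).

Individual stages are plain functions — `scan_drach()`, `call_methylation()`,
`translation_table()`, `parclip_enrichment()`, `merge_sg_set()`,
`mann_whitney_u()` — and file readers/writers (`read_bedgraph()`,
`read_annotation()`, `write_dataset()`, `write_pipeline_outputs()`) connect
the pipeline to on-disk FASTA/TSV/bedGraph data.

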