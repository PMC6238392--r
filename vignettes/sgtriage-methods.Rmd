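---
title: "Methods: m6A methylation, translation state and stress-granule triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m6A methylation, translation state and stress-granule triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Under oxidative stress, bulk translation collapses and a large fraction of
cytosolic mRNAs is sequestered into stress granules (SGs). `sgtriage` models
the three measurements that together explain *which* mRNAs go where, all in
transcript coordinates (0-based, half-open):

1. **m⁶A methylation state.** m⁶A is deposited at DRACH motifs
   (`[AGT][AG]AC[TAC]` in the DNA alphabet; 18 pentamers; the methyl mark
   sits on the central adenosine). Antibody IP coverage compared with input
   RNA-seq coverage localizes methylation as enrichment peaks. A transcript's
   methylation level is the m⁶A/A ratio: methylated DRACH motifs over
   predicted DRACH motifs.
2. **Translation state.** Ribosome density `RD = RPF[RPM] / mRNA[RPM]` is a
   translation-efficiency proxy; the translation ratio `R_t` — the fraction
   of a gene's footprint signal inside the first 100 nt of its CDS —
   separates genuinely translated genes (uniform footprints, low `R_t`) from
   genes stalled at initiation (5′ pile-up, high `R_t`).
3. **SG membership.** Whole-SG PAR-CLIP counts, compared between stress and
   control, census the SG transcriptome; the SG metagene set is the union of
   PAR-CLIP-enriched transcripts and initiation-stalled transcripts.

## Stage-by-stage procedure and parameters

### DRACH scanning and segment binning

Scanning is exhaustive consensus matching (IUPAC degenerate matching via
Biostrings), reporting every window including overlaps. A degenerate
consensus either matches a pentamer or it does not, so no p-value machinery
is layered on top. Junction-spanning motifs belong to the segment containing
the methylatable A (`a_pos = start + 2`). For metagene profiles each segment
is cut into contiguous near-equal bins — bin *b* of a segment of length *L*
split *n* ways spans `[floor(bL/n), floor((b+1)L/n))` — with 10/30/10 bins
for 5′UTR/CDS/3′UTR by default, roughly proportional to typical human
segment lengths. For genes with several isoforms the longest is kept (ties:
lexicographically smallest ID).

### m⁶A calling

Per transcript: IP and input profiles are each divided by their own mean
("internal" normalization), the normalized input is subtracted, and maximal
runs of adjusted value > τ at least `min_width` nt long become peaks.
Defaults: τ = 0.5 normalized units, `min_width` = 10 nt. The published
workflow this reimplements states the normalization, the subtraction and the
exclusion rule but not its peak-calling rule; threshold-and-run is the
simplest rule whose recovery is verifiable against planted truth, and both
knobs are exposed. Transcripts whose maximal **raw** IP coverage is below 15
are excluded — the threshold is applied to raw counts because a normalized
threshold of 15 would be dimensionless. Negative adjusted values are kept
(peaks need strictly positive excess). Peaks covering no predicted motif are
dropped; every motif under a retained peak is called methylated, once per
condition. Stress-induced sites are the stress-only calls (losses are not
"induced").

### Translation classification

`R_t` is computed in `"fraction"` mode by default: window reads over CDS
reads, a number in [0, 1], with library factors cancelling. The literal
RPKM-over-RPKM form is also provided (`"literal_rpkm"`), but note that under
it a perfectly uniform gene scores exactly 1 — i.e. "stalled" — which
contradicts using uniform footprint distributions as the criterion for
genuine translation; this is why fraction mode is the default. The window is
the first 100 nt of the CDS and the denominator is CDS reads (both
configurable; "full gene" is ambiguous between CDS and transcript, and the
CDS is where footprints live). `R_t ≤ 0.5` (inclusive) is translated,
`> 0.5` stalled, undefined (zero reads or zero mRNA) undetected.

RD is normalized per condition to the **median** RD of mitochondrially
encoded genes. Mitochondrial ribosomes ignore the cytosolic stress response,
so this baseline removes the library-renormalization artifact that otherwise
hides a global shift: when nearly all nuclear genes lose footprints
uniformly, per-million scaling silently re-inflates them, and the unchanged
mitochondrial genes are the reference that restores the true scale. The
global shift statistic is the median over genes detected in both conditions
of `log2(RD_norm_control / RD_norm_stress)`.

### Detection, replicate merging and SG selection

Spike-ins at known concentrations define detection: the floor is the minimum
RPKM among spike-ins with nonzero counts in **every** replicate; detection is
inclusive (`rpkm ≥ floor`). Replicates merge by summing counts and library
sizes behind a Pearson r² gate on log-RPKM of co-detected transcripts
(default 0.9). The pipeline gates PAR-CLIP replicates at 0.6 instead:
transcript-level CLIP libraries are intrinsically noisier, and replicate r²
near 0.7 is ordinary for acceptable libraries of this type, whereas 0.9
would refuse them wholesale.

PAR-CLIP enrichment is `log2((rpkm_stress + ε) / (rpkm_control + ε))` with
ε = half the smallest nonzero RPKM of the pair. Two deliberate choices:

* **Common library scale (default).** When a large fraction of the
  transcriptome is genuinely enriched in the stress library, per-library
  RPKM normalization compresses the very signal being measured (the stress
  library total grows, deflating every stress RPKM). The default therefore
  expresses both libraries on the geometric mean of the two library sizes,
  making the ratio a per-transcript count ratio — the per-cell-equivalent
  comparison that spike-in calibration would provide — while keeping
  enrichment exactly antisymmetric under swapping the libraries.
  `scale = "per_library"` restores plain RPKM.
* **Twofold cutoff (default `log2_cutoff = 1`).** The selection has been
  described both as "twofold enrichment over control" and with a "log₂ = 2"
  wording; the two readings differ by a factor of two in log space. We take
  twofold as operative — with client enrichment around fourfold, a cutoff
  placed exactly *at* the typical client fold would classify by noise sign
  alone — and the cutoff is an explicit knob (`log2_cutoff = 2` gives the
  stricter reading).

A transcript is an SG client if detected in stress and enriched at or above
the cutoff. The SG metagene set is the union of PAR-CLIP clients and stalled
transcripts, provenance-tagged (`parclip` / `stalled` / `both`).

### Statistics

Mann–Whitney is exact (full enumeration) for pooled samples of at most 12
without ties, otherwise normal approximation with midrank-tie and continuity
corrections; two-sided by default. The hypergeometric overlap tail
`P(X ≥ k)` uses the numerically stable distribution function; the universe
size must be supplied explicitly and the pipeline uses the detected
transcriptome of the relevant condition. Venn counting handles up to three
sets exactly.

## The synthetic-data generator

`sim_config()` defaults define the conditions the pipeline is validated
under; they were fixed once, at design time:

| parameter | default | what it emulates |
|---|---|---|
| `n_transcripts`, `seed` | 2000, 42 | desk-scale transcriptome |
| segment lengths | lognormal, medians ≈150/900/500 nt | human 5′UTR/CDS/3′UTR scales |
| `n_mitochondrial` | 13 | the mitochondrial mRNA complement |
| `n_spikeins` | 20, depths 2⁻⁴–2⁶ | ERCC-like calibration ladder |
| `min_depth` | 30× | coverage adequate for peak calling |
| control site rates | utr5 .01 / cds .005 / utr3 .05 per motif | 3′-biased baseline methylation; realizes ~45% of mRNAs with ≥1 site |
| `fraction_sg_clients` | 0.55 | ≈ 6,020 / 10,791 |
| `fraction_stress_methylated` | 0.70 | ≈ 70% of clients gaining 5′ sites |
| stress site rates | utr5 .15 / first 20% of CDS .08 / utr3 0 | stress-induced 5′ additions |
| `ip_enrichment`, `peak_halfwidth` | 8, 25 nt | triangular MeRIP fragment kernel |
| `stall_fraction` | 0.85 | initiation pile-up of stalled genes |
| `rd_log2_shift` | 2.9 | global translational shutdown |
| `parclip_fold`, `parclip_cv` | 4, 20% | SG client enrichment and noise |
| `fraction_degraded_stress` | 0.065 | stress loss of detected mRNAs |
| `fraction_stalled_stress` | 0.95 | stalled share of footprint-bearing genes |

Noise model: per-base counts are Poisson (variance = mean) around the
expectation; PAR-CLIP adds multiplicative lognormal noise at the transcript
level. Degraded transcripts drop to zero expectation under stress, i.e.
below the spike-in floor. Methylation truth under stress is a superset of
control truth per transcript. Mitochondrial genes never stall, are never SG
clients and are never degraded. Everything is deterministic under a fixed
seed.

**What it does not emulate** — and hence what passing tests do not show
about real data: fragment-length and GC biases, antibody off-target binding
(m⁶Am, rRNA background), isoform mixtures, PCR duplication, positional
biases of CLIP crosslinking, codon-level footprint periodicity, partial
rather than all-or-none degradation, and correlated biological replicate
structure beyond shared expectations. Recovery near 1.0 on this generator
verifies the *logic* of the chain, not its robustness to those artifacts.

## Scoring conventions

Methylation calls are scored against planted sites by proximity: a call is a
true positive within 25 nt (the IP kernel half-width) of a planted site on
the same transcript. This is the standard evaluation for peak-resolution
methods: the calling rule itself declares every motif under a peak
methylated, so motifs neighbouring a true site within the kernel are correct
at the method's resolution, and exact-position matching would penalize any
faithful implementation. Sites on transcripts excluded by the coverage
filter are not scored as missed — the filter flags them as unanalyzable.
Translation and SG classification are scored as label agreement and
precision/recall/F1 on the planted labels.

## Numerical choices and degenerate inputs

All-zero profiles mean-normalize to zeros; zero mRNA makes RD undefined
(undetected, never an error mid-pipeline); transcripts with zero predicted
motifs are flagged and omitted from m⁶A/A distributions; empty metagene bins
are missing, not zero; `R_t` of a CDS shorter than the window uses the whole
CDS; detection and classification boundaries are inclusive as documented
(`rpkm ≥ floor`, `R_t ≤ 0.5` translated, `log2 ≥ cutoff` client); isoform
ties break lexicographically; over-binning a segment is an error in the
explicit binning API but tolerated in metagene pooling by capping bins at
the segment length, so short UTRs still contribute.

## Problem sizes

The validation suite runs the full chain at n = 2,000 transcripts
(seed 42) plus an 80-transcript set for unit-level checks; the scanner is
cross-checked against a brute-force oracle on 1,000 random 1-kb sequences;
rank-sum calibration uses 2,000 null simulations at n = 30 per arm. These
sizes make every planted effect measurable with comfortable margins while
keeping a full run in tens of seconds.

## Known limitations

Single-nucleotide m⁶A methods (miCLIP), m⁶Am/cap chemistry, non-coding RNA
methylation, codon-level ribosome dynamics, CLIP binding-site peak calling,
genome-coordinate/splicing handling and multiple-testing machinery are out
of scope. The peak caller is deliberately minimal; on real data with uneven
input coverage a model-based caller may be preferable, and the τ and width
knobs exist for that reason.
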