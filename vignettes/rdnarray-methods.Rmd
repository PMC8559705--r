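---
title: "Methods: split-and-map analysis of rDNA arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-and-map analysis of rDNA arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnarray)
```

## The model

Ribosomal DNA is analysed as a tandem array of one repeat unit: a coding
45S rRNA gene followed by an intergenic spacer (IGS) that carries two
variable satellite blocks, the R repeat (~680 bp per unit, 0–4 units)
near the transcription terminator and the Butterfly/Long repeat
(~4,500 bp per unit, typically two units) mid-IGS. A single long read can
span several copies; the package never aligns it base-by-base. Instead
each read is split into 300-nt sections and every section is mapped
independently against a single repeat unit, giving an ordered list of
(read offset, unit position, strand) points — the split-read dot plot.
Splitting deliberately discards base-level detail (no CIGAR
interpretation anywhere in the package): sequencing errors and
nucleotide-level variation average out within a section, while structural
features appear as discontinuities in the trace.

All coordinates are 0-based half-open in *unit space*, and displacement
arithmetic is circular: a tandem array wraps at the unit boundary, so the
signed displacement between two unit positions is taken with minimal
absolute value (`circular_delta()`, tie at exactly L/2 resolved to
+L/2). For each consecutive pair of mapped same-strand sections the
*deviation* is the circular difference between the observed reference
displacement and the expected one (the read-offset difference, signed by
strand). Deviations drive everything: > 100 nt is a *gap* (used only to
rank candidate unit references — fewest gaps wins), > 500 nt is a
*structural event*, with positive deviation labelled deletion (reference
sequence skipped) and negative duplication (reference re-traversed).
Both thresholds are strict inequalities.

## Key parameters

| parameter | default | role |
|---|---|---|
| `split_length` | 300 nt | section size; resolution vs mapping-rate trade-off |
| `min_tail` | 150 nt | terminal partial section kept iff at least this long |
| gap `tolerance` | 100 nt | reference-ranking gap bound (exclusive) |
| `structural_threshold` | 500 nt | event bound (exclusive) |
| `min_rdna` | 40,000 nt | continuous rDNA span required of a WGS read |
| `min_coding_fraction` | 0.10 | sections mapping to 45S, the microsatellite-decoy guard |
| `end_tolerance` | 50 nt | Cas9 terminus-to-cut-site distance |
| `min_opposite_fraction` | 0.10 | opposite-strand fraction calling a read inverted (strict) |
| quality drop | 5 Phred / 3 bins / 2 kb | sustained post-inversion drop flag |
| anchors | 10,000 / 20,000 / 30,000 (+500) | repeat-genotyping anchor sections |
| `short_delta`, `type_cutoff` | 2,000 nt, 0.2 | IGS short/long typing |
| `methyl_border` | 0.1 | all-or-none 45S class border (strict >) |
| `strong_cutoff` | 0.3 | 45S–IGS correlation stratum (strict >) |
| posterior `threshold` | 0.8 | "threshold" methylation metric |
| `genome_size` | 6.27e9 | diploid human genome for copy-number conversion |

The 0.2 IGS type cutoff separates the two observed groups of
short-proportion values; no numeric cutoff is inherited from elsewhere,
so it is exposed as a parameter. The quality-drop triple (5 Phred
sustained over 3 bins within 2 kb) is this package's operationalisation
of a qualitative observation — a sharp, sustained drop right after the
strand switch — and is fully configurable.

## The built-in aligner

Sections are placed by exact 15-mer seeding with voting on the
(target position − query position) diagonal, on both strands, against a
circularised unit (the index wraps k−1 bases past the origin). Diagonals
closer than 30 nt are merged into one cluster to absorb indel jitter, a
cluster needs ≥ 8 votes to count as a hit, and the primary hit is the
cluster with most votes, ties broken towards the forward strand and then
the lowest unit position — a deterministic, seed-free rule. The same
engine maps the three 500-nt genotyping anchors onto whole reads,
returning every qualifying cluster so each array copy yields one hit
(leftmost hit per copy segment on duplications, flagged `multi_hit`).
minimap2 can be swapped in through the same `align_query()` contract and
serves as an independent cross-check in the test suite; it is never the
implementation.

## Copy segmentation and landmark projection

Per-copy accounting needs copy boundaries, which no published convention
fixes; the package defines them as crossings of the reference origin
(unit start as deposited). Mapped dominant-strand sections are unwrapped
into a monotone coordinate (each step is the expected displacement plus
the wrapped deviation, so structural jumps below L/2 do not break the
unwrap), the unwrap is extrapolated linearly to both read edges, and
boundaries are placed where it crosses multiples of the unit length —
with a 25 nt tolerance at the read edges so a read that starts or ends
exactly at the origin owns that boundary. Complete segments lie between
two boundaries; flanks are flagged incomplete and excluded from per-copy
methylation (how partial copies at read ends should enter per-copy
averages is otherwise undefined). The coding and Butterfly/Long
sub-intervals are projected into read space by interpolation along the
same unwrap, which is what lets methylation calls (read coordinates) be
assigned to unit-space features without base-level alignment.

Inverted reads (strand transition) are rejected by the segmenter and
routed to the palindrome analysis. For a read with a single transition
the inversion offset starts as the midpoint between the flanking strand
runs (±half a section), then is refined by solving for the read offset
at which both flanks extrapolate to the same unit coordinate — exact for
a strand reflection, which both the template-switch artifact and a
genomic palindrome are — bringing the estimate to indel-level precision
while still using split alignments only. The refinement is accepted only
when it falls between the two flanking sections, otherwise the midpoint
stands.

## Suppression of satellite length variation

R and Butterfly/Long unit counts vary between copies as a matter of
course, so events there are not "noncanonical". An event is suppressed
when **either** (a) both flanking sections' alignment spans overlap the
same satellite interval, or (b) the event's implied reference span — the
skipped stretch for a deletion, the re-traversed stretch for a
duplication, of width |deviation| — lies inside a satellite interval
expanded by one section length. Rule (a) is the natural reading of
"both neighbouring sections within the region"; rule (b) covers the case
where the aligner realises a satellite-count jump at the block boundary,
leaving one flank just outside the region — with a single-unit reference
the jump's read-space location depends on which block unit each section
happens to match, an ambiguity that manual plot inspection would resolve
and rule (b) resolves automatically. A genuine event extending beyond
the satellite is contained by neither flank rule nor span rule and stays
counted.

Two further numerical choices on the event stream: single-section
excursions that immediately revert (the next pair cancels the deviation
within 100 nt) are dropped as mapping ambiguities in repeated sequence
(`drop_blips`, configurable) — a real structure shifts the register
persistently; and noncanonical rates are reported both per copy and per
read, since published percentages do not say which denominator was used.

## The synthetic-data generator

`make_synthetic_reference()` builds a unit with the coding region at
[0, 13000), an R block of `n_r` 680-bp units at 15,000 and a
Butterfly/Long block of `n_bl` 4,500-bp units between the second and
third anchors, in a random backbone (default unit: 41,040 bp). Satellite
units are internally composite (two or three diverged sub-periods) and
block copies are mutually diverged ~5% (each copy independently mutated
at 2.5% from a base unit) — realistic satellite divergence, and enough
that every 300-nt window of the block has a unique best location, so
error-free round-trip mapping is exact. Array copies for a read are the
reference unit with blocks resized at unit granularity *reusing the
reference's own units* (contract = drop trailing units, expand = append
freshly diverged ones): gene-conversion-homogenised arrays keep interior
units near-identical, and this is what makes natural count variation
land inside the suppression rules rather than at arbitrary positions.

Adjacent-copy correlation is modelled by cloning the previous copy's
repeat counts with probability `q` (default 0.8); `q = 0` gives the
i.i.d. null used for type-I checks. Methylation states follow a
two-state Markov chain parameterised by its stationary unmethylated
proportion `p` and stationary switch frequency σ (default 0.05, i.e.
1 in 20 pairs): P(U→M) = σ/2p, P(M→U) = σ/2(1−p). Per-CpG posteriors are
Beta-distributed — unmethylated Beta(1, 20), methylated Beta(8, 8) — at
0.02 CpG/base; IGS CpGs draw methylated-like regardless of the copy's
45S state, and the Butterfly/Long span carries no CpGs (microsatellite).
Sequencing errors default to 3% substitution / 1% insertion / 1%
deletion with qualities consistent with the total rate; the
template-switch artifact appends the reverse complement truncated to a
termination fraction (uniform in (0,1]) with a 7-Phred second-strand
drop; true palindromes reflect at a fixed unit coordinate with two
independently drawn arm lengths. Every generator is a pure function of
(configuration, seed), and truth records carry all planted quantities in
post-error read coordinates.

What the generator does **not** emulate: realistic per-base quality
dynamics (only step changes), homopolymer-biased Nanopore errors,
chimeric non-palindromic junctions, CpG-density variation along the
unit, basecaller-specific posterior miscalibration, and genome-wide
background (background reads are uniform random). Passing tests
therefore demonstrate the correctness of the analysis logic under a
controlled generative model, not performance on any particular real
dataset.

## Statistical components

- Adjacent-vs-random copy similarity: one-sided Wilcoxon rank-sum
  (normal approximation, ties allowed), one comparison per repeat per
  sample, no multiple-testing correction at that level; degenerate
  all-tied input returns p = 1 with a flag.
- Random-pair controls draw distinct copies uniformly from the sample
  pool, seeded.
- 45S–IGS correlation: Pearson on the > 0.3 stratum, flank = the IGS
  downstream of the copy (with the unit origin at the 45S start, the
  copy's own spacer); undetermined below 10 copies or at zero variance.
- R-repeat count vs 45S methylation: Spearman per sample with
  Benjamini–Hochberg correction across samples; samples with fewer than
  10 paired copies or zero variance are skipped.
- Copy number: base-weighted depth ratio (rDNA bases over total bases),
  not read counts, which are length-confounded; genome size is a
  documented assumption (6.27e9, diploid).
- Constant-active-copy fit: least squares for `proportion = A/N` has the
  closed form `A = Σ(p/N) / Σ(1/N²)`; the object also reports Pearson
  r for (N, p) and (N, N·p).

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run the pipeline at desk
scale: 50 error-free and 200 error-carrying two-unit reads for the
mapping and structural checks, 200 template-switch artifacts and 200
(100 in the script) true palindromes for triage, ~300 informative copies
for genotyping recovery, 200 adjacent pairs (with 100 i.i.d. replicates)
for the homogenization statistic, 300 copies at ~50 CpGs each for
methylation classes, 2,000 pairs for the switch rate, and 8 samples with
250–700 copies for the active-copy fit — sizes chosen so each property
is measured with small Monte Carlo error while the whole suite stays
fast on one CPU. Every random draw is seeded; reruns are byte-identical.

## Known limitations

- Section-level resolution: breakpoints are located to within ~one
  section (300 nt); base-resolution refinement is out of scope.
- Reads with two or more strand transitions are reported raw, not
  classified.
- The built-in aligner assumes satellite units diverged enough for
  unique 15-mer seeds; on a reference with *perfectly* identical
  satellite units, sections inside a block tie and fall to the
  lowest-coordinate rule.
- Copies are not phased to chromosomes; per-chromosome methylation
  structure is only reflected indirectly through run lengths.
- The MM/ML-tagged BAM methylation reader is not implemented; the
  canonical input is the per-CpG TSV (`read_id`, `position`,
  `posterior`).
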