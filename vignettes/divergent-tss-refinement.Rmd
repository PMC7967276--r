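---
title: "Refining divergent ncRNA transcription start sites from 5'-end RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining divergent ncRNA transcription start sites from 5'-end RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtss)
```

## The problem

Bacterial genomes carry dozens of small regulatory RNAs (ncRNAs/sRNAs)
encoded in intergenic regions, each nominally an independent transcription
unit with its own promoter. Annotated 5' ends of these RNAs, however, are
often approximate: 5'-end-specific RNA-seq — in which each sequenced read
starts exactly at the 5' terminus of a transcript — frequently places the
real transcription start site (TSS) tens of base pairs upstream (a longer
RNA than annotated) or downstream (a shorter one). Because many ncRNAs sit
head-to-head with a neighbouring protein-coding gene, a shifted TSS can also
change the RNA's functional category: an ncRNA whose (refined) transcript
span overlaps the 5' untranslated region (5'UTR) of the divergent mRNA is,
in effect, an antisense RNA.

`divtss` implements this refinement workflow as a reusable, deterministic
pipeline:

1. **read filtering** — 3' adapter trimming, removal of reads shorter than
   16 nt, and selection of alignments that match the genome perfectly
   (SAM tags `XM:i:0` and `NM:i:0`);
2. **pileup** — strand-specific per-position counts of read 5' ends;
3. **normalization** — per-replicate scaling by `N_av/N_i` and averaging of
   replicates within a growth condition;
4. **TSS calling** — peak detection near each annotated ncRNA 5' end, with
   primary/secondary ranking, signed shifts, and optional concordance with
   an external promoter-prediction track;
5. **orientation** — classification of each ncRNA against its nearest
   neighbouring gene (codirected / divergent / 5'-overlapping), *bona fide*
   flagging, and inter-TSS distance statistics for divergent pairs;
6. **REP screen** — scanning intergenic regions between collinear genes for
   REP (repetitive extragenic palindromic) elements, divergent-TSS evidence
   upstream of them, and candidate intrinsic terminators (poly-T track
   preceded by a hairpin) in between.

A synthetic-data generator provides desk-scale fixtures with known planted
truth, so every stage is testable without any sequencing download.

## Depth normalization

Replicates of one growth condition differ in sequencing depth. With
`N_i` the number of perfectly matching reads in replicate `i` of a
condition group and `N_av` the group mean, each replicate's counts are
scaled by

$$c_i = N_{av} / N_i,$$

and the condition track is the per-position mean of the scaled replicate
counts (a position absent from a replicate contributes zero to its term).
This scheme has the exact identity $\sum_i c_i N_i = n\,N_{av}$, which the
test suite asserts on randomized inputs. Coefficients are kept at full
precision internally and rounded to 4 decimal places only in report output.
The "series of experiments" over which `N_av` is taken is always the
condition group — replicates sharing a growth condition — because that is
the grouping under which the published per-replicate coefficients for this
kind of data are reproduced.

No other normalization (RPKM/TPM, median-of-ratios) is offered: 5'-end
counts are not length-dependent, and the goal is comparability of peak
heights across replicates, not differential expression.

## 5'-end assignment

For a plus-strand alignment the 5' end is the leftmost reference position;
for a minus-strand alignment it is `pos + reference_span(CIGAR) - 1`, where
the reference span sums the lengths of the M/D/N/=/X operations.
Soft-clipped bases do not shift the counted position — with perfect-match
filtering upstream (`NM = 0`, `XM = 0`) clipping is rare anyway, and using
the aligned end keeps the rule deterministic. Records missing either tag
fail the filter (both labels are required), and secondary/supplementary
alignments are excluded before counting so no read is counted twice.

Adapter matching is an exact full-string search truncating the read at the
leftmost occurrence of the adapter. The trimming rule searches the whole
read rather than only a 3'-anchored suffix; this is the package's own
deterministic choice and is recorded in the run manifest, not presented as
a property of any upstream protocol.

## TSS calling

Published TSS refinements of this kind rest on by-eye inspection of
superimposed profiles. `divtss` replaces that with an explicit rule so the
analysis is reproducible: within a window of `window` bp centred on the
annotated 5' end, every strand-matching local maximum of the averaged
normalized track with height at least `min_height` is a TSS call.

* `window = 300` bp by default — wide enough to cover the largest 5'-end
  shifts reported for refined bacterial annotations (up to ~164 bp) with
  margin;
* `min_height = 5` normalized counts by default — a floor that suppresses
  sporadic single-read positions at the depths the fixture emulates.

Both are analysis parameters, exposed in the configuration and written to
the manifest; they are not claims about any particular dataset. Ranking and
tie-breaking are deterministic: the highest peak is `primary`; ties break
toward the annotated position, then upstream. A plateau of equal adjacent
values yields a single call at the plateau position closest to the
annotated 5' end (tie again broken upstream).

The signed offset of a call is defined so that **negative always means
extension**: `called - annotated` on the plus strand and
`annotated - called` on the minus strand. Transcript variants implied by
multiple TSSs use the annotated 3' end, so pairwise length differences equal
pairwise TSS separations exactly.

## Orientation taxonomy

Each ncRNA is paired with the protein-coding gene whose transcript 5' end
(the experimentally supported mRNA start `mrna_tss` when known, else the
CDS start) is closest to the ncRNA 5' end; equidistant candidates resolve
to the ncRNA's upstream side. The pair is then classified:

* same strand → **codirected** (head-to-tail);
* opposite strands, transcription pointing apart, disjoint spans →
  **divergent** (head-to-head);
* opposite strands with intersecting transcript spans →
  **overlapping_5prime**, with the overlap length in bp;
* opposite strands transcribing toward each other → **convergent**, a
  label kept outside the three-way taxonomy but reported rather than
  rejected, since real annotations contain such pairs.

"Transcription pointing apart" is decided by comparing span midpoints of
the plus- and minus-strand members (plus-member midpoint at or right of the
minus-member midpoint); this gives a total, mirror-invariant rule even for
nested spans. The neighbour's transcript span includes its 5'UTR whenever
`mrna_tss` is set — exactly the knowledge that reclassifies some nominally
divergent ncRNAs as antisense. An ncRNA is *bona fide* when its span
overlaps no opposite-strand transcript span in the annotation.

The inter-TSS distance of a divergent pair is the plain absolute difference
of the two 5'-end coordinates, with no ±1 adjustment — the unverifiable
alternative conventions differ by at most 1 bp and the choice is
documented. Summaries report min/median/max with the even-count median as
the mean of the central pair.

## The REP screen

REP elements are ~35-bp quasi-palindromic repeats abundant between
enterobacterial genes. The screen asks, for each intergenic region (IGR)
between two *collinear* genes that contains a REP match: is there a
divergent TSS (on the strand opposite to the flanking genes) upstream of
the REP, and does a candidate intrinsic terminator intervene — i.e. would
transcription read through the REP and include it in the RNA?

Three encodings of the consensus are scanned: two literal 35/36-nt
variants, and the symmetric degenerate form
`GCKGATGGCGRGCK…RCGYCTTATCMGGCCTAC` whose unspecified centre is modelled as
a bounded spacer of 0–3 `N` positions (one concrete pattern per width; the
3-`N` form reaches the canonical 35 bp). Matching is IUPAC-compatible with
a mismatch budget; a genome `N` matches only a pattern `N`. Overlapping
hits from different encodings are collapsed to the best-scoring one.

Terminator heuristics follow common intrinsic-terminator practice, are all
configuration-exposed, and are logged:

| parameter | default | meaning |
|---|---|---|
| `max_mismatches` | 3 | mismatch budget per REP hit |
| `min_run` | 4 | minimum poly-T run on the transcribed strand |
| `min_stem` | 4 | minimum hairpin stem length (bp) |
| `min_loop` / `max_loop` | 3 / 8 | loop length bounds (nt) |
| `search_window` | 20 | window upstream of the T track searched for the stem |

The loop minimum of 3 nt is the physical minimum for a hairpin turn; a
smaller "loop" cannot form, so stems separated by 0–2 nt are not counted.
The TSS-to-REP distance is measured in the transcription direction from the
called TSS to the nearest REP boundary at or downstream of it. A locus
"reads through" when a divergent TSS and a REP exist with no
hairpin-plus-poly-T candidate between them. These are screening heuristics:
no folding thermodynamics and no rho-dependent termination model is
implied.

## The synthetic fixture

The generator's standard fixture defines the study conditions under which
the pipeline is validated:

* a 50 kb genome laid out in 3 kb blocks, with uniform random background;
* twelve ncRNA/gene pairs — five divergent with inter-TSS distances
  7/84/84/170/290 bp (median 84), four codirected, three 5'-overlapping
  with a 41-bp 5'UTR duplex — and planted true TSSs shifted against the
  annotation by 0, −26, −27, +29, +43, −65 and +60 bp, covering both
  extension and shortening in both strand orientations;
* four REP intergenic loci between collinear genes: read-through
  (TSS + REP, nothing between), terminated (hairpin + T₆ between TSS and
  REP), TSS-less, and poly-T-without-hairpin;
* two conditions × two replicates, 5,000 reads per replicate at base depth
  with per-replicate depth multipliers (1.0, 1.6) so the normalization
  coefficients differ from 1;
* read length 30 nt; configurable fractions of reads receive 1–2
  substitutions (default 0 in the clean fixture), a 3' adapter suffix
  (10%), or truncation below 16 nt (5%).

Reads are planted exactly at their TSS (no 5'-end jitter) by default,
because genuine primary TSS signals in 5'-end data are single-nucleotide
peaks; an optional geometric jitter exists for robustness experiments.
Alignments are written directly from read provenance (an alignment oracle),
with `NM`/`XM` equal to the planted substitution count, so no aligner is
needed and the SAM is exact by construction. The stretches between a
planted TSS and its REP element are overwritten with an A-free periodic
fill so that poly-T tracks and hairpins occur exactly where planted.

What the fixture does **not** emulate: positional read noise, rRNA/tRNA
background, quality-dependent error models, mapping ambiguity from genomic
repeats, or biological replicate variability beyond depth. Passing the
planted-truth suite therefore demonstrates that the pipeline's logic is
correct and deterministic — not that its defaults are optimal for any
particular real library.

## Numerical and degenerate-input choices

* Coordinates are 1-based and inclusive throughout; 0-based half-open
  conversion happens only inside the BED/bedGraph readers/writers.
* Circular genomes are recorded as such, but intervals crossing the origin
  are rejected with a clear error; no analysed locus type spans it.
* Empty tracks, zero-peak windows, and IGRs without TSS or REP produce
  empty-but-well-formed results, never errors; a replicate with zero
  perfect-match reads is an error (its coefficient would divide by zero).
* Pileups use sparse position→count maps; a dense representation is never
  materialized for a 4.6 Mb-scale genome.
* All randomness is seed-derived; rerunning any stage with the same
  configuration reproduces byte-identical outputs, and the run manifest
  records every parameter and input checksum.

## Problem sizes

The shipped validation uses the 50 kb / 12-pair / 2×2 / 5,000-read fixture
for end-to-end recovery, 20,000 reads for the binomial filter check, 100
random 10-kb sequences for scanner cross-validation, and 100 seeded
repetitions of the conservation/neutrality/mirroring invariants. These
sizes give exact planted-truth recovery and tight binomial intervals while
keeping a full run in the order of minutes on one CPU.

## Known limitations

* TSS calling is threshold-based; it does not model overdispersed noise
  and will report any isolated position above `min_height` as a peak.
  Condition dependence is reported descriptively (one call set per
  condition), with no statistical test between conditions.
* The REP screen's terminator flags are sequence heuristics; hairpin
  stability is not scored.
* Counts that depend on a specific annotation release and manual curation
  (how many ncRNAs are divergent, how many REP loci have TSSs, etc.) are
  properties of those inputs, not of this implementation, and are not
  reproduced as fixed numbers.
* Single-chromosome genomes only; spliced features and annotation liftover
  are out of scope.
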