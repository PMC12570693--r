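---
title: "Comparing repeat and SNV variant frequencies between DNA and cDNA amplicons"
author: "amplistr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing repeat and SNV variant frequencies between DNA and cDNA amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

The human rDNA intergenic spacer contains the gene of the promoter-associated
RNA (pRNA), a non-coding transcript that silences rDNA through NoRC. Inside
the pRNA gene lie two short-tandem-repeat tracts of the motif CCCT (called Q1
and Q2) and a biallelic C/T site at U13369.1 position 41,574. If a DNA
variant inhibits pRNA expression, it will be seen **more often in genomic DNA
than in the cDNA** made from the transcript pool: the transcript
under-samples the inhibiting alleles. `amplistr` implements the deep-
sequencing analysis behind that comparison as a reusable, fully tested
pipeline: two amplicon libraries (nominally "DNA" and "cDNA", but any
two-condition design works) are cleaned, aligned to the reference amplicon,
reduced to the repeat region with flanking bases, clustered, and summarised
as repeat-number class tables, flank-variant tables and targeted SNV
frequencies, with two-sample proportion tests on every row.

The statistical core is elementary by design: for a variant with frequency
$f_1$ at coverage $n_1$ in one sample and $f_2$, $n_2$ in the other, counts
$k_i = \mathrm{round}(f_i n_i)$ are compared with the 2×2 chi-square test
without continuity correction (identical to the two-sided two-proportion
z-test, $z^2 = \chi^2$), falling back to Fisher's exact test whenever an
expected cell count drops below 5. No continuity correction and no
multiple-testing adjustment are applied by default, because the analysis
reports raw per-row p-values; a Bonferroni option exists for table-wide
scans.

## Reference model and coordinates

All positions are 1-based locus coordinates on the U13369.1 scale and all
intervals are half-open `[start, end)` — a convention fixed by the printed
PCR products: amplicon Q1 spans 41,469–41,790 and is 321 bp, amplicon Q2
spans 41,748–42,033 and is 285 bp, which are exactly the half-open lengths.
A locus position maps to the 0-based amplicon index `pos - origin`.

The true tract coordinates are not published, so `default_layout()` is a
synthetic stand-in that pins down everything that *is* printed: the primer
sequences at the product ends, the tract contexts
`TTTTCTTCCT (CCCT)n GCTCCC` (Q1) and `TGTTCTTTCT (CCCT)n GCTTCC` (Q2), and
the `CCC` context of the 41,574 site. The Q1 tract is placed at
[41,653, 41,685) with reference count 8 so that the published indel
positions 41,663 and 41,665 fall inside it; the Q2 tract at [41,840, 41,876)
with reference count 9 so that the published flank-variant hotspot 41,878 is
the third base of its 3' flank. Everything else is a seeded random spacer:
coordinates behave realistically while no copyrighted reference sequence
ships with the package. Consequently the reference is *synthetic* — analyses
of real U13369.1 data should supply the real amplicon FASTA and tract
coordinates through `reference_amplicon()`/`repeat_region()`.

## Pipeline stages and their parameters

1. **Read cleaning.** Optional 3' adapter removal (best-scoring full or
   suffix occurrence, `max_error_rate` 0.1, `min_overlap` 3, ties to the
   longest removal); 3' quality trimming by the running-sum rule at
   Phred 18 (the algorithm standard trimmers use for a `-q` cutoff —
   end-trimming, not masking, which would corrupt alignment); reads under
   60 bp discarded. A 60-bp read is kept, 59 bp is not.
2. **Alignment.** A semi-global affine-gap aligner: global in the read,
   free end gaps in the reference, scores (match +1, mismatch −4, gap open
   −6, gap extend −1; a k-gap costs `open + k·extend`), mirroring the
   scoring of the standard short-read mapper this replaces. Both
   orientations are scored and the better kept (ties toward `+`). Large
   problems run in a band of half-width 30 around the modal diagonal of
   exact 15-mer seed matches; problems under 40,000 DP cells run the full
   unbanded DP. Reads sharing no exact seed with the amplicon are reported
   unmapped without running the DP — with sequencing error around 10⁻³ a
   genuine amplicon read essentially always carries intact 15-mers, and
   this is also what rejects reads from the other amplicon cheaply. A read
   is unmapped when its best score is below `0.5 × read length`; rejected
   outright when longer than the amplicon + 50.
3. **Indel left-normalisation.** Every I/D run is shifted to its leftmost
   equivalent placement. Indel placement inside `(CCCT)n` is otherwise
   ambiguous, and all equivalent placements must yield the same repeat
   call; the operation is score-preserving and idempotent, and the test
   suite asserts call invariance across constructed placements.
4. **Extraction.** The CIGAR is walked over the reference columns of the
   tract ± flanks (5/5 bp for calling and clustering, 10/6 nt for flank
   profiling): M emits the read base, D emits `-`, and insertion bases
   attach to their anchor column (the next reference column); an insertion
   anchored at the interval start belongs to the segment, one at the end
   column does not — the half-open convention carried through. Reads not
   covering the full interval are dropped and counted; a deletion spanning
   the interval still covers it (an all-gap segment is data: it is how
   large deletions are seen).
5. **Clustering.** `exact_group()` groups segments by exact string
   equality (count-descending, ties lexicographic) and carries the
   reference cut at the same interval — this is the cluster report the
   analysis publishes. A CD-HIT-style greedy clusterer over whole reads
   (`greedy_cluster()`, identity = matches/shorter-length under ungapped
   sliding, threshold 0.9) is provided and oracle-tested, but
   `run_pipeline()` leaves it **off by default**: collapsing reads onto
   90%-identity representatives erases sub-threshold point variation — a
   single-base variant in a 250 bp read is 99.6% identity — and the SNV
   and flank-variant frequencies are precisely what the pipeline exists to
   measure. Ungapped identity is deliberately indel-sensitive, so
   repeat-number variants would survive the pass; point variants would
   not. The pass is available (`first_pass_identity`) for denoising
   workflows that only target repeat-length distributions.
6. **Repeat calling.** The tract is located between flank anchors: the
   last `min(5, flank)` bases of the 5' flank and the first `min(5,
   flank)` bases of the 3' flank, each tolerating one mismatch so that a
   flank SNV does not destroy the call; anchor search prefers the position
   closest to its expected offset. `n_observed` is the longest run of
   exact CCCT copies in the tract; the class follows the tract-length
   change `delta_len`: 0 → reference, divisible by 4 → deletion/insertion,
   otherwise **complex** (e.g. the published 7-bp `delTCCCTCC` and 5-bp
   `insTCCTC`). Complex events count inside "Indels" but outside
   "Deletions"/"Insertions": the published tables separate deletions and
   insertions by whole repeat units and never state how partial units were
   binned, so the package gives them their own class rather than guessing.
7. **Tables and re-referencing.** Class fractions are computed over all
   calls; rows under 2% are suppressed from the report but retained
   internally (and used by the comparison tests). When no read matches the
   nominal reference count — the Q2 situation — the modal `n_observed`
   (each read one vote; ties to the smaller count) becomes a substitute
   reference "Ref#" and classes are recomputed against it. The mode is
   taken over reads rather than clusters because reads are the sampling
   unit of every other frequency in the analysis.
8. **Flank profiling.** Segments re-extracted with 10/6 nt flanks are
   compared column-wise to the reference cut; gap columns are ignored
   (they are repeat-length signal, already counted) and excluded from the
   per-position denominators. The output is a Reference/Variants table
   plus per-position counts of each non-reference base.
9. **SNV frequencies.** The base carried at the target column by every
   alignment whose M-operations cover it; deletions and Ns are excluded
   from coverage; an uncovered site reports a missing frequency, not 0.

## The synthetic data generator

Because the original sequencing data are not deposited, the generator is a
first-class module that emulates the study's conditions: two amplicons
sampled equally; per-molecule repeat counts, SNV alleles and flank variants
drawn from template mixes that transcribe the published tables (Q1 DNA
reference/deletions/insertions/complex = 0.20/0.65/0.08/0.07 with the
complex mass as the 7-bp deletion; Q1 cDNA 0.95/0.02/0.02/0.01; Q2
dominated by a modal count of 6 with 7% one-unit-shorter molecules in DNA
and ~0% in cDNA; 41,574 T allele at 0.68 vs 0.95; 3' flank variants at
0.15/0.02 for Q1 and 0.02/0 for Q2, the latter at position 41,878).
Reads are 250 bp from a uniformly chosen molecule end — a deliberate
single-end emulation of the 250 bp paired protocol over 285–321 bp
amplicons, since read pairing adds no analytical content here and the
coverage filter handles partial reads. Per-base substitution error is
10⁻³ (the upper end of the run's reported error rates), 1-bp indel error
2×10⁻⁵ (indel errors on this platform are roughly two orders of magnitude
rarer than substitutions), PCR stutter adds or removes one repeat unit in
0.2% of molecules (flagged in the truth table as stutter, not as template
identity — stutter is the dominant STR artifact and the deletion calls must
be shown robust to it), strands are emitted 50/50, and qualities follow a
two-state model (Phred 37 body; in 5% of reads a Phred 12 tail of geometric
mean length 20) — just enough structure to exercise the Q18 trimming rule.

What the generator does **not** model: learned Illumina error profiles,
quality-by-cycle structure, chimeras, paired-end merging artifacts, or PCR
amplification bias beyond single-unit stutter. Passing recovery tests
therefore demonstrates the pipeline's correctness on data with the stated
statistical structure, not robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

Traceback ties prefer M over D over I, and alignment ends at the smallest
reference column among score ties; together with the radix (C-locale)
string sorts in clustering this makes every output byte-deterministic.
Frequencies are reported at full precision in the data structures and JSON,
and rounded to two decimals in the rendered report files, matching the
published tables' formatting. Quality-trim ties prefer the longer removal.
Weights in a template specification must sum to 1 within 10⁻⁹. Empty
inputs: an empty read set filters to empty with zeroed counters; an empty
cluster list renders a header-only report; a site covered by no read
reports a missing frequency; a segment whose flank anchors cannot be found
is classed complex and flagged unanchored rather than silently dropped.

Strand invariance deserves one note: alignment, extraction and counting are
exactly strand-invariant (asserted by tests), but 3' quality trimming is by
definition read-directional — reverse-complementing a read moves its
low-quality tail to the other end. The end-to-end invariance test therefore
runs with quality tails disabled; with tails enabled the differences are
confined to the handful of reads whose trimmed window changes.

The parameter-recovery checks compare, for the repeat-class tables (against
both the nominal reference and Ref#) and the SNV frequencies, the measured
count with the exact central 99% binomial interval around the truth-table
fraction over the same covered reads. The flank Reference/Variants split is
checked per-position against its planted variant instead: the table's
"Variants" row is a union over 16 flank columns and absorbs roughly
16 × 10⁻³ of sequencing error by construction, which is measurement, not
miscounting.

## Problem sizes

The shipped tests simulate 20,000 reads per sample for the recovery
analysis (the full two-sample pipeline runs in well under a minute), 50,000
reads for the goodness-of-fit check of the generator's marginals, and
500+ random instances for the aligner/DP-oracle equivalence; these sizes
give binomial standard errors a few parts per thousand, ample for every
fraction the tables report.

## Known limitations

- The default reference is synthetic (see above); real-data use requires
  the real amplicon sequence and tract coordinates.
- Repeat alleles and SNVs are not phased into haplotypes; the data model
  would permit it, but no operation is defined.
- The aligner targets a single known amplicon: no multi-locus mapping, no
  mapping-quality model, no chimera splitting.
- `counts_from_frequency()` reconstructs counts by rounding published
  (frequency, coverage) pairs; at low coverage the reconstruction error
  can reach half a count, which is why the Fisher fallback matters.
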