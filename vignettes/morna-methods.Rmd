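---
title: "Counting microRNA-offset RNAs and testing seed-window target enrichment"
author: "morna package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting microRNA-offset RNAs and testing seed-window target enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

MicroRNA-offset RNAs (moRs) are ~20-nt small RNAs processed from pri-miR
sequence immediately adjacent to a mature miR arm. They are easy to miss in
standard small-RNA pipelines because they fall just outside the annotated
mature coordinates. `morna` implements two connected analyses:

1. **Quantification** of miR and moR abundance from aligned small-RNA reads,
   using fixed coordinate windows derived from a miRBase-style annotation,
   with even allotment of reads among nearby loci and normalization to reads
   per million region-mapped reads (RPMR).
2. **Seed-window target analysis** for a small RNA of interest: every 7-nt
   window of the RNA is treated as a candidate seed, 3'UTRs are scanned for
   its exact seed-match (the DNA reverse complement), and the hit genes are
   cross-tabulated against microarray differential-expression classes with
   an exact binomial tail test. A companion constructor models the bulged
   tandem binding sites of sponge (decoy) transcripts used for
   loss-of-function experiments.

## The classification windows

All internal coordinates are 1-based closed intervals held in `GRanges`, the
Bioconductor convention; GFF3 input (1-based) and BED output (0-based
half-open) are converted only at the I/O boundary. For a mature arm at
$[s, e]$ on the plus strand, with slack $a$ (default 3 nt) and moR extent
$b$ (default 35 nt):

* miR window: $[s - a,\; e + a]$ — a read counts as a miR read when it falls
  entirely inside the mature coordinates plus or minus $a$ nt.
* 5p moR window: $[s - b,\; s + a]$ — from $b$ nt upstream of the first base
  of a 5p miR to $a$ nt inside it.
* 3p moR window: $[e - a,\; e + b]$ — the mirror image downstream of the
  last base of a 3p miR.

On the minus strand the same definitions apply in transcript orientation.
Windows are clipped at position 1 but deliberately not clipped to the
pri-miR interval: the rules are defined relative to the mature arms only,
and moR windows routinely extend past the annotated hairpin.

Two consequences are load-bearing and are asserted by the tests:

* every moR window is $b + a + 1 = 39$ nt long;
* the same-arm miR and moR windows overlap by exactly $2a + 1 = 7$ nt, so no
  read of at least `min_insert` = 14 nt (the shortest insert that survives
  the length filter, "longer than 13 bases") can be contained in both. The
  classification precedence (miR windows before moR windows) therefore never
  decides the category of a legal read; it exists only to make the contract
  total for degenerate inputs.

Reads are attached to every pri-miR locus on the same chromosome and strand
within 50 nt gap distance (overlap counts as 0; the 50-nt bound is
inclusive), and a read near $k$ loci contributes weight $1/k$ to each —
"allotted evenly". A read assigned to a locus but contained in no window
(loop reads, boundary-straddling reads) contributes to neither the counts
nor the RPMR denominator, which is the per-library sum of assigned weights
over the four categories. Same-strand matching is required throughout:
miR/moR identity is strand-specific, so antisense reads are never counted.
Whether the original 50-bp rule measured distance to the hairpin or to the
mature arms is not decidable from the written rules; this package measures
gap distance to the pri-miR interval, the simplest reading, and exposes the
choice via `locus_distance`.

Adapter trimming is exact-substring with a terminal partial match of at
least 6 nt and no error tolerance. No published trimmer parameters exist to
match; an exact contract is reproducible and testable, and alignments may
be supplied directly, bypassing the trim/filter stage entirely.

## Seed windows and the enrichment test

A small RNA of length $L$ has $L - 6$ candidate seed windows; the window at
start 2 (nucleotides 2-8) is the classic miR seed. A gene is a predicted
target of a window when its 3'UTR contains the window's seed-match 7-mer at
least once (exact match, sense strand, `N` never matches); multiplicity is
recorded but a single site suffices, and one UTR record per gene is
required (callers with multiple transcripts should pre-select, typically
the longest UTR). No conservation filtering, context scoring or 7mer-A1/8mer
subtypes are applied: those need multi-genome alignments or trained models,
and the enrichment analysis here is deliberately a pure seed-presence test.

Predicted targets are cross-tabulated against DE classes obtained by strict
thresholding: down-regulated when the signed fold change is below
$-1.3$ and the adjusted p value below $0.002$, up-regulated symmetrically,
unchanged otherwise, with genes absent from (or flagged undetected on) the
array excluded from the denominator. The enrichment evidence for a window
with $k$ down-regulated among $n$ detected targets is the exact upper tail
$P(X \ge k)$, $X \sim \mathrm{Binomial}(n, p_0)$, computed by log-space
summation of the exact terms. The null rate $p_0$ defaults to the fraction
of all detected genes that are down-regulated — the natural "by chance"
rate for the question asked — and can be overridden when a different null
is wanted. Windows are ranked by tail probability, ties broken by larger
$k$ then smaller start; a Bonferroni column (tail times the number of
windows) is reported as supplementary output but does not drive the
ranking, since the analysis reports raw binomial evidence.

## Sponge site model

The bulged decoy sites used to sequester a small RNA decompose as
`anchor5 + bulge + anchor3`: the reverse complement of the RNA's 3'-terminal
hexamer, three arbitrary bases opposite RNA positions 9-11, and the reverse
complement of RNA positions 1-8. The bulge prevents Ago2-mediated
endonucleolytic cleavage, so `build_sponge()` warns when a supplied bulge
restores perfect central complementarity. Counting sites in a construct is
a left-to-right non-overlapping regex scan, and
`count_sponge_sites(build_sponge(rna, n)) == n` holds constructively.

The full sequence of the studied moR is not recoverable from its published
description — only the 5' octamer and 3' terminal hexamer are fixed by the
printed sponge sites. The sequence used in examples and tests
(`CUGUACCAGAUAACGUCGGA`) is a synthetic placeholder consistent with both
anchors; its middle third is arbitrary and nothing in the package depends
on it.

## What the synthetic generators emulate

The generators produce every input the pipeline consumes, with ground-truth
labels, at desk scale:

* **Annotation** (`gen_annotation`): 20 pri-miR loci by default on a 100-kb
  chromosome, each with 5p and 3p arms of 20-23 nt separated by a 12-18 nt
  loop and 10 nt of pri-miR flank, singleton loci at least 200 nt apart.
  When `multi_locus_fraction > 0`, about a tenth of the loci form
  same-strand pairs with a 100-nt gap, the geometry of genomic miR
  clusters; these are the only arrangement in which a short read can sit
  within 50 nt of two loci at once.
* **Reads** (`simulate_reads`): 10,000 reads by default, drawn from a
  category mix (defaults 0.35/0.25/0.15/0.10 over the four windows plus
  0.15 background) with lengths 18-26 nt placed uniformly inside the true
  category's window; background reads land at least 100 nt from any locus;
  multi-locus reads are centred in a pair's gap, within 50 nt of both loci
  and inside no window, so their truth is "allotted 0.5/0.5, counted
  nowhere".
* **UTRs** (`gen_utrs`): 2000 genes of 300-800 nt of uniform random DNA; 3%
  receive one planted seed match at a uniform position (substituted in
  place). The length range sits in the shorter half of mammalian 3'UTR
  lengths and keeps the background 7-mer hit rate near 3%, the same order
  as the planted rate, which makes the recovery experiment non-trivial.
* **DE tables** (`gen_de_table`): planted targets down-regulated with
  probability 0.5 against a 5% background rate, 5% up-regulation, 90%
  detection; magnitudes and adjusted p values are drawn from ranges that
  strictly pass (1.4-4, < 1.5e-3) or strictly fail (1-1.25, >= 5e-3) the
  default thresholds, so the thresholded class of every generated row
  equals the intended class exactly.

Each generator is a pure function of its seed (annotation and reads split
one seed as `seed` and `seed + 1`). What the simulations do *not* model:
sequencing error, quality scores, non-uniform base composition, isomiR 5'
heterogeneity, hairpin thermodynamics, or correlated gene expression.
Passing the recovery tests therefore demonstrates the correctness of the
counting and testing machinery under the stated generative model, not
performance on real libraries, where adapter chemistry and mapping
ambiguity add noise the generators deliberately omit.

## Numerical and design choices

* 1-based closed `GRanges` internally (rather than 0-based half-open):
  interval arithmetic, overlap queries and distance semantics come from
  IRanges/GenomicRanges, which the rest of the Bioconductor ecosystem
  shares; conversions happen once, at the I/O boundary.
* Boundary conventions are inclusive everywhere a rule says "within":
  gap distance of exactly 50 qualifies a locus, a read exactly filling a
  window is contained, and both DE thresholds are strict inequalities.
* `binomial_tail` clamps its log-sum-exp result at 1; tails are accurate to
  better than 1e-12 relative error against independent implementations for
  n up to 200 (tested), and monotone in k and p0 up to float jitter below
  1e-12.
* The locus index is a nested containment list (`GNCList`), giving
  better-than-linear distance queries over large annotations.
* The null-calibration check for the enrichment test uses the randomized
  probability integral transform: the raw discrete upper-tail p-value is
  super-uniform by construction, so a literal uniformity test on it would
  fail for reasons unrelated to correctness.
* Problem sizes in the test-suite experiments — 10k reads over 20 loci for
  the reference-equivalence check, 100 seeded replicates for planted-window
  recovery, 200 for null calibration — are the smallest at which the
  targeted properties are statistically sharp.

## Limitations

* No aligner, no mismatch handling, and no isomiR sub-classification: the
  pipeline's contract begins at aligned segments.
* Multi-mapping reads are handled only through even allotment of the
  candidate-locus union; probabilistic rescue (as in EM-based quantifiers)
  is out of scope.
* The seed scan is single-species and presence-based; it will not reproduce
  conservation-filtered target lists from multi-genome tools, only the
  seed-presence superset.
* DE classification consumes a precomputed table; array normalization and
  moderated test statistics are upstream concerns.
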