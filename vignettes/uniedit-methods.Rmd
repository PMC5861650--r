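---
title: "Quantifying genome-editing outcomes from anchored uni-directional tagmentation libraries"
author: "uniedit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genome-editing outcomes from anchored uni-directional tagmentation libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and what the package computes

CRISPR nucleases cut chromosomes; cells repair the cuts in many ways. A
single cut mostly re-ligates with small insertions or deletions (indels),
but a pair of cuts can additionally excise the intervening fragment
(a large deletion), re-insert it backwards (an inversion), join like ends of
homologous chromosomes or sister chromatids (homolog fusions), or — with
cuts on two chromosomes — produce balanced, dicentric, or acentric
translocations. PCR assays with two fixed primers cannot see most of these:
any rearrangement that moves one primer site away is invisible, and
variable-length amplicons distort quantification.

Anchored uni-directional sequencing solves this by fixing only **one** side
of each library molecule. A transposase (Tn5) simultaneously fragments
genomic DNA and attaches an adapter carrying a sample barcode and a 10-nt
unique molecular identifier (UMI); a single locus-specific **anchor primer**
then amplifies from a fixed genomic position into the random tagmentation
breakpoint. Whatever is joined to the anchored side — wild-type sequence,
an indel, or any rearrangement partner — is captured, and the UMI lets PCR
duplicates collapse to one original molecule, so category frequencies are
molecule-based rather than read-based.

`uniedit` implements the analysis side of this design end to end:

1. **Outcome model** (`enumerate_outcomes()`, `build_amplicons()`): for one
   or two cuts, every junction formed by joining two free chromosome ends in
   either orientation is enumerated. A junction's sequence is
   `left_flank(end1) + right_flank(end2)`, with a flank
   reverse-complemented when the orientation demands; because swapping the
   two slots reverse-complements the whole junction, unordered end pairs
   enumerate the distinct classes — 10 for two cuts (on one locus or two),
   3 for a single cut. A class is detectable by a primer set iff one
   primer's free end takes part in the junction (`detectable_classes()`);
   with one primer on one flank of each of two cuts, 7 of the 10 classes are
   detectable.
2. **Preprocessing** (`demultiplex()`, `extract_umi()`, `trim_adapter()`):
   dual-barcode demultiplexing with at most one mismatch per index and
   no tie-breaking, UMI extraction from the header comment or an index
   read, and 3'-adapter read-through trimming by suffix/prefix overlap.
3. **Alignment** (`align_semiglobal()`, `assign_amplicons()`): each mate is
   aligned to every reference amplicon on both strands with a semi-global
   ("glocal") affine-gap aligner — the read end-to-end, reference end gaps
   free — and the pair is assigned to the amplicon with the best summed
   mate score among amplicons where both mates pass identity and coverage
   thresholds.
4. **Quantification** (`classify_pairs()`, `collapse_umis()`, `tally()`):
   junction support requires a read to completely cover a window around the
   junction; wild-type-amplicon reads are inspected for indels around the
   cut; reads collapse by (sample, UMI) to molecules; frequencies are
   UMI counts over all detectable molecules including wild type.
5. **Validation statistics** (`haplome_equivalents()`, `min_trials()`,
   `fit_linearity()`, `compare_slopes()`, `estimate_llod()`): input
   accounting, exact binomial power, titration linearity and
   limit-of-detection.
6. **Simulator** (`simulate_library()`): ground-truth-labelled synthetic
   libraries that exercise every stage offline.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| flank | 350 bp | amplicon half-length; comfortably exceeds read length (150) plus the junction window |
| junction window | 15 bp per side | a read supports a junction only if it completely covers this window |
| indel window | 15 bp per side | cut-site neighbourhood inspected for indels on the wild-type amplicon |
| barcode mismatches | 1 per index | demultiplexing tolerance; ties are never broken |
| match / mismatch / gap open / gap extend | +2 / −4 / −6 / −1 | glocal alignment scores; a length-L gap costs 6 + L |
| min identity | 0.8 | fraction of alignment columns that must match for a mate to pass |
| UMI length | 10 nt | the adapter's ten ambiguity positions; 4^10 ≈ 10^6 labels |
| pg per haplome | 3.5 pg | mass of one haploid human genome; 50 ng ≈ 14,300 haplomes (3.2–3.4 Gb assumptions give 14,200–14,700) |

### Coordinate conventions

All coordinates are 0-based and half-open, everywhere — internal offsets,
the junction-offset sidecar TSV, and the truth table. A cut position `p` is
an inter-base coordinate: the LEFT free end is `[0, p)`, the RIGHT free end
`[p, L)`. The junction of an amplicon built with flank `f` is at offset
`f`, and "covers the window" means covering `[f - w, f + w)` — a read whose
alignment ends at `f + w - 1` does **not** cover it.

## Design choices where the design was genuinely open

**Reverse-complement canonicalization.** Junction classes that are
reverse complements of each other are the same molecule read from opposite
strands, so they are stored once, LEFT end first where possible, ties by
locus name then position. This is what makes "ten possible end-joining
outcomes" the exact count for two cuts.

**Re-ligated homolog joins are not a class.** Joining the left end of one
allele to the right end of another reconstructs the wild-type sequence
exactly; sequence-based classification cannot see it, so it is subsumed by
the religation/indel category rather than pretending otherwise.

**Centromere labels are annotations, not classes.** Balanced / dicentric /
acentric describe where centromeres end up and follow mechanically from an
optional per-locus centromere side; they add no sequence information.

**Glocal rather than local alignment.** Reads are aligned end-to-end with
free reference end gaps, approximating the stringency of end-to-end
short-read alignment. Soft clipping is deliberately not modelled: a mate
that runs off its amplicon fails the identity threshold and the pair falls
back to its other mate.

**Single-mate rescue prefers the anchored mate.** When no amplicon passes
on both mates, assignment falls back to a single passing mate, and
primer-side (R1) evidence is preferred over breakpoint-side (R2) evidence at
equal quality. The anchored mate is the one that reads across the junction;
the breakpoint-side mate of a rearranged molecule often lies entirely in
sequence shared with the wild-type amplicon and would otherwise drag
assignments toward wild type on ties. Wild-type-preferring tie-breaking
still applies within each evidence tier, keeping the conservative error
direction (against calling rearrangements on ambiguous evidence).

**Indels inside a junction window.** On a junction amplicon, a read that
covers the window but carries an extra indel stays in the junction category
with the indel recorded — end joining frequently leaves indels at the novel
junction, and these are the same molecules. By default, however, the window
itself must be gap-free for junction support (`require_gapfree = TRUE`);
the spanning-only reading is available behind the flag, because on
wild-type amplicons an in-window indel is exactly the signal being called,
coverage there is always spanning-based.

**Inversion aggregation.** A dual-cut inversion creates two novel
junctions. The enumeration exposes both (`INVERSION_J1`, `INVERSION_J2`);
quantification aggregates them into one `INVERSION` category in which a
molecule supporting either junction counts once. With a single primer only
the primer-adjacent junction is detectable, so in practice the aggregate
equals the one junction's count.

**Denominator.** Frequencies divide UMI counts by **all** molecules
assigned to a detectable category including wild type. Unassignable,
ambiguous (tied majority vote), uninformative (never covering a window) and
low-support molecules are excluded from the denominator and reported in a
QC table. Pie-chart-style percentages that sum below 100% are therefore
interpretable as "fraction of captured molecules".

**Exact binomial tails.** Power and limit-of-detection calculations use
exact binomial tail probabilities (`pbinom`), never a normal approximation;
`min_trials()` finds the minimal n by bisection over the monotone tail.

**The LLoD rule.** "Lower limit of detection" is reported as the lowest
titration level at which at least 90% of replicates detect one or more
molecules **and** the median measured frequency is within 2-fold of truth.
The literature often reports an LLoD without stating a rule; this package's
rule is explicit and adjustable (`detection_rate`, `max_fold_error`), and
readers comparing assays should quote it.

## What the simulator emulates — and what it does not

`simulate_library()` draws each molecule's outcome from the configured
proportions, realizes its full-length sequence (wild type; one indel
touching the cut, deletion/insertion 50/50 with geometric sizes capped at
30; the excision, inversion, fusion or translocation product), places the
anchored fragment from the primer 3' end to a uniform tagmentation
breakpoint with uniform fragment length (150–600 bp), tags it with a random
10-nt UMI, replicates it a geometric number of times (mean 5) as PCR
duplicates sharing fragment ends, and applies independent per-base
substitution errors (default 0.001) to every copy, including barcode and
UMI bases. A per-molecule dropout probability is available as a crude
stand-in for library process yield (~20% in a typical prep); it claims no
mechanistic fidelity.

Deliberately not modelled: Tn5 insertion-site sequence bias (a pluggable
breakpoint distribution would slot in where the uniform draw is), polymerase
jackpot errors (duplicates re-draw errors from the true fragment),
quality-score realism beyond a constant Q, chimeric PCR artifacts,
microhomology or templated insertions at junctions, and the genome-wide
fate of unassignable reads (the pipeline reports an `UNASSIGNED` bucket;
mapping it against a background genome is an external step whose results
can be joined back by read id). Passing recovery tests on simulated data
therefore demonstrates that the **analysis** is correct and unbiased under
the stated generative model — not that the wet assay is free of capture or
amplification bias on real libraries; assay calibration against standards
remains a wet-lab concern.

Fragments shorter than the read length yield truncated reads, flagged in
the truth table; adapter read-through trimming is exercised on constructed
fixtures.

## Numerical and degenerate-input behaviour

* Alignment traceback ties resolve deterministically, match/substitution
  over deletion over insertion, and the leftmost reference end position
  wins; assignment ties prefer wild-type amplicons, then the smaller
  amplicon id. Reruns on identical inputs are byte-identical; frequencies
  are printed to six decimals.
* The batch assigner short-circuits exact substring matches, restricts the
  ungapped candidate scan to diagonals supported by shared 12-mers, and
  refines with a banded dynamic program (band 45, comfortably above the
  30-bp indel cap) around the scan diagonal; `align_semiglobal()` is the
  exact full-matrix reference the fast path is tested against, along with
  an independent memoised oracle and `Biostrings::pairwiseAlignment`.
* Empty FASTQ input produces empty tables with a zero denominator and no
  division; a failing sample is isolated and marked in the run summary
  while the remaining samples complete.
* UMI collisions (two molecules drawing the same 10-mer) merge molecules;
  at 30,000 molecules per library the birthday rate is ~1.4% of molecules
  and category-proportional, well inside the 3-SE recovery bands used in
  the tests. The truth table records collisions so tests can reason about
  them explicitly.
* The directional 1-mismatch UMI collapse (`HAMMING1`) absorbs a UMI with
  count c into a 1-neighbour with count at least 2c − 1, using
  masked-position keys so it scales linearly in the number of UMIs; the
  default remains exact grouping.

## Benchmark scenarios and problem sizes

The package ships two fixed synthetic models (`synthetic_dual_guide_model()`:
one 3,000-bp locus, cuts 1,176 bp apart, primer 100 bp downstream of the
second cut; `synthetic_translocation_model()`: two 2,500-bp loci, one cut
and one primer each). Their sequences are fixed constants of the scenario;
only molecule sampling, fragmentation, duplication and errors respond to
the caller's seed.

The shipped benchmarks run the full file-based pipeline at 30,000 molecules
(dual-guide excision mix: 17% indels, 40% deletion, 18% inversion, 0.75%
homolog fusion, remainder wild type), 2 × 20,000 molecules (translocation
mix: 82% / 91% indels, 2.5% inter-locus fusions per library), 10,000
molecules for assignment robustness, and 2 × 7 titration libraries of 2,860
molecules (the unique-molecule yield of a 50-ng input at ~20% process
yield) from 50% down to 0.1%. These sizes keep each benchmark in the
minutes range on one core while leaving binomial standard errors far below
the effects being measured. The replicate-reproducibility R² of the
titration benchmark is reported as computed; note that at 2,860 molecules
the 0.1% level holds an expected 2.9 molecules, so sampling noise alone
places the two-replicate log-scale R² near 0.98–0.99.

## Known limitations

* Enumeration is specified for at most two simultaneous cuts; the end/join
  formalism does not preclude more, but multiplex panels are out of scope.
* Junction classification is sequence-based; outcomes that reconstruct
  wild-type sequence (perfect religation, homolog-swap religation) are
  indistinguishable from unedited molecules by design.
* The built-in aligner is the reference path; hooking an external aligner
  in is an interface seam (`export_sam()` provides the hand-off format),
  not a tested configuration.
* Base-editing/SNV quantification and de-novo off-target site discovery
  are out of scope.
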