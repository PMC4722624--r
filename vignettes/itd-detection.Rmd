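---
title: "Soft-clip based detection of FLT3 internal tandem duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-clip based detection of FLT3 internal tandem duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itdscan)
```

## The problem

Internal tandem duplications (ITDs) of *FLT3* exons 13–15 are recurrent,
prognostically adverse mutations in acute myeloid leukemia. Their lengths
span from a handful of bases to beyond 200 bp, their allelic burden can be
very low, and one sample may carry several independent ITD clones. On
amplicon deep-sequencing panels they are notoriously hard to call from
short reads: a short duplication in the middle of a read aligns as a simple
insertion (CIGAR `I`) that any general-purpose caller sees, but once the
duplication is long — or sits close to an amplicon end — the read no longer
contains enough wild-type sequence downstream of the event, and the aligner
soft-clips the extra bases (CIGAR `S`) instead. Soft-clipped bases are
ignored by general-purpose variant callers as if they were adapter
sequence, so exactly the long, clinically dramatic ITDs are the ones that
vanish from standard pipelines.

A BWA-MEM-style aligner, however, does not discard the information: it
emits a *separate* secondary/supplementary alignment that maps the clipped
bases back to the same locus. `itdscan` exploits this: it correlates each
qualifying soft-clipping point in a primary alignment with the realignment
of its clipped bases, and reads the duplication length directly off the
distance between the two.

## The detection model

Let `c` be the reference position of the last aligned base before a
terminal soft clip (the *clip point*), and `s` the reference position where
the clipped bases realign (the *realignment start*), with `s <= c` for a
tandem duplication. The inferred length is

```
L = c - s + 1
```

(`infer_itd_length()`). Left-side clips are handled mirror-wise with the
realignment *end*. The analysis is performed per read and per direction, so

* a single supporting read yields a call (rare subclones are not averaged
  away), and
* several distinct (position, length) pairs yield several calls
  (multi-clone samples).

Aggregated calls report per-direction support, the depth at the call
position, and `vaf = support / depth`.

### Micro-homology correction

Modern aligners extend a local alignment as long as bases keep matching.
At a duplication junction there is a 1-in-4 chance per base that the
reference continues with the same letter the read has, so the realignment
is frequently extended one to three bases *across* the junction. Taking
`c - s + 1` at face value then systematically over-estimates `L`. The
evidence collector therefore subtracts the overlap between the primary
alignment's and the realignment's query intervals (both are known in
original-read coordinates, counting soft- and hard-clipped bases). With
this correction the inferred length is exact for every true tandem
duplication; without it, roughly a quarter of simulated duplications come
out off by one to three bases. The same idea corrects the read-pair route
below (`L = overlap + (c1 + 1 - c2)`).

### Evidence quality control

Two artifact classes are filtered:

* **Anchor filter** (`min_anchor`, default 15 bp): the aligned block
  adjacent to the clip must be a matched (`M`) run of at least this length
  on *both* the primary and the realignment. This removes
  junction-crossing primaries that swallowed part of the second copy via a
  small indel and would otherwise produce off-by-a-few length evidence (the
  only source of wrong-length evidence we observed on the exhaustive grid).
* **Minimum inferred length** (`= min_clip`, default 10 bp): a genuine
  duplication shorter than the clip threshold is represented by the aligner
  as a CIGAR insertion, not a clip, so sub-threshold "evidence" can only be
  chance micro-homology at an unrelated breakpoint and is discarded.

`min_clip` (default 10 bp) separates ITD-scale clips from the consistently
short soft clips produced by read-through into universal adapters. Primary
alignments need `mapq >= 1` by default; realignment records are not MAPQ
filtered because supplementary records are often MAPQ 0.

### Pure insertions

A rare ITD type consists entirely of inserted sequence of unknown origin;
its clipped bases realign nowhere, and the route above stays silent. These
are recovered by comparing the clip points within a read pair: one mate
right-clips at `c1`, the other left-clips at `c2 = c1 + 1` (up to
micro-homology slack of one base), and the insert is reconstructed as the
longest overlap between the two clipped sequences. When only one mate
covers the breakpoint, the clip length itself is reported as a
lower-confidence length estimate. Because the rule demands facing clips at
the *same* breakpoint, it can never fire on a tandem duplication (whose
mates always cover the junction with consistent geometry) — this is tested
on the full simulation grid.

### Position reporting

Tandem duplications are coordinate-ambiguous inside a repeat; calls are
reported at the leftmost equivalent start, matching VCF left-alignment
norms and making call merging well-defined. Pure-insertion calls are *not*
shifted: their inserted sequence is arbitrary, so moving the breakpoint
without rotating the insert would corrupt the record.

## The simulator

The simulator produces the idealised data the detection envelope is
defined on: error-free, fixed-start amplicon read pairs.

* **Allele construction.** The duplicated segment is the `L` bases starting
  at ROI position `p`. Since the amplicon is primer-defined, the mutant
  amplicon is `ref[amplicon_start .. p+L-1]` followed by
  `ref[p .. roi_end]`: the first copy may run past the ROI end into genomic
  flank, the second copy ends at the downstream primer. The allele length
  is always `roi_length + L` and the duplication junction always has a
  back-jump of exactly `L` — which is what makes every grid cell carry a
  well-defined truth. (Inserting the copy *after* the ROI instead would
  destroy the junction geometry for every segment crossing the ROI end.)
* **Reads.** Mate 1 is the first `min(read_length, template_length)` bases
  of the template, mate 2 the reverse complement of the last as many; all
  pairs from one allele are identical, qualities are uniformly Q30 (and
  ignored downstream). Reads truncate at the template length: the 242 bp
  wild-type amplicon yields 242 bp reads under the 275 bp default.
* **Burden.** `round(n_pairs * burden)` pairs (half-up, floored at 1 when
  burden > 0) carry the ITD; the single-read-clone scenario is therefore
  always constructible. With the defaults (burden 0.5, 2000 pairs) a
  combination is 1000 ITD + 1000 wild-type pairs.
* **Read names** encode `<combination_id>:<allele>:<pair_index>`, so pooled
  multi-combination runs demultiplex by name after alignment.

Nothing in the simulator draws random numbers; re-running writes
byte-identical FASTQ.

### Primer flanks: 15 bp upstream, 26 bp downstream

The templates carry primer-binding sequence around the ROI (configurable
via `primer_5p`/`primer_3p`; 0/0 gives ROI-only templates). The exact
primer lengths of the TruSight-style *FLT3* amplicon are not public; the
defaults were fixed once, before any grid was run, from the assay's
amplicon architecture and the aligner's scoring arithmetic:

* panel amplicons run 225–275 bp, so with a 201 bp ROI the primers sum to
  24–74 bp; 15 + 26 gives a 242 bp amplicon inside that range;
* `bwa mem` only outputs an alignment scoring at least 30; a duplication at
  the very start of the ROI produces a left clip of `primer_5p + L` bases,
  so `primer_5p = 15` makes a 15 bp duplication the shortest realignable
  event at the amplicon start;
* a duplication starting at ROI position `p` leaves a clipped tail of
  `(202 - p) + primer_3p` bases, so `primer_3p = 26` puts the score-30
  boundary exactly after position 198, leaving the last three start
  positions geometrically undetectable.

ROI-only templates, by contrast, make every start position beyond ~172
undetectable — an envelope no amplicon assay of this class shows — which is
why primer-containing templates are the default.

## Grid evaluation

`run_detection_grid()` simulates every (start, length) combination —
40,401 for the 201 bp ROI — aligns pooled batches of 500 combinations with
the external aligner (default `bwa mem` with default parameters; the
version is recorded in the grid metadata), runs the caller, and scores each
cell with the detection-match criterion: *some call has exactly the
simulated length, at a position within `L` bp of the simulated start* (the
position tolerance absorbs repeat-induced left-alignment shifts; the length
must be exact).

Because reads are error-free and identical within a combination, 4 ITD + 4
wild-type pairs per cell give the same detection map as the 1000 + 1000
preset, and pooling is a pure optimisation — both invariances are tested.
The full grid runs in about two minutes on one CPU.

## Measured envelope and aligner-version sensitivity

With the pinned aligner of this build (bwa 0.7.19, default parameters) and
the synthetic 201 bp reference, the acceptance script measures:

* overall detection rate **69.4 %** of 40,401 combinations;
* maximum detected length **201 bp at every start position 1–198**;
* per-position minimum detectable length spanning **25–80 bp**;
* no start position entirely blind: positions 199–201, whose clipped tails
  are one to three bases short of the aligner's score-30 output threshold,
  still pick up sporadic detections where chance micro-homology lends the
  realignment the missing bases.

The *outer* structure of the envelope (full-length ceiling, per-position
floor rising toward mid-amplicon, geometric blindness pressure at the last
three positions) is stable; the *edge* of the envelope is not an intrinsic
property of the method but of the aligner build. Near its output threshold,
bwa 0.7.19 suppresses short tail realignments unless the junction end falls
within a few bases of the template end, which raises the late-position
minima from the ~15 bp that score arithmetic predicts to ~25 bp, and its
willingness to extend alignments through chance homology converts
"impossible" sub-threshold tails into occasional detections. Older builds
of the same aligner family behave differently at exactly these margins.
Users comparing against envelope figures obtained with another aligner
build should expect the rate to move by a few points and the floor by up to
ten bases; the grid metadata records the aligner version for exactly this
reason, and the acceptance tests that pin the envelope edge to one
particular aligner build are expected to fail under any other.

## Reporting policy

Clinical reporting uses two thresholds: minimum VAF 10 % and minimum depth
500-fold, both inclusive. `apply_reporting_policy()` *labels* calls
(`PASS`, `LowVAF`, `LowDepth`) and never drops them — sub-threshold signal
is routinely what resolves discordances between assays, so it must remain
inspectable. The VCF writer serialises every call, resolving the duplicate
sequence from the reference (explicit ALT allele) and falling back to a
symbolic `<DUP:TANDEM>` with `SVLEN` only when the sequence cannot be
resolved.

## What the synthetic reference does and does not show

The shipped reference (`synthetic_flt3_amplicon.fa`) is a deterministic
random 801 bp sequence (300 bp flank + 201 bp ROI + 300 bp flank) with no
duplicated 15-mer, so seed-and-extend alignment is never confounded by
spurious repeats; it is labelled synthetic and carries no biological
meaning. Passing tests on it demonstrate the *geometry* of the method:
exact length recovery, burden recovery, single-read sensitivity, null
safety on wild-type data. They do not demonstrate robustness to sequencing
errors (the simulator is error-free by design), to the repeat structure of
the real *FLT3* locus, to indel sequencing artifacts near homopolymers, or
to library chemistry effects such as read-through adapter contamination —
on real data those are handled (or not) upstream by the aligner and the
clip-length threshold.

## Numerical choices and degenerate inputs

* Thresholds (`min_vaf`, `min_depth`) are inclusive (`>=`).
* Rounding of ITD pair counts is half-up with a floor of one pair when
  burden is positive.
* Duplicated segments containing `N` are refused (fail fast rather than
  emit ambiguous reads); segments extending past the available right flank
  are an error with the missing extent in the message.
* Wild-type-only input produces an empty call set and a header-only VCF,
  exit status 0.
* When several realignment records qualify for one clip, each contributes
  evidence; aggregation counts a read at most once per direction per
  (position, length).
* Ties in pure-insertion overlap are resolved toward the longest overlap.

## Limitations

* The caller sees only what the aligner clips: duplications the aligner
  absorbs as CIGAR `I` operations are intentionally out of scope (they are
  the easy case for general-purpose callers) — the envelope floor above is
  precisely the boundary between the two regimes.
* Depth is computed from primary alignments overlapping the call position;
  on real libraries with PCR duplicates this is raw, not deduplicated,
  depth.
* The pure-insertion length falls back to the clip length (flagged
  `LOWCONF`) when mates do not both span the insert; with 2 x 275 bp reads
  this limits confident insert sizing to inserts covered by both mates.
* CRAM input, duplicate marking, and base-quality recalibration are out of
  scope.
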