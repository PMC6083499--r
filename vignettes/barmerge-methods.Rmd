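---
title: "Merging paired reads and finishing DNA barcodes with barmerge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging paired reads and finishing DNA barcodes with barmerge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barmerge)
```

## The problem

A DNA barcode is a short standardized marker sequence (COI for animals,
rbcL/matK/ITS for plants and fungi) used to discriminate species. Whether
the marker is Sanger-sequenced (one forward and one reverse trace per
specimen) or read on a short-read instrument as a 2x250 bp paired-end
library, the raw product is the same shape: two reads from opposite ends
of one fragment that overlap in the middle and must be combined into a
single high-quality consensus before submission to a reference database.
barmerge implements that reconstruction and the finishing steps around
it: quality trimming and filtering of the FASTQ input, overlap-based
merging that tolerates both substitutions and indels, per-run quality
reporting, and stop-codon/frameshift correction for barcodes from coding
regions.

## The merge algorithm

`merge_pair()` works seed-first rather than alignment-first, which is what
makes it fast enough to process large batches without a full
dynamic-programming alignment per pair:

1. **Orientation.** The reverse read is reverse-complemented
   (`orient_reverse = TRUE`; Illumina R2 and Sanger reverse traces are
   opposite-strand). If no seed is found in that orientation, anchoring is
   retried against the un-complemented read, so forward-sense input also
   works without preprocessing.
2. **Seeding** (`find_anchor()`). The `seed_length`-mer (default 16)
   ending at the forward read's 3' end is searched for verbatim in the
   oriented mate. On failure the window slides toward the 5' end by
   `seed_step` (default 12) and the search repeats until the window would
   leave the read. If the seed occurs at several positions of the mate,
   the occurrence implying the longest overlap span wins, leftmost on
   ties; with 16 bp seeds a spurious second hit is rare in practice.
3. **Overlap scan** (`scan_overlap()`). The reads are laid out according
   to the anchor and compared column by column. Equal bases — and any
   column involving the generic base `N` — count toward the identity
   score; a base against a gap column also counts (so gap columns do not
   dilute identity, matching the convention that identity is scored over
   alignment columns). At a mismatch, the next `tolerance` columns
   (default 5) are inspected: if they all match, the column is a true
   substitution; otherwise a single-base gap is tried in either read
   (reverse read preferred on ties) and re-tested, up to `repeats`
   (default 4) times. If no insertion restores the register the gaps are
   rolled back and a plain mismatch is charged, which keeps a run of
   disagreement from spiralling into an unbounded gap chain. A run of gap
   columns inserted at one site counts as **one** gap opening.
4. **Acceptance** (`accept_overlap()`). A merge requires
   `overlap_columns >= min_overlap` (default 25),
   `identity_fraction >= min_identity` (default 0.90) and
   `gap_openings <= max_gap_openings` (default 5), all inclusive.
5. **Consensus** (`build_consensus()`). Forward 5' tail + per-column
   consensus + reverse 3' tail. Equal bases keep the higher of the two
   qualities; a true mismatch is resolved toward the higher-quality base
   (ties to the forward read, deterministically); a base beats a gap; a
   called base beats `N`; two `N`s stay `N`.

### Scanning outward from the seed

The seed is the only stretch of the overlap whose register is verified by
an exact match, so the scan proceeds outward from it: rightward to the
forward read's 3' end and leftward to the overlap's 5' boundary (the
leftward pass runs the same scanner on the reversed segments). A naive 5'
to 3' scan from the anchor-implied boundary would mis-register every
column on the far side of an indel: the indel shifts the true 5' boundary
by one base, the first column starts misaligned, and the scanner charges
a spurious extra gap opening at the boundary. Scanning from the seed
makes one real indel cost exactly one gap opening, and any surplus base
at the 5' boundary simply falls outside the scored overlap and is kept as
non-overlap prefix material in the consensus.

### Where the tolerance rule differs from exhaustive alignment

The test suite checks the scan's mismatch and gap-opening counts against
an exhaustive affine-gap aligner on constructed overlaps with up to two
substitutions and one single-base indel. Two structural caveats define
the construction, and they are limits of any fixed-look-ahead scanner,
not of the tests: an indel closer to the overlap's edge than the
look-ahead window is indistinguishable from a substitution (the window is
truncated), and inside a tandem micro-repeat with period up to `repeats`
a shifted register also satisfies the look-ahead, so the greedy scan and
a global aligner may legitimately place gaps differently. Errors in the
constructed cases are therefore separated by more than the tolerance
window, kept clear of the boundaries, and placed in repeat-free
sequence.

## Trimming and filtering

`trim_read()` slides a `window` of 10 bp in `step`s of 1 bp inward from
each end and removes bases while the window's arithmetic-mean Phred
quality is below 20 (Phred 20 = 1% error probability — the conventional
error-probability threshold for barcode work), stopping at the first
passing window; a read shorter than the window is one whole-read window.
The pass is idempotent by construction: whatever survives ends in a
window that passed. `filter_read()` then discards reads shorter than 50
bp (checked first) or with overall mean quality below 20; both bounds
treat "below" strictly, so a mean of exactly 20.0 and a length of exactly
50 survive. Discarded mates are written to separate `rejected` files, and
a pair proceeds to merging only when **both** mates survive — a
conservative gate, since a barcode supported by a single low-quality
direction is not worth submitting.

`quality_report()` tabulates, per read, the fraction of bases below a
user threshold and flags reads above a configurable fraction (default
0.10) as candidates for re-sequencing.

## Stop-codon and frameshift correction

For barcodes from coding regions, `correct_sequence()` orients the
consensus against the forward read (shared 16-mer counting), translates
it in six frames (`+1,+2,+3` from offsets 0/1/2, `-1,-2,-3` on the
reverse complement), picks the frame whose longest stop-free amino-acid
run is maximal — which simultaneously minimizes the impact of stop
codons — and trims everything outside that run, including the bounding
stop codons. Ties go to frame order `+1,+2,+3,-1,-2,-3`. Two deliberate
choices:

* An initiating ATG is **not** required. Barcode amplicons are internal
  gene fragments (rbcL, COI) and rarely begin at a start codon; requiring
  one would truncate valid barcodes.
* A chosen run shorter than `min_orf_aa` (default 10 aa) is flagged "no
  credible ORF" and the sequence passes through untrimmed, rather than
  emitting a fragment of a spurious micro-ORF.

On very short sequences the rule can surprise: the reverse complement of
a stop-bounded mini-ORF is often stop-free over its whole length and
therefore wins. This is the rule working as stated — with realistic
barcode lengths (hundreds of codons) the coding frame dominates all five
alternatives by a wide margin.

NCBI translation tables 1 (standard), 2 (vertebrate mitochondrial), 5
(invertebrate mitochondrial — needed for COI) and 11 (bacterial/plastid)
are available through `codon_table()`; codons containing `N` translate to
`X`, never to a stop, so an ambiguous base can never trigger a trim.
For reverse frames the reported ORF coordinates refer to the oriented
input, while `corrected_nt` reads in the chosen frame's direction so that
translating it reproduces `corrected_aa` exactly.

## The simulator

`simulate_pairs()` emulates, at desk scale, a MiSeq-like 2x250 bp run
over ~400 bp fragments — the regime where paired reads overlap by ~100
bp: fragment lengths are Normal(400, 10) rounded, with draws outside
`[read_length, 2*read_length - 25]` rejected so every pair has a usable
overlap; fragment starts are uniform on the reference. Per-base Phred
values follow a monotone mean curve from 37 at cycle 1 to 30 at the last
cycle with Gaussian jitter (sd 3, floor 2) — stated here as the fixture
definition, not as a claim about any instrument. Substitutions are
injected per base with probability `10^(-q/10)`, i.e. the error the
emitted quality claims, and single-base insertions/deletions occur at
`indel_rate` (default 1e-4). Every injected error is recorded in a truth
structure sufficient to replay each read byte-exactly from its fragment
(`replay_truth()`), which is what the simulator's own tests and the
evaluation harness lean on.

`simulate_sanger_pair()` produces the long (500-700 bp) forward/reverse
mates of a Sanger-style barcode with a low-high-low quality ramp, so that
end-trimming, `N` handling (Ns are injected at sub-Q20 positions) and the
QC + merge path are exercised end to end; `clean` and `low` profiles give
the two extremes (exact recovery; both mates discarded).

What the generator does **not** emulate: position- and motif-dependent
error profiles learned from real instruments, quality miscalibration,
chimeras, adapter read-through, or chromatogram-level artifacts. Passing
tests on simulated data therefore demonstrate the algorithm's
correctness under its stated error model, not performance on any
particular instrument's quirks.

## Evaluation harness

`evaluate_merged()` mirrors the usual merged-pair benchmark: the fraction
of pairs merged, merged-length moments, and identity / mismatch /
gap-opening means from aligning each merged sequence back to the
reference. The aligner is `Biostrings::pairwiseAlignment()` (local,
match +1, mismatch -1, gap open 2, extend 0.5, both strands, score floor
30), chosen to approximate a megablast-style aligner on near-identical
sequences; absolute mismatch and gap counts from other aligners can
differ slightly, which the report header discloses. Identity is computed
over alignment columns, gap columns included, to share its denominator
with the other counts. Local alignment against a long reference is
quadratic, so when simulation truth is available each merged sequence is
aligned only against a +/-50 bp window around its true fragment, and the
alignment-derived means may be computed on a subsample
(`sample_n`) — merge rates and lengths always use all pairs.

## Problem sizes and reproducibility

The package's own checks run at these sizes, chosen to exercise every
code path at desk scale: 1,000 zero-error pairs for exact recovery;
10,000 MiSeq-like pairs from a random 1 Mb reference (GC 0.5) for the
merge-rate and length summary, with alignment statistics on a 1,500-pair
subsample; 500 constructed overlaps against the exhaustive aligner; 1,000
random quality strings against the brute-force trim oracle; 100
randomized CDS-in-flank constructions for frame correction. All
randomness flows through explicit seeds, and re-running the pipeline on
the same input and configuration is byte-identical.

## Known limitations

* One merge per pair: no multi-read assembly, no k-mer-frequency
  rescue of non-overlapping pairs, and no statistical test on the
  overlap (a pair either passes the length/identity/gap thresholds or is
  passed through unmerged).
* The seed must match exactly; a pair whose true overlap is shorter than
  `seed_length` can never anchor and is reported `no_seed`.
* Identity counts `N`-columns and gap columns as hits, which slightly
  flatters low-quality overlaps; the quality filter upstream is the
  intended guard.
* Frameshift "correction" trims to the longest intact reading — it does
  not re-insert the missing base, so material on the far side of a
  frameshift is discarded by design.
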