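# barmerge

Merging paired reads and finishing DNA barcodes.

DNA barcoding identifies species from short standardized marker sequences
(COI, rbcL, matK, ITS). Whether the marker was Sanger-sequenced (one
forward and one reverse read per specimen) or read as a 2×250 bp
paired-end library, the raw data are two reads from opposite ends of one
fragment that overlap in the middle. `barmerge` reconstructs the fragment
and prepares it for submission:

* **Merging** — a seed-and-extend overlap merger that tolerates both
  substitutions and indels and keeps the non-overlapped tails. A
  `seed_length`-mer (16 bp) from the forward read's 3′ end anchors the
  pair (sliding inward by `seed_step` = 12 bp on failure); the overlap is
  then scanned column by column outward from the seed. At a mismatch, if
  the next `tolerance` = 5 columns all match it is a substitution;
  otherwise single-base gaps are inserted and re-tested up to
  `repeat` = 4 times, rolled back to a plain mismatch if the register
  never recovers. A merge is accepted when the overlap spans ≥
  `min_overlap` (25) columns at ≥ `min_identity` (90%) with ≤
  `max_gap_openings` (5); conflicting bases are resolved toward the
  higher Phred quality, and a called base always beats an `N`.
* **QC** — sliding-window quality trimming (window 10 bp, step 1 bp,
  mean Phred < 20 trimmed from both ends) and filtering (length < 50 bp
  or mean quality < 20 discarded), plus a per-read quality report.
* **ORF finishing** — for coding barcodes: orient, translate in six
  frames, keep the frame with the largest ORF (longest stop-free
  amino-acid run), trim the bounding stop codons; tables 1, 2, 5 and 11.
* **Simulation & evaluation** — a paired-read generator with a
  quality-dependent error model and exact truth records, and an
  alignment-based harness reporting merge rate, lengths, identity,
  mismatches and gap openings against a reference.

## Worked example

Simulate 500 MiSeq-like pairs from a random reference, merge them, and
score the merged sequences against the reference:

```r
library(barmerge)

ref <- random_reference(200000, seed = 42)
sim <- simulate_pairs(ref, sim_params(n_pairs = 500), seed = 43)
res <- merge_pairs(sim$pairs, merge_params(min_overlap = 10))
summary(res)
#> pairs: 500  merged: 500 (100.00%)
#> merged length: 400.05 +/- 9.87 bp; overlap 100.0 col; identity 99.80%; gaps 0.02

evaluate_merged(res, ref, truth = sim$truth, sample_n = 200)
#> Merge evaluation (native local aligner; absolute mismatch/gap counts may differ from BLAST-derived figures)
#>   input pairs : 500
#>   merged      : 500 (100.00%)
#>   merged length: 400.05 +/- 9.87 bp
#>   identity: 99.94% +/- 0.13; mismatches 0.23; gap openings 0.01 (on 200 aligned, 0 unaligned)
```

All 500 pairs merge; merged lengths track the simulated fragment
distribution (400 ± 10 bp), and aligning the consensuses back to the
reference shows the residual error the quality model injected (~0.2
mismatches per ~400 bp merged sequence). A single pair shows the
diagnostics:

```r
merge_pair(sim$pairs[[1]])
#> <merge_outcome> status: merged
#>   overlap 99 col, identity 100.0%, 0 mismatch, 0 gap opening(s)
#>   consensus: 401 bp
```

The whole pipeline (QC → merge → optional ORF correction → reports) runs
on paired FASTQ files with `run_pipeline(fwd, rev, out_dir)`, or from a
shell via the bundled CLI:

```sh
inst/cli/barmerge pipeline --fwd fwd.fastq --rev rev.fastq --out out/ --coding --table 5
```

Outputs: `barcodes.fasta` (+ `barcodes.faa` with `--coding`),
`unmerged_1/2.fastq`, `rejected_1/2.fastq`, `qc_report.tsv`,
`merge_report.tsv` and a `run.log` with all effective parameters; every
input pair lands in exactly one of merged/unmerged/rejected.

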