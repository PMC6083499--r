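test_that("anchoring finds a shared 3'-end seed and slides on failure", {
  p <- merge_params()
  set.seed(404)
  # forward ends with S, oriented reverse starts with S
  S <- random_seq(16)
  fwd <- bar_read("f", paste0(random_seq(50), S), rep(40L, 66))
  rev <- bar_read("r", paste0(S, random_seq(50)), rep(40L, 66))
  a <- find_anchor(fwd, rev, p)
  expect_equal(a$seed_start_fwd, 50L)
  expect_equal(a$seed_start_rev, 0L)
  expect_equal(a$overlap_len, 16L)

  # seed only found after sliding: shared block ends 12 bp before fwd's 3' end
  frag <- random_seq(120)
  fwd2 <- bar_read("f", paste0(substr(frag, 1, 80), random_seq(12)),
                   rep(40L, 92))
  rev2 <- bar_read("r", substr(frag, 41, 120), rep(40L, 80))
  a2 <- find_anchor(fwd2, rev2, p)
  expect_false(is.null(a2))
  expect_lt(a2$seed_start_fwd, 92L - 16L)

  # no shared 16-mer at all
  none <- find_anchor(bar_read("x", strrep("A", 60), rep(40L, 60)),
                      bar_read("y", strrep("C", 60), rep(40L, 60)), p)
  expect_null(none)

  # read shorter than the seed
  expect_null(find_anchor(bar_read("s", "ACGT", rep(40L, 4)),
                          bar_read("y", random_seq(30), rep(40L, 30)), p))
})

test_that("a multi-hit seed resolves to the occurrence with the longest overlap", {
  p <- merge_params()
  set.seed(405)
  S <- random_seq(16)
  # S occurs twice in the mate; enumerate both and check the chosen one
  mid <- random_seq(40)
  fwd <- bar_read("f", paste0(random_seq(30), S), rep(40L, 46))
  rev <- bar_read("r", paste0(S, mid, S, random_seq(20)), rep(40L, 92))
  a <- find_anchor(fwd, rev, p)
  occs <- as.integer(gregexpr(S, rev$seq, fixed = TRUE)[[1]]) - 1L
  expect_length(occs, 2L)
  spans <- vapply(occs, function(o) {
    off <- a$seed_start_fwd - o
    min(nchar(fwd$seq), off + nchar(rev$seq)) - max(0L, off)
  }, numeric(1))
  expect_equal(a$seed_start_rev, occs[which.max(spans)])
  expect_equal(a$overlap_len, max(spans))
})

test_that("a clean overlap scores full identity over its columns", {
  p <- merge_params()
  frag <- random_reference(130, seed = 406)
  fwd <- bar_read("f", substr(frag, 1, 80), rep(40L, 80))
  rev <- bar_read("r", substr(frag, 51, 130), rep(40L, 80))
  a <- find_anchor(fwd, rev, p)
  sc <- scan_overlap(fwd, rev, a, p)$score
  expect_equal(sc$overlap_columns, 30L)
  expect_equal(sc$identity_count, 30L)
  expect_equal(sc$mismatch_count, 0L)
  expect_equal(sc$gap_openings, 0L)
  expect_equal(sc$identity_fraction, 1)
})

test_that("an isolated substitution is charged as one mismatch", {
  p <- merge_params()
  frag <- random_reference(130, seed = 407)
  fwd_seq <- mutate_base(substr(frag, 1, 80), 60)   # inside the overlap
  fwd <- bar_read("f", fwd_seq, rep(40L, 80))
  rev <- bar_read("r", substr(frag, 51, 130), rep(40L, 80))
  sc <- scan_overlap(fwd, rev, find_anchor(fwd, rev, p), p)$score
  expect_equal(sc$mismatch_count, 1L)
  expect_equal(sc$gap_openings, 0L)
  expect_equal(sc$overlap_columns, 30L)
})

test_that("a single-base insertion is absorbed as one gap opening", {
  p <- merge_params()
  set.seed(408)
  frag <- random_seq(130)
  # insert one base into the forward copy of the overlap, mid-region
  fwd_seq <- paste0(substr(frag, 1, 64), "A", substr(frag, 65, 80))
  fwd <- bar_read("f", fwd_seq, rep(40L, 81))
  rev <- bar_read("r", substr(frag, 51, 130), rep(40L, 80))
  a <- find_anchor(fwd, rev, p)
  scan <- scan_overlap(fwd, rev, a, p)
  sc <- scan$score
  expect_equal(sc$gap_openings, 1L)
  expect_equal(sc$mismatch_count, 0L)
  # the DP aligner places exactly one gap on the true overlap copies
  dp <- dp_align_counts(substr(fwd_seq, 51, 81), substr(frag, 51, 80))
  expect_equal(unname(dp["gap_openings"]), 1L)
  expect_equal(unname(dp["mismatch"]), 0L)
})

test_that("acceptance thresholds are inclusive and name the rejection", {
  p <- merge_params()
  sc <- function(cols, idf, gaps = 0L)
    structure(list(identity_count = round(idf * cols),
                   mismatch_count = cols - round(idf * cols),
                   gap_openings = gaps, overlap_columns = cols,
                   identity_fraction = idf), class = "overlap_score")
  expect_equal(accept_overlap(sc(20, 1.0), p)$reason, "short_overlap")
  expect_equal(accept_overlap(sc(189, 0.273), p)$reason, "low_identity")
  expect_true(accept_overlap(sc(25, 0.90, 5L), p)$accepted)   # boundary
  expect_equal(accept_overlap(sc(25, 0.90, 6L), p)$reason, "too_many_gaps")
  expect_equal(accept_overlap(sc(24, 1.0), p)$reason, "short_overlap")
})

test_that("consensus resolves conflicts by quality and honors the N policy", {
  p <- merge_params()
  frag <- random_reference(130, seed = 409)
  # mismatch at overlap position: fwd has wrong base at low quality
  fwd_seq <- mutate_base(substr(frag, 1, 80), 60)
  fq <- rep(40L, 80); fq[60] <- 10L
  fwd <- bar_read("f", fwd_seq, fq)
  rev <- bar_read("r", substr(frag, 51, 130), rep(35L, 80))
  out <- merge_pair(bar_read_pair(fwd, reverse_complement(rev)), p)
  expect_equal(out$status, "merged")
  expect_equal(out$consensus$seq, frag)        # high-quality base won
  expect_equal(out$consensus$quals[60], 35L)

  # same position, but now the wrong base has the HIGHER quality
  fq2 <- rep(40L, 80); fq2[60] <- 41L
  out2 <- merge_pair(bar_read_pair(bar_read("f", fwd_seq, fq2),
                                   reverse_complement(rev)), p)
  expect_equal(substr(out2$consensus$seq, 60, 60), substr(fwd_seq, 60, 60))

  # N against a called base takes the called base, both-N stays N
  fwd_n <- substr(frag, 1, 80)
  substr(fwd_n, 70, 70) <- "N"
  out3 <- merge_pair(bar_read_pair(bar_read("f", fwd_n, rep(2L, 80)),
                                   reverse_complement(rev)), p)
  expect_equal(out3$consensus$seq, frag)
  rev_n <- substr(frag, 51, 130)
  substr(rev_n, 20, 20) <- "N"                 # same fragment position 70
  out4 <- merge_pair(bar_read_pair(bar_read("f", fwd_n, rep(40L, 80)),
                                   reverse_complement(
                                     bar_read("r", rev_n, rep(40L, 80)))), p)
  expect_equal(substr(out4$consensus$seq, 70, 70), "N")
})

test_that("merge_pair recovers the fragment from error-free innie pairs", {
  p <- merge_params()
  set.seed(410)
  for (i in 1:25) {
    flen <- sample(300:470, 1)
    frag <- random_seq(flen)
    pair <- pair_from_fragment(frag, 250L)
    out <- merge_pair(pair, p)
    expect_equal(out$status, "merged")
    expect_equal(out$consensus$seq, frag)
    # clean merges have no gap columns: length is additive in the overlap
    expect_equal(nchar(out$consensus$seq),
                 500L - out$score$overlap_columns)
  }
})

test_that("merging is symmetric under mate swap and re-complementation", {
  p <- merge_params()
  set.seed(411)
  for (i in 1:10) {
    frag <- random_seq(sample(320:460, 1))
    pair <- pair_from_fragment(frag, 250L)
    a <- merge_pair(pair, p)
    expect_equal(a$status, "merged")
    # swapping the mates reports the consensus on the other strand
    swapped <- bar_read_pair(pair$reverse, pair$forward)
    b <- merge_pair(swapped, p)
    expect_equal(b$status, "merged")
    expect_equal(rc_str(b$consensus$seq), a$consensus$seq)
    # re-complementing both mates of the swap restores the original strand
    recomp <- bar_read_pair(reverse_complement(pair$reverse),
                            reverse_complement(pair$forward))
    d <- merge_pair(recomp, p)
    expect_equal(d$status, "merged")
    expect_equal(d$consensus$seq, a$consensus$seq)
  }
})

test_that("orientation falls back when the reverse read is already forward-sense", {
  p <- merge_params()
  frag <- random_reference(400, seed = 412)
  fwd <- bar_read("f", substr(frag, 1, 250), rep(40L, 250))
  rev_fs <- bar_read("r", substr(frag, 151, 400), rep(40L, 250))
  out <- merge_pair(bar_read_pair(fwd, rev_fs), p)
  expect_equal(out$status, "merged")
  expect_equal(out$orientation, "as_is")
  expect_equal(out$consensus$seq, frag)
})

test_that("pairs without a usable overlap are rejected with a reason", {
  p <- merge_params()
  set.seed(413)
  # no common 16-mer in either orientation: AC-repeat vs poly-A
  fseq <- strrep("AC", 125); rseq <- strrep("A", 250)
  for (s in c(rseq, rc_str(rseq)))
    expect_length(intersect(barmerge:::kmer_set(fseq, 16L),
                            barmerge:::kmer_set(s, 16L)), 0L)
  out <- merge_pair(bar_read_pair(bar_read("f", fseq, rep(40L, 250)),
                                  bar_read("r", rseq, rep(40L, 250))), p)
  expect_equal(out$status, "no_seed")
  expect_null(out$consensus)

  # true overlap of 20 bp with perfect identity: below min_overlap 25
  frag <- random_seq(480)
  out2 <- merge_pair(pair_from_fragment(frag, 250L), p)
  expect_equal(out2$status, "short_overlap")
  expect_equal(out2$score$overlap_columns, 20L)
  expect_equal(out2$score$identity_fraction, 1)

  # true overlap of 12 bp: shorter than the seed, no anchor possible
  frag3 <- random_seq(488)
  out3 <- merge_pair(pair_from_fragment(frag3, 250L), p)
  expect_equal(out3$status, "no_seed")

  # long overlap but random-sequence identity (~25%): low_identity
  S <- random_seq(16)
  fwd4 <- bar_read("f", paste0(random_seq(173), S), rep(40L, 189))
  rev4 <- bar_read("r", paste0(random_seq(173), S), rep(40L, 189))
  # the un-complemented fallback anchors the reads tail-to-tail:
  # an overlap of 189 columns of mostly noise
  a4 <- find_anchor(fwd4, rev4, p)
  out4 <- merge_pair(bar_read_pair(fwd4, rev4), p)
  expect_false(is.null(a4))
  expect_equal(out4$status, "low_identity")
})

test_that("accepted merges always satisfy the thresholds they were tested on", {
  p <- merge_params(min_overlap = 10L)
  ref <- random_reference(2e5, gc = 0.5, seed = 414)
  sim <- simulate_pairs(ref, sim_params(n_pairs = 400), seed = 415)
  res <- merge_pairs(sim$pairs, p)
  rep_ <- res$report
  merged <- rep_[rep_$status == "merged", ]
  expect_gt(nrow(merged), 0L)
  expect_true(all(merged$overlap_columns >= p$min_overlap))
  expect_true(all(merged$identity_pct >= 100 * p$min_identity))
  expect_true(all(merged$gap_openings <= p$max_gap_openings))
  # consensus length never exceeds the summed read lengths
  lens <- vapply(sim$pairs, function(pr)
    nchar(pr$forward$seq) + nchar(pr$reverse$seq), numeric(1))
  expect_true(all(merged$merged_length <= lens[rep_$status == "merged"]))
})

test_that("scan counts match the DP aligner on sparse-error overlaps", {
  p <- merge_params()
  set.seed(416)
  for (i in seq_len(120)) {
    case <- make_overlap_case(ov_len = sample(40:60, 1),
                              n_sub = sample(0:2, 1),
                              n_ind = sample(0:1, 1))
    a <- find_anchor(case$fwd, case$rev, p)
    expect_false(is.null(a))
    scan <- scan_overlap(case$fwd, case$rev, a, p)
    # oracle: exhaustive DP alignment of the true overlap copies
    dp <- dp_align_counts(case$ov_fwd, case$ov_rev)
    expect_equal(scan$score$mismatch_count, unname(dp["mismatch"]))
    expect_equal(scan$score$gap_openings, unname(dp["gap_openings"]))
  }
})
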