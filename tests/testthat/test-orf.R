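test_that("six-frame translation reads both strands at all offsets", {
  fr <- translate_six_frames("ATGAAATAG")
  expect_equal(fr[["+1"]], "MK*")
  expect_equal(fr[["+2"]], "*N")      # TGA AAT -> * N
  expect_equal(fr[["+3"]], "EI")      # GAA ATA -> E I
  # reverse strand: revcomp is CTATTTCAT
  expect_equal(fr[["-1"]], "LFH")
  expect_length(fr, 6L)

  # codons containing N give X, never a stop
  expect_equal(translate_six_frames("ANGAAA")[["+1"]], "XK")
  expect_false(grepl("\\*", translate_six_frames("TNAANNNNA")[["+1"]]))

  expect_error(translate_six_frames("AT"), "codon")
})

translate_codons_chk <- function(nt, code) {
  substr(translate_six_frames(paste0(nt, "AAA"), code)[["+1"]], 1, 1)
}

test_that("alternative genetic codes change the stop set", {
  # AGA is Arg under the standard code but a stop in vertebrate mito (2)
  expect_equal(translate_codons_chk("AGA", codon_table(1)), "R")
  expect_equal(translate_codons_chk("AGA", codon_table(2)), "*")
  # TGA is a stop under table 1 but Trp under tables 2 and 5
  expect_equal(translate_codons_chk("TGA", codon_table(5)), "W")
})

test_that("frame selection maximizes the stop-free run with ordered ties", {
  frames <- c("+1" = "AA*BBBB*C", "+2" = "DDDDDDDD", "+3" = "E*E*E*E*",
              "-1" = "FFFF*FFF", "-2" = "G", "-3" = "")
  sel <- select_frame(frames)
  expect_equal(sel$frame, "+2")
  expect_equal(sel$aa_len, 8L)
  expect_equal(unname(sel$stops_found[c("+1", "+3")]), c(2L, 4L))

  # all frames contain stops: longest inter-stop run wins
  frames2 <- c("+1" = "A*AA*A", "+2" = "BBB*B", "+3" = "*CC*",
               "-1" = "D*D", "-2" = "*E", "-3" = "F*")
  sel2 <- select_frame(frames2)
  expect_equal(sel2$frame, "+2")
  expect_equal(sel2$aa_start, 1L)
  expect_equal(sel2$aa_len, 3L)

  # tie between +1 and -1 resolves to +1
  frames3 <- c("+1" = "AAA*", "+2" = "B*", "+3" = "C*", "-1" = "*DDD",
               "-2" = "E*", "-3" = "F*")
  expect_equal(select_frame(frames3)$frame, "+1")
})

test_that("orientation follows shared k-mers with the forward read", {
  set.seed(501)
  core <- random_seq(80)
  fwd_read <- bar_read("f", core, rep(40L, 80))
  consensus <- bar_read("c", paste0(random_seq(30), core, random_seq(30)),
                        rep(40L, 140))
  expect_equal(orient_to_forward(consensus, fwd_read)$seq, consensus$seq)
  flipped <- reverse_complement(consensus)
  expect_equal(orient_to_forward(flipped, fwd_read)$seq, consensus$seq)
  unrelated <- bar_read("u", strrep("AT", 40), rep(40L, 80))
  expect_warning(out <- orient_to_forward(unrelated, fwd_read),
                 "undetermined")
  expect_equal(out$seq, unrelated$seq)
})

test_that("bounding stop codons are trimmed from the chosen frame", {
  nt <- paste0(
    "TAA", "ATGGAGTTGAACTTTACTGGGCACAGCCTTCCTGGCGCCATGCCGCCGAGTGATGTTTACTCA",
    "TGA")
  fc <- correct_sequence(bar_read("b", nt, rep(40L, nchar(nt))),
                         min_orf_aa = 1)
  expect_equal(fc$chosen_frame, "+1")
  expect_equal(fc$orf_start, 3L)
  expect_equal(fc$orf_end, nchar(nt) - 3L)
  expect_equal(fc$corrected_nt, substr(nt, 4, nchar(nt) - 3))
  expect_false(grepl("\\*", fc$corrected_aa))
  expect_equal(nchar(fc$corrected_nt), 3L * nchar(fc$corrected_aa))

  # already stop-free in frame +1: unchanged
  clean <- substr(nt, 4, nchar(nt) - 3)
  fc2 <- correct_sequence(bar_read("b", clean, rep(40L, nchar(clean))),
                          min_orf_aa = 1)
  expect_equal(fc2$chosen_frame, "+1")
  expect_equal(fc2$corrected_nt, clean)
})

test_that("a too-short ORF passes through untrimmed with a flag", {
  set.seed(502)
  nt <- "TAGATGTAGCCC"
  expect_warning(fc <- correct_sequence(bar_read("x", nt, rep(40L, 12)),
                                        min_orf_aa = 10),
                 "no credible ORF")
  expect_false(fc$credible)
  expect_equal(fc$corrected_nt, nt)
})

test_that("clean CDS in random flanks is recovered on either strand", {
  set.seed(503)
  ok_frames <- character(0)
  for (i in 1:100) {
    # a long ORF so no random stop-free run on the other strand can beat it
    cds <- random_cds(250)
    flank5 <- random_seq(sample(10:40, 1))
    flank3 <- random_seq(sample(10:40, 1))
    sense <- paste0(flank5, "TAA", cds, "TGA", flank3)
    on_minus <- runif(1) < 0.5
    nt <- if (on_minus) rc_str(sense) else sense
    fc <- correct_sequence(bar_read("t", nt, rep(40L, nchar(nt))))
    expect_true(fc$credible)
    expect_false(grepl("\\*", fc$corrected_aa))
    expect_equal(nchar(fc$corrected_nt) %% 3L, 0L)
    # the recovered run must contain the full CDS
    expect_true(grepl(cds, fc$corrected_nt, fixed = TRUE))
    expect_equal(substr(fc$chosen_frame, 1, 1), if (on_minus) "-" else "+")
    ok_frames <- c(ok_frames, fc$chosen_frame)
  }
  expect_gt(length(unique(ok_frames)), 2L)   # offsets vary the frame
})

test_that("frameshift input yields a stop-free product from the intact side", {
  set.seed(504)
  for (i in 1:20) {
    cds <- random_cds(80)                    # 240 nt
    pos <- sample(60:180, 1)
    shifted <- paste0(substr(cds, 1, pos - 1),
                      substr(cds, pos + 1, nchar(cds)))  # one deleted base
    fc <- correct_sequence(bar_read("fs", shifted,
                                    rep(40L, nchar(shifted))),
                           min_orf_aa = 5)
    expect_true(fc$credible)
    expect_false(grepl("\\*", fc$corrected_aa))
    expect_equal(nchar(fc$corrected_nt) %% 3L, 0L)
  }
})

test_that("correction is idempotent on its own output", {
  set.seed(505)
  for (i in 1:20) {
    cds <- random_cds(50)
    nt <- paste0(random_seq(20), "TAA", cds, "TAG", random_seq(20))
    fc <- correct_sequence(bar_read("t", nt, rep(40L, nchar(nt))))
    again <- correct_sequence(bar_read("t", fc$corrected_nt,
                                       rep(40L, nchar(fc$corrected_nt))))
    expect_equal(again$corrected_nt, fc$corrected_nt)
    expect_equal(again$corrected_aa, fc$corrected_aa)
    expect_equal(again$chosen_frame, "+1")
  }
})
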