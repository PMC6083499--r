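# Independent oracles and generators for the test suite. These deliberately
# avoid the package's internal code paths: the trim oracle is a dumb window
# scan, and alignment counts come from Biostrings' dynamic-programming
# aligner.

# Brute-force sliding-window trim: scan every window position from one end,
# stop at the first window whose mean reaches the threshold. Returns the
# surviving 1-based [start, end] interval (start > end when emptied).
oracle_trim_interval <- function(quals, window, step, threshold) {
  n <- length(quals)
  side <- function(q) {
    pos <- 1L
    repeat {
      if (pos > length(q)) return(length(q))
      win <- q[pos:min(pos + window - 1L, length(q))]
      if (mean(win) >= threshold) return(pos - 1L)
      pos <- pos + step
    }
  }
  t5 <- side(quals)
  rest <- if (t5 < n) quals[(t5 + 1L):n] else integer(0)
  t3 <- side(rev(rest))
  c(start = t5 + 1L, end = t5 + length(rest) - t3)
}

# Dynamic-programming alignment counts (mismatches, gap openings) of two
# sequences via Biostrings' global aligner with unit match/mismatch scores
# and an affine gap cost that keeps indels as single openings.
dp_align_counts <- function(s1, s2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 1)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  n_gap_runs <- function(s) {
    m <- gregexpr("-+", s)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }
  c(mismatch = Biostrings::nmismatch(pa),
    gap_openings = n_gap_runs(ap) + n_gap_runs(as_))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_read <- function(id, n, qmin = 2L, qmax = 41L) {
  bar_read(id, random_seq(n), sample(qmin:qmax, n, replace = TRUE))
}

# Mutate one base of a sequence to a different base.
mutate_base <- function(s, pos) {
  b <- substr(s, pos, pos)
  repl <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  substr(s, pos, pos) <- repl
  s
}

# Build an innie read pair from a fragment: forward read is the first
# `len` bases, reverse read is the reverse complement of the last `len`.
pair_from_fragment <- function(frag, len, q = 40L, id = "pair") {
  n <- nchar(frag)
  fwd <- bar_read(id, substr(frag, 1L, len), rep(q, len))
  rev <- reverse_complement(
    bar_read(id, substr(frag, n - len + 1L, n), rep(q, len)))
  bar_read_pair(fwd, rev)
}

rc_str <- function(s) barmerge:::revcomp_str(s)

# Construct an overlap instance: fwd = flank + overlap copy, rev =
# mutated overlap copy + flank, with n_sub substitutions and n_ind
# single-base indels placed in the reverse copy. Errors are separated by
# more than the tolerance window, clear of the 3'-end seed region, and at
# least tolerance+2 columns from the overlap's 5' edge (an indel closer
# to an edge than the look-ahead window is indistinguishable from a
# mismatch by construction of the tolerance rule). Returns the reads and
# the two true overlap copies for the DP oracle.
# TRUE when s contains a tandem micro-repeat of period <= max_p spanning
# at least `run` shifted matches: inside such repeats a fixed-length
# look-ahead cannot distinguish an indel from a shifted register, so the
# greedy scan and a global DP aligner may legitimately disagree there.
has_microrepeat <- function(s, max_p = 4L, run = 5L) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(v)
  for (p in seq_len(max_p)) {
    if (n - p < run) next
    eq <- v[seq_len(n - p)] == v[(p + 1L):n]
    r <- rle(eq)
    if (any(r$values & r$lengths >= run)) return(TRUE)
  }
  FALSE
}

make_overlap_case <- function(ov_len, n_sub = 0L, n_ind = 0L,
                              flank = 60L, q = 40L) {
  repeat {
    ov <- random_seq(ov_len)
    if (!has_microrepeat(ov)) break
  }
  ov_rev <- ov
  slots <- seq(8L, ov_len - 22L, by = 8L)
  picks <- sample(slots, min(n_sub + n_ind, length(slots)))
  sub_pos <- head(picks, n_sub)
  ind_pos <- tail(picks, max(0L, length(picks) - n_sub))
  for (sp in sub_pos) ov_rev <- mutate_base(ov_rev, sp)
  if (length(ind_pos)) {
    ip <- ind_pos[1L]
    ov_rev <- if (runif(1) < 0.5)
      paste0(substr(ov_rev, 1, ip), sample(c("A", "C", "G", "T"), 1),
             substr(ov_rev, ip + 1, nchar(ov_rev)))
    else
      paste0(substr(ov_rev, 1, ip - 1), substr(ov_rev, ip + 1, nchar(ov_rev)))
  }
  fwd_seq <- paste0(random_seq(flank), ov)
  rev_seq <- paste0(ov_rev, random_seq(flank))
  list(fwd = bar_read("f", fwd_seq, rep(q, nchar(fwd_seq))),
       rev = bar_read("r", rev_seq, rep(q, nchar(rev_seq))),
       ov_fwd = ov, ov_rev = ov_rev,
       n_sub = length(sub_pos), n_ind = length(ind_pos))
}

# Random coding sequence of n_codons sense codons starting with ATG.
random_cds <- function(n_codons) {
  code <- codon_table(1L)
  sense <- setdiff(names(code), names(code)[code == "*"])
  paste0("ATG", paste(sample(sense, n_codons - 1L, replace = TRUE),
                      collapse = ""))
}
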