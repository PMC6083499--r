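#' Fetch an NCBI genetic-code table
#'
#' Returns the codon-to-amino-acid map for an NCBI translation table.
#' Tables 1 (standard), 2 (vertebrate mitochondrial), 5 (invertebrate
#' mitochondrial, used for COI barcodes) and 11 (bacterial/plastid) are the
#' ones commonly needed for barcode markers; any table id known to
#' Biostrings is accepted. Codons containing `N` translate to `X`, never to
#' a stop.
#'
#' @param table_id NCBI genetic-code table number (default 1).
#' @return A named character vector mapping the 64 codons to amino acids
#'   (`*` = stop), with attribute `table_id`.
#' @export
codon_table <- function(table_id = 1L) {
  code <- Biostrings::getGeneticCode(as.character(table_id))
  structure(code[1:64], table_id = as.integer(table_id))
}

translate_codons <- function(nt_chars, code) {
  n_codons <- length(nt_chars) %/% 3L
  if (n_codons == 0L) return("")
  idx <- seq_len(n_codons * 3L)
  codons <- paste0(nt_chars[idx[c(TRUE, FALSE, FALSE)]],
                   nt_chars[idx[c(FALSE, TRUE, FALSE)]],
                   nt_chars[idx[c(FALSE, FALSE, TRUE)]])
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"                  # codons with N or other ambiguity
  paste(aa, collapse = "")
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames `+1`, `+2`, `+3` read the sequence from offsets 0, 1, 2; `-1`,
#' `-2`, `-3` read the reverse complement from the same offsets. Trailing
#' partial codons are dropped.
#'
#' @param nt Nucleotide string (at least 3 nt).
#' @param code A [codon_table()] map.
#' @return Named character vector of 6 amino-acid strings
#'   (`+1,+2,+3,-1,-2,-3`), stops as `*`.
#' @examples
#' translate_six_frames("ATGAAATAG")[["+1"]]
#' @export
translate_six_frames <- function(nt, code = codon_table(1L)) {
  nt <- toupper(nt)
  if (nchar(nt) < 3L)
    stop("sequence shorter than one codon (", nchar(nt), " nt)",
         call. = FALSE)
  fchars <- s2c(nt)
  rchars <- s2c(revcomp_str(nt))
  out <- c(
    "+1" = translate_codons(fchars, code),
    "+2" = translate_codons(fchars[-1L], code),
    "+3" = translate_codons(fchars[-(1:2)], code),
    "-1" = translate_codons(rchars, code),
    "-2" = translate_codons(rchars[-1L], code),
    "-3" = translate_codons(rchars[-(1:2)], code))
  out
}

# longest stop-free run in an amino-acid string: c(start, len), 1-based
longest_run <- function(aa) {
  n <- nchar(aa)
  if (n == 0L) return(c(start = 0L, len = 0L))
  v <- s2c(aa)
  bounds <- c(0L, which(v == "*"), n + 1L)
  lens <- diff(bounds) - 1L
  i <- which.max(lens)                  # ties -> earliest run
  c(start = bounds[i] + 1L, len = lens[i])
}

#' Choose the reading frame with the largest ORF
#'
#' For each of the six translations the longest stop-free amino-acid run is
#' computed; the frame with the maximal run wins (this simultaneously
#' minimizes the impact of stop codons). Ties are broken in frame order
#' `+1, +2, +3, -1, -2, -3`. An initiating ATG is not required: barcode
#' amplicons are gene fragments and rarely begin at a start codon.
#'
#' @param frames Named 6-element character vector from
#'   [translate_six_frames()].
#' @return A list with `frame` (name), `aa_start`, `aa_len` (1-based run
#'   coordinates in that frame's translation) and `stops_found` (stop count
#'   per frame).
#' @export
select_frame <- function(frames) {
  stopifnot(length(frames) == 6L, !is.null(names(frames)))
  runs <- vapply(frames, longest_run, integer(2))
  stops <- vapply(frames, function(a) sum(s2c(a) == "*"), integer(1))
  best <- which.max(runs["len", ])      # which.max takes the first maximum
  list(frame = names(frames)[best],
       aa_start = unname(runs["start", best]),
       aa_len = unname(runs["len", best]),
       stops_found = stops)
}

#' Orient a consensus to the forward sense
#'
#' Compares the consensus as-is and reverse-complemented against the
#' forward read by counting shared k-mers (k = 16 by default); the
#' orientation sharing more k-mers is returned. When neither orientation
#' shares a k-mer the consensus is returned unchanged with a warning.
#'
#' @param consensus,fwd_read [bar_read] objects.
#' @param k K-mer length for the comparison.
#' @return The consensus, possibly reverse-complemented.
#' @export
orient_to_forward <- function(consensus, fwd_read, k = 16L) {
  stopifnot(nchar(consensus$seq) > 0L, nchar(fwd_read$seq) > 0L)
  ref <- kmer_set(fwd_read$seq, k)
  fwd_shared <- length(intersect(kmer_set(consensus$seq, k), ref))
  rc_seq <- revcomp_str(consensus$seq)
  rc_shared <- length(intersect(kmer_set(rc_seq, k), ref))
  if (fwd_shared == 0L && rc_shared == 0L) {
    warning("orientation undetermined for '", consensus$id,
            "': no shared ", k, "-mer with the forward read", call. = FALSE)
    return(consensus)
  }
  if (rc_shared > fwd_shared) reverse_complement(consensus) else consensus
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Stop-codon and frameshift correction
#'
#' Orients the consensus to the forward sense (against the forward read,
#' when given), translates it in six frames, selects the frame with the
#' largest ORF, and trims everything outside that stop-free run, including
#' the bounding stop codons. The emitted nucleotide sequence always reads
#' in the chosen frame's direction, so translating it reproduces
#' `corrected_aa` exactly. A chosen run shorter than `min_orf_aa` is
#' flagged as `no credible ORF` and the sequence is passed through
#' untrimmed with a warning.
#'
#' @param consensus A [bar_read] (>= 3 nt).
#' @param fwd_read Optional forward [bar_read] used to orient the
#'   consensus; `NULL` skips orientation.
#' @param code A [codon_table()] map.
#' @param min_orf_aa Minimum credible ORF length in amino acids.
#' @return A list of class `frame_correction`: `chosen_frame`, `orf_start`
#'   and `orf_end` (0-based half-open on the oriented input strand),
#'   `corrected_nt`, `corrected_aa`, `stops_found` (per frame), `credible`
#'   (logical), and `oriented` (the oriented input read).
#' @examples
#' # a 21-codon ORF bounded by stops on both sides
#' nt <- paste0("TAA",
#'   "ATGGAGTTGAACTTTACTGGGCACAGCCTTCCTGGCGCCATGCCGCCGAGTGATGTTTACTCA",
#'   "TGA")
#' fc <- correct_sequence(bar_read("b1", nt, rep(40L, nchar(nt))),
#'                        min_orf_aa = 1)
#' fc$chosen_frame   # "+1": bounding stops trimmed away
#' fc$corrected_aa
#' @export
correct_sequence <- function(consensus, fwd_read = NULL,
                             code = codon_table(1L), min_orf_aa = 10L) {
  stopifnot(inherits(consensus, "bar_read"))
  if (nchar(consensus$seq) < 3L)
    stop("consensus shorter than one codon", call. = FALSE)
  oriented <- if (!is.null(fwd_read)) orient_to_forward(consensus, fwd_read)
              else consensus
  frames <- translate_six_frames(oriented$seq, code)
  sel <- select_frame(frames)
  n <- nchar(oriented$seq)
  if (sel$aa_len < min_orf_aa) {
    warning("no credible ORF in '", consensus$id, "' (longest run ",
            sel$aa_len, " aa < ", min_orf_aa,
            "); sequence passed through untrimmed", call. = FALSE)
    return(structure(list(chosen_frame = sel$frame, orf_start = NA_integer_,
                          orf_end = NA_integer_, corrected_nt = oriented$seq,
                          corrected_aa = NA_character_,
                          stops_found = sel$stops_found, credible = FALSE,
                          oriented = oriented),
                     class = "frame_correction"))
  }
  strand <- substr(sel$frame, 1L, 1L)
  offset <- as.integer(substr(sel$frame, 2L, 2L)) - 1L
  # coordinates on the reading strand, 1-based
  nt_start <- offset + 3L * (sel$aa_start - 1L) + 1L
  nt_end <- nt_start + 3L * sel$aa_len - 1L
  reading <- if (strand == "+") oriented$seq else revcomp_str(oriented$seq)
  corrected_nt <- substr(reading, nt_start, nt_end)
  corrected_aa <- substr(frames[[sel$frame]], sel$aa_start,
                         sel$aa_start + sel$aa_len - 1L)
  # map back to the oriented input strand (0-based half-open)
  if (strand == "+") {
    orf_start <- nt_start - 1L; orf_end <- nt_end
  } else {
    orf_start <- n - nt_end; orf_end <- n - nt_start + 1L
  }
  structure(list(chosen_frame = sel$frame, orf_start = orf_start,
                 orf_end = orf_end, corrected_nt = corrected_nt,
                 corrected_aa = corrected_aa, stops_found = sel$stops_found,
                 credible = TRUE, oriented = oriented),
            class = "frame_correction")
}

#' @export
print.frame_correction <- function(x, ...) {
  cat("<frame_correction> frame ", x$chosen_frame,
      if (!x$credible) " (no credible ORF; passed through)", "\n", sep = "")
  if (x$credible)
    cat("  ORF [", x$orf_start, ", ", x$orf_end, ") on oriented input; ",
        nchar(x$corrected_aa), " aa\n", sep = "")
  invisible(x)
}
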