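#' Read a 4-line FASTQ file
#'
#' Parses Sanger/Illumina-1.8+ FASTQ (Phred+33 qualities). Records must be
#' exactly four lines: `@id`, sequence, `+`, quality string. Gzip-compressed
#' files are decompressed transparently. Phred+64 encodings are not
#' auto-detected and will fail the quality-range check.
#'
#' @param path Path to a FASTQ file (optionally `.gz`).
#' @return A list of [bar_read] objects in file order.
#' @seealso [write_fastq()], [pair_streams()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': line count ", length(lines),
         " is not a multiple of 4", call. = FALSE)
  n <- length(lines) %/% 4L
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    off <- (i - 1L) * 4L
    hdr <- lines[off + 1L]; seq <- lines[off + 2L]
    plus <- lines[off + 3L]; qual <- lines[off + 4L]
    if (!startsWith(hdr, "@"))
      stop("malformed FASTQ '", path, "' at record ", i,
           ": header does not start with '@'", call. = FALSE)
    if (!startsWith(plus, "+"))
      stop("malformed FASTQ '", path, "' at record ", i,
           ": separator line does not start with '+'", call. = FALSE)
    if (nchar(seq) != nchar(qual))
      stop("malformed FASTQ '", path, "' at record ", i,
           ": sequence length ", nchar(seq), " != quality length ",
           nchar(qual), call. = FALSE)
    q <- decode_phred(qual)
    if (length(q) && (min(q) < 0L || max(q) > 93L))
      stop("malformed FASTQ '", path, "' at record ", i,
           ": quality characters outside Phred+33 range", call. = FALSE)
    reads[[i]] <- bar_read(sub("^@", "", hdr), seq, q)
  }
  reads
}

decode_phred <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - 33L
}

encode_phred <- function(q) {
  if (!length(q)) return("")
  if (max(q) > 93L)
    stop("cannot encode Phred score > 93 in Phred+33", call. = FALSE)
  intToUtf8(q + 33L)
}

#' Pair two FASTQ streams positionally
#'
#' Record *i* of the forward file is paired with record *i* of the reverse
#' file. Ids are not used for matching (the stated input contract is
#' same-order files); differing ids at the same index produce a warning,
#' not an error.
#'
#' @param fwd_path,rev_path FASTQ files with mates in the same order.
#' @return A list of [bar_read_pair] objects.
#' @export
pair_streams <- function(fwd_path, rev_path) {
  fwd <- read_fastq(fwd_path)
  rev <- read_fastq(rev_path)
  pair_reads(fwd, rev)
}

#' Pair two read lists positionally
#' @param fwd,rev Lists of [bar_read] of equal length.
#' @return A list of [bar_read_pair].
#' @export
pair_reads <- function(fwd, rev) {
  if (length(fwd) != length(rev))
    stop("unequal record counts: ", length(fwd), " != ", length(rev),
         call. = FALSE)
  mismatched <- 0L
  pairs <- vector("list", length(fwd))
  for (i in seq_along(fwd)) {
    if (first_token(fwd[[i]]$id) != first_token(rev[[i]]$id))
      mismatched <- mismatched + 1L
    pairs[[i]] <- bar_read_pair(fwd[[i]], rev[[i]])
  }
  if (mismatched > 0L)
    warning(mismatched, " pair(s) have differing mate ids; ",
            "pairing is positional", call. = FALSE)
  pairs
}

first_token <- function(x) sub("[ /].*$", "", x)

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads A list of [bar_read] objects.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * length(reads))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    off <- (i - 1L) * 4L
    lines[off + 1L] <- paste0("@", r$id)
    lines[off + 2L] <- r$seq
    lines[off + 3L] <- "+"
    lines[off + 4L] <- encode_phred(r$quals)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write reads as wrapped FASTA
#'
#' Qualities are dropped. Sequence lines wrap at `width` characters.
#'
#' @param reads A list of [bar_read] objects.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path, width = 70L) {
  seqs <- vapply(reads, function(r) r$seq, character(1))
  names(seqs) <- vapply(reads, function(r) r$id, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Read a FASTA file as plain sequences
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}
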