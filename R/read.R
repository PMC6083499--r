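#' Construct a read
#'
#' A read is a named nucleotide sequence with one Phred quality score per
#' base. Sequences are normalized to uppercase; characters outside
#' `{A,C,G,T,N}` (e.g. IUPAC ambiguity codes) are mapped to `N` with a
#' warning, since downstream stages only define behavior for `N`.
#'
#' @param id Character label for the read.
#' @param seq Nucleotide string.
#' @param quals Integer vector of Phred scores (0-93), one per base.
#' @return An object of class `bar_read`: a list with elements `id`, `seq`
#'   (uppercase string) and `quals` (integer vector).
#' @examples
#' r <- bar_read("r1", "acgtn", c(30, 30, 30, 30, 2))
#' r$seq
#' @export
bar_read <- function(id, seq, quals) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    warning("read '", id, "': characters outside {A,C,G,T,N} mapped to N",
            call. = FALSE)
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  quals <- as.integer(quals)
  if (nchar(seq) != length(quals))
    stop("read '", id, "': sequence length (", nchar(seq),
         ") != quality length (", length(quals), ")", call. = FALSE)
  if (length(quals) && (anyNA(quals) || min(quals) < 0L || max(quals) > 93L))
    stop("read '", id, "': Phred scores must be integers in [0, 93]",
         call. = FALSE)
  structure(list(id = id, seq = seq, quals = quals), class = "bar_read")
}

#' @export
print.bar_read <- function(x, ...) {
  n <- nchar(x$seq)
  cat("<bar_read> ", x$id, "  (", n, " bp",
      if (n) sprintf(", mean Q%.1f", mean(x$quals)), ")\n", sep = "")
  if (n) {
    shown <- if (n > 60) paste0(substr(x$seq, 1, 60), "...") else x$seq
    cat("  ", shown, "\n", sep = "")
  }
  invisible(x)
}

#' Length of a read in bases
#' @param x A `bar_read`.
#' @export
read_length <- function(x) nchar(x$seq)

#' Construct a read pair
#'
#' Pairs a forward and a reverse read. Both reads must be non-empty.
#'
#' @param forward,reverse `bar_read` objects.
#' @return An object of class `bar_read_pair`.
#' @export
bar_read_pair <- function(forward, reverse) {
  stopifnot(inherits(forward, "bar_read"), inherits(reverse, "bar_read"))
  if (nchar(forward$seq) == 0L || nchar(reverse$seq) == 0L)
    stop("both mates of a pair must be non-empty", call. = FALSE)
  structure(list(forward = forward, reverse = reverse),
            class = "bar_read_pair")
}

#' @export
print.bar_read_pair <- function(x, ...) {
  cat("<bar_read_pair>\n  fwd: ", x$forward$id, " (", nchar(x$forward$seq),
      " bp)\n  rev: ", x$reverse$id, " (", nchar(x$reverse$seq), " bp)\n",
      sep = "")
  invisible(x)
}

#' Reverse-complement a read
#'
#' Complements the sequence (A<->T, C<->G, N->N), reverses it, and reverses
#' the quality vector alongside. The id is preserved. Applying the function
#' twice returns the original read.
#'
#' @param r A `bar_read`.
#' @return A `bar_read` on the opposite strand.
#' @export
reverse_complement <- function(r) {
  stopifnot(inherits(r, "bar_read"))
  r$seq <- revcomp_str(r$seq)
  r$quals <- rev(r$quals)
  r
}

# reverse-complement a plain string over {A,C,G,T,N}
revcomp_str <- function(s) {
  if (nchar(s) == 0L) return(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# split a string into single characters
s2c <- function(s) {
  if (nchar(s) == 0L) character(0) else strsplit(s, "", fixed = TRUE)[[1L]]
}
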