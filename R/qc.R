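#' Trimming and filtering parameters
#'
#' Defaults follow common barcode-pipeline practice: a 10 bp sliding window
#' advanced 1 bp at a time, trimming each end while the window's mean Phred
#' quality is below 20; afterwards, reads shorter than 50 bp or with overall
#' mean quality below 20 are discarded. Phred 20 corresponds to a 1%
#' base-call error probability.
#'
#' @param window Sliding-window width in bp.
#' @param step Window step in bp.
#' @param min_window_mean_qual Minimum mean Phred inside a window for
#'   trimming to stop (strictly-below fails).
#' @param min_mean_qual Minimum mean Phred of the trimmed read.
#' @param min_length Minimum length of the trimmed read in bp.
#' @return A list of class `trim_params`.
#' @export
trim_params <- function(window = 10L, step = 1L, min_window_mean_qual = 20,
                        min_mean_qual = 20, min_length = 50L) {
  window <- as.integer(window); step <- as.integer(step)
  min_length <- as.integer(min_length)
  stopifnot(window >= 1L, step >= 1L, min_length >= 1L)
  structure(list(window = window, step = step,
                 min_window_mean_qual = min_window_mean_qual,
                 min_mean_qual = min_mean_qual, min_length = min_length),
            class = "trim_params")
}

# number of bases to trim from the 5' side of a quality vector:
# windows start at offsets 0, step, 2*step, ...; a window is the next
# `window` bases, clipped at the read end (a read shorter than `window`
# is one whole-read window); trimming stops at the first window whose
# mean quality reaches the threshold.
trim_offset <- function(q, p) {
  n <- length(q)
  if (n == 0L) return(0L)
  s <- 1L
  while (s <= n) {
    e <- min(s + p$window - 1L, n)
    if (mean(q[s:e]) >= p$min_window_mean_qual) return(s - 1L)
    s <- s + p$step
  }
  n
}

#' Quality-trim both ends of a read
#'
#' Slides a window inward from the 5' end, removing bases while the window
#' mean quality is below the threshold; stops at the first passing window;
#' then repeats symmetrically from the 3' end of the remainder. The result
#' is a contiguous substring of the input (possibly empty) with qualities
#' carried along; attributes `trimmed_5p` and `trimmed_3p` record the bases
#' removed from each end. Re-trimming a trimmed read changes nothing.
#'
#' @param r A [bar_read].
#' @param p A [trim_params] object.
#' @return The trimmed `bar_read`.
#' @export
trim_read <- function(r, p = trim_params()) {
  stopifnot(inherits(r, "bar_read"))
  q <- r$quals
  t5 <- trim_offset(q, p)
  rest <- if (t5 < length(q)) q[(t5 + 1L):length(q)] else integer(0)
  t3 <- trim_offset(rev(rest), p)
  keep_len <- length(rest) - t3
  out <- r
  if (keep_len > 0L) {
    out$seq <- substr(r$seq, t5 + 1L, t5 + keep_len)
    out$quals <- q[(t5 + 1L):(t5 + keep_len)]
  } else {
    out$seq <- ""
    out$quals <- integer(0)
    t5 <- length(q); t3 <- 0L          # report full loss on the 5' side
  }
  attr(out, "trimmed_5p") <- t5
  attr(out, "trimmed_3p") <- t3
  out
}

#' Filter a trimmed read by length and mean quality
#'
#' @param r A (trimmed) [bar_read].
#' @param p A [trim_params] object.
#' @return A list of class `qc_outcome` with `read` (the read, or `NULL`
#'   when discarded), `status` (`kept`, `filtered_length`,
#'   `filtered_quality`), `trimmed_5p`, `trimmed_3p`.
#' @export
filter_read <- function(r, p = trim_params()) {
  n <- nchar(r$seq)
  status <- if (n < p$min_length) "filtered_length"
    else if (mean(r$quals) < p$min_mean_qual) "filtered_quality"
    else "kept"
  qc_outcome(if (status == "kept") r else NULL, status,
             attr(r, "trimmed_5p") %||% 0L, attr(r, "trimmed_3p") %||% 0L)
}

qc_outcome <- function(read, status, t5, t3) {
  structure(list(read = read, status = status,
                 trimmed_5p = as.integer(t5), trimmed_3p = as.integer(t3)),
            class = "qc_outcome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trim and filter one read
#'
#' Convenience wrapper: [trim_read()] then [filter_read()]. A read emptied
#' entirely by trimming gets status `emptied_by_trim`.
#'
#' @inheritParams trim_read
#' @return A `qc_outcome` (see [filter_read()]).
#' @export
qc_read <- function(r, p = trim_params()) {
  tr <- trim_read(r, p)
  if (nchar(tr$seq) == 0L)
    return(qc_outcome(NULL, "emptied_by_trim",
                      attr(tr, "trimmed_5p"), attr(tr, "trimmed_3p")))
  filter_read(tr, p)
}

#' Trim and filter a list of reads
#'
#' @param reads A list of [bar_read] objects.
#' @param p A [trim_params] object.
#' @return A list of `qc_outcome` objects, one per input read.
#' @export
qc_reads <- function(reads, p = trim_params()) {
  lapply(reads, qc_read, p = p)
}

#' Per-read quality report
#'
#' For each read: length, mean Phred quality, number and fraction of bases
#' below `threshold`, and a `flagged` column marking potentially problematic
#' reads whose below-threshold fraction exceeds `flag_fraction`. Run-level
#' totals are attached as the `totals` attribute.
#'
#' @param reads A list of [bar_read] objects.
#' @param threshold Minimum accepted Phred value (default 20).
#' @param flag_fraction Fraction of sub-threshold bases above which a read
#'   is flagged (default 0.10).
#' @return A `data.frame` of class `quality_report`.
#' @export
quality_report <- function(reads, threshold = 20, flag_fraction = 0.10) {
  stopifnot(threshold >= 0)
  n <- length(reads)
  df <- data.frame(
    id = character(n), length = integer(n), mean_qual = numeric(n),
    n_below = integer(n), frac_below = numeric(n), flagged = logical(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- reads[[i]]
    len <- length(r$quals)
    nb <- sum(r$quals < threshold)
    df$id[i] <- r$id
    df$length[i] <- len
    df$mean_qual[i] <- if (len) mean(r$quals) else NA_real_
    df$n_below[i] <- nb
    df$frac_below[i] <- if (len) nb / len else 0
    df$flagged[i] <- len > 0L && nb / len > flag_fraction
  }
  attr(df, "totals") <- list(
    n_reads = n,
    total_bases = sum(df$length),
    total_below = sum(df$n_below),
    n_flagged = sum(df$flagged),
    threshold = threshold)
  class(df) <- c("quality_report", "data.frame")
  df
}

#' @export
print.quality_report <- function(x, ...) {
  t <- attr(x, "totals")
  cat("Quality report (threshold Q", t$threshold, "): ", t$n_reads,
      " reads, ", t$total_bases, " bases, ", t$total_below,
      " below threshold, ", t$n_flagged, " read(s) flagged\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 20L))
  if (nrow(x) > 20L) cat("... (", nrow(x) - 20L, " more)\n", sep = "")
  invisible(x)
}

#' Write a quality report as TSV
#' @param report A [quality_report()] result.
#' @param path Output path.
#' @export
write_quality_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot per-read quality profiles
#'
#' Draws each read's Phred values along the read with the threshold line;
#' flagged reads are highlighted.
#'
#' @param reads A list of [bar_read] objects.
#' @param threshold Threshold line to draw.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_quality_profiles <- function(reads, threshold = 20, ...) {
  if (!length(reads)) {
    warning("no reads to plot", call. = FALSE)
    return(invisible(NULL))
  }
  maxlen <- max(vapply(reads, function(r) length(r$quals), integer(1)))
  m <- matrix(NA_real_, nrow = maxlen, ncol = length(reads))
  for (i in seq_along(reads)) {
    q <- reads[[i]]$quals
    if (length(q)) m[seq_along(q), i] <- q
  }
  graphics::matplot(m, type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.5),
                    xlab = "position (bp)", ylab = "Phred quality", ...)
  graphics::abline(h = threshold, col = "firebrick", lty = 2)
  invisible(NULL)
}
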