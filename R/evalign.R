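#' Align a merged sequence against a reference
#'
#' Best local alignment of the merged read against either strand of the
#' reference (match +1, mismatch -1, gap open -2, gap extend -0.5 by
#' default, chosen to behave like a megablast-style aligner on
#' near-identical sequences). Identity is computed over alignment columns,
#' gap columns included, so it shares the denominator with the mismatch
#' and gap counts.
#'
#' @param merged A [bar_read] or a nucleotide string.
#' @param ref Reference nucleotide string (or a window of it).
#' @param match,mismatch,gap_opening,gap_extension Alignment scores.
#' @param score_floor Alignments scoring below this are reported as
#'   unaligned.
#' @return A list with `aligned` (logical), `identity_pct`, `mismatches`,
#'   `gap_openings`, `align_columns`, `score`, `strand`.
#' @export
align_merged <- function(merged, ref, match = 1, mismatch = -1,
                         gap_opening = 2, gap_extension = 0.5,
                         score_floor = 30) {
  seq <- if (inherits(merged, "bar_read")) merged$seq else toupper(merged)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  best <- NULL; strand <- NA_character_
  for (s in c("+", "-")) {
    qry <- if (s == "+") seq else revcomp_str(seq)
    pa <- Biostrings::pairwiseAlignment(qry, ref, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = gap_opening,
                                        gapExtension = gap_extension)
    if (is.null(best) || Biostrings::score(pa) > Biostrings::score(best)) {
      best <- pa; strand <- s
    }
  }
  sc <- Biostrings::score(best)
  if (sc < score_floor)
    return(list(aligned = FALSE, identity_pct = NA_real_,
                mismatches = NA_integer_, gap_openings = NA_integer_,
                align_columns = NA_integer_, score = sc,
                strand = NA_character_))
  ap <- as.character(Biostrings::alignedPattern(best))
  as_ <- as.character(Biostrings::alignedSubject(best))
  cols <- nchar(ap)
  gaps_p <- gap_runs(ap); gaps_s <- gap_runs(as_)
  nmatch <- Biostrings::nmatch(best)
  list(aligned = TRUE,
       identity_pct = 100 * nmatch / cols,
       mismatches = Biostrings::nmismatch(best),
       gap_openings = gaps_p + gaps_s,
       align_columns = cols,
       score = sc,
       strand = strand)
}

gap_runs <- function(s) {
  m <- gregexpr("-+", s)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' Evaluate merge outcomes against a reference
#'
#' Mirrors a merged-pair benchmark: the fraction of pairs merged, the mean
#' and SD of merged lengths, and the mean identity, mismatch and
#' gap-opening counts from aligning merged sequences back to the
#' reference. When simulation `truth` is supplied, each merged sequence is
#' aligned only against a window of the reference around its true fragment
#' (local alignment against a whole long reference is quadratic);
#' `sample_n` caps how many merged pairs are aligned (means are computed
#' over the aligned subsample; lengths and merge rates always use all
#' pairs).
#'
#' @param result A [merge_pairs()] result.
#' @param ref Reference nucleotide string.
#' @param truth Optional truth list from [simulate_pairs()].
#' @param sample_n Maximum number of merged pairs to align (default all).
#' @param window_margin Bases of reference context around the true
#'   fragment when `truth` is used.
#' @param ... Passed to [align_merged()].
#' @return A list of class `merge_eval` with the summary statistics and
#'   the per-pair alignment table.
#' @export
evaluate_merged <- function(result, ref, truth = NULL, sample_n = Inf,
                            window_margin = 50L, ...) {
  rep <- result$report
  merged_idx <- which(rep$status == "merged")
  n_input <- nrow(rep)
  n_merged <- length(merged_idx)
  lens <- rep$merged_length[merged_idx]

  take <- merged_idx
  if (is.finite(sample_n) && n_merged > sample_n)
    take <- sort(sample(merged_idx, sample_n))

  aligns <- vector("list", length(take))
  for (k in seq_along(take)) {
    i <- take[k]
    cons <- result$outcomes[[i]]$consensus
    target <- ref
    if (!is.null(truth)) {
      t <- truth[[i]]
      lo <- max(1L, t$frag_start - window_margin)
      hi <- min(nchar(ref), t$frag_start + t$frag_len - 1L + window_margin)
      target <- substr(ref, lo, hi)
    }
    aligns[[k]] <- align_merged(cons, target, ...)
  }
  aligned <- vapply(aligns, `[[`, logical(1), "aligned")
  idn <- vapply(aligns, `[[`, numeric(1), "identity_pct")[aligned]
  mm <- vapply(aligns, function(a)
    as.numeric(a$mismatches), numeric(1))[aligned]
  go <- vapply(aligns, function(a)
    as.numeric(a$gap_openings), numeric(1))[aligned]

  stats <- list(
    n_input_pairs = n_input,
    n_merged = n_merged,
    pct_merged = 100 * n_merged / max(n_input, 1L),
    mean_len = if (n_merged) mean(lens) else NA_real_,
    sd_len = if (n_merged > 1L) stats::sd(lens) else NA_real_,
    n_aligned = sum(aligned),
    n_unaligned = sum(!aligned),
    mean_identity_pct = if (any(aligned)) mean(idn) else NA_real_,
    sd_identity = if (sum(aligned) > 1L) stats::sd(idn) else NA_real_,
    mean_mismatches = if (any(aligned)) mean(mm) else NA_real_,
    mean_gap_openings = if (any(aligned)) mean(go) else NA_real_)
  structure(c(stats, list(alignments = aligns, sampled_idx = take)),
            class = "merge_eval")
}

#' @export
print.merge_eval <- function(x, ...) {
  cat("Merge evaluation (native local aligner; absolute mismatch/gap",
      "counts may differ from BLAST-derived figures)\n")
  cat(sprintf("  input pairs : %d\n  merged      : %d (%.2f%%)\n",
              x$n_input_pairs, x$n_merged, x$pct_merged))
  if (x$n_merged)
    cat(sprintf("  merged length: %.2f +/- %.2f bp\n", x$mean_len,
                if (is.na(x$sd_len)) 0 else x$sd_len))
  if (x$n_aligned)
    cat(sprintf(
      "  identity: %.2f%% +/- %.2f; mismatches %.2f; gap openings %.2f (on %d aligned, %d unaligned)\n",
      x$mean_identity_pct, if (is.na(x$sd_identity)) 0 else x$sd_identity,
      x$mean_mismatches, x$mean_gap_openings, x$n_aligned, x$n_unaligned))
  invisible(x)
}

#' Write evaluation statistics as TSV
#' @param eval_ A [evaluate_merged()] result.
#' @param path Output path.
#' @export
write_eval_stats <- function(eval_, path) {
  keys <- c("n_input_pairs", "n_merged", "pct_merged", "mean_len", "sd_len",
            "n_aligned", "n_unaligned", "mean_identity_pct", "sd_identity",
            "mean_mismatches", "mean_gap_openings")
  df <- data.frame(statistic = keys,
                   value = vapply(keys, function(k)
                     as.numeric(eval_[[k]]), numeric(1)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
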