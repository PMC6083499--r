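#' Run the full barcode pipeline on paired FASTQ input
#'
#' Trim and filter both mates, merge the pairs where both mates survive,
#' optionally apply stop-codon/frameshift correction for coding barcodes,
#' and write all outputs: `barcodes.fasta` (merged consensuses),
#' `barcodes.faa` (proteins, `--coding` only), `unmerged_1/2.fastq`
#' (QC-passing pairs that did not merge), `rejected_1/2.fastq` (pairs
#' where at least one mate failed QC), `qc_report.tsv`,
#' `merge_report.tsv`, and `run.log` with the effective parameters and
#' per-stage counts. Every input pair lands in exactly one of
#' merged/unmerged/rejected.
#'
#' @param fwd_path,rev_path Paired FASTQ files (same order in both).
#' @param out_dir Output directory (created if needed).
#' @param trim A [trim_params] object.
#' @param merge A [merge_params] object.
#' @param coding Apply ORF correction to merged barcodes.
#' @param table NCBI genetic-code table for `coding`.
#' @param min_orf_aa Minimum credible ORF length in amino acids.
#' @param report_threshold Phred threshold for the quality report.
#' @param id_suffix Suffix for consensus ids.
#' @return A list of class `barmerge_run` with per-stage counts and output
#'   paths, invisibly.
#' @export
run_pipeline <- function(fwd_path, rev_path, out_dir,
                         trim = trim_params(), merge = merge_params(),
                         coding = FALSE, table = 1L, min_orf_aa = 10L,
                         report_threshold = 20, id_suffix = "") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- pair_streams(fwd_path, rev_path)
  n_pairs <- length(pairs)

  # QC both mates
  qc_f <- qc_reads(lapply(pairs, `[[`, "forward"), trim)
  qc_r <- qc_reads(lapply(pairs, `[[`, "reverse"), trim)
  both_kept <- vapply(seq_len(n_pairs), function(i)
    qc_f[[i]]$status == "kept" && qc_r[[i]]$status == "kept", logical(1))

  qc_rep <- data.frame(
    id = vapply(pairs, function(p) p$forward$id, character(1)),
    status_fwd = vapply(qc_f, `[[`, character(1), "status"),
    status_rev = vapply(qc_r, `[[`, character(1), "status"),
    trimmed_5p_fwd = vapply(qc_f, `[[`, integer(1), "trimmed_5p"),
    trimmed_3p_fwd = vapply(qc_f, `[[`, integer(1), "trimmed_3p"),
    trimmed_5p_rev = vapply(qc_r, `[[`, integer(1), "trimmed_5p"),
    trimmed_3p_rev = vapply(qc_r, `[[`, integer(1), "trimmed_3p"),
    stringsAsFactors = FALSE)

  # a pair proceeds to merging only when BOTH mates survive
  survivors <- which(both_kept)
  surv_pairs <- lapply(survivors, function(i)
    bar_read_pair(qc_f[[i]]$read, qc_r[[i]]$read))
  rejected <- which(!both_kept)

  result <- if (length(surv_pairs)) merge_pairs(surv_pairs, merge, id_suffix)
            else list(outcomes = list(),
                      report = data.frame(id = character(0),
                                          status = character(0)))
  merged_local <- if (length(surv_pairs))
    which(result$report$status == "merged") else integer(0)
  unmerged_local <- setdiff(seq_along(surv_pairs), merged_local)

  merged_reads <- lapply(result$outcomes[merged_local], `[[`, "consensus")

  # optional stop-codon / frameshift correction
  proteins <- NULL
  if (coding && length(merged_reads)) {
    code <- codon_table(table)
    corrected <- vector("list", length(merged_reads))
    proteins <- vector("list", length(merged_reads))
    for (k in seq_along(merged_reads)) {
      fwd_in <- surv_pairs[[merged_local[k]]]$forward
      fc <- correct_sequence(merged_reads[[k]], fwd_in, code, min_orf_aa)
      nt <- fc$corrected_nt
      corrected[[k]] <- bar_read(merged_reads[[k]]$id, nt,
                                 rep(40L, nchar(nt)))
      proteins[[k]] <- if (fc$credible)
        list(id = merged_reads[[k]]$id, aa = fc$corrected_aa) else NULL
    }
    merged_reads <- corrected
    proteins <- Filter(Negate(is.null), proteins)
  }

  paths <- list(
    barcodes = file.path(out_dir, "barcodes.fasta"),
    unmerged_1 = file.path(out_dir, "unmerged_1.fastq"),
    unmerged_2 = file.path(out_dir, "unmerged_2.fastq"),
    rejected_1 = file.path(out_dir, "rejected_1.fastq"),
    rejected_2 = file.path(out_dir, "rejected_2.fastq"),
    qc_report = file.path(out_dir, "qc_report.tsv"),
    merge_report = file.path(out_dir, "merge_report.tsv"),
    log = file.path(out_dir, "run.log"))

  write_fasta(merged_reads, paths$barcodes)
  if (coding) {
    paths$proteins <- file.path(out_dir, "barcodes.faa")
    write_faa(proteins, paths$proteins)
  }
  write_fastq(lapply(surv_pairs[unmerged_local], `[[`, "forward"),
              paths$unmerged_1)
  write_fastq(lapply(surv_pairs[unmerged_local], `[[`, "reverse"),
              paths$unmerged_2)
  write_fastq(lapply(pairs[rejected], `[[`, "forward"), paths$rejected_1)
  write_fastq(lapply(pairs[rejected], `[[`, "reverse"), paths$rejected_2)
  utils::write.table(qc_rep, paths$qc_report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(surv_pairs))
    utils::write.table(result$report, paths$merge_report, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  else
    writeLines(paste(c("id", "status", "overlap_columns", "identity_pct",
                       "mismatches", "gap_openings", "merged_length"),
                     collapse = "\t"), paths$merge_report)

  counts <- list(n_input_pairs = n_pairs,
                 n_rejected = length(rejected),
                 n_qc_passed = length(surv_pairs),
                 n_merged = length(merged_local),
                 n_unmerged = length(unmerged_local))
  stopifnot(counts$n_rejected + counts$n_merged + counts$n_unmerged ==
              n_pairs)
  if (n_pairs == 0L || counts$n_merged == 0L)
    warning("no merged barcodes produced", call. = FALSE)

  log_lines <- c(
    paste0("barmerge ", as.character(utils::packageVersion("barmerge"))),
    paste0("R ", R.version.string),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("input_fwd=", fwd_path),
    paste0("input_rev=", rev_path),
    paste0("coding=", coding, if (coding) paste0(" table=", table)),
    params_lines("trim", trim),
    params_lines("merge", merge),
    vapply(names(counts), function(k)
      paste0(k, "=", counts[[k]]), character(1)))
  writeLines(log_lines, paths$log)

  structure(list(counts = counts, paths = paths), class = "barmerge_run")
}

params_lines <- function(prefix, p) {
  vapply(names(unclass(p)), function(k)
    paste0(prefix, ".", k, "=", p[[k]]), character(1))
}

write_faa <- function(proteins, path) {
  lines <- unlist(lapply(proteins, function(p)
    c(paste0(">", p$id), strwrap_seq(p$aa, 70L))))
  writeLines(if (is.null(lines)) character(0) else lines, path)
  invisible(path)
}

strwrap_seq <- function(s, width) {
  n <- nchar(s)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

#' @export
print.barmerge_run <- function(x, ...) {
  c <- x$counts
  cat("<barmerge_run>\n",
      sprintf("  input pairs : %d\n", c$n_input_pairs),
      sprintf("  rejected QC : %d\n", c$n_rejected),
      sprintf("  merged      : %d\n", c$n_merged),
      sprintf("  unmerged    : %d\n", c$n_unmerged),
      sprintf("  outputs in  : %s\n", dirname(x$paths$barcodes)), sep = "")
  invisible(x)
}
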