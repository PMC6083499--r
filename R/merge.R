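#' Merge algorithm parameters
#'
#' Tunables of the seed-and-extend overlap merger. A seed of `seed_length`
#' bases is taken from the forward read's 3' end and searched for verbatim
#' in the (oriented) reverse read; on failure the seed window slides toward
#' the 5' end by `seed_step` and the search is retried. Once anchored, the
#' full implied overlap is scanned column by column; at a mismatch the next
#' `tolerance` columns are inspected and, if they do not all match, a gap is
#' inserted and re-tested up to `repeats` times before falling back to a
#' plain mismatch. A merge is accepted when the overlap spans at least
#' `min_overlap` alignment columns, its identity fraction is at least
#' `min_identity`, and at most `max_gap_openings` gap runs were opened
#' (all thresholds inclusive).
#'
#' @param min_overlap Minimum overlap length in alignment columns (default 25).
#' @param min_identity Minimum identity fraction of the overlap (default 0.90).
#' @param max_gap_openings Maximum gap openings in the overlap (default 5).
#' @param seed_length Seed length in bp (default 16).
#' @param seed_step Seed slide step in bp (default 12).
#' @param tolerance Look-ahead length in columns after a mismatch (default 5).
#' @param repeats Maximum gap-insertion retries at one site (default 4).
#' @param orient_reverse Reverse-complement the reverse read before
#'   anchoring (default `TRUE`); if no seed is found, the other orientation
#'   is tried as a fallback.
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(min_overlap = 25L, min_identity = 0.90,
                         max_gap_openings = 5L, seed_length = 16L,
                         seed_step = 12L, tolerance = 5L, repeats = 4L,
                         orient_reverse = TRUE) {
  seed_length <- as.integer(seed_length); seed_step <- as.integer(seed_step)
  tolerance <- as.integer(tolerance); repeats <- as.integer(repeats)
  stopifnot(seed_length >= 1L, seed_step >= 1L,
            min_identity > 0, min_identity <= 1,
            tolerance >= 1L, repeats >= 0L)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity,
                 max_gap_openings = as.integer(max_gap_openings),
                 seed_length = seed_length, seed_step = seed_step,
                 tolerance = tolerance, repeats = repeats,
                 orient_reverse = isTRUE(orient_reverse)),
            class = "merge_params")
}

#' Anchor two reads on a shared seed
#'
#' Takes the `seed_length`-mer ending at the forward read's 3' end and
#' searches for it as an exact substring of the oriented reverse read. On
#' failure the seed window slides toward the forward read's 5' end by
#' `seed_step` and the search is retried until the window would leave the
#' read. When the seed occurs at several positions of the mate, the
#' occurrence implying the longest overlap span wins (ties: leftmost).
#'
#' @param fwd Forward [bar_read].
#' @param rev_oriented Reverse read, already oriented to the same strand.
#' @param p A [merge_params] object.
#' @return A list of class `overlap_anchor` with 0-based `seed_start_fwd`,
#'   `seed_start_rev`, the relative `offset` of the reverse read in forward
#'   coordinates, and the implied ungapped `overlap_len`; or `NULL` when no
#'   seed is shared.
#' @export
find_anchor <- function(fwd, rev_oriented, p = merge_params()) {
  nf <- nchar(fwd$seq); nr <- nchar(rev_oriented$seq)
  L <- p$seed_length
  if (nf < L || nr < L) return(NULL)
  s <- nf - L + 1L                      # 1-based seed start in fwd
  while (s >= 1L) {
    seed <- substr(fwd$seq, s, s + L - 1L)
    occ <- gregexpr(seed, rev_oriented$seq, fixed = TRUE)[[1L]]
    if (occ[1L] != -1L) {
      offs <- (s - 1L) - (occ - 1L)     # 0-based offset of rev within fwd
      span <- pmin(nf, offs + nr) - pmax(0L, offs)
      best <- which.max(span)           # ties -> leftmost occurrence
      return(structure(list(seed_start_fwd = s - 1L,
                            seed_start_rev = occ[best] - 1L,
                            offset = offs[best],
                            overlap_len = span[best],
                            seed_length = L),
                       class = "overlap_anchor"))
    }
    s <- s - p$seed_step
  }
  NULL
}

# columns match when the bases are equal or either is the generic base N
col_ok <- function(a, b) (a == b) | a == "N" | b == "N"

# Column-wise scan of two character vectors starting at (i0, j0), applying
# the tolerance/gap-insertion/roll-back rules, until either vector is
# exhausted. Returns per-column index vectors (NA = gap), the counters,
# and the first unconsumed position of each vector.
scan_columns <- function(f, r, i0, j0, p) {
  nf <- length(f); nr <- length(r)
  tol <- p$tolerance
  i <- i0; j <- j0
  cap <- max(0L, nf - i + 1L) + max(0L, nr - j + 1L) + 8L
  af <- integer(cap); ar <- integer(cap)
  k <- 0L
  identity <- 0L; mism <- 0L; gaps <- 0L

  la_ok <- function(fi, rj, need1 = FALSE) {
    t <- min(tol, nf - fi + 1L, nr - rj + 1L)
    if (t < 1L) return(!need1)
    all(col_ok(f[fi:(fi + t - 1L)], r[rj:(rj + t - 1L)]))
  }

  while (i <= nf && j <= nr) {
    m <- min(nf - i, nr - j) + 1L
    ok <- col_ok(f[i:(i + m - 1L)], r[j:(j + m - 1L)])
    run <- which(!ok)[1L]
    run <- if (is.na(run)) m else run - 1L
    if (run > 0L) {                     # vectorized stretch of matches
      af[k + seq_len(run)] <- i:(i + run - 1L)
      ar[k + seq_len(run)] <- j:(j + run - 1L)
      k <- k + run; identity <- identity + run
      i <- i + run; j <- j + run
      if (i > nf || j > nr) break
    }
    # mismatch column at (i, j)
    if (la_ok(i + 1L, j + 1L)) {
      mism <- mism + 1L
      k <- k + 1L; af[k] <- i; ar[k] <- j
      i <- i + 1L; j <- j + 1L
      next
    }
    placed <- FALSE
    for (g in seq_len(p$repeats)) {
      if (i + g <= nf && la_ok(i + g, j, need1 = TRUE)) {
        # g gap columns in r: f bases against gaps
        af[k + seq_len(g)] <- i:(i + g - 1L)
        ar[k + seq_len(g)] <- NA_integer_
        k <- k + g; identity <- identity + g; gaps <- gaps + 1L
        i <- i + g
        placed <- TRUE
        break
      }
      if (j + g <= nr && la_ok(i, j + g, need1 = TRUE)) {
        af[k + seq_len(g)] <- NA_integer_
        ar[k + seq_len(g)] <- j:(j + g - 1L)
        k <- k + g; identity <- identity + g; gaps <- gaps + 1L
        j <- j + g
        placed <- TRUE
        break
      }
    }
    if (!placed) {                      # roll back: plain mismatch
      mism <- mism + 1L
      k <- k + 1L; af[k] <- i; ar[k] <- j
      i <- i + 1L; j <- j + 1L
    }
  }
  list(fwd_idx = af[seq_len(k)], rev_idx = ar[seq_len(k)],
       identity = identity, mismatch = mism, gaps = gaps,
       next_i = i, next_j = j)
}

#' Scan the implied overlap column by column
#'
#' The reads are laid out according to the anchor and the overlap is
#' scanned outward from the seed -- the one stretch whose register is
#' verified -- leftward to the overlap's 5' boundary and rightward to its
#' 3' end, so that an indel inside the overlap cannot mis-register the
#' columns on its far side. Equal bases (or a base against `N`) increment
#' the identity count; a base against a gap column also increments it. At
#' a mismatch the next `tolerance` columns are inspected: if they all
#' match, a mismatch is charged and the scan advances; otherwise
#' single-base gaps are inserted (tried in either read, reverse read
#' preferred on ties) and re-tested up to `repeats` times; if the
#' look-ahead never succeeds the gaps are rolled back and a plain mismatch
#' is charged. Consecutive gap columns inserted at one site count as one
#' gap opening. Near the overlap boundaries the look-ahead compares only
#' the remaining columns. When indels leave surplus bases at the overlap's
#' 5' boundary, those bases fall outside the scored overlap and are kept
#' as non-overlap prefix material.
#'
#' @param fwd Forward [bar_read].
#' @param rev_oriented Oriented reverse [bar_read].
#' @param anchor An `overlap_anchor` from [find_anchor()].
#' @param p A [merge_params] object.
#' @return A list of class `overlap_scan` with `score` (an `overlap_score`:
#'   `identity_count`, `mismatch_count`, `gap_openings`, `overlap_columns`,
#'   `identity_fraction`), `alignment` (two integer vectors `fwd_idx`,
#'   `rev_idx` of 1-based read positions per column, `NA` marking a gap),
#'   and the bounds of the unconsumed prefix/suffix bases on each read
#'   (`pre_f_len`, `pre_r_len`, `suf_f_start`, `suf_r_start`).
#' @export
scan_overlap <- function(fwd, rev_oriented, anchor, p = merge_params()) {
  f <- s2c(fwd$seq); r <- s2c(rev_oriented$seq)
  nf <- length(f); nr <- length(r)
  L <- anchor$seed_length
  sf <- anchor$seed_start_fwd + 1L      # 1-based seed starts
  sr <- anchor$seed_start_rev + 1L

  # rightward from the seed's 3' side
  right <- scan_columns(f, r, sf + L, sr + L, p)
  # leftward from the seed's 5' side: run the same scanner on the
  # reversed left segments, then map the columns back
  lf <- rev(f[seq_len(sf - 1L)])
  lr <- rev(r[seq_len(sr - 1L)])
  left <- scan_columns(lf, lr, 1L, 1L, p)

  left_f <- sf - left$fwd_idx           # NA-preserving index mapping
  left_r <- sr - left$rev_idx
  ord <- rev(seq_along(left_f))
  af <- c(left_f[ord], sf:(sf + L - 1L), right$fwd_idx)
  ar <- c(left_r[ord], sr:(sr + L - 1L), right$rev_idx)

  identity <- left$identity + L + right$identity
  mism <- left$mismatch + right$mismatch
  gaps <- left$gaps + right$gaps
  k <- length(af)

  score <- structure(list(identity_count = identity, mismatch_count = mism,
                          gap_openings = gaps, overlap_columns = k,
                          identity_fraction = if (k) identity / k else 0),
                     class = "overlap_score")
  structure(list(score = score,
                 alignment = list(fwd_idx = af, rev_idx = ar),
                 pre_f_len = sf - left$next_i,
                 pre_r_len = sr - left$next_j,
                 suf_f_start = right$next_i,
                 suf_r_start = right$next_j),
            class = "overlap_scan")
}

#' Accept or reject an overlap
#'
#' @param score An `overlap_score` from [scan_overlap()].
#' @param p A [merge_params] object.
#' @return A list with `accepted` (logical) and `reason` (`NA` when
#'   accepted, else one of `short_overlap`, `low_identity`,
#'   `too_many_gaps`).
#' @export
accept_overlap <- function(score, p = merge_params()) {
  reason <- NA_character_
  if (score$overlap_columns < p$min_overlap) reason <- "short_overlap"
  else if (score$identity_fraction < p$min_identity) reason <- "low_identity"
  else if (score$gap_openings > p$max_gap_openings) reason <- "too_many_gaps"
  list(accepted = is.na(reason), reason = reason)
}

#' Build the quality-aware consensus of an accepted overlap
#'
#' The consensus is the forward read's non-overlapped 5' tail, the
#' per-column overlap consensus, and the reverse read's non-overlapped 3'
#' tail. Per overlap column: equal bases keep the base with the higher of
#' the two qualities; at a true mismatch the base with the higher quality
#' wins (ties go to the forward read); a base against a gap keeps the base
#' and its quality; a generic base `N` against a called base yields the
#' called base; two `N`s stay `N`.
#'
#' @param fwd Forward [bar_read].
#' @param rev_oriented Oriented reverse [bar_read].
#' @param scan An `overlap_scan` from [scan_overlap()].
#' @param id_suffix Suffix appended to the forward read's id.
#' @return The consensus [bar_read].
#' @export
build_consensus <- function(fwd, rev_oriented, scan, id_suffix = "") {
  f <- s2c(fwd$seq); r <- s2c(rev_oriented$seq)
  fq <- fwd$quals; rq <- rev_oriented$quals
  nf <- length(f); nr <- length(r)
  ai <- scan$alignment$fwd_idx; aj <- scan$alignment$rev_idx

  fb <- ifelse(is.na(ai), NA_character_, f[ifelse(is.na(ai), 1L, ai)])
  rb <- ifelse(is.na(aj), NA_character_, r[ifelse(is.na(aj), 1L, aj)])
  fqv <- ifelse(is.na(ai), NA_integer_, fq[ifelse(is.na(ai), 1L, ai)])
  rqv <- ifelse(is.na(aj), NA_integer_, rq[ifelse(is.na(aj), 1L, aj)])

  base <- character(length(fb)); qual <- integer(length(fb))
  gap_f <- is.na(fb); gap_r <- is.na(rb)
  both <- !gap_f & !gap_r

  base[gap_f] <- rb[gap_f]; qual[gap_f] <- rqv[gap_f]
  base[gap_r] <- fb[gap_r]; qual[gap_r] <- fqv[gap_r]

  if (any(both)) {
    fN <- both & fb == "N" & rb != "N"
    rN <- both & rb == "N" & fb != "N"
    nn <- both & fb == "N" & rb == "N"
    eq <- both & !fN & !rN & !nn & fb == rb
    mm <- both & !fN & !rN & !nn & fb != rb
    base[fN] <- rb[fN]; qual[fN] <- rqv[fN]
    base[rN] <- fb[rN]; qual[rN] <- fqv[rN]
    base[nn] <- "N";    qual[nn] <- pmax(fqv[nn], rqv[nn])
    base[eq] <- fb[eq]; qual[eq] <- pmax(fqv[eq], rqv[eq])
    fwd_wins <- mm & fqv >= rqv
    rev_wins <- mm & fqv < rqv
    base[fwd_wins] <- fb[fwd_wins]; qual[fwd_wins] <- fqv[fwd_wins]
    base[rev_wins] <- rb[rev_wins]; qual[rev_wins] <- rqv[rev_wins]
  }

  # non-overlapped 5' tail: unconsumed left bases (at most one read has any)
  if (scan$pre_f_len > 0L) {
    pre_b <- f[seq_len(scan$pre_f_len)]
    pre_q <- fq[seq_len(scan$pre_f_len)]
  } else if (scan$pre_r_len > 0L) {
    pre_b <- r[seq_len(scan$pre_r_len)]
    pre_q <- rq[seq_len(scan$pre_r_len)]
  } else {
    pre_b <- character(0); pre_q <- integer(0)
  }
  # non-overlapped 3' tail: whichever read the rightward scan left over
  if (scan$suf_r_start <= nr) {
    suf_b <- r[scan$suf_r_start:nr]
    suf_q <- rq[scan$suf_r_start:nr]
  } else if (scan$suf_f_start <= nf) {
    suf_b <- f[scan$suf_f_start:nf]
    suf_q <- fq[scan$suf_f_start:nf]
  } else {
    suf_b <- character(0); suf_q <- integer(0)
  }

  bar_read(paste0(fwd$id, id_suffix),
           paste(c(pre_b, base, suf_b), collapse = ""),
           c(pre_q, qual, suf_q))
}

#' Merge one read pair
#'
#' By default the reverse read is reverse-complemented before anchoring
#' (Illumina R2 and Sanger reverse traces are opposite-strand); if no seed
#' is found in that orientation, anchoring is retried against the
#' un-complemented reverse read. The stages are [find_anchor()],
#' [scan_overlap()], [accept_overlap()] and, on acceptance,
#' [build_consensus()].
#'
#' @param pair A [bar_read_pair].
#' @param p A [merge_params] object.
#' @param id_suffix Suffix appended to the forward id on the consensus.
#' @return A list of class `merge_outcome` with `status` (one of `merged`,
#'   `no_seed`, `short_overlap`, `low_identity`, `too_many_gaps`),
#'   `consensus` (a [bar_read], or `NULL`), `score`, `anchor`, and
#'   `orientation` (`"rc"` or `"as_is"`).
#' @examples
#' frag <- random_reference(400, seed = 1)
#' fwd <- bar_read("p", substr(frag, 1, 250), rep(40L, 250))
#' rev <- reverse_complement(
#'   bar_read("p", substr(frag, 151, 400), rep(40L, 250)))
#' out <- merge_pair(bar_read_pair(fwd, rev))
#' out$status
#' identical(out$consensus$seq, frag)
#' @export
merge_pair <- function(pair, p = merge_params(), id_suffix = "") {
  stopifnot(inherits(pair, "bar_read_pair"))
  fwd <- pair$forward
  orientations <- if (p$orient_reverse) c("rc", "as_is") else c("as_is", "rc")
  anchor <- NULL; rev_o <- NULL; used <- NA_character_
  for (o in orientations) {
    cand <- if (o == "rc") reverse_complement(pair$reverse) else pair$reverse
    a <- find_anchor(fwd, cand, p)
    if (!is.null(a)) { anchor <- a; rev_o <- cand; used <- o; break }
  }
  if (is.null(anchor))
    return(merge_outcome("no_seed", NULL, NULL, NULL, NA_character_))
  scan <- scan_overlap(fwd, rev_o, anchor, p)
  acc <- accept_overlap(scan$score, p)
  if (!acc$accepted)
    return(merge_outcome(acc$reason, NULL, scan$score, anchor, used))
  cons <- build_consensus(fwd, rev_o, scan, id_suffix)
  merge_outcome("merged", cons, scan$score, anchor, used)
}

merge_outcome <- function(status, consensus, score, anchor, orientation) {
  structure(list(status = status, consensus = consensus, score = score,
                 anchor = anchor, orientation = orientation),
            class = "merge_outcome")
}

#' @export
print.merge_outcome <- function(x, ...) {
  cat("<merge_outcome> status:", x$status, "\n")
  if (!is.null(x$score))
    cat(sprintf("  overlap %d col, identity %.1f%%, %d mismatch, %d gap opening(s)\n",
                x$score$overlap_columns, 100 * x$score$identity_fraction,
                x$score$mismatch_count, x$score$gap_openings))
  if (!is.null(x$consensus))
    cat("  consensus:", nchar(x$consensus$seq), "bp\n")
  invisible(x)
}

#' Merge a list of read pairs
#'
#' @param pairs A list of [bar_read_pair] objects.
#' @param p A [merge_params] object.
#' @param id_suffix Suffix appended to forward ids on consensus reads.
#' @return A list of class `merge_result`: `outcomes` (list of
#'   `merge_outcome`), and `report`, a per-pair `data.frame` with columns
#'   `id`, `status`, `overlap_columns`, `identity_pct`, `mismatches`,
#'   `gap_openings`, `merged_length`.
#' @export
merge_pairs <- function(pairs, p = merge_params(), id_suffix = "") {
  n <- length(pairs)
  outcomes <- vector("list", n)
  id <- character(n); status <- character(n)
  cols <- rep(NA_integer_, n); idf <- rep(NA_real_, n)
  mm <- rep(NA_integer_, n); go <- rep(NA_integer_, n)
  mlen <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    out <- merge_pair(pairs[[i]], p, id_suffix)
    outcomes[[i]] <- out
    id[i] <- pairs[[i]]$forward$id
    status[i] <- out$status
    if (!is.null(out$score)) {
      cols[i] <- out$score$overlap_columns
      idf[i] <- 100 * out$score$identity_fraction
      mm[i] <- out$score$mismatch_count
      go[i] <- out$score$gap_openings
    }
    if (!is.null(out$consensus)) mlen[i] <- nchar(out$consensus$seq)
  }
  report <- data.frame(id = id, status = status, overlap_columns = cols,
                       identity_pct = idf, mismatches = mm,
                       gap_openings = go, merged_length = mlen,
                       stringsAsFactors = FALSE)
  structure(list(outcomes = outcomes, report = report),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  tab <- table(x$report$status)
  n <- nrow(x$report)
  cat("<merge_result> ", n, " pair(s): ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "\n", sep = "")
  merged <- x$report$status == "merged"
  if (any(merged))
    cat(sprintf("  merged: %.2f%%; mean length %.2f bp; mean identity %.2f%%\n",
                100 * mean(merged), mean(x$report$merged_length[merged]),
                mean(x$report$identity_pct[merged])))
  invisible(x)
}

#' @export
summary.merge_result <- function(object, ...) {
  rep <- object$report
  merged <- rep$status == "merged"
  out <- list(
    n_pairs = nrow(rep),
    n_merged = sum(merged),
    pct_merged = 100 * mean(merged),
    mean_length = mean(rep$merged_length[merged]),
    sd_length = stats::sd(rep$merged_length[merged]),
    mean_overlap = mean(rep$overlap_columns[merged]),
    mean_identity_pct = mean(rep$identity_pct[merged]),
    mean_gap_openings = mean(rep$gap_openings[merged]),
    status_counts = table(rep$status))
  class(out) <- "summary.merge_result"
  out
}

#' @export
print.summary.merge_result <- function(x, ...) {
  cat(sprintf("pairs: %d  merged: %d (%.2f%%)\n",
              x$n_pairs, x$n_merged, x$pct_merged))
  if (x$n_merged > 0)
    cat(sprintf("merged length: %.2f +/- %.2f bp; overlap %.1f col; identity %.2f%%; gaps %.2f\n",
                x$mean_length, x$sd_length, x$mean_overlap,
                x$mean_identity_pct, x$mean_gap_openings))
  invisible(x)
}

#' Write merger outputs to files
#'
#' Merged consensuses go to FASTA (and optionally FASTQ with the consensus
#' qualities); un-merged pairs pass through unchanged as FASTQ; the
#' per-pair report is written as TSV.
#'
#' @param result A [merge_pairs()] result.
#' @param pairs The input pairs (for un-merged passthrough).
#' @param out_dir Output directory (created if needed).
#' @param fastq Also write `merged.fastq` with consensus qualities.
#' @return Named list of written paths, invisibly.
#' @export
write_merge_result <- function(result, pairs, out_dir, fastq = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  merged_reads <- Filter(Negate(is.null),
                         lapply(result$outcomes, `[[`, "consensus"))
  unmerged <- which(result$report$status != "merged")
  paths <- list(
    merged_fasta = file.path(out_dir, "merged.fasta"),
    unmerged_1 = file.path(out_dir, "unmerged_1.fastq"),
    unmerged_2 = file.path(out_dir, "unmerged_2.fastq"),
    report = file.path(out_dir, "merge_report.tsv"))
  write_fasta(merged_reads, paths$merged_fasta)
  if (fastq) {
    paths$merged_fastq <- file.path(out_dir, "merged.fastq")
    write_fastq(merged_reads, paths$merged_fastq)
  }
  write_fastq(lapply(pairs[unmerged], `[[`, "forward"), paths$unmerged_1)
  write_fastq(lapply(pairs[unmerged], `[[`, "reverse"), paths$unmerged_2)
  utils::write.table(result$report, paths$report, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
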