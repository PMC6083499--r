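#' Simulation parameters for paired-read generation
#'
#' Defaults emulate a MiSeq-like 2x250 bp run over ~400 bp fragments:
#' fragment lengths are Normal(`frag_mean`, `frag_sd`) rounded and redrawn
#' when outside `[read_length, 2*read_length - min_overlap_floor]` (so every
#' pair has a usable overlap), per-base Phred values follow a monotone
#' mean curve from `q_start` at cycle 1 to `q_end` at the last cycle with
#' Gaussian jitter, and substitutions are injected at each base with
#' probability `10^(-q/10) * sub_rate_scale`. Single-base insertions and
#' deletions occur at `indel_rate` per base.
#'
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in bp (default 250).
#' @param frag_mean,frag_sd Fragment-length distribution in bp
#'   (defaults 400 and 10).
#' @param sub_rate_scale Multiplier on the quality-implied substitution
#'   probability (0 disables substitutions).
#' @param indel_rate Per-base probability of a single-base indel.
#' @param q_start,q_end Mean Phred at the first and last cycle.
#' @param q_jitter_sd Gaussian jitter SD on the quality curve.
#' @param q_floor Minimum emitted Phred value.
#' @param min_overlap_floor Guaranteed minimum true overlap in bp.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 1000L, read_length = 250L, frag_mean = 400,
                       frag_sd = 10, sub_rate_scale = 1.0,
                       indel_rate = 1e-4, q_start = 37, q_end = 30,
                       q_jitter_sd = 3, q_floor = 2L,
                       min_overlap_floor = 25L) {
  stopifnot(n_pairs >= 1L, read_length >= 1L,
            frag_mean >= read_length, sub_rate_scale >= 0, indel_rate >= 0,
            2 * read_length - min_overlap_floor > frag_mean)
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 sub_rate_scale = sub_rate_scale, indel_rate = indel_rate,
                 q_start = q_start, q_end = q_end,
                 q_jitter_sd = q_jitter_sd, q_floor = as.integer(q_floor),
                 min_overlap_floor = as.integer(min_overlap_floor)),
            class = "sim_params")
}

#' Generate a random reference sequence
#'
#' I.i.d. bases at the requested GC content; reproducible under `seed`.
#'
#' @param length Reference length in bp.
#' @param gc GC fraction (default 0.5).
#' @param seed Optional integer seed (sets the global RNG).
#' @return A nucleotide string.
#' @export
random_reference <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

BASES <- c("A", "C", "G", "T")
# ALT[base, k] = the k-th alternative base, k in 1:3
ALT <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
             G = c("A", "C", "T"), T = c("A", "C", "G"))

# mean quality curve over `len` cycles
quality_curve <- function(len, p) {
  if (len == 1L) return(p$q_start)
  p$q_start + (p$q_end - p$q_start) * (seq_len(len) - 1) / (len - 1)
}

draw_quals <- function(len, p) {
  q <- round(quality_curve(len, p) + stats::rnorm(len, 0, p$q_jitter_sd))
  as.integer(pmax(q, p$q_floor))
}

# build one read from a template: walk the template applying indel events
# (positions are read coordinates), then inject substitutions; every
# injected error is recorded so the read can be replayed from the template.
# Returns list(seq chars, quals, events data.frame).
synth_read <- function(tmpl_chars, p) {
  L <- p$read_length
  nt <- length(tmpl_chars)
  ev_pos <- integer(0); ev_type <- character(0); ev_base <- character(0)

  # indel skeleton
  if (p$indel_rate > 0 && any(hit <- stats::runif(L) < p$indel_rate)) {
    out <- character(L)
    tpos <- 1L; k <- 1L
    while (k <= L && tpos <= nt) {
      if (hit[k]) {
        if (stats::runif(1) < 0.5) {    # insertion: emit a random base
          b <- sample(BASES, 1L)
          out[k] <- b
          ev_pos <- c(ev_pos, k); ev_type <- c(ev_type, "ins")
          ev_base <- c(ev_base, b)
          k <- k + 1L
          next
        } else {                        # deletion: skip one template base
          ev_pos <- c(ev_pos, k); ev_type <- c(ev_type, "del")
          ev_base <- c(ev_base, tmpl_chars[tpos])
          tpos <- tpos + 1L
          if (tpos > nt) break
        }
      }
      out[k] <- tmpl_chars[tpos]
      tpos <- tpos + 1L; k <- k + 1L
    }
    chars <- out[seq_len(k - 1L)]       # may be < L if template exhausted
  } else {
    chars <- tmpl_chars[seq_len(min(L, nt))]
  }

  quals <- draw_quals(length(chars), p)
  if (p$sub_rate_scale > 0) {
    perr <- 10^(-quals / 10) * p$sub_rate_scale
    sub <- which(stats::runif(length(chars)) < perr & chars != "N")
    if (length(sub)) {
      alt_k <- sample.int(3L, length(sub), replace = TRUE)
      newb <- ALT[cbind(match(chars[sub], BASES), alt_k)]
      chars[sub] <- newb
      ev_pos <- c(ev_pos, sub); ev_type <- c(ev_type, rep("sub", length(sub)))
      ev_base <- c(ev_base, newb)
    }
  }
  list(chars = chars, quals = quals,
       events = data.frame(pos = ev_pos, type = ev_type, base = ev_base,
                           stringsAsFactors = FALSE))
}

#' Replay recorded errors onto a template
#'
#' Reconstructs a simulated read from its template and the recorded error
#' events (the simulation truth). Byte-identical to the emitted read.
#'
#' @param template Template string (the fragment, oriented as read).
#' @param events A `data.frame` with columns `pos`, `type`
#'   (`sub`/`ins`/`del`), `base`.
#' @param read_length Target read length.
#' @return The reconstructed read sequence as a string.
#' @export
replay_truth <- function(template, events, read_length) {
  tmpl <- s2c(template)
  L <- as.integer(read_length)
  indels <- events[events$type != "sub", , drop = FALSE]
  out <- character(L)
  tpos <- 1L; k <- 1L
  ii <- 1L
  indels <- indels[order(indels$pos), , drop = FALSE]
  while (k <= L && tpos <= length(tmpl)) {
    if (ii <= nrow(indels) && indels$pos[ii] == k) {
      if (indels$type[ii] == "ins") {
        out[k] <- indels$base[ii]
        k <- k + 1L; ii <- ii + 1L
        next
      } else {
        tpos <- tpos + 1L; ii <- ii + 1L
        if (tpos > length(tmpl)) break
      }
    }
    out[k] <- tmpl[tpos]
    tpos <- tpos + 1L; k <- k + 1L
  }
  out <- out[seq_len(k - 1L)]
  subs <- events[events$type == "sub", , drop = FALSE]
  out[subs$pos] <- subs$base
  paste(out, collapse = "")
}

#' Simulate paired-end reads from a reference
#'
#' Draws fragments from the reference, reads `read_length` bases from each
#' end (the reverse read is emitted as the reverse-complement strand), and
#' injects quality-dependent substitutions and rate-based indels. The
#' returned truth records, for every pair, the fragment coordinates and
#' sequence, the true overlap, and each injected error, sufficient to
#' replay the reads exactly (see [replay_truth()]).
#'
#' @param ref Reference nucleotide string (longer than the largest
#'   fragment).
#' @param p A [sim_params] object.
#' @param seed Optional integer seed.
#' @return A list of class `sim_result`: `pairs` (list of
#'   [bar_read_pair]), `truth` (list with `frag_start`, `frag_len`,
#'   `fragment`, `true_overlap`, `events_fwd`, `events_rev`).
#' @export
simulate_pairs <- function(ref, p = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- toupper(ref)
  nref <- nchar(ref)
  n <- p$n_pairs
  L <- p$read_length
  lo <- L
  hi <- min(2L * L - p$min_overlap_floor, nref)
  stopifnot(hi >= lo)

  lens <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {                # rejection sampling within bounds
    draw <- as.integer(round(stats::rnorm(length(todo), p$frag_mean, p$frag_sd)))
    ok <- draw >= lo & draw <= hi
    lens[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  starts <- 1L + as.integer(floor(stats::runif(n) * (nref - lens + 1)))
  frags <- substring(ref, starts, starts + lens - 1L)
  # reverse-read templates: reverse complement of the whole fragment
  rc_frags <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(frags)))

  pairs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    fc <- s2c(frags[i])
    rc <- s2c(rc_frags[i])
    s1 <- synth_read(fc, p)
    s2 <- synth_read(rc, p)
    id <- sprintf("sim_%06d", i)
    fwd <- bar_read(id, paste(s1$chars, collapse = ""), s1$quals)
    rev <- bar_read(id, paste(s2$chars, collapse = ""), s2$quals)
    pairs[[i]] <- bar_read_pair(fwd, rev)
    truth[[i]] <- list(id = id, frag_start = starts[i], frag_len = lens[i],
                       fragment = frags[i],
                       true_overlap = 2L * L - lens[i],
                       events_fwd = s1$events, events_rev = s2$events)
  }
  structure(list(pairs = pairs, truth = truth, params = p),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  lens <- vapply(x$truth, `[[`, integer(1), "frag_len")
  nerr <- sum(vapply(x$truth, function(t)
    nrow(t$events_fwd) + nrow(t$events_rev), integer(1)))
  cat("<sim_result> ", length(x$pairs), " pair(s), fragment ",
      sprintf("%.1f +/- %.1f bp", mean(lens), stats::sd(lens)),
      ", ", nerr, " injected error(s)\n", sep = "")
  invisible(x)
}

#' Write simulated pairs and truth to files
#'
#' @param sim A [simulate_pairs()] result.
#' @param fwd_path,rev_path FASTQ output paths.
#' @param truth_path Optional TSV path for the per-pair truth summary.
#' @return Named list of paths, invisibly.
#' @export
write_sim_result <- function(sim, fwd_path, rev_path, truth_path = NULL) {
  write_fastq(lapply(sim$pairs, `[[`, "forward"), fwd_path)
  write_fastq(lapply(sim$pairs, `[[`, "reverse"), rev_path)
  if (!is.null(truth_path)) {
    df <- data.frame(
      id = vapply(sim$truth, `[[`, character(1), "id"),
      frag_start = vapply(sim$truth, `[[`, integer(1), "frag_start"),
      frag_len = vapply(sim$truth, `[[`, integer(1), "frag_len"),
      true_overlap = vapply(sim$truth, `[[`, integer(1), "true_overlap"),
      n_errors_fwd = vapply(sim$truth, function(t) nrow(t$events_fwd),
                            integer(1)),
      n_errors_rev = vapply(sim$truth, function(t) nrow(t$events_rev),
                            integer(1)),
      stringsAsFactors = FALSE)
    utils::write.table(df, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(fwd = fwd_path, rev = rev_path, truth = truth_path))
}

#' Simulate a Sanger-like forward/reverse barcode pair
#'
#' Emulates trace-derived FASTQ mates from one barcode template (400-900
#' bp): the forward read covers the 5' portion, the reverse read the
#' reverse complement of the 3' portion, with read lengths around 500-700
#' bp and a low-high-low quality ramp so that end-trimming is exercised.
#' In the `noisy` profile, substitutions follow the quality-implied rate
#' and `N` is injected at sub-threshold-quality positions with probability
#' `n_prob`; `clean` emits flat high quality with no errors; `low` emits
#' uniformly poor quality (both mates should be discarded by filtering).
#'
#' @param template Nucleotide string, 400-900 bp.
#' @param profile One of `"noisy"`, `"clean"`, `"low"`.
#' @param seed Optional integer seed.
#' @param n_prob Probability of replacing a sub-Q20 base with `N`
#'   (`noisy` profile only).
#' @return A list with `pair` (a [bar_read_pair]) and `template`.
#' @export
simulate_sanger_pair <- function(template, profile = c("noisy", "clean", "low"),
                                 seed = NULL, n_prob = 0.2) {
  profile <- match.arg(profile)
  if (!is.null(seed)) set.seed(seed)
  template <- toupper(template)
  nt <- nchar(template)
  if (nt < 400L || nt > 900L)
    warning("template length ", nt, " bp outside the 400-900 bp range ",
            "this generator emulates", call. = FALSE)

  rlen <- function() min(nt, as.integer(round(stats::runif(1, 500, 700))))
  ramp <- function(len) {
    # low-high-low: ~Q8 at the ends ramping to ~Q45 in the interior
    up <- pmin(1, (seq_len(len) - 1) / 40)
    down <- pmin(1, (len - seq_len(len)) / 60)
    8 + 37 * pmin(up, down)
  }
  one_read <- function(tmpl, id) {
    len <- rlen()
    chars <- s2c(substr(tmpl, 1L, len))
    q <- switch(profile,
      clean = rep(50L, len),
      low = as.integer(pmax(2, round(stats::rnorm(len, 5, 1)))),
      noisy = as.integer(pmax(2, round(ramp(len) +
                                         stats::rnorm(len, 0, 4)))))
    if (profile != "clean") {
      perr <- 10^(-q / 10)
      sub <- which(stats::runif(len) < perr)
      if (length(sub))
        chars[sub] <- ALT[cbind(match(chars[sub], BASES),
                                sample.int(3L, length(sub), replace = TRUE))]
      if (profile == "noisy") {
        lowq <- which(q < 20L & stats::runif(len) < n_prob)
        if (length(lowq)) chars[lowq] <- "N"
      }
    }
    bar_read(id, paste(chars, collapse = ""), pmin(q, 93L))
  }
  fwd <- one_read(template, "sanger/1")
  rev <- one_read(revcomp_str(template), "sanger/2")
  list(pair = bar_read_pair(fwd, rev), template = template)
}
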