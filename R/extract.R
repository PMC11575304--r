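ARTIFACT_LABELS <- c("ok", "quality_fail", "no_primer_found",
                     "primer_dimer_fwd", "primer_dimer_rev_tail",
                     "pair_conflict", "length_fail")

#' Quality-trim a read with the modified-Mott criterion
#'
#' Each base contributes `error_limit - 10^(-Q/10)` to a running score; the
#' contiguous window maximizing the cumulative score is kept (so bases below
#' the Q20-equivalent limit pull the window shut). Ties on the score prefer
#' the longer window, then the leftmost start. If every window scores below
#' the empty window, the read is trimmed to empty.
#'
#' @param seq DNA string.
#' @param qual Phred+33 quality string, same length as `seq`.
#' @param error_limit Error-probability limit (default 0.01, i.e. Q20).
#' @return A list with `seq` and `qual` of the retained window (both `""` if
#'   the read is trimmed away).
#' @export
#' @examples
#' quality_trim("ACGTACGTAC", phred_string(rep(30, 10)))$seq
quality_trim <- function(seq, qual, error_limit = 0.01) {
  stopifnot(nchar(seq) == nchar(qual))
  w <- mott_window(utf8ToInt(qual) - 33L, error_limit)
  if (w[1] == 0L) {
    list(seq = "", qual = "")
  } else {
    list(seq = substr(seq, w[1], w[2]), qual = substr(qual, w[1], w[2]))
  }
}

# Best-scoring contiguous window under the Mott criterion.
# Returns c(start, end), or c(0L, -1L) for the empty window.
mott_window <- function(q, error_limit = 0.01) {
  n <- length(q)
  if (n == 0) return(c(0L, -1L))
  score <- error_limit - 10^(-q / 10)
  cs <- cumsum(score)
  tol <- 1e-12
  best_sum <- 0; best_start <- 0L; best_end <- -1L; best_len <- 0L
  min_pref <- 0; min_idx <- 0L  # prefix sum before position min_idx + 1
  for (j in seq_len(n)) {
    s <- cs[j] - min_pref
    len <- j - min_idx
    if (s > best_sum + tol ||
        (abs(s - best_sum) <= tol &&
         (len > best_len || (len == best_len && min_idx + 1L < best_start)))) {
      best_sum <- s; best_start <- min_idx + 1L; best_end <- j; best_len <- len
    }
    pref <- cs[j]
    if (pref < min_pref - tol) {
      min_pref <- pref; min_idx <- j
    }
  }
  if (best_end < best_start) c(0L, -1L) else c(best_start, best_end)
}

#' Find and remove a primer prefix
#'
#' Matches `primer` against the start of `seq` allowing up to `max_mismatch`
#' substitutions (no indels) and returns the remainder, or `NA` if the prefix
#' does not match.
#'
#' @param seq DNA string.
#' @param primer Primer sequence (length >= 12 recommended).
#' @param max_mismatch Maximum substitutions tolerated (default 2).
#' @return Remainder of `seq` after the primer, or `NA_character_`.
#' @export
find_and_trim_primer <- function(seq, primer, max_mismatch = 2L) {
  lp <- nchar(primer)
  if (nchar(seq) < lp) return(NA_character_)
  if (hamming(substr(seq, 1L, lp), primer) <= max_mismatch) {
    substring(seq, lp + 1L)
  } else {
    NA_character_
  }
}

#' Reconcile the two mates of a primer-trimmed insert
#'
#' Both mates must yield the same insert length. Identical inserts pass
#' through; a single mismatch is resolved in favour of the base with the
#' higher Phred score; anything else is a pair conflict.
#'
#' @param insert1 Insert from the forward mate.
#' @param insert2_revcomp Reverse-complemented insert from the reverse mate
#'   (same orientation as `insert1`).
#' @param qual1,qual2 Quality strings aligned with `insert1` and
#'   `insert2_revcomp` respectively.
#' @return A list with `seq` (the reconciled insert or `NA`) and `conflict`.
#' @export
reconcile_pair <- function(insert1, insert2_revcomp, qual1, qual2) {
  if (nchar(insert1) != nchar(insert2_revcomp)) {
    return(list(seq = NA_character_, conflict = TRUE))
  }
  if (insert1 == insert2_revcomp) {
    return(list(seq = insert1, conflict = FALSE))
  }
  a <- utf8ToInt(insert1); b <- utf8ToInt(insert2_revcomp)
  mm <- which(a != b)
  if (length(mm) > 1L) {
    return(list(seq = NA_character_, conflict = TRUE))
  }
  q1 <- utf8ToInt(qual1)[mm]; q2 <- utf8ToInt(qual2)[mm]
  if (q2 > q1) a[mm] <- b[mm]
  list(seq = intToUtf8(a), conflict = FALSE)
}

#' Spacer length filter
#'
#' @param seq DNA string (candidate spacer).
#' @param min,max Inclusive length bounds (defaults 20 and 40 nt).
#' @return `TRUE` to keep, `FALSE` for a length failure.
#' @export
length_filter <- function(seq, min = 20L, max = 40L) {
  nchar(seq) >= min & nchar(seq) <= max
}

#' Classify a sequence as a primer-dimer artifact
#'
#' No-template controls of repeat-primer amplicon libraries are dominated by
#' primer-dimer inserts whose sequence is a fragment of the fusion primers or
#' of the Illumina overhang tails. A sequence is labelled
#' `primer_dimer_rev_tail` when its reverse complement matches a prefix
#' (>= 15 nt, <= 1 mismatch) of either tail, `primer_dimer_fwd` when it
#' matches inside a fusion primer over >= 15 nt with <= 1 mismatch, and `ok`
#' otherwise.
#'
#' @param seq DNA string (a post-trim candidate insert).
#' @param primers A [primer_set()].
#' @return One of `"primer_dimer_rev_tail"`, `"primer_dimer_fwd"`, `"ok"`.
#' @export
#' @examples
#' classify_artifact("ACATCTCCGAGCCCACGAGAC", crispr_primers("CRISPR3"))
classify_artifact <- function(seq, primers) {
  classify_artifact_vec(seq, primers)
}

classify_artifact_vec <- function(seqs, primers) {
  out <- rep("ok", length(seqs))
  if (length(seqs) == 0) return(out)
  eligible <- which(nchar(seqs) >= 15L)
  if (length(eligible) == 0) return(out)
  tails <- c(primers$fwd_tail, primers$rev_tail)
  rcs <- revcomp(seqs[eligible])
  tail_hit <- vapply(rcs, function(rc) {
    any(vapply(tails, function(tl) {
      k <- min(nchar(rc), nchar(tl))
      k >= 15L && hamming(substr(rc, 1L, k), substr(tl, 1L, k)) <= 1L
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  fwd_hit <- fusion_fragment_hit(seqs[eligible], primers)
  out[eligible[tail_hit]] <- "primer_dimer_rev_tail"
  out[eligible[!tail_hit & fwd_hit]] <- "primer_dimer_fwd"
  out
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1L), k:n)
}

# A sequence carries a fusion-primer fragment iff it contains a 15-mer of a
# fusion primer with <= 1 mismatch. Two trusted-band dictionaries (exact
# 7-nt band at the head resp. tail of each 15-mer) cover a mismatch at any
# position; the dictionaries are cached per primer set.
fusion_fragment_hit <- function(seqs, primers) {
  pd <- fusion_pdicts(primers)
  subj <- Biostrings::DNAStringSet(chartr("N", "A", seqs))
  h1 <- Biostrings::vwhichPDict(pd$head, subj, max.mismatch = 1)
  h2 <- Biostrings::vwhichPDict(pd$tail, subj, max.mismatch = 1)
  lengths(h1) > 0 | lengths(h2) > 0
}

.pdict_cache <- new.env(parent = emptyenv())

fusion_pdicts <- function(primers) {
  key <- paste(primers$fwd_fusion, primers$rev_fusion)
  cached <- .pdict_cache[[key]]
  if (!is.null(cached)) return(cached)
  kmers <- unique(unlist(lapply(c(primers$fwd_fusion, primers$rev_fusion),
                                seq_kmers, k = 15L)))
  pd <- list(
    head = Biostrings::PDict(kmers, tb.start = 1, tb.width = 7),
    tail = Biostrings::PDict(kmers, tb.end = 15, tb.width = 7)
  )
  .pdict_cache[[key]] <- pd
  pd
}

#' Extract spacer observations from paired amplicon reads
#'
#' Runs the full per-pair filter chain: Mott quality trimming of both mates,
#' locus-primer removal (forward primer on R1, reverse primer on R2),
#' read-through trimming of the opposite primer, pair reconciliation,
#' primer-dimer classification, N filtering and the 20-40 nt spacer length
#' filter. Every input pair receives exactly one artifact label and label
#' counts sum to the input pair count.
#'
#' @param r1_path,r2_path Mated FASTQ files.
#' @param primers A [primer_set()].
#' @param sample_id Sample label attached to the observations.
#' @param max_mismatch Substitutions tolerated in the locus primer (default 2).
#' @param error_limit Mott trimming limit (default 0.01).
#' @return A list with `observations` (tibble `sample_id`, `sequence`,
#'   `count`) and `report` (tibble `label`, `count`).
#' @export
extract_sample <- function(r1_path, r2_path, primers, sample_id,
                           max_mismatch = 2L, error_limit = 0.01) {
  pairs <- read_paired_fastq(r1_path, r2_path)
  pairs$n <- 1L
  extract_pairs(pairs, primers, sample_id,
                max_mismatch = max_mismatch, error_limit = error_limit)
}

#' Extract spacer observations from an in-memory pair table
#'
#' Same filter chain as [extract_sample()] but operating on a tibble of
#' (possibly run-length counted) read pairs, as produced by
#' [simulate_sample()]. Columns: `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`,
#' and optionally `n` (pair multiplicity, default 1).
#'
#' @inheritParams extract_sample
#' @param pairs Tibble of read pairs.
#' @return As [extract_sample()].
#' @export
extract_pairs <- function(pairs, primers, sample_id,
                          max_mismatch = 2L, error_limit = 0.01) {
  m <- nrow(pairs)
  n_mult <- if ("n" %in% names(pairs)) as.numeric(pairs$n) else rep(1, m)
  label <- rep(NA_character_, m)
  spacer <- rep(NA_character_, m)

  if (m > 0) {
    t1 <- mott_trim_vec(pairs$r1_seq, pairs$r1_qual, error_limit)
    t2 <- mott_trim_vec(pairs$r2_seq, pairs$r2_qual, error_limit)
    empty <- nchar(t1$seq) == 0 | nchar(t2$seq) == 0
    label[empty] <- "quality_fail"

    live <- which(is.na(label))
    p1 <- prefix_trim_vec(t1$seq[live], t1$qual[live], primers$fwd_locus, max_mismatch)
    no_fwd <- live[is.na(p1$seq)]
    label[no_fwd] <- classify_or(t1$seq[no_fwd], primers, "no_primer_found")
    live2 <- live[!is.na(p1$seq)]
    keep1 <- !is.na(p1$seq)

    p2 <- prefix_trim_vec(t2$seq[live2], t2$qual[live2], primers$rev_locus, max_mismatch)
    no_rev <- live2[is.na(p2$seq)]
    label[no_rev] <- classify_or(t2$seq[no_rev], primers, "no_primer_found")
    live3 <- live2[!is.na(p2$seq)]

    ins1 <- p1$seq[keep1][!is.na(p2$seq)]
    q1 <- p1$qual[keep1][!is.na(p2$seq)]
    ins2 <- p2$seq[!is.na(p2$seq)]
    q2 <- p2$qual[!is.na(p2$seq)]

    # trim read-through into the opposite primer (>= 12 nt anchor, <= 1 mm)
    rt1 <- readthrough_cut(ins1, substr(revcomp(primers$rev_locus), 1L, 12L))
    rt2 <- readthrough_cut(ins2, substr(revcomp(primers$fwd_locus), 1L, 12L))
    ins1 <- substr(ins1, 1L, rt1); q1 <- substr(q1, 1L, rt1)
    ins2 <- substr(ins2, 1L, rt2); q2 <- substr(q2, 1L, rt2)

    ins2rc <- revcomp(ins2)
    q2rc <- reverse_strings(q2)

    conflict <- nchar(ins1) != nchar(ins2rc)
    merged <- ifelse(conflict, NA_character_, ins1)
    fix <- which(!conflict & ins1 != ins2rc)
    for (i in fix) {
      r <- reconcile_pair(ins1[i], ins2rc[i], q1[i], q2rc[i])
      if (r$conflict) conflict[i] <- TRUE else merged[i] <- r$seq
    }
    label[live3[conflict]] <- "pair_conflict"

    live4 <- live3[!conflict]
    merged <- merged[!conflict]
    has_n <- grepl("N", merged, fixed = TRUE)
    label[live4[has_n]] <- "quality_fail"
    live5 <- live4[!has_n]
    merged <- merged[!has_n]

    art <- classify_artifact_vec(merged, primers)
    dimer <- art != "ok"
    label[live5[dimer]] <- art[dimer]
    live6 <- live5[!dimer]
    merged <- merged[!dimer]

    good_len <- length_filter(merged, primers$min_spacer_len, primers$max_spacer_len)
    label[live6[!good_len]] <- "length_fail"
    label[live6[good_len]] <- "ok"
    spacer[live6[good_len]] <- merged[good_len]
  }

  label_counts <- vapply(ARTIFACT_LABELS,
                         function(l) sum(n_mult[label == l]), numeric(1))
  report <- tibble(label = ARTIFACT_LABELS, count = unname(label_counts))
  ok <- !is.na(spacer)
  obs <- if (any(ok)) {
    agg <- rowsum(n_mult[ok], spacer[ok])
    tibble(sample_id = sample_id, sequence = rownames(agg),
           count = as.integer(agg[, 1]))
  } else {
    tibble(sample_id = character(), sequence = character(), count = integer())
  }
  list(observations = obs, report = report)
}

# --- vectorized helpers ----------------------------------------------------

mott_trim_vec <- function(seqs, quals, error_limit) {
  # fast path: reads whose worst base clears the limit keep the full read
  qmin_char <- 33L + ceiling(-10 * log10(error_limit)) # e.g. Q20 for 0.01
  full <- vapply(quals, function(q) {
    nzchar(q) && min(utf8ToInt(q)) >= qmin_char
  }, logical(1), USE.NAMES = FALSE)
  out_seq <- character(length(seqs))
  out_qual <- character(length(seqs))
  out_seq[full] <- seqs[full]
  out_qual[full] <- quals[full]
  for (i in which(!full)) {
    tr <- quality_trim(seqs[i], quals[i], error_limit)
    out_seq[i] <- tr$seq
    out_qual[i] <- tr$qual
  }
  list(seq = out_seq, qual = out_qual)
}

prefix_trim_vec <- function(seqs, quals, primer, max_mismatch) {
  lp <- nchar(primer)
  n <- length(seqs)
  seq_out <- rep(NA_character_, n)
  qual_out <- rep(NA_character_, n)
  long_enough <- nchar(seqs) >= lp
  if (any(long_enough)) {
    pref <- substr(seqs[long_enough], 1L, lp)
    pv <- utf8ToInt(primer)
    mm <- colSums(matrix(utf8ToInt(paste(pref, collapse = "")),
                         nrow = lp) != pv)
    hit <- mm <= max_mismatch
    idx <- which(long_enough)[hit]
    seq_out[idx] <- substring(seqs[idx], lp + 1L)
    qual_out[idx] <- substring(quals[idx], lp + 1L)
  }
  list(seq = seq_out, qual = qual_out)
}

# Position to cut an insert before the first approximate probe hit; returns
# the retained length for each sequence.
readthrough_cut <- function(seqs, probe) {
  keep <- nchar(seqs)
  if (length(seqs) == 0) return(keep)
  hits <- Biostrings::vmatchPattern(probe, Biostrings::DNAStringSet(seqs),
                                    max.mismatch = 1, with.indels = FALSE)
  starts <- Biostrings::startIndex(hits)
  has <- lengths(starts) > 0
  keep[has] <- vapply(starts[has], function(s) min(s) - 1L, integer(1))
  keep
}

reverse_strings <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

classify_or <- function(seqs, primers, fallback) {
  if (length(seqs) == 0) return(character())
  lab <- classify_artifact_vec(seqs, primers)
  ifelse(lab == "ok", fallback, lab)
}
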