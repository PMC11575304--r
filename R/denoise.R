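#' Dereplicate spacer observations into an ASV table
#'
#' Collapses exact-identical sequences within each sample, summing counts.
#'
#' @param observations Tibble with columns `sample_id`, `sequence`, `count`
#'   (e.g. concatenated outputs of [extract_sample()]).
#' @return An [asv_table()].
#' @export
dereplicate <- function(observations) {
  if (nrow(observations) == 0) {
    return(asv_table(tibble(sample_id = character(), sequence = character(),
                            count = integer())))
  }
  agg <- observations %>%
    group_by(.data$sample_id, .data$sequence) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  asv_table(agg)
}

#' Collapse likely sequencing-error variants into their parent ASV
#'
#' Within each sample, a sequence is merged into the most abundant sequence
#' within `max_hamming` substitutions whose count exceeds it by at least
#' `min_fold`; merging repeats until a fixed point. The abundance-ratio rule
#' is keyed to the single denoising parameter reported for the assay
#' (`min_fold_parent_over_abundance = 32`). Per-sample totals are conserved.
#'
#' @param table An [asv_table()].
#' @param min_fold Minimum parent/child abundance ratio (default 32).
#' @param max_hamming Maximum substitution distance to a parent (default 1).
#' @return An [asv_table()] with merged counts; fully merged ASVs are dropped
#'   (see [drop_empty()]).
#' @export
collapse_errors <- function(table, min_fold = 32, max_hamming = 1L) {
  if (nrow(table) == 0) return(table)
  merged <- table %>%
    group_by(.data$sample_id) %>%
    dplyr::group_modify(~ collapse_sample(.x, min_fold, max_hamming)) %>%
    ungroup()
  drop_empty(asv_table(merged))
}

collapse_sample <- function(df, min_fold, max_hamming) {
  seqs <- df$sequence
  counts <- setNames(as.numeric(df$count), seqs)
  repeat {
    ord <- names(sort_counts(counts))
    moved <- FALSE
    # children visited from least to most abundant
    for (child in rev(ord)) {
      if (counts[[child]] == 0) next
      parents <- ord[seq_len(match(child, ord) - 1L)]
      if (length(parents) == 0) next
      ok <- parents[vapply(parents, function(p) {
        counts[[p] ] / counts[[child]] >= min_fold &&
          hamming(p, child) <= max_hamming
      }, logical(1))]
      if (length(ok) > 0) {
        # most abundant qualifying parent; ties by lexicographic order via
        # the canonical sort
        p <- ok[1]
        counts[[p]] <- counts[[p]] + counts[[child]]
        counts[[child]] <- 0
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  tibble(sequence = names(counts), count = as.integer(counts))
}

# descending count, ties by sequence (lexicographic, C locale)
sort_counts <- function(counts) {
  ord <- order(-counts, names(counts), method = "radix")
  counts[ord]
}

#' Drop all-zero ASV columns
#'
#' Removes ASVs whose counts are zero in every sample; samples are retained
#' (an `asv_tbl` keeps its sample set in the `samples` attribute even when a
#' sample has no reads left).
#'
#' @param table An [asv_table()].
#' @return An [asv_table()].
#' @export
drop_empty <- function(table) {
  samples <- asv_samples(table)
  out <- asv_table(table[table$count > 0, , drop = FALSE])
  attr(out, "samples") <- samples
  out
}
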